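#' Coverage-dependent MDA amplification-bias parameters
#'
#' Multiple displacement amplification (MDA) amplifies the two alleles of a
#' diploid cell unevenly, so the observed alternative-read fraction
#' \eqn{\rho_s = k/l} is a distorted measurement of the true allele frequency
#' \eqn{\theta_s \in \{0, 1/2, 1\}}. The distortion is modelled with
#' beta-binomial read-count distributions whose shape parameters scale
#' linearly with the total site coverage \eqn{l}:
#' \eqn{\alpha(l), \beta(l)} for homozygous sites and a symmetric two-component
#' mixture with weight \eqn{w(l)} and shapes \eqn{\alpha_1(l), \alpha_2(l)}
#' for heterozygous sites.
#'
#' The slope/intercept coefficients are empirical, derived from read-count
#' distributions observed at known homozygous and heterozygous sites in MDA
#' single-cell sequencing data. The linear extrapolation leaves the legal
#' parameter range at extreme coverages (\eqn{\alpha(l)} has a negative slope
#' and \eqn{w(l)} a positive one), so shapes are floored at `1e-6` and the
#' mixture weight is clipped to `[0, 1]`.
#'
#' @param l Non-negative integer vector of total single-cell site coverage.
#'
#' @return A tibble with one row per element of `l` and columns `l`, `alpha`,
#'   `beta`, `w`, `alpha1`, `alpha2`.
#'
#' @examples
#' bias_params(c(0, 20, 100))
#' @export
bias_params <- function(l) {
  if (length(l) == 0) {
    return(tibble::tibble(
      l = integer(), alpha = double(), beta = double(), w = double(),
      alpha1 = double(), alpha2 = double()
    ))
  }
  if (any(is.na(l)) || any(l < 0) || any(l != trunc(l))) {
    stop("`l` must be a non-negative integer coverage", call. = FALSE)
  }
  eps <- 1e-6
  p <- .bias_coef
  tibble::tibble(
    l = as.integer(l),
    alpha  = pmax(p["alpha", "slope"] * l + p["alpha", "intercept"], eps),
    beta   = pmax(p["beta", "slope"] * l + p["beta", "intercept"], eps),
    w      = pmin(pmax(p["w", "slope"] * l + p["w", "intercept"], 0), 1),
    alpha1 = pmax(p["alpha1", "slope"] * l + p["alpha1", "intercept"], eps),
    alpha2 = pmax(p["alpha2", "slope"] * l + p["alpha2", "intercept"], eps)
  )
}

# Slope/intercept table of the empirical MDA bias model; one row per
# coverage-scaled parameter.
.bias_coef <- matrix(
  c(
    -0.00003, 0.06857, # alpha
    0.00745, 2.36749,  # beta
    0.00055, 0.54040,  # w
    0.05738, 0.66973,  # alpha1
    0.00323, 0.39926   # alpha2
  ),
  ncol = 2, byrow = TRUE,
  dimnames = list(c("alpha", "beta", "w", "alpha1", "alpha2"),
                  c("slope", "intercept"))
)

#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution,
#' \deqn{BB(k, l; a, b) = \binom{l}{k}
#'   \frac{B(k + a, l - k + b)}{B(a, b)},}
#' evaluated in log space with `lchoose()` and `lbeta()` so that high
#' coverages do not underflow.
#'
#' @param k Integer vector of successes, `0 <= k <= size`.
#' @param size Integer vector of trials.
#' @param alpha,beta Positive shape parameters.
#' @param log If `TRUE`, return log probabilities.
#'
#' @return Numeric vector of (log) probabilities, recycled to the common
#'   length of the inputs.
#'
#' @examples
#' dbetabinom(0:10, 10, 1, 1) # uniform on 0..10
#' @export
dbetabinom <- function(k, size, alpha, beta, log = FALSE) {
  n <- max(length(k), length(size), length(alpha), length(beta))
  k <- rep_len(k, n); size <- rep_len(size, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("beta-binomial shape parameters must be positive", call. = FALSE)
  }
  if (any(k < 0) || any(k > size)) {
    stop("`k` must satisfy 0 <= k <= size", call. = FALSE)
  }
  lp <- lchoose(size, k) + lbeta(k + alpha, size - k + beta) -
    lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' Distribution of the MDA-distorted allele frequency
#'
#' Probability \eqn{P(\rho_s = k/l \mid \theta_s)} of observing `k`
#' alternative reads among `l` at a site whose true single-cell alternative
#' allele frequency is `theta_s`, under the coverage-dependent amplification
#' bias model ([bias_params()]):
#' \itemize{
#' \item `theta_s = 0`: \eqn{BB(k, l; \alpha(l), \beta(l))} — a nonzero
#'   alternative count can arise from amplified copy errors;
#' \item `theta_s = 1/2`: the symmetric mixture
#'   \eqn{w(l)\,BB(k, l; \alpha_1(l), \alpha_1(l)) +
#'   (1 - w(l))\,BB(k, l; \alpha_2(l), \alpha_2(l))}, which peaks at the
#'   extreme counts \eqn{k = 0} and \eqn{k = l} (allele dropout);
#' \item `theta_s = 1`: the `theta_s = 0` case with shapes swapped,
#'   \eqn{BB(k, l; \beta(l), \alpha(l))}.
#' }
#'
#' @param k Integer vector of alternative-read counts.
#' @param l Integer vector of total site coverage.
#' @param theta_s True single-cell allele frequency; each element must be
#'   one of `0`, `0.5`, `1`.
#' @param log If `TRUE`, return log probabilities.
#'
#' @return Numeric vector of (log) probabilities.
#'
#' @examples
#' sum(sc_freq_likelihood(0:20, 20, 0.5)) # sums to one
#' sc_freq_likelihood(0, 20, 0.5) > sc_freq_likelihood(10, 20, 0.5)
#' @export
sc_freq_likelihood <- function(k, l, theta_s, log = FALSE) {
  n <- max(length(k), length(l), length(theta_s))
  k <- rep_len(k, n); l <- rep_len(l, n); theta_s <- rep_len(theta_s, n)
  if (!all(theta_s %in% c(0, 0.5, 1))) {
    stop("`theta_s` must be one of 0, 0.5, 1", call. = FALSE)
  }
  p <- bias_params(l)
  lp <- numeric(n)
  i0 <- theta_s == 0
  i1 <- theta_s == 1
  ih <- theta_s == 0.5
  if (any(i0)) {
    lp[i0] <- dbetabinom(k[i0], l[i0], p$alpha[i0], p$beta[i0], log = TRUE)
  }
  if (any(i1)) {
    # symmetry of the homozygous cases: swap the shape parameters
    lp[i1] <- dbetabinom(k[i1], l[i1], p$beta[i1], p$alpha[i1], log = TRUE)
  }
  if (any(ih)) {
    c1 <- base::log(p$w[ih]) +
      dbetabinom(k[ih], l[ih], p$alpha1[ih], p$alpha1[ih], log = TRUE)
    c2 <- base::log1p(-p$w[ih]) +
      dbetabinom(k[ih], l[ih], p$alpha2[ih], p$alpha2[ih], log = TRUE)
    lp[ih] <- .logaddexp(c1, c2)
  }
  if (log) lp else exp(lp)
}

# log(exp(a) + exp(b)) without overflow; handles -Inf arguments.
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log(sum(exp(x))) for a vector, -Inf-safe.
.logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + base::log(sum(exp(x - m)))
}
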