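#' Convert PHRED base qualities to error probabilities
#'
#' @param qual Numeric vector of PHRED base qualities.
#' @param cap Upper cap on the error probability (default 0.75, the value at
#'   which a base call carries no information about a 4-letter alphabet).
#' @return Numeric vector of per-base miscall probabilities
#'   `min(10^(-qual/10), cap)`.
#' @examples
#' read_error_prob(c(10, 20, 30))
#' @export
read_error_prob <- function(qual, cap = 0.75) {
  pmin(10^(-qual / 10), cap)
}

#' Per-read likelihood under a biallelic site model
#'
#' Probability of observing one read's allele class given the true
#' alternative allele frequency `rho` of its template population. A read
#' calls ALT either because it sampled an ALT template and was read
#' correctly, or because it sampled a REF template and was miscalled into the
#' ALT base (one of three possible wrong bases):
#' \deqn{P(ALT \mid \rho) = \rho (1 - e) + (1 - \rho) e/3}
#' and symmetrically for REF. Reads in class OTHER are excluded from the
#' biallelic model upstream and are rejected here.
#'
#' @param allele Character vector, `"REF"` or `"ALT"`.
#' @param error_prob Per-base miscall probability `e`.
#' @param rho True alternative allele frequency in `[0, 1]`.
#' @return Numeric vector of probabilities.
#' @examples
#' read_likelihood("ALT", 0.01, 0.5)
#' @export
read_likelihood <- function(allele, error_prob, rho) {
  if (any(!allele %in% c("REF", "ALT"))) {
    stop("`allele` must be \"REF\" or \"ALT\"; OTHER reads are excluded ",
         "from the biallelic model", call. = FALSE)
  }
  if (any(rho < 0 | rho > 1)) {
    stop("`rho` must be in [0, 1]", call. = FALSE)
  }
  len <- max(length(allele), length(error_prob), length(rho))
  allele <- rep_len(allele, len)
  error_prob <- rep_len(error_prob, len)
  rho <- rep_len(rho, len)
  p_alt <- rho * (1 - error_prob) + (1 - rho) * error_prob / 3
  p_ref <- (1 - rho) * (1 - error_prob) + rho * error_prob / 3
  ifelse(allele == "ALT", p_alt, p_ref)
}

# Normalize a reads data frame to (allele, e) and enforce read filters:
# OTHER reads dropped, base quality floor Q >= 3, error cap e <= 0.75.
.prep_reads <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0) {
    return(tibble::tibble(allele = character(), e = double()))
  }
  e <- if ("error_prob" %in% names(reads)) {
    pmin(reads$error_prob, 0.75)
  } else if ("base_qual" %in% names(reads)) {
    read_error_prob(reads$base_qual)
  } else {
    stop("reads need an `error_prob` or `base_qual` column", call. = FALSE)
  }
  keep <- reads$allele %in% c("REF", "ALT")
  if ("base_qual" %in% names(reads)) keep <- keep & reads$base_qual >= 3
  tibble::tibble(allele = reads$allele[keep], e = e[keep])
}

# log P(Z | rho) for one read set at each frequency in `rho`, computed from
# per-(allele, e) class counts so reads sharing a class cost O(1).
.reads_loglik <- function(prep, rho) {
  .reads_loglik2(prep$allele, prep$e, rho)
}

.reads_loglik2 <- function(alleles, es, rho) {
  out <- rep(0, length(rho))
  for (a in c("REF", "ALT")) {
    ei <- es[alleles == a]
    if (length(ei) == 0) next
    for (e in unique(ei)) {
      out <- out + sum(ei == e) * base::log(read_likelihood(a, e, rho))
    }
  }
  out
}

#' Single-cell read-set likelihood at a fixed distorted frequency
#'
#' \eqn{P(Z^s \mid \rho_s) = \prod_i P(Z^s_i \mid \rho_s)} over all REF/ALT
#' reads of the single-cell pileup (the empty product is 1). Computed as a
#' log-space sum.
#'
#' @param reads Data frame of single-cell reads with columns `allele`
#'   (`"REF"`/`"ALT"`; `"OTHER"` rows are dropped) and `base_qual` or
#'   `error_prob`.
#' @param rho Distorted alternative allele frequency (vectorized).
#' @param log If `TRUE`, return the log likelihood.
#' @return Numeric vector, one likelihood per element of `rho`.
#' @export
sc_sample_likelihood <- function(reads, rho, log = FALSE) {
  lp <- .reads_loglik(.prep_reads(reads), rho)
  if (log) lp else exp(lp)
}

#' Single-cell likelihood of a true allele frequency
#'
#' Marginalizes the single-cell read-set likelihood over the MDA-distorted
#' frequency grid \eqn{\rho_s \in \{0/l, \ldots, l/l\}}:
#' \deqn{P(Z^s \mid \theta_s) = \sum_{k=0}^{l}
#'   P(Z^s \mid \rho_s = k/l)\, P(\rho_s = k/l \mid \theta_s)}
#' with the distortion term from [sc_freq_likelihood()]. With zero coverage
#' the likelihood is 1 for every `theta_s`.
#'
#' @inheritParams sc_sample_likelihood
#' @param theta_s True single-cell allele frequency, one of `0`, `0.5`, `1`
#'   (vectorized).
#' @return Numeric vector, one likelihood per element of `theta_s`.
#' @export
sc_theta_likelihood <- function(reads, theta_s, log = FALSE) {
  prep <- .prep_reads(reads)
  l <- nrow(prep)
  grid <- if (l == 0) 0 else (0:l) / l
  data_lp <- .reads_loglik(prep, grid)
  lp <- vapply(theta_s, function(th) {
    .logsumexp(data_lp + sc_freq_likelihood(0:l, l, th, log = TRUE))
  }, numeric(1))
  if (log) lp else exp(lp)
}

# theta_b grid: all m/n for moderate bulk coverage; downsampled to 1001
# equally spaced frequencies for very deep bulks to keep the sums linear.
.bulk_grid <- function(n) {
  if (n == 0) 0 else if (n <= 1000) (0:n) / n else seq(0, 1, length.out = 1001)
}

#' Bulk read-set likelihood at a fixed bulk allele frequency
#'
#' The bulk sample is not amplified, so its observed frequency is the true
#' one (\eqn{\rho_b = \theta_b}) and the likelihood is the plain product of
#' per-read probabilities at \eqn{\theta_b = m/n}.
#'
#' @param reads Data frame of bulk reads (columns as in
#'   [sc_sample_likelihood()]).
#' @param m Alternative-allele count on the frequency grid (vectorized).
#' @param n Grid denominator; defaults to the number of REF/ALT reads.
#' @param log If `TRUE`, return the log likelihood.
#' @return Numeric vector, one likelihood per element of `m`.
#' @export
bulk_theta_likelihood <- function(reads, m, n = NULL, log = FALSE) {
  prep <- .prep_reads(reads)
  if (is.null(n)) n <- nrow(prep)
  if (any(m < 0 | m > n)) stop("`m` must be in 0..n", call. = FALSE)
  rho <- if (n == 0) rep(0, length(m)) else m / n
  lp <- .reads_loglik(prep, rho)
  if (log) lp else exp(lp)
}

#' Bulk likelihood summed over an allele-frequency interval
#'
#' Sums [bulk_theta_likelihood()] over all grid frequencies `m/n` that fall
#' inside a single-cell event's bulk interval, honouring the open/closed
#' endpoints of the event definition (see [event_regions()]). An interval
#' that contains no grid point has likelihood 0.
#'
#' @inheritParams bulk_theta_likelihood
#' @param interval A one-row data frame or list with fields `theta_b_lo`,
#'   `theta_b_hi`, `lo_open`, `hi_open` (as returned by [event_regions()]),
#'   or a numeric `c(lo, hi)` treated as closed.
#' @return A single (log) likelihood.
#' @export
bulk_range_likelihood <- function(reads, interval, log = FALSE) {
  prep <- .prep_reads(reads)
  n <- nrow(prep)
  grid <- .bulk_grid(n)
  keep <- .in_interval(grid, interval)
  lp <- if (!any(keep)) -Inf else {
    .logsumexp(.reads_loglik(prep, grid[keep]))
  }
  if (log) lp else exp(lp)
}

# Membership of grid frequencies in an event interval with explicit
# open/closed endpoints. Grid points are compared exactly: the endpoints
# 0, 1/2 and 1 are all exactly representable.
.in_interval <- function(x, interval) {
  if (is.numeric(interval)) {
    interval <- list(theta_b_lo = interval[1], theta_b_hi = interval[2],
                     lo_open = FALSE, hi_open = FALSE)
  }
  lo_ok <- if (isTRUE(interval$lo_open)) x > interval$theta_b_lo else
    x >= interval$theta_b_lo
  hi_ok <- if (isTRUE(interval$hi_open)) x < interval$theta_b_hi else
    x <= interval$theta_b_hi
  lo_ok & hi_ok
}
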