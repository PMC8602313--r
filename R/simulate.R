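#' Simulate single-cell MDA pileups with a matched bulk sample
#'
#' Generates per-site read pileups from the generative assumptions of the
#' calling model, together with a truth table, for calibration, recovery and
#' FDR experiments:
#' \itemize{
#' \item each site is assigned a germline genotype from
#'   `genotype_proportions`; the bulk population is homogeneous at germline
#'   sites, so its true alternative allele frequency equals the single-cell
#'   frequency \eqn{\theta_s \in \{0, 1/2, 1\}};
#' \item the single-cell alternative read count `k` is drawn directly from
#'   the coverage-dependent amplification-bias distributions
#'   ([sc_freq_likelihood()]), which compound amplification bias and
#'   amplification/sequencing error, and the pileup contains `k` ALT and
#'   `l - k` REF reads at the configured base quality;
#' \item the bulk has no amplification step: the number of alternative
#'   templates is Binomial(`n`, \eqn{\theta_b}) and each read is then
#'   miscalled with probability \eqn{e = 10^{-Q/10}}, uniformly into the
#'   three other bases (so 1/3 of miscalls reach the other modelled allele
#'   and 2/3 fall into class OTHER).
#' }
#'
#' Optionally, a number of designated somatic sites carries a subclonal
#' heterozygous genotype: the cell is heterozygous there while only
#' `subclone_fraction` of the bulk population is, giving a bulk frequency of
#' `subclone_fraction / 2`.
#'
#' @param n_sites Number of candidate sites to simulate.
#' @param genotype_proportions Length-3 simplex of germline genotype weights
#'   (hom_ref, het, hom_alt).
#' @param sc_coverage,bulk_coverage Single-cell and bulk coverage: the fixed
#'   per-site value (`coverage_model = "fixed"`) or the Poisson mean.
#' @param coverage_model `"fixed"` or `"poisson"`.
#' @param base_quality PHRED base quality assigned to all simulated reads.
#' @param n_somatic_sites Number of sites (taken from the end) simulated as
#'   subclonal somatic het sites.
#' @param subclone_fraction Fraction of bulk cells carrying the somatic het
#'   genotype at somatic sites.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'   `NULL` uses (and advances) the current RNG state.
#' @return A list of class `sim_dataset` with elements `pileups` (a long
#'   read-level tibble suitable for [call_sites()]) and `truth` (one row per
#'   site: `genotype`, `theta_s`, `theta_b`, realized `l`, `k`, `n`,
#'   `m_true`, somatic flag, and the `dropout` indicator — a het site whose
#'   amplified counts lost one allele, `k %in% c(0, l)` with `l >= 1`).
#' @examples
#' sim <- simulate_dataset(n_sites = 20, seed = 42)
#' sim$truth
#' @export
simulate_dataset <- function(n_sites = 1000,
                             genotype_proportions = c(hom_ref = 0.9,
                                                      het = 0.05,
                                                      hom_alt = 0.05),
                             sc_coverage = 20,
                             bulk_coverage = 30,
                             coverage_model = c("fixed", "poisson"),
                             base_quality = 30,
                             n_somatic_sites = 0,
                             subclone_fraction = 0.2,
                             seed = NULL) {
  coverage_model <- match.arg(coverage_model)
  if (length(genotype_proportions) != 3 || any(genotype_proportions < 0) ||
      abs(sum(genotype_proportions) - 1) > 1e-8) {
    stop("`genotype_proportions` must be 3 non-negative weights summing to 1",
         call. = FALSE)
  }
  if (n_somatic_sites > n_sites) {
    stop("`n_somatic_sites` cannot exceed `n_sites`", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  gts <- c("hom_ref", "het", "hom_alt")
  genotype <- sample(gts, n_sites, replace = TRUE,
                     prob = genotype_proportions)
  somatic <- seq_len(n_sites) > n_sites - n_somatic_sites
  genotype[somatic] <- "het"
  theta_s <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[genotype]
  theta_b <- unname(theta_s)
  theta_b[somatic] <- subclone_fraction / 2

  l <- switch(coverage_model,
              fixed = rep.int(as.integer(sc_coverage), n_sites),
              poisson = stats::rpois(n_sites, sc_coverage))
  n <- switch(coverage_model,
              fixed = rep.int(as.integer(bulk_coverage), n_sites),
              poisson = stats::rpois(n_sites, bulk_coverage))

  # single-cell ALT counts from the amplification-bias distributions,
  # drawn per (coverage, theta_s) group from the exact pmf
  k <- integer(n_sites)
  grp <- paste(l, theta_s)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    li <- l[idx[1]]
    if (li == 0) next
    pmf <- sc_freq_likelihood(0:li, li, theta_s[idx[1]])
    k[idx] <- sample.int(li + 1, length(idx), replace = TRUE,
                         prob = pmf) - 1L
  }

  m_true <- stats::rbinom(n_sites, n, theta_b)

  e <- read_error_prob(base_quality)
  pos <- seq_len(n_sites)
  site <- tibble::tibble(chrom = "sim1", pos = pos, ref = "A", alt = "C")

  cell_reads <- tibble::tibble(
    pos = rep.int(pos, l),
    sample = "cell",
    allele = unlist(lapply(seq_len(n_sites), function(i) {
      rep(c("ALT", "REF"), c(k[i], l[i] - k[i]))
    }), use.names = FALSE)
  )
  bulk_template <- tibble::tibble(
    pos = rep.int(pos, n),
    sample = "bulk",
    allele = unlist(lapply(seq_len(n_sites), function(i) {
      rep(c("ALT", "REF"), c(m_true[i], n[i] - m_true[i]))
    }), use.names = FALSE)
  )
  # per-read sequencing miscalls in the bulk: uniform over the 3 other bases
  nb <- nrow(bulk_template)
  flip <- stats::runif(nb) < e
  to_other <- flip & stats::runif(nb) < 2 / 3
  to_swap <- flip & !to_other
  allele <- bulk_template$allele
  allele[to_swap] <- ifelse(allele[to_swap] == "ALT", "REF", "ALT")
  allele[to_other] <- "OTHER"
  bulk_template$allele <- allele

  pileups <- dplyr::bind_rows(cell_reads, bulk_template)
  pileups <- dplyr::left_join(site, pileups, by = "pos")
  pileups <- pileups[!is.na(pileups$sample), ]
  pileups$base_qual <- base_quality
  pileups <- tibble::as_tibble(pileups)

  truth <- dplyr::bind_cols(site, tibble::tibble(
    genotype = genotype,
    theta_s = unname(theta_s),
    theta_b = theta_b,
    l = l, k = k, n = n, m_true = m_true,
    somatic = somatic,
    dropout = genotype == "het" & l >= 1 & (k == 0L | k == l)
  ))
  structure(list(pileups = pileups, truth = truth), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated single-cell/bulk dataset:", nrow(x$truth), "sites,",
      nrow(x$pileups), "reads\n")
  print(utils::head(x$truth))
  invisible(x)
}

#' Draw allele counts from a Polya-urn amplification process
#'
#' Mechanistic counterpart of the beta-binomial amplification-bias model:
#' an urn holds `alpha` alternative and `beta` reference units; each draw
#' returns the drawn unit plus one copy (a polymerase strand copy), and the
#' count of alternative draws among `size` is returned. Marginally the
#' counts follow \eqn{BB(size; \alpha, \beta)}, which is exercised as a
#' mechanism cross-check in the test suite.
#'
#' @param n_draws Number of replicate counts to draw.
#' @param size Number of urn draws (reads) per replicate.
#' @param alpha,beta Initial urn weights (positive; need not be integer).
#' @return Integer vector of alternative counts, length `n_draws`.
#' @examples
#' table(rpolya_urn(100, 4, 1, 1))
#' @export
rpolya_urn <- function(n_draws, size, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("urn weights must be positive",
                                    call. = FALSE)
  vapply(seq_len(n_draws), function(i) {
    a <- alpha; b <- beta; k <- 0L
    for (t in seq_len(size)) {
      if (stats::runif(1) < a / (a + b)) {
        k <- k + 1L; a <- a + 1
      } else {
        b <- b + 1
      }
    }
    k
  }, integer(1))
}
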