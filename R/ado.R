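#' Allele-dropout-rate estimators over ground-truth heterozygous sites
#'
#' Allele dropout (ADO) — the complete loss of one allele during MDA — is
#' only identifiable unambiguously at sites known to be heterozygous, so all
#' three estimators operate on a supplied set of truth-het sites with
#' single-cell coverage of at least one read:
#' \describe{
#' \item{expected}{[expected_ado_rate()] — mean over sites of the total
#'   dropout posterior \eqn{P(E_{ado\,to\,ref}) + P(E_{ado\,to\,alt})}, the
#'   model's expected value of allele dropout.}
#' \item{mismatch}{[mismatch_ado_rate()] — the fraction of covered truth-het
#'   sites whose maximum-posterior genotype call is homozygous (false
#'   homozygous calls at het sites are counted as dropouts).}
#' \item{naive}{[naive_ado_rate()] — the fraction of covered truth-het sites
#'   with single-cell coverage of at least seven reads and one allele
#'   entirely unobserved; the coverage floor makes it reasonably certain
#'   both alleles would be sampled without amplification bias. This
#'   estimator undercounts when coverage is low.}
#' }
#'
#' @param calls A tibble of calls from [call_sites()] restricted (or
#'   restrictable via `truth_het`) to ground-truth heterozygous sites.
#' @param truth_het Optional data frame of truth-het sites with columns
#'   `chrom` and `pos` (and optionally `ref`, `alt`) used to subset `calls`.
#' @return `ado_report()` returns a one-row tibble with the three rates and
#'   the shared denominator `n_sites_covered`; the individual estimators
#'   return a single rate (`NA` when no site qualifies).
#' @examples
#' sim <- simulate_dataset(n_sites = 50, seed = 1)
#' calls <- call_sites(sim$pileups)
#' het <- sim$truth[sim$truth$genotype == "het", ]
#' ado_report(calls, truth_het = het)
#' @name ado_rates
NULL

.restrict_truth_het <- function(calls, truth_het) {
  if (is.null(truth_het)) return(calls)
  keys <- c("chrom", "pos", intersect(c("ref", "alt"), names(truth_het)))
  dplyr::semi_join(calls, truth_het, by = keys)
}

.covered <- function(calls) calls[!is.na(calls$l) & calls$l >= 1, ]

#' @rdname ado_rates
#' @export
expected_ado_rate <- function(calls, truth_het = NULL) {
  x <- .covered(.restrict_truth_het(calls, truth_het))
  if (nrow(x) == 0) return(NA_real_)
  mean(compound_posterior(x, c("ado_to_ref", "ado_to_alt")))
}

#' @rdname ado_rates
#' @export
mismatch_ado_rate <- function(calls, truth_het = NULL) {
  x <- .covered(.restrict_truth_het(calls, truth_het))
  if (nrow(x) == 0) return(NA_real_)
  mean(x$genotype %in% c("hom_ref", "hom_alt"))
}

#' @rdname ado_rates
#' @export
naive_ado_rate <- function(calls, truth_het = NULL) {
  x <- .covered(.restrict_truth_het(calls, truth_het))
  if (nrow(x) == 0) return(NA_real_)
  mean(x$l >= 7 & (x$k == 0 | x$k == x$l))
}

#' @rdname ado_rates
#' @export
ado_report <- function(calls, truth_het = NULL) {
  x <- .covered(.restrict_truth_het(calls, truth_het))
  tibble::tibble(
    expected_rate = expected_ado_rate(x),
    mismatch_rate = mismatch_ado_rate(x),
    naive_rate = naive_ado_rate(x),
    n_sites_covered = nrow(x)
  )
}
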