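#' The seven mutually exclusive single-cell events
#'
#' The joint space of true allele frequencies — \eqn{\theta_s \in \{0, 1/2,
#' 1\}} in the single cell and \eqn{\theta_b \in [0, 1]} in the bulk — is
#' partitioned into seven mutually exclusive events. The bulk population is
#' assumed to mix at most two genotype subpopulations that are one mutated
#' allele apart, so an intermediate \eqn{\theta_b} implies which genotypes
#' can exist in the population; where the bulk contradicts the single-cell
#' frequency (e.g. \eqn{\theta_s = 0} but \eqn{\theta_b \ge 1/2}), the bulk
#' is trusted and the event is interpreted as allele dropout or an amplified
#' copy error in the cell.
#'
#' The events (and the single-cell genotype each implies) are:
#' \describe{
#' \item{hom_ref}{\eqn{\{0\} \times [0, 1/2)} — true homozygous reference.}
#' \item{err_alt}{\eqn{\{1/2, 1\} \times \{0\}} — amplified copy error
#'   showing an alternative allele absent from the population (genotype
#'   hom_ref).}
#' \item{ado_to_alt}{\eqn{\{1\} \times (0, 1/2]} — dropout of the reference
#'   allele in a heterozygous cell (genotype het).}
#' \item{het}{\eqn{\{1/2\} \times (0, 1)} — true heterozygous.}
#' \item{ado_to_ref}{\eqn{\{0\} \times [1/2, 1)} — dropout of the
#'   alternative allele in a heterozygous cell (genotype het).}
#' \item{err_ref}{\eqn{\{0, 1/2\} \times \{1\}} — copy error showing a
#'   reference allele in a homozygous-alternative population (genotype
#'   hom_alt).}
#' \item{hom_alt}{\eqn{\{1\} \times (1/2, 1]} — true homozygous
#'   alternative.}
#' }
#'
#' Interval endpoints are applied strictly to the bulk frequency grid
#' \eqn{m/n}: for every fixed \eqn{\theta_s} the bulk intervals of the
#' events containing it partition \eqn{[0, 1]}, so each grid point belongs
#' to exactly one event.
#'
#' @return A tibble with columns `event`, `theta_s` (list column of
#'   single-cell frequencies), `theta_b_lo`, `theta_b_hi`, `lo_open`,
#'   `hi_open`, `genotype`.
#' @examples
#' event_regions()
#' @export
event_regions <- function() {
  tibble::tibble(
    event = c("hom_ref", "err_alt", "ado_to_alt", "het", "ado_to_ref",
              "err_ref", "hom_alt"),
    theta_s = list(0, c(0.5, 1), 1, 0.5, 0, c(0, 0.5), 1),
    theta_b_lo = c(0, 0, 0, 0, 0.5, 1, 0.5),
    theta_b_hi = c(0.5, 0, 0.5, 1, 1, 1, 1),
    lo_open = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    hi_open = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    genotype = c("hom_ref", "hom_ref", "het", "het", "het", "hom_alt",
                 "hom_alt")
  )
}

.event_names <- c("hom_ref", "err_alt", "ado_to_alt", "het", "ado_to_ref",
                  "err_ref", "hom_alt")

# Genotype-implying compound events.
.genotype_compounds <- list(
  hom_ref = c("hom_ref", "err_alt"),
  het = c("het", "ado_to_ref", "ado_to_alt"),
  hom_alt = c("hom_alt", "err_ref")
)

# Alt-presence compound: every event whose region implies the alternative
# allele exists in cell or bulk.
.alt_presence_events <- c("ado_to_ref", "err_ref", "het", "ado_to_alt",
                          "hom_alt")

# cache of log P(rho_s = k/l | theta_s) grids, keyed by coverage l
.sc_pmf_cache <- new.env(parent = emptyenv())

.sc_freq_logpmf <- function(l) {
  key <- as.character(l)
  hit <- .sc_pmf_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- 0:l
  out <- cbind(
    `0` = sc_freq_likelihood(grid, l, 0, log = TRUE),
    `0.5` = sc_freq_likelihood(grid, l, 0.5, log = TRUE),
    `1` = sc_freq_likelihood(grid, l, 1, log = TRUE)
  )
  if (l <= 2000) .sc_pmf_cache[[key]] <- out
  out
}

#' Likelihood of one single-cell event
#'
#' \eqn{P(Z^s, Z^b \mid E) = \left[\sum_{\theta_s \in E}
#' P(Z^s \mid \theta_s)\right] \times \sum_{m/n \in E} P(Z^b \mid \theta_b =
#' m/n)} under a flat prior over the \eqn{(\theta_s, m/n)} cells of the
#' region. With `impute = TRUE` and zero single-cell coverage every
#' single-cell factor is 1, so the event likelihood reduces to the size of
#' the \eqn{\theta_s} set times the bulk factor.
#'
#' @param cell_reads,bulk_reads Data frames of reads (columns `allele` and
#'   `base_qual` or `error_prob`).
#' @param event Event name (see [event_regions()]) or a one-row region.
#' @param impute Allow zero single-cell coverage (bulk-driven imputation).
#' @param log If `TRUE`, return the log likelihood.
#' @return A single (log) likelihood.
#' @export
event_likelihood <- function(cell_reads, bulk_reads, event, impute = FALSE,
                             log = FALSE) {
  regions <- event_regions()
  if (is.character(event)) {
    if (!event %in% regions$event) {
      stop("unknown event name: ", event, call. = FALSE)
    }
    region <- regions[regions$event == event, ]
  } else {
    region <- event
  }
  cell <- .prep_reads(cell_reads)
  if (nrow(cell) == 0 && !impute) {
    stop("zero single-cell coverage; use `impute = TRUE` or skip the site",
         call. = FALSE)
  }
  sc_lp <- .sc_theta_logliks(cell$allele, cell$e)
  th_idx <- match(as.character(unlist(region$theta_s)), names(sc_lp))
  sc_term <- .logsumexp(sc_lp[th_idx])
  bl_term <- bulk_range_likelihood(bulk_reads, region, log = TRUE)
  lp <- sc_term + bl_term
  if (log) lp else exp(lp)
}

# named length-3 vector of log P(Z^s | theta_s) for theta_s in {0, 0.5, 1}
.sc_theta_logliks <- function(alleles, es) {
  l <- length(alleles)
  out <- c(`0` = 0, `0.5` = 0, `1` = 0)
  if (l == 0) return(out)
  data_lp <- .reads_loglik2(alleles, es, (0:l) / l)
  pmf <- .sc_freq_logpmf(l)
  for (j in 1:3) out[j] <- .logsumexp(data_lp + pmf[, j])
  out
}

# theta_s member indices (into {0, 0.5, 1}) and bulk grid membership per
# event, cached by bulk coverage n.
.event_theta_idx <- list(1L, c(2L, 3L), 3L, 2L, 1L, c(1L, 2L), 3L)

.bulk_member_cache <- new.env(parent = emptyenv())

.bulk_members <- function(n) {
  key <- as.character(n)
  hit <- .bulk_member_cache[[key]]
  if (!is.null(hit)) return(hit)
  regions <- event_regions()
  grid <- .bulk_grid(n)
  out <- lapply(1:7, function(i) which(.in_interval(grid, regions[i, ])))
  if (n <= 2000) .bulk_member_cache[[key]] <- out
  out
}

# Seven event log-likelihoods for one site, from plain read vectors.
# flat_bulk replaces every bulk factor with 1 (cell-only degenerate mode).
.site_event_logliks <- function(cell_alleles, cell_e, bulk_alleles, bulk_e,
                                flat_bulk = FALSE) {
  sc_lp <- .sc_theta_logliks(cell_alleles, cell_e)
  n <- length(bulk_alleles)
  if (!flat_bulk) {
    grid <- .bulk_grid(n)
    blp <- .reads_loglik2(bulk_alleles, bulk_e, grid)
    members <- .bulk_members(n)
  }
  out <- numeric(7)
  for (i in 1:7) {
    sc_term <- .logsumexp(sc_lp[.event_theta_idx[[i]]])
    bl_term <- if (flat_bulk) 0 else {
      idx <- members[[i]]
      if (length(idx) == 0) -Inf else .logsumexp(blp[idx])
    }
    out[i] <- sc_term + bl_term
  }
  names(out) <- .event_names
  out
}

#' Posterior probabilities of the seven single-cell events
#'
#' For every candidate site in a pileup, computes the posterior probability
#' of each single-cell event under a flat prior over the joint allele
#' frequency space:
#' \deqn{P(E \mid Z^s, Z^b) = \frac{P(Z^s, Z^b \mid E)}
#'   {\sum_{E' } P(Z^s, Z^b \mid E')}.}
#' All sums run in log space with log-sum-exp.
#'
#' Sites whose bulk coverage is below `min_bulk_cov` (or zero) are
#' uncallable and get `NA` posteriors, as do sites below `min_sc_cov`
#' single-cell coverage unless `impute = TRUE`, in which case zero-coverage
#' sites are imputed from the bulk alone (all single-cell likelihoods 1) and
#' flagged in the `imputed` column.
#'
#' @param pileup Data frame of reads with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample` (`"cell"` or `"bulk"`), `allele` (`"REF"`, `"ALT"`,
#'   `"OTHER"`), and `base_qual` (or `error_prob`). One row per read.
#' @param impute Impute zero-coverage single-cell sites from the bulk.
#' @param min_sc_cov Minimum single-cell coverage to call a site (default 1).
#' @param min_bulk_cov Minimum bulk coverage to call a site (default 1).
#' @param missing_bulk `"missing"` (default) marks zero-bulk sites
#'   uncallable; `"flat"` evaluates them with a flat bulk factor per event,
#'   i.e. cell-only calling in which the event partition carries no genotype
#'   information (all three genotype posteriors become 1/3).
#' @return A tibble with one row per site: the site key, read-count summary
#'   columns `l`, `k` (single cell), `n`, `m_obs` (bulk), one posterior
#'   column per event (`p_hom_ref`, `p_err_alt`, `p_ado_to_alt`, `p_het`,
#'   `p_ado_to_ref`, `p_err_ref`, `p_hom_alt`) and the `imputed` flag.
#' @examples
#' sim <- simulate_dataset(n_sites = 5, seed = 1)
#' site_posteriors(sim$pileups)
#' @export
site_posteriors <- function(pileup, impute = FALSE, min_sc_cov = 1,
                            min_bulk_cov = 1,
                            missing_bulk = c("missing", "flat")) {
  missing_bulk <- match.arg(missing_bulk)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample", "allele")
                %in% names(pileup)))
  pe <- if ("error_prob" %in% names(pileup)) {
    pmin(pileup$error_prob, 0.75)
  } else {
    read_error_prob(pileup$base_qual)
  }
  keep <- pileup$allele %in% c("REF", "ALT")
  if ("base_qual" %in% names(pileup)) keep <- keep & pileup$base_qual >= 3
  key <- paste(pileup$chrom, pileup$pos, pileup$ref, pileup$alt, sep = "\r")
  sites <- dplyr::distinct(pileup, .data$chrom, .data$pos, .data$ref,
                           .data$alt)
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = "\r")
  # per-site read class summaries (allele, e, count) for both samples
  reads <- tibble::tibble(key = key[keep],
                          sample = pileup$sample[keep],
                          allele = pileup$allele[keep],
                          e = pe[keep])
  split_idx <- split(seq_len(nrow(reads)), factor(reads$key, levels = skey))
  ns <- nrow(sites)
  probs <- matrix(NA_real_, ns, 7,
                  dimnames = list(NULL, paste0("p_", .event_names)))
  l <- k <- n <- m_obs <- integer(ns)
  imputed <- rep(NA, ns)
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(ns)) {
    idx <- split_idx[[i]]
    is_cell <- reads$sample[idx] == "cell"
    ca <- reads$allele[idx][is_cell]; ce <- reads$e[idx][is_cell]
    ba <- reads$allele[idx][!is_cell]; be <- reads$e[idx][!is_cell]
    l[i] <- length(ca); k[i] <- sum(ca == "ALT")
    n[i] <- length(ba); m_obs[i] <- sum(ba == "ALT")
    flat <- FALSE
    if (n[i] == 0 || n[i] < min_bulk_cov) {
      if (missing_bulk == "flat" && n[i] == 0) flat <- TRUE else next
    }
    if (l[i] < min_sc_cov && !(impute && l[i] == 0)) next
    # posteriors depend only on the count summary when base qualities are
    # homogeneous per sample; memoize those signatures
    uce <- unique(ce); ube <- unique(be)
    sig <- if (length(uce) <= 1 && length(ube) <= 1) {
      paste(l[i], k[i], n[i], m_obs[i],
            if (length(uce)) uce else "", if (length(ube)) ube else "",
            flat)
    }
    pr <- if (!is.null(sig)) memo[[sig]]
    if (is.null(pr)) {
      ll <- .site_event_logliks(ca, ce, ba, be, flat_bulk = flat)
      marg <- .logsumexp(ll)
      pr <- if (is.infinite(marg)) NULL else exp(ll - marg)
      if (is.null(pr)) next
      if (!is.null(sig)) memo[[sig]] <- pr
    }
    probs[i, ] <- pr
    imputed[i] <- impute && l[i] == 0
  }
  dplyr::bind_cols(
    sites,
    tibble::tibble(l = l, k = k, n = n, m_obs = m_obs),
    tibble::as_tibble(probs),
    tibble::tibble(imputed = imputed)
  )
}

#' Posterior probability of a compound event
#'
#' Compound events are unions of the seven mutually exclusive single-cell
#' events; their posterior is the sum of the member posteriors. The
#' alt-presence compound (`ado_to_ref`, `err_ref`, `het`, `ado_to_alt`,
#' `hom_alt`) collects every event implying that the alternative allele is
#' present in the cell.
#'
#' @param posteriors A tibble from [site_posteriors()] (posterior columns
#'   `p_<event>`).
#' @param events Character vector of event names forming the compound.
#' @return Numeric vector of compound posteriors, one per row.
#' @examples
#' sim <- simulate_dataset(n_sites = 5, seed = 1)
#' ep <- site_posteriors(sim$pileups)
#' compound_posterior(ep, c("het", "hom_alt"))
#' @export
compound_posterior <- function(posteriors, events) {
  bad <- setdiff(events, .event_names)
  if (length(bad) > 0) {
    stop("unknown event name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(events) == 0) return(rep(0, nrow(posteriors)))
  cols <- paste0("p_", unique(events))
  rowSums(as.matrix(posteriors[, cols, drop = FALSE]))
}

#' Genotype calls from event posteriors
#'
#' Each event implies a single-cell genotype: `hom_ref` and `err_alt` imply
#' homozygous reference (the alternative allele seen in the cell is an
#' amplified copy error absent from the bulk); `het`, `ado_to_ref` and
#' `ado_to_alt` imply heterozygous (a dropout event means the cell truly
#' carries the dropped allele); `hom_alt` and `err_ref` imply homozygous
#' alternative. The call is the genotype compound with the maximum
#' posterior; exact ties resolve in the fixed order hom_ref, het, hom_alt.
#'
#' @param posteriors A tibble from [site_posteriors()].
#' @return The input with columns appended: `p_gt_hom_ref`, `p_gt_het`,
#'   `p_gt_hom_alt` (genotype compound posteriors), `genotype` (the call),
#'   `genotype_posterior`, and `p_alt_presence`.
#' @examples
#' sim <- simulate_dataset(n_sites = 5, seed = 1)
#' genotype_call(site_posteriors(sim$pileups))
#' @export
genotype_call <- function(posteriors) {
  gt <- vapply(.genotype_compounds, function(ev) {
    compound_posterior(posteriors, ev)
  }, numeric(nrow(posteriors)))
  gt <- matrix(gt, nrow = nrow(posteriors),
               dimnames = list(NULL, names(.genotype_compounds)))
  callable <- !is.na(gt[, 1])
  pick <- rep(NA_integer_, nrow(gt))
  if (any(callable)) {
    pick[callable] <- max.col(gt[callable, , drop = FALSE],
                              ties.method = "first")
  }
  dplyr::bind_cols(
    posteriors,
    tibble::tibble(
      p_gt_hom_ref = unname(gt[, "hom_ref"]),
      p_gt_het = unname(gt[, "het"]),
      p_gt_hom_alt = unname(gt[, "hom_alt"]),
      genotype = colnames(gt)[pick],
      genotype_posterior = unname(gt[cbind(seq_len(nrow(gt)), pick)]),
      p_alt_presence = unname(
        compound_posterior(posteriors, .alt_presence_events))
    )
  )
}

#' Call single-cell events and genotypes for a pileup
#'
#' The main entry point: computes the seven-event posteriors per site
#' ([site_posteriors()]) and appends genotype calls and the alt-presence
#' compound posterior ([genotype_call()]).
#'
#' @inheritParams site_posteriors
#' @return A tibble of per-site calls; see [site_posteriors()] and
#'   [genotype_call()] for the columns.
#' @examples
#' sim <- simulate_dataset(n_sites = 10, seed = 1)
#' calls <- call_sites(sim$pileups)
#' @export
call_sites <- function(pileup, impute = FALSE, min_sc_cov = 1,
                       min_bulk_cov = 1,
                       missing_bulk = c("missing", "flat")) {
  genotype_call(site_posteriors(pileup, impute = impute,
                                min_sc_cov = min_sc_cov,
                                min_bulk_cov = min_bulk_cov,
                                missing_bulk = missing_bulk))
}
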