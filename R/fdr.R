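#' Bayesian expected-FDR control over posterior probabilities
#'
#' Selects calls for a compound event so that the expected Bayesian false
#' discovery rate — the mean of \eqn{1 - p_i} over the selected set — does
#' not exceed a nominal level. Sites are sorted by descending posterior and
#' the longest prefix satisfying the constraint is selected; because the
#' prefix means of \eqn{1 - p_i} are non-decreasing in this order, the
#' prefix rule yields the maximal selection. Sites tied at the threshold
#' posterior are included only if the constraint still holds with all of
#' them, so a posterior value always maps to a single decision.
#'
#' @param calls A data frame of calls with one posterior probability per
#'   row, e.g. from [call_sites()] or [read_calls()].
#' @param events Character vector of event names whose compound posterior is
#'   controlled (default: the alt-presence compound). Ignored if `posterior`
#'   names an existing column.
#' @param fdr Nominal expected FDR in `[0, 1]`.
#' @param posterior Optional name of a column already holding the posterior
#'   to control on.
#' @return An object of class `fdr_selection`: a list with `calls` (the
#'   input with logical column `selected` and the controlled `posterior`),
#'   `alpha`, `threshold` (minimal selected posterior; slightly above 1 when
#'   nothing is selected), `achieved_efdr`, and `n_selected`. Use [tidy()]
#'   for the selected calls and [glance()] for the summary.
#' @examples
#' calls <- tibble::tibble(id = 1:3, p = c(0.99, 0.98, 0.50))
#' sel <- control_fdr(calls, fdr = 0.02, posterior = "p")
#' glance(sel)
#' @export
control_fdr <- function(calls, events = c("ado_to_ref", "err_ref", "het",
                                          "ado_to_alt", "hom_alt"),
                        fdr = 0.05, posterior = NULL) {
  if (fdr < 0 || fdr > 1) stop("`fdr` must be in [0, 1]", call. = FALSE)
  p <- if (!is.null(posterior)) {
    calls[[posterior]]
  } else {
    compound_posterior(calls, events)
  }
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE)) {
    stop("posteriors must be probabilities in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  usable <- which(!is.na(p))
  ord <- usable[order(p[usable], decreasing = TRUE)]
  ps <- p[ord]
  n_sel <- 0L
  if (length(ps) > 0) {
    efdr <- cumsum(1 - ps) / seq_along(ps)
    j <- if (any(efdr <= fdr)) max(which(efdr <= fdr)) else 0L
    if (j > 0 && j < length(ps) && ps[j + 1] == ps[j]) {
      # the cut falls inside a group tied at the threshold posterior; the
      # prefix means are non-decreasing, so the full group must violate the
      # constraint — drop the whole group (all-or-none)
      j <- sum(ps > ps[j])
    }
    n_sel <- j
  }
  selected <- rep(FALSE, length(p))
  if (n_sel > 0) selected[ord[seq_len(n_sel)]] <- TRUE
  out <- dplyr::bind_cols(calls,
                          tibble::tibble(posterior = p, selected = selected))
  structure(
    list(
      calls = out,
      alpha = fdr,
      events = if (is.null(posterior)) events else NULL,
      threshold = if (n_sel > 0) ps[n_sel] else 1 + 1e-9,
      achieved_efdr = if (n_sel > 0) mean(1 - ps[seq_len(n_sel)]) else 0,
      n_selected = n_sel
    ),
    class = "fdr_selection"
  )
}

#' @export
print.fdr_selection <- function(x, ...) {
  cat("Bayesian FDR selection\n")
  cat("  nominal expected FDR: ", format(x$alpha), "\n", sep = "")
  if (!is.null(x$events)) {
    cat("  compound event: ", paste(x$events, collapse = " + "), "\n",
        sep = "")
  }
  cat("  selected: ", x$n_selected, " of ", nrow(x$calls), " sites\n",
      sep = "")
  cat("  posterior threshold: ", format(x$threshold), "\n", sep = "")
  cat("  achieved expected FDR: ", format(x$achieved_efdr), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FDR selection
#'
#' @param x An `fdr_selection` from [control_fdr()].
#' @param all If `TRUE` return all calls with the `selected` flag; default
#'   returns only the selected calls.
#' @param ... Unused.
#' @return A tibble of calls.
#' @export
tidy.fdr_selection <- function(x, all = FALSE, ...) {
  out <- tibble::as_tibble(x$calls)
  if (all) out else out[out$selected, , drop = FALSE]
}

#' One-row summary of an FDR selection
#'
#' @param x An `fdr_selection` from [control_fdr()].
#' @param ... Unused.
#' @return A one-row tibble with `alpha`, `n_selected`, `threshold`,
#'   `achieved_efdr`.
#' @export
glance.fdr_selection <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_selected = x$n_selected,
                 threshold = x$threshold, achieved_efdr = x$achieved_efdr)
}
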