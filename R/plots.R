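#' Plot the amplification-bias read-count distributions
#'
#' Shows \eqn{P(\rho_s = k/l \mid \theta_s)} for the three true single-cell
#' allele frequencies at a given coverage. At heterozygous sites the
#' beta-binomial mixture peaks at the extreme counts `k = 0` and `k = l`,
#' visualizing how likely allele dropout is.
#'
#' @param l Site coverage to display.
#' @return A ggplot object.
#' @examples
#' plot_bias_model(20)
#' @export
plot_bias_model <- function(l = 20) {
  df <- tidyr::expand_grid(k = 0:l, theta_s = c(0, 0.5, 1))
  df$prob <- sc_freq_likelihood(df$k, l, df$theta_s)
  df$theta_s <- factor(df$theta_s,
                       labels = c("theta_s = 0 (hom ref)",
                                  "theta_s = 1/2 (het)",
                                  "theta_s = 1 (hom alt)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$prob)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$theta_s), scales = "free_y") +
    ggplot2::labs(
      x = "alternative read count k",
      y = "P(k / l | theta_s)",
      title = sprintf("MDA amplification-bias model at coverage l = %d", l)
    )
}

#' Plot per-site event posteriors
#'
#' Stacked posterior probabilities of the seven single-cell events across
#' sites, ordered as given.
#'
#' @param calls A tibble from [site_posteriors()] or [call_sites()].
#' @param max_sites Cap on the number of sites drawn.
#' @return A ggplot object.
#' @export
plot_event_posteriors <- function(calls, max_sites = 100) {
  calls <- calls[!is.na(calls$p_hom_ref), , drop = FALSE]
  calls <- utils::head(calls, max_sites)
  calls$site <- factor(paste0(calls$chrom, ":", calls$pos),
                       levels = unique(paste0(calls$chrom, ":", calls$pos)))
  long <- tidyr::pivot_longer(
    calls[, c("site", paste0("p_", .event_names))],
    cols = -"site", names_to = "event", values_to = "posterior",
    names_prefix = "p_"
  )
  long$event <- factor(long$event, levels = .event_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$posterior,
                                     fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "posterior probability")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FDR selection
#'
#' Expected Bayesian FDR of the posterior-sorted prefix against its size,
#' with the nominal level and the selected prefix marked.
#'
#' @param object An `fdr_selection` from [control_fdr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_selection <- function(object, ...) {
  p <- sort(object$calls$posterior[!is.na(object$calls$posterior)],
            decreasing = TRUE)
  df <- tibble::tibble(rank = seq_along(p),
                       efdr = cumsum(1 - p) / seq_along(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$efdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_selected,
                        linetype = "dotted") +
    ggplot2::labs(x = "calls selected (sorted by posterior)",
                  y = "expected FDR of the prefix")
}
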