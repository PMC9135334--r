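#' Plot a pPSE profile along the sequence
#'
#' Raw neighbour counts per residue, with the smoothed profile overlaid
#' when present.
#'
#' @param profile A `ppse_profile` tibble (optionally smoothed).
#' @return A ggplot object.
#' @export
plot_ppse <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$ppse)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::labs(x = "Residue position", y = "pPSE (neighbour count)") +
    ggplot2::theme_minimal()
  if ("ppse_smooth" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$ppse_smooth),
                                color = "#2166ac", linewidth = 0.9)
  }
  if (length(unique(profile$protein_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~protein_id, scales = "free_x")
  }
  p
}

#' @method autoplot ppse_profile
#' @export
autoplot.ppse_profile <- function(object, ...) plot_ppse(object)

#' Odds-ratio forest plot of enrichment results
#'
#' @param object A `structptm_enrichment` tibble.
#' @param alpha Significance level on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot structptm_enrichment
#' @export
autoplot.structptm_enrichment <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$label <- if ("protein_id" %in% names(d)) d$protein_id else d$ptm_type
  d$significant <- !is.na(d$adj_p_value) & d$adj_p_value <= alpha
  d <- d[is.finite(d$odds_ratio) & d$odds_ratio > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$odds_ratio), y = .data$label,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey55")) +
    ggplot2::labs(x = "log2 odds ratio", y = NULL, color = paste0("adj p <= ", alpha)) +
    ggplot2::theme_minimal()
}

#' Binned 3D co-modification profile plot
#'
#' Observed modified fraction per distance bin (bars) against the
#' randomized background mean with one-standard-deviation error bars;
#' significant bins are highlighted.
#'
#' @param object A `structptm_proximity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot structptm_proximity
#' @export
autoplot.structptm_proximity <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$bin <- factor(sprintf("(%g,%g]", d$bin_lo, d$bin_hi),
                  levels = sprintf("(%g,%g]", d$bin_lo, d$bin_hi))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction_observed,
                                   fill = .data$significant)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_random), color = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_random - .data$sd_random,
                                        ymax = .data$mean_random + .data$sd_random),
                           width = 0.25, color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#f4a582")) +
    ggplot2::labs(x = "PAE-aware 3D distance bin (Å)",
                  y = "Fraction of modified acceptors",
                  fill = "|z| ≥ 1.96") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a log-odds PSSM
#'
#' @param pssm A [build_pssm()] matrix.
#' @return A ggplot object.
#' @export
plot_pssm <- function(pssm) {
  d <- tibble::as_tibble(as.table(unclass(pssm)), .name_repair = "minimal")
  names(d) <- c("aa", "offset", "score")
  d$offset <- factor(d$offset, levels = colnames(pssm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$aa,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "Offset from acceptor", y = NULL, fill = "bits") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
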