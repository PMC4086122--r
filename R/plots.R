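#' Plot a score or normalized profile along the genome
#'
#' Draws per-window values against genomic position, one panel per
#' chromosome. For normalized profiles the y axis is flipped so that better
#' (lower) values plot higher, matching how binding evidence is read.
#'
#' @param profile A score profile (`score` column) or normalized profile
#'   (`norm` column) tibble.
#' @param windows The window tibble the profile is aligned to.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, windows) {
  value_col <- if ("norm" %in% names(profile)) "norm" else "score"
  df <- profile |>
    left_join(windows[, c("index", "chrom", "start", "end")], by = "index") |>
    mutate(midpoint = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data[[value_col]])) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = if (value_col == "norm") "normalized score (0 = best)" else "raw score (bits)",
                  title = profile$feature_id[1]) +
    ggplot2::theme_minimal()
  if (value_col == "norm") p <- p + ggplot2::scale_y_reverse()
  p
}

#' Plot enrichment results
#'
#' Bar chart of -log10 p per feature, strongest enrichment first, faceted by
#' user set when several were tested.
#'
#' @param object A `met_enrichment` tibble.
#' @param top_n Show at most this many features per user set (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.met_enrichment <- function(object, top_n = 20, ...) {
  df <- as_tibble(object) |>
    group_by(.data$user_set) |>
    arrange(.data$p_value, .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    ungroup() |>
    mutate(neg_log10_p = -log10(.data$p_value),
           feature_id = stats::reorder(.data$feature_id, .data$neg_log10_p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_log10_p, y = .data$feature_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$user_set), scales = "free_y") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL) +
    ggplot2::theme_minimal()
}
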