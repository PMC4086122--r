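#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' One row per (user set x feature) with the contingency counts and p-value;
#' the overlap gene list is collapsed to a comma-separated string. Adds a
#' Benjamini-Hochberg adjusted p column (`p_adjusted`) for convenience — the
#' canonical ranking of the method uses raw p-values.
#'
#' @param x A `met_enrichment` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.met_enrichment <- function(x, ...) {
  as_tibble(x) |>
    mutate(
      overlap_genes = vapply(.data$overlap_genes, paste, character(1), collapse = ","),
      p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$feature_id)
}

#' One-row summary of an enrichment result
#'
#' @param x A `met_enrichment` tibble.
#' @param max_p Significance threshold for the significant-test count
#'   (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: number of tests, significant count and
#'   fraction, best feature and its p-value.
#' @export
glance.met_enrichment <- function(x, max_p = 0.05, ...) {
  df <- as_tibble(x) |> arrange(.data$p_value, .data$feature_id)
  tibble(
    n_tests = nrow(df),
    n_significant = sum(df$p_value <= max_p),
    frac_significant = mean(df$p_value <= max_p),
    best_feature = df$feature_id[1],
    best_p = df$p_value[1],
    fingerprint = df$fingerprint[1])
}
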