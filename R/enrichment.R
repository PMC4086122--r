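#' One-sided Fisher's exact test for target-set overlap
#'
#' Tests whether a feature's target gene set overlaps a user gene set more
#' than expected from random draws out of the gene universe. The p-value is
#' the upper hypergeometric tail: with universe size N, target size K',
#' user-set size n and overlap a, `p = P(X >= a)` for
#' X ~ Hypergeometric(N, K', n) — enrichment only, depletion is not tested.
#' User genes absent from the universe are dropped with a warning; the
#' target set is intersected with the universe as well.
#'
#' @param target A target-set tibble from [build_target_set()] (or a
#'   character vector of gene ids).
#' @param user_set Character vector of user gene ids.
#' @param universe Character vector of universe gene ids.
#' @param feature_id Label for the result row.
#' @return A one-row tibble: `feature_id`, `universe_size`, `target_size`,
#'   `user_size`, `overlap`, `p_value`, `overlap_genes` (list column,
#'   lexicographic).
#' @export
fisher_enrichment <- function(target, user_set, universe, feature_id = NULL) {
  if (length(universe) == 0) abort("empty gene universe")
  universe <- unique(universe)
  target_ids <- if (is.data.frame(target)) target$gene_id else target
  if (is.null(feature_id)) {
    feature_id <- if (is.data.frame(target) && "feature_id" %in% names(target)) {
      target$feature_id[1]
    } else "feature"
  }
  dropped <- setdiff(user_set, universe)
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " user gene(s) absent from the universe dropped"))
  }
  user <- unique(intersect(user_set, universe))
  if (length(user) == 0) abort("user set is empty after intersecting with the universe")
  targ <- unique(intersect(target_ids, universe))
  ov <- sort(intersect(targ, user))
  N <- length(universe)
  Kp <- length(targ)
  n <- length(user)
  a <- length(ov)
  p <- phyper(a - 1, Kp, N - Kp, n, lower.tail = FALSE)
  tibble(feature_id = feature_id, universe_size = N, target_size = Kp,
         user_size = n, overlap = a, p_value = p, overlap_genes = list(ov))
}

#' Filter and rank enrichment results for display
#'
#' Keeps rows with `p_value <= max_p`, sorted ascending by p (ties by
#' feature id). The unfiltered table should still be written to the
#' all-results file (see [write_reports()]).
#'
#' @param results An enrichment result tibble.
#' @param max_p Display threshold in (0, 1] (default 0.05).
#' @return The filtered, ranked tibble.
#' @export
rank_and_threshold <- function(results, max_p = 0.05) {
  if (max_p <= 0 || max_p > 1) abort("max_p must be in (0, 1]")
  results |>
    filter(.data$p_value <= max_p) |>
    arrange(.data$p_value, .data$feature_id)
}
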