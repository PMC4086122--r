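#' Rank-normalize a score profile
#'
#' Converts raw per-window scores into values in (0, 1] where 0 is best: the
#' window ranked r-th best (higher raw score = better) among the N scorable
#' windows gets r / N, so a window in the top 1% genome-wide gets 0.01. Ties
#' receive the mean of their tied ranks divided by N, which preserves the
#' rank sum. Unscorable windows get exactly 1.
#'
#' @param profile A score profile tibble (`feature_id`, `index`, `score`,
#'   `scorable`).
#' @return A normalized profile tibble: `feature_id`, `index`, `norm`,
#'   `scorable`, with attribute `normalization = "standard"`.
#' @export
rank_normalize <- function(profile) {
  if (nrow(profile) == 0) abort("empty profile")
  scorable <- profile$scorable
  if (!any(scorable)) abort("all windows are unscorable; nothing to rank")
  norm <- rep(1, nrow(profile))
  s <- profile$score[scorable]
  norm[scorable] <- rank(-s, ties.method = "average") / length(s)
  out <- tibble(feature_id = profile$feature_id, index = profile$index,
                norm = norm, scorable = scorable)
  attr(out, "normalization") <- "standard"
  out
}

# contiguous balanced partition: n items into n_bins bins, sizes differ <= 1,
# larger bins first
balanced_bins <- function(n, n_bins) {
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  rep(seq_len(n_bins), times = sizes)
}

#' G/C-binned rank normalization
#'
#' Removes compositional bias: a G/C-rich motif scores well in G/C-rich
#' windows for composition alone, so windows are first split into `n_bins`
#' equal-population bins by their G/C fraction and rank normalization is
#' applied independently within each bin. Bin sizes differ by at most one
#' window (larger bins take the lower G/C values). Unscorable windows get 1
#' and are excluded from binning. With `n_bins = 1` the result is identical
#' to [rank_normalize()].
#'
#' @param profile A score profile tibble.
#' @param windows A window tibble carrying a `gc` column (see
#'   [compute_gc()]); rows aligned with `profile` by `index`.
#' @param n_bins Number of G/C bins (default 20).
#' @return A normalized profile tibble with attribute
#'   `normalization = "gc"`.
#' @export
gc_rank_normalize <- function(profile, windows, n_bins = 20L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) abort("n_bins must be >= 1")
  if (!"gc" %in% names(windows)) abort("windows must carry a 'gc' column; run compute_gc() first")
  gc <- windows$gc[match(profile$index, windows$index)]
  if (anyNA(gc)) abort("profile window indices missing from the window table")
  scorable <- profile$scorable
  n_sc <- sum(scorable)
  if (n_sc < n_bins) {
    abort(paste0("only ", n_sc, " scorable windows for ", n_bins,
                 " G/C bins; use fewer bins"))
  }
  norm <- rep(1, nrow(profile))
  sc_idx <- which(scorable)
  # sort scorable windows by gc (ties broken by window index: deterministic)
  ord <- sc_idx[order(gc[sc_idx], profile$index[sc_idx])]
  bin_of <- balanced_bins(length(ord), n_bins)
  for (b in seq_len(n_bins)) {
    members <- ord[bin_of == b]
    s <- profile$score[members]
    norm[members] <- rank(-s, ties.method = "average") / length(s)
  }
  out <- tibble(feature_id = profile$feature_id, index = profile$index,
                norm = norm, scorable = scorable)
  attr(out, "normalization") <- "gc"
  out
}

#' Phylogenetic weights from a species tree
#'
#' Default weighting for multi-species score averaging: each species' weight
#' is proportional to its root-to-leaf path length along branch lengths,
#' normalized to sum to 1. A degenerate tree with all-zero path lengths
#' falls back to equal weights.
#'
#' @param tree An `ape::phylo` tree, or a path to a Newick file.
#' @return Named numeric vector of weights over the tree's tip labels,
#'   summing to 1.
#' @export
phylo_weights <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree$edge.length) || length(tree$tip.label) == 1) {
    w <- rep(1, length(tree$tip.label))
  } else {
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    w <- if (sum(depths) > 0) depths else rep(1, length(tree$tip.label))
  }
  setNames(w / sum(w), tree$tip.label)
}

#' Combine multi-species score profiles by phylogenetic averaging
#'
#' Averages per-window scores across species with weights derived from a
#' species tree (or supplied explicitly), so windows whose motif presence is
#' conserved across the clade score higher than reference-only signal. The
#' orthology mapping is the caller's responsibility: every species profile
#' must already be aligned to the reference window set, with `NA` where a
#' species has no orthologous window; such species are dropped for that
#' window and the remaining weights renormalized. The averaged profile is a
#' raw profile and is then rank-normalized like any other.
#'
#' @param profiles A long tibble with columns `species`, `index`, `score`
#'   (NA = no ortholog), covering the reference window indices.
#' @param tree An `ape::phylo` or Newick path; every species in `profiles`
#'   must be a tip. Ignored when `weights` is given.
#' @param weights Optional named weight vector overriding the tree-derived
#'   scheme.
#' @param feature_id Label for the output profile.
#' @return A score profile tibble over the reference windows.
#' @export
phylo_average <- function(profiles, tree = NULL, weights = NULL,
                          feature_id = "phylo_avg") {
  species <- unique(profiles$species)
  if (is.null(weights)) {
    if (is.null(tree)) abort("either a tree or explicit weights is required")
    weights <- phylo_weights(tree)
  } else {
    weights <- weights / sum(weights)
  }
  missing_sp <- setdiff(species, names(weights))
  if (length(missing_sp) > 0) {
    abort(paste0("species absent from the tree/weights: ",
                 paste(missing_sp, collapse = ", ")))
  }
  out <- profiles |>
    mutate(w = unname(weights[.data$species])) |>
    filter(!is.na(.data$score)) |>
    group_by(.data$index) |>
    summarise(score = sum(.data$w * .data$score) / sum(.data$w), .groups = "drop")
  all_idx <- sort(unique(profiles$index))
  score <- rep(NA_real_, length(all_idx))
  score[match(out$index, all_idx)] <- out$score
  scorable <- !is.na(score)
  score[!scorable] <- 0
  tibble(feature_id = feature_id, index = all_idx, score = score,
         scorable = scorable)
}

#' Mask a normalized profile by chromatin accessibility
#'
#' Retains only the most accessible windows as candidate binding locations:
#' the accessibility threshold is the value at the
#' `ceiling(retain_fraction * N)`-th highest rank, windows at or above it
#' keep their normalized score, and every other window is set to exactly 1
#' (no binding). Ties at the threshold are all retained, so the retained
#' count can exceed the nominal fraction.
#'
#' @param norm A normalized profile tibble (from [rank_normalize()] or
#'   [gc_rank_normalize()]).
#' @param access A score profile of raw accessibility values aligned to the
#'   same windows (see [signal_to_windows()]).
#' @param retain_fraction Fraction of windows to retain (default 0.10).
#' @return The masked normalized profile, attribute
#'   `normalization = "filtered"`.
#' @export
accessibility_filter <- function(norm, access, retain_fraction = 0.10) {
  if (retain_fraction <= 0 || retain_fraction > 1) {
    abort("retain_fraction must be in (0, 1]")
  }
  a <- access$score[match(norm$index, access$index)]
  if (anyNA(a)) abort("accessibility profile does not cover all windows")
  n <- length(a)
  if (length(unique(a)) == 1) {
    warn("all accessibility values are equal; filter retains every window")
  }
  k <- ceiling(retain_fraction * n)
  threshold <- sort(a, decreasing = TRUE)[k]
  out <- norm
  out$norm[a < threshold] <- 1
  attr(out, "normalization") <- "filtered"
  out
}
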