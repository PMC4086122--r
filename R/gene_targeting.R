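#' Define regulatory regions for genes
#'
#' Three region types are supported:
#' \describe{
#'   \item{`fixed`}{A strand-aware span of `upstream` bp before and
#'     `downstream` bp after the TSS (e.g. 5 kb upstream / 2 kb downstream);
#'     for `-` genes upstream extends toward higher coordinates. Clamped to
#'     the chromosome.}
#'   \item{`nearest_tss`}{The 1-D Voronoi partition of each chromosome by
#'     TSS position: every base closer to this gene's TSS than to any other
#'     (ties to the lower-coordinate TSS).}
#'   \item{`territory`}{The gene body extended halfway across the gap to the
#'     nearest non-overlapping neighbor on each side (left extension takes
#'     the floor of the half-gap, right the ceiling, so adjacent territories
#'     tile exactly); with no neighbor the territory runs to the chromosome
#'     end. Overlapping neighbors are skipped.}
#' }
#' Regions may overlap between genes in `fixed` mode; `nearest_tss` regions
#' partition the chromosome.
#'
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @param mode `"fixed"`, `"nearest_tss"` or `"territory"`.
#' @param lengths Named chromosome lengths (or a `met_genome`) for clamping.
#' @param upstream,downstream Fixed-mode span in bp around the TSS.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `mode`,
#'   `regionless` (TRUE when the clamped region is empty).
#' @export
define_regions <- function(genes, mode = c("fixed", "nearest_tss", "territory"),
                           lengths, upstream = 5000L, downstream = 2000L) {
  mode <- match.arg(mode)
  if (inherits(lengths, "met_genome")) lengths <- chrom_lengths(lengths)
  missing_chr <- setdiff(unique(genes$chrom), names(lengths))
  if (length(missing_chr) > 0) {
    abort(paste0("gene(s) on chromosome(s) without a length: ",
                 paste(missing_chr, collapse = ", ")))
  }
  regions <- switch(mode,
    fixed = regions_fixed(genes, upstream, downstream),
    nearest_tss = regions_nearest_tss(genes, lengths),
    territory = regions_territory(genes, lengths)
  )
  regions$start <- pmax(regions$start, 0L)
  regions$end <- pmin(regions$end, unname(lengths[regions$chrom]))
  regions$regionless <- regions$start >= regions$end
  regions$mode <- mode
  regions[, c("gene_id", "chrom", "start", "end", "mode", "regionless")]
}

regions_fixed <- function(genes, upstream, downstream) {
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  if (upstream < 0 || downstream < 0) abort("upstream/downstream must be >= 0")
  if (upstream == 0 && downstream == 0) {
    abort("fixed regions require upstream > 0 or downstream > 0")
  }
  plus <- genes$strand == "+"
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)),
    end = as.integer(ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L))
  )
}

regions_nearest_tss <- function(genes, lengths) {
  # per-chromosome cuts: gene i owns positions <= midpoint(tss_i, tss_{i+1});
  # an exact-midpoint tie goes to the lower-coordinate TSS
  res <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$tss, g$gene_id), ]
    n <- nrow(g)
    cuts <- if (n > 1) as.integer(floor((g$tss[-n] + g$tss[-1]) / 2)) + 1L else integer(0)
    chrom_end <- unname(as.integer(lengths[chrom]))
    res[[chrom]] <- tibble(
      gene_id = g$gene_id, chrom = chrom,
      start = c(0L, cuts),
      end = c(cuts, chrom_end)
    )
  }
  bind_rows(res)
}

regions_territory <- function(genes, lengths) {
  res <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$start, g$gene_id), ]
    n <- nrow(g)
    start <- integer(n)
    end <- integer(n)
    L <- as.integer(lengths[chrom])
    for (i in seq_len(n)) {
      # nearest non-overlapping neighbors (skip overlapping genes)
      left <- g[g$end <= g$start[i], ]
      right <- g[g$start >= g$end[i], ]
      if (nrow(left) > 0) {
        gap <- g$start[i] - max(left$end)
        start[i] <- g$start[i] - as.integer(floor(gap / 2))
      } else {
        start[i] <- 0L
      }
      if (nrow(right) > 0) {
        gap <- min(right$start) - g$end[i]
        end[i] <- g$end[i] + as.integer(ceiling(gap / 2))
      } else {
        end[i] <- L
      }
    }
    res[[chrom]] <- tibble(gene_id = g$gene_id, chrom = chrom,
                           start = start, end = end)
  }
  bind_rows(res)
}

#' Assign windows to gene regions
#'
#' A window belongs to a region iff its midpoint lies inside one of the
#' region's intervals; with the 2x-overlapping default tiling this gives each
#' window a single location, so region window counts are not inflated by
#' window overlap. Under `fixed` regions a window can belong to several
#' genes; under `nearest_tss` the assignment is a partition.
#'
#' @param regions A region tibble from [define_regions()].
#' @param windows A window tibble from [tile_windows()].
#' @return A tibble `gene_id`, `index` (one row per gene-window membership).
#' @export
assign_windows <- function(regions, windows) {
  mid <- (windows$start + windows$end) / 2
  res <- list()
  for (chrom in unique(regions$chrom)) {
    r <- regions[regions$chrom == chrom & !regions$regionless, ]
    if (nrow(r) == 0) next
    wsel <- which(windows$chrom == chrom)
    if (length(wsel) == 0) next
    m <- mid[wsel]
    for (i in seq_len(nrow(r))) {
      hit <- wsel[m >= r$start[i] & m < r$end[i]]
      if (length(hit) > 0) {
        res[[length(res) + 1L]] <- tibble(gene_id = r$gene_id[i],
                                          index = windows$index[hit])
      }
    }
  }
  if (length(res) == 0) return(tibble(gene_id = character(0), index = integer(0)))
  bind_rows(res)
}

#' Per-gene regulatory scores
#'
#' For each gene, `P_g` is the best (minimum) normalized window score in its
#' region, `w_g` the number of windows in the region, and the combined score
#' is `S_g = 1 - (1 - P_g)^w_g` — the probability that the minimum of `w_g`
#' uniform draws beats `P_g`, so a good `P_g` found among many windows is
#' discounted. Masked windows carry value 1, so they count toward `w_g` but
#' can never supply `P_g`. Genes with no windows get `S_g = 1`.
#'
#' @param norm A normalized profile tibble.
#' @param assignment A gene-window assignment from [assign_windows()].
#' @param gene_ids Genes to report; defaults to those present in
#'   `assignment` (pass the full annotation's ids to include window-less
#'   genes).
#' @param count_masked Should windows carrying normalized value 1 (masked
#'   or worst-ranked) count toward `w_g`? Default `TRUE`: `w_g` describes
#'   the searched extent of the region. `FALSE` gives the alternative
#'   reading in which only windows still in play are counted.
#' @return A tibble `gene_id`, `P_g`, `w_g`, `S_g` (lower `S_g` = stronger
#'   evidence).
#' @export
score_genes <- function(norm, assignment, gene_ids = NULL, count_masked = TRUE) {
  val <- norm$norm[match(assignment$index, norm$index)]
  if (anyNA(val)) abort("assignment references windows absent from the profile")
  if (!count_masked) {
    keep <- val < 1
    assignment <- assignment[keep, , drop = FALSE]
    val <- val[keep]
  }
  per_gene <- tibble(gene_id = assignment$gene_id, val = val) |>
    group_by(.data$gene_id) |>
    summarise(P_g = min(.data$val), w_g = n(), .groups = "drop")
  if (!is.null(gene_ids)) {
    missing_g <- setdiff(gene_ids, per_gene$gene_id)
    if (length(missing_g) > 0) {
      per_gene <- bind_rows(per_gene,
        tibble(gene_id = missing_g, P_g = NA_real_, w_g = 0L))
    }
    per_gene <- per_gene[per_gene$gene_id %in% gene_ids, ]
  }
  per_gene |>
    mutate(S_g = ifelse(.data$w_g >= 1, 1 - (1 - .data$P_g)^.data$w_g, 1)) |>
    arrange(.data$gene_id)
}

#' Build a top-K target gene set
#'
#' Restricts gene scores to the universe, orders ascending by `S_g` (ties by
#' gene id) and keeps the best `K` genes: the putative regulatory targets of
#' the feature.
#'
#' @param scores A gene score tibble from [score_genes()].
#' @param universe Character vector of universe gene ids.
#' @param K Maximum target-set size (default 500).
#' @return A tibble `gene_id`, `S_g`, `rank`, at most `K` rows.
#' @export
build_target_set <- function(scores, universe, K = 500L) {
  K <- as.integer(K)
  if (K < 1) abort("K must be >= 1")
  if (length(universe) == 0) abort("empty gene universe")
  out <- scores |>
    filter(.data$gene_id %in% universe) |>
    arrange(.data$S_g, .data$gene_id) |>
    head(K) |>
    mutate(rank = row_number()) |>
    select("gene_id", "S_g", "rank")
  out
}
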