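#' Bundle pipeline inputs
#'
#' Collects the per-species inputs one analysis needs so configurations can
#' be run against them repeatedly with shared caching.
#'
#' @param genome A `met_genome`.
#' @param genes Gene annotation tibble.
#' @param motifs A `met_motifs` collection (named list of count matrices),
#'   or `NULL` for ChIP-only runs.
#' @param chip Optional named list of ChIP signal tibbles (bedGraph-style),
#'   each becoming one cis-regulatory feature.
#' @param access Optional accessibility signal tibble (DNase/ATAC), used when
#'   a configuration enables the accessibility filter.
#' @param ortho_scores Optional named list (by motif id) of long tibbles
#'   `species`, `index`, `score`: per-species window scores aligned to the
#'   reference windows, used when a configuration enables conservation.
#' @param tree Optional `ape::phylo` or Newick path for conservation weights.
#' @return A `met_data` list.
#' @export
met_data <- function(genome, genes, motifs = NULL, chip = NULL, access = NULL,
                     ortho_scores = NULL, tree = NULL) {
  structure(list(genome = genome, genes = genes, motifs = motifs, chip = chip,
                 access = access, ortho_scores = ortho_scores, tree = tree),
            class = "met_data")
}

#' Describe one analysis configuration
#'
#' A configuration fixes every knob that defines a target-gene-set
#' definition: normalization method, regulatory-region type, accessibility
#' filter, conservation, and the target-set size.
#'
#' @param region Region preset string (`"up1k"`, `"up10k"`, `"up5k-down2k"`,
#'   `"nearest-tss"`, `"territory"`, or `"upNk-downMk"` generally).
#' @param normalization `"standard"` or `"gc"`.
#' @param accessibility Apply the accessibility filter? (needs
#'   `met_data$access`).
#' @param conservation Combine multi-species scores before normalization?
#'   (needs `met_data$ortho_scores` and `tree`).
#' @param K Target-set size (default 500).
#' @param max_p Display p-value threshold (default 0.05).
#' @param n_bins G/C bins for `normalization = "gc"` (default 20).
#' @param retain_fraction Accessibility retain fraction (default 0.10).
#' @param window_length,shift Window tiling in bp (defaults 500 / 250).
#' @param bg_order Background Markov order (default 2).
#' @return A `met_config` list with a stable `fingerprint`.
#' @export
met_config <- function(region = "up5k-down2k",
                       normalization = c("standard", "gc"),
                       accessibility = FALSE, conservation = FALSE,
                       K = 500L, max_p = 0.05, n_bins = 20L,
                       retain_fraction = 0.10, window_length = 500L,
                       shift = 250L, bg_order = 2L) {
  normalization <- match.arg(normalization)
  cfg <- list(
    region = parse_region(region),
    region_label = region,
    normalization = normalization,
    accessibility = isTRUE(accessibility),
    conservation = isTRUE(conservation),
    K = as.integer(K), max_p = as.numeric(max_p), n_bins = as.integer(n_bins),
    retain_fraction = as.numeric(retain_fraction),
    window_length = as.integer(window_length), shift = as.integer(shift),
    bg_order = as.integer(bg_order)
  )
  cfg$fingerprint <- config_fingerprint(cfg)
  structure(cfg, class = "met_config")
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  if (region %in% c("nearest-tss", "nearest_tss")) {
    return(list(mode = "nearest_tss", upstream = 0L, downstream = 0L))
  }
  if (region == "territory") {
    return(list(mode = "territory", upstream = 0L, downstream = 0L))
  }
  m <- stringr::str_match(region, "^up([0-9.]+)k(?:-down([0-9.]+)k)?$")
  if (is.na(m[1, 1])) {
    abort(paste0("unknown region preset: '", region,
                 "' (expected upNk[-downMk], nearest-tss or territory)"))
  }
  list(mode = "fixed",
       upstream = as.integer(round(as.numeric(m[1, 2]) * 1000)),
       downstream = if (is.na(m[1, 3])) 0L else as.integer(round(as.numeric(m[1, 3]) * 1000)))
}

#' Stable fingerprint of a configuration
#'
#' Canonicalizes the option list (sorted names, fingerprint field excluded)
#' and hashes it, so identical option sets always share a fingerprint and
#' distinct ones essentially never collide.
#'
#' @param config A `met_config` or plain option list.
#' @return A hex string.
#' @export
config_fingerprint <- function(config) {
  opts <- unclass(config)
  opts$fingerprint <- NULL
  opts <- opts[order(names(opts))]
  digest::digest(opts, algo = "xxhash64")
}

#' Create a profile cache
#'
#' Window tilings, background models and raw score profiles do not depend on
#' downstream options (regions, K, user sets), so configurations sharing the
#' scoring stage reuse them. The cache records hit/miss counts.
#'
#' @return An environment usable as the `cache` argument of
#'   [run_configuration()].
#' @export
met_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  e
}

cache_fetch <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (exists(key, envir = cache$store, inherits = FALSE)) {
    cache$hits <- cache$hits + 1L
    return(get(key, envir = cache$store, inherits = FALSE))
  }
  cache$misses <- cache$misses + 1L
  val <- compute()
  assign(key, val, envir = cache$store)
  val
}

#' Cache hit/miss counts
#' @param cache A cache from [met_cache()].
#' @return Named integer vector `hits`, `misses`.
#' @export
cache_stats <- function(cache) {
  c(hits = cache$hits, misses = cache$misses)
}

# raw (pre-normalization) profiles for every feature under a configuration
compute_raw_profiles <- function(data, config, windows, cache) {
  scoring_key <- paste(config$window_length, config$shift, config$bg_order,
                       config$conservation, sep = "|")
  profiles <- list()
  if (!is.null(data$motifs)) {
    bg <- cache_fetch(cache, paste0("bg|", config$bg_order),
                      function() train_background(data$genome, config$bg_order))
    for (id in names(data$motifs)) {
      key <- paste0("profile|", scoring_key, "|motif|", id)
      profiles[[id]] <- cache_fetch(cache, key, function() {
        motif <- motif_probabilities(data$motifs[[id]], motif_id = id)
        prof <- score_genome(data$genome, windows, motif, bg)
        if (config$conservation) {
          ortho <- data$ortho_scores[[id]]
          ref <- tibble(species = "reference", index = prof$index,
                        score = ifelse(prof$scorable, prof$score, NA_real_))
          prof2 <- phylo_average(bind_rows(ref, ortho), tree = data$tree,
                                 feature_id = id)
          prof2$scorable <- prof$scorable & prof2$scorable
          prof2
        } else prof
      })
    }
  }
  if (!is.null(data$chip)) {
    for (id in names(data$chip)) {
      key <- paste0("profile|", scoring_key, "|chip|", id)
      profiles[[id]] <- cache_fetch(cache, key, function() {
        signal_to_windows(windows, data$chip[[id]], feature_id = id)
      })
    }
  }
  profiles
}

#' Run one analysis configuration
#'
#' Executes the full pipeline for a configuration: tile windows, score every
#' feature (motif and/or ChIP), normalize, apply the optional accessibility
#' mask, define regulatory regions, compute per-gene scores, build top-K
#' target sets and test each user set with one-sided Fisher's exact tests.
#' Deterministic given its inputs; the configuration fingerprint is embedded
#' in every result row.
#'
#' @param data A `met_data` bundle.
#' @param config A `met_config`.
#' @param user_sets A named list of character vectors (a bare vector is
#'   treated as one set named `"set1"`).
#' @param universe Optional universe gene ids; defaults to every gene in the
#'   annotation.
#' @param cache Optional [met_cache()] shared across configurations.
#' @return A `met_enrichment` tibble: one row per (user set x feature) with
#'   contingency counts, `p_value`, `overlap_genes` and `fingerprint`.
#' @export
run_configuration <- function(data, config, user_sets, universe = NULL,
                              cache = NULL) {
  if (!inherits(config, "met_config")) abort("config must be a met_config")
  if (config$conservation && (is.null(data$ortho_scores) || is.null(data$tree))) {
    abort("conservation requested but ortho_scores/tree missing from met_data")
  }
  if (config$accessibility && is.null(data$access)) {
    abort("accessibility filter requested but no accessibility track in met_data")
  }
  if (is.null(data$motifs) && is.null(data$chip)) {
    abort("no features: met_data carries neither motifs nor chip tracks")
  }
  if (!is.list(user_sets)) user_sets <- list(set1 = user_sets)
  if (is.null(names(user_sets))) {
    names(user_sets) <- paste0("set", seq_along(user_sets))
  }
  if (is.null(universe)) universe <- data$genes$gene_id

  lens <- chrom_lengths(data$genome)
  win_key <- paste0("windows|", config$window_length, "|", config$shift)
  windows <- cache_fetch(cache, win_key, function() {
    compute_gc(tile_windows(lens, config$window_length, config$shift), data$genome)
  })
  profiles <- compute_raw_profiles(data, config, windows, cache)

  access_prof <- NULL
  if (config$accessibility) {
    access_prof <- cache_fetch(cache, paste0(win_key, "|access"), function() {
      signal_to_windows(windows, data$access, feature_id = "accessibility")
    })
  }

  regions <- define_regions(data$genes, mode = config$region$mode, lengths = lens,
                            upstream = config$region$upstream,
                            downstream = config$region$downstream)
  assignment <- assign_windows(regions, windows)

  rows <- list()
  for (id in names(profiles)) {
    norm <- if (config$normalization == "gc") {
      gc_rank_normalize(profiles[[id]], windows, n_bins = config$n_bins)
    } else {
      rank_normalize(profiles[[id]])
    }
    if (!is.null(access_prof)) {
      norm <- accessibility_filter(norm, access_prof,
                                   retain_fraction = config$retain_fraction)
    }
    scores <- score_genes(norm, assignment, gene_ids = data$genes$gene_id)
    target <- build_target_set(scores, universe, K = config$K)
    for (us in names(user_sets)) {
      row <- fisher_enrichment(target, user_sets[[us]], universe, feature_id = id)
      row$user_set <- us
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- bind_rows(rows)
  out$fingerprint <- config$fingerprint
  out <- out[, c("feature_id", "user_set", "fingerprint", "universe_size",
                 "target_size", "user_size", "overlap", "p_value", "overlap_genes")]
  class(out) <- c("met_enrichment", class(out))
  attr(out, "config") <- config
  out
}

#' Run a batch of configurations and write reports
#'
#' Runs every configuration against the same inputs, sharing a profile cache
#' so window scoring is executed once per feature even when configurations
#' differ only downstream of scoring. Invalid configurations are reported
#' and do not stop valid ones. Writes the summary and per-configuration
#' detail TSVs plus a machine-readable JSON run manifest (options,
#' fingerprints, package version, seed, input checksums).
#'
#' @inheritParams run_configuration
#' @param configs A list of `met_config` objects.
#' @param out_dir Output directory.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents how synthetic inputs were generated).
#' @return Invisibly, a list with `results` (per-configuration tibbles),
#'   `errors` (per-configuration error messages), `cache` and `files`.
#' @export
run_all <- function(data, configs, user_sets, universe = NULL,
                    out_dir = ".", seed = NULL) {
  if (length(configs) == 0) abort("at least one configuration is required")
  if (inherits(configs, "met_config")) configs <- list(configs)
  cache <- met_cache()
  results <- list()
  errors <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    res <- tryCatch(
      run_configuration(data, cfg, user_sets, universe = universe, cache = cache),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cfg$fingerprint]] <- conditionMessage(res)
      inform(paste0("configuration ", cfg$fingerprint, " failed: ",
                    conditionMessage(res)))
    } else {
      results[[cfg$fingerprint]] <- res
    }
  }
  files <- character(0)
  if (length(results) > 0) {
    files <- write_reports(results, out_dir,
                           max_p = configs[[1]]$max_p)
  }
  manifest <- list(
    package = "cisenrich",
    version = as.character(utils::packageVersion("cisenrich")),
    seed = seed,
    configurations = lapply(configs, function(cfg) {
      opts <- unclass(cfg)
      opts$region <- NULL
      opts
    }),
    errors = errors,
    inputs = list(
      genome_checksum = digest::digest(unclass(data$genome)),
      n_genes = nrow(data$genes),
      n_motifs = length(data$motifs),
      universe_size = length(if (is.null(universe)) data$genes$gene_id else universe)
    ),
    cache = as.list(cache_stats(cache))
  )
  mf <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, mf)
  invisible(list(results = results, errors = errors, cache = cache, files = files))
}
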