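#' Tile chromosomes into fixed windows
#'
#' Tiles every chromosome into windows of `window_length` bp placed every
#' `shift` bp, the atomic scoring unit of the pipeline. Trailing bases that
#' cannot host a full window are left uncovered so that all regular windows
#' have identical length; a chromosome shorter than `window_length` yields a
#' single window covering the whole chromosome, flagged `short`.
#'
#' @param lengths Named vector of chromosome lengths in bp, or a `met_genome`.
#' @param window_length Window size in bp (default 500).
#' @param shift Step between window starts in bp (default 250).
#' @return A tibble with columns `index` (dense, 0-based), `chrom`, `start`,
#'   `end` (0-based half-open) and `short`.
#' @export
tile_windows <- function(lengths, window_length = 500L, shift = 250L) {
  if (inherits(lengths, "met_genome")) lengths <- chrom_lengths(lengths)
  window_length <- as.integer(window_length)
  shift <- as.integer(shift)
  if (window_length < 1L) abort("window_length must be >= 1")
  if (shift < 1L || shift > window_length) abort("shift must satisfy 1 <= shift <= window_length")
  if (any(lengths <= 0)) abort("chromosome lengths must be positive")
  per_chrom <- purrr::imap(as.list(lengths), function(L, chrom) {
    L <- as.integer(L)
    if (L < window_length) {
      tibble(chrom = chrom, start = 0L, end = L, short = TRUE)
    } else {
      starts <- seq.int(0L, L - window_length, by = shift)
      tibble(chrom = chrom, start = starts, end = starts + window_length, short = FALSE)
    }
  })
  win <- bind_rows(per_chrom)
  win$index <- seq_len(nrow(win)) - 1L
  win[, c("index", "chrom", "start", "end", "short")]
}

#' Per-window G/C content
#'
#' Adds the G/C fraction of each window, computed over non-N bases only, plus
#' an `all_n` flag for windows with no informative sequence (their `gc` is 0
#' and they are excluded from G/C binning downstream).
#'
#' @param windows A window tibble from [tile_windows()].
#' @param genome A `met_genome`.
#' @return `windows` with `gc` and `all_n` columns added.
#' @export
compute_gc <- function(windows, genome) {
  lens <- chrom_lengths(genome)
  missing_chr <- setdiff(unique(windows$chrom), names(lens))
  if (length(missing_chr) > 0) {
    abort(paste0("windows on chromosome(s) absent from genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  oob <- windows$end > lens[windows$chrom] | windows$start < 0
  if (any(oob)) {
    abort(paste0("window(s) outside chromosome bounds at index ",
                 paste(windows$index[oob], collapse = ", ")))
  }
  gc <- numeric(nrow(windows))
  all_n <- logical(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    sel <- windows$chrom == chrom
    seqs <- Biostrings::DNAStringSet(
      substring(unclass(genome)[[chrom]], windows$start[sel] + 1L, windows$end[sel]))
    freq <- Biostrings::letterFrequency(seqs, c("G", "C", "A", "T"))
    informative <- rowSums(freq)
    gc_count <- freq[, "G"] + freq[, "C"]
    gc[sel] <- ifelse(informative > 0, gc_count / informative, 0)
    all_n[sel] <- informative == 0
  }
  windows$gc <- gc
  windows$all_n <- all_n
  windows
}

#' Project interval signal onto windows
#'
#' Converts a bedGraph-style interval track into one value per window: the
#' length-weighted mean of the track over the window, with uncovered bases
#' counting as signal 0 (read-count semantics: no reads means zero signal).
#'
#' @param windows A window tibble from [tile_windows()].
#' @param track A signal tibble from [read_signal_track()].
#' @param feature_id Label stored in the output profile (default `"signal"`).
#' @return A score profile tibble: columns `feature_id`, `index`, `score`,
#'   `scorable` (here always `TRUE`).
#' @export
signal_to_windows <- function(windows, track, feature_id = "signal") {
  extra <- setdiff(unique(track$chrom), unique(windows$chrom))
  if (length(extra) > 0) {
    abort(paste0("track chromosome(s) not present in windows: ",
                 paste(extra, collapse = ", ")))
  }
  score <- numeric(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    wsel <- which(windows$chrom == chrom)
    tsel <- track$chrom == chrom
    if (!any(tsel)) next
    score[wsel] <- weighted_interval_mean(
      windows$start[wsel], windows$end[wsel],
      track$start[tsel], track$end[tsel], track$value[tsel])
  }
  tibble(feature_id = feature_id, index = windows$index, score = score, scorable = TRUE)
}

# Length-weighted mean of (istart, iend, value] intervals over each window;
# uncovered bases contribute value 0. Intervals are disjoint and sorted.
weighted_interval_mean <- function(wstart, wend, istart, iend, value) {
  n <- length(wstart)
  out <- numeric(n)
  # windows overlap each other, so locate the interval range per window
  first <- findInterval(wstart, iend, left.open = TRUE) + 1L
  last <- findInterval(wend - 1L, istart)
  for (i in seq_len(n)) {
    if (first[i] > last[i]) next
    j <- first[i]:last[i]
    ov <- pmin(wend[i], iend[j]) - pmax(wstart[i], istart[j])
    ov <- pmax(ov, 0L)
    out[i] <- sum(ov * value[j]) / (wend[i] - wstart[i])
  }
  out
}
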