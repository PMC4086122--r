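#' Train an order-k Markov background model
#'
#' Counts all non-N (k+1)-mers genome-wide with add-one smoothing, giving the
#' conditional probability of each base given its preceding k bases. Lower
#' order marginal tables (orders 0..k-1) are kept as well: a window is scored
#' standalone, so its first k positions fall back to the longest available
#' context.
#'
#' @param genome A `met_genome`.
#' @param order Markov order k >= 0 (default 2).
#' @return A `met_background` object: list with `order`, `tables` (one
#'   conditional table per order 0..k, each a vector of length 4^j * 4 in
#'   context-major order) and `trained_on`.
#' @export
train_background <- function(genome, order = 2L) {
  order <- as.integer(order)
  if (order < 0L) abort("order must be >= 0")
  seqs <- Biostrings::DNAStringSet(unclass(genome))
  tables <- vector("list", order + 1L)
  for (j in 0:order) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = j + 1L))
    if (j == 0 && sum(counts) == 0) {
      abort("genome has no non-N bases; cannot train a background model")
    }
    # counts are in lexicographic order AA..TT = context-major, base-minor
    m <- matrix(counts + 1, ncol = 4L, byrow = TRUE)  # 4^j contexts x 4 bases
    m <- m / rowSums(m)
    tables[[j + 1L]] <- as.numeric(t(m))
  }
  structure(
    list(order = order, tables = tables,
         trained_on = paste0(length(seqs), " sequence(s), ",
                             sum(Biostrings::width(seqs)), " bp")),
    class = "met_background")
}

#' Convert a count matrix to a motif probability model
#'
#' Adds a pseudocount of 0.5 to every cell and normalizes each position to a
#' probability distribution.
#'
#' @param counts A width x 4 non-negative count matrix (columns A, C, G, T).
#' @param motif_id Identifier stored with the model.
#' @param pseudocount Added to every cell before normalizing (default 0.5).
#' @return A `met_motif` object: list with `motif_id`, `theta` (width x 4
#'   probability matrix) and `width`.
#' @export
motif_probabilities <- function(counts, motif_id = "motif", pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) abort("motif counts must have 4 columns (A, C, G, T)")
  if (any(counts < 0)) abort("motif counts must be non-negative")
  theta <- counts + pseudocount
  theta <- theta / rowSums(theta)
  structure(list(motif_id = motif_id, theta = theta, width = nrow(theta)),
            class = "met_motif")
}

#' Consensus sequence of a motif
#'
#' The arg-max base at each position (ties broken toward A < C < G < T).
#'
#' @param motif A `met_motif` or a width x 4 count matrix.
#' @return A single consensus string.
#' @export
motif_consensus <- function(motif) {
  theta <- if (inherits(motif, "met_motif")) motif$theta else as.matrix(motif)
  paste(c("A", "C", "G", "T")[apply(theta, 1, which.max)], collapse = "")
}

# encode A/C/G/T/N as 0..4 for the C++ scorer
encode_seq <- function(seq) {
  lut <- rep(4L, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt(seq) + 1L]
}

check_motif_width <- function(motif, max_width) {
  if (motif$width > max_width) {
    abort(paste0("motif ", motif$motif_id, " wider (", motif$width,
                 ") than the allowed maximum (", max_width, ")"))
  }
}

#' Block-HMM score of one sequence window
#'
#' Scores a nucleotide sequence for motif presence with a generative block
#' model: the sequence is parsed as a mixture of background letters
#' (probability 1 - p) and motif blocks of width W (probability p), motif
#' emission being an equal mixture of the forward and reverse-complement
#' strand. The score is log2 of the likelihood ratio against pure background,
#' maximized over p in \[0, 0.5\] (EM with golden-section fallback), so it
#' integrates strong and weak sites and is always >= 0. Sequences shorter
#' than the motif score exactly 0. Because a Markov background of order >= 1
#' is not reverse-complement invariant, the reported score is
#' strand-symmetrized: the mean of the scores of the window and of its
#' reverse complement, making score(seq) == score(revcomp(seq)) exact.
#'
#' @param seq A nucleotide string (A/C/G/T/N).
#' @param motif A `met_motif` from [motif_probabilities()].
#' @param bg A `met_background` from [train_background()].
#' @param p Fixed block probability; `NULL` (default) maximizes over p.
#' @param max_width Maximum allowed motif width (default 30).
#' @param tol EM convergence tolerance on p (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @return A single score in bits (log2 likelihood ratio), >= 0 when p is
#'   optimized.
#' @export
stubb_window_score <- function(seq, motif, bg, p = NULL, max_width = 30L,
                               tol = 1e-6, max_iter = 200L) {
  check_motif_width(motif, max_width)
  x <- encode_seq(toupper(seq))
  cpp_score_windows(x, 0L, length(x), motif$theta, bg$tables, bg$order,
                    if (is.null(p)) -1 else p, tol, as.integer(max_iter))[1]
}

#' Parse likelihood of a sequence at fixed block probability
#'
#' The total probability of the sequence under the block model at a given p:
#' the sum over all parses into background letters and motif blocks of the
#' parse probability. Intended for verification against explicit parse
#' enumeration on short sequences (the value underflows for long ones).
#'
#' @inheritParams stubb_window_score
#' @param p Block probability in \[0, 0.5\].
#' @return The likelihood (a probability).
#' @export
stubb_likelihood <- function(seq, motif, bg, p) {
  x <- encode_seq(toupper(seq))
  cpp_parse_likelihood(x, motif$theta, bg$tables, bg$order, p)
}

#' Score every genome window for one motif
#'
#' Applies [stubb_window_score()] to each window; windows consisting only of
#' N bases get score 0 and are flagged unscorable. Deterministic and
#' independent of chromosome processing order.
#'
#' @param genome A `met_genome`.
#' @param windows A window tibble from [tile_windows()].
#' @param motif A `met_motif`.
#' @param bg A `met_background`.
#' @inheritParams stubb_window_score
#' @return A score profile tibble: `feature_id`, `index`, `score`,
#'   `scorable`.
#' @export
score_genome <- function(genome, windows, motif, bg, max_width = 30L,
                         tol = 1e-6, max_iter = 200L) {
  check_motif_width(motif, max_width)
  score <- numeric(nrow(windows))
  have_flag <- "all_n" %in% names(windows)
  scorable <- if (have_flag) !windows$all_n else logical(nrow(windows))
  for (chrom in names(genome)) {
    sel <- which(windows$chrom == chrom)
    if (length(sel) == 0) next
    x <- encode_seq(unclass(genome)[[chrom]])
    score[sel] <- cpp_score_windows(
      x, windows$start[sel], windows$end[sel], motif$theta, bg$tables,
      bg$order, -1, tol, as.integer(max_iter))
    if (!have_flag) {
      for (i in sel) {
        scorable[i] <- any(x[(windows$start[i] + 1L):windows$end[i]] != 4L)
      }
    }
  }
  tibble(feature_id = motif$motif_id, index = windows$index,
         score = score, scorable = scorable)
}
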