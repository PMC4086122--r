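# Shared in-code fixtures and independent oracles.

# small deterministic genome/background shared across scoring tests
tiny_genome <- function(seed = 7, length = 2000) {
  make_genome(n_chrom = 1, chrom_length = length, seed = seed)
}

tiny_background <- function(order = 2) {
  train_background(tiny_genome(), order = order)
}

random_motif_probs <- function(width, id = "m") {
  mat <- matrix(runif(width * 4, 0.1, 10), nrow = width)
  colnames(mat) <- c("A", "C", "G", "T")
  motif_probabilities(mat, id)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_str <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Independent oracle for the block-model likelihood: enumerate every parse of
# the sequence into single background letters and W-blocks and sum the parse
# probabilities. Exponential in length; for short sequences only.
enumerate_parse_likelihood <- function(seq, theta, bg_tables, k, p) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N")) - 1L
  L <- length(x)
  W <- nrow(theta)
  bprob <- function(i) {
    if (x[i] == 4) return(1)
    m <- min(i - 1, k)
    while (m > 0 && any(x[(i - m):(i - 1)] == 4)) m <- m - 1
    ctx <- 0
    for (j in seq_len(m)) ctx <- ctx * 4 + x[i - m + j - 1]
    bg_tables[[m + 1]][ctx * 4 + x[i] + 1]
  }
  bemit <- function(i) {
    if (any(x[i:(i + W - 1)] == 4)) return(0)
    fwd <- prod(theta[cbind(1:W, x[i:(i + W - 1)] + 1)])
    rev <- prod(theta[cbind(W:1, 3 - x[i:(i + W - 1)] + 1)])
    0.5 * (fwd + rev)
  }
  recurse <- function(i) {
    if (i > L) return(1)
    tot <- (1 - p) * bprob(i) * recurse(i + 1)
    if (i + W - 1 <= L) tot <- tot + p * bemit(i) * recurse(i + W)
    tot
  }
  recurse(1)
}

# Independent oracle for the one-sided Fisher p: explicit hypergeometric
# tail summation with choose().
hypergeom_tail_oracle <- function(N, K, n, a) {
  i <- a:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
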