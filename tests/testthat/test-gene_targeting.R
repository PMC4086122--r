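mk_genes <- function(...) {
  g <- tibble::tribble(...)
  g$tss <- as.integer(ifelse(g$strand == "+", g$start, g$end - 1L))
  g
}

test_that("fixed regions are strand-aware spans around the TSS", {
  genes <- mk_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "plus",  "chr1", 10000L, 11000L, "+",
    "minus", "chr1", 30000L, 31000L, "-")
  r <- define_regions(genes, "fixed", c(chr1 = 50000L),
                      upstream = 5000L, downstream = 2000L)
  expect_equal(unlist(r[r$gene_id == "plus", c("start", "end")], use.names = FALSE),
               c(5000L, 12000L))
  # minus gene, tss = 30999: mirrored span
  expect_equal(unlist(r[r$gene_id == "minus", c("start", "end")], use.names = FALSE),
               c(30999L - 2000L + 1L, 30999L + 5000L + 1L))

  # clamped at chromosome start
  r2 <- define_regions(mk_genes(~gene_id, ~chrom, ~start, ~end, ~strand,
                                "edge", "chr1", 1000L, 2000L, "+"),
                       "fixed", c(chr1 = 50000L), upstream = 5000L, downstream = 0L)
  expect_equal(r2$start, 0L)
  expect_error(define_regions(genes, "fixed", c(chr1 = 50000L),
                              upstream = 0L, downstream = 0L), "fixed")
})

test_that("nearest-TSS regions partition each chromosome by TSS proximity", {
  single <- mk_genes(~gene_id, ~chrom, ~start, ~end, ~strand,
                     "solo", "chr1", 5000L, 6000L, "+")
  r1 <- define_regions(single, "nearest_tss", c(chr1 = 20000L))
  expect_equal(unlist(r1[, c("start", "end")], use.names = FALSE), c(0L, 20000L))

  genes <- mk_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "a", "chr1", 1000L, 2000L, "+",
    "b", "chr1", 7000L, 8000L, "+")
  r <- define_regions(genes, "nearest_tss", c(chr1 = 10000L))
  # cut at midpoint of tss 1000 and 7000 = 4000, tie to the lower TSS
  expect_equal(r$end[r$gene_id == "a"], 4001L)
  expect_equal(r$start[r$gene_id == "b"], 4001L)
  # regions tile the chromosome
  expect_equal(sum(r$end - r$start), 10000L)
})

test_that("territory regions split gaps and run to chromosome ends", {
  genes <- mk_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "left",  "chr1", 1000L, 2000L, "+",
    "mid",   "chr1", 4000L, 5000L, "+",
    "right", "chr1", 8000L, 9000L, "+")
  r <- define_regions(genes, "territory", c(chr1 = 12000L))
  expect_equal(unlist(r[r$gene_id == "mid", c("start", "end")], use.names = FALSE),
               c(3000L, 6500L))
  # no neighbor: to the chromosome end
  expect_equal(r$start[r$gene_id == "left"], 0L)
  expect_equal(r$end[r$gene_id == "right"], 12000L)
  # adjacent territories tile without gap or overlap
  rr <- r[order(r$start), ]
  expect_equal(rr$start[-1], rr$end[-nrow(rr)])
})

test_that("windows join regions by midpoint", {
  w <- tile_windows(c(chr1 = 20000L))
  region <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 5000L,
                           end = 12000L, mode = "fixed", regionless = FALSE)
  asg <- assign_windows(region, w)
  expect_equal(nrow(asg), 28)  # midpoints 250k + 250 in [5000, 12000)

  narrow <- tibble::tibble(gene_id = "tiny", chrom = "chr1", start = 12010L,
                           end = 12090L, mode = "fixed", regionless = FALSE)
  expect_equal(nrow(assign_windows(narrow, w)), 0)
})

test_that("nearest-TSS window assignment is a partition", {
  set.seed(141)
  g <- make_genome(1, 50000, seed = 141)
  genes <- make_annotation(g, 10, seed = 141)
  w <- tile_windows(g)
  r <- define_regions(genes, "nearest_tss", chrom_lengths(g))
  asg <- assign_windows(r, w)
  expect_equal(nrow(asg), dplyr::n_distinct(asg$index))
  expect_equal(sort(unique(asg$index)), w$index)
})

test_that("gene scores follow S_g = 1 - (1 - P_g)^w_g", {
  norm <- tibble::tibble(feature_id = "f", index = 0:9,
                         norm = c(0.01, rep(0.5, 9)), scorable = TRUE)
  # w_g = 1: S_g equals P_g
  asg1 <- tibble::tibble(gene_id = "g1", index = 0L)
  expect_equal(score_genes(norm, asg1)$S_g, 0.01)

  # printed-formula value at P = 0.01, w = 10
  asg10 <- tibble::tibble(gene_id = "g2", index = 0:9)
  s <- score_genes(norm, asg10)
  expect_equal(s$P_g, 0.01)
  expect_equal(s$w_g, 10L)
  expect_equal(s$S_g, 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(s$S_g, 0.0956179249912, tolerance = 1e-9)

  # P_g -> 0 drives S_g -> 0
  tiny <- tibble::tibble(feature_id = "f", index = 0:4,
                         norm = c(1e-12, 1, 1, 1, 1), scorable = TRUE)
  expect_lt(score_genes(tiny, tibble::tibble(gene_id = "g", index = 0:4))$S_g, 1e-10)

  # genes without windows score 1
  s0 <- score_genes(norm, asg1, gene_ids = c("g1", "lonely"))
  expect_equal(s0$S_g[s0$gene_id == "lonely"], 1)
  expect_equal(s0$w_g[s0$gene_id == "lonely"], 0L)
})

test_that("S_g is strictly monotone in P_g and w_g", {
  set.seed(151)
  # grid kept where (1 - P)^w stays resolvable in double precision, so
  # strictness is not lost to saturation of S_g at 1
  P <- sort(runif(200, 1e-6, 0.6))
  S <- function(P, w) 1 - (1 - P)^w
  # increasing in P at fixed w
  for (wi in c(1, 5, 30)) {
    expect_true(all(diff(S(P, wi)) > 0))
  }
  # increasing in w at fixed P
  for (Pi in c(0.001, 0.3, 0.6)) {
    expect_true(all(diff(S(Pi, 1:30)) > 0))
  }
  # adding a masked (value 1) window never decreases S_g
  norm <- tibble::tibble(feature_id = "f", index = 0:2,
                         norm = c(0.2, 1, 1), scorable = TRUE)
  s1 <- score_genes(norm, tibble::tibble(gene_id = "g", index = 0:1))$S_g
  s2 <- score_genes(norm, tibble::tibble(gene_id = "g", index = 0:2))$S_g
  expect_gte(s2, s1)
  # the accessible-only reading ignores masked windows in w_g
  alt <- score_genes(norm, tibble::tibble(gene_id = "g", index = 0:2),
                     count_masked = FALSE)
  expect_equal(alt$w_g, 1L)
  expect_equal(alt$S_g, 0.2)
})

test_that("target sets restrict to the universe, order by score, cap at K", {
  scores <- tibble::tibble(
    gene_id = c("d", "a", "b", "c", "z"),
    P_g = 0.1, w_g = 1L,
    S_g = c(0.5, 0.1, 0.3, 0.3, 0.05))
  t1 <- build_target_set(scores, universe = c("a", "b", "c", "d"), K = 2)
  # z excluded (not in universe); ties at 0.3 break lexicographically
  expect_equal(t1$gene_id, c("a", "b"))
  t2 <- build_target_set(scores, universe = c("a", "b", "c", "d"), K = 10)
  expect_equal(t2$gene_id, c("a", "b", "c", "d"))
  expect_error(build_target_set(scores, universe = character(0)), "universe")
})
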