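mk_profile <- function(scores, scorable = TRUE, id = "f") {
  tibble::tibble(feature_id = id, index = seq_along(scores) - 1L,
                 score = scores, scorable = rep_len(scorable, length(scores)))
}

test_that("rank normalization maps best ranks to smallest values", {
  # 100 distinct scores: best window gets 1/100
  p <- mk_profile(sample(seq_len(100)))
  n <- rank_normalize(p)
  expect_equal(n$norm[which.max(p$score)], 0.01)
  expect_equal(sort(n$norm), seq_len(100) / 100)

  # full tie: everyone gets (N+1)/(2N)
  n_tie <- rank_normalize(mk_profile(rep(3, 10)))
  expect_equal(n_tie$norm, rep(11 / 20, 10))

  # mean tied ranks
  n4 <- rank_normalize(mk_profile(c(5, 3, 3, 1)))
  expect_equal(n4$norm, c(0.25, 0.625, 0.625, 1.0))

  # unscorable windows carry exactly 1 and are excluded from N
  pu <- mk_profile(c(5, 4, 0), scorable = c(TRUE, TRUE, FALSE))
  expect_equal(rank_normalize(pu)$norm, c(0.5, 1.0, 1.0))

  expect_error(rank_normalize(mk_profile(c(1, 2), scorable = FALSE)), "unscorable")
})

test_that("rank-normalized values conserve the rank sum", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    scores <- sample(round(runif(n, 0, 50)))  # heavy ties
    out <- rank_normalize(mk_profile(scores))
    expect_equal(mean(out$norm), (n + 1) / (2 * n), tolerance = 1e-9)
  }
})

test_that("G/C binning balances bin sizes and normalizes within bins", {
  set.seed(101)
  mk_windows <- function(n) tibble::tibble(index = seq_len(n) - 1L, gc = runif(n))
  p <- mk_profile(runif(2000))
  w <- mk_windows(2000)
  out <- gc_rank_normalize(p, w, n_bins = 20)
  # with distinct scores, every bin of 100 contributes values k/100
  expect_equal(sort(unique(out$norm)), seq_len(100) / 100)
  expect_equal(sum(out$norm == 0.01), 20)  # one best window per bin

  p1 <- mk_profile(runif(2001))
  out1 <- gc_rank_normalize(p1, mk_windows(2001), n_bins = 20)
  # exactly one bin of 101: its best window gets 1/101
  expect_equal(sum(out1$norm == 1 / 101), 1)

  # a window best within its bin gets 1/bin_size regardless of global rank
  w3 <- tibble::tibble(index = 0:5, gc = c(0.1, 0.15, 0.2, 0.7, 0.75, 0.8))
  p3 <- mk_profile(c(9, 8, 7, 3, 2, 1))
  out3 <- gc_rank_normalize(p3, w3, n_bins = 2)
  expect_equal(out3$norm[4], 1 / 3)  # score 3 is globally 4th but best in its bin

  expect_error(gc_rank_normalize(mk_profile(runif(10)), mk_windows(10), n_bins = 11),
               "fewer bins")
})

test_that("G/C binning with one bin is bit-identical to standard normalization", {
  set.seed(111)
  scores <- round(runif(500, 0, 20))
  p <- mk_profile(scores, scorable = c(rep(TRUE, 480), rep(FALSE, 20)))
  w <- tibble::tibble(index = seq_len(500) - 1L, gc = runif(500))
  expect_identical(gc_rank_normalize(p, w, n_bins = 1)$norm,
                   rank_normalize(p)$norm)
})

test_that("phylogenetic averaging weights species by the tree", {
  # single-species tree: identity
  t1 <- ape::read.tree(text = "(only:1.0);")
  prof <- tibble::tibble(species = "only", index = 0:4, score = c(5, 4, 3, 2, 1))
  out <- phylo_average(prof, t1)
  expect_equal(out$score, c(5, 4, 3, 2, 1))

  # two species at equal distance: equal weights
  t2 <- ape::read.tree(text = "(sp1:1.0,sp2:1.0);")
  expect_equal(unname(phylo_weights(t2)), c(0.5, 0.5))
  prof2 <- tibble::tibble(species = rep(c("sp1", "sp2"), each = 1),
                          index = 0L, score = c(4, 2))
  expect_equal(phylo_average(prof2, t2)$score, 3.0)

  # conserved presence beats reference-only signal
  t3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  conserved <- tibble::tibble(species = c("a", "b", "c"), index = 0L, score = 5)
  ref_only <- tibble::tibble(species = c("a", "b", "c"), index = 0L,
                             score = c(5, 0, 0))
  expect_gt(phylo_average(conserved, t3)$score,
            phylo_average(ref_only, t3)$score)

  # missing species per window are dropped with weights renormalized
  prof_na <- tibble::tibble(species = c("sp1", "sp2"), index = 0L,
                            score = c(4, NA))
  expect_equal(phylo_average(prof_na, t2)$score, 4.0)

  expect_error(phylo_average(
    tibble::tibble(species = "spX", index = 0L, score = 1), t2), "spX")
})

test_that("accessibility filter retains the top fraction and masks the rest", {
  set.seed(121)
  n <- 1000
  norm <- rank_normalize(mk_profile(runif(n)))
  access <- mk_profile(sample(seq_len(n)), id = "dhs")
  out <- accessibility_filter(norm, access, retain_fraction = 0.10)
  kept <- out$norm != 1 | norm$norm == 1
  expect_equal(sum(out$norm == norm$norm & access$score > n - 100), 100)
  expect_true(all(out$norm[access$score <= n - 100] == 1))

  # retain_fraction = 1 is a no-op
  expect_identical(accessibility_filter(norm, access, retain_fraction = 1)$norm,
                   norm$norm)

  # ties at the threshold are retained
  norm10 <- rank_normalize(mk_profile(seq_len(10)))
  acc10 <- mk_profile(c(9, 9, 9, 8, 7, 6, 5, 4, 3, 2), id = "dhs")
  out10 <- accessibility_filter(norm10, acc10, retain_fraction = 0.10)
  expect_equal(sum(out10$norm != 1 | norm10$norm == 1), 3)

  expect_warning(accessibility_filter(norm10, mk_profile(rep(1, 10))), "equal")
})

test_that("masking never lowers a normalized value", {
  set.seed(131)
  for (i in 1:10) {
    n <- 200
    norm <- rank_normalize(mk_profile(runif(n)))
    access <- mk_profile(runif(n), id = "dhs")
    out <- accessibility_filter(norm, access, retain_fraction = runif(1, 0.05, 0.9))
    expect_true(all(out$norm >= norm$norm - 1e-15))
  }
})
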