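# small shared pipeline inputs for orchestration tests
local_case <- local({
  case <- NULL
  function() {
    if (is.null(case)) {
      case <<- make_benchmark_case(n_genes = 30, planted_fraction = 0.2,
                                   n_decoys = 2, chrom_length = 2e5, seed = 68)
    }
    case
  }
})

test_that("configuration fingerprints are stable and option-sensitive", {
  c1 <- met_config(region = "up5k-down2k", normalization = "gc")
  c2 <- met_config(region = "up5k-down2k", normalization = "gc")
  expect_identical(c1$fingerprint, c2$fingerprint)
  expect_false(met_config(region = "up1k")$fingerprint == c1$fingerprint)
  # distinct random option draws essentially never collide
  set.seed(181)
  fps <- replicate(200, met_config(
    region = sample(c("up1k", "up10k", "up5k-down2k", "nearest-tss", "territory"), 1),
    normalization = sample(c("standard", "gc"), 1),
    K = sample(1000, 1), max_p = runif(1),
    retain_fraction = runif(1))$fingerprint)
  expect_equal(anyDuplicated(fps), 0)
  expect_error(met_config(region = "sideways"), "region")
})

test_that("run_configuration crosses user sets with features deterministically", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  cfg <- met_config(region = "up5k", normalization = "standard", K = 10)
  sets <- list(s1 = case$genes$gene_id[1:10], s2 = case$genes$gene_id[11:20])
  res <- run_configuration(data, cfg, sets)
  expect_equal(nrow(res), 2 * 3)  # 2 user sets x 3 features
  expect_true(all(res$fingerprint == cfg$fingerprint))
  expect_true(all(res$universe_size == 30))
  res2 <- run_configuration(data, cfg, sets)
  expect_identical(as.data.frame(res)[names(res) != "overlap_genes"],
                   as.data.frame(res2)[names(res2) != "overlap_genes"])
  expect_identical(res$overlap_genes, res2$overlap_genes)
})

test_that("invalid option combinations fail before any computation", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  expect_error(
    run_configuration(data, met_config(conservation = TRUE), list(s = "g0001")),
    "conservation")
  expect_error(
    run_configuration(data, met_config(accessibility = TRUE), list(s = "g0001")),
    "accessibility")
  expect_error(
    run_configuration(met_data(case$genome, case$genes), met_config(),
                      list(s = "g0001")), "features")
})

test_that("configurations differing downstream of scoring share cached profiles", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  cache <- met_cache()
  sets <- list(s1 = case$truth$planted_genes)
  r1 <- run_configuration(data, met_config(region = "up5k", K = 10), sets,
                          cache = cache)
  after_first <- cache_stats(cache)
  r2 <- run_configuration(data, met_config(region = "nearest-tss", K = 10), sets,
                          cache = cache)
  after_second <- cache_stats(cache)
  # second configuration recomputes nothing: all lookups hit
  expect_equal(after_second[["misses"]], after_first[["misses"]])
  expect_gt(after_second[["hits"]], after_first[["hits"]])
  # but results differ because the region mode differs
  expect_false(identical(r1$p_value, r2$p_value))
})

test_that("run_all isolates invalid configurations and writes a manifest", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  out <- tempfile()
  good <- met_config(region = "up5k", K = 10)
  bad <- met_config(region = "up5k", K = 10, accessibility = TRUE)  # no track
  run <- run_all(data, list(good, bad), list(planted = case$truth$planted_genes),
                 out_dir = out, seed = 68)
  expect_length(run$results, 1)
  expect_length(run$errors, 1)
  expect_match(run$errors[[bad$fingerprint]], "accessibility")
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, paste0("details_", good$fingerprint, ".tsv"))))
  manifest <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(manifest$seed, 68)
  expect_length(manifest$configurations, 2)

  # identical rerun produces byte-identical reports
  out2 <- tempfile()
  run_all(data, list(good, bad), list(planted = case$truth$planted_genes),
          out_dir = out2, seed = 68)
  f1 <- file.path(out, paste0("details_", good$fingerprint, ".tsv"))
  f2 <- file.path(out2, paste0("details_", good$fingerprint, ".tsv"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tidy and glance summarize enrichment results", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  res <- run_configuration(data, met_config(region = "up5k", K = 10),
                           list(planted = case$truth$planted_genes))
  td <- tidy(res)
  expect_true(all(c("p_adjusted", "overlap_genes") %in% names(td)))
  expect_type(td$overlap_genes, "character")
  expect_true(!is.unsorted(td$p_value))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_tests, 3)
  expect_equal(gl$best_feature, td$feature_id[1])
})

test_that("profile and enrichment plots build without error", {
  case <- local_case()
  data <- met_data(case$genome, case$genes, motifs = case$motifs)
  w <- compute_gc(tile_windows(case$genome), case$genome)
  bg <- train_background(case$genome)
  prof <- score_genome(case$genome, w,
                       motif_probabilities(case$motifs[["planted"]], "planted"), bg)
  expect_s3_class(plot_profile(prof, w), "ggplot")
  expect_s3_class(plot_profile(rank_normalize(prof), w), "ggplot")
  res <- run_configuration(data, met_config(region = "up5k", K = 10),
                           list(planted = case$truth$planted_genes))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("the command-line wrapper runs end to end on written fixtures", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  case <- local_case()
  dir <- tempfile()
  files <- write_benchmark_case(case, dir)
  out <- file.path(dir, "results")
  cli <- system.file("cli", "enrich.R", package = "cisenrich")
  expect_true(file.exists(cli))
  status <- system2("Rscript", c(
    cli, "run",
    "--genome", files["genome"], "--genes", files["genes"],
    "--motifs", files["motifs"], "--user-sets", files["user_set"],
    "--region", "up5k", "--norm", "standard", "--K", "10",
    "--max-p", "1", "--out", out),
    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "summary.tsv")))
  smry <- readr::read_tsv(file.path(out, "summary.tsv"), show_col_types = FALSE)
  expect_equal(smry$n_tests, 3)
})
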