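test_that("fixture generation is valid, complete and byte-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixtures(d1, n_patterns = 4, seed = 99)
  generate_fixtures(d2, n_patterns = 4, seed = 99)
  for (m in c("csr", "border_attraction", "border_repulsion")) {
    fs <- list.files(file.path(d1, m), pattern = "\\.csv$")
    expect_length(fs, 4)
    for (f in fs) {
      pat <- read_pattern(file.path(d1, m, f))
      expect_equal(nrow(pat$centers), 10)
      expect_equal(pat$radii, rep(5, 10))
      expect_equal(pat$domain$radius, 30)
      expect_equal(nrow(validate_pattern(pat)), 0)
      expect_identical(readLines(file.path(d1, m, f)),
                       readLines(file.path(d2, m, f)))
    }
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("fixture masks round-trip through extract_pattern", {
  d <- withr::local_tempdir()
  generate_fixtures(d, n_patterns = 1, seed = 5, with_masks = TRUE)
  f <- file.path(d, "csr")
  pat <- read_pattern(file.path(f, "pattern_001.csv"))
  mask <- read_mask_tiff(file.path(f, "pattern_001_mask.tif"))
  labs <- read_labels_tiff(file.path(f, "pattern_001_labels.tif"))
  res <- extract_pattern(mask, labs, c(1, 1, 1))
  o <- match(pat$labels, res$pattern$labels)
  ## grid origin offset: bbox lower corner minus one voxel
  off <- -30 - 1
  rec <- res$pattern$centers + off
  expect_lt(max(abs(rec[o, ] - pat$centers)), 1)
  expect_lt(max(abs(res$pattern$radii[o] / pat$radii - 1)), 0.1)
})

test_that("run_full_analysis produces a complete deterministic report", {
  set.seed(61)
  d <- domain_sphere(30)
  pats <- lapply(1:10, function(i) simulate_csr(d, rep(5, 10)))
  rep1 <- run_full_analysis(pats, models = "csr", descriptors = c("G", "B"),
                            n_sim1 = 19, n_sim2 = 19, L = 500, seed = 8)
  rep2 <- run_full_analysis(pats, models = "csr", descriptors = c("G", "B"),
                            n_sim1 = 19, n_sim2 = 19, L = 500, seed = 8)
  expect_identical(rep1$sdi, rep2$sdi)
  expect_equal(nrow(rep1$uniformity), 2)
  expect_equal(nrow(rep1$distances), 3)
  expect_true(all(rep1$sdi$csr$sdi >= 0 & rep1$sdi$csr$sdi <= 1))
  ## output files
  out <- withr::local_tempdir()
  run_full_analysis(pats, models = "csr", descriptors = "B",
                    n_sim1 = 9, n_sim2 = 9, L = 500, seed = 8,
                    out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("sdi_csr.csv", "uniformity.csv", "mean_distances.csv",
           "manifest.json")))))
  expect_error(run_full_analysis(withr::local_tempdir()), "no pattern")
})

test_that("the command-line dispatcher wires the subcommands together", {
  dir <- withr::local_tempdir()
  expect_equal(sdi_cli(character(0)), 1L)
  expect_equal(sdi_cli("no-such-subcommand"), 1L)
  ## simulate -> describe -> sdi
  simdir <- file.path(dir, "sims")
  expect_equal(sdi_cli(c("simulate", "--model", "csr", "--domain",
                         "sphere:30", "--radii",
                         "5,5,5,5,5,5,5,5,5,5", "--n", "2",
                         "--seed", "3", "--out", simdir)), 0L)
  expect_length(list.files(simdir, pattern = "\\.csv$"), 2)
  desc <- file.path(dir, "desc.csv")
  expect_equal(sdi_cli(c("describe", "--pattern",
                         file.path(simdir, "pattern_001.csv"),
                         "--out", desc, "--L", "500", "--seed", "1")), 0L)
  tab <- read.csv(desc)
  expect_setequal(unique(tab$descriptor), c("F", "G", "H", "B", "C", "Z"))
  sj <- file.path(dir, "sdi.json")
  expect_equal(sdi_cli(c("sdi", "--pattern",
                         file.path(simdir, "pattern_001.csv"),
                         "--model", "csr", "--descriptors", "G,B",
                         "--nsim", "19", "--L", "500", "--seed", "2",
                         "--out", sj)), 0L)
  res <- jsonlite::read_json(sj)
  expect_length(res$results, 2)
  expect_true(res$results[[1]]$sdi >= 0 && res$results[[1]]$sdi <= 1)
  ## user error surfaces as status 1, not an R error
  expect_equal(sdi_cli(c("describe", "--pattern", "missing.csv",
                         "--out", desc)), 1L)
})
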