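test_that("extract_pattern computes centroid/volume/radius from one voxel", {
  mask <- array(TRUE, c(9, 9, 9))
  labs <- array(0L, c(9, 9, 9))
  labs[5, 5, 5] <- 1L                 # 0-based voxel index (4,4,4)
  res <- extract_pattern(mask, labs, c(1, 1, 1))
  expect_equal(res$pattern$centers, matrix(c(4.5, 4.5, 4.5), 1))
  expect_equal(res$morphology$objects$volume, 1)
  expect_equal(res$morphology$objects$radius, (3 / (4 * pi))^(1 / 3),
               tolerance = 1e-9)
})

test_that("rasterize / extract round trip recovers the pattern", {
  set.seed(21)
  pat <- simulate_csr(domain_sphere(20), c(8, 4, 3))
  ras <- rasterize_pattern(pat, c(1, 1, 1))
  res <- extract_pattern(ras$nucleus, ras$labels, ras$spacing)
  ## map back to the pattern frame
  rec <- sweep(res$pattern$centers, 2, -ras$offset)
  o <- match(pat$labels, res$pattern$labels)
  expect_lt(max(abs(rec[o, ] - pat$centers)), 1)       # within one voxel
  expect_lt(max(abs(res$pattern$radii[o] / pat$radii - 1)), 0.1)
  expect_true(all(res$morphology$objects$sphericity > 0.9))
  expect_true(all(res$morphology$objects$sphericity <= 1.01))
  ## label voxel count of the largest object close to its sphere volume
  expect_equal(sum(ras$labels == 1L), 4 / 3 * pi * 8^3, tolerance = 0.1)
})

test_that("touching labels yield a violation report, not an error", {
  mask <- array(TRUE, c(12, 12, 12))
  labs <- array(0L, dim(mask))
  labs[3:5, 3:5, 3:5] <- 1L
  labs[6:8, 3:5, 3:5] <- 2L           # shares a face with label 1
  res <- extract_pattern(mask, labs, c(1, 1, 1))
  expect_gt(nrow(res$violations), 0)
  expect_true(any(res$violations$type == "pair"))
  expect_error(extract_pattern(array(FALSE, dim(mask)), labs, c(1, 1, 1)),
               "outside")
})

test_that("validate_pattern measures violation magnitudes; contact allowed", {
  d <- domain_sphere(50)
  two <- function(gap) object_pattern(
    d, rbind(c(-1 - gap / 2, 0, 0), c(1 + gap / 2, 0, 0)), c(1, 1),
    validate = FALSE)
  expect_equal(nrow(validate_pattern(two(0))), 0)      # touching is legal
  v <- validate_pattern(two(-0.1))
  expect_equal(v$type, "pair")
  expect_equal(v$magnitude, 0.1, tolerance = 1e-9)
  vc <- validate_pattern(object_pattern(domain_sphere(10),
                                        matrix(c(0, 0, 9.5), 1), 1,
                                        validate = FALSE))
  expect_equal(vc$type, "containment")
  expect_equal(vc$magnitude, 0.5, tolerance = 1e-9)
})

test_that("pattern files round-trip losslessly with their domain", {
  dir <- withr::local_tempdir()
  set.seed(33)
  pat <- simulate_csr(domain_sphere(30), rep(5, 6))
  pat$metadata <- list(source = "unit-test", spacing = c(1, 1, 1))
  f <- file.path(dir, "p.csv")
  write_pattern(pat, f)
  back <- read_pattern(f)
  expect_equal(back$centers, pat$centers, tolerance = 1e-11)
  expect_equal(back$radii, pat$radii)
  expect_equal(back$labels, pat$labels)
  expect_equal(back$domain$radius, 30)
  expect_equal(back$metadata$source, "unit-test")
  ## empty pattern round trip
  e <- object_pattern(domain_sphere(5), NULL, numeric(0))
  fe <- file.path(dir, "empty.csv")
  write_pattern(e, fe)
  expect_equal(nrow(read_pattern(fe)$centers), 0)
  ## malformed file: negative radius
  bad <- file.path(dir, "bad.csv")
  writeLines(c("label,x,y,z,radius", "1,0,0,0,-2"), bad)
  file.copy(file.path(dir, "p.json"), file.path(dir, "bad.json"))
  expect_error(read_pattern(bad), "radius")
  ## mesh-domain sidecar
  pm <- object_pattern(make_icosphere(R = 8, subdiv = 2),
                       matrix(c(0, 0, 0), 1), 1)
  fm <- file.path(dir, "mesh.csv")
  write_pattern(pm, fm)
  bm <- read_pattern(fm)
  expect_equal(bm$domain$vertices, pm$domain$vertices, tolerance = 1e-9)
})

test_that("TIFF stacks round-trip masks and labels", {
  dir <- withr::local_tempdir()
  m <- make_ball_mask(4)
  f <- file.path(dir, "m.tif")
  write_mask_tiff(m, f)
  expect_identical(read_mask_tiff(f), m)
  labs <- array(0L, dim(m)); labs[m] <- 3L
  fl <- file.path(dir, "l.tif")
  write_labels_tiff(labs, fl)
  expect_identical(read_labels_tiff(fl), labs)
})

test_that("extraction is translation-equivariant in whole voxels", {
  m1 <- make_ball_mask(5, margin = 6)
  m2 <- make_ball_mask(5, margin = 6, center_offset = c(2, -1, 3))
  l1 <- array(0L, dim(m1)); l1[m1] <- 1L
  l2 <- array(0L, dim(m2)); l2[m2] <- 1L
  r1 <- extract_pattern(m1, l1, c(0.5, 0.5, 2))
  r2 <- extract_pattern(m2, l2, c(0.5, 0.5, 2))
  expect_equal(r2$pattern$centers - r1$pattern$centers,
               matrix(c(2, -1, 3) * c(0.5, 0.5, 2), 1))
  expect_equal(r1$pattern$radii, r2$pattern$radii)
})
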