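test_that("estimators reproduce hand-computed examples", {
  d <- domain_sphere(100)
  ## F with two positions around an object at the origin
  p1 <- object_pattern(d, matrix(0, 1, 3), 1)
  f <- estimate_F(p1, rbind(c(1, 0, 0), c(2, 0, 0)))
  expect_equal(eval_cdf(f, 1.5), 0.5)
  expect_equal(eval_cdf(f, 2.5), 1)
  expect_equal(eval_cdf(f, 1), 0)      # strict inequality at a jump
  ## three collinear centroids at 0, 1, 3
  p3 <- object_pattern(d, cbind(c(0, 1, 3), 0, 0), rep(0.1, 3))
  ghz <- estimate_pairwise(p3)
  expect_equal(ghz$G$x, c(1, 2)); expect_equal(ghz$G$w, c(2 / 3, 1 / 3))
  expect_equal(ghz$H$x, c(1, 2, 3)); expect_equal(ghz$H$w, rep(1 / 3, 3))
  expect_equal(ghz$Z$x, c(2, 3)); expect_equal(ghz$Z$w, c(1 / 3, 2 / 3))
  sd3 <- summary_distances(p3)
  expect_equal(sd3$mean_nn, 4 / 3)
  expect_equal(sd3$mean_pair, 2)
  expect_equal(sd3$mean_far, 8 / 3)
  ## equilateral triangle: all three summaries equal the side
  s <- 2.5
  tri <- object_pattern(d, rbind(c(0, 0, 0), c(s, 0, 0),
                                 c(s / 2, s * sqrt(3) / 2, 0)), rep(0.1, 3))
  expect_equal(unlist(summary_distances(tri)), c(s, s, s),
               ignore_attr = TRUE)
  expect_equal(pattern_energy(tri), -s)
  ## B and C in a sphere
  d10 <- domain_sphere(10)
  pb <- object_pattern(d10, matrix(c(0, 0, 4), 1), 1)
  bc <- estimate_boundary(pb)
  expect_equal(bc$B$x, 6)
  expect_equal(bc$C$x, 4)
  ctr <- object_pattern(d10, matrix(0, 1, 3), 1)
  bc2 <- estimate_boundary(ctr)
  expect_equal(bc2$B$x, 10); expect_equal(bc2$C$x, 0)
})

test_that("evaluation follows the strict-inequality step convention", {
  f <- sdi3d:::.dist_cdf("G", 2)
  expect_equal(eval_cdf(f, 2), 0)
  expect_equal(eval_cdf(f, 2.001), 1)
  expect_equal(eval_cdf(f, 1.999), 0)
  g <- sdi3d:::.dist_cdf("H", c(1, 1, 3))
  expect_equal(eval_cdf(g, c(1, 2, 3, 4)), c(0, 2 / 3, 2 / 3, 1))
  expect_equal(g$cum, c(2 / 3, 1))
})

test_that("all six estimators agree with a brute-force oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:15, 1)
    pat <- random_pattern(domain_sphere(30), n)
    pos <- eval_positions(pat$domain, 150)
    est <- estimate_descriptors(pat, positions = pos)
    oracle <- oracle_eval(pat, pos)
    ## probe off the jumps: the two routes compute identical distances only
    ## up to round-off, so probing exactly at a jump is ill-posed
    probe <- sort(c(runif(15, 0, 70), est$H$x + 1e-7, est$H$x - 1e-7))
    for (id in c("F", "G", "H", "B", "C", "Z"))
      expect_equal(eval_cdf(est[[id]], probe), oracle(id, probe),
                   tolerance = 1e-12)
  }
})

test_that("Z <= H <= G pointwise (sandwich property)", {
  set.seed(18)
  for (rep in 1:40) {
    pat <- random_pattern(domain_sphere(25), sample(2:12, 1))
    est <- estimate_pairwise(pat)
    x <- sort(unique(c(est$G$x, est$H$x, est$Z$x)))
    x <- c(x, x + 1e-9)
    expect_true(all(eval_cdf(est$Z, x) <= eval_cdf(est$H, x) + 1e-12))
    expect_true(all(eval_cdf(est$H, x) <= eval_cdf(est$G, x) + 1e-12))
  }
})

test_that("pairwise descriptors are rigid-rotation invariant", {
  set.seed(19)
  pat <- random_pattern(domain_sphere(20), 8)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- object_pattern(pat$domain, pat$centers %*% t(Rz), pat$radii,
                        validate = FALSE)
  a <- estimate_pairwise(pat); b <- estimate_pairwise(rot)
  for (id in c("G", "H", "Z")) expect_equal(a[[id]]$x, b[[id]]$x)
  ## F invariant when positions rotate jointly
  pos <- eval_positions(pat$domain, 300, seed = 5)
  fa <- estimate_F(pat, pos)
  fb <- estimate_F(rot, pos %*% t(Rz))
  expect_equal(fa$x, fb$x)
})

test_that("B and C mirror each other in a sphere", {
  ## distance to border = R - distance to centre, so
  ## B(x) = 1 - lim_{y -> (R - x)^-} C(y)
  set.seed(20)
  R <- 15
  pat <- random_pattern(domain_sphere(R), 9)
  bc <- estimate_boundary(pat)
  x <- seq(0.5, R - 0.5, by = 0.5)
  lhs <- eval_cdf(bc$B, x)
  rhs <- 1 - sdi3d:::.eval_cdf_right(bc$C, R - x)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("eval_positions validates its inputs and is reproducible", {
  d <- domain_sphere(5)
  expect_error(eval_positions(d, 50), "at least 100")
  a <- eval_positions(d, 200, seed = 3)
  b <- eval_positions(d, 200, seed = 3)
  expect_identical(a, b)
  expect_equal(attr(a, "provenance"), "random_uniform")
  md <- domain_mask(make_ball_mask(6), c(1, 1, 1))
  v <- eval_positions(md, method = "voxel")
  expect_equal(nrow(v), sum(md$mask))
  expect_equal(attr(v, "provenance"), "voxel_centers")
  expect_error(estimate_F(object_pattern(d, NULL, numeric(0)), a),
               "empty pattern")
})
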