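test_that("sphere boundary queries match closed forms", {
  d <- domain_sphere(10)
  expect_equal(boundary_distance(d, c(0, 0, 4)), 6)
  expect_equal(boundary_distance(d, c(0, 0, 0)), 10)
  expect_equal(boundary_nearest(d, c(0, 0, 4)), matrix(c(0, 0, 10), 1))
  ## centre tie broken deterministically
  q <- boundary_nearest(d, c(0, 0, 0))
  expect_equal(sqrt(sum(q^2)), 10)
  expect_equal(q, boundary_nearest(d, c(0, 0, 0)))
  expect_error(boundary_distance(d, c(0, 0, 11)), "outside")
  ## off-centre sphere
  d2 <- domain_sphere(5, center = c(1, 2, 3))
  expect_equal(domain_centroid(d2), c(1, 2, 3))
  expect_equal(boundary_distance(d2, c(1, 2, 3)), 5)
})

test_that("distance + norm identity and nearest-point consistency hold", {
  set.seed(5)
  d <- domain_sphere(10)
  p <- runif_domain(200, d)
  expect_equal(boundary_distance(d, p) + sqrt(rowSums(p^2)),
               rep(10, 200))
  q <- boundary_nearest(d, p)
  expect_equal(sqrt(rowSums((p - q)^2)), boundary_distance(d, p),
               tolerance = 1e-9)
  ## ellipsoid: same consistency, plus an independent dense-surface check
  e <- domain_ellipsoid(c(4, 3, 2))
  pe <- runif_domain(20, e)
  bd <- boundary_distance(e, pe)
  qe <- boundary_nearest(e, pe)
  expect_equal(sqrt(rowSums((pe - qe)^2)), bd, tolerance = 1e-9)
  ## surface points satisfy the ellipsoid equation
  expect_equal(rowSums(sweep(qe, 2, c(4, 3, 2), "/")^2), rep(1, 20),
               tolerance = 1e-7)
  ## oracle: min distance over a dense parametric surface grid
  th <- seq(0, pi, length.out = 180)
  ph <- seq(0, 2 * pi, length.out = 360)
  g <- expand.grid(th = th, ph = ph)
  surf <- cbind(4 * sin(g$th) * cos(g$ph), 3 * sin(g$th) * sin(g$ph),
                2 * cos(g$th))
  for (i in 1:5) {
    dd <- min(sqrt(rowSums(sweep(surf, 2, pe[i, ])^2)))
    expect_lt(abs(bd[i] - dd), 5e-3)     # grid discretization slack
    expect_lte(bd[i], dd + 1e-9)         # true distance is a lower bound
  }
})

test_that("contains_sphere allows boundary contact", {
  d <- domain_sphere(10)
  expect_true(contains_sphere(d, c(0, 0, 4), 6))
  expect_false(contains_sphere(d, c(0, 0, 4), 6.01))
  expect_false(contains_sphere(d, c(0, 0, 12), 1))
})

test_that("uniform sampling matches ball moments and radial law", {
  set.seed(9)
  d <- domain_sphere(1)
  p <- runif_domain(1e5, d)
  r <- sqrt(rowSums(p^2))
  ## E||p|| = 3R/4 for the uniform unit ball
  expect_lt(abs(mean(r) - 3 / 4), 3 * sd(r) / sqrt(1e5))
  expect_lt(abs(mean(r > 0.5) - 7 / 8), 3 * sqrt(7 / 8 * 1 / 8 / 1e5))
  ## chi-square on the radial CDF r^3 (10 equiprobable shells)
  br <- (seq(0, 1, by = 0.1))^(1 / 3)
  cnt <- table(cut(r[1:10000], br))
  chi <- sum((cnt - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 9))
  ## determinism
  set.seed(4); a <- runif_domain(10, d)
  set.seed(4); b <- runif_domain(10, d)
  expect_identical(a, b)
})

test_that("mesh domains reproduce analytic sphere geometry", {
  ico <- make_icosphere(R = 10, subdiv = 4)   # 2562 vertices
  expect_equal(nrow(ico$vertices), 2562)
  expect_equal(domain_volume(ico), 4 / 3 * pi * 1000, tolerance = 0.01)
  expect_equal(domain_centroid(ico), c(0, 0, 0), tolerance = 1e-9)
  set.seed(2)
  p <- runif_domain(20, domain_sphere(9.9))
  bd <- boundary_distance(ico, p)
  ## matches the analytic distance within the mesh chord error (0.5% of R)
  expect_lt(max(abs(bd - (10 - sqrt(rowSums(p^2))))), 0.005 * 10)
  ## nearest point lies on a mesh triangle (barycentric residual ~ 0)
  q <- boundary_nearest(ico, p[1:5, ])
  for (i in 1:5) {
    dmin <- min(sqrt(rowSums((ico$vertices - matrix(q[i, ], nrow(ico$vertices),
                                                    3, byrow = TRUE))^2)))
    expect_lt(dmin, 0.6)  # within a chord of some vertex
  }
  ## containment: inside / outside points classified correctly
  expect_true(all(contains_point(ico, p)))
  expect_false(any(contains_point(ico, p + 25)))
})

test_that("box mesh has exact centroid and volume", {
  v <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  box <- domain_mesh(v, f)
  expect_equal(domain_volume(box), 8)
  expect_equal(domain_centroid(box), c(1, 1, 1))
  expect_equal(boundary_distance(box, c(1, 1, 1)), 1)
  expect_error(domain_mesh(v, f[-1, ]), "watertight")
})

test_that("mask domains answer containment and metric queries", {
  m <- make_ball_mask(8)
  d <- domain_mask(m, c(1, 1, 1))
  ctr <- c(11, 11, 11)                 # true ball centre in physical units
  expect_true(contains_point(d, ctr))
  expect_false(contains_point(d, c(1, 1, 1)))
  expect_equal(domain_volume(d), sum(m))
  expect_lt(max(abs(domain_centroid(d) - ctr)), 0.5)
  expect_equal(boundary_distance(d, ctr)[1], 8, tolerance = 0.1)
  set.seed(1)
  p <- runif_domain(50, d)
  expect_true(all(contains_point(d, p)))
})
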