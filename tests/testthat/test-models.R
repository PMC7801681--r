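test_that("csr with one object is uniform in the eroded ball", {
  set.seed(31)
  R <- 10; r <- 3
  d <- domain_sphere(R)
  cen <- t(vapply(1:4000, function(i)
    simulate_csr(d, r)$centers[1, ], numeric(3)))
  rr <- sqrt(rowSums(cen^2))
  ## mean distance to centre = 3(R - r)/4 under uniformity in radius R - r
  expect_lt(abs(mean(rr) - 3 * (R - r) / 4), 3 * sd(rr) / sqrt(4000))
  expect_lte(max(rr), R - r)
})

test_that("csr detects infeasible packings", {
  ## two unit spheres in R = 1.9: centres confined to a 0.9-ball but must
  ## be >= 2 apart
  expect_error(simulate_csr(domain_sphere(1.9), c(1, 1),
                            restart_threshold = 40, max_restarts = 4),
               "infeasible")
  expect_error(simulate_csr(domain_sphere(2), c(2.5)), "infeasible")
})

test_that("every simulator output satisfies the constraints", {
  set.seed(32)
  d <- domain_sphere(30)
  r <- rep(5, 10)
  specs <- list(
    model_spec("csr", r),
    model_spec("border_attraction", r, mu = 5, sigma = 5),
    model_spec("border_repulsion", r, mu = 15, sigma = 5),
    model_spec("orbital", r, orbits = runif(10, 5, 20)),
    model_spec("max_repulsion", r),
    model_spec("orbital_max_repulsion", r, orbits = runif(10, 5, 20)))
  for (sp in specs) for (k in 1:3) {
    pat <- simulate_model(d, sp)
    expect_equal(nrow(validate_pattern(pat)), 0, info = sp$model)
  }
})

test_that("border attraction reduces and repulsion increases border gaps", {
  set.seed(33)
  d <- domain_sphere(30)
  r <- rep(5, 10)
  mb <- function(pat) mean(boundary_distance(d, pat$centers))
  csr <- replicate(200, mb(simulate_csr(d, r)))
  att <- replicate(200, mb(simulate_border_biased(d, r, "attraction",
                                                  mu = 5, sigma = 5)))
  rep_ <- replicate(200, mb(simulate_border_biased(d, r, "repulsion",
                                                   mu = 15, sigma = 5)))
  expect_lt(wilcox.test(att, csr, alternative = "less")$p.value, 1e-3)
  expect_lt(wilcox.test(rep_, csr, alternative = "greater")$p.value, 1e-3)
})

test_that("attraction with mu >= R reduces to csr", {
  ## every candidate is then on the favoured side, acceptance always 1
  set.seed(34)
  d <- domain_sphere(10)
  pat <- simulate_border_biased(d, c(2, 2), "attraction", mu = 10, sigma = 1)
  expect_equal(nrow(validate_pattern(pat)), 0)
  ## distributional check: mean centre distance matches csr over replicates
  a <- replicate(400, mean(sqrt(rowSums(
    simulate_border_biased(d, c(2, 2), "attraction", mu = 10,
                           sigma = 1)$centers^2))))
  b <- replicate(400, mean(sqrt(rowSums(simulate_csr(d, c(2, 2))$centers^2))))
  expect_gt(wilcox.test(a, b)$p.value, 1e-4)
})

test_that("orbital placement hits the orbit and detects empty orbits", {
  set.seed(35)
  d <- domain_sphere(10)
  pat <- simulate_orbital(d, 2, 4)
  expect_equal(sqrt(sum(pat$centers^2)), 6, tolerance = 1e-9)
  ## direction uniform on the shell: mean unit vector near 0
  u <- t(vapply(1:2000, function(i)
    simulate_orbital(d, 2, 4)$centers[1, ] / 6, numeric(3)))
  expect_lt(max(abs(colMeans(u))), 3 / sqrt(2000 / 3))
  expect_error(simulate_orbital(d, 2, 10.5), "orbit")
  expect_error(simulate_orbital(d, 2, 1), "radius")
  ## conditioning on measured boundary distances reproduces B exactly
  base <- simulate_csr(d, rep(1, 5))
  orb <- boundary_distance(d, base$centers)
  sim <- simulate_orbital(d, rep(1, 5), orb)
  expect_equal(sort(estimate_boundary(sim)$B$x),
               sort(estimate_boundary(base)$B$x), tolerance = 1e-9)
})

test_that("orbital sampling works on mesh domains by rejection", {
  set.seed(36)
  ico <- make_icosphere(R = 10, subdiv = 3)
  pat <- simulate_orbital(ico, c(1, 1), c(3, 5), orbit_tol = 0.05)
  bd <- boundary_distance(ico, pat$centers)
  expect_lt(max(abs(sort(bd) - c(3, 5))), 0.05 + 1e-9)
})

test_that("pattern energy matches hand calculations", {
  d <- domain_sphere(100)
  two <- object_pattern(d, rbind(c(0, 0, 0), c(3, 0, 0)), c(1, 1))
  expect_equal(pattern_energy(two), -3)
  coll <- object_pattern(d, cbind(c(0, 1, 3), 0, 0), rep(0.1, 3))
  expect_equal(pattern_energy(coll), -4 / 3)
  expect_error(pattern_energy(object_pattern(d, matrix(0, 1, 3), 1)),
               "at least 2")
})

test_that("annealing reaches the two-object antipodal optimum", {
  set.seed(37)
  R <- 30; r <- 5
  d <- domain_sphere(R)
  fit <- maximize_repulsion(simulate_csr(d, c(r, r)))
  expect_equal(-fit$energy, 2 * (R - r), tolerance = 0.02)
  expect_lte(fit$energy, fit$initial_energy)
})

test_that("annealing traces are valid and constraints are preserved", {
  set.seed(38)
  d <- domain_sphere(30)
  for (k in 1:5) {
    init <- simulate_csr(d, rep(5, 10))
    fit <- maximize_repulsion(init)
    expect_lte(fit$energy, fit$initial_energy)
    expect_true(all(diff(fit$trace$best) <= 1e-12))  # best nonincreasing
    expect_equal(fit$energy, min(fit$trace$best))
    expect_equal(nrow(validate_pattern(fit$pattern)), 0)
  }
  ## orbit-constrained annealing preserves boundary distances
  orb <- runif(10, 5, 20)
  init <- simulate_orbital(d, rep(5, 10), orb)
  fit <- maximize_repulsion(init, on_orbits = TRUE)
  expect_lt(max(abs(boundary_distance(d, fit$pattern$centers) -
                      boundary_distance(d, init$centers))), 1e-9)
  expect_lte(fit$energy, fit$initial_energy)
})

test_that("annealing on a mesh domain uses the general-path sampler", {
  set.seed(39)
  ico <- make_icosphere(R = 12, subdiv = 2)
  init <- simulate_csr(ico, c(2, 2, 2))
  fit <- maximize_repulsion(init, control = list(max_moves = 600,
                                                 window = 100))
  expect_lte(fit$energy, fit$initial_energy)
  expect_equal(nrow(validate_pattern(fit$pattern)), 0)
})

test_that("annealed configurations are lower-energy than csr draws", {
  set.seed(40)
  d <- domain_sphere(30)
  r <- rep(5, 10)
  e_csr <- replicate(40, pattern_energy(simulate_csr(d, r)))
  e_max <- replicate(40, maximize_repulsion(simulate_csr(d, r))$energy)
  expect_lt(wilcox.test(e_max, e_csr, alternative = "less")$p.value, 1e-3)
})
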