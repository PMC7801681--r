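#' Spatial model specifications
#'
#' A `model_spec` bundles the parameters of one of the six spatial models,
#' all conditioned on the object radii (and, for orbital variants, on the
#' per-object orbit distances measured on an observed pattern):
#' \describe{
#'   \item{csr}{completely random hard-sphere packing: objects inserted
#'     sequentially at uniform positions subject to non-overlap and
#'     containment.}
#'   \item{border_attraction / border_repulsion}{as csr, but a valid
#'     candidate at boundary distance `d` is accepted with probability 1 on
#'     the favoured side of `mu` and `exp(-((d - mu) / sigma)^2 / 2)`
#'     otherwise.}
#'   \item{orbital}{each object uniform on its orbit, the iso-surface of its
#'     fixed distance to the domain boundary.}
#'   \item{max_repulsion / orbital_max_repulsion}{the configuration
#'     minimizing the energy `E = -(1/N) sum_i min_j ||p_i - p_j||` found by
#'     Metropolis annealing, started from a csr (resp. orbital) draw; the
#'     orbital variant keeps every boundary distance fixed.}
#' }
#'
#' @param model one of `"csr"`, `"orbital"`, `"max_repulsion"`,
#'   `"orbital_max_repulsion"`, `"border_attraction"`, `"border_repulsion"`.
#' @param radii strictly positive object radii.
#' @param orbits per-object boundary distances (orbital variants), each
#'   `>=` the corresponding radius.
#' @param mu,sigma border-bias parameters (lengths, `> 0`).
#' @param restart_threshold failed placement attempts for one object before
#'   the whole pattern is cleared and the insertion order re-randomized.
#' @param max_restarts global restarts before giving up (packing infeasible).
#' @param orbit_tol tolerance on `|boundary distance - orbit|`; default 1%
#'   of the mean radius.
#' @param anneal optional list overriding the annealing controls
#'   `beta0` (default: calibrated so initial uphill acceptance is about 0.5),
#'   `beta_growth` (1.05 per sweep), `delta0` (mean radius), `window`
#'   (50 N moves), `tol` (1e-4 relative energy change between consecutive
#'   windows), `max_moves` (2000 N), `probe_moves` (100).
#' @return a `model_spec`.
#' @export
model_spec <- function(model = c("csr", "orbital", "max_repulsion",
                                 "orbital_max_repulsion", "border_attraction",
                                 "border_repulsion"),
                       radii, orbits = NULL, mu = NULL, sigma = NULL,
                       restart_threshold = 1000L, max_restarts = 100L,
                       orbit_tol = NULL, anneal = list()) {
  model <- match.arg(model)
  radii <- as.numeric(radii)
  stopifnot(length(radii) >= 1, all(radii > 0))
  orbital <- model %in% c("orbital", "orbital_max_repulsion")
  if (orbital) {
    if (is.null(orbits)) stop("orbital models need per-object orbit distances")
    orbits <- as.numeric(orbits)
    if (length(orbits) != length(radii))
      stop("need one orbit distance per object")
    if (any(orbits < radii - 1e-9 * mean(radii)))
      stop("orbit distances must be >= the corresponding radii")
  }
  if (model %in% c("border_attraction", "border_repulsion")) {
    if (is.null(mu) || is.null(sigma) || mu <= 0 || sigma <= 0)
      stop("border-biased models need mu > 0 and sigma > 0")
  }
  if (is.null(orbit_tol)) orbit_tol <- 0.01 * mean(radii)
  structure(list(model = model, radii = radii, orbits = orbits,
                 mu = mu, sigma = sigma,
                 restart_threshold = as.integer(restart_threshold),
                 max_restarts = as.integer(max_restarts),
                 orbit_tol = orbit_tol, anneal = anneal),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec:", x$model, ">", length(x$radii), "objects\n")
  invisible(x)
}

#' Condition a model on an observed pattern
#'
#' Builds a [model_spec] whose radii (and orbit distances, for orbital
#' variants) are taken from the pattern, as required for the SDI
#' goodness-of-fit test: simulations must share the observed domain, object
#' count and object sizes so that only the organization rule differs.
#'
#' @param pattern an [object_pattern].
#' @param model model id, see [model_spec()].
#' @param ... further arguments passed to [model_spec()] (`mu`, `sigma`,
#'   annealing controls, ...).
#' @export
condition_spec <- function(pattern, model, ...) {
  orbital <- model %in% c("orbital", "orbital_max_repulsion")
  orbits <- NULL
  if (orbital) {
    orbits <- boundary_distance(pattern$domain, pattern$centers)
    orbits <- pmax(orbits, pattern$radii)   # clamp sub-radius measurements
  }
  model_spec(model, radii = pattern$radii, orbits = orbits, ...)
}

## Sequential hard-core insertion with restarts. `gen(i, m)` draws m
## candidate centres for object i; `paccept(i, cand)` returns per-candidate
## acceptance probabilities (NULL = always accept). Only hard-core /
## containment failures count toward the restart threshold.
.place_sequential <- function(domain, radii, gen, paccept,
                              restart_threshold, max_restarts,
                              check_contain = TRUE) {
  n <- length(radii)
  for (restart in 0:max_restarts) {
    ord <- sample.int(n)
    placed <- matrix(NA_real_, n, 3)
    pr <- numeric(0)
    pc <- NULL
    failed <- FALSE
    for (i in ord) {
      fails <- 0L
      found <- FALSE
      while (!found) {
        m <- 16L
        cand <- gen(i, m)
        ok <- if (check_contain) contains_sphere(domain, cand, radii[i])
        else rep(TRUE, nrow(cand))
        if (!is.null(pc) && any(ok)) {
          ci <- which(ok)
          d2 <- outer(rowSums(cand[ci, , drop = FALSE]^2), rowSums(pc^2),
                      "+") - 2 * cand[ci, , drop = FALSE] %*% t(pc)
          rr <- outer(rep(radii[i], length(ci)), pr, "+")
          ok[ci] <- rowSums(d2 < rr^2 - 1e-12) == 0L
        }
        if (!any(ok)) {
          fails <- fails + m
        } else {
          first_ok <- which(ok)[1]
          fails <- fails + sum(!ok[seq_len(first_ok - 1L)])
          sel <- which(ok)
          if (is.null(paccept)) {
            keep <- sel[1]
          } else {
            pa <- paccept(i, cand[sel, , drop = FALSE])
            hit <- which(stats::runif(length(sel)) < pa)
            keep <- if (length(hit)) sel[hit[1]] else NA_integer_
          }
          if (!is.na(keep)) {
            placed[i, ] <- cand[keep, ]
            pc <- placed[!is.na(placed[, 1]), , drop = FALSE]
            pr <- radii[!is.na(placed[, 1])]
            found <- TRUE
          }
        }
        if (!found && fails >= restart_threshold) break
      }
      if (!found) { failed <- TRUE; break }
    }
    if (!failed) return(placed)
  }
  stop("packing infeasible: could not place all objects after ",
       max_restarts + 1, " restart cycles")
}

#' Simulate a completely random hard-sphere pattern
#'
#' Objects are inserted one after the other at positions drawn uniformly
#' over the domain, rejecting candidates that overlap previously placed
#' objects or cross the boundary; when one object accumulates
#' `restart_threshold` failed attempts, the pattern is cleared and the
#' insertion order re-randomized.
#'
#' @param domain a [domain3].
#' @param radii object radii.
#' @inheritParams model_spec
#' @return an [object_pattern].
#' @export
simulate_csr <- function(domain, radii, restart_threshold = 1000L,
                         max_restarts = 100L) {
  .check_radii_feasible(domain, radii)
  gen <- function(i, m) runif_domain(m, domain)
  centers <- .place_sequential(domain, radii, gen, NULL,
                               restart_threshold, max_restarts)
  object_pattern(domain, centers, radii, validate = FALSE)
}

.check_radii_feasible <- function(domain, radii) {
  if (inherits(domain, c("sphere_domain", "ellipsoid_domain")) &&
      any(radii >= domain_inradius(domain)))
    stop("packing infeasible: object radius exceeds the domain inradius")
}

#' Simulate a border-biased hard-sphere pattern
#'
#' As [simulate_csr()], but a hard-core-valid candidate at boundary distance
#' `d` is retained with probability 1 if `d < mu` (attraction mode; `d > mu`
#' for repulsion) and `exp(-((d - mu) / sigma)^2 / 2)` otherwise; rejected
#' candidates are redrawn.
#'
#' @inheritParams simulate_csr
#' @param mode `"attraction"` (toward the boundary) or `"repulsion"`.
#' @param mu distance threshold (length).
#' @param sigma softness of the acceptance fall-off (length).
#' @export
simulate_border_biased <- function(domain, radii,
                                   mode = c("attraction", "repulsion"),
                                   mu, sigma, restart_threshold = 1000L,
                                   max_restarts = 100L) {
  mode <- match.arg(mode)
  stopifnot(mu > 0, sigma > 0)
  .check_radii_feasible(domain, radii)
  gen <- function(i, m) runif_domain(m, domain)
  paccept <- function(i, cand) {
    d <- boundary_distance(domain, cand)
    favoured <- if (mode == "attraction") d < mu else d > mu
    ifelse(favoured, 1, exp(-0.5 * ((d - mu) / sigma)^2))
  }
  centers <- .place_sequential(domain, radii, gen, paccept,
                               restart_threshold, max_restarts)
  object_pattern(domain, centers, radii, validate = FALSE)
}

#' Simulate an orbital hard-sphere pattern
#'
#' Each object is placed uniformly at random on its orbit, the iso-surface
#' of a fixed distance to the domain boundary, subject to the same hard-core
#' constraint and restart machinery as [simulate_csr()]. For spherical
#' domains the orbit is sampled analytically (uniform direction on the
#' concentric shell); for other domains, by rejection from uniform domain
#' points within `orbit_tol` of the target iso-surface.
#'
#' @inheritParams simulate_csr
#' @param orbits per-object centroid-to-boundary distances, each `>=` the
#'   corresponding radius and `<=` the domain inradius.
#' @param orbit_tol iso-surface tolerance for rejection sampling (also the
#'   reported tolerance of the output), default 1% of the mean radius.
#' @export
simulate_orbital <- function(domain, radii, orbits,
                             orbit_tol = 0.01 * mean(radii),
                             restart_threshold = 1000L, max_restarts = 100L) {
  orbits <- as.numeric(orbits)
  stopifnot(length(orbits) == length(radii))
  if (any(orbits < radii - 1e-9 * mean(radii)))
    stop("orbit distance smaller than object radius")
  if (inherits(domain, "sphere_domain")) {
    if (any(orbits > domain$radius))
      stop("empty orbit: orbit distance exceeds the domain inradius")
    gen <- function(i, m) {
      u <- matrix(rnorm(3 * m), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      sweep(u * (domain$radius - orbits[i]), 2, domain$center, "+")
    }
    ## shell radius s = R - orbit guarantees containment when orbit >= r
    centers <- .place_sequential(domain, radii, gen, NULL,
                                 restart_threshold, max_restarts,
                                 check_contain = FALSE)
  } else {
    gen <- function(i, m) {
      out <- matrix(NA_real_, 0, 3)
      tries <- 0L
      while (nrow(out) < m) {
        cand <- runif_domain(512L, domain)
        bd <- boundary_distance(domain, cand)
        hit <- abs(bd - orbits[i]) <= orbit_tol & bd >= radii[i]
        out <- rbind(out, cand[hit, , drop = FALSE])
        tries <- tries + 512L
        if (tries >= 2e5 && nrow(out) == 0L)
          stop("empty orbit: no domain point within orbit_tol of the ",
               "target iso-surface (orbit distance ", orbits[i], ")")
      }
      out[seq_len(m), , drop = FALSE]
    }
    centers <- .place_sequential(domain, radii, gen, NULL,
                                 restart_threshold, max_restarts,
                                 check_contain = FALSE)
  }
  object_pattern(domain, centers, radii, validate = FALSE)
}

#' Configuration energy of a pattern
#'
#' `E = -(1/N) sum_i min_{j != i} ||p_i - p_j||`, the negative mean
#' nearest-neighbour distance; lower energy means stronger mutual repulsion.
#'
#' @param pattern an [object_pattern] with `N >= 2`.
#' @return a (negative) length.
#' @export
pattern_energy <- function(pattern) {
  n <- nrow(pattern$centers)
  if (n < 2) stop("energy needs at least 2 objects")
  dm <- as.matrix(stats::dist(pattern$centers))
  diag(dm) <- NA
  -mean(apply(dm, 1, min, na.rm = TRUE))
}

#' Anneal a pattern toward maximal repulsion
#'
#' Runs Metropolis simulated annealing on the configuration energy
#' (negative mean nearest-neighbour distance): one object at a time is
#' displaced uniformly within a ball of adaptive radius, moves that violate
#' the hard-core or containment constraints count as rejections, downhill
#' moves are always accepted and uphill moves with probability
#' `exp(-beta dE)` under a geometric beta schedule. The best-visited
#' configuration is returned. With `on_orbits = TRUE`, each displacement is
#' projected back onto the object's boundary-distance iso-surface, so orbit
#' distances are preserved.
#'
#' Termination ("stabilization of energy") is operationalized as a relative
#' mean-energy change below `tol` between consecutive windows of `50 N`
#' proposed moves, with a hard cap of `2000 N` moves; non-convergence within
#' the cap is reported, not raised.
#'
#' @param initial a valid [object_pattern] (for `on_orbits = TRUE`, its
#'   boundary distances define the orbits).
#' @param on_orbits keep each object's boundary distance fixed.
#' @param control list of annealing controls, see [model_spec()].
#' @return an object of class `maxrep_fit`: list with `pattern` (best
#'   configuration), `energy`, `initial_energy`, `trace` (per-window mean /
#'   best energy and acceptance fraction), `converged`, `moves`.
#' @export
maximize_repulsion <- function(initial, on_orbits = FALSE, control = list()) {
  stopifnot(inherits(initial, "object_pattern"))
  n <- nrow(initial$centers)
  if (n < 2) stop("maximal repulsion needs at least 2 objects")
  ctl <- utils::modifyList(list(beta0 = -1, beta_growth = 1.05,
                                delta0 = mean(initial$radii),
                                window = 50L * n, tol = 1e-4,
                                max_moves = 2000L * n, probe_moves = 100L),
                           control)
  domain <- initial$domain
  orbits <- if (on_orbits)
    boundary_distance(domain, initial$centers) else numeric(n)
  E0 <- pattern_energy(initial)
  if (inherits(domain, "sphere_domain")) {
    res <- .mh_maxrep_sphere(initial$centers, initial$radii, domain$center,
                             domain$radius, on_orbits, orbits,
                             ctl$beta0, ctl$beta_growth, ctl$delta0,
                             as.integer(ctl$window), ctl$tol,
                             as.integer(ctl$max_moves),
                             as.integer(ctl$probe_moves))
  } else {
    res <- .mh_maxrep_general(initial, on_orbits, orbits, ctl)
  }
  pat <- object_pattern(domain, res$centers, initial$radii,
                        labels = initial$labels, metadata = initial$metadata,
                        validate = FALSE)
  structure(list(pattern = pat, energy = res$energy, initial_energy = E0,
                 trace = data.frame(window = seq_along(res$trace_energy),
                                    energy = res$trace_energy,
                                    best = res$trace_best,
                                    accept = res$trace_accept),
                 converged = res$converged, moves = res$moves),
            class = "maxrep_fit")
}

#' @export
print.maxrep_fit <- function(x, ...) {
  cat("<maxrep_fit> energy", format(x$initial_energy), "->",
      format(x$energy), if (x$converged) "(converged)" else
        "(move budget exhausted)", "\n")
  invisible(x)
}

#' @export
plot.maxrep_fit <- function(x, ...) {
  graphics::plot(x$trace$window, x$trace$energy, type = "l",
                 xlab = "window", ylab = "energy", ...)
  graphics::lines(x$trace$window, x$trace$best, lty = 2)
  graphics::legend("topright", c("window mean", "best visited"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

## R fallback annealer for non-spherical domains; same scheme as the C++
## sphere path, with iso-surface projection along the boundary-distance
## gradient for orbit-constrained moves.
.mh_maxrep_general <- function(initial, on_orbits, orbits, ctl) {
  domain <- initial$domain
  P <- initial$centers
  radii <- initial$radii
  n <- nrow(P)
  orbit_tol <- 0.01 * mean(radii)
  E <- pattern_energy(initial)
  best <- P; bestE <- E
  energy_of <- function(M) {
    dm <- as.matrix(stats::dist(M)); diag(dm) <- NA
    -mean(apply(dm, 1, min, na.rm = TRUE))
  }
  project_orbit <- function(p, target) {
    for (k in 1:5) {
      if (!contains_point(domain, matrix(p, 1))) return(NULL)
      bd <- boundary_distance(domain, matrix(p, 1))
      if (abs(bd - target) <= orbit_tol) return(p)
      q <- boundary_nearest(domain, matrix(p, 1))[1, ]
      g <- (p - q) / max(bd, 1e-12)
      p <- p + (target - bd) * g
    }
    NULL
  }
  valid <- function(p, i) {
    if (!all(contains_sphere(domain, matrix(p, 1), radii[i]))) return(FALSE)
    if (n > 1) {
      d <- sqrt(colSums((t(P[-i, , drop = FALSE]) - p)^2))
      if (any(d < radii[-i] + radii[i] - 1e-12)) return(FALSE)
    }
    TRUE
  }
  delta <- ctl$delta0
  ## probe calibration
  beta <- ctl$beta0
  if (beta <= 0) {
    up <- numeric(0)
    for (t in seq_len(ctl$probe_moves)) {
      i <- sample.int(n, 1)
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3) * delta
      cand <- P[i, ] + u
      if (on_orbits) cand <- project_orbit(cand, orbits[i])
      if (is.null(cand) || !valid(cand, i)) next
      M <- P; M[i, ] <- cand
      dE <- energy_of(M) - E
      if (dE > 0) up <- c(up, dE)
    }
    beta <- if (length(up)) log(2) / stats::median(up) else 1
  }
  tr_e <- tr_b <- tr_a <- numeric(0)
  moves <- 0L; win_cnt <- 0L; win_acc <- 0L; win_sum <- 0
  prev_mean <- Inf; converged <- FALSE
  while (moves < ctl$max_moves) {
    i <- sample.int(n, 1)
    moves <- moves + 1L; win_cnt <- win_cnt + 1L
    u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3) * delta
    cand <- P[i, ] + u
    if (on_orbits && !is.null(cand)) cand <- project_orbit(cand, orbits[i])
    acc <- FALSE
    if (!is.null(cand) && valid(cand, i)) {
      M <- P; M[i, ] <- cand
      E2 <- energy_of(M)
      dE <- E2 - E
      if (dE < 0 || runif(1) < exp(-min(beta * dE, 700))) {
        P <- M; E <- E2; acc <- TRUE
        if (E < bestE) { bestE <- E; best <- P }
      }
    }
    if (acc) win_acc <- win_acc + 1L
    win_sum <- win_sum + E
    if (moves %% n == 0L) beta <- min(beta * ctl$beta_growth, 1e12)
    if (win_cnt == ctl$window) {
      m <- win_sum / ctl$window
      tr_e <- c(tr_e, m); tr_b <- c(tr_b, bestE)
      tr_a <- c(tr_a, win_acc / ctl$window)
      delta <- if (win_acc / ctl$window > 0.3) delta / 0.9 else delta * 0.9
      if (is.finite(prev_mean) && abs(m - prev_mean) < ctl$tol * abs(m)) {
        converged <- TRUE; break
      }
      prev_mean <- m; win_cnt <- 0L; win_acc <- 0L; win_sum <- 0
    }
  }
  list(centers = best, energy = bestE, trace_energy = tr_e,
       trace_best = tr_b, trace_accept = tr_a, converged = converged,
       moves = moves)
}

#' Draw patterns from a conditioned model
#'
#' Single dispatcher used by the SDI machinery and the command-line tools.
#'
#' @param domain a [domain3].
#' @param spec a [model_spec].
#' @param n number of patterns.
#' @return one [object_pattern] (`simulate_model`) or a list of them
#'   (`simulate_patterns`).
#' @export
simulate_model <- function(domain, spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$model,
    csr = simulate_csr(domain, spec$radii, spec$restart_threshold,
                       spec$max_restarts),
    border_attraction = simulate_border_biased(
      domain, spec$radii, "attraction", spec$mu, spec$sigma,
      spec$restart_threshold, spec$max_restarts),
    border_repulsion = simulate_border_biased(
      domain, spec$radii, "repulsion", spec$mu, spec$sigma,
      spec$restart_threshold, spec$max_restarts),
    orbital = simulate_orbital(domain, spec$radii, spec$orbits,
                               spec$orbit_tol, spec$restart_threshold,
                               spec$max_restarts),
    max_repulsion = maximize_repulsion(
      simulate_csr(domain, spec$radii, spec$restart_threshold,
                   spec$max_restarts),
      on_orbits = FALSE, control = spec$anneal)$pattern,
    orbital_max_repulsion = maximize_repulsion(
      simulate_orbital(domain, spec$radii, spec$orbits, spec$orbit_tol,
                       spec$restart_threshold, spec$max_restarts),
      on_orbits = TRUE, control = spec$anneal)$pattern)
}

#' @rdname simulate_model
#' @export
simulate_patterns <- function(domain, spec, n) {
  lapply(seq_len(n), function(k) simulate_model(domain, spec))
}
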