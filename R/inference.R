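## SDI goodness-of-fit machinery.
##
## The test logic: the observed descriptor function is compared with its
## average over a first set of conditioned model simulations through the
## maximal signed deviation S = f_obs(x*) - f_model(x*), where x* maximizes
## |f_obs - f_model|. A second simulation set, scored against the same
## first-set mean by the same rule, calibrates S: the Spatial Distribution
## Index is the fraction of second-set statistics strictly above the
## observed one -- a Monte-Carlo p-value against the "observed function
## above the model mean" alternative. An SDI near 0 therefore means the
## observed descriptor runs above the model expectation at the maximizing
## abscissa (for B: objects closer to the boundary than the model
## predicts); an SDI near 1 means it runs below. Under the generating model
## the observed pattern and the second-set simulations are exchangeable, so
## the SDI is uniform on the lattice {0, 1/n2, ..., 1}; systematic
## departures from uniformity over a population of patterns indicate model
## misfit.

## pooled mean of a list of empirical CDFs (itself a weighted step function)
.pooled_cdf <- function(cdfs, id) {
  n <- length(cdfs)
  .dist_cdf(id, unlist(lapply(cdfs, `[[`, "x")),
            unlist(lapply(cdfs, function(f) f$w)) / n)
}

## maximal signed deviation between two step functions; the sup of |f - g|
## is attained among the right-limits at the union of jump abscissae; ties
## are broken toward the smallest abscissa
.sup_dev <- function(f, g) {
  u <- sort(c(f$x, g$x))
  d <- .eval_cdf_right(f, u) - .eval_cdf_right(g, u)
  i <- which.max(abs(d))
  list(x = u[i], S = d[i])
}

#' Simulation-averaged descriptor function with a pointwise 95% envelope
#'
#' Simulates `n_sim` patterns under a model conditioned on the observed
#' pattern, estimates the chosen descriptor on each, and returns the
#' pointwise mean together with an order-statistic envelope (by default the
#' 3rd-smallest / 3rd-largest of 99 values, approximating the 2.5th and
#' 97.5th percentiles). The envelope is a diagnostic band; inference uses
#' the SDI ([sdi_test()]).
#'
#' @param pattern an [object_pattern].
#' @param model a model id (see [model_spec()]) to be conditioned on the
#'   pattern, or a ready-made [model_spec].
#' @param descriptor one of `"F","G","H","B","C","Z"`.
#' @param n_sim number of simulations.
#' @param positions evaluation positions for F; generated (and shared across
#'   simulations) when `NULL`.
#' @param L number of random evaluation positions when generating them.
#' @param seed optional integer seed.
#' @param max_grid cap on the evaluation-grid size; the sorted union of all
#'   jump abscissae is thinned by even-index subsampling beyond this.
#' @param ... passed to [condition_spec()].
#' @return a `model_fn` object: grid, mean, lower/upper envelope, the
#'   observed descriptor and the spec used.
#' @export
estimate_model_function <- function(pattern, model, descriptor, n_sim = 99L,
                                    positions = NULL, L = 10000L,
                                    seed = NULL, max_grid = 5000L, ...) {
  spec <- if (inherits(model, "model_spec")) model
  else condition_spec(pattern, model, ...)
  if (!is.null(seed)) set.seed(seed)
  if (descriptor == "F" && is.null(positions))
    positions <- eval_positions(pattern$domain, L)
  obs <- estimate_descriptors(pattern, descriptor, positions)[[1]]
  sims <- simulate_patterns(pattern$domain, spec, n_sim)
  cdfs <- lapply(sims, function(s)
    estimate_descriptors(s, descriptor, positions)[[1]])
  grid <- sort(unique(c(obs$x, unlist(lapply(cdfs, `[[`, "x")))))
  if (length(grid) > max_grid)
    grid <- grid[unique(round(seq(1, length(grid), length.out = max_grid)))]
  vals <- vapply(cdfs, .eval_cdf_right, numeric(length(grid)), x = grid)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  k <- ceiling(0.025 * (n_sim + 1))
  sorted <- apply(vals, 1, sort)
  mean_ <- rowMeans(vals)
  ## for few-jump (small N) descriptors the discrete order statistics can
  ## fall on one side of the mean; keep the band around the mean
  structure(list(descriptor = descriptor, grid = grid,
                 mean = mean_,
                 lower = pmin(sorted[k, ], mean_),
                 upper = pmax(sorted[n_sim + 1 - k, ], mean_),
                 n_sim = n_sim, spec = spec, observed = obs),
            class = "model_fn")
}

#' @export
print.model_fn <- function(x, ...) {
  cat("<model_fn ", x$descriptor, "> mean over ", x$n_sim, " ", x$spec$model,
      " simulations, grid of ", length(x$grid), " points\n", sep = "")
  invisible(x)
}

#' @export
plot.model_fn <- function(x, ...) {
  graphics::plot(x$grid, x$mean, type = "l", ylim = c(0, 1),
                 xlab = "distance", ylab = paste0(x$descriptor, "(x)"), ...)
  graphics::lines(x$grid, x$lower, lty = 3)
  graphics::lines(x$grid, x$upper, lty = 3)
  plot(x$observed, add = TRUE, col = "blue")
  graphics::legend("bottomright",
                   c("model mean", "95% envelope", "observed"),
                   lty = c(1, 3, 1), col = c(1, 1, "blue"), bty = "n")
  invisible(x)
}

#' SDI goodness-of-fit test of a spatial model on one pattern
#'
#' The central test of the package. For each requested descriptor, a first
#' set of `n_sim1` conditioned simulations yields the model-mean function;
#' the observed maximal signed deviation `S` from that mean is compared with
#' the deviations of `n_sim2` further simulations (each scored exactly like
#' an observation, with its own maximizing abscissa), and the Spatial
#' Distribution Index is the fraction of second-set deviations strictly
#' above the observed one, a Monte-Carlo p-value against the "observed
#' function above the model mean" alternative. An SDI near 0 flags a
#' descriptor running above the model expectation (for B: objects closer to
#' the boundary than the model predicts), an SDI near 1 one running below;
#' over a population of patterns from the model, SDIs are uniform (see
#' [test_uniformity()]).
#'
#' Simulations are conditioned on the observed domain, object count and
#' radii (and orbit distances for orbital variants); for descriptor F the
#' same evaluation positions are shared between the observed pattern and
#' every simulation.
#'
#' @param pattern an [object_pattern].
#' @param model model id or [model_spec] (see [condition_spec()]).
#' @param descriptors subset of `c("F","G","H","B","C","Z")`.
#' @param n_sim1,n_sim2 sizes of the two simulation sets (99 by default, so
#'   SDIs live on a lattice of multiples of 1/99).
#' @param L number of shared random evaluation positions for F.
#' @param positions optional explicit positions for F.
#' @param seed optional integer seed making the whole test reproducible.
#' @param ... passed to [condition_spec()] (e.g. `mu`, `sigma`).
#' @return an `sdi_test` object; its `results` data frame has one row per
#'   descriptor with columns `descriptor`, `S`, `x_star`, `sdi`.
#' @export
sdi_test <- function(pattern, model,
                     descriptors = c("F", "G", "H", "B", "C", "Z"),
                     n_sim1 = 99L, n_sim2 = 99L, L = 10000L,
                     positions = NULL, seed = NULL, ...) {
  stopifnot(inherits(pattern, "object_pattern"))
  descriptors <- match.arg(descriptors, c("F", "G", "H", "B", "C", "Z"),
                           several.ok = TRUE)
  spec <- if (inherits(model, "model_spec")) model
  else condition_spec(pattern, model, ...)
  if (!is.null(seed)) set.seed(seed)
  if ("F" %in% descriptors && is.null(positions))
    positions <- eval_positions(pattern$domain, L)
  obs <- estimate_descriptors(pattern, descriptors, positions)
  sims <- simulate_patterns(pattern$domain, spec, n_sim1 + n_sim2)
  sim_cdfs <- lapply(sims, function(s)
    estimate_descriptors(s, descriptors, positions))
  rows <- lapply(descriptors, function(id) {
    first <- lapply(sim_cdfs[seq_len(n_sim1)], `[[`, id)
    second <- lapply(sim_cdfs[n_sim1 + seq_len(n_sim2)], `[[`, id)
    mean1 <- .pooled_cdf(first, id)
    so <- .sup_dev(obs[[id]], mean1)
    s_sim <- vapply(second, function(f) .sup_dev(f, mean1)$S, numeric(1))
    data.frame(descriptor = id, S = so$S, x_star = so$x,
               sdi = mean(s_sim > so$S))
  })
  structure(list(results = do.call(rbind, rows), spec = spec,
                 n_sim1 = n_sim1, n_sim2 = n_sim2, seed = seed,
                 n_positions = if (is.null(positions)) NA_integer_
                 else nrow(positions)),
            class = "sdi_test")
}

#' @export
print.sdi_test <- function(x, ...) {
  cat("SDI test against the", x$spec$model, "model (",
      x$n_sim1, "+", x$n_sim2, "simulations )\n")
  print(x$results, row.names = FALSE)
  cat("SDIs are multiples of 1/", x$n_sim2,
      "; values near 0/1 indicate misfit\n", sep = "")
  invisible(x)
}

#' @rdname sdi_test
#' @param descriptor a single descriptor id.
#' @return `compute_sdi()` returns the single result row as a list
#'   (`descriptor`, `S`, `x_star`, `sdi`, `n_sim1`, `n_sim2`).
#' @export
compute_sdi <- function(pattern, model, descriptor, n_sim1 = 99L,
                        n_sim2 = 99L, L = 10000L, positions = NULL,
                        seed = NULL, ...) {
  fit <- sdi_test(pattern, model, descriptor, n_sim1 = n_sim1,
                  n_sim2 = n_sim2, L = L, positions = positions,
                  seed = seed, ...)
  c(as.list(fit$results[1, ]), n_sim1 = n_sim1, n_sim2 = n_sim2)
}

#' Population-level uniformity test of SDI values
#'
#' Under a model that fits, per-pattern SDIs are uniform on `[0, 1]`; the
#' two-sided Kolmogorov-Smirnov test against the uniform distribution is
#' applied to the (discrete, lattice-valued) SDIs exactly as observed,
#' without continuity correction.
#'
#' @param sdis numeric vector of at least 10 SDI values in `[0, 1]`.
#' @return an `sdi_pop` object with the KS statistic `D`, the asymptotic
#'   two-sided `p.value` and the sample.
#' @export
test_uniformity <- function(sdis) {
  sdis <- as.numeric(sdis)
  if (length(sdis) < 10)
    stop("population uniformity test needs at least 10 SDI values")
  if (any(sdis < 0 | sdis > 1)) stop("SDI values must lie in [0, 1]")
  ks <- suppressWarnings(stats::ks.test(sdis, "punif", exact = FALSE))
  structure(list(n = length(sdis), D = unname(ks$statistic),
                 p.value = ks$p.value, sdis = sdis),
            class = "sdi_pop")
}

#' @export
print.sdi_pop <- function(x, ...) {
  cat("KS uniformity test on", x$n, "SDIs: D =", format(x$D),
      ", p =", format.pval(x$p.value), "\n")
  invisible(x)
}

#' @export
plot.sdi_pop <- function(x, breaks = seq(0, 1, by = 0.1), ...) {
  graphics::hist(x$sdis, breaks = breaks, xlab = "SDI",
                 main = "SDI distribution", ...)
  graphics::abline(h = x$n * diff(breaks)[1], lty = 2)
  invisible(x)
}

#' Matched comparison of observed and model-predicted mean distances
#'
#' For each pattern, the observed mean nearest-neighbour / pairwise /
#' farthest-neighbour distance is paired with the average of the same
#' summary over conditioned model simulations, and the paired differences
#' are tested with the two-sided Wilcoxon signed-rank test.
#'
#' @param patterns list of at least 6 [object_pattern]s.
#' @param model model id or function of a pattern returning a [model_spec].
#' @param which `"nearest"`, `"pair"` or `"farthest"`.
#' @param n_sim_per_pattern simulations per pattern for the prediction.
#' @param seed optional integer seed.
#' @param ... passed to [condition_spec()].
#' @return list with the per-pattern `observed` and `predicted` vectors,
#'   Wilcoxon `statistic` and `p.value`.
#' @export
compare_mean_distances <- function(patterns, model,
                                   which = c("nearest", "pair", "farthest"),
                                   n_sim_per_pattern = 19L, seed = NULL,
                                   ...) {
  which <- match.arg(which)
  if (length(patterns) < 6)
    stop("matched comparison needs at least 6 patterns")
  if (!is.null(seed)) set.seed(seed)
  key <- switch(which, nearest = "mean_nn", pair = "mean_pair",
                farthest = "mean_far")
  obs <- pred <- numeric(length(patterns))
  for (k in seq_along(patterns)) {
    pat <- patterns[[k]]
    spec <- if (is.function(model)) model(pat)
    else if (inherits(model, "model_spec")) model
    else condition_spec(pat, model, ...)
    obs[k] <- summary_distances(pat)[[key]]
    sims <- simulate_patterns(pat$domain, spec, n_sim_per_pattern)
    pred[k] <- mean(vapply(sims, function(s) summary_distances(s)[[key]],
                           numeric(1)))
  }
  d <- obs - pred
  if (all(d == 0)) {
    wt <- list(statistic = NA_real_, p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(obs, pred, paired = TRUE))
  }
  list(which = which, observed = obs, predicted = pred,
       statistic = unname(wt$statistic), p.value = wt$p.value)
}
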