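#' Empirical distance-distribution functions
#'
#' The six descriptors of a hard-sphere pattern are cumulative distribution
#' functions of centroid-based distances:
#' \describe{
#'   \item{F}{empty space: distance from a spatial position to the nearest
#'     object centroid, over a set of evaluation positions.}
#'   \item{G}{per-object nearest-neighbour centroid distance.}
#'   \item{H}{all unordered pairwise centroid distances.}
#'   \item{B}{per-object distance to the nearest point of the domain
#'     boundary.}
#'   \item{C}{per-object distance to the domain centroid.}
#'   \item{Z}{per-object farthest-neighbour centroid distance.}
#' }
#' All estimators use the strict indicator `1{d < x}`: a `dist_cdf` is a
#' step function that is 0 at each jump abscissa and steps up just after it
#' (see [eval_cdf()]).
#'
#' @name descriptors
NULL

.dist_cdf <- function(id, d, w = NULL) {
  if (length(d) == 0) stop("no distances to build an empirical CDF from")
  if (is.null(w)) w <- rep(1 / length(d), length(d))
  o <- order(d, method = "radix")
  d <- d[o]; w <- w[o]
  keep <- !duplicated(d)
  x <- d[keep]
  cw <- cumsum(w)
  cum <- cw[c(which(keep)[-1] - 1L, length(d))]
  structure(list(id = id, x = x, w = diff(c(0, cum)), cum = cum),
            class = "dist_cdf")
}

#' Evaluate an empirical distance CDF
#'
#' Uses the strict convention of the indicator-sum estimators: the value at
#' `x` is the total weight of jump abscissae strictly below `x`, so
#' `eval_cdf(f, a) == 0` when `a` is the smallest jump point.
#'
#' @param f a `dist_cdf`.
#' @param x numeric vector of distances.
#' @return values in `[0, 1]`.
#' @export
eval_cdf <- function(f, x) {
  stopifnot(inherits(f, "dist_cdf"))
  i <- findInterval(x, f$x, left.open = TRUE)
  c(0, f$cum)[i + 1L]
}

## right-limit evaluation (weight of jumps <= x); the attained values of the
## step function on each interval, used for sup-deviation computations
.eval_cdf_right <- function(f, x) {
  i <- findInterval(x, f$x)
  c(0, f$cum)[i + 1L]
}

#' @export
print.dist_cdf <- function(x, ...) {
  cat("<dist_cdf ", x$id, "> ", length(x$x), " jump(s) on [",
      format(min(x$x)), ", ", format(max(x$x)), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.dist_cdf <- function(x, add = FALSE, ...) {
  xs <- c(0, rep(x$x, each = 2), max(x$x) * 1.05)
  ys <- c(0, 0, rep(x$cum, each = 2))
  if (add) graphics::lines(xs, ys, ...)
  else graphics::plot(xs, ys, type = "l", xlab = "distance",
                      ylab = paste0(x$id, "(x)"), ylim = c(0, 1), ...)
  invisible(x)
}

#' Evaluation positions for the empty-space function F
#'
#' For image-backed (voxel mask) domains the natural choice is the set of
#' foreground voxel centres (`method = "voxel"`). For analytic or mesh
#' domains, `method = "random"` draws `L` points uniformly over the domain
#' volume; the same positions should be shared between an observed pattern
#' and all its model simulations (see [sdi_test()]), which removes one
#' source of Monte-Carlo variance.
#'
#' @param domain a [domain3].
#' @param L number of random positions (`>= 100`).
#' @param method `"random"` or `"voxel"` (mask domains only).
#' @param seed optional integer seed, for a reproducible position set.
#' @return an `L x 3` matrix with attribute `provenance`.
#' @export
eval_positions <- function(domain, L = 10000L, method = c("random", "voxel"),
                           seed = NULL) {
  method <- match.arg(method)
  if (method == "voxel") {
    if (!inherits(domain, "mask_domain"))
      stop("method = \"voxel\" requires a voxel-mask domain")
    idx <- which(domain$mask, arr.ind = TRUE)
    pos <- sweep(idx - 0.5, 2, domain$spacing, "*")
  } else {
    if (L < 100L) stop("need at least 100 evaluation positions")
    if (!is.null(seed)) {
      old <- .save_rng()
      on.exit(.restore_rng(old))
      set.seed(seed)
    }
    pos <- runif_domain(L, domain)
  }
  if (nrow(pos) < 100L) stop("need at least 100 evaluation positions")
  attr(pos, "provenance") <- if (method == "voxel") "voxel_centers"
  else "random_uniform"
  pos
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Estimate the empty-space function F
#'
#' ECDF of the distance from each evaluation position to the nearest object
#' centroid.
#'
#' @param pattern an [object_pattern] with at least one object.
#' @param positions evaluation positions (matrix, see [eval_positions()]).
#' @return a `dist_cdf`.
#' @export
estimate_F <- function(pattern, positions) {
  stopifnot(inherits(pattern, "object_pattern"))
  n <- nrow(pattern$centers)
  if (n < 1) stop("F is undefined for an empty pattern")
  q <- as_points(positions)
  if (nrow(q) == 0) stop("no evaluation positions")
  d <- .nearest_centroid_dist(q, pattern$centers)
  .dist_cdf("F", d)
}

.nearest_centroid_dist <- function(q, p) {
  ## min_i ||q_k - p_i|| for all k, blocked to bound memory
  n <- nrow(p)
  pn <- rowSums(p^2)
  out <- numeric(nrow(q))
  bs <- max(1L, floor(2e6 / n))
  for (s in seq(1, nrow(q), by = bs)) {
    e <- min(s + bs - 1, nrow(q))
    qb <- q[s:e, , drop = FALSE]
    d2 <- outer(rowSums(qb^2), pn, "+") - 2 * qb %*% t(p)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Estimate the pairwise descriptors G, H and Z
#'
#' G: per-object nearest-neighbour distance (weight 1/N each); H: all
#' N(N-1)/2 unordered pair distances (weight 2/(N(N-1)) each); Z: per-object
#' farthest-neighbour distance.
#'
#' @param pattern an [object_pattern] with `N >= 2`.
#' @return named list of `dist_cdf` objects `G`, `H`, `Z`.
#' @export
estimate_pairwise <- function(pattern) {
  n <- nrow(pattern$centers)
  if (n < 2) stop("pairwise descriptors need at least 2 objects")
  dm <- as.matrix(stats::dist(pattern$centers))
  diag(dm) <- NA
  list(G = .dist_cdf("G", .row_extreme(dm, min)),
       H = .dist_cdf("H", dm[upper.tri(dm)]),
       Z = .dist_cdf("Z", .row_extreme(dm, max)))
}

## row minima/maxima of a symmetric distance matrix with NA diagonal
.row_extreme <- function(dm, fun) {
  args <- c(lapply(seq_len(ncol(dm)), function(j) dm[, j]), list(na.rm = TRUE))
  unname(do.call(if (identical(fun, min)) pmin else pmax, args))
}

#' Estimate the boundary descriptors B and C
#'
#' B: per-object distance to the closest boundary point; C: per-object
#' distance to the domain centroid.
#'
#' @param pattern an [object_pattern] with `N >= 1`.
#' @return named list of `dist_cdf` objects `B`, `C`.
#' @export
estimate_boundary <- function(pattern) {
  n <- nrow(pattern$centers)
  if (n < 1) stop("boundary descriptors need at least 1 object")
  bd <- boundary_distance(pattern$domain, pattern$centers)
  ctr <- domain_centroid(pattern$domain)
  dc <- sqrt(rowSums(sweep(pattern$centers, 2, ctr)^2))
  list(B = .dist_cdf("B", bd), C = .dist_cdf("C", dc))
}

#' Estimate any subset of the six descriptors
#'
#' @param pattern an [object_pattern].
#' @param which character subset of `c("F","G","H","B","C","Z")`.
#' @param positions evaluation positions, required when `"F"` is requested.
#' @return named list of `dist_cdf` objects.
#' @export
estimate_descriptors <- function(pattern,
                                 which = c("F", "G", "H", "B", "C", "Z"),
                                 positions = NULL) {
  which <- match.arg(which, c("F", "G", "H", "B", "C", "Z"),
                     several.ok = TRUE)
  out <- list()
  if ("F" %in% which) {
    if (is.null(positions)) stop("descriptor F needs evaluation positions")
    out$F <- estimate_F(pattern, positions)
  }
  if (any(c("G", "H", "Z") %in% which)) {
    ghz <- estimate_pairwise(pattern)
    out <- c(out, ghz[intersect(c("G", "H", "Z"), which)])
  }
  if (any(c("B", "C") %in% which)) {
    bc <- estimate_boundary(pattern)
    out <- c(out, bc[intersect(c("B", "C"), which)])
  }
  out[which]
}

#' Mean nearest-, pairwise and farthest-neighbour distances
#'
#' Means over the same distance sets as the G, H and Z estimators.
#'
#' @param pattern an [object_pattern] with `N >= 2`.
#' @return list with `mean_nn`, `mean_pair`, `mean_far`.
#' @export
summary_distances <- function(pattern) {
  n <- nrow(pattern$centers)
  if (n < 2) stop("summary distances need at least 2 objects")
  dm <- as.matrix(stats::dist(pattern$centers))
  diag(dm) <- NA
  list(mean_nn = mean(apply(dm, 1, min, na.rm = TRUE)),
       mean_pair = mean(dm[upper.tri(dm)]),
       mean_far = mean(apply(dm, 1, max, na.rm = TRUE)))
}
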