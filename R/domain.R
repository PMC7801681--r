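#' @useDynLib sdi3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

## Points are n x 3 numeric matrices in physical units throughout.
as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z)")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

#' Confined 3D domains
#'
#' A `domain3` represents a bounded, closed region of 3D space in which
#' object patterns live: an analytic sphere or axis-aligned ellipsoid, a
#' watertight triangular boundary mesh, or a binary voxel mask with
#' (possibly anisotropic) voxel spacing. All coordinates and distances are
#' in physical units (e.g. micrometres).
#'
#' @param center numeric length-3 centre.
#' @param radius sphere radius (> 0).
#' @name domain3
NULL

#' @rdname domain3
#' @export
domain_sphere <- function(radius, center = c(0, 0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            length(center) == 3L, all(is.finite(center)))
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = c("sphere_domain", "domain3"))
}

#' @rdname domain3
#' @param semiaxes numeric length-3 strictly positive semi-axis lengths.
#' @export
domain_ellipsoid <- function(semiaxes, center = c(0, 0, 0)) {
  stopifnot(length(semiaxes) == 3L, all(semiaxes > 0),
            length(center) == 3L, all(is.finite(center)))
  structure(list(kind = "ellipsoid", center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes)),
            class = c("ellipsoid_domain", "domain3"))
}

#' @export
print.domain3 <- function(x, ...) {
  cat("<domain3:", x$kind, "> ")
  switch(x$kind,
    sphere = cat("R =", format(x$radius), "centre =",
                 paste(format(x$center), collapse = ", ")),
    ellipsoid = cat("semi-axes =", paste(format(x$semiaxes), collapse = ", ")),
    mesh = cat(nrow(x$vertices), "vertices,", nrow(x$faces), "faces"),
    mask = cat(paste(dim(x$mask), collapse = "x"), "voxels, spacing =",
               paste(format(x$spacing), collapse = ", ")))
  cat("\n  volume =", format(domain_volume(x)), "\n")
  invisible(x)
}

## ---- generic queries ----------------------------------------------------

#' Geometric queries on confined domains
#'
#' `contains_point()` tests point membership; `boundary_distance()` returns
#' the Euclidean distance from an interior point to the nearest point of the
#' domain boundary; `boundary_nearest()` returns that nearest boundary point;
#' `domain_centroid()`, `domain_volume()` and `domain_inradius()` return the
#' volume centroid, volume and (for analytic domains, exact) inradius;
#' `contains_sphere()` tests whether a whole sphere of radius `r` centred at
#' `p` fits inside the domain, boundary contact allowed;
#' `runif_domain()` draws points uniformly over the domain volume.
#'
#' @param domain a [domain3] object.
#' @param p points, an `n x 3` matrix (or length-3 vector).
#' @param r sphere radius (or vector, recycled), `>= 0`.
#' @param n number of points to draw.
#' @return distances/logicals of length `n`, or an `n x 3` matrix of points.
#' @name domain-queries
NULL

#' @rdname domain-queries
#' @export
contains_point <- function(domain, p) UseMethod("contains_point")

#' @rdname domain-queries
#' @export
boundary_distance <- function(domain, p) UseMethod("boundary_distance")

#' @rdname domain-queries
#' @export
boundary_nearest <- function(domain, p) UseMethod("boundary_nearest")

#' @rdname domain-queries
#' @export
domain_centroid <- function(domain) UseMethod("domain_centroid")

#' @rdname domain-queries
#' @export
domain_volume <- function(domain) UseMethod("domain_volume")

#' @rdname domain-queries
#' @export
domain_inradius <- function(domain) UseMethod("domain_inradius")

#' @rdname domain-queries
#' @export
domain_bbox <- function(domain) UseMethod("domain_bbox")

#' @rdname domain-queries
#' @export
contains_sphere <- function(domain, p, r) {
  p <- as_points(p)
  stopifnot(all(r >= 0))
  r <- rep_len(r, nrow(p))
  ok <- contains_point(domain, p)
  if (any(ok)) ok[ok] <- boundary_distance(domain, p[ok, , drop = FALSE]) >= r[ok]
  ok
}

#' @rdname domain-queries
#' @export
runif_domain <- function(n, domain) UseMethod("runif_domain", domain)

.check_inside <- function(domain, p) {
  if (!all(contains_point(domain, p)))
    stop("point outside domain")
}

## ---- analytic sphere ----------------------------------------------------

#' @export
contains_point.sphere_domain <- function(domain, p) {
  p <- as_points(p)
  d2 <- (p[, 1] - domain$center[1])^2 + (p[, 2] - domain$center[2])^2 +
    (p[, 3] - domain$center[3])^2
  d2 <= domain$radius^2
}

#' @export
boundary_distance.sphere_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  d <- sqrt((p[, 1] - domain$center[1])^2 + (p[, 2] - domain$center[2])^2 +
              (p[, 3] - domain$center[3])^2)
  domain$radius - d
}

#' @export
boundary_nearest.sphere_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  v <- sweep(p, 2, domain$center)
  d <- sqrt(rowSums(v^2))
  ## deterministic tie-break at the exact centre: project along +x
  deg <- d < .Machine$double.eps * domain$radius
  if (any(deg)) {
    v[deg, ] <- rep(c(1, 0, 0), each = sum(deg))
    d[deg] <- 1
  }
  sweep(v * (domain$radius / d), 2, domain$center, "+")
}

#' @export
domain_centroid.sphere_domain <- function(domain) domain$center

#' @export
domain_volume.sphere_domain <- function(domain) 4 / 3 * pi * domain$radius^3

#' @export
domain_inradius.sphere_domain <- function(domain) domain$radius

#' @export
domain_bbox.sphere_domain <- function(domain)
  rbind(domain$center - domain$radius, domain$center + domain$radius)

#' @export
runif_domain.sphere_domain <- function(n, domain) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- domain$radius * runif(n)^(1 / 3)
  sweep(u * r, 2, domain$center, "+")
}

## ---- analytic ellipsoid -------------------------------------------------

#' @export
contains_point.ellipsoid_domain <- function(domain, p) {
  p <- as_points(p)
  v <- sweep(sweep(p, 2, domain$center), 2, domain$semiaxes, "/")
  rowSums(v^2) <= 1
}

## Closest surface point of an axis-aligned ellipsoid from an interior
## query: x_i = a_i^2 y_i / (a_i^2 + t) with t the root of
## sum (a_i y_i / (a_i^2 + t))^2 = 1 on (-min a^2, 0].
.ellipsoid_nearest1 <- function(a, y) {
  eps <- 1e-12 * max(a)
  y[abs(y) < eps] <- eps          # regularize exact-axis degeneracies
  f <- function(t) sum((a^2 * y / (a^2 + t))^2 / a^2) - 1
  lo <- -min(a)^2
  lo <- lo + 1e-12 * min(a)^2
  while (f(lo) < 0) lo <- lo / 2  # paranoid: step toward 0 keeping f(lo) > 0
  t <- stats::uniroot(f, c(lo, 0), tol = 1e-14 * min(a)^2)$root
  a^2 * y / (a^2 + t)
}

#' @export
boundary_nearest.ellipsoid_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  y <- sweep(p, 2, domain$center)
  q <- t(apply(y, 1, function(yi) .ellipsoid_nearest1(domain$semiaxes, yi)))
  sweep(q, 2, domain$center, "+")
}

#' @export
boundary_distance.ellipsoid_domain <- function(domain, p) {
  p <- as_points(p)
  q <- boundary_nearest(domain, p)
  sqrt(rowSums((p - q)^2))
}

#' @export
domain_centroid.ellipsoid_domain <- function(domain) domain$center

#' @export
domain_volume.ellipsoid_domain <- function(domain)
  4 / 3 * pi * prod(domain$semiaxes)

#' @export
domain_inradius.ellipsoid_domain <- function(domain) min(domain$semiaxes)

#' @export
domain_bbox.ellipsoid_domain <- function(domain)
  rbind(domain$center - domain$semiaxes, domain$center + domain$semiaxes)

#' @export
runif_domain.ellipsoid_domain <- function(n, domain) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- runif(n)^(1 / 3)
  sweep(sweep(u * r, 2, domain$semiaxes, "*"), 2, domain$center, "+")
}

## rejection sampler shared by mesh and mask domains
.runif_reject <- function(n, domain) {
  bb <- domain_bbox(domain)
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  frac <- max(domain_volume(domain) / prod(bb[2, ] - bb[1, ]), 1e-3)
  while (got < n) {
    m <- ceiling((n - got) / frac * 1.2) + 8L
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]),
                  runif(m, bb[1, 2], bb[2, 2]),
                  runif(m, bb[1, 3], bb[2, 3]))
    keep <- cand[contains_point(domain, cand), , drop = FALSE]
    if (nrow(keep) > 0) {
      take <- min(nrow(keep), n - got)
      out[(got + 1):(got + take), ] <- keep[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

## generic fallback inradius: best boundary distance over centroid and a
## deterministic interior probe sample (approximate for mesh/mask domains)
.inradius_probe <- function(domain, n = 256L) {
  ctr <- matrix(domain_centroid(domain), ncol = 3)
  best <- if (contains_point(domain, ctr)) boundary_distance(domain, ctr) else 0
  bb <- domain_bbox(domain)
  g <- as.matrix(expand.grid(
    seq(bb[1, 1], bb[2, 1], length.out = 8L)[2:7],
    seq(bb[1, 2], bb[2, 2], length.out = 8L)[2:7],
    seq(bb[1, 3], bb[2, 3], length.out = 8L)[2:7]))
  g <- g[contains_point(domain, g), , drop = FALSE]
  if (nrow(g) > 0) best <- max(best, max(boundary_distance(domain, g)))
  best
}
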