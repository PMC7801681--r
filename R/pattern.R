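#' Object patterns: hard spheres in a confined domain
#'
#' An `object_pattern` is an ordered set of non-intersecting spheres
#' (centroid + equivalent radius, physical units) contained in a [domain3].
#' The hard-core constraint (`||p_i - p_j|| >= r_i + r_j`) and the
#' containment constraint (`boundary distance >= r_i`) both allow exact
#' contact.
#'
#' @param domain a [domain3].
#' @param centers `N x 3` matrix of object centroids.
#' @param radii numeric vector of `N` strictly positive equivalent radii.
#' @param labels optional unique positive integer labels (default `1:N`).
#' @param metadata free-form list (source image id, voxel spacing, ...).
#' @param validate if `TRUE` (default) raise an error when the hard-core or
#'   containment constraints are violated; use [validate_pattern()] to get a
#'   violation report instead.
#' @return an `object_pattern`.
#' @export
object_pattern <- function(domain, centers, radii, labels = NULL,
                           metadata = list(), validate = TRUE) {
  stopifnot(inherits(domain, "domain3"))
  if (is.null(centers) || length(centers) == 0L) {
    centers <- matrix(numeric(0), 0, 3)
  }
  centers <- as_points(centers)
  n <- nrow(centers)
  radii <- as.numeric(radii)
  if (length(radii) != n) stop("need one radius per centre")
  if (n > 0 && any(radii <= 0)) stop("radii must be strictly positive")
  if (is.null(labels)) labels <- seq_len(n)
  labels <- as.integer(labels)
  if (length(labels) != n || anyDuplicated(labels) || (n > 0 && any(labels < 1)))
    stop("labels must be unique positive integers, one per object")
  pat <- structure(list(domain = domain, centers = centers, radii = radii,
                        labels = labels, metadata = metadata),
                   class = "object_pattern")
  if (validate && n > 0) {
    viol <- validate_pattern(pat)
    if (nrow(viol) > 0)
      stop("invalid pattern: ", nrow(viol), " constraint violation(s); ",
           "use validate = FALSE and validate_pattern() to inspect")
  }
  pat
}

#' @export
print.object_pattern <- function(x, ...) {
  cat("<object_pattern>", nrow(x$centers), "objects in a", x$domain$kind,
      "domain\n")
  if (nrow(x$centers) > 0)
    cat("  radii: [", format(min(x$radii)), ",", format(max(x$radii)), "]\n")
  invisible(x)
}

#' @export
summary.object_pattern <- function(object, ...) {
  n <- nrow(object$centers)
  out <- list(n = n, domain_kind = object$domain$kind,
              domain_volume = domain_volume(object$domain),
              radii = object$radii,
              violations = validate_pattern(object))
  if (n >= 2) out <- c(out, summary_distances(object))
  class(out) <- "summary.object_pattern"
  out
}

#' @export
print.summary.object_pattern <- function(x, ...) {
  cat("Object pattern:", x$n, "objects,", x$domain_kind, "domain (volume",
      format(x$domain_volume), ")\n")
  if (x$n > 0)
    cat("Radii: mean", format(mean(x$radii)), "range [",
        format(min(x$radii)), ",", format(max(x$radii)), "]\n")
  if (!is.null(x$mean_nn))
    cat("Mean distances - nearest neighbour:", format(x$mean_nn),
        " pairwise:", format(x$mean_pair),
        " farthest neighbour:", format(x$mean_far), "\n")
  nv <- nrow(x$violations)
  cat(if (nv == 0) "No constraint violations\n"
      else paste(nv, "constraint violation(s)\n"))
  invisible(x)
}

#' @export
plot.object_pattern <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  bb <- domain_bbox(x$domain)
  graphics::plot(NA, xlim = bb[, ax[1]], ylim = bb[, ax[2]], asp = 1,
                 xlab = substr(plane, 1, 1), ylab = substr(plane, 2, 2),
                 main = paste("object pattern (", plane, " projection)"), ...)
  th <- seq(0, 2 * pi, length.out = 64)
  for (i in seq_len(nrow(x$centers)))
    graphics::lines(x$centers[i, ax[1]] + x$radii[i] * cos(th),
                    x$centers[i, ax[2]] + x$radii[i] * sin(th))
  invisible(x)
}

#' Check the hard-core and containment constraints of a pattern
#'
#' Lists every violated object pair (centre distance below the sum of radii)
#' and every containment failure (boundary distance below the radius), with
#' the violation magnitude. Exact contact is not a violation.
#'
#' @param pattern an [object_pattern].
#' @param tol non-negative slack below which a deficit is ignored
#'   (guards floating-point round-off; default `1e-9` times the mean radius).
#' @return a data frame with columns `type` (`"pair"` or `"containment"`),
#'   `i`, `j` (labels; `j` is `NA` for containment rows) and `magnitude`.
#' @export
validate_pattern <- function(pattern, tol = NULL) {
  stopifnot(inherits(pattern, "object_pattern"))
  n <- nrow(pattern$centers)
  empty <- data.frame(type = character(0), i = integer(0), j = integer(0),
                      magnitude = numeric(0))
  if (n == 0) return(empty)
  if (is.null(tol)) tol <- 1e-9 * mean(pattern$radii)
  out <- empty
  if (n >= 2) {
    dm <- as.matrix(stats::dist(pattern$centers))
    rs <- outer(pattern$radii, pattern$radii, "+")
    idx <- which(upper.tri(dm) & dm < rs - tol, arr.ind = TRUE)
    if (nrow(idx) > 0)
      out <- rbind(out, data.frame(
        type = "pair", i = pattern$labels[idx[, 1]],
        j = pattern$labels[idx[, 2]],
        magnitude = rs[idx] - dm[idx]))
  }
  inside <- contains_point(pattern$domain, pattern$centers)
  bd <- rep(-Inf, n)
  if (any(inside))
    bd[inside] <- boundary_distance(pattern$domain,
                                    pattern$centers[inside, , drop = FALSE])
  bad <- which(bd < pattern$radii - tol)
  if (length(bad) > 0)
    out <- rbind(out, data.frame(
      type = "containment", i = pattern$labels[bad], j = NA_integer_,
      magnitude = pattern$radii[bad] - pmax(bd[bad], 0)))
  out
}

## ---- pattern file I/O ---------------------------------------------------

.domain_to_list <- function(domain, path_stem) {
  switch(domain$kind,
    sphere = list(kind = "sphere", center = domain$center,
                  radius = domain$radius),
    ellipsoid = list(kind = "ellipsoid", center = domain$center,
                     semiaxes = domain$semiaxes),
    mesh = {
      f <- paste0(path_stem, "_domain.ply")
      write_ply(domain, f)
      list(kind = "mesh", file = basename(f))
    },
    mask = {
      f <- paste0(path_stem, "_domain.tif")
      write_mask_tiff(domain$mask, f)
      list(kind = "mask", file = basename(f), spacing = domain$spacing)
    })
}

.domain_from_list <- function(x, dir) {
  switch(x$kind,
    sphere = domain_sphere(x$radius, unlist(x$center)),
    ellipsoid = domain_ellipsoid(unlist(x$semiaxes), unlist(x$center)),
    mesh = read_ply(file.path(dir, x$file)),
    mask = domain_mask(read_mask_tiff(file.path(dir, x$file)),
                       unlist(x$spacing)),
    stop("unknown domain kind in sidecar: ", x$kind))
}

#' Read and write object patterns
#'
#' A pattern is stored as a CSV of objects (columns `label,x,y,z,radius`,
#' physical units, 12 significant digits) plus a JSON sidecar
#' (`<stem>.json`) holding the domain description and metadata. Analytic
#' domains are stored inline; mesh and mask domains are written alongside as
#' ascii PLY / TIFF files and referenced by name.
#'
#' @param pattern an [object_pattern].
#' @param path CSV file path.
#' @return `read_pattern()` returns an [object_pattern]; the writer returns
#'   `path` invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "object_pattern"))
  stem <- sub("\\.csv$", "", path)
  df <- data.frame(label = pattern$labels,
                   x = pattern$centers[, 1], y = pattern$centers[, 2],
                   z = pattern$centers[, 3], radius = pattern$radii)
  num <- vapply(df, function(col)
    if (is.double(col)) format(col, digits = 12, trim = TRUE,
                               scientific = FALSE) else format(col),
    character(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, 1, dimnames = list(NULL, names(df)))
  if (nrow(df) == 0L) num <- matrix(character(0), 0, 5,
                                    dimnames = list(NULL, names(df)))
  utils::write.table(num, path, sep = ",", quote = FALSE, row.names = FALSE)
  side <- list(domain = .domain_to_list(pattern$domain, stem),
               metadata = pattern$metadata)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  stem <- sub("\\.csv$", "", path)
  side_path <- paste0(stem, ".json")
  if (!file.exists(side_path))
    stop("missing domain sidecar: ", side_path)
  side <- jsonlite::read_json(side_path)
  domain <- .domain_from_list(side$domain, dirname(path))
  df <- utils::read.csv(path, colClasses = c(label = "integer"))
  need <- c("label", "x", "y", "z", "radius")
  if (!all(need %in% names(df))) stop("malformed pattern file: need columns ",
                                      paste(need, collapse = ","))
  if (nrow(df) > 0 && any(df$radius <= 0))
    stop("invalid pattern file: non-positive radius")
  object_pattern(domain, as.matrix(df[, c("x", "y", "z")]), df$radius,
                 labels = df$label,
                 metadata = if (is.null(side$metadata)) list() else side$metadata,
                 validate = FALSE)
}

#' Read / write binary voxel masks as multi-page TIFF stacks
#'
#' Slices along the third array axis are stored as TIFF pages (uint8 0/1).
#' Voxel spacing is never read from TIFF tags; supply it explicitly.
#'
#' @param mask 3D logical array.
#' @param path TIFF file path.
#' @export
write_mask_tiff <- function(mask, path) {
  slices <- lapply(seq_len(dim(mask)[3]),
                   function(k) (mask[, , k] * 1))
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  arr <- array(0, c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  arr > 0.5
}

#' Read / write integer label images as multi-page TIFF stacks
#'
#' Labels are scaled to the unit range on write (divided by 255) and
#' restored on read, supporting up to 255 labels.
#' @param labels 3D integer array.
#' @param path TIFF file path.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 255L) stop("more than 255 labels")
  slices <- lapply(seq_len(dim(labels)[3]), function(k) labels[, , k] / 255)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  arr <- array(0L, c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- as.integer(round(slices[[k]] * 255))
  arr
}

## ---- extraction from labeled images ------------------------------------

#' Extract an object pattern and morphology statistics from labeled images
#'
#' Per label: the centroid is the (binary-weighted) mean of voxel centres in
#' physical units; the volume is voxel count times voxel volume; the
#' equivalent radius is `(3V / 4 pi)^(1/3)`; sphericity
#' `psi = pi^(1/3) (6V)^(2/3) / A` is computed from the volume and surface
#' area of the label's iso-surface mesh (extracted from a box-smoothed
#' indicator so that the voxelization staircase does not inflate the area).
#' The domain is the boundary mesh of the nucleus mask ([mask_to_mesh()]).
#'
#' Patterns whose equivalent spheres violate the hard-core or containment
#' constraints (possible for touching or elongated real objects) are
#' returned together with the violation report, not rejected.
#'
#' @param nucleus_mask 3D logical array (the domain).
#' @param labels 3D integer array, 0 = background; every labeled voxel must
#'   lie inside `nucleus_mask`.
#' @param spacing per-axis voxel spacing (physical units).
#' @return a list with elements `pattern` ([object_pattern]), `morphology`
#'   (per-object data frame plus domain-level summaries) and `violations`
#'   (see [validate_pattern()]).
#' @export
extract_pattern <- function(nucleus_mask, labels, spacing) {
  stopifnot(length(dim(nucleus_mask)) == 3L,
            all(dim(nucleus_mask) == dim(labels)),
            length(spacing) == 3L, all(spacing > 0))
  mode(nucleus_mask) <- "logical"
  labels <- array(as.integer(labels), dim(labels))
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  if (any(labels > 0L & !nucleus_mask))
    stop("labeled voxel outside the nucleus mask")
  domain <- mask_to_mesh(nucleus_mask, spacing)
  voxvol <- prod(spacing)
  labs <- sort(unique(labels[labels > 0L]))
  n <- length(labs)
  cen <- matrix(NA_real_, n, 3)
  vol <- rad <- sph <- numeric(n)
  for (k in seq_len(n)) {
    idx <- which(labels == labs[k], arr.ind = TRUE)
    cen[k, ] <- colMeans(sweep(idx - 0.5, 2, spacing, "*"))
    vol[k] <- nrow(idx) * voxvol
    rad[k] <- (3 * vol[k] / (4 * pi))^(1 / 3)
    ## sphericity from the label's own (smoothed) surface mesh
    lo <- pmax(apply(idx, 2, min) - 3L, 1L)
    hi <- pmin(apply(idx, 2, max) + 3L, dim(labels))
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == labs[k]
    field <- .box_smooth(sub * 1)
    if (max(field) <= 0.5) field <- sub * 1   # objects a few voxels small
    surf <- .isosurface(field, spacing)
    vm <- abs(.mesh_signed_volume(surf$vertices, surf$faces))
    am <- .mesh_area(surf$vertices, surf$faces)
    sph[k] <- pi^(1 / 3) * (6 * vm)^(2 / 3) / am
  }
  pat <- object_pattern(domain, cen, rad, labels = labs,
                        metadata = list(spacing = spacing),
                        validate = FALSE)
  ## domain shape: principal radii from the voxel-centre covariance
  nidx <- which(nucleus_mask, arr.ind = TRUE)
  pc <- sweep(nidx - 0.5, 2, spacing, "*")
  ev <- sort(eigen(stats::cov(pc), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  morph <- list(
    objects = data.frame(label = labs, volume = vol, radius = rad,
                         sphericity = sph),
    domain = list(volume = domain_volume(domain), n_objects = n,
                  elongation = sqrt(ev[1] / ev[2]),
                  flatness = sqrt(ev[2] / ev[3])))
  list(pattern = pat, morphology = morph, violations = validate_pattern(pat))
}

#' Rasterize an object pattern into voxel images
#'
#' Test-fixture generator: builds a nucleus mask (voxel centres inside the
#' domain) and an integer label image (voxel centre within `r_i` of `p_i`
#' gets label `i`) on a grid covering the domain bounding box with one voxel
#' of margin. The grid origin is shifted so that voxel `(1,1,1)` has its
#' centre at `offset + spacing / 2`; `offset` is returned so that extracted
#' coordinates can be mapped back to the pattern frame.
#'
#' @param pattern an [object_pattern].
#' @param spacing per-axis voxel size.
#' @return list with `nucleus` (logical array), `labels` (integer array),
#'   `spacing` and `offset`.
#' @export
rasterize_pattern <- function(pattern, spacing) {
  stopifnot(inherits(pattern, "object_pattern"),
            length(spacing) == 3L, all(spacing > 0))
  if (nrow(pattern$centers) > 0 && max(spacing) > min(2 * pattern$radii))
    warning("voxel spacing exceeds the smallest object diameter")
  bb <- domain_bbox(pattern$domain)
  offset <- bb[1, ] - spacing
  dims <- ceiling((bb[2, ] - offset) / spacing) + 1L
  ax <- lapply(1:3, function(a) offset[a] + (seq_len(dims[a]) - 0.5) * spacing[a])
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  nucleus <- array(contains_point(pattern$domain, grid), dims)
  labs <- array(0L, dims)
  for (i in seq_len(nrow(pattern$centers))) {
    p <- pattern$centers[i, ]
    r <- pattern$radii[i]
    lo <- pmax(floor((p - r - offset) / spacing), 1)
    hi <- pmin(ceiling((p + r - offset) / spacing) + 1, dims)
    sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
    loc <- as.matrix(expand.grid(ax[[1]][sx], ax[[2]][sy], ax[[3]][sz]))
    inobj <- rowSums(sweep(loc, 2, p)^2) <= r^2
    sub <- labs[sx, sy, sz, drop = FALSE]
    sub[inobj] <- pattern$labels[i]
    labs[sx, sy, sz] <- sub
  }
  list(nucleus = nucleus, labels = labs, spacing = as.numeric(spacing),
       offset = offset)
}
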