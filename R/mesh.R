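## Triangular-mesh domains: watertight closed surfaces in physical units.

#' Triangular-mesh domain
#'
#' Builds a [domain3] backed by a closed (watertight) triangular boundary
#' mesh. The mesh is validated (every undirected edge shared by exactly two
#' faces) and re-oriented if needed so that face normals point outward.
#'
#' @param vertices `n x 3` numeric matrix of vertex positions (physical units).
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @export
domain_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (!.mesh_watertight(faces))
    stop("mesh is not watertight (every edge must be shared by exactly 2 faces)")
  vol <- .mesh_signed_volume(vertices, faces)
  if (vol < 0) {                      # flip to outward orientation
    faces <- faces[, c(1L, 3L, 2L)]
    vol <- -vol
  }
  d <- structure(list(kind = "mesh", vertices = vertices, faces = faces,
                      volume = vol), class = c("mesh_domain", "domain3"))
  d$centroid <- .mesh_centroid(vertices, faces, vol)
  ## precomputed per-face edge vectors for distance / intersection queries
  A <- vertices[faces[, 1], , drop = FALSE]
  d$fA <- A
  d$fE1 <- vertices[faces[, 2], , drop = FALSE] - A
  d$fE2 <- vertices[faces[, 3], , drop = FALSE] - A
  d
}

.mesh_watertight <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  all(cnt == 2L)
}

.mesh_signed_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ## sum of signed tetra volumes with apex at the origin
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

.mesh_centroid <- function(v, f, vol) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
    a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  colSums(det * (a + b + c_) / 4) / 6 / vol
}

.mesh_area <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

## Closest point on each triangle to p (Ericson's region method),
## vectorized over faces. Returns list(d2 = squared distances, q = points).
.tri_closest <- function(A, E1, E2, p) {
  m <- nrow(A)
  P <- matrix(p, m, 3, byrow = TRUE)
  ap <- P - A
  d1 <- rowSums(E1 * ap); d2 <- rowSums(E2 * ap)
  bp <- ap - E1
  d3 <- rowSums(E1 * bp); d4 <- rowSums(E2 * bp)
  cp <- ap - E2
  d5 <- rowSums(E1 * cp); d6 <- rowSums(E2 * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  u <- numeric(m); v <- numeric(m)     # barycentric along E1 (u) and E2 (v)
  done <- logical(m)
  ## vertex A
  reg <- !done & d1 <= 0 & d2 <= 0
  done <- done | reg
  ## vertex B
  reg <- !done & d3 >= 0 & d4 <= d3
  u[reg] <- 1; done <- done | reg
  ## vertex C
  reg <- !done & d6 >= 0 & d5 <= d6
  v[reg] <- 1; done <- done | reg
  ## edge AB
  reg <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  u[reg] <- d1[reg] / (d1[reg] - d3[reg]); done <- done | reg
  ## edge AC
  reg <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  v[reg] <- d2[reg] / (d2[reg] - d6[reg]); done <- done | reg
  ## edge BC
  reg <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  w <- (d4[reg] - d3[reg]) / ((d4[reg] - d3[reg]) + (d5[reg] - d6[reg]))
  u[reg] <- 1 - w; v[reg] <- w; done <- done | reg
  ## interior
  reg <- !done
  denom <- va[reg] + vb[reg] + vc[reg]
  u[reg] <- vb[reg] / denom
  v[reg] <- vc[reg] / denom
  q <- A + u * E1 + v * E2
  list(d2 = rowSums((q - P)^2), q = q)
}

.mesh_nearest1 <- function(domain, p) {
  cl <- .tri_closest(domain$fA, domain$fE1, domain$fE2, p)
  i <- which.min(cl$d2)                 # first index: deterministic tie-break
  list(d = sqrt(cl$d2[i]), q = cl$q[i, ], face = i)
}

## Ray-parity point-in-mesh test for one point; retries with perturbed
## direction on degenerate hits (edge/vertex grazing, parallel faces).
.mesh_contains1 <- function(domain, p) {
  dir <- c(0.5773502691896258, 0.5773502691896258, 0.5773502691896257)
  for (try in 1:8) {
    E1 <- domain$fE1; E2 <- domain$fE2
    s <- matrix(p, nrow(E1), 3, byrow = TRUE) - domain$fA
    h <- cbind(dir[2] * E2[, 3] - dir[3] * E2[, 2],
               dir[3] * E2[, 1] - dir[1] * E2[, 3],
               dir[1] * E2[, 2] - dir[2] * E2[, 1])
    a <- rowSums(E1 * h)
    q <- cbind(s[, 2] * E1[, 3] - s[, 3] * E1[, 2],
               s[, 3] * E1[, 1] - s[, 1] * E1[, 3],
               s[, 1] * E1[, 2] - s[, 2] * E1[, 1])
    ok <- abs(a) > 1e-12
    f <- ifelse(ok, 1 / a, 0)
    u <- f * rowSums(s * h)
    v <- f * (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3])
    tt <- f * rowSums(E2 * q)
    eps <- 1e-9
    hit <- ok & u > eps & u < 1 - eps & v > eps & (u + v) < 1 - eps & tt > eps
    loose <- ok & u > -eps & v > -eps & (u + v) < 1 + eps & tt > -eps
    if (!any(loose & !hit)) return(sum(hit) %% 2L == 1L)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
  }
  sum(hit) %% 2L == 1L
}

#' @export
contains_point.mesh_domain <- function(domain, p) {
  p <- as_points(p)
  bb <- domain_bbox(domain)
  out <- logical(nrow(p))
  inbb <- p[, 1] >= bb[1, 1] & p[, 1] <= bb[2, 1] &
    p[, 2] >= bb[1, 2] & p[, 2] <= bb[2, 2] &
    p[, 3] >= bb[1, 3] & p[, 3] <= bb[2, 3]
  for (i in which(inbb)) out[i] <- .mesh_contains1(domain, p[i, ])
  out
}

#' @export
boundary_distance.mesh_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  vapply(seq_len(nrow(p)), function(i) .mesh_nearest1(domain, p[i, ])$d,
         numeric(1))
}

#' @export
boundary_nearest.mesh_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  t(vapply(seq_len(nrow(p)), function(i) .mesh_nearest1(domain, p[i, ])$q,
           numeric(3)))
}

#' @export
domain_centroid.mesh_domain <- function(domain) domain$centroid

#' @export
domain_volume.mesh_domain <- function(domain) domain$volume

#' @export
domain_inradius.mesh_domain <- function(domain) .inradius_probe(domain)

#' @export
domain_bbox.mesh_domain <- function(domain)
  rbind(apply(domain$vertices, 2, min), apply(domain$vertices, 2, max))

#' @export
runif_domain.mesh_domain <- function(n, domain) .runif_reject(n, domain)

## ---- voxel-mask domain --------------------------------------------------

#' Voxel-mask domain
#'
#' Builds a [domain3] from a 3D logical (or 0/1) array and per-axis voxel
#' spacing in physical units. Voxel `(i, j, k)` (1-based array index) has its
#' centre at `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)`. Containment
#' is tested by voxel membership; metric boundary queries (distance to the
#' boundary, nearest boundary point) use the iso-surface mesh extracted at
#' level 0.5 by [mask_to_mesh()], which is computed on first use and cached.
#'
#' @param mask 3D logical array (foreground = inside).
#' @param spacing numeric length-3, strictly positive voxel spacing.
#' @export
domain_mask <- function(mask, spacing) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mode(mask) <- "logical"
  if (!any(mask)) stop("empty mask")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(kind = "mask", mask = mask, spacing = as.numeric(spacing),
                 cache = new.env(parent = emptyenv())),
            class = c("mask_domain", "domain3"))
}

.mask_mesh <- function(domain) {
  if (is.null(domain$cache$mesh))
    domain$cache$mesh <- mask_to_mesh(domain$mask, domain$spacing,
                                      keep_largest = TRUE)
  domain$cache$mesh
}

#' @export
contains_point.mask_domain <- function(domain, p) {
  p <- as_points(p)
  dm <- dim(domain$mask)
  i <- floor(p[, 1] / domain$spacing[1]) + 1
  j <- floor(p[, 2] / domain$spacing[2]) + 1
  k <- floor(p[, 3] / domain$spacing[3]) + 1
  ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
  out <- logical(nrow(p))
  out[ok] <- domain$mask[cbind(i[ok], j[ok], k[ok])]
  out
}

#' @export
boundary_distance.mask_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  mesh <- .mask_mesh(domain)
  vapply(seq_len(nrow(p)), function(i) .mesh_nearest1(mesh, p[i, ])$d,
         numeric(1))
}

#' @export
boundary_nearest.mask_domain <- function(domain, p) {
  p <- as_points(p)
  .check_inside(domain, p)
  mesh <- .mask_mesh(domain)
  t(vapply(seq_len(nrow(p)), function(i) .mesh_nearest1(mesh, p[i, ])$q,
           numeric(3)))
}

#' @export
domain_centroid.mask_domain <- function(domain) {
  idx <- which(domain$mask, arr.ind = TRUE)
  colMeans(sweep(idx - 0.5, 2, domain$spacing, "*"))
}

#' @export
domain_volume.mask_domain <- function(domain)
  sum(domain$mask) * prod(domain$spacing)

#' @export
domain_inradius.mask_domain <- function(domain) .inradius_probe(domain)

#' @export
domain_bbox.mask_domain <- function(domain)
  rbind(c(0, 0, 0), dim(domain$mask) * domain$spacing)

#' @export
runif_domain.mask_domain <- function(n, domain) .runif_reject(n, domain)

## ---- PLY I/O ------------------------------------------------------------

#' Read / write triangular meshes as ascii PLY
#'
#' Vertices are stored in physical units. `read_ply()` returns a
#' [domain_mesh()]; `write_ply()` writes one.
#'
#' @param path file path.
#' @param mesh a mesh domain.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  v <- matrix(scan(text = lines[(endh + 1):(endh + nv)], quiet = TRUE),
              nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[(endh + nv + 1):(endh + nv + nf)],
                   quiet = TRUE), nf, 4, byrow = TRUE)
  if (!all(f[, 1] == 3)) stop("only triangular faces are supported")
  domain_mesh(v, f[, 2:4] + 1L)
}

#' @rdname read_ply
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh_domain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 12, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
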