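# Shared fixture builders: rasterized balls, subdivided icosphere meshes,
# random hard-sphere patterns, and a brute-force descriptor oracle.

make_ball_mask <- function(r, margin = 3, center_offset = c(0, 0, 0)) {
  d <- 2 * (r + margin) + 1
  ctr <- r + margin + 0.5 + center_offset
  i <- seq_len(d)
  g <- expand.grid(i = i, j = i, k = i)
  array((g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2 <= r^2,
        c(d, d, d))
}

# icosahedron subdivided `subdiv` times, vertices projected to radius R
make_icosphere <- function(R = 1, subdiv = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * R
  domain_mesh(sweep(v, 2, center, "+"), f)
}

random_pattern <- function(domain = domain_sphere(30), n = 10, r = NULL) {
  if (is.null(r)) r <- runif(n, 1, 4)
  simulate_csr(domain, r)
}

# Independent brute-force oracle: builds each descriptor's defining
# distance set by explicit double loops (no sorting / weight aggregation /
# cumulative-sum machinery), then evaluates the indicator-sum estimator
# directly as the proportion of distances strictly below x.
# Returns a function of (id, x).
oracle_eval <- function(pattern, positions = NULL) {
  p <- pattern$centers
  n <- nrow(p)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt(sum((p[i, ] - p[j, ])^2))
  gd <- zd <- numeric(n)
  for (i in seq_len(n)) {
    gd[i] <- min(m[i, -i])
    zd[i] <- max(m[i, -i])
  }
  hd <- numeric(0)
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n)
    hd <- c(hd, m[i, j])
  fd <- NULL
  if (!is.null(positions)) {
    fd <- numeric(nrow(positions))
    for (k in seq_len(nrow(positions))) {
      dmin <- Inf
      for (i in seq_len(n))
        dmin <- min(dmin, sqrt(sum((positions[k, ] - p[i, ])^2)))
      fd[k] <- dmin
    }
  }
  bd <- boundary_distance(pattern$domain, p)
  ctr <- domain_centroid(pattern$domain)
  cd <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  sets <- list(F = fd, G = gd, H = hd, B = bd, C = cd, Z = zd)
  function(id, x) vapply(x, function(xx) mean(sets[[id]] < xx), numeric(1))
}
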