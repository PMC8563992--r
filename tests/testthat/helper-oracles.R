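# Independent oracles used by the tests. These deliberately share no code
# with the package: flood-fill labeling, moment formulas evaluated directly,
# and a brute-force half-plane-intersection Voronoi construction.

# Queue-based flood fill labeling (4- or 8-connectivity).
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nbr))) {
        r2 <- r + nbr[k, 1]; c2 <- cc + nbr[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + r2
          if (mask[q] == 1 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Major axis length of the second-moment-matched ellipse, computed directly
# from a set of (row, col) pixel coordinates.
oracle_major_axis <- function(rc) {
  n <- nrow(rc)
  if (n == 1) return(0)
  mu <- colMeans(rc)
  d <- sweep(rc, 2, mu)
  covm <- crossprod(d) / n
  4 * sqrt(max(eigen(covm, symmetric = TRUE, only.values = TRUE)$values))
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane n.x <= c0.
oracle_clip <- function(poly, n, c0) {
  k <- nrow(poly)
  d <- as.vector(poly %*% n) - c0
  out <- NULL
  for (t in seq_len(k)) {
    u <- t %% k + 1
    if (d[t] <= 0) out <- rbind(out, poly[t, ])
    if ((d[t] <= 0) != (d[u] <= 0)) {
      s <- d[t] / (d[t] - d[u])
      out <- rbind(out, poly[t, ] + s * (poly[u, ] - poly[t, ]))
    }
  }
  out
}

# Voronoi cell of site i by intersecting bisector half-planes, starting
# from a large bounding box. Returns list(vertices, bounded): the cell is
# bounded iff no vertex lies on the box.
oracle_voronoi_cell <- function(i, P) {
  span <- max(diff(range(P[, 1])), diff(range(P[, 2])))
  M <- 1e6 * span  # far beyond any sliver circumcenter of a bounded cell
  cx <- mean(range(P[, 1])); cy <- mean(range(P[, 2]))
  poly <- rbind(c(cx - M, cy - M), c(cx + M, cy - M),
                c(cx + M, cy + M), c(cx - M, cy + M))
  for (j in seq_len(nrow(P))) {
    if (j == i) next
    nvec <- P[j, ] - P[i, ]
    c0 <- sum(nvec * (P[i, ] + P[j, ]) / 2)
    poly <- oracle_clip(poly, nvec, c0)
    if (is.null(poly) || nrow(poly) < 3) return(NULL)
  }
  lim <- M * 0.99
  on_box <- abs(poly[, 1] - cx) >= lim | abs(poly[, 2] - cy) >= lim
  list(vertices = poly, bounded = !any(on_box))
}

oracle_polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Distance from a point to a polygon boundary (closed ring).
oracle_dist_to_ring <- function(pt, ring) {
  k <- nrow(ring)
  dmin <- Inf
  for (t in seq_len(k)) {
    a <- ring[t, ]; b <- ring[t %% k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    s <- if (len2 == 0) 0 else max(0, min(1, sum((pt - a) * ab) / len2))
    dmin <- min(dmin, sqrt(sum((a + s * ab - pt)^2)))
  }
  dmin
}

# Binary disc mask fixture: foreground where (r-r0)^2+(c-c0)^2 <= rad^2,
# on a 1-based matrix grid.
fixture_disc_mask <- function(nr, nc, centers, radii) {
  m <- matrix(0L, nr, nc)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  for (k in seq_len(nrow(centers))) {
    sel <- (g$r - centers[k, 1])^2 + (g$c - centers[k, 2])^2 <= radii[k]^2
    m[cbind(g$r[sel], g$c[sel])] <- 1L
  }
  m
}
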