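#' Circumcenter of a triangle
#'
#' The point equidistant from the three vertices ("outer center"). Computed
#' in a local frame anchored at the first vertex for numerical accuracy.
#'
#' @param p1,p2,p3 Numeric length-2 vectors `(x, y)`.
#' @return A numeric length-2 vector `(x, y)`.
#' @export
circumcenter <- function(p1, p2, p3) {
  bx <- p2[1] - p1[1]; by <- p2[2] - p1[2]
  cx <- p3[1] - p1[1]; cy <- p3[2] - p1[2]
  d <- 2 * (bx * cy - by * cx)
  scale2 <- max(bx^2 + by^2, cx^2 + cy^2, .Machine$double.xmin)
  if (abs(d) <= 1e-12 * scale2) {
    abort("Degenerate (collinear) triangle has no circumcenter.",
          class = "ricevor_degenerate_geometry")
  }
  b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  c(p1[1] + (cy * b2 - by * c2) / d,
    p1[2] + (bx * c2 - cx * b2) / d)
}

# Circumcenters and squared circumradii for vertex-index triples, vectorised.
# Degenerate triples get r2 = Inf (they are always invalidated by the next
# insertion in the Bowyer-Watson loop).
circum_rows <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1] - ax; by <- P[tri[, 2], 2] - ay
  cx <- P[tri[, 3], 1] - ax; cy <- P[tri[, 3], 2] - ay
  d <- 2 * (bx * cy - by * cx)
  b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  bad <- abs(d) <= 1e-14 * pmax(b2, c2)
  d[bad] <- NA_real_
  ux <- (cy * b2 - by * c2) / d
  uy <- (bx * c2 - cx * b2) / d
  r2 <- ux^2 + uy^2
  ux <- ux + ax; uy <- uy + ay
  ux[bad] <- ax[bad]; uy[bad] <- ay[bad]; r2[bad] <- Inf
  cbind(ux, uy, r2, deparse.level = 0)
}

as_xy_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    m <- points[, 1:2, drop = FALSE]
  } else {
    points <- as.data.frame(points)
    if (!all(c("x", "y") %in% names(points))) {
      abort("`points` needs `x` and `y` columns.", class = "ricevor_invalid_input")
    }
    m <- cbind(points$x, points$y)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("Point coordinates must be finite.", class = "ricevor_invalid_input")
  dimnames(m) <- NULL
  m
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental insertion (Bowyer-Watson) with a far-away enclosing
#' super-triangle, so the result satisfies the empty-circumcircle property
#' up to floating-point tolerance; co-circular quadruples (exact lattices)
#' are resolved deterministically by insertion order. Input units are
#' arbitrary and carried through unchanged.
#'
#' @param points Data frame with `x`, `y` columns, or a 2-column matrix.
#'   At least 3 points, not all collinear, no duplicates.
#' @return A `rice_delaunay` object: list with `points` (n x 2 matrix),
#'   `triangles` (m x 3 integer matrix of vertex indices),
#'   `circumcenters` (m x 2 matrix) and `incidence` (per-vertex list of
#'   incident triangle rows).
#' @export
delaunay <- function(points) {
  P0 <- as_xy_matrix(points)
  n <- nrow(P0)
  if (n < 3) {
    abort("Need at least 3 points to triangulate.", class = "ricevor_degenerate_input")
  }
  span <- max(diff(range(P0[, 1])), diff(range(P0[, 2])))
  if (span <= 0) {
    abort("All points coincide; cannot triangulate.", class = "ricevor_degenerate_input")
  }
  if (anyDuplicated(round(P0 / (1e-9 * span)))) {
    abort("Duplicate points (within 1e-9 of the span) are not allowed.",
          class = "ricevor_degenerate_input")
  }
  ctr <- c(mean(range(P0[, 1])), mean(range(P0[, 2])))
  M <- 1e5 * span
  P <- rbind(P0,
             c(ctr[1] - 3 * M, ctr[2] - M),
             c(ctr[1] + 3 * M, ctr[2] - M),
             c(ctr[1], ctr[2] + 3 * M))
  cap <- 8L * (n + 3L)
  tris <- matrix(0L, cap, 3)
  cc <- matrix(NA_real_, cap, 3)   # ux, uy, r2
  active <- logical(cap)
  tris[1, ] <- c(n + 1L, n + 2L, n + 3L)
  cc[1, ] <- circum_rows(P, tris[1, , drop = FALSE])
  active[1] <- TRUE
  m <- 1L
  eps2 <- (1e-7 * span)^2

  for (q in seq_len(n)) {
    act <- which(active[seq_len(m)])
    dx <- P[q, 1] - cc[act, 1]
    dy <- P[q, 2] - cc[act, 2]
    bad <- act[dx * dx + dy * dy < cc[act, 3] - eps2]
    if (!length(bad)) {
      abort("Internal triangulation failure (no cavity found).",
            class = "ricevor_degenerate_geometry")
    }
    bt <- tris[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2), drop = FALSE],
               bt[, c(2, 3), drop = FALSE],
               bt[, c(3, 1), drop = FALSE])
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    key <- lo * (n + 4) + hi
    once <- !(key %in% key[duplicated(key)])
    e <- e[once, , drop = FALSE]
    active[bad] <- FALSE
    k <- nrow(e)
    if (m + k > cap) {
      grow <- max(cap, m + k)
      tris <- rbind(tris, matrix(0L, grow, 3))
      cc <- rbind(cc, matrix(NA_real_, grow, 3))
      active <- c(active, logical(grow))
      cap <- cap + grow
    }
    idx <- m + seq_len(k)
    tris[idx, ] <- cbind(rep(q, k), e)
    cc[idx, ] <- circum_rows(P, tris[idx, , drop = FALSE])
    active[idx] <- TRUE
    m <- m + k
  }

  keep <- which(active[seq_len(m)])
  real <- keep[apply(tris[keep, , drop = FALSE] <= n, 1, all)]
  if (!length(real)) {
    abort("Degenerate input: all points are collinear.",
          class = "ricevor_degenerate_input")
  }
  triangles <- tris[real, , drop = FALSE]
  centers <- circum_rows(P, triangles)[, 1:2, drop = FALSE]
  incidence <- vector("list", n)
  for (t in seq_len(nrow(triangles))) {
    for (v in triangles[t, ]) incidence[[v]] <- c(incidence[[v]], t)
  }
  structure(
    list(points = P0, triangles = triangles, circumcenters = centers,
         incidence = incidence, span = span),
    class = "rice_delaunay"
  )
}

#' @export
print.rice_delaunay <- function(x, ...) {
  cat(sprintf("<rice_delaunay> %d points, %d triangles\n",
              nrow(x$points), nrow(x$triangles)))
  invisible(x)
}

#' Area of a simple polygon
#'
#' Absolute value of the shoelace sum; invariant to vertex orientation.
#'
#' @param ring Matrix or data frame of ordered vertices (columns `x`, `y`
#'   or the first two columns), at least 3 of them.
#' @return Non-negative area in squared input units.
#' @export
polygon_area <- function(ring) {
  v <- as_xy_matrix(ring)
  if (nrow(v) < 3) {
    abort("A polygon needs at least 3 vertices.", class = "ricevor_degenerate_input")
  }
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Collapse circumcenters closer than tol to a single representative,
# preserving first occurrence. Co-circular lattice quadruples give
# coincident circumcenters whose naive ring would self-intersect.
dedupe_vertices <- function(v, tol) {
  k <- nrow(v)
  if (k <= 1) return(v)
  keep <- rep(TRUE, k)
  for (i in 2:k) {
    prev <- which(keep[seq_len(i - 1)])
    if (any((v[prev, 1] - v[i, 1])^2 + (v[prev, 2] - v[i, 2])^2 <= tol^2)) {
      keep[i] <- FALSE
    }
  }
  v[keep, , drop = FALSE]
}

#' Voronoi cell of one site from its incident Delaunay triangles
#'
#' Collects the circumcenters of every Delaunay triangle incident to the
#' site, merges coincident centers, and — for interior sites, whose
#' incident triangles close into a fan — orders them angularly around the
#' site into the cell polygon. Hull sites have an open fan: their cell is
#' unbounded and its area undefined (excluded from all statistics).
#'
#' @param site_index Index of the site in the triangulation's point set.
#' @param tri A `rice_delaunay` object from [delaunay()].
#' @return A list with `site_index`, `site` (x, y), `bounded`, `vertices`
#'   (ordered matrix for bounded cells, unordered circumcenters otherwise)
#'   and `area` (`NA` for unbounded cells).
#' @export
build_cell <- function(site_index, tri) {
  stopifnot(inherits(tri, "rice_delaunay"))
  tids <- tri$incidence[[site_index]]
  if (is.null(tids) || !length(tids)) {
    abort(sprintf("Site %d participates in no triangle.", site_index),
          class = "ricevor_degenerate_geometry")
  }
  verts <- tri$triangles[tids, , drop = FALSE]
  others <- verts[verts != site_index]
  bounded <- length(tids) >= 3 && all(tabulate(factor(others)) == 2L)
  v <- tri$circumcenters[tids, , drop = FALSE]
  v <- dedupe_vertices(v, 1e-9 * max(1, tri$span))
  site <- tri$points[site_index, ]
  area <- NA_real_
  if (bounded && nrow(v) >= 3) {
    ang <- atan2(v[, 2] - site[2], v[, 1] - site[1])
    v <- v[order(-ang), , drop = FALSE]  # clockwise in standard orientation
    area <- polygon_area(v)
  } else {
    bounded <- FALSE
  }
  list(site_index = site_index, site = site, bounded = bounded,
       vertices = v, area = area)
}

# TRUE for query points inside (or on, within tol) the convex hull of P0.
points_in_hull <- function(v, P0, tol) {
  h <- grDevices::chull(P0)
  hp <- P0[h, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3) return(rep(FALSE, nrow(v)))
  ctr <- colMeans(hp)
  inside <- rep(TRUE, nrow(v))
  for (e in seq_len(k)) {
    a <- hp[e, ]; b <- hp[if (e == k) 1 else e + 1, ]
    cross_q <- (b[1] - a[1]) * (v[, 2] - a[2]) - (b[2] - a[2]) * (v[, 1] - a[1])
    cross_c <- (b[1] - a[1]) * (ctr[2] - a[2]) - (b[2] - a[2]) * (ctr[1] - a[1])
    inside <- inside & (sign(cross_c) * cross_q >= -tol)
  }
  inside
}

#' Voronoi tessellation of cluster positions
#'
#' Tessellates a planar point set by the circumcenter construction: a
#' Delaunay triangulation is built, and each site's occupied region is the
#' polygon of circumcenters of its incident triangles. Bounded cells
#' satisfy the defining criteria of the occupied-region assignment: one
#' cell per site, pairwise disjoint interiors, full coverage of the
#' spanned region, and shared boundaries passing through the midpoint
#' between adjacent sites. Cells of convex-hull sites are unbounded and
#' carry `area = NA`. The construction is unit-agnostic: the downstream CV
#' index is identical for pixel or cm coordinates.
#'
#' Bounded cells of sites just inside the hull can still reach far outside
#' the stand (their vertices are circumcenters of sliver triangles along
#' the hull), and their areas reflect the arbitrary hull geometry, not
#' local crowding. Such cells are flagged `edge = TRUE` — the standard
#' border correction — and the area statistics use the `core` cells:
#' bounded, with every polygon vertex inside the convex hull of the sites.
#' On a perfect lattice every bounded cell is a core cell.
#'
#' @param points Data frame with `x`, `y` columns (>= 4 points with at
#'   least one interior point for a nontrivial result), or 2-column matrix.
#' @return A `rice_tessellation` object: list with `cells` (tibble:
#'   `site_id`, `x`, `y`, `bounded`, `edge`, `core`, `n_vertices`,
#'   `area`), `polygons` (list of ordered vertex matrices), `n_interior`
#'   (number of core cells), and `triangulation`.
#' @export
tessellate <- function(points) {
  tri <- delaunay(points)
  n <- nrow(tri$points)
  cells <- vector("list", n)
  for (i in seq_len(n)) cells[[i]] <- build_cell(i, tri)
  bounded <- vapply(cells, `[[`, logical(1), "bounded")
  tol <- 1e-9 * max(1, tri$span)
  edge <- vapply(seq_len(n), function(i) {
    if (!bounded[i]) return(TRUE)
    !all(points_in_hull(cells[[i]]$vertices, tri$points, tol))
  }, logical(1))
  tab <- tibble(
    site_id = seq_len(n),
    x = tri$points[, 1],
    y = tri$points[, 2],
    bounded = bounded,
    edge = edge,
    core = bounded & !edge,
    n_vertices = vapply(cells, function(c) nrow(c$vertices), integer(1)),
    area = vapply(cells, `[[`, double(1), "area")
  )
  structure(
    list(cells = tab,
         polygons = lapply(cells, `[[`, "vertices"),
         n_interior = sum(tab$core),
         triangulation = tri),
    class = "rice_tessellation"
  )
}

#' @export
print.rice_tessellation <- function(x, ...) {
  cat(sprintf("<rice_tessellation> %d sites, %d bounded cells\n",
              nrow(x$cells), x$n_interior))
  if (x$n_interior > 0) {
    a <- interior_areas(x)
    cat(sprintf("  bounded cell area: mean %.4g, cv %.4g\n",
                mean(a), stats::sd(a) * sqrt((length(a) - 1) / length(a)) / mean(a)))
  }
  invisible(x)
}

#' Areas of the core (interior, border-corrected) Voronoi cells
#'
#' Areas entering the heterogeneity statistics: bounded cells whose
#' polygon lies entirely inside the convex hull of the sites. Set
#' `include_edge = TRUE` to get every bounded cell instead.
#'
#' @param tess A `rice_tessellation`.
#' @param include_edge Also include bounded edge-affected cells.
#' @return Numeric vector of cell areas.
#' @export
interior_areas <- function(tess, include_edge = FALSE) {
  stopifnot(inherits(tess, "rice_tessellation"))
  sel <- if (include_edge) tess$cells$bounded else tess$cells$core
  tess$cells$area[sel]
}
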