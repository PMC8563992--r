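test_that("circumcenter is equidistant from the vertices", {
  expect_equal(circumcenter(c(0, 0), c(2, 0), c(0, 2)), c(1, 1))
  # equilateral triangle: circumcenter = centroid
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(circumcenter(eq[1, ], eq[2, ], eq[3, ]), colMeans(eq),
               tolerance = 1e-12)
  set.seed(3)
  for (k in 1:20) {
    p <- matrix(rnorm(6, sd = 10), 3, 2)
    cc <- tryCatch(circumcenter(p[1, ], p[2, ], p[3, ]), error = function(e) NULL)
    if (is.null(cc)) next
    d <- sqrt(rowSums(sweep(p, 2, cc)^2))
    expect_lt(max(d) - min(d), 1e-9 * max(d))
  }
  expect_error(circumcenter(c(0, 0), c(1, 1), c(2, 2)),
               class = "ricevor_degenerate_geometry")
})

test_that("delaunay triangulates simple configurations correctly", {
  tri <- delaunay(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_identical(nrow(tri$triangles), 1L)

  sq <- delaunay(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_identical(nrow(sq$triangles), 2L)
  # the two triangles share exactly one diagonal edge
  edges <- apply(sq$triangles, 1, function(v) {
    combn(sort(v), 2, paste, collapse = "-")
  })
  expect_identical(sum(table(c(edges)) == 2), 1L)

  expect_error(delaunay(cbind(0:4, 0:4)), class = "ricevor_degenerate_input")
  expect_error(delaunay(rbind(c(0, 0), c(1, 1))), class = "ricevor_degenerate_input")
  expect_error(delaunay(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))),
               class = "ricevor_degenerate_input")
})

test_that("delaunay satisfies the empty-circumcircle property on random sets", {
  set.seed(11)
  for (rep in 1:10) {
    P <- cbind(runif(25, 0, 100), runif(25, 0, 100))
    tri <- delaunay(P)
    for (t in seq_len(nrow(tri$triangles))) {
      v <- tri$triangles[t, ]
      cc <- tri$circumcenters[t, ]
      r2 <- sum((P[v[1], ] - cc)^2)
      d2 <- (P[, 1] - cc[1])^2 + (P[, 2] - cc[2])^2
      inside <- setdiff(which(d2 < r2 * (1 - 1e-9)), v)
      expect_length(inside, 0)
    }
  }
})

test_that("polygon_area is the orientation-invariant shoelace value", {
  sqr <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sqr), 1)
  expect_equal(polygon_area(sqr[4:1, ]), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0))),
               class = "ricevor_degenerate_input")
})

test_that("lattice cells are rectangles of area PD x RD", {
  # 3x3 unit lattice: centre cell is the unit square
  lat3 <- lattice_points(3, 3, pd = 1, rd = 1)
  t3 <- tessellate(lat3)
  expect_identical(t3$n_interior, 1L)
  expect_equal(interior_areas(t3), 1)
  centre <- which(t3$cells$bounded)
  expect_identical(t3$cells$site_id[centre], 5L)

  # anisotropic spacing: cell area equals PD * RD exactly
  t32 <- tessellate(lattice_points(5, 5, pd = 3, rd = 2))
  expect_equal(interior_areas(t32), rep(6, 9), tolerance = 1e-9)

  # 15 x 15 lattice with RD:PD = 2:3 -> 13 x 13 bounded cells
  t15 <- tessellate(lattice_points(15, 15, pd = 30, rd = 20))
  expect_identical(t15$n_interior, 169L)
  expect_equal(interior_areas(t15), rep(600, 169), tolerance = 1e-6)
  # corner and edge sites are unbounded
  corner <- t15$cells[t15$cells$x == 30 & t15$cells$y == 20, ]
  expect_false(corner$bounded)
})

test_that("every bounded cell contains its own site", {
  set.seed(21)
  P <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  tess <- tessellate(P)
  for (i in which(tess$cells$bounded)) {
    ring <- tess$polygons[[i]]
    # winding: site inside convex ring iff all cross products share a sign
    v <- sweep(ring, 2, c(tess$cells$x[i], tess$cells$y[i]))
    k <- nrow(v)
    cr <- v[, 1] * v[c(2:k, 1), 2] - v[c(2:k, 1), 1] * v[, 2]
    expect_true(all(cr > 0) || all(cr < 0))
  }
})

test_that("circumcenter-ring areas match the half-plane-intersection oracle", {
  set.seed(31)
  n_sets <- 55
  checked <- 0
  for (rep in seq_len(n_sets)) {
    n <- sample(8:30, 1)
    P <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    tess <- tessellate(P)
    for (i in seq_len(n)) {
      want <- oracle_voronoi_cell(i, P)
      expect_identical(tess$cells$bounded[i], want$bounded)
      if (want$bounded) {
        a_want <- oracle_polygon_area(want$vertices)
        expect_equal(tess$cells$area[i], a_want, tolerance = 1e-8)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 200)
})

test_that("shared cell boundaries lie on the site-pair perpendicular bisector", {
  # the shared boundary of two adjacent cells is a segment of the
  # perpendicular bisector of their sites, whose line passes the midpoint
  set.seed(41)
  P <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  tess <- tessellate(P)
  tri <- tess$triangulation
  checked <- 0
  edges <- unique(t(apply(
    rbind(tri$triangles[, 1:2], tri$triangles[, 2:3], tri$triangles[, c(3, 1)]),
    1, sort)))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (!tess$cells$bounded[i] || !tess$cells$bounded[j]) next
    share <- which(apply(tri$triangles, 1, function(v) all(c(i, j) %in% v)))
    if (length(share) != 2) next
    c1 <- tri$circumcenters[share[1], ]; c2 <- tri$circumcenters[share[2], ]
    seg <- c2 - c1
    if (sqrt(sum(seg^2)) < 1e-9) next
    mid <- (P[i, ] + P[j, ]) / 2
    d_line <- abs(seg[1] * (mid[2] - c1[2]) - seg[2] * (mid[1] - c1[1])) /
      sqrt(sum(seg^2))
    expect_lt(d_line, 1e-9)
    checked <- checked + 1
  }
  expect_gt(checked, 10)

  # on a lattice the midpoint lies on the shared edge segment itself
  latt <- tessellate(lattice_points(5, 5, pd = 3, rd = 2))
  cells <- latt$cells
  core <- cells[cells$bounded, ]
  for (k in seq_len(nrow(core) - 1)) {
    a <- core[k, ]
    nb <- core[core$y == a$y & abs(core$x - a$x - 3) < 1e-9, ]
    if (nrow(nb) != 1) next
    mid <- c((a$x + nb$x) / 2, (a$y + nb$y) / 2)
    expect_lt(oracle_dist_to_ring(mid, latt$polygons[[a$site_id]]), 1e-9)
    expect_lt(oracle_dist_to_ring(mid, latt$polygons[[nb$site_id]]), 1e-9)
  }
})

test_that("tessellation is equivariant under rigid motions", {
  set.seed(51)
  P <- cbind(runif(25, 0, 10), runif(25, 0, 10))
  base <- tessellate(P)
  theta <- 0.7
  Rm <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  moved <- tessellate(P %*% t(Rm) + matrix(c(5, -3), 25, 2, byrow = TRUE))
  expect_identical(base$cells$bounded, moved$cells$bounded)
  sel <- base$cells$bounded
  expect_equal(moved$cells$area[sel], base$cells$area[sel], tolerance = 1e-9)
})

test_that("total bounded area is invariant to point ordering", {
  set.seed(61)
  P <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  t1 <- tessellate(P)
  perm <- sample(30)
  t2 <- tessellate(P[perm, ])
  expect_equal(sum(t1$cells$area[t1$cells$bounded]),
               sum(t2$cells$area[t2$cells$bounded]), tolerance = 1e-9)
  expect_identical(t1$n_interior, t2$n_interior)
})

test_that("edge-affected cells are excluded from area statistics", {
  set.seed(71)
  P <- cbind(runif(100, 0, 100), runif(100, 0, 100))
  tess <- tessellate(P)
  expect_true(all(tess$cells$core == (tess$cells$bounded & !tess$cells$edge)))
  expect_identical(tess$n_interior, sum(tess$cells$core))
  expect_lt(tess$n_interior, sum(tess$cells$bounded))
  # core areas are never the wild hull-sliver ones
  expect_lt(max(interior_areas(tess)), 10 * mean(interior_areas(tess)))
  expect_identical(length(interior_areas(tess, include_edge = TRUE)),
                   sum(tess$cells$bounded))
})

test_that("cv is identical for pixel and ground units", {
  set.seed(81)
  P <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  cv_px <- heterogeneity_cv(tessellate(P))$cv
  cv_cm <- heterogeneity_cv(tessellate(P * 0.2))$cv
  expect_equal(cv_px, cv_cm, tolerance = 1e-12)
})
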