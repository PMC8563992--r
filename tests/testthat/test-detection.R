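make_image <- function(R, G, B, gsd = NULL) {
  arr <- array(0L, dim = c(nrow(R), ncol(R), 3))
  arr[, , 1] <- R; arr[, , 2] <- G; arr[, , 3] <- B
  rice_image(arr, gsd = gsd)
}

test_that("binarize applies the colour rule pixel-wise with strict inequalities", {
  R <- matrix(c(240, 240, 0, 221), 2, 2)
  G <- matrix(c(230, 230, 0, 221), 2, 2)
  B <- matrix(c(150, 200, 0, 199), 2, 2)
  m <- binarize(make_image(R, G, B))
  expect_identical(m[1, 1], 1L)  # (240+230)/2 = 235 > 220 and 150 < 200
  expect_identical(m[2, 1], 0L)  # B = 200 is not strictly < 200
  expect_identical(m[1, 2], 0L)  # black pixel
  expect_identical(m[2, 2], 1L)  # 221 > 220, 199 < 200

  black <- make_image(matrix(0, 4, 5), matrix(0, 4, 5), matrix(0, 4, 5))
  expect_true(all(binarize(black) == 0L))
})

test_that("binarize commutes with row permutations of the image", {
  set.seed(101)
  R <- matrix(sample(0:255, 60, TRUE), 6, 10)
  G <- matrix(sample(0:255, 60, TRUE), 6, 10)
  B <- matrix(sample(0:255, 60, TRUE), 6, 10)
  perm <- sample(6)
  m1 <- binarize(make_image(R, G, B))[perm, ]
  m2 <- binarize(make_image(R[perm, ], G[perm, ], B[perm, ]))
  expect_identical(m1, m2)
})

test_that("binarize rejects non-image input", {
  expect_error(binarize(matrix(0, 3, 3)), class = "ricevor_invalid_input")
  expect_error(rice_image(array(300, dim = c(2, 2, 3))),
               class = "ricevor_invalid_input")
})

test_that("component major axis length matches the second-moment oracle", {
  # 1 x 10 horizontal run: oracle value 4 * sqrt(99/12) ~ 11.489
  mask <- matrix(0L, 5, 14)
  mask[3, 3:12] <- 1L
  comp <- label_components(mask)
  expect_equal(comp$table$major_axis_length,
               oracle_major_axis(cbind(rep(3, 10), 3:12)))
  expect_gt(comp$table$major_axis_length, 3)

  set.seed(7)
  blob <- fixture_disc_mask(40, 40, cbind(20, 20), 8)
  got <- label_components(blob)$table$major_axis_length
  rc <- which(blob == 1, arr.ind = TRUE)
  expect_equal(got, oracle_major_axis(rc), tolerance = 1e-12)
})

test_that("remove_noise drops sub-threshold components and never adds pixels", {
  mask <- matrix(0L, 8, 16)
  mask[2, 2] <- 1L           # isolated pixel, major axis 0
  mask[5, 3:12] <- 1L        # 1 x 10 run, major axis ~ 11.5
  out <- remove_noise(mask)
  expect_identical(sum(out[2, ]), 0L)
  expect_identical(out[5, 3:12], rep(1L, 10))
  expect_true(all(out <= mask))

  empty <- matrix(0L, 4, 4)
  expect_identical(remove_noise(empty), empty)
})

test_that("disc dilation matches the Euclidean-distance definition and is extensive", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  d1 <- dilate_disk(m, 1)
  expect_identical(sum(d1), 5L)  # centre + 4-neighbour cross
  expect_identical(d1[4, 3:5], rep(1L, 3))
  expect_identical(d1[3, 4], 1L)
  expect_identical(d1[3, 3], 0L)

  # radius 2: enumerate offsets with dr^2 + dc^2 <= 4
  d2 <- dilate_disk(m, 2)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  expected <- sum(offs$dr^2 + offs$dc^2 <= 4)
  expect_identical(sum(d2), as.integer(expected))

  set.seed(42)
  rnd <- matrix(rbinom(15 * 15, 1, 0.2), 15, 15)
  expect_true(all(dilate_disk(rnd, 3) >= rnd))
  empty <- matrix(0L, 5, 5)
  expect_identical(dilate_disk(empty, 4), empty)
  expect_error(dilate_disk(m, 0), class = "ricevor_invalid_parameter")
})

test_that("erosion matches the all-neighbours-foreground definition", {
  blob <- fixture_disc_mask(31, 31, rbind(c(16, 16), c(5, 26)), c(9, 3))
  r <- 3
  er <- erode_disk(blob, r)
  expect_true(all(er <= blob))
  # oracle: pixel survives iff every pixel within Euclidean distance r is
  # foreground (out-of-image neighbours count as background)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  want <- matrix(0L, 31, 31)
  for (rr in 1:31) for (cc in 1:31) {
    nb_r <- rr + offs$dr; nb_c <- cc + offs$dc
    inb <- nb_r >= 1 & nb_r <= 31 & nb_c >= 1 & nb_c <= 31
    want[rr, cc] <- as.integer(all(inb) && all(blob[cbind(nb_r, nb_c)] == 1L))
  }
  expect_identical(er, want)
})

test_that("labeling respects 4- vs 8-connectivity and matches flood fill", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_identical(nrow(label_components(m, 8)$table), 1L)
  expect_identical(nrow(label_components(m, 4)$table), 2L)
  expect_identical(nrow(label_components(matrix(0L, 3, 3))$table), 0L)

  set.seed(99)
  for (conn in c(4, 8)) {
    for (rep in 1:5) {
      rnd <- matrix(rbinom(20 * 25, 1, 0.35), 20, 25)
      got <- label_components(rnd, conn)
      want <- oracle_label(rnd, conn)
      expect_identical(max(got$labels), max(want))
      # same partition: label images agree up to renumbering
      key_got <- got$labels[rnd == 1]
      key_want <- want[rnd == 1]
      expect_identical(length(unique(paste(key_got, key_want))),
                       length(unique(key_got)))
    }
  }
})

test_that("component centroids are pixel-coordinate means and border flags set", {
  mask <- matrix(0L, 6, 6)
  mask[2:3, 2:3] <- 1L   # 2x2 block, centroid (1.5, 1.5) 0-based
  mask[1, 6] <- 1L       # border pixel
  tab <- label_components(mask)$table
  blk <- tab[tab$area == 4, ]
  expect_equal(blk$centroid_row, 1.5)
  expect_equal(blk$centroid_col, 1.5)
  expect_false(blk$on_border)
  expect_true(tab$on_border[tab$area == 1])
})

test_that("split_and_refine separates merged blobs and filters small remnants", {
  # eight ordinary hills (discs r = 12) plus one giant of two tangent discs
  centers <- rbind(
    cbind(rep(c(40, 100, 160, 220), 2), rep(c(40, 100), each = 4)))
  nr <- 380; nc <- 260
  mask <- fixture_disc_mask(nr, nc, centers, rep(12, 8))
  giant_a <- c(262, 80); giant_b <- c(318, 80)  # tangent: distance 56 = 2 * 28
  mask <- pmax(mask, fixture_disc_mask(nr, nc, rbind(giant_a, giant_b), c(28, 28)))
  comp <- label_components(mask)
  expect_identical(nrow(comp$table), 9L)

  pts <- split_and_refine(comp, detection_params())
  expect_identical(sum(pts$stage == "direct"), 8L)
  expect_identical(sum(pts$stage == "refined"), 2L)
  ref <- pts[pts$stage == "refined", ]
  ref <- ref[order(ref$row_px), ]
  expect_lt(abs(ref$row_px[1] - (giant_a[1] - 1)), 2)
  expect_lt(abs(ref$col_px[1] - (giant_a[2] - 1)), 2)
  expect_lt(abs(ref$row_px[2] - (giant_b[1] - 1)), 2)

  # a giant whose eroded remnants are too small contributes nothing
  mask2 <- fixture_disc_mask(200, 200, rbind(c(50, 50), c(50, 120), c(140, 50),
                                             c(140, 120), c(95, 160)),
                             c(6, 6, 6, 6, 15))
  comp2 <- label_components(mask2)
  pts2 <- split_and_refine(comp2, detection_params())
  expect_identical(sum(pts2$stage == "refined"), 0L)
  expect_identical(sum(pts2$stage == "direct"), 4L)
})

test_that("equal-area components are all accepted directly", {
  mask <- fixture_disc_mask(150, 150, rbind(c(40, 40), c(40, 110), c(110, 40)),
                            c(10, 10, 10))
  pts <- split_and_refine(label_components(mask), detection_params())
  expect_identical(nrow(pts), 3L)
  expect_true(all(pts$stage == "direct"))
})

test_that("detect_clusters recovers every cluster on a clean rendered scene", {
  pos <- lattice_points(3, 3, pd = 16, rd = 16)
  sc <- render_scene(pos, width = 320, height = 320, seed = 5)
  det <- detect_clusters(sc$image)
  expect_identical(nrow(det), 9L)
  m <- match_positions(det, sc$truth, max_dist = 30)
  expect_identical(m$counts$TP, 9L)
  expect_identical(m$counts$FP, 0L)
  expect_lt(max(m$pairs$distance), 5)
  # determinism
  det2 <- detect_clusters(sc$image)
  expect_identical(as.data.frame(det), as.data.frame(det2))
  # ground coordinates follow the gsd
  expect_equal(det$x_cm, det$col_px * 0.2)
})

test_that("detection returns no positions on a soil-only scene", {
  sc <- render_scene(tibble::tibble(x = numeric(), y = numeric()),
                     width = 120, height = 120,
                     bubble_density = 5e-5, seed = 3)
  det <- detect_clusters(sc$image)
  expect_identical(nrow(det), 0L)
})

test_that("pipeline is equivariant to integer translations away from borders", {
  pos <- lattice_points(3, 3, pd = 16, rd = 16)
  sc <- render_scene(pos, width = 340, height = 340, seed = 8,
                     bubble_density = 0, speckle_density = 0)
  base <- detect_clusters(sc$image)
  dr <- 6L; dc <- 9L
  arr <- sc$image$data
  shifted <- array(70L, dim = dim(arr))  # constant soil-coloured fill
  shifted[, , 2] <- 60L; shifted[, , 3] <- 40L
  h <- dim(arr)[1]; w <- dim(arr)[2]
  shifted[(1 + dr):h, (1 + dc):w, ] <- arr[1:(h - dr), 1:(w - dc), ]
  det2 <- detect_clusters(rice_image(shifted, gsd = 0.2))
  expect_identical(nrow(det2), nrow(base))
  o1 <- order(base$row_px, base$col_px)
  o2 <- order(det2$row_px, det2$col_px)
  expect_equal(det2$row_px[o2], base$row_px[o1] + dr, tolerance = 1e-8)
  expect_equal(det2$col_px[o2], base$col_px[o1] + dc, tolerance = 1e-8)
})

test_that("pixel_to_ground scales coordinates and distances linearly", {
  pts <- tibble::tibble(row_px = c(100, 40), col_px = c(50, 80))
  out <- pixel_to_ground(pts, gsd = 0.2)
  expect_equal(out$x_cm, c(10, 16))
  expect_equal(out$y_cm, c(20, 8))
  d_px <- sqrt(diff(pts$row_px)^2 + diff(pts$col_px)^2)
  d_cm <- sqrt(diff(out$y_cm)^2 + diff(out$x_cm)^2)
  expect_equal(d_cm, d_px * 0.2)
  ident <- pixel_to_ground(pts, gsd = 1)
  expect_equal(ident$x_cm, pts$col_px)
  expect_error(pixel_to_ground(pts, gsd = 0), class = "ricevor_invalid_parameter")
  expect_error(pixel_to_ground(pts, gsd = -1), class = "ricevor_invalid_parameter")
})
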