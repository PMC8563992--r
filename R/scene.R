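#' Render a synthetic paddy-field scene with exact ground truth
#'
#' Draws a nadir RGB image emulating light-yellow upright seedlings on dark
#' soil shortly after transplanting: each cluster is a tuft of blades
#' (thick line segments radiating from the cluster position at evenly
#' spread, jittered angles, the way shoots of one hill fan out in every
#' direction), optionally with high-blue "bubble" discs on the water surface
#' and isolated bright speckle pixels. Colour samplers are constrained so
#' that every blade pixel satisfies the detection colour rule
#' `(R + G)/2 > 220 & B < 200`, soil always fails the first clause, and
#' bubbles always fail the second (`B >= 200`) — so the renderer exercises
#' exactly the contrasts the detector relies on. Deterministic under
#' `seed`.
#'
#' @param positions Data frame of cluster positions in cm (`x`, `y`), e.g.
#'   from [lattice_points()] or [perturb_lattice()]. Mapped to pixels as
#'   `col_px = x / gsd`, `row_px = y / gsd`; positions outside the image
#'   are an error listing the offenders.
#' @param width,height Image size in pixels.
#' @param gsd Ground-sampling distance in cm per pixel (default 0.2).
#' @param blades_per_cluster Number of blades per tuft (default 7).
#' @param blade_length_px Maximum blade length in pixels (default 18).
#' @param blade_width_px Blade stroke width in pixels (default 3).
#' @param bubble_density Expected bubbles per pixel (default 2e-5).
#' @param speckle_density Expected speckle pixels per pixel (default 5e-4).
#' @param seed Optional integer seed.
#' @return A `rice_scene` object: list with `image` (a [rice_image()] with
#'   the given `gsd`), `truth` (tibble `id`, `row_px`, `col_px`, `x_cm`,
#'   `y_cm`, `n_pixels`) and `foreground` (0/1 matrix of rendered blade
#'   pixels).
#' @export
render_scene <- function(positions, width = 320, height = 320, gsd = 0.2,
                         blades_per_cluster = 7, blade_length_px = 18,
                         blade_width_px = 3, bubble_density = 2e-5,
                         speckle_density = 5e-4, seed = NULL) {
  check_gsd(gsd)
  positions <- as.data.frame(positions)
  if (nrow(positions) > 0 && !all(c("x", "y") %in% names(positions))) {
    abort("`positions` needs `x` and `y` columns (cm).", class = "ricevor_invalid_input")
  }
  row_px <- if (nrow(positions)) positions$y / gsd else numeric()
  col_px <- if (nrow(positions)) positions$x / gsd else numeric()
  outside <- which(row_px < 0 | row_px > height - 1 | col_px < 0 | col_px > width - 1)
  if (length(outside)) {
    abort(sprintf("Positions outside the %d x %d image at gsd %g: %s",
                  height, width, gsd, paste(outside, collapse = ", ")),
          class = "ricevor_invalid_input")
  }
  npx <- height * width
  with_seed_or_stream(seed, {
    R <- matrix(floor(runif(npx, 60, 121)), height, width)
    Gc <- matrix(floor(runif(npx, 50, 111)), height, width)
    B <- matrix(floor(runif(npx, 30, 91)), height, width)

    # high-blue bubbles: bright in R and G but rejected by the B clause
    n_bub <- stats::rpois(1, bubble_density * npx)
    for (b in seq_len(n_bub)) {
      ctr <- c(runif(1, 0, height - 1), runif(1, 0, width - 1))
      rad <- runif(1, 2, 5)
      px <- disc_pixels(ctr[1], ctr[2], rad, height, width)
      R[px] <- floor(runif(length(px), 210, 256))
      Gc[px] <- floor(runif(length(px), 210, 256))
      B[px] <- floor(runif(length(px), 200, 256))
    }

    # isolated bright speckles (sub-threshold major axis; denoise removes them)
    n_spk <- stats::rpois(1, speckle_density * npx)
    if (n_spk > 0) {
      px <- sample.int(npx, min(n_spk, npx))
      R[px] <- floor(runif(length(px), 230, 256))
      Gc[px] <- floor(runif(length(px), 225, 256))
      B[px] <- floor(runif(length(px), 120, 181))
    }

    # seedling tufts, drawn last so clusters are never occluded
    fg <- matrix(0L, height, width)
    n_pixels <- integer(nrow(positions))
    for (k in seq_len(nrow(positions))) {
      px <- integer()
      base_ang <- runif(1, 0, 2 * pi)
      for (bl in seq_len(blades_per_cluster)) {
        # shoots spread roughly radially in all directions around the hill
        ang <- base_ang + 2 * pi * (bl - 1) / blades_per_cluster +
          runif(1, -0.25, 0.25)
        len <- blade_length_px * runif(1, 0.8, 1)
        tt <- seq(0, len, by = 0.5)
        rr <- row_px[k] + sin(ang) * tt
        cc <- col_px[k] + cos(ang) * tt
        for (s in seq_along(tt)) {
          px <- c(px, disc_pixels(rr[s], cc[s], blade_width_px / 2, height, width))
        }
      }
      px <- unique(px)
      fg[px] <- 1L
      n_pixels[k] <- length(px)
      R[px] <- floor(runif(length(px), 230, 256))
      Gc[px] <- floor(runif(length(px), 225, 256))
      B[px] <- floor(runif(length(px), 120, 181))
    }

    img <- array(0L, dim = c(height, width, 3L))
    img[, , 1] <- R; img[, , 2] <- Gc; img[, , 3] <- B
    truth <- tibble(
      id = seq_len(nrow(positions)),
      row_px = row_px, col_px = col_px,
      x_cm = col_px * gsd, y_cm = row_px * gsd,
      n_pixels = n_pixels
    )
    structure(
      list(image = rice_image(img, gsd = gsd), truth = truth, foreground = fg),
      class = "rice_scene"
    )
  })
}

# Linear indices of pixels within `rad` of (r0, c0), clipped to the image.
disc_pixels <- function(r0, c0, rad, height, width) {
  rs <- max(0, floor(r0 - rad)):min(height - 1, ceiling(r0 + rad))
  cs <- max(0, floor(c0 - rad)):min(width - 1, ceiling(c0 + rad))
  if (!length(rs) || !length(cs)) return(integer())
  g <- expand.grid(r = rs, c = cs)
  sel <- (g$r - r0)^2 + (g$c - c0)^2 <= rad^2
  as.integer(g$r[sel] + g$c[sel] * height + 1L)
}

#' @export
print.rice_scene <- function(x, ...) {
  cat(sprintf("<rice_scene> %d x %d px, %d clusters, gsd %.3g cm/px\n",
              x$image$height, x$image$width, nrow(x$truth), x$image$gsd))
  invisible(x)
}

#' Write / read ground-truth cluster positions
#'
#' Plain CSV with header `id,row_px,col_px,x_cm,y_cm,n_pixels`
#' (`n_pixels` optional on read). `read_ground_truth(write_ground_truth(x))`
#' is the identity; malformed numeric fields raise a parse error naming the
#' offending line.
#'
#' @param truth Ground-truth tibble (from `render_scene()$truth`).
#' @param path CSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  need <- c("id", "row_px", "col_px", "x_cm", "y_cm")
  if (!all(need %in% names(truth))) {
    abort("Ground truth needs id,row_px,col_px,x_cm,y_cm columns.",
          class = "ricevor_invalid_input")
  }
  cols <- c(need, intersect("n_pixels", names(truth)))
  readr::write_csv(as_tibble(truth)[cols], path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read_point_csv(path, required = c("id", "row_px", "col_px", "x_cm", "y_cm"))
}
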