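#' Colour-rule binarization of a field image
#'
#' Classifies each pixel as seedling foreground when `(R + G)/2` strictly
#' exceeds `rg_threshold` and `B` is strictly below `b_threshold`. The rule
#' exploits that light-yellow seedlings have high red and green but moderate
#' blue, soil is dark in all channels, and water-surface bubbles — though
#' bright in R and G — carry a high blue channel and are rejected by the
#' second clause.
#'
#' @param image A [rice_image()].
#' @param params A [detection_params()] list.
#' @return An integer 0/1 matrix of dimension `height x width`.
#' @export
binarize <- function(image, params = detection_params()) {
  if (!inherits(image, "rice_image")) {
    abort("`image` must be a rice_image (8-bit RGB).", class = "ricevor_invalid_input")
  }
  stopifnot(inherits(params, "rice_detection_params"))
  rg <- (image$data[, , 1] + image$data[, , 2]) / 2
  mask <- (rg > params$rg_threshold) & (image$data[, , 3] < params$b_threshold)
  matrix(as.integer(mask), nrow = image$height, ncol = image$width)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    abort("`mask` must be a 0/1 matrix.", class = "ricevor_invalid_input")
  }
  invisible(mask)
}

#' Discrete disc structuring element
#'
#' Returns the `(2r+1) x (2r+1)` 0/1 matrix with entry 1 at offset
#' `(dr, dc)` iff `dr^2 + dc^2 <= r^2`. This definition is fixed because the
#' bit-exact behaviour of the morphological steps depends on it.
#'
#' @param radius Disc radius in pixels, >= 1.
#' @return An integer 0/1 matrix.
#' @export
disc_kernel <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius < 1) {
    abort("`radius` must be a single number >= 1.", class = "ricevor_invalid_parameter")
  }
  r <- floor(radius)
  d <- seq.int(-r, r)
  matrix(as.integer(outer(d^2, d^2, `+`) <= radius^2), nrow = 2 * r + 1)
}

#' Disc dilation / erosion of a binary mask
#'
#' `dilate_disk()` unions discs of the given radius centred on every
#' foreground pixel (used to merge the shoots of one rice hill into a single
#' blob); `erode_disk()` is its adjoint and shrinks blobs (used to split
#' merged hills).
#'
#' @param mask A 0/1 matrix.
#' @param radius Disc radius in pixels, >= 1 (see [disc_kernel()]).
#' @return A 0/1 matrix of the same dimension.
#' @export
dilate_disk <- function(mask, radius) {
  check_mask(mask)
  k <- disc_kernel(radius)
  out <- EBImage::dilate(mask, k)
  matrix(as.integer(out > 0), nrow = nrow(mask))
}

#' @rdname dilate_disk
#' @export
erode_disk <- function(mask, radius) {
  check_mask(mask)
  k <- disc_kernel(radius)
  out <- EBImage::erode(mask, k)
  matrix(as.integer(out > 0), nrow = nrow(mask))
}

# Merge 4-connected labels that touch diagonally, giving 8-connected
# components. Union-find over the label ids found in diagonally adjacent
# pixel pairs.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L || max(lab) == 0) return(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Label connected components and measure them
#'
#' Labels the foreground of a binary mask (4- or 8-connectivity) and
#' computes, per component: pixel area, centroid (unweighted mean of member
#' pixel coordinates, 0-based `(row, col)`), the major axis length of the
#' ellipse with matching second central moments (`4 * sqrt(lambda_max)` of
#' the per-pixel coordinate covariance with divisor n; 0 for a single
#' pixel), and whether the component touches the image border.
#'
#' @param mask A 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A `rice_components` object: list with `labels` (integer matrix,
#'   0 = background, components numbered 1..k) and `table` (tibble with
#'   columns `id`, `area`, `major_axis_length`, `centroid_row`,
#'   `centroid_col`, `on_border`).
#' @export
label_components <- function(mask, connectivity = 8) {
  check_mask(mask)
  if (!connectivity %in% c(4, 8)) {
    abort("`connectivity` must be 4 or 8.", class = "ricevor_invalid_parameter")
  }
  lab <- EBImage::bwlabel(mask)  # 4-connected
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)
  # renumber to consecutive 1..k in first-pixel order
  ids <- unique(lab[lab > 0])
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(
    list(labels = lab, table = component_table(lab), connectivity = connectivity),
    class = "rice_components"
  )
}

# Vectorised per-label geometry from a label matrix.
component_table <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(tibble(
      id = integer(), area = integer(), major_axis_length = double(),
      centroid_row = double(), centroid_col = double(), on_border = logical()
    ))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  g <- lab[idx]
  r <- (idx - 1L) %% nr     # 0-based row
  cc <- (idx - 1L) %/% nr   # 0-based col
  k <- max(g)
  n <- tabulate(g, k)
  sr <- rowsum_vec(r, g, k) / n
  sc <- rowsum_vec(cc, g, k) / n
  mu_rr <- rowsum_vec(r * r, g, k) / n - sr^2
  mu_cc <- rowsum_vec(cc * cc, g, k) / n - sc^2
  mu_rc <- rowsum_vec(r * cc, g, k) / n - sr * sc
  lam <- ((mu_rr + mu_cc) + sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)) / 2
  border <- rowsum_vec(as.numeric(r == 0 | r == nr - 1L | cc == 0 | cc == nc - 1L), g, k) > 0
  tibble(
    id = seq_len(k),
    area = as.integer(n),
    major_axis_length = 4 * sqrt(pmax(lam, 0)),
    centroid_row = sr,
    centroid_col = sc,
    on_border = border
  )
}

rowsum_vec <- function(x, g, k) {
  out <- numeric(k)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Remove small noise components
#'
#' Drops every connected component whose second-moment major axis length is
#' strictly smaller than `min_denoise_major_axis` (isolated pixels have
#' length 0 and always go). No foreground pixel is ever added.
#'
#' @inheritParams binarize
#' @param mask A 0/1 matrix.
#' @return A 0/1 matrix.
#' @export
remove_noise <- function(mask, params = detection_params()) {
  comp <- label_components(mask, params$connectivity)
  if (nrow(comp$table) == 0) return(mask)
  keep <- comp$table$id[comp$table$major_axis_length >= params$min_denoise_major_axis]
  matrix(as.integer(comp$labels %in% keep), nrow = nrow(mask))
}

#' Quantile split and erosion refinement of labelled components
#'
#' Components whose area is at or below the `split_quantile` area quantile
#' are accepted as single rice clusters and contribute their centroid
#' directly (`stage = "direct"`). Larger components — candidates for several
#' hills merged by the dilation — are eroded with a disc of
#' `erosion_radius`, relabelled, and each eroded sub-component with strictly
#' more than `refine_min_area` pixels and a major axis strictly above
#' `refine_min_major_axis` contributes its centroid (`stage = "refined"`).
#'
#' @param components A `rice_components` object from [label_components()].
#' @param params A [detection_params()] list.
#' @return A tibble with columns `row_px`, `col_px`, `stage`, `area`,
#'   `on_border`.
#' @export
split_and_refine <- function(components, params = detection_params()) {
  stopifnot(inherits(components, "rice_components"))
  tab <- components$table
  empty <- tibble(
    row_px = double(), col_px = double(), stage = character(),
    area = integer(), on_border = logical()
  )
  if (nrow(tab) == 0) return(empty)
  q <- quantile(tab$area, params$split_quantile, type = 7, names = FALSE)
  direct <- tab[tab$area <= q, ]
  out <- tibble(
    row_px = direct$centroid_row, col_px = direct$centroid_col,
    stage = rep("direct", nrow(direct)),
    area = direct$area, on_border = direct$on_border
  )
  big_ids <- tab$id[tab$area > q]
  if (length(big_ids)) {
    big_mask <- matrix(as.integer(components$labels %in% big_ids),
                       nrow = nrow(components$labels))
    eroded <- erode_disk(big_mask, params$erosion_radius)
    sub <- label_components(eroded, components$connectivity)$table
    keep <- sub[sub$area > params$refine_min_area &
                  sub$major_axis_length > params$refine_min_major_axis, ]
    out <- dplyr::bind_rows(out, tibble(
      row_px = keep$centroid_row, col_px = keep$centroid_col,
      stage = rep("refined", nrow(keep)),
      area = keep$area, on_border = keep$on_border
    ))
  }
  dplyr::distinct(out, .data$row_px, .data$col_px, .keep_all = TRUE)
}

#' Detect rice clusters in a field image
#'
#' Runs the full recognition pipeline: colour-rule binarization, removal of
#' small-noise components, disc dilation to merge the shoots of each hill,
#' component labeling, and the quantile-split / erosion refinement that
#' separates hills merged by the dilation. Deterministic for fixed input
#' and parameters.
#'
#' @inheritParams binarize
#' @return A tibble of class `rice_clusters` with columns `id`, `row_px`,
#'   `col_px`, `x_cm`, `y_cm` (`NA` when the image has no ground-sampling
#'   distance), `stage` (`"direct"` or `"refined"`) and `on_border`.
#'   Attributes: `gsd`, `provenance = "detected"`.
#' @export
detect_clusters <- function(image, params = detection_params()) {
  mask <- binarize(image, params)
  mask <- remove_noise(mask, params)
  mask <- dilate_disk(mask, params$dilation_radius)
  comp <- label_components(mask, params$connectivity)
  pts <- split_and_refine(comp, params)
  res <- tibble(
    id = seq_len(nrow(pts)),
    row_px = pts$row_px, col_px = pts$col_px,
    x_cm = if (is.null(image$gsd)) NA_real_ else pts$col_px * image$gsd,
    y_cm = if (is.null(image$gsd)) NA_real_ else pts$row_px * image$gsd,
    stage = pts$stage, on_border = pts$on_border
  )
  new_rice_clusters(res, gsd = image$gsd, provenance = "detected")
}

new_rice_clusters <- function(df, gsd = NULL, provenance = "detected") {
  structure(
    as_tibble(df),
    gsd = gsd, provenance = provenance,
    class = c("rice_clusters", class(tibble()))
  )
}

#' Convert pixel coordinates to ground distances
#'
#' Multiplies pixel coordinates by the ground-sampling distance, filling the
#' `x_cm` (from `col_px`) and `y_cm` (from `row_px`) columns. Pairwise
#' distances scale exactly linearly with `gsd`.
#'
#' @param points A data frame with `row_px` and `col_px` columns.
#' @param gsd Ground-sampling distance in cm per pixel, > 0.
#' @return The input with `x_cm` and `y_cm` (re)computed; `gsd` recorded as
#'   an attribute.
#' @export
pixel_to_ground <- function(points, gsd) {
  check_gsd(gsd)
  if (!all(c("row_px", "col_px") %in% names(points))) {
    abort("`points` needs `row_px` and `col_px` columns.", class = "ricevor_invalid_input")
  }
  out <- dplyr::mutate(as_tibble(points),
                       x_cm = .data$col_px * gsd, y_cm = .data$row_px * gsd)
  new_rice_clusters(out, gsd = gsd,
                    provenance = attr(points, "provenance") %||% "detected")
}
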