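# Strict CSV point-table reader shared by the ground-truth and cluster
# readers: comma-separated, UTF-8, header required, '.' decimal. Numeric
# columns are validated and parse errors name the first offending data line
# (1-based, counting the header as line 1).
read_point_csv <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ricevor_io_error")
  }
  df <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE, progress = FALSE)),
    error = function(e) {
      abort(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)),
            class = "ricevor_parse_error")
    }
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "ricevor_parse_error")
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("Non-numeric value in column '%s' of '%s' at line %d.",
                      col, path, bad[1] + 1L),
              class = "ricevor_parse_error")
      }
      df[[col]] <- num
    }
  }
  df
}

#' Write / read a detected-cluster point table
#'
#' CSV with header `id,row_px,col_px,x_cm,y_cm,stage` (`stage` is
#' `"direct"` or `"refined"`; ground coordinates may be `NA` when no
#' ground-sampling distance is known).
#'
#' @param clusters A [detect_clusters()] tibble (or compatible data frame).
#' @param path CSV path.
#' @return `write_points_csv()` returns `path` invisibly;
#'   `read_points_csv()` returns a `rice_clusters` tibble.
#' @export
write_points_csv <- function(clusters, path) {
  need <- c("id", "row_px", "col_px", "x_cm", "y_cm", "stage")
  df <- as_tibble(clusters)
  for (col in setdiff(need, names(df))) {
    df[[col]] <- if (col == "stage") NA_character_ else NA_real_
  }
  readr::write_csv(df[need], path)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- read_point_csv(path, required = c("id", "row_px", "col_px"),
                       numeric_cols = c("id", "row_px", "col_px", "x_cm", "y_cm"))
  new_rice_clusters(df, provenance = "file")
}

#' Extract planar coordinates from a point table
#'
#' Picks coordinate columns from whatever a point table carries — bare
#' `x`/`y` (simulation output), ground `x_cm`/`y_cm`, or pixel
#' `col_px`/`row_px` — and returns them as an `x`/`y` tibble ready for
#' [tessellate()]. Columns must be complete (finite) to be chosen.
#'
#' @param points A data frame of positions.
#' @param units `"auto"` (prefer x/y, then cm, then px) or one of `"cm"`,
#'   `"px"`, `"xy"` to force a pair.
#' @return A tibble with columns `x` and `y`.
#' @export
cluster_coords <- function(points, units = c("auto", "cm", "px", "xy")) {
  units <- match.arg(units)
  points <- as.data.frame(points)
  has <- function(cols) all(cols %in% names(points)) &&
    (nrow(points) == 0 || all(is.finite(as.matrix(points[cols]))))
  pick <- switch(units,
    cm = if (has(c("x_cm", "y_cm"))) c("x_cm", "y_cm"),
    px = if (has(c("col_px", "row_px"))) c("col_px", "row_px"),
    xy = if (has(c("x", "y"))) c("x", "y"),
    auto = if (has(c("x", "y"))) c("x", "y")
      else if (has(c("x_cm", "y_cm"))) c("x_cm", "y_cm")
      else if (has(c("col_px", "row_px"))) c("col_px", "row_px")
  )
  if (is.null(pick)) {
    abort("No complete coordinate columns found (expected x/y, x_cm/y_cm or col_px/row_px).",
          class = "ricevor_invalid_input")
  }
  tibble(x = as.numeric(points[[pick[1]]]), y = as.numeric(points[[pick[2]]]))
}

#' Write Voronoi cells as GeoJSON
#'
#' A `FeatureCollection` with one feature per site: bounded cells carry
#' their polygon ring (closed), unbounded cells a `null` geometry;
#' properties are `site_id`, `area` and `bounded`.
#'
#' @param tess A [tessellate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(tess, path) {
  stopifnot(inherits(tess, "rice_tessellation"))
  features <- purrr::pmap(
    list(tess$cells$site_id, tess$cells$bounded, tess$cells$area, tess$polygons),
    function(id, bounded, area, poly) {
      geom <- if (bounded) {
        ring <- rbind(poly, poly[1, , drop = FALSE])
        list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(i) c(ring[i, 1], ring[i, 2]))))
      } else {
        NULL
      }
      list(type = "Feature", geometry = geom,
           properties = list(site_id = id, area = area, bounded = bounded))
    }
  )
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                           auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write cell areas as CSV
#'
#' Header `site_id,area,bounded`; unbounded cells keep `NA` area.
#'
#' @inheritParams write_cells_geojson
#' @return `path`, invisibly.
#' @export
write_areas_csv <- function(tess, path) {
  stopifnot(inherits(tess, "rice_tessellation"))
  readr::write_csv(tess$cells[c("site_id", "area", "bounded")], path)
  invisible(path)
}

#' Write a uniformity report as JSON
#'
#' Report fields: `n` (sites), `n_interior` (bounded cells), `mean`,
#' `sigma`, `cv`, `uniformity` (null when perfectly uniform).
#'
#' @param tess A [tessellate()] result.
#' @param path Output path.
#' @return The report list, invisibly.
#' @export
write_uniformity_report <- function(tess, path) {
  het <- heterogeneity_cv(tess)
  report <- list(
    n = nrow(tess$cells), n_interior = tess$n_interior,
    mean = het$mean, sigma = het$sigma, cv = het$cv,
    uniformity = if (het$perfectly_uniform) NULL else het$uniformity,
    perfectly_uniform = het$perfectly_uniform
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
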