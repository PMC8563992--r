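#' Plot a tessellation
#'
#' Bounded cells drawn as polygons filled by area, sites overplotted;
#' hull sites (unbounded cells) shown as open points.
#'
#' @param object A [tessellate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rice_tessellation <- function(object, ...) {
  cells <- object$cells
  rings <- purrr::imap(object$polygons, function(v, i) {
    if (!cells$bounded[i] || nrow(v) < 3) return(NULL)
    tibble(site_id = cells$site_id[i], x = v[, 1], y = v[, 2],
           area = cells$area[i])
  })
  rings <- dplyr::bind_rows(rings)
  p <- ggplot2::ggplot()
  if (nrow(rings)) {
    p <- p + ggplot2::geom_polygon(
      data = rings,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$site_id,
                   fill = .data$area),
      colour = "grey20", linewidth = 0.2
    )
  }
  p +
    ggplot2::geom_point(
      data = cells,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$bounded),
      size = 0.8
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cell area", shape = "bounded",
                  title = "Voronoi cells of cluster positions")
}

#' Plot a CV experiment
#'
#' For `perturb`/`omit` modes: mean CV against the parameter level with a
#' one-standard-deviation ribbon. For the `random` mode: a histogram of
#' replicate CVs.
#'
#' @param object A [run_cv_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rice_cv_experiment <- function(object, ...) {
  if (object$mode == "random") {
    return(
      ggplot2::ggplot(object$results, ggplot2::aes(x = .data$cv)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey20") +
        ggplot2::labs(x = "heterogeneity index (CV)", y = "replicates",
                      title = "CV of fully random layouts")
    )
  }
  xlab <- switch(object$mode,
                 perturb = "perturbation SD (fraction of spacing)",
                 omit = "omission probability")
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$level, y = .data$cv_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cv_mean - .data$cv_sd,
                   ymax = .data$cv_mean + .data$cv_sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xlab, y = "mean heterogeneity index (CV)",
                  title = sprintf("CV trend under %s", object$mode))
}

#' Plot detected clusters over the binary context
#'
#' @param object A [detect_clusters()] result.
#' @param ... Unused.
#' @return A ggplot object (image row axis reversed, as displayed).
#' @export
autoplot.rice_clusters <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$col_px, y = .data$row_px,
                               colour = .data$stage)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)", colour = "stage",
                  title = "Detected rice clusters")
}
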