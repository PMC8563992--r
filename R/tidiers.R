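#' Tidy a tessellation into its per-cell table
#'
#' @param x A [tessellate()] result.
#' @param ... Unused.
#' @return A tibble with one row per site: `site_id`, `x`, `y`, `bounded`,
#'   `n_vertices`, `area`.
#' @export
tidy.rice_tessellation <- function(x, ...) {
  x$cells
}

#' One-row summary of a tessellation
#'
#' @inheritParams tidy.rice_tessellation
#' @return A tibble with `n_sites`, `n_interior`, `mean_area`, `cv`.
#' @export
glance.rice_tessellation <- function(x, ...) {
  a <- interior_areas(x)
  cv <- if (length(a)) heterogeneity_cv(a)$cv else NA_real_
  tibble(n_sites = nrow(x$cells), n_interior = x$n_interior,
         mean_area = if (length(a)) mean(a) else NA_real_, cv = cv)
}

#' One-row summary of a heterogeneity result
#'
#' @param x A [heterogeneity_cv()] result.
#' @param ... Unused.
#' @return A tibble with `n`, `mean`, `sigma`, `cv`, `uniformity`,
#'   `perfectly_uniform`.
#' @export
glance.rice_heterogeneity <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sigma = x$sigma, cv = x$cv,
         uniformity = x$uniformity, perfectly_uniform = x$perfectly_uniform)
}

#' Tidy a CV experiment into per-replicate rows
#'
#' @param x A [run_cv_experiment()] result.
#' @param ... Unused.
#' @return The per-replicate results tibble.
#' @export
tidy.rice_cv_experiment <- function(x, ...) {
  x$results
}

#' Per-level summary of a CV experiment
#'
#' @inheritParams tidy.rice_cv_experiment
#' @return The per-level summary tibble (`level`, `cv_mean`, `cv_sd`,
#'   `replicates`, `n_flagged`).
#' @export
glance.rice_cv_experiment <- function(x, ...) {
  x$summary
}

#' Tidy a match result into its pair table
#'
#' @param x A [match_positions()] result.
#' @param ... Unused.
#' @return The pairs tibble (`detected`, `truth`, `distance`).
#' @export
tidy.rice_match <- function(x, ...) {
  x$pairs
}

#' One-row confusion summary of a match result
#'
#' @inheritParams tidy.rice_match
#' @return A tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
glance.rice_match <- function(x, ...) {
  as_tibble(x$counts)
}

#' Gamma-fit parameters as a tibble
#'
#' @param x A [fit_gamma()] result.
#' @param ... Unused.
#' @return A tibble with `shape`, `scale`, `rate`, `mean_model`,
#'   `mean_sample`, `n`.
#' @export
glance.rice_gamma_fit <- function(x, ...) {
  tibble(shape = x$shape, scale = x$scale, rate = x$rate,
         mean_model = x$mean_model, mean_sample = x$mean_sample, n = x$n)
}
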