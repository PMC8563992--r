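#' Rectangular lattice of cluster positions
#'
#' The reference layout of a transplanted stand: `x(i, j) = PD * i`,
#' `y(i, j) = RD * j` for rows `i = 1..cols` along a planting row and
#' `j = 1..rows` across rows, where `PD` is the plant spacing and `RD` the
#' row spacing. Defaults follow the standard simulated plot: 15 x 15
#' clusters with row:plant spacing RD:PD = 2:3 (20 cm x 30 cm).
#'
#' @param rows,cols Lattice extent in clusters (>= 3 each).
#' @param pd Plant spacing (x step), > 0. Units are arbitrary (cm used
#'   throughout the package).
#' @param rd Row spacing (y step), > 0.
#' @return A tibble with columns `i`, `j`, `x`, `y` and attribute
#'   `spec = list(rows, cols, pd, rd)`.
#' @export
lattice_points <- function(rows = 15, cols = 15, pd = 30, rd = 20) {
  if (rows < 3 || cols < 3 || pd <= 0 || rd <= 0) {
    abort("Need rows, cols >= 3 and positive spacings.", class = "ricevor_invalid_parameter")
  }
  grid <- expand.grid(i = seq_len(cols), j = seq_len(rows))
  out <- tibble(i = grid$i, j = grid$j, x = pd * grid$i, y = rd * grid$j)
  attr(out, "spec") <- list(rows = rows, cols = cols, pd = pd, rd = rd)
  out
}

lattice_spec <- function(lattice) {
  sp <- attr(lattice, "spec")
  if (is.null(sp)) {
    abort("`lattice` must come from lattice_points().", class = "ricevor_invalid_input")
  }
  sp
}

#' Gaussian perturbation of a lattice
#'
#' Adds independent zero-mean Gaussian offsets to every lattice position:
#' `x = PD*i + N(0, sigma1^2)`, `y = RD*j + N(0, sigma2^2)`. With
#' `fractional = TRUE` (default) `sigma1` is expressed as a fraction of the
#' plant spacing and `sigma2` as a fraction of the row spacing, matching
#' the canonical grids `sigma1 = 0, 0.1 PD, ..., PD` and
#' `sigma2 = 0, 0.1 RD, ..., RD`. `sigma1 = sigma2 = 0` reproduces the
#' lattice exactly.
#'
#' @param lattice A [lattice_points()] tibble.
#' @param sigma1,sigma2 Non-negative noise SDs for x and y.
#' @param fractional Interpret sigmas as fractions of PD / RD (default)
#'   rather than absolute lengths.
#' @param seed Optional integer seed; the result is a pure function of
#'   (lattice, sigmas, seed).
#' @return A tibble `i`, `j`, `x`, `y` with the same attribute `spec`.
#' @export
perturb_lattice <- function(lattice, sigma1, sigma2, fractional = TRUE, seed = NULL) {
  sp <- lattice_spec(lattice)
  if (sigma1 < 0 || sigma2 < 0) {
    abort("Perturbation SDs must be non-negative.", class = "ricevor_invalid_parameter")
  }
  s1 <- if (fractional) sigma1 * sp$pd else sigma1
  s2 <- if (fractional) sigma2 * sp$rd else sigma2
  n <- nrow(lattice)
  out <- with_seed_or_stream(seed, {
    dplyr::mutate(lattice,
                  x = .data$x + if (s1 > 0) rnorm(n, 0, s1) else 0,
                  y = .data$y + if (s2 > 0) rnorm(n, 0, s2) else 0)
  })
  attr(out, "spec") <- sp
  out
}

#' Boundary-preserving random omission of lattice clusters
#'
#' Simulates transplanter skips: the boundary ring of the lattice is always
#' retained (keeping the tessellation window stable), and each interior
#' cluster is independently removed with probability `p`.
#'
#' @inheritParams perturb_lattice
#' @param p Omission probability per interior cluster, in `[0, 1]`.
#' @return A tibble `i`, `j`, `x`, `y` (subset of the lattice rows), with
#'   attribute `spec`.
#' @export
omit_clusters <- function(lattice, p, seed = NULL) {
  sp <- lattice_spec(lattice)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a probability in [0, 1].", class = "ricevor_invalid_parameter")
  }
  boundary <- lattice$i %in% c(1L, sp$cols) | lattice$j %in% c(1L, sp$rows)
  drop <- with_seed_or_stream(seed, runif(nrow(lattice)) < p) & !boundary
  out <- lattice[!drop, ]
  attr(out, "spec") <- sp
  out
}

#' Fully random cluster layout
#'
#' `n` i.i.d. uniform points in a rectangle, the null model of a completely
#' random stand. The default extent is the rectangle spanned by the default
#' 15 x 15 lattice, so results are directly comparable with the lattice
#' scenarios.
#'
#' @param n Number of points (>= 4).
#' @param xlim,ylim Extent of the rectangle (length-2 numeric).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
random_field <- function(n = 225, xlim = c(30, 450), ylim = c(20, 300), seed = NULL) {
  if (n < 4 || diff(xlim) <= 0 || diff(ylim) <= 0) {
    abort("Need n >= 4 and a positive-extent rectangle.", class = "ricevor_invalid_parameter")
  }
  with_seed_or_stream(seed, tibble(
    x = runif(n, xlim[1], xlim[2]),
    y = runif(n, ylim[1], ylim[2])
  ))
}

# CV of bounded Voronoi cell areas for one layout; NA (flagged) when the
# layout is degenerate (too few points or no interior cell).
layout_cv <- function(points) {
  if (nrow(points) < 4) return(list(cv = NA_real_, n_interior = 0L, flagged = TRUE))
  tess <- tryCatch(tessellate(points), error = function(e) NULL)
  if (is.null(tess) || tess$n_interior < 1) {
    return(list(cv = NA_real_, n_interior = if (is.null(tess)) 0L else tess$n_interior,
                flagged = TRUE))
  }
  list(cv = heterogeneity_cv(tess)$cv, n_interior = tess$n_interior, flagged = FALSE)
}

#' CV-versus-parameter simulation experiment
#'
#' Runs one of the three layout generators over a parameter grid and
#' summarises the heterogeneity index per level. For each (level,
#' replicate): generate the layout, tessellate it, and compute the CV of
#' bounded cell areas. Replicate seeds are drawn once from `base_seed` and
#' reused across levels (paired seeds), so level-to-level CV differences
#' are not masked by Monte-Carlo noise. Degenerate layouts (fewer than 4
#' points or no interior cell) are flagged, never silently dropped.
#'
#' @param mode `"perturb"` (levels are sigma fractions applied to both
#'   axes: `sigma1 = level * PD`, `sigma2 = level * RD`), `"omit"` (levels
#'   are omission probabilities) or `"random"` (levels ignored; one level
#'   `"random"`).
#' @param levels Numeric vector of parameter levels (defaults per mode:
#'   `seq(0, 1, 0.1)` for perturb, `seq(0.01, 0.5, 0.01)` for omit).
#' @param replicates Replicates per level (default 100).
#' @param base_seed Integer master seed; the whole experiment is a pure
#'   function of it.
#' @param rows,cols,pd,rd Lattice geometry (see [lattice_points()]); also
#'   sets the random-field extent and `n = rows * cols`.
#' @return A `rice_cv_experiment` object: list with `results` (tibble
#'   `level`, `replicate`, `seed`, `cv`, `n_interior`, `flagged`),
#'   `summary` (tibble `level`, `cv_mean`, `cv_sd`, `replicates`), `mode`
#'   and `base_seed`.
#' @export
run_cv_experiment <- function(mode = c("perturb", "omit", "random"),
                              levels = NULL, replicates = 100,
                              base_seed = 1,
                              rows = 15, cols = 15, pd = 30, rd = 20) {
  mode <- match.arg(mode)
  if (replicates < 1) {
    abort("`replicates` must be >= 1.", class = "ricevor_invalid_parameter")
  }
  if (is.null(levels)) {
    levels <- switch(mode,
      perturb = seq(0, 1, by = 0.1),
      omit = seq(0.01, 0.5, by = 0.01),
      random = NA_real_
    )
  }
  if (mode == "random") levels <- NA_real_
  lat <- lattice_points(rows, cols, pd, rd)
  rep_seeds <- withr::with_seed(as.integer(base_seed),
                                sample.int(.Machine$integer.max, replicates))
  grid <- tidyr::expand_grid(level = levels, replicate = seq_len(replicates))
  res <- purrr::pmap(grid, function(level, replicate) {
    s <- rep_seeds[replicate]
    pts <- switch(mode,
      perturb = perturb_lattice(lat, sigma1 = level, sigma2 = level, seed = s),
      omit = omit_clusters(lat, p = level, seed = s),
      random = random_field(n = rows * cols, xlim = range(lat$x),
                            ylim = range(lat$y), seed = s)
    )
    c(list(level = level, replicate = replicate, seed = s), layout_cv(pts))
  })
  results <- dplyr::bind_rows(res)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$level),
    cv_mean = mean(.data$cv, na.rm = TRUE),
    cv_sd = sd(.data$cv, na.rm = TRUE),
    replicates = dplyr::n(),
    n_flagged = sum(.data$flagged),
    .groups = "drop"
  )
  structure(
    list(results = results, summary = summary, mode = mode,
         base_seed = base_seed,
         lattice = list(rows = rows, cols = cols, pd = pd, rd = rd)),
    class = "rice_cv_experiment"
  )
}

#' @export
print.rice_cv_experiment <- function(x, ...) {
  cat(sprintf("<rice_cv_experiment> mode '%s', %d level(s) x %d replicates (seed %d)\n",
              x$mode, nrow(x$summary), max(x$results$replicate), x$base_seed))
  print(x$summary, n = Inf)
  invisible(x)
}
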