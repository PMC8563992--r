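#' Coefficient-of-variation heterogeneity index
#'
#' Summarises a sample of per-cluster occupied areas \eqn{x_i} by
#' \eqn{\bar x = \sum x_i / n}, the population root-mean-squared deviation
#' \eqn{\sigma = \sqrt{\sum (x_i - \bar x)^2 / n}} (divisor `n`, not
#' `n - 1`), and the heterogeneity index \eqn{CV = \sigma / \bar x}. CV is
#' 0 for a perfect lattice and invariant to permutation and positive
#' rescaling of the areas, so pixel and ground units give identical values.
#'
#' @param areas A numeric vector of positive areas, a data frame with an
#'   `area` column (rows with `bounded == FALSE` are dropped if that column
#'   exists), or a [tessellate()] result (bounded cells used).
#' @return A `rice_heterogeneity` object: list with `n`, `mean`, `sigma`,
#'   `cv`, `uniformity` (`1/cv`, `NA` when cv is 0) and
#'   `perfectly_uniform`.
#' @export
heterogeneity_cv <- function(areas) {
  x <- extract_areas(areas)
  if (length(x) < 1 || anyNA(x)) {
    abort("Need at least one non-missing area.", class = "ricevor_invalid_input")
  }
  if (any(x <= 0) || mean(x) <= 0) {
    abort("Areas must be strictly positive.", class = "ricevor_invalid_input")
  }
  m <- mean(x)
  sigma <- sqrt(sum((x - m)^2) / length(x))
  cv <- sigma / m
  structure(
    list(n = length(x), mean = m, sigma = sigma, cv = cv,
         uniformity = if (cv > 0) 1 / cv else NA_real_,
         perfectly_uniform = cv == 0),
    class = "rice_heterogeneity"
  )
}

extract_areas <- function(areas) {
  if (inherits(areas, "rice_tessellation")) return(interior_areas(areas))
  if (is.data.frame(areas)) {
    if (!"area" %in% names(areas)) {
      abort("Data frame input needs an `area` column.", class = "ricevor_invalid_input")
    }
    if ("bounded" %in% names(areas)) areas <- areas[areas$bounded %in% TRUE, ]
    return(as.numeric(areas$area))
  }
  as.numeric(areas)
}

#' @export
print.rice_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "<rice_heterogeneity> n = %d, mean = %.6g, sigma = %.6g, cv = %.6g%s\n",
    x$n, x$mean, x$sigma, x$cv,
    if (x$perfectly_uniform) " (perfectly uniform)"
    else sprintf(", uniformity = %.6g", x$uniformity)
  ))
  invisible(x)
}

#' Uniformity index (reciprocal of CV)
#'
#' Larger values mean a more even stand. A perfectly uniform sample
#' (CV = 0) has no finite reciprocal: the return value is then `NA` carrying
#' the attribute `perfectly_uniform = TRUE` as a distinguished flag.
#'
#' @param x A `rice_heterogeneity` object or a single non-negative CV value.
#' @return `1/cv`, or flagged `NA` when `cv == 0`.
#' @export
uniformity_index <- function(x) {
  cv <- if (inherits(x, "rice_heterogeneity")) x$cv else as.numeric(x)
  if (length(cv) != 1 || is.na(cv) || cv < 0) {
    abort("`x` must be a heterogeneity result or a single cv >= 0.",
          class = "ricevor_invalid_input")
  }
  if (cv == 0) {
    return(structure(NA_real_, perfectly_uniform = TRUE))
  }
  1 / cv
}

#' Benchmark confusion counts from six scored UAV images
#'
#' Manually scored rice-cluster confusion counts for six UAV images of
#' transplanted paddy fields (true positives, false negatives, false
#' positives; true negatives are 0 by convention since every detection is a
#' positive call). These printed counts are the standard input for checking
#' the score formulas in [detection_scores()].
#'
#' @return A tibble with columns `image`, `TP`, `FN`, `FP`, `TN`.
#' @export
uav_eval_counts <- function() {
  tibble(
    image = paste0("S", 1:6),
    TP = c(210L, 244L, 250L, 233L, 267L, 233L),
    FN = c(16L, 8L, 13L, 9L, 12L, 11L),
    FP = c(10L, 4L, 9L, 6L, 7L, 9L),
    TN = c(0L, 0L, 0L, 0L, 0L, 0L)
  )
}

#' Detection-quality scores from confusion counts
#'
#' Computes, per row of counts:
#' `precision = TP/(TP+FP)`, `accuracy = (TP+FN)/(TP+FP+TN+FN)`,
#' `recall = TP/(TP+FN)`, and `f1` as the harmonic mean of the unrounded
#' precision and recall. The accuracy formula is deliberately the
#' field-specific one with true clusters (recognised or missed) in the
#' numerator, not the usual `(TP+TN)/total`; with `TN = 0` the two differ.
#'
#' @param counts Data frame with non-negative integer columns `TP`, `FP`,
#'   `FN`, `TN` (one row per image), or a named list/vector with those
#'   elements.
#' @return A tibble of class `rice_detection_eval`: the input columns plus
#'   `precision`, `accuracy`, `recall`, `f1` (unrounded, in `[0, 1]`).
#' @export
detection_scores <- function(counts) {
  if (!is.data.frame(counts)) counts <- as_tibble(as.list(counts))
  need <- c("TP", "FP", "FN", "TN")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs TP, FP, FN and TN.", class = "ricevor_invalid_input")
  }
  cts <- counts[need]
  if (any(as.matrix(cts) < 0) || anyNA(cts)) {
    abort("Confusion counts must be non-negative.", class = "ricevor_invalid_input")
  }
  with_counts <- function(den, metric) {
    if (any(den == 0)) {
      abort(sprintf("Metric '%s' is undefined: zero denominator.", metric),
            class = "ricevor_undefined_metric")
    }
    den
  }
  precision <- counts$TP / with_counts(counts$TP + counts$FP, "precision")
  accuracy <- (counts$TP + counts$FN) /
    with_counts(counts$TP + counts$FP + counts$TN + counts$FN, "accuracy")
  recall <- counts$TP / with_counts(counts$TP + counts$FN, "recall")
  f1 <- 2 * precision * recall / with_counts(precision + recall, "f1")
  out <- dplyr::mutate(as_tibble(counts),
                       precision = precision, accuracy = accuracy,
                       recall = recall, f1 = f1)
  class(out) <- c("rice_detection_eval", class(tibble()))
  out
}

#' Round scores for reporting
#'
#' Half-up rounding to `digits` decimals, applied only at reporting time
#' (scores are computed and combined unrounded).
#'
#' @param scores A [detection_scores()] result.
#' @param digits Decimal places (default 2).
#' @return The tibble with the four score columns rounded.
#' @export
round_scores <- function(scores, digits = 2) {
  dplyr::mutate(as_tibble(scores), dplyr::across(
    dplyr::all_of(c("precision", "accuracy", "recall", "f1")),
    ~ round_half_up(.x, digits)
  ))
}

# Pick the coordinate columns shared by both point tables; mixing tables
# that only carry pixel columns with tables that only carry ground columns
# is an error rather than a silent unit mismatch.
shared_coords <- function(a, b) {
  pairs <- list(xy = c("x", "y"), px = c("col_px", "row_px"), cm = c("x_cm", "y_cm"))
  usable <- function(df, cols) {
    all(cols %in% names(df)) && (nrow(df) == 0 || all(is.finite(as.matrix(df[cols]))))
  }
  for (p in pairs) {
    if (usable(a, p) && usable(b, p)) return(p)
  }
  abort("Point tables share no coordinate columns (mixed units?). Expected both to have x/y, col_px/row_px or x_cm/y_cm.",
        class = "ricevor_invalid_input")
}

#' Match detected positions to ground truth
#'
#' Greedy globally-nearest one-to-one matching: candidate pairs within
#' `max_dist` are taken in order of increasing distance (ties broken by
#' lowest detected then truth index), each point used at most once.
#' `TP` is the number of pairs, `FP` the unmatched detections, `FN` the
#' unmatched truth points, and `TN = 0` by convention.
#'
#' @param detected,truth Data frames of positions sharing coordinate
#'   columns (`x`/`y`, `col_px`/`row_px` or `x_cm`/`y_cm`), same units.
#' @param max_dist Maximum pairing distance (> 0), in the shared units. A
#'   sensible default is half the nominal plant spacing.
#' @return A `rice_match` object: list with `pairs` (tibble `detected`,
#'   `truth`, `distance`), `counts` (named list TP/FP/FN/TN) and `units`.
#' @export
match_positions <- function(detected, truth, max_dist) {
  if (!is.numeric(max_dist) || length(max_dist) != 1 || max_dist <= 0) {
    abort("`max_dist` must be a single positive number.", class = "ricevor_invalid_parameter")
  }
  detected <- as.data.frame(detected); truth <- as.data.frame(truth)
  cols <- shared_coords(detected, truth)
  D <- as.matrix(detected[cols]); G <- as.matrix(truth[cols])
  nd <- nrow(D); nt <- nrow(G)
  pairs <- tibble(detected = integer(), truth = integer(), distance = double())
  if (nd > 0 && nt > 0) {
    dm <- sqrt(outer(D[, 1], G[, 1], `-`)^2 + outer(D[, 2], G[, 2], `-`)^2)
    cand <- which(dm <= max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dm[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ti <- cand[i, 2]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble(
        detected = as.integer(cand[, 1]),
        truth = as.integer(cand[, 2]),
        distance = dm[cand]
      )
    }
  }
  counts <- list(TP = nrow(pairs), FP = nd - nrow(pairs),
                 FN = nt - nrow(pairs), TN = 0L)
  structure(list(pairs = pairs, counts = counts,
                 units = paste(cols, collapse = "/"), max_dist = max_dist),
            class = "rice_match")
}

#' @export
print.rice_match <- function(x, ...) {
  cat(sprintf("<rice_match> TP %d, FP %d, FN %d (max_dist %.3g, coords %s)\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$max_dist, x$units))
  invisible(x)
}

#' Localisation errors of matched positions
#'
#' Converts the pixel distance of each matched pair to a ground distance
#' (cm) via the ground-sampling distance.
#'
#' @param match A [match_positions()] result whose distances are in pixels.
#' @param gsd Ground-sampling distance in cm per pixel, > 0.
#' @return A tibble with `detected`, `truth`, `error_cm`; attribute
#'   `mean_error` (`NA` when there are no pairs).
#' @export
location_errors <- function(match, gsd) {
  stopifnot(inherits(match, "rice_match"))
  check_gsd(gsd)
  out <- tibble(
    detected = match$pairs$detected,
    truth = match$pairs$truth,
    error_cm = match$pairs$distance * gsd
  )
  attr(out, "mean_error") <- if (nrow(out)) mean(out$error_cm) else NA_real_
  out
}

#' Maximum-likelihood gamma fit of localisation errors
#'
#' Fits a two-parameter gamma distribution (shape, scale; zero location) to
#' strictly positive error distances by maximum likelihood, and reports the
#' model mean `shape * scale` alongside the sample mean.
#'
#' @param errors Numeric vector of at least 10 strictly positive distances
#'   (cm), or the tibble from [location_errors()].
#' @return A `rice_gamma_fit` object: list with `shape`, `scale`, `rate`,
#'   `mean_model`, `mean_sample`, `n`.
#' @export
fit_gamma <- function(errors) {
  if (is.data.frame(errors)) errors <- errors$error_cm
  x <- as.numeric(errors)
  if (anyNA(x) || any(x <= 0)) {
    abort("Gamma support violation: errors must be strictly positive.",
          class = "ricevor_invalid_input")
  }
  if (length(x) < 10) {
    abort("Need at least 10 error values to fit a gamma distribution.",
          class = "ricevor_insufficient_data")
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "gamma")),
    error = function(e) {
      abort(sprintf("Degenerate gamma fit (zero-variance or ill-conditioned sample): %s",
                    conditionMessage(e)),
            class = "ricevor_degenerate_fit")
    }
  )
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  structure(
    list(shape = shape, scale = 1 / rate, rate = rate,
         mean_model = shape / rate, mean_sample = mean(x), n = length(x)),
    class = "rice_gamma_fit"
  )
}

#' @export
print.rice_gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<rice_gamma_fit> shape %.3f, scale %.3f (model mean %.3f, sample mean %.3f, n = %d)\n",
    x$shape, x$scale, x$mean_model, x$mean_sample, x$n
  ))
  invisible(x)
}

#' Relative error between two scalars
#'
#' `|a - b| / |b|`, the agreement measure between an automated and a
#' reference value of the same index.
#'
#' @param a,b Numeric scalars; `b` must be nonzero.
#' @return A non-negative fraction.
#' @export
relative_error <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b)) {
    abort("`a` and `b` must be single numbers.", class = "ricevor_invalid_input")
  }
  if (b == 0) {
    abort("Relative error is undefined for a zero reference value.",
          class = "ricevor_invalid_input")
  }
  abs(a - b) / abs(b)
}
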