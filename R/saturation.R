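#' Hyperbolic saturation model: predicted detections
#'
#' The gene-discovery curve is modelled as `y = a*x/(b + x)`: `a` is the
#' asymptotic number of detectable genes and `b` the read count at which
#' half of them are seen (so `predict_detections(a, b, b) == a/2`).
#'
#' @param a asymptotic detections (genes), > 0.
#' @param b half-saturation read count, > 0.
#' @param x read count(s).
#' @return predicted detections.
#' @export
predict_detections <- function(a, b, x) {
  stopifnot(a > 0, b > 0, all(x >= 0))
  a * x / (b + x)
}

#' Slope of the saturation curve at a given read count
#'
#' The analytic derivative of `a*x/(b+x)` is `a*b/(b+x)^2`, the marginal
#' gene-discovery rate (genes per additional read). Evaluated at a
#' library's final read count it measures how exhaustively the library was
#' sequenced: values near zero mean further sequencing would find almost
#' nothing new.
#'
#' @inheritParams predict_detections
#' @return slope in genes per read.
#' @export
slope_at <- function(a, b, x) {
  stopifnot(a > 0, b > 0, all(x >= 0))
  a * b / (b + x)^2
}

#' Fit the hyperbolic saturation model to a detection curve
#'
#' Least-squares fit of `y = a*x/(b+x)` by Levenberg-Marquardt
#' (minpack.lm). Starting values: `a0 = 1.2 * max(y)`; `b0` is the `x` at
#' which the curve first crosses `a0/2`, by linear interpolation (falling
#' back to `median(x)` when it never does). Replicated curves are averaged
#' per sample size before fitting.
#'
#' @param curve data frame with columns `n` (sample size) and `detections`;
#'   a `rep` column, if present, is averaged out.
#' @param final_x read count at which to evaluate the final slope; defaults
#'   to the largest sample size in the curve. For a real library this is
#'   its total read count entering the analysis.
#' @return object of class `saturation_fit`: list with `a`, `b`,
#'   `r_squared`, `final_x`, `slope_final`, `converged`. On
#'   non-convergence `converged` is `FALSE` and the parameters are `NA`.
#' @export
fit_hyperbola <- function(curve, final_x = NULL) {
  stopifnot(all(c("n", "detections") %in% names(curve)))
  if ("rep" %in% names(curve)) curve <- curve_means(curve)
  d <- stats::aggregate(detections ~ n, data = curve, FUN = mean)
  d <- d[order(d$n), ]
  d <- d[d$detections > 0, ]
  if (nrow(d) < 3)
    stop("need at least 3 distinct sample sizes with positive detections",
         call. = FALSE)
  if (is.null(final_x)) final_x <- max(d$n)

  a0 <- 1.2 * max(d$detections)
  half <- a0 / 2
  above <- which(d$detections > half)
  b0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    x1 <- d$n[i - 1]; x2 <- d$n[i]
    y1 <- d$detections[i - 1]; y2 <- d$detections[i]
    x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  } else if (length(above)) {
    d$n[1]
  } else {
    stats::median(d$n)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(detections ~ a * n / (b + n), data = d,
                      start = list(a = a0, b = b0),
                      lower = c(a = 1e-9, b = 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-10, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                          final_x = final_x, slope_final = NA_real_,
                          converged = FALSE, n_points = nrow(d)),
                     class = "saturation_fit"))
  }
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((d$detections - mean(d$detections))^2)
  structure(list(
    a = unname(co["a"]), b = unname(co["b"]),
    r_squared = 1 - sse / sst,
    final_x = final_x,
    slope_final = slope_at(unname(co["a"]), unname(co["b"]), final_x),
    converged = TRUE, n_points = nrow(d)
  ), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("saturation fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "saturation fit y = ax/(b+x): a = %.0f genes, b = %.0f reads\n",
    x$a, x$b))
  cat(sprintf("  R^2 = %.4f; slope at final read count (%g) = %.4f genes/read\n",
              x$r_squared, x$final_x, x$slope_final))
  invisible(x)
}

#' Fit saturation curves for every detection threshold of a library
#'
#' One fit per threshold `k` in a long-format rarefaction table, returned
#' in the layout of a survey completeness table: fit parameters, goodness
#' of fit, total detections in the full pool, and the slope at the
#' library's final read count.
#'
#' @param curves long-format data frame from [build_curves()].
#' @param final_x read count for the final-slope column; defaults to the
#'   largest sample size.
#' @param library label for the output rows.
#' @return data frame: `library`, `k`, `a`, `b`, `r_squared`,
#'   `total_detected`, `slope_final`, `converged`.
#' @export
fit_table <- function(curves, final_x = NULL, library = "lib1") {
  ks <- sort(unique(curves$k))
  rows <- lapply(ks, function(k) {
    cc <- curves[curves$k == k, , drop = FALSE]
    full <- cc[cc$n == max(cc$n), "detections"]
    f <- tryCatch(fit_hyperbola(cc, final_x = final_x), error = function(e) {
      structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                     final_x = NA_real_, slope_final = NA_real_,
                     converged = FALSE), class = "saturation_fit")
    })
    data.frame(library = library, k = k, a = f$a, b = f$b,
               r_squared = f$r_squared,
               total_detected = round(mean(full)),
               slope_final = f$slope_final, converged = f$converged)
  })
  do.call(rbind, rows)
}
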