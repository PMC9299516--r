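#' Assemble a concentration-response curve of reactive fractions
#'
#' Collects per-concentration replicate summaries of the fraction of
#' reactive cells into a sorted curve object. A zero-concentration control
#' point is kept aside (`baseline`) and excluded from logistic fitting.
#'
#' @param df Data frame with one row per concentration: columns
#'   `concentration` (molar), `mean` (mean reactive fraction) and optionally
#'   `sem`, `n_replicates`. Duplicate concentrations are an error.
#' @param compound Compound label.
#' @param mode `"agonist"` (fraction rises with concentration) or
#'   `"antagonist"` (fraction falls).
#' @return An object of class `dose_response_curve`.
#' @export
build_curve <- function(df, compound = "compound",
                        mode = c("agonist", "antagonist")) {
  mode <- match.arg(mode)
  if (!all(c("concentration", "mean") %in% names(df))) {
    stop("'df' must contain 'concentration' and 'mean' columns", call. = FALSE)
  }
  if (anyDuplicated(df$concentration)) {
    stop("duplicate concentration keys", call. = FALSE)
  }
  if (any(df$concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  baseline <- df[df$concentration == 0, , drop = FALSE]
  pts <- df[df$concentration > 0, , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("need at least 3 positive concentrations for a curve", call. = FALSE)
  }
  pts <- pts[order(pts$concentration), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(compound = compound, mode = mode, points = pts,
                 baseline = baseline, fit = NULL),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s (%s), %d concentrations %.3g..%.3g M\n",
              x$compound, x$mode, nrow(x$points), min(x$points$concentration),
              max(x$points$concentration)))
  if (!is.null(x$fit)) {
    f <- x$fit
    cat(sprintf("  fit: bottom %.3g, top %.3g, %s %.3g M, hill %.3g (%s)\n",
                f$bottom, f$top, if (x$mode == "agonist") "EC50" else "IC50",
                f$midpoint, f$hill_slope,
                if (f$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Fit a four-parameter logistic (Hill) model to a curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^((log10(mid) - log10(c)) * slope))`
#' on log10 concentration. Positive slope corresponds to an agonist
#' (response rises with concentration) and the midpoint to the EC50;
#' negative slope to an antagonist and the IC50. Non-convergence or a
#' midpoint outside `[min conc / 10, max conc * 10]` is flagged, never an
#' exception.
#'
#' @param curve A [build_curve()] result.
#' @param fix_bottom Optionally fix the bottom asymptote (then 3 points
#'   suffice); `NULL` fits all four parameters (needs >= 4 points).
#' @param weights `"none"` (default) or `"inv_sem2"` (weights 1/SEM^2).
#' @return The curve with a `fit` element: `bottom`, `top`, `midpoint`,
#'   `hill_slope`, `converged`, `residual_sd`.
#' @export
fit_hill <- function(curve, fix_bottom = NULL,
                     weights = c("none", "inv_sem2")) {
  stopifnot(inherits(curve, "dose_response_curve"))
  weights <- match.arg(weights)
  pts <- curve$points
  npar <- if (is.null(fix_bottom)) 4L else 3L
  if (nrow(pts) < npar) {
    stop(sprintf("need >= %d concentrations for a %d-parameter fit",
                 npar, npar), call. = FALSE)
  }
  x <- log10(pts$concentration)
  y <- pts$mean
  w <- if (weights == "inv_sem2") {
    if (is.null(pts$sem) || any(!is.finite(pts$sem)) || any(pts$sem <= 0)) {
      stop("'inv_sem2' weighting needs positive finite SEMs", call. = FALSE)
    }
    1 / pts$sem^2
  } else rep(1, length(y))
  unconverged <- function(reason) {
    curve$fit <- list(bottom = NA_real_, top = NA_real_,
                      midpoint = NA_real_, hill_slope = NA_real_,
                      converged = FALSE, reason = reason,
                      residual_sd = NA_real_)
    curve
  }
  if (stats::sd(y) < 1e-12) return(unconverged("flat response"))
  slope0 <- if (curve$mode == "agonist") 1 else -1
  half <- (min(y) + max(y)) / 2
  mid0 <- x[which.min(abs(y - half))]
  start <- list(top = max(y), logmid = mid0, slope = slope0)
  if (is.null(fix_bottom)) start$bottom <- min(y)
  fml <- if (is.null(fix_bottom)) {
    y ~ bottom + (top - bottom) / (1 + 10^((logmid - x) * slope))
  } else {
    substitute(y ~ b0 + (top - b0) / (1 + 10^((logmid - x) * slope)),
               list(b0 = fix_bottom))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(fml), data = data.frame(x = x, y = y),
                      start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unconverged("optimizer failure"))
  cf <- stats::coef(fit)
  bottom <- if (is.null(fix_bottom)) unname(cf["bottom"]) else fix_bottom
  top <- unname(cf["top"])
  midpoint <- 10^unname(cf["logmid"])
  in_range <- midpoint >= min(pts$concentration) / 10 &&
    midpoint <= max(pts$concentration) * 10
  curve$fit <- list(bottom = min(bottom, top), top = max(bottom, top),
                    midpoint = midpoint, hill_slope = unname(cf["slope"]),
                    converged = in_range,
                    reason = if (in_range) NA_character_ else
                      "midpoint outside concentration range",
                    residual_sd = stats::sigma(fit))
  curve
}
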