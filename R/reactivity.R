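#' Well-specific noise-based reactivity threshold
#'
#' The binary reactive/non-reactive endpoint uses a per-well threshold
#' derived from the fluorescence changes evoked by negative-control
#' stimulation: `mean(delta F) + 3 * SD(delta F)`, with a fixed upper cap
#' (default 18 intensity units). The SD is the sample SD (n - 1 denominator).
#'
#' @param control_delta_f Numeric vector of negative-control delta F values
#'   (>= 2 values required).
#' @param cap Upper limit of the threshold (fluorescence units, >= 0).
#' @param well_id Optional well identifier carried into the result.
#' @return An object of class `reactivity_threshold` with elements `value`,
#'   `control_mean`, `control_sd`, `cap`, `capped`, `n_control`, `well_id`.
#' @examples
#' compute_threshold(c(2, 6))           # 4 + 3 * 2.83 = 12.49
#' compute_threshold(c(5, 10, 15))      # 10 + 3 * 5 = 25 -> capped at 18
#' @export
compute_threshold <- function(control_delta_f, cap = 18, well_id = NA_character_) {
  if (!is.numeric(control_delta_f) || length(control_delta_f) < 2L) {
    stop("need at least 2 control delta F values to estimate the noise level",
         call. = FALSE)
  }
  if (!is.numeric(cap) || length(cap) != 1L || cap < 0) {
    stop("'cap' must be a single non-negative number", call. = FALSE)
  }
  m <- mean(control_delta_f)
  s <- stats::sd(control_delta_f)
  naive <- m + 3 * s
  structure(list(value = min(naive, cap), control_mean = m, control_sd = s,
                 cap = cap, capped = naive > cap,
                 n_control = length(control_delta_f), well_id = well_id),
            class = "reactivity_threshold")
}

#' @export
print.reactivity_threshold <- function(x, ...) {
  cat(sprintf(
    "<reactivity_threshold> %.4g (mean %.4g + 3 x SD %.4g%s; n = %d)\n",
    x$value, x$control_mean, x$control_sd,
    if (x$capped) sprintf(", capped at %g", x$cap) else "", x$n_control))
  invisible(x)
}

#' Binary reactive/non-reactive calls
#'
#' A cell is reactive iff its delta F strictly exceeds the threshold value;
#' ties are non-reactive.
#'
#' @param delta_f Data frame with a `delta_f` column (e.g. from
#'   [compute_delta_f()]), or a bare numeric vector.
#' @param threshold A [compute_threshold()] result, or a single number.
#' @return The input data frame with a logical `reactive` column appended
#'   (a data frame is built around a bare numeric input).
#' @export
classify <- function(delta_f, threshold) {
  thr <- if (inherits(threshold, "reactivity_threshold")) threshold$value
         else as.numeric(threshold)
  if (length(thr) != 1L || !is.finite(thr)) {
    stop("'threshold' must resolve to a single finite value", call. = FALSE)
  }
  if (is.numeric(delta_f)) {
    delta_f <- data.frame(cell_id = seq_along(delta_f), delta_f = delta_f)
  }
  if (!"delta_f" %in% names(delta_f)) {
    stop("'delta_f' must contain a 'delta_f' column", call. = FALSE)
  }
  delta_f$reactive <- delta_f$delta_f > thr
  delta_f
}

#' Fraction of reactive cells in a well
#'
#' @param calls Data frame with a logical `reactive` column (from
#'   [classify()]); if a `stimulus` column is present the summary is computed
#'   per stimulus.
#' @param well_id Optional well identifier.
#' @return Data frame with columns `well_id`, `stimulus` (if any), `n_cells`,
#'   `n_reactive`, `fraction_reactive`.
#' @export
fraction_reactive <- function(calls, well_id = NA_character_) {
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    stop("no cells in well: cannot compute a reactive fraction", call. = FALSE)
  }
  if (!is.logical(calls$reactive)) {
    stop("'calls' must carry a logical 'reactive' column", call. = FALSE)
  }
  grp <- if ("stimulus" %in% names(calls)) calls$stimulus else
    rep("all", nrow(calls))
  agg <- lapply(split(calls$reactive, grp), function(r) {
    data.frame(n_cells = length(r), n_reactive = sum(r),
               fraction_reactive = mean(r))
  })
  out <- do.call(rbind, agg)
  out <- cbind(data.frame(well_id = well_id, stimulus = names(agg)), out)
  rownames(out) <- NULL
  out
}

#' Summarise reactive fractions over replicates
#'
#' Technical replicates (wells) within the same biological replicate are
#' averaged first; the mean and SEM are then taken across biological
#' replicates. With a single biological replicate the SEM is undefined
#' (`NA`), never 0.
#'
#' @param df Data frame with columns `condition`, `replicate` (biological
#'   replicate id) and the value column; extra grouping columns (e.g.
#'   `stimulus`) can be listed in `by`.
#' @param value Name of the value column (default `"fraction_reactive"`).
#' @param by Extra grouping column names.
#' @return Data frame with per-condition `n_replicates`, `mean`, `sem`.
#' @examples
#' df <- data.frame(condition = "ctrl", replicate = 1:3,
#'                  fraction_reactive = c(0.2, 0.3, 0.4))
#' summarize_replicates(df)   # mean 0.3, sem 0.0577
#' @export
summarize_replicates <- function(df, value = "fraction_reactive",
                                 by = character(0)) {
  need <- c("condition", "replicate", value, by)
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  keys1 <- df[, c("condition", by, "replicate"), drop = FALSE]
  # technical replicates -> one value per biological replicate
  rep_means <- stats::aggregate(df[[value]], by = as.list(keys1), FUN = mean)
  names(rep_means)[ncol(rep_means)] <- value
  keys2 <- rep_means[, c("condition", by), drop = FALSE]
  out <- stats::aggregate(rep_means[[value]], by = as.list(keys2),
                          FUN = function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  stats_m <- out$x
  out$x <- NULL
  out$n_replicates <- as.integer(stats_m[, "n"])
  out$mean <- stats_m[, "mean"]
  out$sem <- stats_m[, "sem"]
  out
}

#' Overlap of responders to two sequential stimuli
#'
#' Cross-tabulates the binary reactivity calls of the same cells to two
#' stimuli (e.g. a purinergic agonist followed by capsaicin) into the four
#' population fractions: responding to both, to A only, to B only, or to
#' neither. The fractions sum to 1.
#'
#' @param calls_A,calls_B Data frames with `cell_id` and logical `reactive`
#'   columns, covering the same cell set.
#' @return A list of class `overlap_summary` with `n_cells`,
#'   `fraction_both`, `fraction_A_only`, `fraction_B_only`,
#'   `fraction_neither`.
#' @export
double_stim_overlap <- function(calls_A, calls_B) {
  if (!setequal(calls_A$cell_id, calls_B$cell_id) ||
      nrow(calls_A) != nrow(calls_B)) {
    stop("the two call sets must cover the same cells", call. = FALSE)
  }
  b <- calls_B$reactive[match(calls_A$cell_id, calls_B$cell_id)]
  a <- calls_A$reactive
  n <- length(a)
  structure(list(n_cells = n,
                 fraction_both = sum(a & b) / n,
                 fraction_A_only = sum(a & !b) / n,
                 fraction_B_only = sum(!a & b) / n,
                 fraction_neither = sum(!a & !b) / n),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "<overlap_summary> n = %d: both %.1f%%, A only %.1f%%, B only %.1f%%, neither %.1f%%\n",
    x$n_cells, 100 * x$fraction_both, 100 * x$fraction_A_only,
    100 * x$fraction_B_only, 100 * x$fraction_neither))
  invisible(x)
}

#' Compare reactive fractions between conditions
#'
#' Two conditions are compared by a two-sample t-test (paired or unpaired);
#' three or more by one-way ANOVA followed by Dunnett-style comparisons
#' against the reference condition (all-pairs Tukey optional). Inputs are
#' biological-replicate-level values (average technical replicates first,
#' e.g. via [summarize_replicates()]).
#'
#' @param df Data frame with columns `condition`, the value column, and (for
#'   paired designs) `replicate`.
#' @param reference Reference (control) condition label.
#' @param value Name of the value column.
#' @param design `"unpaired"` (default) or `"paired"` (pairing by
#'   `replicate`).
#' @param posthoc `"dunnett"` (comparisons vs the reference) or `"tukey"`
#'   (all pairs), for >= 3 conditions.
#' @return Data frame with columns `comparison`, `estimate` (difference in
#'   means) and `p_value`.
#' @export
compare_conditions <- function(df, reference, value = "fraction_reactive",
                               design = c("unpaired", "paired"),
                               posthoc = c("dunnett", "tukey")) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (!all(c("condition", value) %in% names(df))) {
    stop("'df' must contain 'condition' and '", value, "' columns",
         call. = FALSE)
  }
  conds <- unique(as.character(df$condition))
  if (!reference %in% conds) {
    stop("reference condition '", reference, "' not present", call. = FALSE)
  }
  counts <- table(df$condition)
  if (any(counts < 2L)) {
    stop("every condition needs >= 2 replicates for significance testing",
         call. = FALSE)
  }
  v <- df[[value]]
  if (length(conds) == 2L) {
    other <- setdiff(conds, reference)
    x <- v[df$condition == other]
    y <- v[df$condition == reference]
    if (design == "paired") {
      ord_x <- order(df$replicate[df$condition == other])
      ord_y <- order(df$replicate[df$condition == reference])
      x <- x[ord_x]; y <- y[ord_y]
    }
    est <- mean(x) - mean(y)
    p <- tryCatch(
      stats::t.test(x, y, paired = (design == "paired"))$p.value,
      error = function(e) if (isTRUE(all.equal(est, 0))) 1 else 0)
    if (is.nan(p)) p <- if (isTRUE(all.equal(est, 0))) 1 else 0
    return(data.frame(comparison = paste(other, "-", reference),
                      estimate = est, p_value = p))
  }
  d <- data.frame(y = v, condition = stats::relevel(factor(df$condition),
                                                    ref = reference))
  fit <- stats::aov(y ~ condition, data = d)
  cmp <- if (posthoc == "dunnett") multcomp::mcp(condition = "Dunnett")
         else multcomp::mcp(condition = "Tukey")
  gl <- summary(multcomp::glht(fit, linfct = cmp))
  data.frame(comparison = names(gl$test$coefficients),
             estimate = unname(gl$test$coefficients),
             p_value = unname(gl$test$pvalues))
}

#' Per-well reactivity thresholds for a delta F table
#'
#' Resolves the negative-control delta F source for each well: if the well's
#' own protocol contained a negative-control stimulus (`control_stimulus`),
#' its delta F values are used; otherwise the delta F values of all control
#' wells (`is_control` in the metadata) on the same plate are pooled. The
#' mode used is recorded per well.
#'
#' @param delta_f Data frame with columns `well_id`, `cell_id`, `stimulus`,
#'   `delta_f`.
#' @param wells Data frame with columns `well_id`, `plate`, `is_control`
#'   (logical).
#' @param control_stimulus Label of the negative-control stimulus.
#' @param cap Threshold cap (fluorescence units).
#' @return Named list of [compute_threshold()] results, one per well, each
#'   with an added `mode` element (`"same_well"` or `"pooled_controls"`).
#' @export
well_thresholds <- function(delta_f, wells, control_stimulus = "HBSS",
                            cap = 18) {
  need <- c("well_id", "stimulus", "delta_f")
  if (!all(need %in% names(delta_f))) {
    stop("'delta_f' must contain well_id, stimulus, delta_f", call. = FALSE)
  }
  out <- list()
  for (w in unique(delta_f$well_id)) {
    own <- delta_f$delta_f[delta_f$well_id == w &
                           delta_f$stimulus == control_stimulus]
    if (length(own) >= 2L) {
      th <- compute_threshold(own, cap = cap, well_id = w)
      th$mode <- "same_well"
    } else {
      plate <- wells$plate[match(w, wells$well_id)]
      ctrl_wells <- wells$well_id[wells$is_control & wells$plate %in% plate]
      pooled <- delta_f$delta_f[delta_f$well_id %in% ctrl_wells]
      if (length(pooled) < 2L) {
        stop(sprintf(paste0(
          "well '%s' has no negative-control stimulus and no control wells ",
          "on its plate; add an '%s' stimulus or mark control wells ",
          "(is_control) in the metadata"), w, control_stimulus),
          call. = FALSE)
      }
      th <- compute_threshold(pooled, cap = cap, well_id = w)
      th$mode <- "pooled_controls"
    }
    out[[w]] <- th
  }
  out
}
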