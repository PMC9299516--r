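#' Stimulation protocol of a calcium-imaging recording
#'
#' Describes when each stimulus was added and which time windows are used to
#' quantify responses. Windows are half-open `[start, end)`; a frame belongs
#' to a window iff its timestamp falls inside. The baseline window must end
#' at or before the first stimulus; each stimulus response window ends at the
#' next stimulus addition (or `response_window_length` later, whichever is
#' earlier) and never extends past the recording end.
#'
#' @param stimuli Named numeric vector: stimulus label -> addition time (s),
#'   in increasing order.
#' @param duration Recording length in seconds.
#' @param baseline_window Length-2 numeric `(start, end)`; default
#'   `(0, first stimulus time)`.
#' @param response_window_length Maximum response window per stimulus in
#'   seconds; `NULL` = up to the next stimulus / end of recording.
#' @param rebaseline_length Seconds of trace immediately preceding a
#'   second or later stimulus used to re-anchor its baseline, so that a
#'   sustained response to an earlier stimulus does not inflate later
#'   response amplitudes.
#' @return An object of class `stimulation_protocol`.
#' @examples
#' stimulation_protocol(c(A = 10, B = 27), duration = 45)
#' @export
stimulation_protocol <- function(stimuli, duration = 45,
                                 baseline_window = c(0, unname(stimuli[1L])),
                                 response_window_length = NULL,
                                 rebaseline_length = 5) {
  if (length(stimuli) < 1L || is.null(names(stimuli)) ||
      any(!nzchar(names(stimuli)))) {
    stop("'stimuli' must be a non-empty named vector of addition times",
         call. = FALSE)
  }
  if (is.unsorted(stimuli, strictly = TRUE) && length(stimuli) > 1L) {
    stop("stimulus addition times must be strictly increasing", call. = FALSE)
  }
  if (baseline_window[2L] > stimuli[1L]) {
    stop("baseline window must end at or before the first stimulus",
         call. = FALSE)
  }
  if (max(stimuli) > duration) {
    stop("stimulus addition after end of recording", call. = FALSE)
  }
  ends <- c(unname(stimuli[-1L]), duration)
  if (!is.null(response_window_length)) {
    ends <- pmin(ends, unname(stimuli) + response_window_length)
  }
  windows <- data.frame(stimulus = names(stimuli), start = unname(stimuli),
                        end = ends)
  structure(list(stimuli = stimuli, duration = duration,
                 baseline_window = as.numeric(baseline_window),
                 response_windows = windows,
                 rebaseline_length = rebaseline_length),
            class = "stimulation_protocol")
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat(sprintf("<stimulation_protocol> %.3g s recording, baseline [%g, %g) s\n",
              x$duration, x$baseline_window[1L], x$baseline_window[2L]))
  for (i in seq_len(nrow(x$response_windows))) {
    w <- x$response_windows[i, ]
    cat(sprintf("  %s: added %g s, response window [%g, %g) s\n",
                w$stimulus, w$start, w$start, w$end))
  }
  invisible(x)
}

#' Stimulus-evoked fluorescence changes (delta F) per cell
#'
#' For each cell and stimulus, delta F is the maximum trace value inside the
#' stimulus response window minus the baseline (mean, by default, of the
#' pre-stimulus window), in raw intensity units. For the second and later
#' stimuli the baseline is re-anchored to the `rebaseline_length` seconds
#' immediately preceding that stimulus addition, so carry-over from a
#' sustained earlier response is removed.
#'
#' @param traces Matrix (cells x frames) with frame times (seconds) as column
#'   names.
#' @param protocol A [stimulation_protocol()].
#' @param baseline_stat `"mean"` (default) or `"median"` of the baseline
#'   window.
#' @param response_stat `"max"` (default) or `"mean"` over the response
#'   window.
#' @return Data frame with columns `cell_id`, `stimulus`, `delta_f`
#'   (one row per cell and stimulus).
#' @examples
#' tr <- matrix(c(rep(100, 20), rep(130, 70)), nrow = 1)
#' colnames(tr) <- format((0:89) / 2)
#' rownames(tr) <- "c1"
#' compute_delta_f(tr, stimulation_protocol(c(A = 10)))
#' @export
compute_delta_f <- function(traces, protocol,
                            baseline_stat = c("mean", "median"),
                            response_stat = c("max", "mean")) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  baseline_stat <- match.arg(baseline_stat)
  response_stat <- match.arg(response_stat)
  times <- as.numeric(colnames(traces))
  if (anyNA(times)) {
    stop("trace column names must be numeric frame times in seconds",
         call. = FALSE)
  }
  bstat <- if (baseline_stat == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  n <- nrow(traces)
  if (n == 0L) {
    return(data.frame(cell_id = character(0), stimulus = character(0),
                      delta_f = numeric(0)))
  }
  ids <- rownames(traces)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_len(n))
  win <- protocol$response_windows
  out <- vector("list", nrow(win))
  for (k in seq_len(nrow(win))) {
    if (k == 1L) {
      b0 <- protocol$baseline_window[1L]; b1 <- protocol$baseline_window[2L]
    } else {
      b1 <- win$start[k]; b0 <- b1 - protocol$rebaseline_length
    }
    bidx <- which(times >= b0 & times < b1)
    ridx <- which(times >= win$start[k] & times < win$end[k])
    if (!length(ridx)) {
      stop(sprintf("response window of stimulus '%s' contains no frames",
                   win$stimulus[k]), call. = FALSE)
    }
    if (!length(bidx)) {
      stop(sprintf("baseline window of stimulus '%s' contains no frames",
                   win$stimulus[k]), call. = FALSE)
    }
    base <- bstat(traces[, bidx, drop = FALSE])
    resp <- if (response_stat == "max") {
      apply(traces[, ridx, drop = FALSE], 1L, max)
    } else {
      rowMeans(traces[, ridx, drop = FALSE])
    }
    out[[k]] <- data.frame(cell_id = ids, stimulus = win$stimulus[k],
                           delta_f = unname(resp - base))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
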