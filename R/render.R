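#' Fluorescence image stack
#'
#' Container for a time series of grayscale frames. Frames are stored as a
#' 3-D array indexed `[y, x, frame]`; `frame_times` gives one strictly
#' increasing timestamp (seconds) per frame.
#'
#' @param frames Numeric 3-D array `[y, x, frame]` of intensities.
#' @param frame_times Numeric vector, one timestamp per frame, strictly
#'   increasing.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_times) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be a 3-D array [y, x, frame]", call. = FALSE)
  }
  if (length(frame_times) != dim(frames)[3L]) {
    stop("need exactly one frame time per frame", call. = FALSE)
  }
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0)) {
    stop("'frame_times' must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px, t = %.3g..%.3g s\n",
              d[3], d[1], d[2], min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Render simulated traces into a synthetic image stack
#'
#' Draws each cell as an isotropic 2-D Gaussian spot whose integrated
#' intensity is proportional to that cell's trace value in each frame, on a
#' constant background. The spot radius is taken as `2 * spot_sigma`; cell
#' positions must keep a pairwise distance of at least twice that radius so
#' that spots are resolvable.
#'
#' @param traces Matrix (cells x frames) of fluorescence values; column names
#'   are frame times in seconds.
#' @param truth Data frame with columns `x`, `y` (pixel positions, 1-based)
#'   as produced by [simulate_well()].
#' @param frame_shape Integer 2-vector `c(ny, nx)`; default sized to fit all
#'   positions with a margin.
#' @param spot_sigma Gaussian spot SD in pixels.
#' @param gain Conversion factor from trace fluorescence units to integrated
#'   camera counts.
#' @param background Constant background level in counts.
#' @param max_count Saturation level (default 16-bit).
#' @return An [image_stack()] with integer-quantized frames.
#' @export
render_image_stack <- function(traces, truth, frame_shape = NULL,
                               spot_sigma = 1.5, gain = 20, background = 40,
                               max_count = 65535) {
  n <- nrow(traces)
  if (n != nrow(truth)) stop("'traces' and 'truth' disagree on cell count",
                             call. = FALSE)
  ft <- as.numeric(colnames(traces))
  if (anyNA(ft)) stop("trace column names must be frame times", call. = FALSE)
  if (is.null(frame_shape)) {
    m <- ceiling(4 * spot_sigma)
    frame_shape <- if (n == 0L) c(32L, 32L) else
      c(max(truth$y) + m, max(truth$x) + m)
  }
  ny <- frame_shape[1L]; nx <- frame_shape[2L]
  radius <- 2 * spot_sigma
  if (n > 0) {
    if (any(truth$x < 1 | truth$x > nx | truth$y < 1 | truth$y > ny)) {
      stop("cell positions must lie inside the frame", call. = FALSE)
    }
    if (n > 1) {
      d <- stats::dist(cbind(truth$x, truth$y))
      if (min(d) < 2 * radius) {
        stop(sprintf(
          "cell placement error: minimum pairwise distance %.2f px < %.2f px",
          min(d), 2 * radius), call. = FALSE)
      }
    }
  }
  npix <- ny * nx
  nt <- ncol(traces)
  if (n == 0L) {
    frames <- array(round(background), dim = c(ny, nx, nt))
    return(image_stack(frames, ft))
  }
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  W <- matrix(0, npix, n)  # unit-mass spot profile per cell
  for (i in seq_len(n)) {
    g <- exp(-((xx - truth$x[i])^2 + (yy - truth$y[i])^2) / (2 * spot_sigma^2))
    W[, i] <- g / (2 * pi * spot_sigma^2)
  }
  flat <- background + W %*% (gain * traces)   # npix x nt
  flat <- round(pmin(pmax(flat, 0), max_count))
  frames <- array(flat, dim = c(ny, nx, nt))
  image_stack(frames, ft)
}

#' Write an image stack as a multi-frame 16-bit grayscale TIFF
#'
#' Frame times are not stored in the TIFF; keep the stimulation protocol (or
#' pass `frame_times` back to [read_image_stack()]).
#'
#' @param stack An [image_stack()]; intensities must lie in `[0, 65535]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- dim(stack$frames)[3L]
  pages <- lapply(seq_len(nt), function(k) stack$frames[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-frame grayscale TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param frame_times Numeric vector of frame timestamps (seconds), or
#'   `frame_rate` to derive them as `0, 1/rate, ...`.
#' @param frame_rate Frames per second; ignored when `frame_times` is given.
#' @return An [image_stack()] with intensities on the original 16-bit scale.
#' @export
read_image_stack <- function(path, frame_times = NULL, frame_rate = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- length(pages)
  d <- dim(pages[[1L]])
  frames <- array(0, dim = c(d[1L], d[2L], nt))
  for (k in seq_len(nt)) frames[, , k] <- round(pages[[k]] * 65535)
  if (is.null(frame_times)) frame_times <- (seq_len(nt) - 1) / frame_rate
  image_stack(frames, frame_times)
}
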