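#' Detect cell bodies in a fluorescence image stack
#'
#' Segmentation stand-in for dedicated Ca2+-imaging software: the temporal
#' maximum projection is Gaussian-smoothed, the median background is
#' subtracted, and local maxima exceeding a prominence threshold are kept
#' greedily (brightest first) subject to a minimum pairwise separation.
#' Fixed-radius circular ROIs are returned; candidates whose disk would cross
#' the frame border are dropped. Two cells closer than `min_separation`
#' merge into a single ROI. Deterministic for fixed parameters.
#'
#' @param stack An [image_stack()].
#' @param smooth_sigma Gaussian smoothing SD in pixels.
#' @param min_separation Minimum distance between accepted ROI centres (px).
#' @param radius ROI radius in pixels.
#' @param min_prominence Intensity above background required of a peak;
#'   default `3 * mad` of the smoothed projection (so a uniform, cell-free
#'   stack yields no ROIs).
#' @return Data frame with columns `cell_id`, `x`, `y`, `radius` (pixel
#'   coordinates, 1-based).
#' @export
detect_cells <- function(stack, smooth_sigma = 1.5, min_separation = 6,
                         radius = 3, min_prominence = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (any(d == 0)) stop("empty image stack", call. = FALSE)
  proj <- apply(stack$frames, c(1, 2), max)
  ksz <- min(2L * ceiling(3 * smooth_sigma) + 1L, dim(proj) - 1 + (dim(proj) %% 2))
  ksz <- max(3L, ksz - (1L - ksz %% 2L))  # odd, >= 3, <= image size
  kern <- EBImage::makeBrush(ksz, shape = "gaussian", sigma = smooth_sigma)
  sm <- EBImage::filter2(proj, kern)
  bg <- stats::median(sm)
  if (is.null(min_prominence)) min_prominence <- 3 * stats::mad(sm)
  ny <- d[1L]; nx <- d[2L]
  cand <- which(sm - bg > min_prominence, arr.ind = TRUE)
  if (nrow(cand)) {
    # strict 8-neighbour local maximum
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      y <- cand[i, 1L]; x <- cand[i, 2L]
      ys <- max(1L, y - 1L):min(ny, y + 1L)
      xs <- max(1L, x - 1L):min(nx, x + 1L)
      nb <- sm[ys, xs]
      keep[i] <- sum(nb >= sm[y, x]) == 1L  # only the centre itself
    }
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
                      radius = numeric(0)))
  }
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1L]; x <- cand[i, 2L]
    if (x - radius < 1 || x + radius > nx || y - radius < 1 || y + radius > ny)
      next
    if (nrow(sel) == 0L ||
        min(sqrt((sel[, 1] - x)^2 + (sel[, 2] - y)^2)) >= min_separation) {
      sel <- rbind(sel, c(x, y))
    }
  }
  n <- nrow(sel)
  data.frame(cell_id = sprintf("roi_%03d", seq_len(n)),
             x = sel[, 1], y = sel[, 2], radius = radius)
}

#' Extract per-cell traces from an image stack
#'
#' The trace value of a cell in a frame is the mean pixel intensity inside
#' its circular ROI. Cell order and count are preserved.
#'
#' @param stack An [image_stack()].
#' @param rois Data frame with columns `cell_id`, `x`, `y`, `radius` as
#'   returned by [detect_cells()].
#' @return Matrix (cells x frames); row names are cell ids, column names the
#'   frame times in seconds.
#' @export
extract_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  ny <- d[1L]; nx <- d[2L]; nt <- d[3L]
  n <- nrow(rois)
  out <- matrix(0, n, nt,
                dimnames = list(rois$cell_id, format(stack$frame_times)))
  if (n == 0L) return(out)
  if (any(rois$radius <= 0)) stop("ROI radius must be > 0", call. = FALSE)
  if (any(rois$x - rois$radius < 1 | rois$x + rois$radius > nx |
          rois$y - rois$radius < 1 | rois$y + rois$radius > ny)) {
    stop("ROI extends outside frame bounds", call. = FALSE)
  }
  flat <- matrix(stack$frames, ny * nx, nt)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(n)) {
    disk <- which((xx - rois$x[i])^2 + (yy - rois$y[i])^2 <= rois$radius[i]^2)
    out[i, ] <- colMeans(flat[disk, , drop = FALSE])
  }
  out
}
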