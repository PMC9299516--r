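#' Configuration for a simulated calcium-imaging well
#'
#' Defines the statistical conditions of one simulated well: a mixed
#' population of non-responders and cells responding to either or both of two
#' test stimuli, recorded for 45 s at a fixed frame rate with stimuli applied
#' after a 10-s baseline. Defaults mirror the assay design the package
#' targets: the class mixture reproduces the observed population split
#' (40% responding to the purinergic stimulus only, 10% to the TRPV1 stimulus
#' only, 25% to both), response amplitudes sit well above the reactivity cap,
#' and photobleaching gives a mild negative drift of the baseline.
#'
#' Stimulus labels `"A"` and `"B"` denote the two test stimuli whose
#' amplitudes are governed by the responder class; any other label (e.g.
#' `"HBSS"`) is treated as a negative-control addition whose amplitude is
#' drawn for every cell from the artifact distribution (default 0), which is
#' how mechanical-allodynia scenarios with elevated buffer-evoked responses
#' are simulated.
#'
#' @param n_cells Number of cells in the well.
#' @param class_probabilities Named numeric 4-vector over
#'   `c("none", "A_only", "B_only", "both")`; must sum to 1.
#' @param amplitude_mean,amplitude_sd Normal distribution of response
#'   amplitudes (fluorescence units; truncated at 0) for responding cells.
#' @param noise_sd Per-frame Gaussian noise SD (fluorescence units).
#' @param bleach_rate Exponential photobleaching rate of the baseline
#'   (per second).
#' @param frame_rate Acquisition rate, frames per second.
#' @param duration Recording length in seconds.
#' @param baseline_duration Baseline recording before the first stimulus,
#'   seconds.
#' @param stimulus_times Named numeric vector of stimulus addition times in
#'   seconds, within `[baseline_duration, duration]`.
#' @param artifact_amplitude_mean,artifact_amplitude_sd Distribution of the
#'   response evoked by negative-control additions in every cell (default 0:
#'   no response).
#' @param baseline_level_mean,baseline_level_sd Distribution of resting
#'   fluorescence per cell (truncated below at 1).
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @return A `sim_well_config` list.
#' @export
sim_well_config <- function(n_cells = 200,
                            class_probabilities = c(none = 0.25, A_only = 0.40,
                                                    B_only = 0.10, both = 0.25),
                            amplitude_mean = 60, amplitude_sd = 15,
                            noise_sd = 2, bleach_rate = 0.001,
                            frame_rate = 2, duration = 45,
                            baseline_duration = 10,
                            stimulus_times = c(A = 10),
                            artifact_amplitude_mean = 0,
                            artifact_amplitude_sd = 0,
                            baseline_level_mean = 100,
                            baseline_level_sd = 10,
                            seed = 1L) {
  cfg <- list(n_cells = n_cells, class_probabilities = class_probabilities,
              amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
              noise_sd = noise_sd, bleach_rate = bleach_rate,
              frame_rate = frame_rate, duration = duration,
              baseline_duration = baseline_duration,
              stimulus_times = stimulus_times,
              artifact_amplitude_mean = artifact_amplitude_mean,
              artifact_amplitude_sd = artifact_amplitude_sd,
              baseline_level_mean = baseline_level_mean,
              baseline_level_sd = baseline_level_sd,
              seed = seed)
  validate_sim_well_config(cfg)
  structure(cfg, class = "sim_well_config")
}

validate_sim_well_config <- function(cfg) {
  if (!is.numeric(cfg$n_cells) || cfg$n_cells < 0 ||
      cfg$n_cells != round(cfg$n_cells)) {
    stop("'n_cells' must be a non-negative integer", call. = FALSE)
  }
  p <- cfg$class_probabilities
  if (length(p) != 4L ||
      !setequal(names(p), c("none", "A_only", "B_only", "both"))) {
    stop("'class_probabilities' must be named over none/A_only/B_only/both",
         call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("'class_probabilities' must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (cfg$frame_rate <= 0 || cfg$duration <= 0) {
    stop("'frame_rate' and 'duration' must be positive", call. = FALSE)
  }
  if (cfg$duration < cfg$baseline_duration) {
    stop("'duration' must be at least 'baseline_duration'", call. = FALSE)
  }
  st <- cfg$stimulus_times
  if (length(st) > 0) {
    if (is.null(names(st)) || any(!nzchar(names(st)))) {
      stop("'stimulus_times' must be a named vector", call. = FALSE)
    }
    if (any(st < cfg$baseline_duration) || any(st > cfg$duration)) {
      stop("stimulus times must lie within [baseline_duration, duration]",
           call. = FALSE)
    }
  }
  if (cfg$noise_sd < 0 || cfg$bleach_rate < 0) {
    stop("'noise_sd' and 'bleach_rate' must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Frame times of a simulated recording
#' @param cfg A [sim_well_config()].
#' @return Numeric vector of frame timestamps in seconds (first frame at 0).
#' @export
sim_frame_times <- function(cfg) {
  n <- round(cfg$duration * cfg$frame_rate)
  (seq_len(n) - 1) / cfg$frame_rate
}

# Deterministic signal component of one cell's trace (no noise).
trace_signal <- function(cfg, baseline_level, amplitudes, templates) {
  t <- sim_frame_times(cfg)
  y <- baseline_level * exp(-cfg$bleach_rate * t)
  for (lab in names(cfg$stimulus_times)) {
    a <- amplitudes[[lab]]
    if (!is.null(a) && a != 0) {
      y <- y + a * eval_kinetic(templates[[lab]], t - cfg$stimulus_times[[lab]])
    }
  }
  y
}

#' Simulate one cell's fluorescence trace
#'
#' Generates one per-frame fluorescence sequence: an exponentially bleaching
#' baseline plus an amplitude-scaled kinetic template anchored at the
#' stimulus time, plus i.i.d. Gaussian noise.
#'
#' @param template A [kinetic_template()].
#' @param cfg A [sim_well_config()] supplying frame rate, duration, bleach
#'   rate and noise SD.
#' @param amplitude Response amplitude in fluorescence units.
#' @param baseline_level Resting fluorescence.
#' @param stimulus_time Stimulus addition time (seconds); defaults to the
#'   first entry of `cfg$stimulus_times`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed.
#' @return Numeric vector of length `round(duration * frame_rate)`.
#' @export
make_trace <- function(template, cfg, amplitude, baseline_level = 100,
                       stimulus_time = cfg$stimulus_times[[1L]], seed = NULL) {
  validate_sim_well_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  t <- sim_frame_times(cfg)
  y <- baseline_level * exp(-cfg$bleach_rate * t) +
    amplitude * eval_kinetic(template, t - stimulus_time)
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(t), 0, cfg$noise_sd)
  y
}

rnorm_trunc <- function(n, mean, sd, lower = 0) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Simulate a full well with ground truth
#'
#' Draws responder classes from the configured mixture, assigns response
#' amplitudes and spatial positions, and synthesises the per-cell fluorescence
#' traces. The returned ground truth supports parameter-recovery tests of the
#' downstream reactivity analysis.
#'
#' @param cfg A [sim_well_config()].
#' @param templates Named list of [kinetic_template()]s, one per stimulus
#'   label in `cfg$stimulus_times`; defaults to [default_templates()].
#' @param grid_spacing Pixel spacing of the cell placement grid used when the
#'   well is rendered to an image stack.
#' @return A list of class `sim_well` with elements `traces` (matrix, cells x
#'   frames, column names = frame times in seconds), `truth` (data frame with
#'   cell_id, responder_class, amplitude_A, amplitude_B, artifact amplitudes,
#'   baseline_level, x, y) and `cfg`.
#' @examples
#' w <- simulate_well(sim_well_config(n_cells = 20, seed = 7))
#' dim(w$traces)
#' table(w$truth$responder_class)
#' @export
simulate_well <- function(cfg, templates = default_templates(names(cfg$stimulus_times)),
                          grid_spacing = 8) {
  validate_sim_well_config(cfg)
  labs <- names(cfg$stimulus_times)
  missing_tpl <- setdiff(labs, names(templates))
  if (length(missing_tpl)) {
    stop("no kinetic template supplied for stimulus: ",
         paste(missing_tpl, collapse = ", "), call. = FALSE)
  }
  set.seed(cfg$seed)
  n <- cfg$n_cells
  t <- sim_frame_times(cfg)
  classes <- c("none", "A_only", "B_only", "both")
  if (n == 0L) {
    traces <- matrix(numeric(0), nrow = 0, ncol = length(t),
                     dimnames = list(NULL, format(t)))
    truth <- data.frame(cell_id = character(0), responder_class = character(0),
                        amplitude_A = numeric(0), amplitude_B = numeric(0),
                        baseline_level = numeric(0), x = numeric(0),
                        y = numeric(0))
    return(structure(list(traces = traces, truth = truth, cfg = cfg),
                     class = "sim_well"))
  }
  cls <- sample(classes, n, replace = TRUE,
                prob = cfg$class_probabilities[classes])
  amp_A <- ifelse(cls %in% c("A_only", "both"),
                  rnorm_trunc(n, cfg$amplitude_mean, cfg$amplitude_sd), 0)
  amp_B <- ifelse(cls %in% c("B_only", "both"),
                  rnorm_trunc(n, cfg$amplitude_mean, cfg$amplitude_sd), 0)
  baseline <- rnorm_trunc(n, cfg$baseline_level_mean, cfg$baseline_level_sd,
                          lower = 1)
  # control (non-A/B) stimuli evoke an artifact response in every cell
  ctrl_labs <- setdiff(labs, c("A", "B"))
  artifact <- lapply(ctrl_labs, function(l) {
    if (cfg$artifact_amplitude_mean == 0 && cfg$artifact_amplitude_sd == 0) {
      numeric(n)
    } else {
      rnorm_trunc(n, cfg$artifact_amplitude_mean, cfg$artifact_amplitude_sd)
    }
  })
  names(artifact) <- ctrl_labs

  # positions on a jittered grid, spacing >= grid_spacing
  side <- ceiling(sqrt(n))
  gx <- ((seq_len(n) - 1) %% side) * grid_spacing + grid_spacing
  gy <- ((seq_len(n) - 1) %/% side) * grid_spacing + grid_spacing

  traces <- matrix(0, nrow = n, ncol = length(t))
  for (i in seq_len(n)) {
    amps <- c(list(A = amp_A[i], B = amp_B[i]),
              lapply(artifact, function(a) a[i]))
    traces[i, ] <- trace_signal(cfg, baseline[i], amps, templates)
  }
  if (cfg$noise_sd > 0) {
    traces <- traces + matrix(stats::rnorm(n * length(t), 0, cfg$noise_sd),
                              nrow = n)
  }
  ids <- sprintf("cell_%03d", seq_len(n))
  rownames(traces) <- ids
  colnames(traces) <- format(t)
  truth <- data.frame(cell_id = ids, responder_class = cls,
                      amplitude_A = amp_A, amplitude_B = amp_B,
                      baseline_level = baseline, x = gx, y = gy)
  for (l in ctrl_labs) truth[[paste0("amplitude_", l)]] <- artifact[[l]]
  structure(list(traces = traces, truth = truth, cfg = cfg),
            class = "sim_well")
}

#' @export
print.sim_well <- function(x, ...) {
  cat(sprintf("<sim_well> %d cells x %d frames (%.3g s at %g fps), stimuli: %s\n",
              nrow(x$traces), ncol(x$traces), x$cfg$duration,
              x$cfg$frame_rate,
              paste(names(x$cfg$stimulus_times), collapse = ", ")))
  invisible(x)
}
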