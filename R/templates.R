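#' Parametric kinetic template for a stimulus-evoked calcium transient
#'
#' A minimal shape family for single-cell Ca2+-indicator responses: after an
#' onset delay the signal rises linearly to a unit peak over `rise_time`, then
#' decays exponentially towards `plateau_fraction` of the peak with time
#' constant `decay_time`. Fast-inactivating purinergic (P2X3-like) responses
#' use a plateau near 0; sustained TRPV1-like responses a plateau near 1.
#'
#' @param name Template label (e.g. the stimulus name).
#' @param onset_delay Seconds between stimulus addition and signal onset.
#' @param rise_time Seconds from onset to the unit peak (0 = instantaneous).
#' @param decay_time Exponential decay time constant in seconds
#'   (0 = immediate drop to the plateau).
#' @param plateau_fraction Fraction of the peak amplitude retained at the end
#'   of the recording window, in \[0, 1\].
#' @return An object of class `kinetic_template`.
#' @examples
#' tpl <- kinetic_template("P2X3", onset_delay = 0.5, rise_time = 1,
#'                         decay_time = 3, plateau_fraction = 0.05)
#' eval_kinetic(tpl, c(-1, 0.5, 1.5, 10))
#' @export
kinetic_template <- function(name, onset_delay = 0, rise_time = 1,
                             decay_time = 5, plateau_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(onset_delay = onset_delay, rise_time = rise_time,
              decay_time = decay_time)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("kinetic template times must be single non-negative numbers",
           call. = FALSE)
    }
  }
  if (!is.numeric(plateau_fraction) || plateau_fraction < 0 ||
      plateau_fraction > 1) {
    stop("'plateau_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, onset_delay = onset_delay,
                 rise_time = rise_time, decay_time = decay_time,
                 plateau_fraction = plateau_fraction),
            class = "kinetic_template")
}

#' Evaluate a kinetic template at times since stimulus addition
#'
#' @param template A [kinetic_template()].
#' @param t Numeric vector of times in seconds relative to stimulus addition.
#' @return Numeric vector in \[0, 1\]; 0 for all `t` before onset.
#' @export
eval_kinetic <- function(template, t) {
  stopifnot(inherits(template, "kinetic_template"), is.numeric(t))
  s <- t - template$onset_delay
  out <- numeric(length(t))
  peak_t <- template$rise_time
  if (template$rise_time > 0) {
    ris <- s >= 0 & s < peak_t
    out[ris] <- s[ris] / template$rise_time
  }
  dec <- s >= peak_t
  p <- template$plateau_fraction
  if (template$decay_time > 0) {
    out[dec] <- p + (1 - p) * exp(-(s[dec] - peak_t) / template$decay_time)
  } else {
    out[dec] <- ifelse(s[dec] == peak_t, 1, p)
  }
  out
}

#' @export
print.kinetic_template <- function(x, ...) {
  cat(sprintf(
    "<kinetic_template '%s'> onset %.2gs, rise %.2gs, decay %.2gs, plateau %.2g\n",
    x$name, x$onset_delay, x$rise_time, x$decay_time, x$plateau_fraction))
  invisible(x)
}

#' Built-in response templates
#'
#' Convenience constructors for the two nociceptor response archetypes and a
#' negative-control (buffer addition) artifact: `p2x3_template()` is a
#' fast-inactivating transient, `trpv1_template()` a sustained response that
#' retains most of its peak throughout the window, and `control_template()`
#' a brief mechanical-artifact transient used for buffer (HBSS) additions.
#'
#' @return A `kinetic_template`.
#' @name builtin_templates
NULL

#' @rdname builtin_templates
#' @export
p2x3_template <- function() {
  kinetic_template("P2X3", onset_delay = 0.5, rise_time = 1,
                   decay_time = 3, plateau_fraction = 0.05)
}

#' @rdname builtin_templates
#' @export
trpv1_template <- function() {
  kinetic_template("TRPV1", onset_delay = 0.5, rise_time = 2,
                   decay_time = 10, plateau_fraction = 0.9)
}

#' @rdname builtin_templates
#' @export
control_template <- function() {
  kinetic_template("control", onset_delay = 0.5, rise_time = 0.5,
                   decay_time = 2, plateau_fraction = 0)
}

#' Default template set for a stimulation protocol
#'
#' Maps stimulus labels to templates: `"A"` (first test stimulus, P2X3-like
#' fast transient), `"B"` (second test stimulus, TRPV1-like sustained); any
#' other label is treated as a buffer-control addition.
#'
#' @param labels Character vector of stimulus labels.
#' @return Named list of `kinetic_template` objects.
#' @export
default_templates <- function(labels) {
  out <- lapply(labels, function(l) {
    switch(l, A = p2x3_template(), B = trpv1_template(), control_template())
  })
  names(out) <- labels
  out
}
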