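#' Pulse shapes for motoneuron spikes
#'
#' Each motoneuron spike is idealised as a brief pulse of width 1 ms: a half
#' sine wave approximating the depolarised portion of the action potential, or
#' a square pulse. Pulses are either normalised to unit peak (the input
#' convention of the calcium-cascade models) or scaled numerically so that the
#' trapezoidal integral under each pulse is exactly 1 (the impulse
#' approximation the Wilson models assume).
#'
#' @param kind `"half_sine"` or `"square"`.
#' @param width Pulse width in seconds (> 0; default 1 ms).
#' @param normalisation `"unit_peak"` or `"unit_area"`.
#' @return An object of class `pulse_shape`.
#' @export
pulse_shape <- function(kind = c("half_sine", "square"), width = 0.001,
                        normalisation = c("unit_peak", "unit_area")) {
  kind <- match.arg(kind)
  normalisation <- match.arg(normalisation)
  if (!is.finite(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(kind = kind, width = width, normalisation = normalisation),
            class = "pulse_shape")
}

# Sample one pulse on the dt grid (sample centres for the half sine, so the
# discrete pulse is symmetric); unit_area rescaling is applied after sampling,
# which makes the trapezoidal area contract exact regardless of dt.
sample_pulse <- function(shape, dt) {
  np <- round(shape$width / dt)
  if (dt >= shape$width || np < 2) {
    stop("dt must resolve the pulse width with at least 2 samples", call. = FALSE)
  }
  p <- switch(shape$kind,
    half_sine = sin(pi * (seq_len(np) - 0.5) / np),
    square = rep(1, np)
  )
  if (shape$normalisation == "unit_area") p <- p / (sum(p) * dt)
  p
}

#' Shape a spike train into a sampled excitation signal
#'
#' Converts spike onset times into the uniformly sampled input the models
#' consume. Each spike contributes one pulse starting at its onset, snapped to
#' the nearest sample of the `dt` grid; overlapping pulses sum (linear
#' superposition of endplate events). The signal is zero away from pulses.
#'
#' @param train A [spike_train()].
#' @param shape A [pulse_shape()].
#' @param dt Sampling interval in seconds (default 0.0002, i.e. 5 kHz).
#' @param total_time Length of the sampled signal in seconds; must be at least
#'   the train duration. Defaults to the train duration plus one pulse width.
#' @return A tibble of class `muscle_signal` with columns `time` and `value`
#'   and attributes `dt` and `pulse` (the shape used).
#' @examples
#' s <- shape_stimulus(constant_train(20, 0.5), pulse_shape(), total_time = 0.6)
#' @export
shape_stimulus <- function(train, shape = pulse_shape(), dt = 0.0002,
                           total_time = NULL) {
  stopifnot(inherits(train, "spike_train"), inherits(shape, "pulse_shape"))
  if (is.null(total_time)) total_time <- train$duration + shape$width
  if (total_time < train$duration) {
    stop("total_time must be >= the train duration", call. = FALSE)
  }
  n <- round(total_time / dt) + 1L
  v <- numeric(n)
  if (length(train$times)) {
    p <- sample_pulse(shape, dt)
    np <- length(p)
    for (s in train$times) {
      i0 <- round(s / dt) + 1L
      idx <- i0:(i0 + np - 1L)
      keep <- idx <= n
      v[idx[keep]] <- v[idx[keep]] + p[keep]
    }
  }
  new_signal(time = (seq_len(n) - 1) * dt, value = v, dt = dt, pulse = shape)
}

new_signal <- function(time, value, dt, pulse = NULL) {
  out <- tibble::tibble(time = time, value = value)
  class(out) <- c("muscle_signal", class(out))
  attr(out, "dt") <- dt
  attr(out, "pulse") <- pulse
  out
}

#' Build a sampled excitation signal from raw values
#'
#' For the models driven directly by a neural-excitation signal u(t) (Zajac,
#' Bluemel) when a hand-constructed input is wanted rather than a shaped spike
#' train.
#'
#' @param values Numeric vector of samples (finite).
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample (default 0).
#' @return A `muscle_signal` tibble.
#' @export
sampled_signal <- function(values, dt = 0.0002, t0 = 0) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must have length >= 1", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  new_signal(time = t0 + (seq_along(values) - 1) * dt, value = values, dt = dt)
}

signal_dt <- function(signal) {
  dt <- attr(signal, "dt")
  if (is.null(dt)) dt <- stats::median(diff(signal$time))
  dt
}
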