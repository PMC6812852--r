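#' Normalise a force trace
#'
#' Rescales force by one of the conventions used when comparing traces:
#' `"per_trace_max"` (maximum of this trace becomes 1), `"per_animal_max"`
#' (divide by a supplied per-animal maximum), `"twitch_peak_to_0.1"` (scale so
#' a supplied single-twitch peak maps to 0.1, putting twitch and tetanus on a
#' common axis), or `"peak_at_50Hz"` (divide by the supplied 50 Hz peak).
#'
#' @param trace A `force_trace`.
#' @param reference Normalisation convention.
#' @param value Reference value for the conventions that need one: the
#'   per-animal maximum, the single-twitch peak, or the 50 Hz peak. Must be
#'   positive.
#' @return A rescaled `force_trace`; the convention is recorded in the trace
#'   metadata.
#' @export
normalize_trace <- function(trace,
                            reference = c("per_trace_max", "per_animal_max",
                                          "twitch_peak_to_0.1", "peak_at_50Hz"),
                            value = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  reference <- match.arg(reference)
  scale <- switch(reference,
    per_trace_max = max(trace$force),
    per_animal_max = value,
    twitch_peak_to_0.1 = if (is.null(value)) NULL else value / 0.1,
    peak_at_50Hz = value
  )
  if (is.null(scale)) {
    stop(sprintf("reference '%s' needs a reference value", reference), call. = FALSE)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("reference value must be positive", call. = FALSE)
  }
  meta <- trace_meta(trace)
  meta$normalisation <- list(reference = reference, scale = scale)
  new_force_trace(trace$time, trace$force / scale, trace_dt(trace), meta)
}

# first linearly interpolated upward/downward crossing of `level` in force,
# searching indices idx; returns the crossing time or NA
first_crossing <- function(time, force, level, idx, rising = TRUE) {
  f <- force[idx]
  hit <- if (rising) f >= level else f <= level
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(time[idx[1]])
  t1 <- time[idx[i - 1]]; t2 <- time[idx[i]]
  f1 <- force[idx[i - 1]]; f2 <- force[idx[i]]
  if (f2 == f1) return(t2)
  t1 + (level - f1) / (f2 - f1) * (t2 - t1)
}

#' Half-maximal rise time
#'
#' Time from stimulation onset to the first (linearly interpolated) crossing
#' of 50% of the trace's peak force after the onset. The onset defaults to the
#' trace's recorded stimulus onset (first spike plus neural delay), so the
#' delay choice does not bias comparisons between models.
#'
#' @param trace A `force_trace` with a positive peak after the onset.
#' @param onset Onset time in seconds; defaults to the trace metadata.
#' @return Rise time in seconds, or `NA` with a warning if half-peak is never
#'   reached.
#' @export
half_rise_time <- function(trace, onset = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(onset)) onset <- trace_meta(trace)$onset
  if (is.null(onset) || is.na(onset)) onset <- trace$time[1]
  idx <- which(trace$time >= onset)
  if (!length(idx) || max(trace$force[idx]) <= 0) {
    stop("trace has no positive peak after the onset", call. = FALSE)
  }
  peak <- max(trace$force[idx])
  tc <- first_crossing(trace$time, trace$force, 0.5 * peak, idx, rising = TRUE)
  if (is.na(tc)) {
    warning("force never reaches half-peak after onset; rise time undefined",
            call. = FALSE)
    return(NA_real_)
  }
  tc - onset
}

#' Half-maximal decay time
#'
#' Time from the post-stimulus peak (the maximum of the trace at or after
#' `stim_end`, i.e. the force the relaxation starts from) to the first
#' interpolated crossing of 50% of that peak.
#'
#' @param trace A `force_trace`.
#' @param stim_end End of stimulation in seconds; defaults to the trace
#'   metadata (last spike plus neural delay).
#' @return Decay time in seconds, or `NA` with a warning if the trace never
#'   falls to half the post-stimulus peak.
#' @export
half_decay_time <- function(trace, stim_end = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(stim_end)) stim_end <- trace_meta(trace)$stim_end
  if (is.null(stim_end) || is.na(stim_end)) stim_end <- trace$time[1]
  idx <- which(trace$time >= stim_end)
  if (!length(idx)) stop("no samples at or after stim_end", call. = FALSE)
  ipk <- idx[which.max(trace$force[idx])]
  peak <- trace$force[ipk]
  if (peak <= 0) stop("no positive post-stimulus peak to decay from", call. = FALSE)
  tail_idx <- ipk:nrow(trace)
  tc <- first_crossing(trace$time, trace$force, 0.5 * peak, tail_idx,
                       rising = FALSE)
  if (is.na(tc)) {
    warning("force never decays to half of the post-stimulus peak; decay time undefined",
            call. = FALSE)
    return(NA_real_)
  }
  tc - trace$time[ipk]
}

#' Root-mean-square error between two force traces
#'
#' If the grids differ, the simulated trace is linearly resampled onto the
#' measured grid first; the traces must cover a common time span.
#'
#' @param measured,simulated `force_trace` tibbles.
#' @return Root-mean-square of the pointwise force differences.
#' @export
rmse <- function(measured, simulated) {
  stopifnot(inherits(measured, "force_trace"), inherits(simulated, "force_trace"))
  if (nrow(measured) == nrow(simulated) &&
      max(abs(measured$time - simulated$time)) < 1e-12) {
    d <- measured$force - simulated$force
  } else {
    if (min(simulated$time) > min(measured$time) + 1e-9 ||
        max(simulated$time) < max(measured$time) - 1e-9) {
      stop("traces do not share a common grid and the simulated trace does not cover the measured time span",
           call. = FALSE)
    }
    s <- approx(simulated$time, simulated$force, xout = measured$time)$y
    d <- measured$force - s
  }
  sqrt(mean(d^2))
}

#' Frequency-response curve of a model
#'
#' Simulates constant-frequency stimulation at each requested frequency and
#' extracts the per-frequency peak force, half-maximal rise time (from
#' stimulus onset) and half-maximal decay time (from stimulus offset) — the
#' numeric backbone of the model-comparison figures.
#'
#' @param model Model name (see [simulate_muscle()]).
#' @param params Matching parameter object.
#' @param freqs Stimulation frequencies in Hz (non-empty).
#' @param stim_duration Stimulation epoch per frequency in seconds.
#' @param config A [sim_config()]; `relax_time` should be long enough for the
#'   decay measurement.
#' @param normalise If `TRUE`, add column `peak_norm`: peak force divided by
#'   the peak at the highest frequency (the 50 Hz convention when 50 Hz is the
#'   maximum).
#' @param ... Passed to the simulator (e.g. `sigmoid` for the van-Zandwijk
#'   variant).
#' @return A tibble of class `frequency_response` with columns `freq_Hz`,
#'   `peak`, `half_rise_s`, `half_decay_s` (and optionally `peak_norm`).
#' @export
frequency_response <- function(model, params, freqs, stim_duration = 2,
                               config = sim_config(), normalise = FALSE, ...) {
  if (!length(freqs)) stop("freqs must be non-empty", call. = FALSE)
  freqs <- sort(as.numeric(freqs))
  rows <- purrr::map(freqs, function(f) {
    tr <- simulate_muscle(model, params, constant_train(f, stim_duration),
                          config, ...)
    onset <- trace_meta(tr)$onset
    stim_end <- trace_meta(tr)$stim_end
    tibble::tibble(
      freq_Hz = f,
      peak = max(tr$force),
      half_rise_s = suppressWarnings(half_rise_time(tr, onset)),
      half_decay_s = suppressWarnings(half_decay_time(tr, stim_end))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (normalise) out$peak_norm <- out$peak / out$peak[which.max(out$freq_Hz)]
  class(out) <- c("frequency_response", class(out))
  attr(out, "model") <- model
  out
}

#' Export a frequency-response table as delimited text
#'
#' @param fr A `frequency_response` tibble.
#' @param path File path.
#' @export
write_frequency_response <- function(fr, path) {
  write.table(as.data.frame(fr), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
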