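#' Motoneuron spike trains
#'
#' A spike train is the ordered set of motoneuron spike onset times (seconds)
#' that drives every activation model, together with the duration of the
#' stimulation epoch. Times must be strictly increasing, non-negative, and lie
#' within `[0, duration]`; the empty train is allowed.
#'
#' @param times Numeric vector of spike onset times in seconds.
#' @param duration Span of the stimulation epoch in seconds; defaults to the
#'   last spike time.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(0, 0.05, 0.1), duration = 1)
#' @export
spike_train <- function(times = numeric(), duration = NULL) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("spike times must be >= 0", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be a finite non-negative number", call. = FALSE)
  }
  if (length(times) && max(times) > duration) {
    stop("all spike times must lie within [0, duration]", call. = FALSE)
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.4g s\n", length(x$times), x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' @rdname spike_train
#' @param x A `spike_train`.
#' @param ... Unused.
#' @export
as_tibble.spike_train <- function(x, ...) {
  tibble::tibble(spike = seq_along(x$times), time = x$times)
}

#' Constant-frequency spike train
#'
#' Builds the regular stimulation trains used throughout the constant-frequency
#' protocols: spikes at `k / freq` for `k = 0, 1, ...` that fall in
#' `[0, duration)`. A frequency of 0 gives the empty train; 1 Hz with a 1 s
#' duration gives the single-twitch stimulus (one spike at t = 0).
#'
#' @param freq Stimulation frequency in Hz (>= 0).
#' @param duration Stimulation epoch in seconds (> 0).
#' @return A [spike_train()].
#' @examples
#' constant_train(50, 2)   # 100 spikes, 0 .. 1.98 s
#' constant_train(1, 1)    # the single-twitch protocol
#' @export
constant_train <- function(freq, duration) {
  if (!is.finite(freq) || freq < 0) stop("freq must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  if (freq == 0) return(spike_train(numeric(), duration))
  k <- 0:(ceiling(freq * duration) - 1)
  times <- k / freq
  spike_train(times[times < duration], duration)
}

#' Homogeneous Poisson spike train
#'
#' Draws one realisation of a homogeneous Poisson process on `[0, duration]`,
#' reproducibly for a fixed seed. Used to probe the models with naturalistic,
#' irregular activity.
#'
#' @param rate Mean spike rate in Hz (>= 0).
#' @param duration Stimulation epoch in seconds.
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's random-number state is left untouched.
#' @return A [spike_train()].
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  if (!is.finite(rate) || rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  draw <- function() {
    n <- stats::rpois(1, rate * duration)
    sort(runif(n, 0, duration))
  }
  times <- if (is.null(seed)) draw() else with_seed(seed, draw())
  # ties have probability zero but runif can collide at double resolution
  times <- unique(times)
  spike_train(times, duration)
}

#' Inter-spike intervals
#'
#' Interval `i` is `time[i] - time[i - 1]`. The first spike has no predecessor;
#' by the single-twitch convention its interval is 1 s, so that the
#' potentiation factor evaluates to c(1) and a lone spike is treated as an
#' unpotentiated twitch.
#'
#' @param train A [spike_train()].
#' @return Numeric vector of intervals in seconds (empty for an empty train).
#' @examples
#' inter_spike_intervals(constant_train(20, 0.2))  # 1.0, 0.05, 0.05, ...
#' @export
inter_spike_intervals <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (!length(train$times)) return(numeric())
  c(1, diff(train$times))
}

#' Read spike times from a plain-text file
#'
#' One spike onset time (seconds) per line; blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path File path.
#' @param duration Optional stimulation epoch; defaults to the last spike time.
#' @return A [spike_train()].
#' @export
read_spike_times <- function(path, duration = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop(sprintf("cannot parse spike time on data line %d: '%s'", bad, lines[bad]),
         call. = FALSE)
  }
  spike_train(times, duration)
}

#' Write spike times to a plain-text file
#'
#' @param train A [spike_train()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  writeLines(c(sprintf("# spike times (s), duration %.17g s", train$duration),
               format(train$times, digits = 17, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
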