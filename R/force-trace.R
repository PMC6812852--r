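#' Simulation configuration
#'
#' Numerical settings shared by all simulators: the fixed sampling step
#' (default 0.0002 s, i.e. 5 kHz, the acquisition rate of the recordings the
#' models were built for), the neural conduction delay by which the stimulus
#' is shifted (default 10 ms), the relaxation time appended after the last
#' spike so the force decay is captured, and the solver for the
#' Hatze-family cascade (`"rk4"`: fixed-step fourth-order Runge-Kutta;
#' `"iterative"`: exact first-order-hold discretisation of each linear
#' second-order stage, precomputed per distinct potentiation value).
#'
#' @param dt Sampling step in seconds (> 0).
#' @param neural_delay Stimulus shift in seconds (>= 0).
#' @param relax_time Post-stimulus relaxation window in seconds (>= 0).
#' @param solver `"rk4"` or `"iterative"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.0002, neural_delay = 0.010, relax_time = 1,
                       solver = c("rk4", "iterative")) {
  solver <- match.arg(solver)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(neural_delay) || neural_delay < 0) {
    stop("neural_delay must be >= 0", call. = FALSE)
  }
  if (!is.finite(relax_time) || relax_time < 0) {
    stop("relax_time must be >= 0", call. = FALSE)
  }
  structure(list(dt = dt, neural_delay = neural_delay, relax_time = relax_time,
                 solver = solver), class = "sim_config")
}

new_force_trace <- function(time, force, dt, meta = list()) {
  out <- tibble::tibble(time = time, force = force)
  class(out) <- c("force_trace", class(out))
  attr(out, "dt") <- dt
  attr(out, "meta") <- meta
  out
}

#' Assemble a force trace from time and force samples
#'
#' Force traces are tibbles with columns `time` and `force` plus `dt` and
#' `meta` attributes. Simulators and the dataset reader produce them; this
#' constructor is for hand-built or externally measured traces.
#'
#' @param time,force Numeric vectors of equal length; `time` uniformly spaced.
#' @param meta Optional named list (stimulation frequency, neuron label,
#'   `stim_end`, normalisation, ...).
#' @return A `force_trace` tibble.
#' @export
force_trace <- function(time, force, meta = list()) {
  if (length(time) != length(force)) stop("time and force lengths differ", call. = FALSE)
  if (any(!is.finite(force))) stop("force values must be finite", call. = FALSE)
  dt <- if (length(time) > 1) stats::median(diff(time)) else NA_real_
  new_force_trace(as.numeric(time), as.numeric(force), dt, meta)
}

trace_dt <- function(trace) {
  dt <- attr(trace, "dt")
  if (is.null(dt) || is.na(dt)) dt <- stats::median(diff(trace$time))
  dt
}

trace_meta <- function(trace) {
  m <- attr(trace, "meta")
  if (is.null(m)) list() else m
}

#' @export
print.force_trace <- function(x, ...) {
  m <- trace_meta(x)
  hdr <- sprintf("<force_trace> %d samples, dt %.4g s, peak %.4g",
                 nrow(x), trace_dt(x), if (nrow(x)) max(x$force) else NA_real_)
  if (!is.null(m$model)) hdr <- paste0(hdr, ", model ", m$model)
  if (!is.null(m$freq)) hdr <- paste0(hdr, sprintf(", %g Hz", m$freq))
  cat(hdr, "\n")
  NextMethod()
}

# tiny polynomial rolling hash over a deparsed object; provenance tag for
# trace headers (not cryptographic)
params_hash <- function(x) {
  s <- paste(deparse(unclass(x)), collapse = "")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a force trace as two-column delimited text
#'
#' The header records the generating model, a parameter hash and the sampling
#' step, then `time_s` and `force` columns follow, tab-separated.
#'
#' @param trace A `force_trace`.
#' @param path File path.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  m <- trace_meta(trace)
  hdr <- c(
    sprintf("# model: %s", if (is.null(m$model)) "unknown" else m$model),
    sprintf("# params_hash: %s",
            if (is.null(m$params)) "none" else params_hash(m$params)),
    sprintf("# dt: %.17g", trace_dt(trace))
  )
  if (!is.null(m$freq)) hdr <- c(hdr, sprintf("# freq_hz: %g", m$freq))
  if (!is.null(m$stim_end)) hdr <- c(hdr, sprintf("# stim_end_s: %.17g", m$stim_end))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s\tforce"), con)
  write.table(data.frame(time_s = trace$time, force = trace$force), con,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_force_trace
#' @export
read_force_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!is_hdr]
  if (length(body) < 2) stop("malformed trace file: no data rows", call. = FALSE)
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("time_s", "force") %in% names(dat))) {
    stop("malformed trace file: expected columns time_s and force", call. = FALSE)
  }
  m <- list(model = meta[["model"]])
  if (!is.null(meta[["freq_hz"]])) m$freq <- as.numeric(meta[["freq_hz"]])
  if (!is.null(meta[["stim_end_s"]])) m$stim_end <- as.numeric(meta[["stim_end_s"]])
  dt <- if (!is.null(meta[["dt"]])) as.numeric(meta[["dt"]]) else NA_real_
  new_force_trace(dat$time_s, dat$force, dt, m)
}
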