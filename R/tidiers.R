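#' Tidy a fitted activation model
#'
#' @param x A [fit_result].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.fit_result <- function(x, ...) {
  vals <- unlist(unclass(x$params))
  vals <- vals[setdiff(names(vals), "tau_deact")]
  tibble::tibble(term = names(vals), estimate = unname(vals))
}

#' @rdname tidy.fit_result
#' @return For `glance`: a one-row tibble with the fit error and provenance.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(model = x$model, rmse = x$rmse, n_restarts = x$n_restarts,
                 best_restart_seed = x$best_restart_seed,
                 algorithm = x$algorithm, scale = x$scale,
                 under_determined = x$under_determined)
}

#' Tidy a potentiation fit
#'
#' @param x A `potentiation_fit`.
#' @param ... Unused.
#' @return One row per stimulation frequency: the inter-spike interval, the
#'   potentiation value from the per-frequency refit, and (when the curve has
#'   been fitted) the Michaelis-Menten-type prediction.
#' @export
tidy.potentiation_fit <- function(x, ...) {
  out <- tibble::tibble(freq_Hz = x$freqs, isi_s = 1 / x$freqs,
                        c = x$c_values)
  if (is.finite(x$K1)) {
    out$c_fitted <- potentiation_factor(out$isi_s, x$K1, x$K2)
  }
  out
}

#' @rdname tidy.potentiation_fit
#' @export
glance.potentiation_fit <- function(x, ...) {
  tibble::tibble(K1 = x$K1, K2 = x$K2,
                 curve_rmse = if (is.null(x$curve_rmse)) NA_real_ else x$curve_rmse,
                 n_freqs = length(x$freqs))
}

#' Plot a force trace
#'
#' @param object A `force_trace`.
#' @param ... Unused.
#' @return A ggplot of force against time; the stimulation window is shaded
#'   when the metadata records it.
#' @export
autoplot.force_trace <- function(object, ...) {
  m <- trace_meta(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (model units)",
                  title = if (!is.null(m$model)) m$model else NULL)
  if (!is.null(m$onset) && !is.null(m$stim_end) &&
      !is.na(m$onset) && !is.na(m$stim_end)) {
    p <- p + ggplot2::annotate("rect", xmin = m$onset, xmax = m$stim_end,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}

#' Plot a frequency-response curve
#'
#' @param object A `frequency_response` tibble.
#' @param ... Unused.
#' @return A ggplot of peak force against stimulation frequency.
#' @export
autoplot.frequency_response <- function(object, ...) {
  ycol <- if ("peak_norm" %in% names(object)) "peak_norm" else "peak"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_Hz, y = .data[[ycol]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulation frequency (Hz)",
                  y = if (ycol == "peak_norm") "peak force (norm.)" else "peak force",
                  title = attr(object, "model"))
}

#' Plot a potentiation fit
#'
#' @param object A `potentiation_fit`.
#' @param ... Unused.
#' @return A ggplot of the potentiation value against the inter-spike
#'   interval, with the fitted curve overlaid when available.
#' @export
autoplot.potentiation_fit <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$isi_s, y = .data$c)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "inter-spike interval (s)", y = "potentiation factor c")
  if (is.finite(object$K1)) {
    grid <- tibble::tibble(isi_s = exp(seq(log(min(dat$isi_s)),
                                           log(max(dat$isi_s)),
                                           length.out = 200)))
    grid$c <- potentiation_factor(grid$isi_s, object$K1, object$K2)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$isi_s, y = .data$c))
  }
  p
}

#' @importFrom rlang .data
NULL
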