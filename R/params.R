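#' Hatze-Zakotnik model parameters
#'
#' The calcium-cascade model is two coupled second-order stages: endplate
#' potential to T-tubular membrane potential (rate coefficients `theta1` in
#' 1/s and `theta2` in 1/s^2), then membrane potential to free calcium
#' concentration (`theta3` in 1/s, `theta4` in 1/s^2). `K1` and `K2` (s^2)
#' parameterise the Michaelis-Menten-type potentiation factor that rescales
#' `theta4` with the preceding inter-spike interval; `K1 >= K2 >= 0` is
#' required so the factor stays in `[0, 1]`.
#'
#' @param theta1,theta2,theta3,theta4 Non-negative stage coefficients.
#' @param K1,K2 Potentiation constants in s^2, `K1 >= K2 >= 0`. Default 0
#'   (no potentiation: the factor is identically 1).
#' @return An object of class `hatze_zakotnik_params`.
#' @export
hatze_zakotnik_params <- function(theta1, theta2, theta3, theta4, K1 = 0, K2 = 0) {
  v <- c(theta1 = theta1, theta2 = theta2, theta3 = theta3, theta4 = theta4,
         K1 = K1, K2 = K2)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all Hatze-Zakotnik parameters must be finite and >= 0", call. = FALSE)
  }
  if (K1 < K2) stop("K1 must be >= K2", call. = FALSE)
  structure(as.list(v), class = c("hatze_zakotnik_params", "muscle_params"))
}

#' Van Zandwijk sigmoid parameters
#'
#' The sigmoid maps calcium concentration to active state:
#' `q(gamma) = 1 / (1 + exp(A * (log(gamma) - log(gamma0))))`. `A` sets the
#' slope and `gamma0` the midpoint (in the units of the calcium state).
#'
#' @param A Dimensionless slope (finite).
#' @param gamma0 Midpoint, > 0.
#' @export
van_zandwijk_params <- function(A, gamma0) {
  if (!is.finite(A)) stop("A must be finite", call. = FALSE)
  if (!is.finite(gamma0) || gamma0 <= 0) stop("gamma0 must be > 0", call. = FALSE)
  structure(list(A = A, gamma0 = gamma0),
            class = c("van_zandwijk_params", "muscle_params"))
}

#' Non-linear Wilson model parameters
#'
#' First-order calcium kinetics with time constant `tau_c`, a Hill-type
#' saturation with half-saturation `k` and exponent `m`, and a force stage
#' with gain `A` and state-dependent time constant `tau1 + tau2 * x`.
#'
#' The force-stage time constant should stay positive over the whole
#' saturation range `x` in `[0, 1]`; parameter sets that violate this at high
#' saturation (possible for fitted sets with negative `tau2`) are accepted
#' with a warning, since the state may never reach the offending range.
#'
#' @param tau_c,tau1,tau2 Time constants in seconds (`tau_c > 0`, `tau1 > 0`).
#' @param k Half-saturation concentration (> 0).
#' @param A Force gain per second.
#' @param m Hill exponent (> 0).
#' @export
wilson_nl_params <- function(tau_c, tau1, tau2, k, A, m) {
  v <- c(tau_c = tau_c, tau1 = tau1, tau2 = tau2, k = k, A = A, m = m)
  if (any(!is.finite(v))) stop("all parameters must be finite", call. = FALSE)
  if (tau_c <= 0) stop("tau_c must be > 0", call. = FALSE)
  if (tau1 <= 0) stop("tau1 must be > 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (m <= 0) stop("m must be > 0", call. = FALSE)
  if (tau1 + min(0, tau2) <= 0) {
    warning(sprintf(paste0("force time constant tau1 + tau2*x becomes non-positive ",
                           "for saturation x >= %.3f; the model is only valid ",
                           "below that level"), tau1 / abs(tau2)), call. = FALSE)
  }
  structure(as.list(v), class = c("wilson_nl_params", "muscle_params"))
}

#' Zajac model parameters
#'
#' Linear first-order activation with activation time constant `tau_act` and
#' ratio `beta_ratio = tau_act / tau_deact` in (0, 1): build-up of activation
#' of a fully excited muscle is faster than relaxation.
#'
#' @param tau_act Activation time constant in seconds (> 0).
#' @param beta_ratio Ratio of activation to deactivation time constants,
#'   strictly between 0 and 1.
#' @export
zajac_params <- function(tau_act, beta_ratio) {
  if (!is.finite(tau_act) || tau_act <= 0) stop("tau_act must be > 0", call. = FALSE)
  if (!is.finite(beta_ratio) || beta_ratio <= 0 || beta_ratio >= 1) {
    stop("beta_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(tau_act = tau_act, beta_ratio = beta_ratio,
                 tau_deact = tau_act / beta_ratio),
            class = c("zajac_params", "muscle_params"))
}

#' Bluemel model parameters
#'
#' Single-pole recursive low-pass filter
#' `a[n] = (1 - filter) * scaling * u[n] + filter * a[n-1]`. The equivalent
#' continuous time constant at step `dt` is `-dt / log(filter)` (see
#' [blumel_time_constant()]).
#'
#' @param filter Per-step decay in (0, 1).
#' @param scaling Dimensionless gain (> 0).
#' @export
blumel_params <- function(filter, scaling) {
  if (!is.finite(filter) || filter <= 0 || filter >= 1) {
    stop("filter must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(scaling) || scaling <= 0) stop("scaling must be > 0", call. = FALSE)
  structure(list(filter = filter, scaling = scaling),
            class = c("blumel_params", "muscle_params"))
}

#' Time constant of the Bluemel filter
#'
#' @param filter Per-step decay in (0, 1).
#' @param dt Step duration in seconds.
#' @return The filter time constant `-dt / log(filter)` in seconds.
#' @export
blumel_time_constant <- function(filter, dt = 0.0002) -dt / log(filter)

#' Linear (third-order) Wilson model parameters
#'
#' `theta3 a''' + theta2 a'' + theta1 a' + a = theta0 u(t)`. The parameter set
#' is rejected unless the characteristic polynomial has all roots in the left
#' half plane, so the impulse response decays to zero.
#'
#' @param theta0 Input gain.
#' @param theta1,theta2,theta3 Coefficients with units s, s^2, s^3
#'   (`theta3 != 0`).
#' @export
wilson_linear_params <- function(theta0, theta1, theta2, theta3) {
  v <- c(theta0 = theta0, theta1 = theta1, theta2 = theta2, theta3 = theta3)
  if (any(!is.finite(v))) stop("all parameters must be finite", call. = FALSE)
  if (theta3 == 0) stop("theta3 must be non-zero", call. = FALSE)
  roots <- polyroot(c(1, theta1, theta2, theta3))
  if (any(Re(roots) >= 0)) {
    stop(sprintf("unstable parameter set: characteristic root(s) with Re >= 0 (%s)",
                 paste(sprintf("%.3g%+.3gi", Re(roots), Im(roots)), collapse = ", ")),
         call. = FALSE)
  }
  structure(as.list(v), class = c("wilson_linear_params", "muscle_params"))
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  vals <- unlist(x)
  cat(paste(sprintf("  %s = %g", names(vals), vals), collapse = "\n"), "\n")
  invisible(x)
}

model_names <- c("hatze_zakotnik", "hatze_van_zandwijk", "wilson_nl",
                 "zajac", "blumel", "wilson_linear")

params_class_for <- function(model) {
  switch(model,
    hatze_zakotnik = "hatze_zakotnik_params",
    hatze_van_zandwijk = "hatze_zakotnik_params",
    wilson_nl = "wilson_nl_params",
    zajac = "zajac_params",
    blumel = "blumel_params",
    wilson_linear = "wilson_linear_params",
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}

#' Published and default parameter sets
#'
#' Named parameter rows for the locust extensor tibiae fits (three SETi and
#' three FETi animals plus the published means, for both the Hatze-Zakotnik
#' and the non-linear Wilson model) and package-default sets for the three
#' linear models. The table as printed in the source typesets large
#' Hatze-stage coefficients with dot thousands separators; the default rows
#' use that reading (the only one that yields over-critically damped,
#' twitch-like dynamics), while the literal decimal reading of the ambiguous
#' mean row is kept as an explicitly flagged `_printed` variant.
#'
#' @param name Row name, e.g. `"zakotnik2006_mean_seti"` or
#'   `"seti_animal_A_wilson"`. Omit to get the full table.
#' @return With `name`: a parameter object with attributes `neuron` and
#'   `fit_error`. Without: a tibble listing all rows.
#' @export
published_params <- function(name = NULL) {
  path <- system.file("extdata", "published_params.csv", package = "imadyn")
  tab <- tibble::as_tibble(read.table(path, header = TRUE, sep = ",",
                                      stringsAsFactors = FALSE))
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (!nrow(row)) {
    stop(sprintf("unknown parameter set '%s'; see published_params() for the list",
                 name), call. = FALSE)
  }
  p <- switch(row$model,
    hatze_zakotnik = hatze_zakotnik_params(row$theta1, row$theta2, row$theta3,
                                           row$theta4, row$K1, row$K2),
    wilson_nl = wilson_nl_params(row$tau_c, row$tau1, row$tau2, row$k, row$A, row$m),
    zajac = zajac_params(row$tau_act, row$beta_ratio),
    blumel = blumel_params(row$filter, row$scaling),
    wilson_linear = wilson_linear_params(row$wl_theta0, row$wl_theta1,
                                         row$wl_theta2, row$wl_theta3),
    stop(sprintf("unknown model '%s' in parameter table", row$model), call. = FALSE)
  )
  attr(p, "neuron") <- row$neuron
  attr(p, "fit_error") <- row$fit_error
  attr(p, "name") <- name
  p
}

#' Serialise / load model parameters
#'
#' Parameters are stored as a small JSON object keyed by model name, so runs
#' are reproducible from files.
#'
#' @param params A `muscle_params` object.
#' @param path File path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "muscle_params"))
  model <- sub("_params$", "", class(params)[1])
  jsonlite::write_json(list(model = model, params = unclass(params)[setdiff(
    names(unclass(params)), "tau_deact")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$model) || is.null(obj$params)) {
    stop("malformed parameter file: needs fields 'model' and 'params'",
         call. = FALSE)
  }
  do.call(paste0(obj$model, "_params"), as.list(obj$params))
}
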