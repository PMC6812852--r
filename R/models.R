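#' Frequency-dependent twitch potentiation factor
#'
#' The Michaelis-Menten-type factor
#' `c(t) = t^2 / (K1 + t^2) - t^2 / (K2 + t^2) + 1`, evaluated at the
#' inter-spike interval `t` (seconds), rescales the calcium-stage coefficient
#' of the Hatze-Zakotnik model. With `K1 >= K2 >= 0` it is confined to
#' `[0, 1]` and converges to 1 as `t` grows (no potentiation for widely
#' separated spikes); its minimum sits at `t = (K1 * K2)^(1/4)`, i.e. shortly
#' before the twitch peak, where summation is strongest.
#'
#' @param t_isi Inter-spike interval(s) in seconds (> 0); vectorised.
#' @param K1,K2 Potentiation constants in s^2, `K1 >= K2 >= 0`.
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @examples
#' potentiation_factor(1, K1 = 1.46e-2, K2 = 3.9e-4)  # ~0.986
#' @export
potentiation_factor <- function(t_isi, K1, K2) {
  if (!is.finite(K1) || !is.finite(K2) || K2 < 0) {
    stop("K1 and K2 must be finite and >= 0", call. = FALSE)
  }
  if (K1 < K2) stop("K1 must be >= K2", call. = FALSE)
  if (any(!is.finite(t_isi)) || any(t_isi <= 0)) {
    stop("t_isi must be > 0", call. = FALSE)
  }
  t2 <- t_isi^2
  t2 / (K1 + t2) - t2 / (K2 + t2) + 1
}

# Shift the train by the neural delay and shape it onto the simulation grid.
# Returns the sampled excitation plus the shifted spike sample indices.
prepare_stimulus <- function(train, shape, config, extra_time = 0) {
  shifted <- spike_train(train$times + config$neural_delay,
                         train$duration + config$neural_delay)
  last <- if (length(shifted$times)) max(shifted$times) else shifted$duration
  total <- max(last + shape$width + config$relax_time + extra_time,
               shifted$duration)
  sig <- shape_stimulus(shifted, shape, dt = config$dt, total_time = total)
  list(signal = sig,
       spike_idx = round(shifted$times / config$dt) + 1L,
       onset = if (length(shifted$times)) shifted$times[1] else NA_real_,
       stim_end = if (length(shifted$times)) last else NA_real_)
}

# Per-sample potentiation factor: piecewise constant, updated at each spike
# from its preceding inter-spike interval; the first spike carries c = 1 by
# the single-twitch convention.
potentiation_series <- function(train, spike_idx, n, K1, K2) {
  cvec <- rep(1, n)
  k <- length(train$times)
  if (k >= 2 && (K1 > 0 || K2 > 0)) {
    isi <- diff(train$times)
    cs <- potentiation_factor(isi, K1, K2)
    for (i in 2:k) {
      i0 <- min(spike_idx[i], n)
      cvec[i0:n] <- cs[i - 1]
    }
  }
  cvec
}

# Exact first-order-hold discretisation of one stage x'' + a x' + b x = u:
# returns Ad (2x2), B0, B1 such that x[k+1] = Ad x[k] + B0 u[k] + B1 u[k+1].
discretise_stage2 <- function(a, b, dt) {
  A <- matrix(c(0, -b, 1, -a), 2, 2)
  B <- c(0, 1)
  Ad <- expm2(A * dt)
  Ai <- solve(A)
  G0 <- Ai %*% (Ad - diag(2)) %*% B
  J <- Ai %*% (dt * Ad) - Ai %*% Ai %*% (Ad - diag(2))
  W <- (J %*% B) / dt
  list(Ad = Ad, B0 = as.numeric(W), B1 = as.numeric(G0 - W))
}

# small dense matrix exponential by scaling-and-squaring with a Taylor series;
# accurate to machine precision for the well-conditioned 2x2 stages used here
expm2 <- function(M) {
  nrm <- max(abs(M))
  k <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  Ms <- M / 2^k
  E <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:20) {
    term <- term %*% Ms / i
    E <- E + term
    if (max(abs(term)) < 1e-18 * max(abs(E))) break
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}

# run one discretised second-order stage over the sampled input, with the
# coefficients (a, b) switching between segments (per-step index seg)
run_stage_foh <- function(u, as, bs, seg, dt) {
  if (length(as) == 1) as <- rep(as, length(bs))
  mats <- Map(function(a, b) discretise_stage2(a, b, dt), as, bs)
  Ad <- do.call(rbind, lapply(mats, function(m) as.numeric(m$Ad)))
  B0 <- do.call(rbind, lapply(mats, function(m) m$B0))
  B1 <- do.call(rbind, lapply(mats, function(m) m$B1))
  cpp_lti2_foh(u, seg, Ad, B0, B1)
}

hatze_gamma <- function(params, train, config, shape) {
  stim <- prepare_stimulus(train, shape, config)
  u <- stim$signal$value
  n <- length(u)
  cvec <- potentiation_series(train, stim$spike_idx, n, params$K1, params$K2)
  gamma <- if (config$solver == "rk4") {
    cpp_rk4_hatze(u, cvec,
                  c(params$theta1, params$theta2, params$theta3, params$theta4),
                  config$dt)
  } else {
    beta <- run_stage_foh(u, params$theta1, params$theta2,
                          integer(n - 1), config$dt)
    cs <- unique(cvec)
    seg <- match(cvec, cs)[-n] - 1L
    run_stage_foh(beta, params$theta3, cs * params$theta4, seg, config$dt)
  }
  list(gamma = gamma, time = stim$signal$time, stim = stim)
}

# Cascade simulation used by the per-frequency refitting stages: the
# calcium-stage coefficients switch to (theta3_eff, theta4_eff) from the
# second spike onward, while the first twitch of the train keeps the
# single-twitch coefficients -- the model's no-potentiation convention for
# the first spike. Solved by the exact-discretisation scheme, which is
# unconditionally stable for any trial coefficients.
hatze_refit_sim <- function(theta, train, config,
                            theta3_eff = theta[3], theta4_eff = theta[4],
                            shape = pulse_shape("half_sine",
                                                normalisation = "unit_peak")) {
  stim <- prepare_stimulus(train, shape, config)
  u <- stim$signal$value
  n <- length(u)
  beta <- run_stage_foh(u, theta[1], theta[2], integer(n - 1), config$dt)
  seg <- integer(n - 1)
  if (length(train$times) >= 2) {
    i2 <- min(stim$spike_idx[2], n)
    seg[i2:(n - 1)] <- 1L
  }
  gamma <- run_stage_foh(beta, c(theta[3], theta3_eff),
                         c(theta[4], theta4_eff), seg, config$dt)
  list(time = stim$signal$time, force = gamma)
}

#' Simulate the Hatze-Zakotnik model
#'
#' Two cascaded second-order stages transform the shaped endplate signal into
#' the calcium concentration that is read out as isometric force. The
#' calcium-stage coefficient `theta4` is rescaled by the potentiation factor
#' evaluated at each spike's preceding inter-spike interval
#' (piecewise-constant from that spike onward; the first spike carries
#' factor 1).
#'
#' @param params [hatze_zakotnik_params()].
#' @param train A [spike_train()].
#' @param config A [sim_config()]; `solver` selects fixed-step RK4 or the
#'   exact-discretisation iterative scheme.
#' @param shape Pulse shape for the endplate signal; the model convention is a
#'   unit-peak half-sine of 1 ms.
#' @return A `force_trace` tibble (force in model units, i.e. the calcium
#'   state; amplitude calibration is absorbed by the fitted coefficients).
#' @export
simulate_hatze_zakotnik <- function(params, train, config = sim_config(),
                                    shape = pulse_shape("half_sine",
                                                        normalisation = "unit_peak")) {
  stopifnot(inherits(params, "hatze_zakotnik_params"),
            inherits(train, "spike_train"), inherits(config, "sim_config"))
  r <- hatze_gamma(params, train, config, shape)
  new_force_trace(r$time, r$gamma, config$dt,
                  list(model = "hatze_zakotnik", params = params,
                       solver = config$solver, onset = r$stim$onset,
                       stim_end = r$stim$stim_end, delay = config$neural_delay))
}

#' Simulate the Hatze-van-Zandwijk model
#'
#' The same two-stage calcium cascade with a fixed `theta4` (no
#' frequency-dependent potentiation); the force-producing active state is the
#' sigmoid of the log calcium concentration,
#' `q = 1 / (1 + exp(A (log gamma - log gamma0)))`. The calcium state is
#' floored at 1e-12 before the log so the resting state is well defined.
#'
#' @param params [hatze_zakotnik_params()] (the `K` constants are ignored).
#' @param sigmoid [van_zandwijk_params()].
#' @inheritParams simulate_hatze_zakotnik
#' @return A `force_trace` with force `q` in (0, 1).
#' @export
simulate_hatze_van_zandwijk <- function(params, sigmoid, train,
                                        config = sim_config(),
                                        shape = pulse_shape("half_sine",
                                                            normalisation = "unit_peak")) {
  stopifnot(inherits(params, "hatze_zakotnik_params"),
            inherits(sigmoid, "van_zandwijk_params"))
  p0 <- hatze_zakotnik_params(params$theta1, params$theta2, params$theta3,
                              params$theta4, 0, 0)
  r <- hatze_gamma(p0, train, config, shape)
  g <- pmax(r$gamma, 1e-12)
  q <- 1 / (1 + exp(sigmoid$A * (log(g) - log(sigmoid$gamma0))))
  new_force_trace(r$time, q, config$dt,
                  list(model = "hatze_van_zandwijk", params = params,
                       sigmoid = sigmoid, solver = config$solver,
                       onset = r$stim$onset, stim_end = r$stim$stim_end,
                       delay = config$neural_delay))
}

#' Simulate the non-linear Wilson model
#'
#' First-order calcium kinetics driven by the impulse-approximated spike train
#' (unit-area pulses), a Hill-type saturation, and a force stage whose time
#' constant depends on the saturation level. Solved by fixed-step RK4.
#'
#' @param params [wilson_nl_params()].
#' @inheritParams simulate_hatze_zakotnik
#' @param shape Pulse shape; the model convention is a width-1 ms pulse scaled
#'   to unit area (impulse approximation).
#' @export
simulate_wilson_nl <- function(params, train, config = sim_config(),
                               shape = pulse_shape("half_sine",
                                                   normalisation = "unit_area")) {
  stopifnot(inherits(params, "wilson_nl_params"),
            inherits(train, "spike_train"), inherits(config, "sim_config"))
  stim <- prepare_stimulus(train, shape, config)
  f <- cpp_rk4_wilson_nl(stim$signal$value, params$tau_c, params$tau1,
                         params$tau2, params$k, params$A, params$m, config$dt)
  new_force_trace(stim$signal$time, f, config$dt,
                  list(model = "wilson_nl", params = params,
                       onset = stim$onset, stim_end = stim$stim_end,
                       delay = config$neural_delay))
}

# accept either a sampled excitation or a spike train (shaped to unit peak so
# the excitation stays in [0, 1], as the first-order models expect)
as_excitation <- function(excitation, config,
                          shape = pulse_shape("half_sine",
                                              normalisation = "unit_peak")) {
  if (inherits(excitation, "spike_train")) {
    stim <- prepare_stimulus(excitation, shape, config)
    list(signal = stim$signal, onset = stim$onset, stim_end = stim$stim_end)
  } else if (inherits(excitation, "muscle_signal") || is.data.frame(excitation)) {
    if (!all(c("time", "value") %in% names(excitation))) {
      stop("excitation must have columns 'time' and 'value'", call. = FALSE)
    }
    list(signal = excitation, onset = NA_real_, stim_end = NA_real_)
  } else {
    stop("excitation must be a spike_train or a sampled signal", call. = FALSE)
  }
}

#' Simulate the Zajac model
#'
#' Linear first-order activation `da/dt + [(beta + (1-beta) u) / tau_act] a =
#' u / tau_act` with excitation `u` in `[0, 1]`: full excitation activates
#' with time constant `tau_act`, relaxation runs with `tau_deact =
#' tau_act / beta`. Advanced by an exact per-step integrating-factor update,
#' which is unconditionally stable.
#'
#' @param params [zajac_params()].
#' @param excitation A `muscle_signal` with values in `[0, 1]`, or a
#'   [spike_train()] (shaped to unit-peak pulses).
#' @param config A [sim_config()].
#' @export
simulate_zajac <- function(params, excitation, config = sim_config()) {
  stopifnot(inherits(params, "zajac_params"), inherits(config, "sim_config"))
  ex <- as_excitation(excitation, config)
  u <- ex$signal$value
  if (any(u < 0 | u > 1 + 1e-9)) {
    stop("Zajac excitation u(t) must lie in [0, 1]", call. = FALSE)
  }
  dt <- signal_dt(ex$signal)
  a <- cpp_zajac(u, params$tau_act, params$beta_ratio, dt)
  new_force_trace(ex$signal$time, a, dt,
                  list(model = "zajac", params = params, onset = ex$onset,
                       stim_end = ex$stim_end, delay = config$neural_delay))
}

#' Simulate the Bluemel model
#'
#' Single-pole recursive low-pass filter of the excitation,
#' `a[n] = (1 - filter) * scaling * u[n] + filter * a[n-1]`, evaluated at the
#' signal's own sampling step. For constant excitation the fixed point is
#' `scaling * u`.
#'
#' @param params [blumel_params()].
#' @inheritParams simulate_zajac
#' @export
simulate_blumel <- function(params, excitation, config = sim_config()) {
  stopifnot(inherits(params, "blumel_params"), inherits(config, "sim_config"))
  ex <- as_excitation(excitation, config)
  dt <- signal_dt(ex$signal)
  a <- cpp_blumel(ex$signal$value, params$filter, params$scaling)
  new_force_trace(ex$signal$time, a, dt,
                  list(model = "blumel", params = params, onset = ex$onset,
                       stim_end = ex$stim_end, delay = config$neural_delay))
}

#' Simulate the linear (third-order) Wilson model
#'
#' Solves `theta3 a''' + theta2 a'' + theta1 a' + a = theta0 u(t)` as a
#' companion system of three first-order equations with fixed-step RK4. The
#' model is linear, so responses to spike trains superpose exactly.
#'
#' @param params [wilson_linear_params()].
#' @inheritParams simulate_wilson_nl
#' @export
simulate_wilson_linear <- function(params, train, config = sim_config(),
                                   shape = pulse_shape("half_sine",
                                                       normalisation = "unit_area")) {
  stopifnot(inherits(params, "wilson_linear_params"),
            inherits(train, "spike_train"), inherits(config, "sim_config"))
  stim <- prepare_stimulus(train, shape, config)
  a <- cpp_rk4_linear3(stim$signal$value, params$theta0, params$theta1,
                       params$theta2, params$theta3, config$dt)
  new_force_trace(stim$signal$time, a, config$dt,
                  list(model = "wilson_linear", params = params,
                       onset = stim$onset, stim_end = stim$stim_end,
                       delay = config$neural_delay))
}

#' Simulate any activation model by name
#'
#' Dispatcher used by the frequency-response machinery, the dataset generator
#' and the command line: `model` is one of `"hatze_zakotnik"`,
#' `"hatze_van_zandwijk"`, `"wilson_nl"`, `"zajac"`, `"blumel"`,
#' `"wilson_linear"`.
#'
#' @param model Model name.
#' @param params The matching parameter object (for
#'   `"hatze_van_zandwijk"`, a list with elements `params` and `sigmoid` or a
#'   `hatze_zakotnik_params` plus `sigmoid` argument in `...`).
#' @param train A [spike_train()] (used as excitation for the first-order
#'   models, shaped to unit-peak pulses).
#' @param config A [sim_config()].
#' @param ... Passed through to the model simulator.
#' @export
simulate_muscle <- function(model, params, train, config = sim_config(), ...) {
  if (!model %in% model_names) {
    stop(sprintf("unknown model '%s' (expected one of %s)", model,
                 paste(model_names, collapse = ", ")), call. = FALSE)
  }
  switch(model,
    hatze_zakotnik = simulate_hatze_zakotnik(params, train, config, ...),
    hatze_van_zandwijk = simulate_hatze_van_zandwijk(params, train = train,
                                                     config = config, ...),
    wilson_nl = simulate_wilson_nl(params, train, config, ...),
    zajac = simulate_zajac(params, train, config),
    blumel = simulate_blumel(params, train, config),
    wilson_linear = simulate_wilson_linear(params, train, config, ...)
  )
}
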