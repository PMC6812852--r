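#' @title Fitted-model containers
#' @description Least-squares fits return a `fit_result`: the model name, the
#'   optimised parameter object, the root-mean-square error, restart
#'   provenance (number of restarts, the seed of the winning restart, the
#'   algorithm that won) and an under-determination flag raised when restarts
#'   that reach the same error disagree materially in parameter values.
#' @name fit_result
NULL

new_fit_result <- function(model, params, rmse, n_restarts, best_restart_seed,
                           algorithm, scale = NA_real_,
                           under_determined = FALSE, notes = character()) {
  structure(list(model = model, params = params, rmse = rmse,
                 n_restarts = n_restarts, best_restart_seed = best_restart_seed,
                 algorithm = algorithm, scale = scale,
                 under_determined = under_determined, notes = notes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s, rmse %.4g, %d restart(s), algorithm %s%s\n",
              x$model, x$rmse, x$n_restarts, x$algorithm,
              if (x$under_determined) " [under-determined]" else ""))
  print(x$params)
  invisible(x)
}

fit_algorithms <- c("levenberg_marquardt", "trust_region")

# one bounded least-squares run; `resid_fn` returns the residual vector
run_ls <- function(par0, lower, upper, resid_fn, algorithm) {
  if (algorithm == "levenberg_marquardt") {
    fit <- minpack.lm::nls.lm(
      par0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                           ptol = 1e-10))
    list(par = fit$par, ssr = sum(resid_fn(fit$par)^2),
         converged = fit$info %in% 1:4)
  } else {
    fit <- stats::nlminb(par0, function(p) sum(resid_fn(p)^2),
                         lower = lower, upper = upper,
                         control = list(iter.max = 100, eval.max = 300))
    list(par = fit$par, ssr = fit$objective, converged = fit$convergence == 0)
  }
}

# multi-restart driver: draw_fn(seed) gives a start; returns best candidate
# plus a dispersion-based under-determination flag
multi_restart <- function(n_restarts, seed, draw_fn, lower, upper, resid_fn,
                          algorithm) {
  algos <- if (algorithm == "both") fit_algorithms else algorithm
  restart_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                              n_restarts))
  cands <- list()
  for (i in seq_len(n_restarts)) {
    par0 <- draw_fn(restart_seeds[i])
    for (alg in algos) {
      res <- tryCatch(run_ls(par0, lower, upper, resid_fn, alg),
                      error = function(e) NULL)
      if (!is.null(res) && all(is.finite(res$par)) && is.finite(res$ssr)) {
        res$seed <- restart_seeds[i]
        res$algorithm <- alg
        cands[[length(cands) + 1]] <- res
      }
    }
  }
  if (!length(cands)) stop("fit failed: no restart converged", call. = FALSE)
  ssrs <- vapply(cands, `[[`, numeric(1), "ssr")
  best <- cands[[which.min(ssrs)]]
  # polish the winner: restart the search from its solution so an
  # iteration-capped run finishes converging
  pol <- tryCatch(run_ls(best$par, lower, upper, resid_fn, best$algorithm),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$ssr) && pol$ssr < best$ssr) {
    best$par <- pol$par
    best$ssr <- pol$ssr
    cands[[which.min(ssrs)]] <- modifyList(cands[[which.min(ssrs)]],
                                           pol[c("par", "ssr")])
    ssrs[which.min(ssrs)] <- pol$ssr
  }
  near <- cands[ssrs <= min(ssrs) * 1.01 + 1e-14]
  spread <- 0
  if (length(near) > 1) {
    pmat <- do.call(rbind, lapply(near, `[[`, "par"))
    rel <- apply(pmat, 2, function(col) {
      (max(col) - min(col)) / max(abs(best$par), 1e-12)
    })
    spread <- max(rel)
  }
  best$under_determined <- spread > 0.1
  best
}

# --- staged Hatze-Zakotnik workflow ---------------------------------------

# simulate the Hatze cascade on the grid of a measured trace. When
# theta4_eff (and optionally theta3_eff) are given, the refit convention
# applies: the modified calcium-stage coefficients act from the second spike
# onward while the first twitch keeps the single-twitch values.
hatze_on_grid <- function(theta, trace, config, freq = NULL,
                          theta4_eff = NULL, theta3_eff = NULL) {
  m <- trace_meta(trace)
  if (is.null(freq)) freq <- m$freq
  stim_dur <- if (!is.null(m$stim_duration)) m$stim_duration else max(trace$time)
  if (is.null(freq)) stop("trace metadata lacks the stimulation frequency",
                          call. = FALSE)
  train <- constant_train(freq, stim_dur)
  relax <- max(0, max(trace$time) -
                 (max(train$times) + config$neural_delay) + config$dt)
  cfg <- sim_config(config$dt, config$neural_delay, relax, config$solver)
  if (is.null(theta4_eff) && is.null(theta3_eff)) {
    p <- hatze_zakotnik_params(theta[1], theta[2], theta[3], theta[4], 0, 0)
    sim <- simulate_hatze_zakotnik(p, train, cfg)
  } else {
    sim <- hatze_refit_sim(theta, train, cfg,
                           theta3_eff = if (is.null(theta3_eff)) theta[3] else theta3_eff,
                           theta4_eff = if (is.null(theta4_eff)) theta[4] else theta4_eff)
  }
  approx(sim$time, sim$force, xout = trace$time, rule = 2)$y
}

# pole with the largest real part (slowest decay) of s^2 + a s + b
slow_pole <- function(a, b) max(Re(polyroot(c(b, a, 1))))

# the two quadratic factors of the cascade commute; fix the labelling so the
# potentiation-carrying stage (theta3, theta4) is the slower one
canonicalise_hatze <- function(theta) {
  if (slow_pole(theta[1], theta[2]) > slow_pole(theta[3], theta[4])) {
    theta <- theta[c(3, 4, 1, 2)]
  }
  theta
}

default_hatze_bounds <- function() {
  # brackets around the range of the per-animal estimates, wide enough to
  # cover both motoneurons without entering degenerate regimes
  list(lower = c(theta1 = 10, theta2 = 300, theta3 = 500, theta4 = 5000),
       upper = c(theta1 = 300, theta2 = 20000, theta3 = 30000, theta4 = 500000))
}

#' Fit the Hatze twitch parameters to a single-twitch response
#'
#' Stage one of the staged workflow: the four cascade coefficients are
#' optimised to the single twitch only (the potentiation factor is 1 there by
#' convention, so the two potentiation constants play no role). The fit runs
#' from multiple random restarts, log-uniform within physiological brackets,
#' and keeps the best. An overall amplitude scale is profiled out analytically
#' at each evaluation, since the measured traces are normalised to the
#' per-animal maximum while the cascade output is in calcium-state units. The
#' two quadratic factors of the cascade commute, so fitted coefficients are
#' canonicalised with the potentiation-carrying stage as the slower factor;
#' parameter recovery is therefore meaningful at the level of the impulse
#' response.
#'
#' @param twitch A `force_trace` of a single-spike response (metadata `freq`
#'   1, or absent).
#' @param config A [sim_config()].
#' @param n_restarts Number of random restarts (default 10 for the staged twitch stage; the simultaneous Wilson fit uses 7).
#' @param seed Master seed; restart seeds derive from it.
#' @param algorithm `"levenberg_marquardt"`, `"trust_region"` (bounded
#'   trust-region quasi-Newton), or `"both"` to run both per restart and keep
#'   the better, as when both optimisers are applied to the same data set.
#' @param bounds List with `lower`/`upper` named vectors for theta1..theta4.
#' @return A [fit_result] whose `params` is [hatze_zakotnik_params()] (K1 =
#'   K2 = 0) and whose `scale` is the fitted amplitude factor.
#' @export
fit_hatze_single_twitch <- function(twitch, config = sim_config(),
                                    n_restarts = 10, seed = 1,
                                    algorithm = c("both", fit_algorithms),
                                    bounds = default_hatze_bounds()) {
  stopifnot(inherits(twitch, "force_trace"))
  algorithm <- match.arg(algorithm)
  if (max(twitch$force) <= 0 || sd(twitch$force) == 0) {
    stop("twitch trace is flat or empty; nothing to fit", call. = FALSE)
  }
  m <- trace_meta(twitch)
  if (!is.null(m$freq) && m$freq > 1) {
    stop("expected a single-twitch trace (stimulation frequency 1)", call. = FALSE)
  }
  y <- twitch$force
  scale_env <- new.env()
  resid_fn <- function(lpar) {
    th <- exp(lpar)
    mod <- tryCatch(hatze_on_grid(th, twitch, config, freq = 1),
                    error = function(e) NULL)
    if (is.null(mod) || !all(is.finite(mod)) || all(mod == 0)) {
      return(rep(1e3, length(y)))
    }
    s <- sum(y * mod) / sum(mod * mod)
    if (!is.finite(s) || s <= 0) return(rep(1e3, length(y)))
    scale_env$s <- s
    y - s * mod
  }
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  draw_fn <- function(s) with_seed(s, runif(4, lo, hi))
  best <- multi_restart(n_restarts, seed, draw_fn, lo, hi, resid_fn, algorithm)
  resid_fn(best$par) # refresh the profiled scale for the winning parameters
  th <- canonicalise_hatze(exp(best$par))
  new_fit_result(
    model = "hatze_zakotnik",
    params = hatze_zakotnik_params(th[1], th[2], th[3], th[4], 0, 0),
    rmse = sqrt(best$ssr / length(y)),
    n_restarts = n_restarts, best_restart_seed = best$seed,
    algorithm = best$algorithm, scale = scale_env$s,
    under_determined = best$under_determined)
}

as_trace_list <- function(traces) {
  if (inherits(traces, "muscle_dataset")) return(traces$traces)
  if (inherits(traces, "force_trace")) return(list(traces))
  stopifnot(is.list(traces))
  traces
}

trace_freq <- function(trace) {
  f <- trace_meta(trace)$freq
  if (is.null(f)) stop("trace metadata lacks the stimulation frequency", call. = FALSE)
  f
}

#' Per-frequency potentiation values by refitting theta4
#'
#' Stage two of the staged workflow: with theta1..theta3 (and the amplitude
#' scale) frozen from the single-twitch fit, theta4 is re-optimised
#' independently for each stimulation frequency, and the potentiation value is
#' the ratio `c(f) = theta4(f) / theta4(twitch)`. The single-twitch entry is 1
#' by construction. The refitted coefficient takes effect from the second
#' spike of the train onward; the first twitch always keeps the single-twitch
#' coefficients, as the no-potentiation convention for a first spike
#' prescribes.
#'
#' @param traces List of per-frequency `force_trace`s (or a `muscle_dataset`);
#'   each trace's metadata must carry `freq`.
#' @param base The [fit_result] of [fit_hatze_single_twitch()] (or a
#'   `hatze_zakotnik_params` plus `scale`).
#' @param config A [sim_config()].
#' @param scale Amplitude scale when `base` is a bare parameter object.
#' @return An object of class `potentiation_fit` with per-frequency `c`
#'   values, refit errors, and (after [fit_potentiation_curve()]) the
#'   potentiation constants.
#' @export
fit_theta4_per_frequency <- function(traces, base, config = sim_config(),
                                     scale = NULL) {
  traces <- as_trace_list(traces)
  if (inherits(base, "fit_result")) {
    scale <- base$scale
    base <- base$params
  }
  stopifnot(inherits(base, "hatze_zakotnik_params"))
  if (is.null(scale) || !is.finite(scale)) {
    stop("an amplitude scale from the single-twitch fit is required", call. = FALSE)
  }
  freqs <- vapply(traces, trace_freq, numeric(1))
  if (!any(freqs <= 1)) {
    stop("a single-twitch trace (frequency 1) is required in the trace set",
         call. = FALSE)
  }
  th <- c(base$theta1, base$theta2, base$theta3, base$theta4)
  ord <- order(freqs)
  traces <- traces[ord]; freqs <- freqs[ord]
  th4 <- numeric(length(freqs)); errs <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    tr <- traces[[i]]
    if (freqs[i] <= 1) {
      th4[i] <- th[4]
      errs[i] <- sqrt(mean((tr$force - scale *
                              hatze_on_grid(th, tr, config, freqs[i]))^2))
      next
    }
    obj <- function(t4) {
      mod <- hatze_on_grid(th, tr, config, freqs[i], theta4_eff = t4)
      sqrt(mean((tr$force - scale * mod)^2))
    }
    opt <- optimize(obj, lower = 0.02 * th[4], upper = 2 * th[4],
                    tol = th[4] * 1e-6)
    th4[i] <- opt$minimum
    errs[i] <- opt$objective
  }
  structure(list(freqs = freqs, c_values = th4 / th[4], theta4_values = th4,
                 theta4_twitch = th[4], rmse_per_freq = errs,
                 base = base, scale = scale,
                 K1 = NA_real_, K2 = NA_real_, weights = NULL),
            class = "potentiation_fit")
}

#' @export
print.potentiation_fit <- function(x, ...) {
  cat(sprintf("<potentiation_fit> %d frequencies; K1 = %.4g, K2 = %.4g\n",
              length(x$freqs), x$K1, x$K2))
  print(tibble::tibble(freq_Hz = x$freqs, c = x$c_values))
  invisible(x)
}

#' Fit the Michaelis-Menten-type potentiation curve
#'
#' Stage three: the per-frequency potentiation values are fitted as a function
#' of the inter-spike interval `t = 1/f` with the bi-sigmoid difference form
#' `c(t) = t^2/(K1 + t^2) - t^2/(K2 + t^2) + 1`, by weighted least squares
#' with weights proportional to the stimulus frequency (improving the fit at
#' short intervals), under the constraint `K1 >= K2 >= 0`.
#'
#' @param fit A `potentiation_fit` from [fit_theta4_per_frequency()], or a
#'   numeric vector of `c` values (then `freqs` must be given).
#' @param freqs Stimulation frequencies in Hz (>= 3 distinct values,
#'   including the single twitch).
#' @param weights Per-point weights; default proportional to frequency.
#' @return The `potentiation_fit` with `K1`, `K2`, `weights` and `curve_rmse`
#'   filled in.
#' @export
fit_potentiation_curve <- function(fit, freqs = NULL, weights = NULL) {
  if (inherits(fit, "potentiation_fit")) {
    cvals <- fit$c_values
    freqs <- fit$freqs
  } else {
    cvals <- as.numeric(fit)
    if (is.null(freqs)) stop("freqs must be supplied", call. = FALSE)
    fit <- structure(list(freqs = freqs, c_values = cvals),
                     class = "potentiation_fit")
  }
  if (length(unique(freqs)) < 3 || !any(freqs <= 1)) {
    stop("need >= 3 distinct frequencies including the single twitch",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- freqs
  w <- sqrt(weights / mean(weights))
  tt <- 1 / freqs
  # K2 = exp(p2), K1 = K2 + exp(p1): the constraint K1 >= K2 >= 0 always holds
  resid_fn <- function(p) {
    K2 <- exp(p[2]); K1 <- K2 + exp(p[1])
    w * (cvals - potentiation_factor(tt, K1, K2))
  }
  starts <- expand.grid(p1 = log(c(1e-3, 1e-2, 1e-1)),
                        p2 = log(c(1e-5, 1e-4, 1e-3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      run_ls(as.numeric(starts[i, ]), lower = rep(log(1e-12), 2),
             upper = rep(log(10), 2), resid_fn, "levenberg_marquardt"),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$ssr < best$ssr)) best <- res
  }
  if (is.null(best)) stop("potentiation-curve fit failed", call. = FALSE)
  K2 <- exp(best$par[2]); K1 <- K2 + exp(best$par[1])
  fit$K1 <- K1; fit$K2 <- K2
  fit$weights <- weights
  fit$curve_rmse <- sqrt(best$ssr / length(cvals))
  if (length(freqs) < 5) {
    fit$notes <- c(fit$notes,
                   "few frequency points: the fitted curve may deviate at individual frequencies")
  }
  fit
}

#' Full staged Hatze-Zakotnik fit
#'
#' Runs the three stages in sequence — single-twitch fit of theta1..theta4,
#' per-frequency re-optimisation of theta4, and the weighted potentiation
#' curve fit of K1 and K2 — and reports the assembled six-parameter model with
#' its overall error across all traces (simulated with the inter-spike
#' interval driven potentiation).
#'
#' @inheritParams fit_theta4_per_frequency
#' @inheritParams fit_hatze_single_twitch
#' @return A [fit_result] with the full parameter set; the staged
#'   intermediate objects are attached as `stages`.
#' @export
fit_hatze_staged <- function(traces, config = sim_config(), n_restarts = 10,
                             seed = 1, algorithm = "both") {
  traces <- as_trace_list(traces)
  freqs <- vapply(traces, trace_freq, numeric(1))
  itw <- which(freqs <= 1)
  if (!length(itw)) {
    stop("staged workflow requires a single-twitch trace (frequency 1)",
         call. = FALSE)
  }
  tw_fit <- fit_hatze_single_twitch(traces[[itw[1]]], config, n_restarts,
                                    seed, algorithm)
  pot <- fit_theta4_per_frequency(traces, tw_fit, config)
  pot <- fit_potentiation_curve(pot)
  p <- tw_fit$params
  full <- hatze_zakotnik_params(p$theta1, p$theta2, p$theta3, p$theta4,
                                pot$K1, pot$K2)
  errs <- vapply(traces, function(tr) {
    m <- trace_meta(tr)
    stim_dur <- if (!is.null(m$stim_duration)) m$stim_duration else max(tr$time)
    train <- constant_train(trace_freq(tr), stim_dur)
    relax <- max(0, max(tr$time) -
                   (max(train$times) + config$neural_delay) + config$dt)
    cfg <- sim_config(config$dt, config$neural_delay, relax, config$solver)
    sim <- simulate_hatze_zakotnik(full, train, cfg)
    mod <- approx(sim$time, sim$force, xout = tr$time, rule = 2)$y
    mean((tr$force - tw_fit$scale * mod)^2)
  }, numeric(1))
  out <- new_fit_result("hatze_zakotnik", full, sqrt(mean(errs)),
                        n_restarts, tw_fit$best_restart_seed,
                        tw_fit$algorithm, scale = tw_fit$scale,
                        under_determined = tw_fit$under_determined)
  out$stages <- list(twitch = tw_fit, potentiation = pot)
  out
}

# --- simultaneous non-linear Wilson fit -----------------------------------

default_wilson_bounds <- function() {
  list(lower = c(tau_c = 0.005, tau1 = 0.002, tau2 = -0.4, k = 0.05,
                 A = 0.5, m = 0.5),
       upper = c(tau_c = 0.6, tau1 = 0.6, tau2 = 0.4, k = 20, A = 500, m = 5))
}

# precompute the shaped unit-area excitation of a fitting trace once, so the
# residual function only runs the compiled kernel and an index lookup
wilson_fit_input <- function(trace, config) {
  m <- trace_meta(trace)
  stim_dur <- if (!is.null(m$stim_duration)) m$stim_duration else max(trace$time)
  train <- constant_train(trace_freq(trace), stim_dur)
  relax <- max(0, max(trace$time) -
                 (max(train$times) + config$neural_delay) + config$dt)
  cfg <- sim_config(config$dt, config$neural_delay, relax, "rk4")
  stim <- prepare_stimulus(train, pulse_shape("half_sine",
                                              normalisation = "unit_area"), cfg)
  grid_match <- nrow(trace) <= length(stim$signal$value) &&
    abs(trace_dt(trace) - cfg$dt) < 1e-12 && abs(trace$time[1]) < 1e-12
  list(u = stim$signal$value, time = stim$signal$time, y = trace$force,
       xout = trace$time, grid_match = grid_match, n = nrow(trace), dt = cfg$dt)
}

wilson_eval <- function(par, inp) {
  f <- cpp_rk4_wilson_nl(inp$u, par[1], par[2], par[3], par[4], par[5], par[6],
                         inp$dt)
  if (inp$grid_match) f[seq_len(inp$n)] else approx(inp$time, f, xout = inp$xout,
                                                    rule = 2)$y
}

#' Simultaneous least-squares fit of the non-linear Wilson model
#'
#' All six parameters are optimised at once against the concatenated residuals
#' of every supplied trace (single twitch and all stimulation frequencies,
#' with equal per-sample weight), from repeated random initialisations —
#' seven by default — keeping the best fit and recording which restart and
#' algorithm produced it.
#'
#' @param traces List of per-frequency `force_trace`s or a `muscle_dataset`
#'   (>= 2 traces for a determinate fit; a single trace is accepted but the
#'   result is checked for under-determination via restart dispersion).
#' @inheritParams fit_hatze_single_twitch
#' @param bounds List with `lower`/`upper` for (tau_c, tau1, tau2, k, A, m).
#' @return A [fit_result] with [wilson_nl_params()].
#' @export
fit_wilson_nl <- function(traces, config = sim_config(), n_restarts = 7,
                          seed = 1, algorithm = c("both", fit_algorithms),
                          bounds = default_wilson_bounds()) {
  algorithm <- match.arg(algorithm)
  traces <- as_trace_list(traces)
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  inputs <- lapply(traces, wilson_fit_input, config = config)
  y <- unlist(lapply(traces, function(tr) tr$force))
  resid_fn <- function(par) {
    if (par[2] + min(0, par[3]) <= 1e-4) return(rep(1e3, length(y)))
    mod <- tryCatch(
      unlist(lapply(inputs, function(inp) wilson_eval(par, inp))),
      error = function(e) NULL)
    if (is.null(mod) || !all(is.finite(mod))) return(rep(1e3, length(y)))
    y - mod
  }
  lo <- bounds$lower; hi <- bounds$upper
  draw_fn <- function(s) with_seed(s, {
    p <- numeric(6)
    pos <- c(1, 2, 4, 5, 6)
    p[pos] <- exp(runif(5, log(pmax(lo[pos], 1e-4)), log(hi[pos])))
    p[3] <- runif(1, max(lo[3], -p[2] + 1e-3), hi[3])
    p
  })
  best <- multi_restart(n_restarts, seed, draw_fn, lo, hi, resid_fn, algorithm)
  par <- best$par
  out <- new_fit_result(
    model = "wilson_nl",
    params = suppressWarnings(wilson_nl_params(par[1], par[2], par[3], par[4],
                                               par[5], par[6])),
    rmse = sqrt(best$ssr / length(y)),
    n_restarts = n_restarts, best_restart_seed = best$seed,
    algorithm = best$algorithm,
    under_determined = best$under_determined || length(traces) < 2)
  if (length(traces) < 2) {
    out$notes <- "fewer than two traces: six parameters are not well constrained"
  }
  out
}

# --- Hatze-van-Zandwijk sigmoid fit ---------------------------------------

#' Fit the van Zandwijk sigmoid on top of fixed twitch coefficients
#'
#' With the four cascade coefficients frozen (from the single-twitch fit), the
#' two sigmoid parameters `A` and `gamma0` mapping calcium concentration to
#' active state are optimised across the traces of all stimulation
#' frequencies simultaneously. A warning note is attached when the fitted
#' midpoint lies outside the range of calcium values the simulations actually
#' visit (the sigmoid then operates on its tail).
#'
#' @param traces List of per-frequency `force_trace`s or a `muscle_dataset`.
#' @param base [fit_result] of the single-twitch stage, or bare
#'   [hatze_zakotnik_params()].
#' @param config A [sim_config()].
#' @return A [fit_result] whose `params` is [van_zandwijk_params()].
#' @export
fit_van_zandwijk <- function(traces, base, config = sim_config()) {
  traces <- as_trace_list(traces)
  if (inherits(base, "fit_result")) base <- base$params
  stopifnot(inherits(base, "hatze_zakotnik_params"))
  th <- c(base$theta1, base$theta2, base$theta3, base$theta4)
  gammas <- lapply(traces, function(tr) {
    pmax(hatze_on_grid(th, tr, config), 1e-12)
  })
  y <- unlist(lapply(traces, function(tr) tr$force))
  g <- unlist(gammas)
  lg <- log(g)
  resid_fn <- function(p) {
    q <- 1 / (1 + exp(p[1] * (lg - p[2])))
    y - q
  }
  grange <- range(lg[g > 1e-12])
  starts <- expand.grid(A = c(-0.5, -2, -8),
                        lg0 = seq(grange[1], grange[2], length.out = 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      run_ls(as.numeric(starts[i, ]), lower = c(-100, grange[1] - 20),
             upper = c(100, grange[2] + 20), resid_fn, "levenberg_marquardt"),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$ssr < best$ssr)) best <- res
  }
  if (is.null(best)) stop("sigmoid fit failed", call. = FALSE)
  params <- van_zandwijk_params(best$par[1], exp(best$par[2]))
  out <- new_fit_result("hatze_van_zandwijk", params,
                        sqrt(best$ssr / length(y)), nrow(starts), NA_integer_,
                        "levenberg_marquardt")
  if (best$par[2] < grange[1] || best$par[2] > grange[2]) {
    out$notes <- "fitted gamma0 lies outside the observed calcium range; sigmoid operates on its tail"
  }
  out$base <- base
  out
}

# --- optional joint theta3/theta4 refinement ------------------------------

#' Per-frequency joint refit of theta3 and theta4
#'
#' Like [fit_theta4_per_frequency()] but with the decay-shaping coefficient
#' theta3 also free per frequency: a nested extension of the staged workflow,
#' so its per-frequency error can never exceed the theta4-only refit on the
#' same data. May or may not improve the assembled model.
#'
#' @inheritParams fit_theta4_per_frequency
#' @return A `potentiation_fit` with `theta3_values` alongside the theta4
#'   machinery; flagged under-determined when only one trace is supplied.
#' @export
fit_theta3_theta4_joint <- function(traces, base, config = sim_config(),
                                    scale = NULL) {
  traces <- as_trace_list(traces)
  if (inherits(base, "fit_result")) {
    scale <- base$scale
    base <- base$params
  }
  stopifnot(inherits(base, "hatze_zakotnik_params"))
  if (is.null(scale)) stop("an amplitude scale is required", call. = FALSE)
  th <- c(base$theta1, base$theta2, base$theta3, base$theta4)
  freqs <- vapply(traces, trace_freq, numeric(1))
  ord <- order(freqs)
  traces <- traces[ord]; freqs <- freqs[ord]
  th3 <- numeric(length(freqs)); th4 <- numeric(length(freqs))
  errs <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    tr <- traces[[i]]
    if (freqs[i] <= 1) {
      th3[i] <- th[3]; th4[i] <- th[4]
      errs[i] <- sqrt(mean((tr$force - scale *
                              hatze_on_grid(th, tr, config, freqs[i]))^2))
      next
    }
    obj <- function(p) {
      mod <- tryCatch(hatze_on_grid(th, tr, config, freqs[i],
                                    theta3_eff = exp(p[1]),
                                    theta4_eff = exp(p[2])),
                      error = function(e) NULL)
      if (is.null(mod) || !all(is.finite(mod))) return(1e6)
      sum((tr$force - scale * mod)^2)
    }
    opt <- stats::nlminb(log(c(th[3], th[4])), obj,
                         lower = log(c(0.1 * th[3], 0.02 * th[4])),
                         upper = log(c(10 * th[3], 2 * th[4])))
    th3[i] <- exp(opt$par[1]); th4[i] <- exp(opt$par[2])
    errs[i] <- sqrt(opt$objective / nrow(tr))
  }
  structure(list(freqs = freqs, c_values = th4 / th[4],
                 theta3_values = th3, theta4_values = th4,
                 theta4_twitch = th[4], rmse_per_freq = errs, base = base,
                 scale = scale, K1 = NA_real_, K2 = NA_real_, weights = NULL,
                 under_determined = length(traces) < 2),
            class = "potentiation_fit")
}

# --- serialisation --------------------------------------------------------

#' Serialise a fit result to JSON
#'
#' Records the model, parameters, error, seeds, algorithm and package version;
#' numbers are written at full precision so the round trip is lossless.
#'
#' @param fit A [fit_result].
#' @param path File path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(model = fit$model,
              params = unclass(fit$params)[setdiff(names(unclass(fit$params)),
                                                   "tau_deact")],
              rmse = fit$rmse, n_restarts = fit$n_restarts,
              best_restart_seed = fit$best_restart_seed,
              algorithm = fit$algorithm, scale = fit$scale,
              under_determined = fit$under_determined,
              notes = as.list(fit$notes),
              package_version = as.character(utils::packageVersion("imadyn")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (obj$model == "hatze_van_zandwijk") "van_zandwijk" else obj$model
  params <- do.call(paste0(model, "_params"), as.list(obj$params))
  new_fit_result(obj$model, params, obj$rmse, obj$n_restarts,
                 obj$best_restart_seed, obj$algorithm,
                 scale = if (is.null(obj$scale)) NA_real_ else obj$scale,
                 under_determined = isTRUE(obj$under_determined),
                 notes = unlist(obj$notes))
}
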