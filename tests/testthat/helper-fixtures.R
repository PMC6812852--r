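# shared fixtures, built once per run and cached across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

quick_cfg <- function(relax = 1, solver = "rk4") {
  sim_config(relax_time = relax, solver = solver)
}

# noiseless synthetic SETi session generated by the calcium-cascade model
# with the animal-A parameter set
hz_dataset <- function() {
  cached("hz_ds", generate_dataset("hatze_zakotnik",
                                   published_params("seti_animal_A_hatze"),
                                   seti_protocol(), noise_sd = 0, seed = 42))
}

wilson_params_A <- function() {
  suppressWarnings(published_params("seti_animal_A_wilson"))
}

# staged fit of the noiseless session (slowest shared fixture)
hz_staged_fit <- function() {
  cached("hz_fit", fit_hatze_staged(hz_dataset(), quick_cfg(), seed = 7))
}

# exponential test trace with known rise/decay time constants
exp_rise_trace <- function(tau, dt = 2e-4, total = 25 * tau) {
  tt <- seq(0, total, dt)
  force_trace(tt, 1 - exp(-tt / tau))
}

exp_decay_trace <- function(tau, dt = 2e-4, total = 6 * tau) {
  tt <- seq(0, total, dt)
  force_trace(tt, exp(-tt / tau))
}

expect_traces_close <- function(a, b, tol) {
  expect_equal(length(a$force), length(b$force))
  expect_lt(max(abs(a$force - b$force)), tol)
}

# superposition oracle: relative gap between a train response and the sum of
# time-shifted single-spike responses; each single-spike simulation extends
# its relaxation so all traces cover the full train's window
superposition_gap <- function(sim, train, relax = 0.5) {
  last <- max(train$times)
  full <- sim(train, relax)
  total <- numeric(nrow(full))
  for (s in train$times) {
    one <- sim(spike_train(s, duration = train$duration),
               relax + (last - s))
    k <- min(nrow(one), length(total))
    total[1:k] <- total[1:k] + one$force[1:k]
  }
  max(abs(full$force - total)) / max(full$force)
}
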