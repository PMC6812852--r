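test_that("potentiation factor matches its closed form and limits", {
  K1 <- 1.46e-2; K2 <- 3.9e-4
  # direct arithmetic evaluation at t = 1 s
  expect_equal(potentiation_factor(1, K1, K2), 0.9860, tolerance = 1e-4)
  # converges to 1 for long intervals
  expect_lt(abs(potentiation_factor(1e3, K1, K2) - 1), 1e-6)
  # K1 = K2: the two fractions cancel
  expect_equal(potentiation_factor(c(0.01, 0.1, 1), 5e-3, 5e-3), rep(1, 3))
  expect_error(potentiation_factor(0.1, 1e-4, 1e-3), "K1")
  expect_error(potentiation_factor(0, K1, K2), "t_isi")

  # minimum located at (K1*K2)^(1/4): brute-force grid vs calculus
  tgrid <- exp(seq(log(1e-3), log(10), length.out = 20001))
  cg <- potentiation_factor(tgrid, K1, K2)
  expect_equal(tgrid[which.min(cg)], (K1 * K2)^0.25, tolerance = 1e-3)
})

test_that("potentiation factor stays within [0, 1] for random valid pairs", {
  set.seed(101)
  tgrid <- exp(seq(log(1e-4), log(1e3), length.out = 200))
  for (i in 1:100) {
    k <- sort(10^runif(2, -6, 0))
    cg <- potentiation_factor(tgrid, k[2], k[1])
    expect_true(all(cg >= 0 & cg <= 1))
  }
})

test_that("Hatze-Zakotnik solvers agree and degenerate inputs behave", {
  cfg_rk <- quick_cfg(relax = 0.5)
  cfg_it <- quick_cfg(relax = 0.5, solver = "iterative")
  rows <- c("seti_animal_A_hatze", "seti_animal_B_hatze", "seti_animal_D_hatze",
            "zakotnik2006_mean_seti", "feti_animal_2_hatze",
            "feti_animal_3_hatze", "feti_animal_4_hatze")
  for (row in rows) {
    p <- published_params(row)
    for (train in list(constant_train(1, 0.5), constant_train(20, 0.5))) {
      a <- simulate_hatze_zakotnik(p, train, cfg_rk)
      b <- simulate_hatze_zakotnik(p, train, cfg_it)
      expect_lt(max(abs(a$force - b$force)), 1e-3 * max(a$force))
    }
  }
  p <- published_params("seti_animal_A_hatze")
  z <- simulate_hatze_zakotnik(p, spike_train(numeric(), 0.2), cfg_rk)
  expect_true(all(z$force == 0))
  expect_true(all(simulate_hatze_zakotnik(p, constant_train(20, 0.5),
                                          cfg_rk)$force >= -1e-12))
})

test_that("non-linear models violate superposition at 20 Hz", {
  train <- constant_train(20, 0.5)
  p <- published_params("seti_animal_A_hatze")
  gap_hz <- superposition_gap(
    function(tr, relax) simulate_hatze_zakotnik(p, tr, quick_cfg(relax)), train)
  expect_gt(gap_hz, 0.05)

  pw <- wilson_params_A()
  gap_w <- superposition_gap(
    function(tr, relax) simulate_wilson_nl(pw, tr, quick_cfg(relax)), train)
  expect_gt(gap_w, 0.05)
})

test_that("tetanus/twitch contrast separates the two non-linear models", {
  cfg <- quick_cfg(relax = 0.5)
  ratio <- function(sim) {
    tw <- sim(constant_train(1, 1))
    te <- sim(constant_train(50, 2))
    max(te$force) / max(tw$force)
  }
  p <- published_params("zakotnik2006_mean_seti")
  r_hz <- ratio(function(tr) simulate_hatze_zakotnik(p, tr, cfg))
  pw <- published_params("wilson2013_mean_seti")
  r_w <- ratio(function(tr) simulate_wilson_nl(pw, tr, cfg))
  # published parameters: saturating calcium cascade vs strongly supra-linear
  # Wilson gain; the Wilson ratio is several-fold larger
  expect_gt(r_w, 3 * r_hz)
  expect_gt(r_w, 30)
})

test_that("the van Zandwijk sigmoid transforms the calcium state pointwise", {
  p <- published_params("seti_animal_A_hatze")
  cfg <- quick_cfg(relax = 0.3)
  train <- constant_train(10, 0.4)
  gam <- simulate_hatze_zakotnik(
    hatze_zakotnik_params(p$theta1, p$theta2, p$theta3, p$theta4), train, cfg)
  for (A in c(-6, 4)) {
    sig <- van_zandwijk_params(A, 1e-11)
    q <- simulate_hatze_van_zandwijk(p, sig, train, cfg)
    g <- pmax(gam$force, 1e-12)
    expect_equal(q$force, 1 / (1 + exp(A * (log(g) - log(1e-11)))),
                 tolerance = 1e-12)
    expect_true(all(q$force > 0 & q$force < 1))
  }
  # A -> 0 gives the flat half-activation state
  q0 <- simulate_hatze_van_zandwijk(p, van_zandwijk_params(0, 1e-11),
                                    train, cfg)
  expect_equal(unique(q0$force), 0.5)
  # q at the midpoint gamma = gamma0 is exactly 1/2
  gmid <- max(gam$force) / 2
  qm <- simulate_hatze_van_zandwijk(p, van_zandwijk_params(-4, gmid),
                                    train, cfg)
  i <- which.min(abs(pmax(gam$force, 1e-12) - gmid))
  expect_equal(qm$force[i], 0.5, tolerance = 1e-3)
})

test_that("Wilson saturation is half-maximal at the half-saturation constant", {
  # C_N = k gives x = 1/2 exactly, so with tau2 = 0 the force stage sees
  # drive A/2; hold C_N at k by construction via a long high-rate train is
  # impractical, so check the algebra through the exposed simulator: a model
  # with m large saturates x to ~1 and halves nowhere else
  x <- function(cn, k, m) cn^m / (cn^m + k^m)
  expect_equal(x(6.55, 6.55, 1.91), 0.5)
  expect_equal(x(2, 2, 7), 0.5)
  p <- published_params("wilson2013_mean_seti")
  cfg <- quick_cfg(relax = 0.3)
  z <- simulate_wilson_nl(p, spike_train(numeric(), 0.2), cfg)
  expect_true(all(z$force == 0))
  f <- simulate_wilson_nl(p, constant_train(30, 0.5), cfg)
  expect_true(all(f$force >= -1e-12))
})

test_that("Zajac activation saturates, relaxes exponentially, and validates input", {
  p <- zajac_params(tau_act = 0.02, beta_ratio = 0.4)
  dt <- 2e-4
  n <- 10001
  u_on <- sampled_signal(rep(1, n), dt)
  a <- simulate_zajac(p, u_on, quick_cfg())
  expect_equal(a$force[n], 1, tolerance = 1e-6) # steady state of full drive

  # step off: decay at rate 1/tau_deact
  u_step <- sampled_signal(c(rep(1, 5000), rep(0, 5001)), dt)
  s <- simulate_zajac(p, u_step, quick_cfg())
  decay <- s$force[5002:6000]
  ratios <- decay[-1] / decay[-length(decay)]
  expect_true(all(abs(ratios - exp(-dt / p$tau_deact)) < 1e-9))

  # activation faster than relaxation whenever beta < 1
  rise <- half_rise_time(simulate_zajac(p, u_on, quick_cfg()), onset = 0)
  fall <- half_decay_time(s, stim_end = 5000 * dt)
  expect_lt(rise, fall)

  expect_error(simulate_zajac(p, sampled_signal(c(0.5, 1.4), dt), quick_cfg()),
               "\\[0, 1\\]")
})

test_that("Bluemel recursion reaches its fixed point and superposes", {
  p <- blumel_params(filter = exp(-1), scaling = 2)
  expect_equal(blumel_time_constant(exp(-1), 0.0002), 0.0002)
  dt <- 2e-4
  u <- sampled_signal(rep(0.5, 4000), dt)
  a <- simulate_blumel(p, u, quick_cfg())
  expect_equal(a$force[4000], 1.0, tolerance = 1e-9) # scaling * u

  pf <- blumel_params(filter = 0.995, scaling = 1.5)
  spike_at <- function(i) {
    v <- numeric(3000); v[i] <- 1
    sampled_signal(v, dt)
  }
  both <- simulate_blumel(pf, sampled_signal(
    as.numeric(seq_len(3000) %in% c(100, 700)), dt), quick_cfg())
  sum_resp <- simulate_blumel(pf, spike_at(100), quick_cfg())$force +
    simulate_blumel(pf, spike_at(700), quick_cfg())$force
  expect_lt(max(abs(both$force - sum_resp)), 1e-9)
})

test_that("the third-order linear model is stable, gains correctly, and superposes", {
  expect_error(wilson_linear_params(1, -0.1, 0.001, 1e-6), "unstable")
  p <- published_params("default_wilson_linear")
  dt <- 2e-4
  z <- simulate_wilson_linear(p, spike_train(numeric(), 0.2), quick_cfg(0.2))
  expect_true(all(z$force == 0))

  # constant excitation: steady state theta0 * u (drive the companion system
  # with a long dense pulse train approximating u = const through unit-area
  # pulses at the sampling rate is awkward; instead integrate a literal step
  # by the same kernel through a square-pulse train covering every sample)
  cfg <- quick_cfg(relax = 1.5)
  tr50 <- simulate_wilson_linear(p, constant_train(50, 3), cfg)
  # mean drive of a 50 Hz unit-area train is 50; DC gain is theta0
  plateau <- max(tr50$force)
  expect_equal(plateau, p$theta0 * 50, tolerance = 0.02)

  # linearity: train response equals the sum of shifted single-spike responses
  gap <- superposition_gap(
    function(tr, relax) simulate_wilson_linear(p, tr, quick_cfg(relax)),
    constant_train(20, 0.3))
  expect_lt(gap, 1e-6)
})

test_that("halving the step changes model output by less than 0.1%", {
  train <- constant_train(20, 0.4)
  p_hz <- published_params("seti_animal_A_hatze")
  p_w <- wilson_params_A()
  p_l <- published_params("default_wilson_linear")
  # unit-area square pulses are the same continuous function on both grids,
  # so the comparison isolates solver convergence from input re-sampling
  sq <- pulse_shape("square", normalisation = "unit_area")
  sims <- list(
    function(dt) simulate_hatze_zakotnik(p_hz, train,
                                         sim_config(dt = dt, relax_time = 0.4),
                                         shape = sq),
    function(dt) simulate_wilson_nl(p_w, train,
                                    sim_config(dt = dt, relax_time = 0.4),
                                    shape = sq),
    function(dt) simulate_wilson_linear(p_l, train,
                                        sim_config(dt = dt, relax_time = 0.4),
                                        shape = sq)
  )
  for (sim in sims) {
    coarse <- sim(2e-4)
    fine <- sim(1e-4)
    on_coarse <- fine$force[seq(1, nrow(fine), by = 2)][seq_len(nrow(coarse))]
    expect_lt(max(abs(coarse$force - on_coarse)) / max(coarse$force), 1e-3)
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(hatze_zakotnik_params(1, 2, 3, 4, K1 = 1e-4, K2 = 1e-3), "K1")
  expect_error(hatze_zakotnik_params(-1, 2, 3, 4), ">= 0")
  expect_error(zajac_params(0.02, 1.2), "between 0 and 1")
  expect_error(blumel_params(1.1, 1), "between 0 and 1")
  expect_error(wilson_nl_params(0, 0.1, 0, 1, 10, 2), "tau_c")
  expect_warning(wilson_nl_params(0.06, 0.186, -0.21, 2.3, 48, 2.6),
                 "non-positive")
  expect_error(van_zandwijk_params(2, -1), "gamma0")
})

test_that("published parameter fixtures load and flag the ambiguous row", {
  tab <- published_params()
  expect_true(all(c("zakotnik2006_mean_seti", "zakotnik2006_mean_seti_printed",
                    "wilson2013_mean_feti", "seti_animal_D_wilson") %in% tab$name))
  expect_true(tab$ambiguous[tab$name == "zakotnik2006_mean_seti_printed"])
  p <- published_params("feti_animal_4_hatze")
  expect_s3_class(p, "hatze_zakotnik_params")
  expect_equal(p$theta4, 120970)
  expect_equal(attr(p, "neuron"), "FETi")
  expect_error(published_params("no_such_row"), "unknown")
})
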