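test_that("the single-twitch fit recovers the generating impulse response", {
  ds <- hz_dataset()
  fit <- hz_staged_fit()$stages$twitch
  twitch <- ds$traces[["1Hz"]]
  # label-symmetric cascade: recovery is judged on the reconstructed twitch,
  # not the raw coefficient vector
  expect_lt(fit$rmse, 1e-3 * max(twitch$force))
  expect_s3_class(fit$params, "hatze_zakotnik_params")
  expect_false(fit$under_determined)
  # canonical ordering puts the potentiation-carrying stage on the slower factor
  sp <- function(a, b) max(Re(polyroot(c(b, a, 1))))
  expect_gte(sp(fit$params$theta3, fit$params$theta4),
             sp(fit$params$theta1, fit$params$theta2) - 1e-9)
})

test_that("a noisy twitch fit hits the noise floor, not below", {
  ds <- generate_dataset("hatze_zakotnik",
                         published_params("seti_animal_A_hatze"),
                         seti_protocol(), noise_sd = 0.02, seed = 9)
  fit <- fit_hatze_single_twitch(ds$traces[["1Hz"]], quick_cfg(),
                                 n_restarts = 3, seed = 5)
  expect_gt(fit$rmse, 0.8 * 0.02)
  expect_lt(fit$rmse, 1.2 * 0.02)
})

test_that("degenerate twitch inputs are rejected", {
  tt <- seq(0, 1, 2e-4)
  expect_error(fit_hatze_single_twitch(force_trace(tt, rep(0, length(tt)))),
               "flat")
})

test_that("per-frequency theta4 refits recover the potentiation curve", {
  ds <- hz_dataset()
  pot <- hz_staged_fit()$stages$potentiation
  p <- ds$generator_params
  expected <- unname(potentiation_factor(1 / pot$freqs, p$K1, p$K2))
  expected[pot$freqs <= 1] <- 1 # single-twitch convention
  expect_equal(unname(pot$c_values), expected, tolerance = 0.02)
  expect_equal(pot$c_values[pot$freqs == 1], 1)
})

test_that("freeing theta4 never fits worse than keeping it fixed", {
  ds <- hz_dataset()
  fit <- hz_staged_fit()
  pot <- fit$stages$potentiation
  base <- fit$stages$twitch
  cfg <- quick_cfg()
  for (i in seq_along(pot$freqs)) {
    tr <- ds$traces[[sprintf("%gHz", pot$freqs[i])]]
    fixed_mod <- imadyn:::hatze_on_grid(
      c(base$params$theta1, base$params$theta2, base$params$theta3,
        base$params$theta4), tr, cfg, pot$freqs[i])
    fixed_rmse <- sqrt(mean((tr$force - base$scale * fixed_mod)^2))
    expect_lte(pot$rmse_per_freq[i], fixed_rmse + 1e-12)
  }
})

test_that("the potentiation-curve fit recovers exact generating constants", {
  K1 <- 1.46e-2; K2 <- 3.9e-4
  freqs <- c(1, 7, 10, 12.5, 15, 20, 25, 30, 40, 50)
  cvals <- potentiation_factor(1 / freqs, K1, K2)
  fit <- fit_potentiation_curve(cvals, freqs)
  expect_equal(fit$K1, K1, tolerance = 0.01)
  expect_equal(fit$K2, K2, tolerance = 0.01)
  # weight scale invariance
  fit2 <- fit_potentiation_curve(cvals, freqs, weights = 2 * freqs)
  expect_equal(fit2$K1, fit$K1, tolerance = 1e-6)
  expect_equal(fit2$K2, fit$K2, tolerance = 1e-6)
  # degenerate no-potentiation data collapses towards K1 = K2
  flat <- fit_potentiation_curve(rep(1, length(freqs)), freqs)
  expect_equal(potentiation_factor(1 / freqs, flat$K1, flat$K2),
               rep(1, length(freqs)), tolerance = 1e-3)
  expect_error(fit_potentiation_curve(c(1, 0.6), c(1, 20)), "3 distinct")
})

test_that("the simultaneous Wilson fit is deterministic and recovers traces", {
  proto <- protocol("SETi", freqs = c(1, 10, 20, 50), stim_duration = 0.6,
                    relax_time = 0.6)
  ds <- generate_dataset("wilson_nl", wilson_params_A(), proto, 0, seed = 11)
  cfg <- sim_config(relax_time = 0.6)
  fit <- fit_wilson_nl(ds, cfg, n_restarts = 3, seed = 21,
                       algorithm = "levenberg_marquardt")
  expect_lt(fit$rmse, 1e-3) # traces are normalised to peak 1
  fit2 <- fit_wilson_nl(ds, cfg, n_restarts = 3, seed = 21,
                        algorithm = "levenberg_marquardt")
  expect_identical(tidy(fit)$estimate, tidy(fit2)$estimate)
  expect_identical(fit$best_restart_seed, fit2$best_restart_seed)

  # a twitch alone cannot pin down six parameters
  single <- fit_wilson_nl(list(ds$traces[["1Hz"]]), cfg, n_restarts = 3,
                          seed = 21, algorithm = "levenberg_marquardt")
  expect_true(single$under_determined)
})

test_that("the sigmoid fit recovers generating parameters and flags tail fits", {
  pA <- published_params("seti_animal_A_hatze")
  sig <- van_zandwijk_params(-8, 2e-11)
  proto <- protocol("SETi", freqs = c(1, 10, 20, 50), stim_duration = 0.6,
                    relax_time = 0.6)
  ds <- generate_dataset("hatze_van_zandwijk", pA, proto, 0, seed = 2,
                         sigmoid = sig)
  cfg <- sim_config(relax_time = 0.6)
  fit <- fit_van_zandwijk(ds, pA, cfg)
  expect_equal(fit$params$A, sig$A, tolerance = 0.02)
  expect_equal(fit$params$gamma0, sig$gamma0, tolerance = 0.02)
  expect_length(fit$notes, 0)

  # on calcium-cascade data with interval-driven potentiation, the sigmoid
  # workflow fits worse than the per-frequency theta4 stage
  ds_hz <- hz_dataset()
  vz <- fit_van_zandwijk(ds_hz, pA, quick_cfg())
  pot <- hz_staged_fit()$stages$potentiation
  expect_gt(vz$rmse, sqrt(mean(pot$rmse_per_freq^2)))
})

test_that("joint theta3/theta4 refits are nested improvements that recover theta3", {
  ds <- hz_dataset()
  fit <- hz_staged_fit()
  pot4 <- fit$stages$potentiation
  joint <- fit_theta3_theta4_joint(ds, fit$stages$twitch, quick_cfg())
  expect_true(all(joint$rmse_per_freq <= pot4$rmse_per_freq + 1e-9))
  # the generator varied theta4 only, so theta3 must come back unchanged
  idx <- joint$freqs > 1
  expect_equal(joint$theta3_values[idx],
               rep(fit$stages$twitch$params$theta3, sum(idx)),
               tolerance = 0.05)
  single <- fit_theta3_theta4_joint(list(ds$traces[["20Hz"]]),
                                    fit$stages$twitch, quick_cfg())
  expect_true(single$under_determined)
})

test_that("fit results serialise losslessly with provenance", {
  fit <- hz_staged_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- read_fit_result(path)
  expect_equal(unclass(back$params), unclass(fit$params))
  expect_equal(back$rmse, fit$rmse)
  expect_equal(as.numeric(back$best_restart_seed),
               as.numeric(fit$best_restart_seed))
  expect_identical(back$algorithm, fit$algorithm)

  ppath <- withr::local_tempfile(fileext = ".json")
  write_params(fit$params, ppath)
  expect_equal(unclass(read_params(ppath)), unclass(fit$params))
})

test_that("tidiers expose parameters and fit provenance as tibbles", {
  fit <- hz_staged_fit()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("theta1", "K1") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.finite(gl$rmse))
  pot <- fit$stages$potentiation
  tp <- tidy(pot)
  expect_true(all(c("freq_Hz", "isi_s", "c") %in% names(tp)))
})
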