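test_that("rise and decay estimators recover tau * ln 2 on exponentials", {
  dt <- 2e-4
  for (tau in c(0.01, 0.05, 0.2, 1)) {
    expect_equal(half_rise_time(exp_rise_trace(tau, dt), onset = 0),
                 tau * log(2), tolerance = dt / (tau * log(2)))
    expect_equal(half_decay_time(exp_decay_trace(tau, dt), stim_end = 0),
                 tau * log(2), tolerance = dt / (tau * log(2)))
  }
})

test_that("rise/decay edge cases are flagged, not silent", {
  tt <- seq(0, 1, 2e-4)
  # trace that starts at its peak: zero rise time
  peak_first <- force_trace(tt, exp(-tt / 0.2))
  expect_equal(half_rise_time(peak_first, onset = 0), 0)
  # a non-decaying trace never reaches half-peak on the way down
  flat <- force_trace(tt, rep(1, length(tt)))
  expect_warning(res <- half_decay_time(flat, stim_end = 0), "undefined")
  expect_true(is.na(res))
  expect_error(half_rise_time(force_trace(tt, rep(0, length(tt))), onset = 0),
               "positive peak")
})

test_that("decay time is invariant to amplitude rescaling", {
  tr <- exp_decay_trace(0.13)
  scaled <- force_trace(tr$time, tr$force * 37)
  expect_equal(half_decay_time(tr, 0), half_decay_time(scaled, 0))
})

test_that("trace normalisation conventions rescale as documented", {
  tt <- seq(0, 1, 1e-3)
  tr <- force_trace(tt, rep(5, length(tt)))
  expect_true(all(normalize_trace(tr, "per_trace_max")$force == 1))

  twitch <- force_trace(tt, 0.02 * sin(pi * tt))
  scaled <- normalize_trace(twitch, "twitch_peak_to_0.1", value = max(twitch$force))
  expect_equal(max(scaled$force), 0.1)

  once <- normalize_trace(tr, "per_trace_max")
  expect_equal(normalize_trace(once, "per_trace_max")$force, once$force)

  expect_error(normalize_trace(tr, "per_animal_max", value = 0), "positive")
  expect_error(normalize_trace(tr, "peak_at_50Hz"), "reference value")
})

test_that("rmse is a symmetric pointwise metric with grid resampling", {
  tt <- seq(0, 1, 1e-3)
  a <- force_trace(tt, sin(pi * tt))
  b <- force_trace(tt, sin(pi * tt) + 0.1)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, b), 0.1, tolerance = 1e-12)
  expect_equal(rmse(a, b), rmse(b, a))

  fine <- force_trace(seq(0, 1, 2.5e-4), sin(pi * seq(0, 1, 2.5e-4)))
  expect_lt(rmse(a, fine), 1e-6)
  short <- force_trace(seq(0, 0.5, 1e-3), sin(pi * seq(0, 0.5, 1e-3)))
  expect_error(rmse(a, short), "cover")
})

test_that("frequency responses carry the documented normalisation and shapes", {
  cfg <- quick_cfg()
  p <- published_params("default_blumel")
  fr <- frequency_response("blumel", p, c(5, 10, 20, 30, 40, 50), 2, cfg,
                           normalise = TRUE)
  expect_equal(fr$peak_norm[fr$freq_Hz == 50], 1)
  expect_gt(summary(stats::lm(peak ~ freq_Hz, fr))$r.squared, 0.999)
  # first-order linear relaxation: decay time identical across frequencies
  expect_lt(diff(range(fr$half_decay_s)) / mean(fr$half_decay_s), 1e-6)

  # the calcium cascade shows strong frequency dependence of decay time
  pa <- published_params("seti_animal_A_hatze")
  fra <- frequency_response("hatze_zakotnik", pa, c(10, 50), 2, cfg)
  expect_gt(abs(diff(fra$half_decay_s)) / min(fra$half_decay_s), 0.1)
  expect_error(frequency_response("blumel", p, numeric(), 2, cfg), "non-empty")
})

test_that("step responses of the linear filter share rise time across drive levels", {
  p <- published_params("default_blumel")
  dt <- 2e-4
  rise_for <- function(level) {
    u <- sampled_signal(rep(level, 5000), dt)
    half_rise_time(simulate_blumel(p, u, quick_cfg()), onset = 0)
  }
  expect_equal(rise_for(0.3), rise_for(0.8), tolerance = 1e-9)
})

test_that("force traces round-trip through delimited text with metadata", {
  tr <- simulate_hatze_zakotnik(published_params("seti_animal_A_hatze"),
                                constant_train(10, 0.3), quick_cfg(0.2))
  m <- attr(tr, "meta"); m$freq <- 10; attr(tr, "meta") <- m
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_trace(tr, path)
  back <- read_force_trace(path)
  expect_equal(back$force, tr$force, tolerance = 1e-12)
  expect_equal(attr(back, "meta")$freq, 10)
  expect_equal(attr(back, "dt"), 2e-4)
  writeLines("time_s\tforce", path)
  expect_error(read_force_trace(path), "malformed")
})
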