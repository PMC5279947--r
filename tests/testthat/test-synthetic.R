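test_that("generators are deterministic given a seed and demand one", {
  cfg <- generator_config(seed = 99)
  expect_identical(make_sweeps(cfg), make_sweeps(cfg))
  expect_identical(make_event_trains(cfg, n_cells = 3, duration = 30),
                   make_event_trains(cfg, n_cells = 3, duration = 30))
  expect_error(generator_config(), "seed")
  expect_error(make_count_pair(100, 120), "seed")
  # generation does not disturb the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_sweeps(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless sweeps collapse to exact linear relations", {
  cfg <- generator_config(n_slices_per_group = 3, slice_gain_cv = 0,
                          noise_cv = 0,
                          epsc_gain_by_group = c(g1 = 2.0, g2 = 3.5),
                          seed = 4)
  sw <- make_sweeps(cfg)
  expect_equal(sw$epsc_pa / sw$fv_uv,
               ifelse(sw$group == "g1", 2.0, 3.5), tolerance = 1e-12)
  expect_equal(sw$fepsp_slope / sw$fv_uv, rep(cfg$fepsp_gain, nrow(sw)),
               tolerance = 1e-12)
  expect_equal(sw$fv_uv,
               cfg$fv_max * sw$stimulus_v / (sw$stimulus_v + cfg$fv_half_sat),
               tolerance = 1e-12)
  expect_equal(nrow(sw), 2 * 3 * length(cfg$intensities) * 10)
})

test_that("saturation flags mark fiber volleys above threshold", {
  cfg <- generator_config(n_slices_per_group = 8, seed = 17)
  sw <- make_sweeps(cfg)
  expect_identical(sw$saturated,
                   sw$fv_uv > cfg$saturation_threshold * cfg$fv_max)
  # high intensities saturate more often, thinning the top of the curve
  top <- sw$stimulus_v >= 80
  expect_gt(mean(sw$saturated[top]), mean(sw$saturated[!top]))
})

test_that("pipeline recovers the preset EPSC/FV gain within 2 SEM", {
  cfg <- preset_config("control", seed = 42)
  resp <- exclude_saturated(average_by_intensity(make_sweeps(cfg), 10))
  s <- response_fv_ratio(resp)$summary
  expect_gte(s$n, 80)
  expect_lt(abs(s$mean_ratio - 2.44), 2 * s$sem)
})

test_that("two-group presets carry the measured gains", {
  g <- epsc_gain_presets()
  expect_equal(unname(g["control_mature"]), 2.44)
  expect_equal(unname(g["control_immature"]), 1.24)
  cfg <- preset_config("ablated_im", seed = 2)
  expect_equal(cfg$epsc_gain_by_group, c(control = 2.2, ablated_im = 3.7))
})

test_that("event trains honour the Poisson/lognormal contract", {
  cfg <- generator_config(event_rate_by_group = c(control = 0.5), seed = 31)
  trains <- make_event_trains(cfg, n_cells = 10, duration = 120)
  expect_length(trains, 10)
  counts <- vapply(trains, function(tr) nrow(tr$events), integer(1))
  lambda_total <- 0.5 * 120 * 10
  expect_lt(abs(sum(counts) - lambda_total), 3 * sqrt(lambda_total))
  for (tr in trains) {
    expect_false(is.unsorted(tr$events$time))
    expect_true(all(tr$events$time >= 0 & tr$events$time < tr$duration))
  }
  # pooled frequency estimate near the generating rate
  freqs <- vapply(trains, function(tr) event_summary(tr)$frequency,
                  numeric(1))
  expect_lt(abs(mean(freqs) - 0.5), 3 * sqrt(0.5 / (120 * 10)))

  rate0 <- generator_config(event_rate_by_group = c(control = 0), seed = 31)
  empty <- make_event_trains(rate0, n_cells = 3, duration = 60)
  expect_true(all(vapply(empty, function(tr) nrow(tr$events), integer(1)) == 0))
})

test_that("event amplitudes have the configured lognormal median", {
  cfg <- generator_config(event_rate_by_group = c(control = 2), seed = 8)
  trains <- make_event_trains(cfg, n_cells = 10, duration = 60)
  amps <- unlist(lapply(trains, function(tr) tr$events$amplitude))
  expect_gt(length(amps), 1000)
  expect_equal(median(amps), exp(cfg$event_amp_mu), tolerance = 0.06)
})

test_that("count pairs hit their target means and feed percent_change", {
  exact <- make_count_pair(16881, 23756, cv = 0, n = 4, seed = 1)
  expect_true(all(exact$reference == 16881))
  expect_true(all(exact$test == 23756))
  expect_equal(percent_change(mean(exact$reference), mean(exact$test)), 41)

  noisy <- make_count_pair(16881, 23756, cv = 0.08, n = 4, seed = 1)
  expect_identical(noisy, make_count_pair(16881, 23756, cv = 0.08, n = 4,
                                          seed = 1))
  expect_lt(abs(mean(noisy$reference) - 16881), 3 * 0.08 * 16881 / sqrt(4))
  expect_lt(abs(mean(noisy$test) - 23756), 3 * 0.08 * 23756 / sqrt(4))
  two <- make_count_pair(100, 120, cv = 0.1, n = 2, seed = 5)
  expect_length(two$reference, 2)
  expect_true(is.finite(sd(two$reference) / sqrt(2)))
})
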