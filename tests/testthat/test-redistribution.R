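test_that("integration curve matches its worked examples and is clamped", {
  expect_equal(synaptic_strength(21), 65.08525, tolerance = 1e-6)
  expect_equal(synaptic_strength(43), 99.76095, tolerance = 1e-6)
  expect_equal(synaptic_strength(1), 4.842369, tolerance = 1e-6)
  # raw value at onset is -0.063, clamped to the narrated 0% floor
  expect_identical(synaptic_strength(0), 0)
  d <- 0:43
  y <- synaptic_strength(d)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 100))
  expect_error(synaptic_strength(-1), "non-negative")
  expect_error(synaptic_strength(2.5), "whole days")
})

test_that("proliferation follows the declining power law", {
  expect_equal(proliferation(0), 4e6 / 42^1.5, tolerance = 1e-12)
  expect_equal(proliferation(0), 14695.56, tolerance = 1e-4)
  expect_equal(proliferation(21), 7999.248, tolerance = 1e-4)
  # the printed formula gives ~9545 at day 14 (not the ~8000 narrated for
  # that day; the formula governs and reaches 8000 only at day 21)
  expect_equal(proliferation(14), 9545.044, tolerance = 1e-4)
  expect_true(all(diff(proliferation(0:43)) < 0))
  expect_error(proliferation(-3), "whole day")
})

test_that("initial pools reproduce the static ~19.6-million total", {
  pools <- initial_pools()
  expect_identical(pools$mature_synapses, 100 * 190000)
  expect_equal(pools$baseline_immature_synapses, 623150.9, tolerance = 1e-6)
  expect_equal(pools$total_synapses, 19.6e6, tolerance = 0.005)
  expect_equal(pools$total_synapses,
               pools$mature_synapses + pools$baseline_immature_synapses)
})

test_that("incorporation schedule applies survival and strength switches", {
  p <- model_params()
  ctrl <- incorporation_schedule(p, "control")
  ko <- incorporation_schedule(p, "bax_ko")
  expect_equal(nrow(ctrl), p$horizon)
  expect_true(all(diff(ctrl$incorporation_day) > 0))
  expect_equal(ctrl$cells[ctrl$incorporation_day == 21], 1599.85,
               tolerance = 1e-4)
  expect_equal(ko$cells[ko$incorporation_day == 21], 5599.474,
               tolerance = 1e-4)
  # knockout survival/strength not yet in effect before onset day
  pre <- ctrl$incorporation_day < p$ko_onset_day
  expect_equal(ko$cells[pre], ctrl$cells[pre])
  expect_true(all(ko$strength_multiplier[pre] == 1))
  expect_true(all(ko$strength_multiplier[!pre] == p$ko_strength_factor))
  expect_true(all(ctrl$strength_multiplier == 1))
  expect_error(incorporation_schedule(p, "mutant"))
})

test_that("immature synapse load follows the cohort convolution", {
  p <- model_params()
  ctrl <- incorporation_schedule(p, "control")
  ko <- incorporation_schedule(p, "bax_ko")
  expect_identical(immature_synapse_load(0, ctrl, p), 0)
  # single-cohort hand computation at day 1
  expect_equal(immature_synapse_load(1, ctrl, p),
               proliferation(1, p) * 0.20 * synaptic_strength(1, p),
               tolerance = 1e-12)
  expect_equal(immature_synapse_load(1, ctrl, p), 13738.69, tolerance = 1e-4)
  t <- 0:p$horizon
  load_c <- immature_synapse_load(t, ctrl, p)
  load_k <- immature_synapse_load(t, ko, p)
  expect_true(all(diff(load_c) > 0))
  expect_true(all(load_k >= load_c))
  expect_error(immature_synapse_load(44, ctrl, p), "horizon")
})

test_that("load matches a per-cell brute-force ledger on a mini instance", {
  p <- model_params(total_cells = 200, horizon = 10)
  ledger <- data.frame(
    incorporation_day = 1:10,
    cells = c(7L, 5L, 9L, 3L, 0L, 4L, 8L, 2L, 6L, 1L),
    strength_multiplier = c(rep(1, 4), rep(1.35, 6))
  )
  for (t in c(0, 1, 3, 7, 10)) {
    expect_equal(immature_synapse_load(t, ledger, p),
                 brute_force_load(t, ledger, p), tolerance = 1e-12)
  }
})

test_that("trajectories conserve the pool and order the conditions", {
  p <- model_params()
  ctrl <- run_simulation(p, "control")
  ko <- run_simulation(p, "bax_ko")
  total <- attr(ctrl, "total_synapses")
  for (tr in list(ctrl, ko)) {
    expect_equal(nrow(tr), p$horizon + 1)
    expect_equal(tr$pct_immature + tr$pct_mature, rep(100, nrow(tr)),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$pct_immature) >= 0))
    expect_true(all(tr$immature_synapses <= total))
    # conservation: synapses held outside the immature cohorts plus the
    # cohort load re-sum to the static pool at every day
    expect_equal(tr$pct_mature / 100 * total + tr$immature_synapses,
                 rep(total, nrow(tr)), tolerance = 1e-9)
  }
  expect_true(all(ko$pct_immature >= ctrl$pct_immature))
  # literal formula: nothing appropriated yet at day 0
  expect_equal(ctrl$pct_immature[1], 0)
})

test_that("baseline-in-numerator variant starts at the immature share", {
  p <- model_params(include_baseline_in_numerator = TRUE)
  tr <- run_simulation(p, "control")
  pools <- initial_pools(p)
  expect_equal(tr$pct_immature[1],
               pools$baseline_immature_synapses / pools$total_synapses * 100,
               tolerance = 1e-12)
  expect_equal(tr$pct_immature[1], 3.1756, tolerance = 1e-4)
  expect_equal(tr$pct_immature + tr$pct_mature, rep(100, nrow(tr)),
               tolerance = 1e-9)
})

test_that("with zero survival the immature share never grows", {
  p <- model_params(survival_wt = 0, survival_ko = 0)
  for (cond in c("control", "bax_ko")) {
    tr <- run_simulation(p, cond)
    expect_true(all(tr$pct_immature == tr$pct_immature[1]))
  }
})

test_that("mature-synapse ratio declines over the comparison window", {
  p <- model_params()
  ctrl <- run_simulation(p, "control")
  ko <- run_simulation(p, "bax_ko")
  r <- predicted_mature_ratio(ko, ctrl)
  expect_equal(r$day, 36:43)
  expect_true(all(r$ratio_pct <= 100))
  expect_lt(r$ratio_pct[r$day == 43], r$ratio_pct[r$day == 36])
  same <- predicted_mature_ratio(ctrl, ctrl)
  expect_equal(same$ratio_pct, rep(100, 8))
  expect_error(predicted_mature_ratio(ko, ctrl, window = 40:50), "window")
  short <- run_simulation(model_params(horizon = 40), "bax_ko")
  expect_error(predicted_mature_ratio(short, ctrl), "mismatched")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(model_params(survival_ko = 1.2), "survival_ko")
  expect_error(model_params(mature_fraction = 1), "mature_fraction")
  expect_error(model_params(total_cells = -5), "total_cells")
  expect_error(model_params(horizon = 50), "horizon")
  expect_error(model_params(ko_strength_factor = 0.5), "ko_strength_factor")
})
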