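#' Synaptic integration curve of adult-born granule cells
#'
#' Relative synaptic strength (percent of the mature level) of an adult-born
#' granule cell `d` days after it begins to integrate, i.e. from two weeks of
#' cell age onward. The curve is logarithmic,
#' `Y(d) = strength_slope * ln(strength_age_offset + d) - strength_intercept`,
#' fit to evoked EPSC amplitudes of immature cells at progressive ages, and is
#' clamped to \[0, 100\]: a cell at integration onset has essentially no
#' excitatory synapses and a cell 43 days later has reached the mature level.
#'
#' @param days_since_incorporation Integer day(s) since integration onset
#'   (vectorised); must be >= 0.
#' @param params A [model_params()] object.
#' @return Percent of mature synaptic strength, in \[0, 100\].
#' @examples
#' synaptic_strength(21) # a 5-week-old cell, ~65%
#' synaptic_strength(43) # an 8-week-old cell, ~100%
#' @export
synaptic_strength <- function(days_since_incorporation, params = model_params()) {
  d <- days_since_incorporation
  if (!is.numeric(d) || anyNA(d) || any(d < 0)) {
    stop("days_since_incorporation must be non-negative", call. = FALSE)
  }
  if (any(d != round(d))) {
    stop("days_since_incorporation must be whole days", call. = FALSE)
  }
  raw <- params$strength_slope * log(params$strength_age_offset + d) -
    params$strength_intercept
  pmin(100, pmax(0, raw))
}

#' Progenitor proliferation rate
#'
#' Number of progenitor cells available per day at simulation day `t`,
#' following the declining power law
#' `P(t) = prolif_scale * (prolif_age_offset + t)^prolif_exponent`. Day 0
#' corresponds to an 8-week-old animal; proliferation decreases strictly with
#' age and is identical in control and knockout conditions (the manipulation
#' alters survival, not proliferation).
#'
#' @param t Integer simulation day(s), >= 0 (vectorised).
#' @inheritParams synaptic_strength
#' @return Cells per day.
#' @examples
#' proliferation(0)  # ~14,700 cells/day
#' proliferation(21) # ~8,000 cells/day
#' @export
proliferation <- function(t, params = model_params()) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0) || any(t != round(t))) {
    stop("t must be a non-negative whole day", call. = FALSE)
  }
  params$prolif_scale * (params$prolif_age_offset + t)^params$prolif_exponent
}

#' Initial synapse pools
#'
#' Sizes the static synapse pool at day 0. Mature cells hold
#' `synapses_per_mature_cell * total_cells * mature_fraction` synapses. The
#' pre-existing immature population (5% of cells, ages spread uniformly over
#' the maturation span) holds the baseline immature pool: the immature cell
#' count divided by the maturation span, times the sum of the integration
#' curve over all ages, scaled to synapses. Their sum is the total pool,
#' which the simulation holds constant.
#'
#' @inheritParams synaptic_strength
#' @return A list with components `mature_synapses`,
#'   `baseline_immature_synapses` and `total_synapses`.
#' @examples
#' initial_pools()$total_synapses # ~19.6e6
#' @export
initial_pools <- function(params = model_params()) {
  mature <- params$synapses_per_mature_cell *
    params$total_cells * params$mature_fraction
  ages <- seq_len(params$maturation_span)
  baseline <- params$total_cells * (1 - params$mature_fraction) /
    params$maturation_span *
    sum(synaptic_strength(ages, params) / 100 * params$synapses_per_mature_cell)
  list(
    mature_synapses = mature,
    baseline_immature_synapses = baseline,
    total_synapses = mature + baseline
  )
}

#' Daily incorporation schedule of new granule cells
#'
#' Builds the cohort ledger: for each day `t = 1..horizon`, the number of new
#' cells incorporating into the network, `I(t) = P(t) * survival`, and the
#' synaptic-strength multiplier they carry. Under `"control"`, survival is
#' `survival_wt` throughout. Under `"bax_ko"`, cohorts incorporating from
#' `ko_onset_day` onward carry the knockout: survival rises to `survival_ko`
#' and their strength is multiplied by `ko_strength_factor` (deletion of the
#' pro-apoptotic pathway both rescues cells from death and blocks synapse
#' pruning).
#'
#' @param condition `"control"` or `"bax_ko"`.
#' @inheritParams synaptic_strength
#' @return A data frame (cohort ledger) with columns `incorporation_day`,
#'   `cells` and `strength_multiplier`, one row per day 1..horizon.
#' @export
incorporation_schedule <- function(params = model_params(),
                                   condition = c("control", "bax_ko")) {
  condition <- match.arg(condition)
  day <- seq_len(params$horizon)
  ko <- condition == "bax_ko" & day >= params$ko_onset_day
  ledger <- data.frame(
    incorporation_day = day,
    cells = proliferation(day, params) *
      ifelse(ko, params$survival_ko, params$survival_wt),
    strength_multiplier = ifelse(ko, params$ko_strength_factor, 1)
  )
  attr(ledger, "condition") <- condition
  ledger
}

#' Synapses appropriated by incorporated immature cohorts
#'
#' Cumulative synapse load of all cohorts incorporated up to day `t`: the
#' convolution `S_I(t) = I(t) Y(1) + I(t-1) Y(2) + ...`, where a cohort
#' incorporated on day `k` contributes its surviving cells times its strength
#' multiplier times the integration curve at age `t - k + 1`, converted to
#' synapses. Cohorts never lose synapses, so the load is non-decreasing in
#' `t`.
#'
#' @param t Integer day(s) in `0..horizon` (vectorised).
#' @param ledger A cohort ledger from [incorporation_schedule()].
#' @inheritParams synaptic_strength
#' @return Synapses held by the incorporated immature population at day `t`.
#' @export
immature_synapse_load <- function(t, ledger, params = model_params()) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0) || any(t != round(t))) {
    stop("t must be a non-negative whole day", call. = FALSE)
  }
  if (any(t > params$horizon)) {
    stop("t exceeds the simulation horizon (", params$horizon, ")",
         call. = FALSE)
  }
  vapply(t, function(day) {
    live <- ledger[ledger$incorporation_day <= day, , drop = FALSE]
    if (nrow(live) == 0L) return(0)
    age <- day - live$incorporation_day + 1
    sum(live$cells * live$strength_multiplier *
          synaptic_strength(age, params) / 100 *
          params$synapses_per_mature_cell)
  }, numeric(1))
}

#' Run the redistribution simulation
#'
#' Day-stepped trajectory of the share of the static synapse pool held by the
#' immature vs mature populations. The denominator is the initial total pool
#' (mature plus baseline immature); the numerator is the load appropriated by
#' newly incorporated cohorts ([immature_synapse_load()]), optionally plus the
#' baseline immature pool when `include_baseline_in_numerator` is set. At
#' every day `pct_immature + pct_mature == 100`, expressing conservation of
#' the pool: every synapse gained by an immature cell is lost by a mature
#' one.
#'
#' @inheritParams incorporation_schedule
#' @return A data frame of class `"trajectory"` with one row per day
#'   `0..horizon` and columns `day`, `condition`, `immature_synapses`,
#'   `pct_immature`, `pct_mature`. The static pool size is attached as
#'   attribute `"total_synapses"`.
#' @examples
#' ctrl <- run_simulation(condition = "control")
#' tail(ctrl, 3)
#' @export
run_simulation <- function(params = model_params(),
                           condition = c("control", "bax_ko")) {
  condition <- match.arg(condition)
  pools <- initial_pools(params)
  ledger <- incorporation_schedule(params, condition)
  day <- 0:params$horizon
  load <- immature_synapse_load(day, ledger, params)
  if (params$include_baseline_in_numerator) {
    load <- load + pools$baseline_immature_synapses
  }
  pct_im <- load / pools$total_synapses * 100
  traj <- data.frame(
    day = day,
    condition = condition,
    immature_synapses = load,
    pct_immature = pct_im,
    pct_mature = 100 - pct_im
  )
  attr(traj, "total_synapses") <- pools$total_synapses
  attr(traj, "params") <- params
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Predicted mature-synapse ratio between conditions
#'
#' Ratio (x100) of the mature synapse share in the knockout condition to the
#' control condition, day by day over a comparison window — the model's
#' prediction of the percent change in mature-cell synapse number, to be
#' compared against the measured percent change in mature-cell EPSC
#' amplitude. The default window is days 36..43, the age of the recordings.
#'
#' @param ko,ctrl Trajectories from [run_simulation()] run with identical
#'   parameters under the two conditions.
#' @param window Integer days over which to form the ratio; must lie within
#'   the simulated horizon.
#' @return A data frame with columns `day` and `ratio_pct`
#'   (`100 * pct_mature_ko / pct_mature_ctrl`).
#' @export
predicted_mature_ratio <- function(ko, ctrl, window = 36:43) {
  if (!identical(ko$day, ctrl$day)) {
    stop("trajectories have mismatched horizons", call. = FALSE)
  }
  if (!all(window %in% ko$day)) {
    stop("comparison window lies outside the simulated horizon", call. = FALSE)
  }
  i_ko <- match(window, ko$day)
  i_ct <- match(window, ctrl$day)
  data.frame(
    day = window,
    ratio_pct = 100 * ko$pct_mature[i_ko] / ctrl$pct_mature[i_ct]
  )
}
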