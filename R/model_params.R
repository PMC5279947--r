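#' Parameters of the synapse-redistribution simulation
#'
#' Bundles every constant of the deterministic redistribution model: the size
#' and composition of the granule-cell (GC) population, the synaptic
#' integration curve of adult-born cells, the declining progenitor
#' proliferation curve, survival rates under control and enhanced-survival
#' (Bax-knockout) conditions, and the simulated time window.
#'
#' Time is measured in days, with day 0 the start of the experiment
#' (tamoxifen-induced recombination in 8-week-old animals). The defaults
#' reproduce the published parameter set: 200,000 GCs of which 95% are mature
#' with 100 synapses each; integration curve
#' `Y(t) = 71.1 ln(14 + t) - 187.7` (percent of mature strength, clamped to
#' \[0, 100\]); proliferation `P(t) = 4e6 (42 + t)^-1.5` cells/day; 20%
#' survival of newborn cells in wild type rising to 70% for knockout cohorts
#' incorporating from day 14 on, which also carry ~35% more synapses
#' (`ko_strength_factor = 1.35`).
#'
#' @param total_cells Total granule cells in the network (unilateral count).
#' @param mature_fraction Fraction of `total_cells` that are mature (> 8
#'   weeks old) at day 0.
#' @param synapses_per_mature_cell Synapses per mature cell; defines 100%
#'   synaptic strength.
#' @param strength_slope,strength_intercept,strength_age_offset Coefficients
#'   of the integration curve
#'   `Y(d) = strength_slope * ln(strength_age_offset + d) - strength_intercept`
#'   (percent of mature strength at `d` days after integration onset).
#' @param maturation_span Days from integration onset to full maturity (the
#'   number of distinct synaptic strengths in the immature population).
#' @param prolif_scale,prolif_age_offset,prolif_exponent Coefficients of the
#'   progenitor proliferation curve
#'   `P(t) = prolif_scale * (prolif_age_offset + t)^prolif_exponent`
#'   (cells/day).
#' @param survival_wt Survival fraction of newborn cells in the wild type.
#' @param survival_ko Survival fraction of knockout-era cohorts.
#' @param ko_onset_day First day on which incorporating cohorts carry the
#'   knockout (recombination takes ~2 weeks to reach incorporating cells).
#' @param ko_strength_factor Multiplier on synaptic strength of knockout-era
#'   cohorts (Bax deletion blocks synapse pruning); deliberately not capped
#'   at 100%.
#' @param horizon Last simulated day; must not exceed `maturation_span`
#'   (cohorts never mature within the simulated window).
#' @param include_baseline_in_numerator If `TRUE`, the pre-existing immature
#'   synapse pool counts towards the immature share `%im`; the default
#'   `FALSE` follows the published formula, which counts newly appropriated
#'   synapses only.
#'
#' @return An object of class `"model_params"`: a validated named list.
#' @seealso [run_simulation()], [initial_pools()], [load_config()]
#' @examples
#' p <- model_params()
#' initial_pools(p)$total_synapses # ~19.6 million
#' @export
model_params <- function(total_cells = 200000,
                         mature_fraction = 0.95,
                         synapses_per_mature_cell = 100,
                         strength_slope = 71.1,
                         strength_intercept = 187.7,
                         strength_age_offset = 14,
                         maturation_span = 43,
                         prolif_scale = 4e6,
                         prolif_age_offset = 42,
                         prolif_exponent = -1.5,
                         survival_wt = 0.20,
                         survival_ko = 0.70,
                         ko_onset_day = 14,
                         ko_strength_factor = 1.35,
                         horizon = 43,
                         include_baseline_in_numerator = FALSE) {
  p <- list(
    total_cells = total_cells,
    mature_fraction = mature_fraction,
    synapses_per_mature_cell = synapses_per_mature_cell,
    strength_slope = strength_slope,
    strength_intercept = strength_intercept,
    strength_age_offset = strength_age_offset,
    maturation_span = maturation_span,
    prolif_scale = prolif_scale,
    prolif_age_offset = prolif_age_offset,
    prolif_exponent = prolif_exponent,
    survival_wt = survival_wt,
    survival_ko = survival_ko,
    ko_onset_day = ko_onset_day,
    ko_strength_factor = ko_strength_factor,
    horizon = horizon,
    include_baseline_in_numerator = include_baseline_in_numerator
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, key, what) {
    if (!ok) stop("invalid model parameter `", key, "`: ", what, call. = FALSE)
  }
  for (key in c("survival_wt", "survival_ko", "mature_fraction")) {
    chk(num1(p[[key]]) && p[[key]] >= 0 && p[[key]] <= 1, key,
        "must be a fraction in [0, 1]")
  }
  for (key in c("total_cells", "synapses_per_mature_cell", "maturation_span",
                "prolif_scale", "prolif_age_offset", "strength_age_offset",
                "ko_onset_day", "horizon")) {
    chk(num1(p[[key]]) && p[[key]] > 0, key, "must be strictly positive")
  }
  chk(p$mature_fraction > 0 && p$mature_fraction < 1, "mature_fraction",
      "must lie strictly inside (0, 1)")
  for (key in c("strength_slope", "strength_intercept", "prolif_exponent")) {
    chk(num1(p[[key]]), key, "must be a finite number")
  }
  chk(num1(p$ko_strength_factor) && p$ko_strength_factor >= 1,
      "ko_strength_factor", "must be >= 1")
  chk(is.logical(p$include_baseline_in_numerator) &&
        length(p$include_baseline_in_numerator) == 1L &&
        !is.na(p$include_baseline_in_numerator),
      "include_baseline_in_numerator", "must be TRUE or FALSE")
  chk(p$horizon <= p$maturation_span, "horizon",
      "must not exceed maturation_span (cohorts never mature in-window)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Synapse-redistribution model parameters\n")
  cat(sprintf("  %-30s %s\n", names(x),
              vapply(x, function(v) format(v, big.mark = ","), character(1))),
      sep = "")
  invisible(x)
}
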