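#' Configuration of the synthetic recording generator
#'
#' Parameters of the seeded generators that emulate the statistical structure
#' of the slice recordings: a saturating fiber-volley recruitment curve with
#' per-slice gain variability, linear EPSC-vs-FV and fEPSP-vs-FV relations
#' with group-specific gains, multiplicative noise, saturation dropout at
#' high intensity, and Poisson spontaneous-event trains with lognormal
#' amplitudes. Group effects enter only through the EPSC gain and event rate,
#' mirroring the experimental finding that fiber volleys and fEPSPs were
#' unchanged by the manipulations.
#'
#' Defaults represent a typical recording session: 15 slices per group,
#' stimulation at 10..100 V, maximal fiber volley 400 uV with
#' half-saturation at 30 V, 20% slice-to-slice gain variability, 15%
#' multiplicative noise, and an EPSC/FV gain of 2.44 pA/uV for the
#' control-mature preset (the measured control-mature ratio; see
#' [epsc_gain_presets()]).
#'
#' @param n_slices_per_group Slices (one recorded cell each) per group.
#' @param intensities Stimulus intensities, volts (within 0..100 V).
#' @param fv_max Asymptotic fiber-volley amplitude, microvolts.
#' @param fv_half_sat Stimulus intensity (V) recruiting half of `fv_max`.
#' @param slice_gain_cv Coefficient of variation of the per-slice recruitment
#'   gain.
#' @param fepsp_gain fEPSP slope per uV of fiber volley.
#' @param epsc_gain_by_group Named vector: EPSC/FV gain (pA/uV) per group.
#' @param noise_cv Coefficient of variation of the per-sweep multiplicative
#'   noise.
#' @param saturation_threshold Fraction of `fv_max` above which a response is
#'   flagged saturated.
#' @param ppr_true True paired-pulse depression factor (second/first pulse).
#' @param event_rate_by_group Named vector: spontaneous-event rate (Hz) per
#'   group.
#' @param event_amp_mu,event_amp_sigma Log-scale mean and sd of the lognormal
#'   event-amplitude distribution (pA).
#' @param seed Integer seed; mandatory — the generators use no implicit
#'   entropy.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_slices_per_group = 15,
                             intensities = seq(10, 100, by = 10),
                             fv_max = 400,
                             fv_half_sat = 30,
                             slice_gain_cv = 0.2,
                             fepsp_gain = 0.004,
                             epsc_gain_by_group = c(control = 2.44),
                             noise_cv = 0.15,
                             saturation_threshold = 0.85,
                             ppr_true = 0.9,
                             event_rate_by_group = c(control = 0.5),
                             event_amp_mu = log(15),
                             event_amp_sigma = 0.5,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory: the generators use no implicit entropy",
         call. = FALSE)
  }
  cfg <- list(
    n_slices_per_group = n_slices_per_group,
    intensities = intensities,
    fv_max = fv_max,
    fv_half_sat = fv_half_sat,
    slice_gain_cv = slice_gain_cv,
    fepsp_gain = fepsp_gain,
    epsc_gain_by_group = epsc_gain_by_group,
    noise_cv = noise_cv,
    saturation_threshold = saturation_threshold,
    ppr_true = ppr_true,
    event_rate_by_group = event_rate_by_group,
    event_amp_mu = event_amp_mu,
    event_amp_sigma = event_amp_sigma,
    seed = as.integer(seed)
  )
  pos <- c("n_slices_per_group", "fv_max", "fv_half_sat", "fepsp_gain",
           "saturation_threshold", "ppr_true", "event_amp_sigma")
  for (key in pos) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L || cfg[[key]] <= 0) {
      stop("generator parameter `", key, "` must be a positive number",
           call. = FALSE)
    }
  }
  for (key in c("slice_gain_cv", "noise_cv")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) {
      stop("generator parameter `", key, "` must be non-negative",
           call. = FALSE)
    }
  }
  if (any(cfg$intensities <= 0) || any(cfg$intensities > 100)) {
    stop("intensities must lie in (0, 100] V", call. = FALSE)
  }
  if (is.null(names(cfg$epsc_gain_by_group)) ||
        any(cfg$epsc_gain_by_group <= 0)) {
    stop("epsc_gain_by_group must be a named vector of positive gains",
         call. = FALSE)
  }
  if (any(cfg$event_rate_by_group < 0)) {
    stop("event rates must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Measured EPSC/FV gains usable as generator presets
#'
#' Named EPSC/FV ratios (pA/uV) echoing the measured group means, for use in
#' `epsc_gain_by_group`: control mature cells 2.44 and control immature cells
#' 1.24; neurogenesis-ablated mice 3.7 against their controls at 2.2;
#' environmental enrichment 2.6 against controls at 1.6 (also the scale of
#' the mature-cell reduction seen with enhanced neurogenesis).
#'
#' @return A named numeric vector of gains.
#' @export
epsc_gain_presets <- function() {
  c(control_mature = 2.44,
    control_immature = 1.24,
    baxko_im_mature = 1.6,
    ablated_im_mature = 3.7,
    ablated_control_mature = 2.2,
    ee_mature = 2.6,
    ee_control_mature = 1.6)
}

#' Two-group generator configuration for a named experiment
#'
#' Convenience constructor pairing each manipulated condition with its
#' control at the measured gains: `"baxko_im"` (2.44 vs 1.6), `"ablated_im"`
#' (2.2 vs 3.7), `"ee"` (1.6 vs 2.6), or the single-group `"control"`
#' (2.44).
#'
#' @param preset One of `"control"`, `"baxko_im"`, `"ablated_im"`, `"ee"`.
#' @param seed Integer seed.
#' @param ... Further arguments to [generator_config()].
#' @return A `"generator_config"`.
#' @export
preset_config <- function(preset = c("control", "baxko_im", "ablated_im", "ee"),
                          seed, ...) {
  preset <- match.arg(preset)
  g <- epsc_gain_presets()
  gains <- switch(preset,
    control = c(control = unname(g["control_mature"])),
    baxko_im = c(control = unname(g["control_mature"]),
                 baxko_im = unname(g["baxko_im_mature"])),
    ablated_im = c(control = unname(g["ablated_control_mature"]),
                   ablated_im = unname(g["ablated_im_mature"])),
    ee = c(control = unname(g["ee_control_mature"]),
           ee = unname(g["ee_mature"]))
  )
  generator_config(epsc_gain_by_group = gains, seed = seed, ...)
}

# multiplicative noise factor 1 + cv*z, truncated so magnitudes stay positive
noise_factor <- function(n, cv) {
  pmax(1 + cv * stats::rnorm(n), 0.1)
}

# run expr with a private, restored RNG state
with_generator_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic sweep table
#'
#' Emulates the increasing-intensity stimulation protocol with simultaneous
#' fiber-volley, fEPSP and EPSC measurement. Each slice draws a recruitment
#' gain; at each intensity `I`, each of 10 sweeps gets
#' `FV = gain * fv_max * I / (I + fv_half_sat) * (1 + noise)`, a fEPSP slope
#' and an EPSC proportional to that sweep's FV (with independent noise and the
#' group's EPSC gain), and is flagged saturated when the FV exceeds
#' `saturation_threshold * fv_max`. Output is byte-identical for identical
#' config and seed.
#'
#' @param config A [generator_config()].
#' @param sweeps_per_intensity Sweeps delivered at each intensity.
#' @return A sweep table (see [average_by_intensity()] for the schema).
#' @export
make_sweeps <- function(config, sweeps_per_intensity = 10) {
  stopifnot(inherits(config, "generator_config"))
  with_generator_seed(config$seed, {
    groups <- names(config$epsc_gain_by_group)
    out <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      gains <- config$epsc_gain_by_group[[g]] # pA/uV for this group
      slice_gain <- pmax(1 + config$slice_gain_cv *
                           stats::rnorm(config$n_slices_per_group), 0.1)
      grid <- expand.grid(
        sweep = seq_len(sweeps_per_intensity),
        stimulus_v = config$intensities,
        slice = seq_len(config$n_slices_per_group)
      )
      n <- nrow(grid)
      drive <- slice_gain[grid$slice] * config$fv_max *
        grid$stimulus_v / (grid$stimulus_v + config$fv_half_sat)
      fv <- drive * noise_factor(n, config$noise_cv)
      fepsp <- config$fepsp_gain * fv * noise_factor(n, config$noise_cv)
      epsc <- gains * fv * noise_factor(n, config$noise_cv)
      out[[gi]] <- data.frame(
        slice_id = sprintf("%s_s%02d", g, grid$slice),
        group = g,
        cell_id = sprintf("%s_s%02d_c1", g, grid$slice),
        stimulus_v = grid$stimulus_v,
        fv_uv = fv,
        fepsp_slope = fepsp,
        epsc_pa = epsc,
        saturated = fv > config$saturation_threshold * config$fv_max
      )
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic spontaneous-event trains
#'
#' Homogeneous Poisson event times over the recording duration with lognormal
#' amplitudes, one train per cell per group at the group's event rate.
#'
#' @param config A [generator_config()].
#' @param n_cells Cells per group.
#' @param duration Recording duration per cell, seconds.
#' @return A list of event trains: each a list with `cell_id`, `group`,
#'   `duration` and an `events` data frame (`time`, `amplitude`), times
#'   sorted.
#' @export
make_event_trains <- function(config, n_cells = 10, duration = 120) {
  stopifnot(inherits(config, "generator_config"))
  if (duration <= 0 || n_cells < 1) {
    stop("need positive duration and at least one cell", call. = FALSE)
  }
  with_generator_seed(config$seed, {
    trains <- list()
    for (g in names(config$event_rate_by_group)) {
      rate <- config$event_rate_by_group[[g]]
      for (cell in seq_len(n_cells)) {
        n_ev <- stats::rpois(1, rate * duration)
        trains[[length(trains) + 1L]] <- list(
          cell_id = sprintf("%s_c%02d", g, cell),
          group = g,
          duration = duration,
          events = data.frame(
            time = sort(stats::runif(n_ev, 0, duration)),
            amplitude = stats::rlnorm(n_ev, config$event_amp_mu,
                                      config$event_amp_sigma)
          )
        )
      }
    }
    trains
  })
}

#' Generate a pair of count samples around target means
#'
#' Stereology-like fixture for percent-change demonstrations: rounded normal
#' draws around a reference and a test mean with a common coefficient of
#' variation.
#'
#' @param mean_ref,mean_test Target group means (must be positive).
#' @param cv Coefficient of variation of the draws.
#' @param n Animals per group (>= 2).
#' @param seed Integer seed.
#' @return A list with numeric vectors `reference` and `test`.
#' @export
make_count_pair <- function(mean_ref, mean_test, cv = 0.1, n = 4, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (mean_ref <= 0 || mean_test <= 0) stop("means must be positive",
                                            call. = FALSE)
  if (n < 2) stop("need n >= 2 per group", call. = FALSE)
  with_generator_seed(seed, {
    list(
      reference = round(stats::rnorm(n, mean_ref, cv * mean_ref)),
      test = round(stats::rnorm(n, mean_test, cv * mean_test))
    )
  })
}
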