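#' Load a model or generator configuration from file
#'
#' Reads a flat key-value configuration (YAML or JSON; a JSON file is valid
#' YAML) whose keys mirror the constructor arguments exactly. Omitted keys
#' take the constructor defaults (the published parameter set for the model);
#' unknown keys are an error, naming the offending key. An empty file yields
#' all defaults.
#'
#' @param path Path to the configuration file.
#' @param type `"model_params"` or `"generator_config"`.
#' @return A validated [model_params()] or [generator_config()] object.
#' @export
load_config <- function(path, type = c("model_params", "generator_config")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a flat key-value mapping",
                          call. = FALSE)
  ctor <- if (type == "model_params") model_params else generator_config
  known <- names(formals(ctor))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (type == "generator_config" && "epsc_gain_by_group" %in% names(cfg)) {
    cfg$epsc_gain_by_group <- unlist(cfg$epsc_gain_by_group)
  }
  if (type == "generator_config" && "event_rate_by_group" %in% names(cfg)) {
    cfg$event_rate_by_group <- unlist(cfg$event_rate_by_group)
  }
  do.call(ctor, cfg)
}

#' Save a configuration to JSON
#'
#' Writes the resolved parameter set to a JSON file that [load_config()]
#' reads back to an identical object.
#'
#' @param config A `model_params` or `generator_config` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  # named-vector maps serialize as JSON objects, not bare arrays
  for (key in c("epsc_gain_by_group", "event_rate_by_group")) {
    if (!is.null(x[[key]])) x[[key]] <- as.list(x[[key]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sweep table from CSV
#'
#' Ingests tabular evoked responses (one row per sweep) with columns
#' `slice_id, group, cell_id, stimulus_v, fv_uv, fepsp_slope, epsc_pa,
#' saturated` (header required, '.' decimal). Response magnitudes are
#' normalised on ingest: amplitudes and slopes are stored as magnitudes
#' (inward currents positive), and the saturation flag is coerced to
#' logical.
#'
#' @param path CSV path.
#' @return A sweep table data frame.
#' @export
read_sweeps <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_sweep_table(x)
  if (any(x$stimulus_v < 0 | x$stimulus_v > 100)) {
    stop("stimulus intensities must lie within 0..100 V", call. = FALSE)
  }
  x$fv_uv <- abs(x$fv_uv)
  x$fepsp_slope <- abs(x$fepsp_slope)
  x$epsc_pa <- abs(x$epsc_pa)
  x$saturated <- as.logical(x$saturated)
  if (anyNA(x$saturated)) stop("saturated column must be logical (TRUE/FALSE)",
                               call. = FALSE)
  x
}

#' Read event trains from CSV
#'
#' Ingests detected-event tables with columns `cell_id, group, duration_s,
#' time_s, amplitude_pa`, one row per event (cells with no events appear as a
#' single row with `NA` time and amplitude).
#'
#' @param path CSV path.
#' @return A list of event trains (see [event_summary()]).
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "group", "duration_s", "time_s", "amplitude_pa")
  if (!all(need %in% names(x))) {
    stop("expected columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(x, x$cell_id), function(cell) {
    ev <- cell[!is.na(cell$time_s), , drop = FALSE]
    ev <- ev[order(ev$time_s), , drop = FALSE]
    list(
      cell_id = cell$cell_id[1L],
      group = cell$group[1L],
      duration = cell$duration_s[1L],
      events = data.frame(time = ev$time_s, amplitude = ev$amplitude_pa)
    )
  })
}

#' Write event trains to CSV
#'
#' Inverse of [read_events()]: one row per event; a train with no events
#' writes a single row with `NA` time and amplitude so its duration is
#' preserved.
#'
#' @param trains A list of event trains.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (nrow(tr$events) == 0L) {
      data.frame(cell_id = tr$cell_id, group = tr$group,
                 duration_s = tr$duration, time_s = NA_real_,
                 amplitude_pa = NA_real_)
    } else {
      data.frame(cell_id = tr$cell_id, group = tr$group,
                 duration_s = tr$duration, time_s = tr$events$time,
                 amplitude_pa = tr$events$amplitude)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest alongside outputs
#'
#' Records provenance for a run: the command, an md5 digest of the resolved
#' configuration, the seed (if any), the output paths and a timestamp, as
#' `manifest.json` in the output directory.
#'
#' @param command Label of the command that ran.
#' @param config The resolved configuration object used.
#' @param outputs Character vector of files written.
#' @param out_dir Directory receiving the manifest.
#' @param seed Seed used, or `NULL` for deterministic commands.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(command, config, outputs, out_dir, seed = NULL) {
  cfg_file <- file.path(out_dir, "config_resolved.json")
  save_config(config, cfg_file)
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = if (is.null(seed)) NA else seed,
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reproduce the redistribution figure
#'
#' Runs the simulation under both conditions, writes the trajectories and the
#' day-36..43 mature-synapse ratio as CSV, and renders the two-line
#' percent-vs-day chart plus the ratio bar series. Fully deterministic.
#'
#' @param params A [model_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param window Days over which to form the knockout/control mature ratio.
#' @return Invisibly, a list with the `trajectories` and `ratio` data frames
#'   and the output file paths.
#' @export
reproduce_figure9 <- function(params = model_params(), out_dir,
                              window = 36:43) {
  if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  ctrl <- run_simulation(params, "control")
  ko <- run_simulation(params, "bax_ko")
  traj <- rbind(as.data.frame(ctrl), as.data.frame(ko))
  ratio <- predicted_mature_ratio(ko, ctrl, window)

  traj_csv <- file.path(out_dir, "trajectories.csv")
  ratio_csv <- file.path(out_dir, "mature_ratio.csv")
  utils::write.csv(traj, traj_csv, row.names = FALSE)
  utils::write.csv(ratio, ratio_csv, row.names = FALSE)

  long <- rbind(
    data.frame(day = traj$day, condition = traj$condition,
               population = "mature", pct = traj$pct_mature),
    data.frame(day = traj$day, condition = traj$condition,
               population = "immature", pct = traj$pct_immature)
  )
  p_share <- ggplot2::ggplot(long,
    ggplot2::aes(x = day, y = pct, colour = condition,
                 linetype = population)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "day", y = "% of synapse pool",
                  title = "Synapse share of mature vs immature granule cells") +
    ggplot2::theme_classic()
  p_ratio <- ggplot2::ggplot(ratio,
    ggplot2::aes(x = factor(day), y = ratio_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "day", y = "mature synapses, knockout/control (%)",
                  title = "Predicted mature-synapse ratio") +
    ggplot2::theme_classic()
  share_png <- file.path(out_dir, "synapse_share.png")
  ratio_png <- file.path(out_dir, "mature_ratio.png")
  ggplot2::ggsave(share_png, p_share, width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(ratio_png, p_ratio, width = 5, height = 4, dpi = 150)

  outputs <- c(traj_csv, ratio_csv, share_png, ratio_png)
  write_manifest("reproduce-fig9", params, outputs, out_dir)
  invisible(list(trajectories = traj, ratio = ratio, outputs = outputs))
}
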