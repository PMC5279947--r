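#' Average repeated sweeps at each stimulus intensity
#'
#' Collapses the repeated stimuli delivered at each intensity (10 per
#' intensity in the recording protocol) into one response per
#' (cell, intensity): arithmetic means of fiber-volley amplitude, fEPSP slope
#' and EPSC amplitude, with the saturation flag decided by majority vote
#' (ties count as saturated).
#'
#' @param sweeps A sweep table: data frame with columns `slice_id`, `group`,
#'   `cell_id`, `stimulus_v`, `fv_uv`, `fepsp_slope`, `epsc_pa`, `saturated`.
#' @param sweeps_per_intensity Optional expected sweep count per
#'   (cell, intensity); a deviation raises a warning (recordings are
#'   occasionally truncated).
#' @return A sweep table with one row per (slice, cell, intensity).
#' @export
average_by_intensity <- function(sweeps, sweeps_per_intensity = NULL) {
  check_sweep_table(sweeps)
  if (nrow(sweeps) == 0L) stop("empty sweep table", call. = FALSE)
  key <- interaction(sweeps$slice_id, sweeps$group, sweeps$cell_id,
                     sweeps$stimulus_v, drop = TRUE, lex.order = TRUE)
  if (!is.null(sweeps_per_intensity)) {
    cnt <- table(key)
    if (any(cnt != sweeps_per_intensity)) {
      warning("some (cell, intensity) groups do not have ",
              sweeps_per_intensity, " sweeps", call. = FALSE)
    }
  }
  idx <- split(seq_len(nrow(sweeps)), key)
  rows <- lapply(idx, function(i) {
    s <- sweeps[i, , drop = FALSE]
    data.frame(
      slice_id = s$slice_id[1L],
      group = s$group[1L],
      cell_id = s$cell_id[1L],
      stimulus_v = s$stimulus_v[1L],
      fv_uv = mean(s$fv_uv),
      fepsp_slope = mean(s$fepsp_slope),
      epsc_pa = mean(s$epsc_pa),
      saturated = mean(s$saturated) >= 0.5
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$slice_id, out$cell_id, out$stimulus_v), ,
      drop = FALSE]
}

#' Drop saturated responses
#'
#' Removes responses flagged as saturated before any downstream statistic, so
#' that responses exhibiting saturation of axonal recruitment drop out of the
#' analysis (hence fewer observations at high stimulus intensities). Row
#' order is preserved.
#'
#' @param responses A sweep table (usually from [average_by_intensity()]).
#' @return The table with saturated rows removed; warns if nothing remains.
#' @export
exclude_saturated <- function(responses) {
  check_sweep_table(responses)
  out <- responses[!responses$saturated, , drop = FALSE]
  if (nrow(out) == 0L && nrow(responses) > 0L) {
    warning("all responses are saturated; returning an empty table",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Flag saturated responses by a plateau rule
#'
#' Fallback saturation detector for tables without an explicit flag: within
#' each cell, a (cell, intensity) response is flagged saturated when its mean
#' fiber-volley amplitude is within `tol` of the cell's maximum and the
#' next-lower intensity is also within `tol` — i.e. the recruitment curve has
#' plateaued. A reproducible stand-in for the operator judgment used at the
#' rig.
#'
#' @param responses An averaged sweep table.
#' @param tol Plateau tolerance as a fraction of the per-cell maximum FV.
#' @return The table with its `saturated` column replaced by the rule.
#' @export
flag_saturated <- function(responses, tol = 0.05) {
  check_sweep_table(responses)
  idx <- split(seq_len(nrow(responses)),
               interaction(responses$slice_id, responses$cell_id, drop = TRUE))
  sat <- logical(nrow(responses))
  for (i in idx) {
    ord <- i[order(responses$stimulus_v[i])]
    fv <- responses$fv_uv[ord]
    near_max <- fv >= (1 - tol) * max(fv)
    plateau <- near_max & c(FALSE, near_max[-length(near_max)])
    sat[ord] <- plateau
  }
  responses$saturated <- sat
  responses
}

#' Bin responses by fiber-volley amplitude
#'
#' Assigns each response to a half-open fiber-volley bin
#' `[k*w, (k+1)*w)` anchored at 0 uV and summarises the chosen response
#' measure per (group, bin): mean, SEM and n. Binning by the simultaneously
#' recorded fiber volley normalises for differences in the number of
#' stimulated axons across slices and removes stimulus intensity from the
#' data set. Empty bins are omitted; SEM is `NA` for singleton bins.
#'
#' @param responses A non-saturated sweep table.
#' @param bin_width Bin width in microvolts (100 uV or 75 uV in the published
#'   figures).
#' @param measure `"epsc"` (EPSC amplitude, pA) or `"fepsp_slope"`.
#' @return A binned summary: data frame with columns `group`, `bin_low`,
#'   `bin_high`, `mean_response`, `sem`, `n`.
#' @export
bin_by_fiber_volley <- function(responses, bin_width = 100,
                                measure = c("epsc", "fepsp_slope")) {
  measure <- match.arg(measure)
  check_sweep_table(responses)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number of microvolts", call. = FALSE)
  }
  if (nrow(responses) == 0L) stop("no responses to bin", call. = FALSE)
  y <- responses[[if (measure == "epsc") "epsc_pa" else "fepsp_slope"]]
  k <- floor(responses$fv_uv / bin_width)
  key <- interaction(responses$group, k, drop = TRUE)
  idx <- split(seq_len(nrow(responses)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    n <- length(i)
    data.frame(
      group = responses$group[i[1L]],
      bin_low = k[i[1L]] * bin_width,
      bin_high = (k[i[1L]] + 1) * bin_width,
      mean_response = mean(y[i]),
      sem = if (n >= 2L) stats::sd(y[i]) / sqrt(n) else NA_real_,
      n = n
    )
  }))
  out <- out[order(out$group, out$bin_low), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "bin_width") <- bin_width
  out
}

#' Per-response response/FV ratios and group summary
#'
#' The per-response synaptic-strength statistic: response measure divided by
#' the simultaneously recorded fiber-volley amplitude (pA/uV for EPSCs),
#' summarised per group as mean +/- SEM over responses. Rows with zero FV
#' cannot be normalised and are dropped with a warning.
#'
#' @inheritParams bin_by_fiber_volley
#' @return A list with `ratios` (the input rows plus a `ratio` column) and
#'   `summary` (per group: `mean_ratio`, `sem`, `n`).
#' @export
response_fv_ratio <- function(responses, measure = c("epsc", "fepsp_slope")) {
  measure <- match.arg(measure)
  check_sweep_table(responses)
  bad <- responses$fv_uv <= 0
  if (any(bad)) {
    warning(sum(bad), " response(s) with non-positive fiber volley excluded",
            call. = FALSE)
    responses <- responses[!bad, , drop = FALSE]
  }
  y <- responses[[if (measure == "epsc") "epsc_pa" else "fepsp_slope"]]
  responses$ratio <- y / responses$fv_uv
  grp <- split(responses$ratio, responses$group)
  summary <- data.frame(
    group = names(grp),
    mean_ratio = vapply(grp, mean, numeric(1)),
    sem = vapply(grp, function(r) {
      if (length(r) >= 2L) stats::sd(r) / sqrt(length(r)) else NA_real_
    }, numeric(1)),
    n = vapply(grp, length, integer(1))
  )
  rownames(summary) <- NULL
  list(ratios = responses, summary = summary)
}

#' Paired-pulse ratio
#'
#' Amplitude of the second evoked response divided by the first (100 ms
#' inter-stimulus interval in the recordings); a proxy for presynaptic
#' release probability.
#'
#' @param amp1,amp2 First and second response amplitudes (pA); vectorised.
#' @return `amp2 / amp1`.
#' @export
paired_pulse_ratio <- function(amp1, amp2) {
  if (!is.numeric(amp1) || !is.numeric(amp2) || anyNA(amp1) || anyNA(amp2)) {
    stop("amplitudes must be numeric", call. = FALSE)
  }
  if (any(amp1 <= 0)) {
    stop("first-pulse amplitude must be positive", call. = FALSE)
  }
  amp2 / amp1
}

#' Frequency and mean amplitude of an event train
#'
#' Summarises a detected spontaneous or asynchronous EPSC train: event
#' frequency (count over recording duration, Hz) and mean event amplitude
#' (pA). An empty train has frequency 0 and undefined (`NA`) amplitude.
#'
#' @param train An event train: list with fields `cell_id`, `duration`
#'   (seconds) and `events` (data frame with `time`, `amplitude`).
#' @return A list with `frequency` (Hz) and `mean_amplitude` (pA or `NA`).
#' @export
event_summary <- function(train) {
  if (!is.list(train) || is.null(train$duration) || is.null(train$events)) {
    stop("train must have fields duration and events", call. = FALSE)
  }
  if (!is.numeric(train$duration) || train$duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  ev <- train$events
  n <- nrow(ev)
  if (n > 0L) {
    if (any(ev$time < 0 | ev$time >= train$duration)) {
      stop("event times must lie in [0, duration)", call. = FALSE)
    }
    if (is.unsorted(ev$time)) stop("event times must be sorted", call. = FALSE)
  }
  list(
    frequency = n / train$duration,
    mean_amplitude = if (n > 0L) mean(ev$amplitude) else NA_real_
  )
}

#' Percent change between two group means
#'
#' Reporting convention for cell-count comparisons: the change of the test
#' mean relative to the reference mean, in percent, rounded to the nearest
#' integer.
#'
#' @param reference_mean,test_mean Group means; `reference_mean` must be
#'   positive. Vectorised.
#' @return Rounded percent change, `100 * (test - reference) / reference`.
#' @examples
#' percent_change(16881, 23756) # +41
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (!is.numeric(reference_mean) || any(reference_mean <= 0)) {
    stop("reference_mean must be positive", call. = FALSE)
  }
  round(100 * (test_mean - reference_mean) / reference_mean)
}

#' Unweighted-means two-factor ANOVA on a binned summary
#'
#' Factorial comparison of groups across fiber-volley bins when cell sizes
#' are unequal (responses drop out at high intensity), using the
#' unweighted-means analysis: main-effect and interaction sums of squares are
#' computed from the unweighted cell means with the harmonic mean of the cell
#' sizes in place of n, and the error mean square is the pooled within-cell
#' variance with `N - cells` degrees of freedom. On a balanced design this
#' reduces exactly to the standard two-way ANOVA.
#'
#' Bins not observed in every group (the non-overlapping tails of the
#' recruitment curves) are dropped before testing; at least two groups and
#' two shared bins, each cell with n >= 2, are required.
#'
#' @param binned A binned summary from [bin_by_fiber_volley()] containing two
#'   or more groups (columns `group`, `bin_low`, `mean_response`, `sem`,
#'   `n`).
#' @return A data frame with one row per effect (`group`, `bin`,
#'   `group:bin`) and columns `df1`, `df2`, `F`, `p`.
#' @export
unweighted_means_test <- function(binned) {
  need <- c("group", "bin_low", "mean_response", "sem", "n")
  if (!all(need %in% names(binned))) {
    stop("binned summary must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(binned$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  shared <- Reduce(intersect,
                   lapply(split(binned$bin_low, binned$group), unique))
  binned <- binned[binned$bin_low %in% shared, , drop = FALSE]
  bins <- sort(unique(binned$bin_low))
  if (length(bins) < 2L) {
    stop("need at least 2 fiber-volley bins shared by every group",
         call. = FALSE)
  }
  if (any(binned$n < 2L)) {
    stop("every (group, bin) cell needs n >= 2", call. = FALSE)
  }
  a <- length(groups)
  b <- length(bins)
  m <- matrix(NA_real_, a, b, dimnames = list(groups, bins))
  nn <- sem <- m
  for (i in seq_len(nrow(binned))) {
    g <- as.character(binned$group[i])
    bl <- as.character(binned$bin_low[i])
    m[g, bl] <- binned$mean_response[i]
    nn[g, bl] <- binned$n[i]
    sem[g, bl] <- binned$sem[i]
  }
  if (anyNA(m)) stop("every (group, bin) cell needs n >= 2", call. = FALSE)

  n_h <- a * b / sum(1 / nn)          # harmonic mean of cell sizes
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_group <- n_h * b * sum((row_m - grand)^2)
  ss_bin <- n_h * a * sum((col_m - grand)^2)
  ss_int <- n_h * sum((m - outer(row_m, rep(1, b)) -
                         outer(rep(1, a), col_m) + grand)^2)
  # pooled within-cell variance from sem = sd/sqrt(n)
  ss_err <- sum((nn - 1) * sem^2 * nn)
  df_err <- sum(nn) - a * b
  ms_err <- ss_err / df_err

  eff <- data.frame(
    effect = c("group", "bin", "group:bin"),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = df_err
  )
  ss <- c(ss_group, ss_bin, ss_int)
  eff$F <- (ss / eff$df1) / ms_err
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff
}

# schema guard shared by the pipeline verbs
check_sweep_table <- function(x) {
  need <- c("slice_id", "group", "cell_id", "stimulus_v", "fv_uv",
            "fepsp_slope", "epsc_pa", "saturated")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("expected a sweep table with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
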