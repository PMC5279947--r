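# Independent oracles and fixture builders shared across tests.

# Brute-force immature synapse load: expand the ledger to explicit per-cell
# records (one row per individual cell) and sum each cell's contribution.
# Only usable with integer cell counts.
brute_force_load <- function(t, ledger, params) {
  total <- 0
  for (i in seq_len(nrow(ledger))) {
    k <- ledger$incorporation_day[i]
    if (k > t) next
    for (cell in seq_len(ledger$cells[i])) {
      y <- synaptic_strength(t - k + 1, params)
      total <- total + ledger$strength_multiplier[i] * y / 100 *
        params$synapses_per_mature_cell
    }
  }
  total
}

# Unweighted-means ANOVA oracle: the cell-mean decomposition is delegated to
# stats::aov on one observation per cell (an independent route to the
# unweighted sums of squares), scaled by the harmonic mean of cell sizes;
# the error term is pooled within-cell variance accumulated in a plain loop.
unweighted_means_oracle <- function(values, group, bin) {
  cells <- split(values, interaction(group, bin, drop = TRUE))
  g <- vapply(strsplit(names(cells), "\\."), `[`, character(1), 1L)
  b <- vapply(strsplit(names(cells), "\\."), `[`, character(1), 2L)
  cm <- vapply(cells, mean, numeric(1))
  ns <- vapply(cells, length, integer(1))
  n_h <- length(cells) / sum(1 / ns)
  fit <- stats::aov(cm ~ factor(g) * factor(b))
  # the saturated cell-mean fit has zero residual df; only its SS
  # decomposition is used, so anova()'s F-test warning is expected
  tab <- suppressWarnings(stats::anova(fit))
  ss <- n_h * tab[["Sum Sq"]][1:3]
  df <- tab[["Df"]][1:3]
  ss_err <- 0
  df_err <- 0
  for (cell in cells) {
    ss_err <- ss_err + sum((cell - mean(cell))^2)
    df_err <- df_err + length(cell) - 1L
  }
  ms_err <- ss_err / df_err
  data.frame(
    effect = c("group", "bin", "group:bin"),
    df1 = df, df2 = df_err,
    F = (ss / df) / ms_err,
    p = stats::pf((ss / df) / ms_err, df, df_err, lower.tail = FALSE)
  )
}

# Binned summary (group, bin_low, mean_response, sem, n) built directly from
# raw values, bypassing bin_by_fiber_volley.
binned_from_raw <- function(values, group, bin_low) {
  key <- interaction(group, bin_low, drop = TRUE)
  cells <- split(seq_along(values), key)
  out <- do.call(rbind, lapply(cells, function(i) {
    data.frame(
      group = group[i[1L]],
      bin_low = bin_low[i[1L]],
      mean_response = mean(values[i]),
      sem = stats::sd(values[i]) / sqrt(length(i)),
      n = length(i)
    )
  }))
  rownames(out) <- NULL
  out
}

# Minimal hand-built sweep table.
sweep_rows <- function(fv, epsc, group = "g1", slice = "s1",
                       stimulus_v = seq_along(fv) * 10,
                       fepsp = 0.004 * fv, saturated = FALSE) {
  data.frame(
    slice_id = slice, group = group, cell_id = paste0(slice, "_c1"),
    stimulus_v = stimulus_v, fv_uv = fv, fepsp_slope = fepsp,
    epsc_pa = epsc, saturated = saturated
  )
}
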