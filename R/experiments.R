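#' Run replicate simulations of one condition
#'
#' Runs `n_reps` independent simulations of the same parameters, with seeds
#' from [derive_seed()] so rows are reproducible and independent of
#' execution order.
#'
#' @param params A `fairplay_params` object.
#' @param n_reps Number of replicates.
#' @param base_seed Sweep-level base seed.
#' @param config_index Zero-based condition index used in seed derivation.
#' @return A data frame with one row per run: the swept fields (`R`, `p`,
#'   `c`, `d`, `P`), `control`, `replicate`, `seed`,
#'   `gene_birth_frequency`, `play_mortality_percent`, `births_in_window`,
#'   `extinct`, `extinction_step`.
#' @export
run_replicates <- function(params, n_reps, base_seed, config_index = 0L) {
  stopifnot(n_reps >= 1L)
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    seed <- derive_seed(base_seed, config_index, k - 1L)
    sim <- run_simulation(params, seed)
    rows[[k]] <- data.frame(
      R = params$R, p = params$p, c = params$c, d = params$d, P = params$P,
      control = !params$learn_fairness, replicate = k - 1L, seed = seed,
      gene_birth_frequency = as.numeric(sim$gene_birth_frequency),
      play_mortality_percent = sim$play_mortality_percent,
      births_in_window = sim$births_in_window,
      extinct = sim$extinct, extinction_step = sim$extinction_step
    )
  }
  do.call(rbind, rows)
}

#' Run the matched control for one condition
#'
#' Identical dynamics except fairness is never learned: juveniles still play
#' and still pay the per-bout mortality cost `c`, isolating play's cost from
#' its benefit.
#'
#' @inheritParams run_replicates
#' @return As [run_replicates()], with `control = TRUE` rows.
#' @export
run_control <- function(params, n_reps, base_seed, config_index = 0L) {
  run_replicates(fp_update(params, learn_fairness = FALSE),
                 n_reps, base_seed, config_index)
}

#' Run every row of an enumerated sweep
#'
#' @param spec A `fairplay_sweep` specification.
#' @param base Base parameters supplying all non-swept fields.
#' @param checkpoint Optional CSV path: completed rows are appended as they
#'   finish, and rows already present (matched by seed) are skipped, so an
#'   interrupted sweep resumes without duplicating work.
#' @param progress Print one line per completed run.
#' @return The full result table (one row per run, as [run_replicates()]).
#' @export
run_sweep <- function(spec, base = fp_params(), checkpoint = NULL,
                      progress = FALSE) {
  runs <- enumerate_sweep(spec)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    runs <- runs[!(runs$seed %in% done$seed), , drop = FALSE]
  }
  rows <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    row <- runs[i, ]
    params <- sweep_params(row, base)
    sim <- run_simulation(params, row$seed)
    out <- data.frame(
      R = params$R, p = params$p, c = params$c, d = params$d, P = params$P,
      control = !params$learn_fairness, replicate = row$replicate,
      seed = row$seed,
      gene_birth_frequency = as.numeric(sim$gene_birth_frequency),
      play_mortality_percent = sim$play_mortality_percent,
      births_in_window = sim$births_in_window,
      extinct = sim$extinct, extinction_step = sim$extinction_step
    )
    rows[[i]] <- out
    if (!is.null(checkpoint)) {
      fresh <- !file.exists(checkpoint)
      utils::write.table(out, checkpoint, sep = ",", row.names = FALSE,
                         col.names = fresh, append = !fresh)
    }
    if (progress)
      message(sprintf("run %d/%d (seed %d) done", i, nrow(runs), row$seed))
  }
  res <- do.call(rbind, c(list(done), rows))
  rownames(res) <- NULL
  res
}

#' Average evolved frequencies over reproductive delays
#'
#' Means of the play-gene birth frequency per `(R, p, c)` cell for one
#' parental-investment level, averaged over replicates and over the delay
#' grid. For `P = 0.1` the averaging window is restricted to `d <= 45`
#' because larger delays often drive those populations extinct. Extinct or
#' undefined-frequency runs are excluded from the mean and counted in the
#' `n_excluded` column.
#'
#' @param table A result table from [run_sweep()] or [run_replicates()].
#' @param P_value The parental investment level to aggregate.
#' @return A data frame with one row per `(R, p, c)` cell: `mean_frequency`,
#'   `se_frequency`, `n_runs`, `n_excluded`.
#' @export
aggregate_over_delays <- function(table, P_value) {
  d_max <- if (isTRUE(all.equal(P_value, 0.1))) 45L else 50L
  sub <- table[table$P == P_value & table$d <= d_max, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no rows for parental investment P = ", P_value, call. = FALSE)
  bad <- sub$extinct | is.na(sub$gene_birth_frequency)
  key <- interaction(sub$R, sub$p, sub$c, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(idx) {
    s <- sub[idx, ]
    ok <- !bad[idx]
    freq <- s$gene_birth_frequency[ok]
    data.frame(R = s$R[1], p = s$p[1], c = s$c[1], P = P_value,
               mean_frequency = mean(freq),
               se_frequency = stats::sd(freq) / sqrt(length(freq)),
               n_runs = length(freq), n_excluded = sum(!ok))
  }))
  rownames(out) <- NULL
  out[order(out$R, out$p, out$c), , drop = FALSE]
}

#' Aggregate a sweep into figure-style summary tables
#'
#' Produces the two standard views of a sweep: mean evolved frequency
#' against mortality cost for each parental investment (averaged over
#' delays and payoff conditions), and mean frequency against reproductive
#' delay for each `(R, p, c)` condition. Means come with standard errors;
#' extinct and undefined runs are excluded but counted.
#'
#' @param table A result table from [run_sweep()].
#' @return A list of two data frames, `freq_by_mortality` and
#'   `freq_by_delay`.
#' @export
figure_tables <- function(table) {
  if (is.null(table) || nrow(table) == 0L)
    stop("empty result table", call. = FALSE)
  bad <- table$extinct | is.na(table$gene_birth_frequency)
  agg <- function(keys) {
    key <- interaction(lapply(keys, function(k) table[[k]]), drop = TRUE)
    out <- do.call(rbind, lapply(split(seq_len(nrow(table)), key),
                                 function(idx) {
      s <- table[idx, , drop = FALSE]
      ok <- !bad[idx]
      freq <- s$gene_birth_frequency[ok]
      cell <- s[1, keys, drop = FALSE]
      cbind(cell, data.frame(
        mean_frequency = if (any(ok)) mean(freq) else NA_real_,
        se_frequency = if (sum(ok) > 1) stats::sd(freq) / sqrt(length(freq))
                       else NA_real_,
        n_runs = sum(ok), n_excluded = sum(!ok)))
    }))
    rownames(out) <- NULL
    out
  }
  list(freq_by_mortality = agg(c("P", "control", "c")),
       freq_by_delay = agg(c("R", "p", "control", "c", "d")))
}

#' Write the figure-style tables as CSV files
#'
#' @param tables Output of [figure_tables()].
#' @param dir Output directory (created if missing).
#' @return The written paths, invisibly.
#' @export
write_figure_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
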