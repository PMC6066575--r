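#' Advance a population by one step
#'
#' Executes the fixed per-step phase order: (1) juvenile play, (2)
#' maturation under the adult cap K, (3) adult foraging, (4) pooling and
#' equal division of the step's gains among each group's fair adults, (5)
#' reproduction under the threshold T and delay d, (6) aging and lifespan
#' deaths (with dependent juveniles), (7) group fission and empty-group
#' cleanup. Pooling always follows all contributions, newborns never mature,
#' forage or pool on their birth step.
#'
#' @param pop A `fairplay_pop` object.
#' @param params A `fairplay_params` object.
#' @return A list with the updated `population` and a one-row `report` data
#'   frame of phase counters (births, play bouts and deaths, maturations,
#'   cap/lifespan/dependent deaths, fissions, adult count, living gene
#'   frequency, and the step's foraged and credited resource totals).
#' @export
step_population <- function(pop, params) {
  if (pop_adult_count(pop) == 0L)
    stop("population is extinct (no adults)", call. = FALSE)
  res <- cpp_step(pop, params)
  list(population = res$population,
       report = as.data.frame(as.list(res$report)))
}

run_phase <- function(pop, params, phase) {
  res <- cpp_phase(pop, params, phase)
  list(population = res$population,
       report = as.data.frame(as.list(res$report)))
}

#' Run a single life-cycle phase
#'
#' Phase-level entry points used for testing and instrumentation; a full
#' step applies them in the order documented in [step_population()].
#' `play_phase` runs juvenile play in one call across all groups;
#' `forage_phase` runs foraging and pooling together (pooling uses only the
#' current step's gains).
#'
#' @param pop A `fairplay_pop` object.
#' @param params A `fairplay_params` object.
#' @return As [step_population()].
#' @export
play_phase <- function(pop, params) run_phase(pop, params, "play")

#' @rdname play_phase
#' @export
mature_phase <- function(pop, params) run_phase(pop, params, "mature")

#' @rdname play_phase
#' @export
forage_phase <- function(pop, params) run_phase(pop, params, "forage")

#' @rdname play_phase
#' @export
reproduction_phase <- function(pop, params) run_phase(pop, params, "reproduce")

#' @rdname play_phase
#' @export
age_phase <- function(pop, params) run_phase(pop, params, "age")

#' @rdname play_phase
#' @export
fission_phase <- function(pop, params) run_phase(pop, params, "fission")

#' Find a play partner for a juvenile
#'
#' Scans the other juveniles of the focal juvenile's group in uniformly
#' random order and returns the id of the first that carries the play gene
#' and has not yet played this step, or `NA` if none is willing.
#'
#' @param pop A `fairplay_pop` object.
#' @param juvenile_id Id of the focal juvenile.
#' @return An agent id or `NA`.
#' @export
find_partner <- function(pop, juvenile_id) {
  out <- cpp_find_partner(pop, as.integer(juvenile_id))
  if (is.na(out)) NA_integer_ else out
}

#' Draw per-step foraging gains
#'
#' Each draw succeeds with probability `p`; a success yields
#' `max(0, R + N(0, sd_R))` resource units, a failure yields 0.
#'
#' @param n Number of draws.
#' @param p Success probability.
#' @param R Mean resource units per success.
#' @param sd_R Gaussian noise SD (the model uses `0.1 * R`).
#' @return A numeric vector of gains.
#' @examples
#' mean(forage(10000, p = 0.0875, R = 40))  # close to pR = 3.5
#' @export
forage <- function(n, p, R, sd_R = 0.1 * R) {
  cpp_forage(as.integer(n), p, R, sd_R)
}

#' Pool and divide one step's gains
#'
#' The current-step gains of the fair members are summed and divided
#' equally among them; selfish members keep their own gains. The total is
#' conserved exactly (up to floating point).
#'
#' @param gains Numeric vector of the step's foraging gains.
#' @param fair Logical vector marking the fair members.
#' @return The per-member credited amounts.
#' @examples
#' pool_and_divide(c(40, 0, 12), fair = c(TRUE, TRUE, FALSE))
#' @export
pool_and_divide <- function(gains, fair) {
  cpp_pool_credits(as.numeric(gains), as.logical(fair))
}

#' Run one complete simulation
#'
#' Initializes a population from `params`, runs `tau` steps (or stops early
#' at extinction, i.e. zero adults), and summarizes the run: the play-gene
#' birth frequency over the measurement window `[burn_in, tau)` and the
#' realized play-mortality percentage (play deaths over juveniles that
#' entered at least one bout). Identical `(params, seed)` always reproduce
#' the identical result, bit for bit.
#'
#' @param params A `fairplay_params` object.
#' @param seed Integer seed for the run's single RNG stream.
#' @param record_trajectory If `TRUE`, keep the per-step counter table.
#' @return A `fairplay_sim` object: `params`, `seed`,
#'   `gene_birth_frequency` (fraction; `NA` if no births fell in the
#'   window), `births_in_window`, `play_mortality_percent`, `extinct`,
#'   `extinction_step`, `trajectory` (data frame or `NULL`), and the final
#'   `population`.
#' @examples
#' \donttest{
#' sim <- run_simulation(fp_params(tau = 2000, burn_in = 1000), seed = 1)
#' sim$gene_birth_frequency
#' }
#' @export
run_simulation <- function(params, seed, record_trajectory = FALSE) {
  validate_params(params)
  set.seed(as.integer(seed))
  res <- cpp_run(params, record_trajectory)
  pop <- res$population
  gf <- gene_birth_frequency(pop$birth_log,
                             window = c(params$burn_in, params$tau - 1L))
  ctr <- pop$counters
  pm <- play_mortality_percent(ctr$play_deaths, ctr$played_juveniles)
  out <- list(
    params = params,
    seed = as.integer(seed),
    gene_birth_frequency = gf,
    births_in_window = attr(gf, "n_births") %||% 0L,
    play_mortality_percent = pm,
    extinct = isTRUE(res$extinct),
    extinction_step = if (isTRUE(res$extinct)) res$extinction_step else NA_integer_,
    trajectory = if (record_trajectory) as.data.frame(res$trajectory) else NULL,
    population = pop
  )
  class(out) <- "fairplay_sim"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fairplay_sim <- function(x, ...) {
  cat("<fairplay_sim>\n")
  cat(sprintf("  seed %d, %d steps%s\n", x$seed, x$params$tau,
              if (x$extinct) sprintf(" (extinct at step %d)", x$extinction_step)
              else ""))
  cat(sprintf("  play-gene birth frequency [%d, %d): %s (%d births)\n",
              x$params$burn_in, x$params$tau,
              if (is.na(x$gene_birth_frequency)) "undefined"
              else sprintf("%.3f", x$gene_birth_frequency),
              x$births_in_window))
  cat(sprintf("  play mortality: %.2f%%\n", x$play_mortality_percent))
  invisible(x)
}

#' Write a run's per-step trajectory as CSV
#'
#' @param sim A `fairplay_sim` run with a recorded trajectory.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  if (is.null(sim$trajectory))
    stop("simulation was run without record_trajectory = TRUE", call. = FALSE)
  utils::write.csv(sim$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Summarize a run as a plain list (for JSON export)
#'
#' @param sim A `fairplay_sim` object.
#' @return A named list of the run's resolved parameters, seed and summary
#'   statistics.
#' @export
sim_summary <- function(sim) {
  list(
    params = sim$params[config_fields()],
    seed = sim$seed,
    gene_birth_frequency = as.numeric(sim$gene_birth_frequency),
    births_in_window = sim$births_in_window,
    play_mortality_percent = sim$play_mortality_percent,
    extinct = sim$extinct,
    extinction_step = sim$extinction_step
  )
}
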