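#' Initialize a population
#'
#' Builds the starting population: `n_init_groups` groups of
#' `n_init_per_group` adults each. Per agent (in group, then member order)
#' the draws are: resources uniform on `init_resource_range`, age a uniform
#' integer on `init_age_range`, play gene on with probability `F0`, then
#' lifespan via [assign_lifespan()]. Initial agents are adults (ages start
#' at or above `j`) and are immediately eligible to reproduce. Gene-carrying
#' initial adults count as fair when learning is enabled and
#' `seed_adults_fair` is set.
#'
#' @param params A `fairplay_params` object.
#' @param seed Optional integer seed applied via [set.seed()] before drawing.
#' @return A `fairplay_pop` object.
#' @examples
#' pop <- init_population(fp_params(), seed = 1)
#' pop_adult_count(pop)
#' @export
init_population <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  cpp_init_population(params)
}

#' Draw lifespans
#'
#' A lifespan is `round(l + N(0, sd_l))` clamped below at 1 step.
#'
#' @param params A `fairplay_params` object supplying `l` and `sd_l`.
#' @param n Number of draws.
#' @return An integer vector of lifespans.
#' @export
assign_lifespan <- function(params, n = 1L) {
  cpp_assign_lifespan(as.integer(n), params$l, params$sd_l)
}

#' Create one offspring of an adult
#'
#' The offspring is a juvenile (age 0, no bouts, not fair) in its parent's
#' group. It receives `P` times the parent's accumulated resources (the
#' parent keeps the rest), inherits the parent's gene state flipped with
#' probability `r`, and gets a fresh lifespan. The birth is appended to the
#' population's birth log with the post-mutation gene state.
#'
#' @param pop A `fairplay_pop` object.
#' @param parent_id Id of a living adult.
#' @param params A `fairplay_params` object.
#' @return The updated population.
#' @export
spawn_offspring <- function(pop, parent_id, params) {
  cpp_spawn_offspring(pop, params, as.integer(parent_id))
}

#' Remove an agent from the population
#'
#' Logs the death and removes the agent. When an adult dies of `"lifespan"`,
#' its living juvenile offspring are removed with it (cause
#' `"parent_death"`): juveniles are assumed dependent on their parent.
#' Groups left with no members disappear.
#'
#' @param pop A `fairplay_pop` object.
#' @param agent_id Id of a living agent.
#' @param cause One of `"play"`, `"lifespan"`, `"cap"`, `"parent_death"`.
#' @return The updated population.
#' @export
remove_agent <- function(pop, agent_id,
                         cause = c("play", "lifespan", "cap", "parent_death")) {
  cause <- match.arg(cause)
  cpp_remove_agent(pop, as.integer(agent_id), cause)
}

#' Build a population from an agent table
#'
#' Test and scenario helper: constructs a `fairplay_pop` from a data frame
#' of agents, filling unspecified per-agent fields with neutral defaults
#' (no resources, no bouts, effectively unlimited lifespan, no parent).
#'
#' @param agents Data frame with at least `id`, `group_id`, `play_gene`,
#'   `adult`, `age`; optional `lifespan`, `resources`, `bouts_played`,
#'   `is_fair`, `played_step`, `played_ever`, `last_repro_step`,
#'   `parent_id`, `birth_step`.
#' @param step Current step index.
#' @return A `fairplay_pop` object.
#' @export
new_population <- function(agents, step = 0L) {
  n <- nrow(agents)
  def <- function(col, value) {
    if (col %in% names(agents)) agents[[col]] else rep_len(value, n)
  }
  agents_full <- data.frame(
    id = as.integer(agents$id),
    group_id = as.integer(agents$group_id),
    play_gene = as.logical(agents$play_gene),
    adult = as.logical(agents$adult),
    birth_step = as.integer(def("birth_step", -as.integer(agents$age))),
    age = as.integer(agents$age),
    lifespan = as.integer(def("lifespan", .Machine$integer.max %/% 2L)),
    resources = as.numeric(def("resources", 0)),
    bouts_played = as.integer(def("bouts_played", 0L)),
    is_fair = as.logical(def("is_fair", FALSE)),
    played_step = as.logical(def("played_step", FALSE)),
    played_ever = as.logical(def("played_ever", FALSE)),
    last_repro_step = as.integer(def("last_repro_step", -1000000L)),
    parent_id = as.integer(def("parent_id", NA_integer_))
  )
  pop <- list(
    agents = agents_full,
    step = as.integer(step),
    next_id = max(agents_full$id) + 1L,
    next_group_id = max(agents_full$group_id) + 1L,
    counters = list(births_total = 0, births_gene = 0, play_deaths = 0,
                    played_juveniles = 0, cap_deaths = 0, lifespan_deaths = 0,
                    parent_deaths = 0, fissions = 0),
    birth_log = data.frame(step = integer(0), gene = integer(0)),
    death_log = data.frame(step = integer(0), cause = integer(0))
  )
  class(pop) <- "fairplay_pop"
  pop
}

#' @export
as.data.frame.fairplay_pop <- function(x, ...) x$agents

#' Number of living adults
#' @param pop A `fairplay_pop` object.
#' @return Integer count.
#' @export
pop_adult_count <- function(pop) sum(pop$agents$adult)

#' Number of living groups
#' @param pop A `fairplay_pop` object.
#' @return Integer count.
#' @export
pop_group_count <- function(pop) length(unique(pop$agents$group_id))

#' Play-gene frequency among living agents
#' @param pop A `fairplay_pop` object.
#' @return A fraction, or `NA` for an empty population.
#' @export
pop_gene_frequency <- function(pop) {
  n <- nrow(pop$agents)
  if (n == 0L) return(NA_real_)
  mean(pop$agents$play_gene)
}

#' @export
print.fairplay_pop <- function(x, ...) {
  n <- nrow(x$agents)
  cat(sprintf("<fairplay_pop> step %d: %d agents (%d adults, %d juveniles) in %d groups\n",
              x$step, n, pop_adult_count(x), n - pop_adult_count(x),
              pop_group_count(x)))
  cat(sprintf("  gene frequency (living): %.3f; births logged: %d\n",
              pop_gene_frequency(x), nrow(x$birth_log)))
  invisible(x)
}

# death-cause codes used in the C++ engine's death log
death_cause_labels <- function(code) {
  c("play", "lifespan", "cap", "parent_death")[code]
}

#' Export the birth and death logs as one event table
#'
#' @param pop A `fairplay_pop` object.
#' @return A data frame with columns `step`, `event` (`"birth"`/`"death"`),
#'   `gene_state` (births only) and `cause` (deaths only).
#' @export
event_log <- function(pop) {
  b <- pop$birth_log
  d <- pop$death_log
  rbind(
    data.frame(step = b$step, event = "birth", gene_state = b$gene,
               cause = NA_character_),
    data.frame(step = d$step, event = "death", gene_state = NA_integer_,
               cause = death_cause_labels(d$cause))
  )
}
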