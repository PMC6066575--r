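#' Model parameters for a fair-play simulation
#'
#' Constructs and validates the full parameter vector of a run. Defaults are
#' the model's standard fixed parameters and initial conditions: a population
#' of at most `K = 1000` adults in at most `G = 50` groups, a juvenile stage
#' of `j = 50` steps, a learning threshold of `alpha = 5` play bouts, a
#' reproductive threshold of `T = 100` resource units with parental
#' investment `P = 0.5`, a per-birth mutation rate `r` of 0.01, and lifespans
#' of `l = 150 +/- sd_l = 25` steps. The foraging noise SD is always derived
#' as `sd_R = 0.1 * R` and cannot be set directly.
#'
#' @param K Maximum number of adults in the population.
#' @param G Maximum number of groups.
#' @param f Group fission size: a group with at least `f` adults splits.
#' @param g Offspring-group size drawn from a fissioning group.
#' @param j Length of the juvenile stage in steps.
#' @param alpha Number of play bouts a juvenile needs to learn fairness.
#' @param P Parental investment: fraction of a parent's accumulated resources
#'   transferred to each offspring.
#' @param T Reproductive threshold in resource units (one offspring per
#'   reproductive event).
#' @param r Mutation rate per birth for flipping the play gene.
#' @param l Mean lifespan in steps.
#' @param sd_l Lifespan standard deviation in steps.
#' @param R Mean resource units obtained by one successful forage.
#' @param p Per-step probability of foraging success.
#' @param c Per-bout probability that a playing juvenile dies.
#' @param d Reproductive delay: minimum steps between an adult's successive
#'   reproductive events.
#' @param F0 Initial frequency of the play gene.
#' @param tau Total simulation steps.
#' @param burn_in First step of the measurement window for the play-gene
#'   birth frequency.
#' @param learn_fairness If `FALSE` (the control condition) juveniles still
#'   play and still pay the mortality cost, but never become fair adults.
#' @param n_init_groups Initial number of groups.
#' @param n_init_per_group Initial number of adults per group.
#' @param init_resource_range Uniform range for initial adult resources.
#' @param init_age_range Uniform integer range for initial adult ages; its
#'   minimum must be at least `j` so all initial agents are adults.
#' @param seed_adults_fair Whether initial gene-carrying adults (who had no
#'   juvenile phase) count as fair when learning is enabled.
#' @return A validated `fairplay_params` object (a named list).
#' @examples
#' pars <- fp_params(R = 40, p = 0.0875, d = 15)
#' pars$sd_R  # always 0.1 * R
#' @export
fp_params <- function(K = 1000L, G = 50L, f = 40L, g = 20L, j = 50L,
                      alpha = 5L, P = 0.5, T = 100, r = 0.01,
                      l = 150, sd_l = 25, R = 40, p = 0.0875,
                      c = 0, d = 15L, F0 = 0.05,
                      tau = 25000L, burn_in = 10000L,
                      learn_fairness = TRUE,
                      n_init_groups = 50L, n_init_per_group = 20L,
                      init_resource_range = c(50, 150),
                      init_age_range = c(50L, 150L),
                      seed_adults_fair = TRUE) {
  pr <- list(
    K = as.integer(K), G = as.integer(G), f = as.integer(f),
    g = as.integer(g), j = as.integer(j), alpha = as.integer(alpha),
    P = as.numeric(P), T = as.numeric(T), r = as.numeric(r),
    l = as.numeric(l), sd_l = as.numeric(sd_l),
    R = as.numeric(R), sd_R = 0.1 * as.numeric(R), p = as.numeric(p),
    c = as.numeric(c), d = as.integer(d), F0 = as.numeric(F0),
    tau = as.integer(tau), burn_in = as.integer(burn_in),
    learn_fairness = isTRUE(as.logical(learn_fairness)),
    n_init_groups = as.integer(n_init_groups),
    n_init_per_group = as.integer(n_init_per_group),
    init_resource_range = as.numeric(init_resource_range),
    init_age_range = as.integer(init_age_range),
    seed_adults_fair = isTRUE(as.logical(seed_adults_fair))
  )
  class(pr) <- "fairplay_params"
  validate_params(pr)
  pr
}

#' Validate a parameter object
#'
#' Checks every invariant of the parameter vector (probabilities in
#' \[0, 1\], `0 < g <= f <= K`, positive counts and durations,
#' `burn_in < tau`, initial ages at least `j`, `sd_R == 0.1 * R`). Errors
#' name the offending field.
#'
#' @param params A `fairplay_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(key, what) {
    stop(sprintf("invalid parameter `%s`: %s", key, what), call. = FALSE)
  }
  for (key in c("p", "c", "r", "F0", "P")) {
    v <- params[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      fail(key, "must be a probability in [0, 1]")
  }
  for (key in c("K", "G", "f", "g", "j", "alpha", "tau",
                "n_init_groups", "n_init_per_group")) {
    v <- params[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != as.integer(v))
      fail(key, "must be a positive integer")
  }
  for (key in c("T", "l")) {
    v <- params[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      fail(key, "must be positive")
  }
  for (key in c("sd_l", "R")) {
    v <- params[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      fail(key, "must be non-negative")
  }
  if (is.na(params$d) || params$d < 0) fail("d", "must be a non-negative integer")
  if (is.na(params$burn_in) || params$burn_in < 0)
    fail("burn_in", "must be non-negative")
  if (params$burn_in >= params$tau) fail("burn_in", "must be less than tau")
  if (params$g > params$f) fail("g", "must satisfy g <= f")
  if (params$f > params$K) fail("f", "must satisfy f <= K")
  if (params$n_init_groups > params$G)
    fail("n_init_groups", "must not exceed G")
  if (!isTRUE(all.equal(params$sd_R, 0.1 * params$R)))
    fail("sd_R", "must equal 0.1 * R (it is derived, not set)")
  rr <- params$init_resource_range
  if (length(rr) != 2L || any(is.na(rr)) || rr[1] > rr[2] || rr[1] < 0)
    fail("init_resource_range", "must be a non-decreasing non-negative pair")
  ar <- params$init_age_range
  if (length(ar) != 2L || any(is.na(ar)) || ar[1] > ar[2])
    fail("init_age_range", "must be a non-decreasing integer pair")
  if (ar[1] < params$j)
    fail("init_age_range", "minimum must be at least j (initial agents are adults)")
  for (key in c("learn_fairness", "seed_adults_fair")) {
    if (!is.logical(params[[key]]) || length(params[[key]]) != 1L ||
        is.na(params[[key]]))
      fail(key, "must be TRUE or FALSE")
  }
  invisible(params)
}

#' Update a parameter object
#'
#' Returns a new validated parameter object with the given fields replaced.
#' `sd_R` is re-derived from `R` and cannot be overridden.
#'
#' @param .params A `fairplay_params` object. (The dotted name avoids
#'   partial matching against field arguments such as `p`.)
#' @param ... Named fields accepted by [fp_params()].
#' @return A new `fairplay_params` object.
#' @export
fp_update <- function(.params, ...) {
  dots <- list(...)
  if ("sd_R" %in% names(dots))
    stop("`sd_R` is derived from R and cannot be set", call. = FALSE)
  if (length(dots) > 0 && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all fields passed to fp_update must be named", call. = FALSE)
  args <- .params[config_fields()]
  args[names(dots)] <- dots
  do.call(fp_params, args)
}

# the user-settable fields, i.e. everything but the derived sd_R
config_fields <- function() {
  setdiff(names(formals(fp_params)), character(0))
}

#' Read a run configuration from JSON
#'
#' Accepts either a path to a JSON file or a literal JSON string holding a
#' flat key-value document. Omitted fields take the [fp_params()] defaults;
#' unknown keys are rejected.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A validated `fairplay_params` object.
#' @export
read_params <- function(source) {
  txt <- if (length(source) == 1L && grepl("^[[:space:]]*\\{", source)) {
    source
  } else {
    if (!file.exists(source)) stop("config file not found: ", source, call. = FALSE)
    paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(x)) stop("config must be a JSON object", call. = FALSE)
  unknown <- setdiff(names(x), config_fields())
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(fp_params, x)
}

#' Write a run configuration to JSON
#'
#' Serializes the user-settable fields (the derived `sd_R` is omitted and
#' re-derived on load, so write/read round-trips are exact).
#'
#' @param params A `fairplay_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- params[config_fields()]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.fairplay_params <- function(x, ...) {
  cat("<fairplay_params>\n")
  cat(sprintf("  population: K=%d adults, G=%d groups (fission f=%d -> g=%d)\n",
              x$K, x$G, x$f, x$g))
  cat(sprintf("  life history: j=%d, lifespan %g+/-%g, delay d=%d, T=%g, P=%g\n",
              x$j, x$l, x$sd_l, x$d, x$T, x$P))
  cat(sprintf("  foraging: R=%g, p=%g (pR=%g, sd_R=%g)\n",
              x$R, x$p, x$p * x$R, x$sd_R))
  cat(sprintf("  play: alpha=%d, c=%g, mutation r=%g, F0=%g, learning %s\n",
              x$alpha, x$c, x$r, x$F0,
              if (x$learn_fairness) "on" else "off (control)"))
  cat(sprintf("  run: tau=%d steps, burn-in %d\n", x$tau, x$burn_in))
  invisible(x)
}
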