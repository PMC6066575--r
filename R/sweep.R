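#' Derive a reproducible per-run seed
#'
#' Maps `(base_seed, config_index, replicate)` to a single RNG seed with the
#' affine counter scheme `base_seed + config_index * stride + replicate`.
#' The mapping is injective as long as `replicate < stride`, so every run of
#' a sweep gets a distinct, order-independent seed.
#'
#' @param base_seed Non-negative integer base seed for the whole sweep.
#' @param config_index Zero-based index of the parameter condition.
#' @param replicate Zero-based replicate index (must be below `stride`).
#' @param stride Replicate stride; the default 2048 supports up to 2048
#'   replicates per condition.
#' @return An integer seed (vectorized over `config_index` and `replicate`).
#' @examples
#' derive_seed(1, 0, 0:4)
#' @export
derive_seed <- function(base_seed, config_index, replicate, stride = 2048L) {
  if (any(base_seed < 0) || any(config_index < 0) || any(replicate < 0))
    stop("seed components must be non-negative", call. = FALSE)
  if (any(replicate >= stride))
    stop("replicate must be below the stride (", stride, ")", call. = FALSE)
  s <- as.numeric(base_seed) + as.numeric(config_index) * stride +
    as.numeric(replicate)
  if (any(s >= 2^31 - 1))
    stop("derived seed exceeds the 32-bit integer range", call. = FALSE)
  as.integer(s)
}

#' Describe a factorial parameter sweep
#'
#' A sweep is the Cartesian product of (R, p) payoff pairs, reproductive
#' delays, play-mortality costs, and parental investments, each condition
#' run for `replicates` independent seeded replicates.
#'
#' @param payoff_R,payoff_p Equal-length vectors of paired resource sizes
#'   and foraging success probabilities.
#' @param delays Reproductive delays to sweep.
#' @param costs Per-bout play mortality probabilities to sweep.
#' @param investments Parental investment fractions to sweep.
#' @param replicates Replicates per condition.
#' @param base_seed Base seed fed to [derive_seed()].
#' @param control If `TRUE` every run disables fairness learning.
#' @return A `fairplay_sweep` specification.
#' @export
sweep_spec <- function(payoff_R, payoff_p, delays = 0:50,
                       costs = c(0, 0.0005, 0.001, 0.0015, 0.002,
                                 0.00225, 0.003),
                       investments = 0.5, replicates = 20L,
                       base_seed = 1L, control = FALSE) {
  if (length(payoff_R) != length(payoff_p) || length(payoff_R) == 0L)
    stop("payoff_R and payoff_p must be non-empty and of equal length",
         call. = FALSE)
  if (length(delays) == 0L || length(costs) == 0L || length(investments) == 0L)
    stop("delays, costs and investments must be non-empty", call. = FALSE)
  if (replicates < 1L) stop("replicates must be at least 1", call. = FALSE)
  spec <- list(payoff_R = as.numeric(payoff_R),
               payoff_p = as.numeric(payoff_p),
               delays = as.integer(delays), costs = as.numeric(costs),
               investments = as.numeric(investments),
               replicates = as.integer(replicates),
               base_seed = as.integer(base_seed),
               control = isTRUE(control))
  class(spec) <- "fairplay_sweep"
  spec
}

#' The constant-expected-payoff sweep (pR = 3.5)
#'
#' Five (R, p) pairs holding the expected per-step payoff at 3.5 units while
#' varying the per-round payoff variance: R = 10, 20, 30, 40, 50 with
#' matched success probabilities.
#'
#' @inheritParams sweep_spec
#' @param ... Further arguments passed to [sweep_spec()].
#' @return A `fairplay_sweep` specification.
#' @export
sweep_set1 <- function(investments = 0.5, replicates = 20L, ...) {
  sweep_spec(payoff_R = c(10, 20, 30, 40, 50),
             payoff_p = c(0.35, 0.175, 0.11667, 0.0875, 0.07),
             investments = investments, replicates = replicates, ...)
}

#' The constant-resource sweep (R = 40, pR from 2 to 5)
#'
#' Seven success probabilities at fixed R = 40 giving expected per-step
#' payoffs from 2 to 5 in increments of 0.5.
#'
#' @inheritParams sweep_set1
#' @return A `fairplay_sweep` specification.
#' @export
sweep_set2 <- function(investments = 0.5, replicates = 20L, ...) {
  sweep_spec(payoff_R = rep(40, 7),
             payoff_p = c(0.05, 0.0625, 0.075, 0.0875, 0.1, 0.1125, 0.125),
             investments = investments, replicates = replicates, ...)
}

#' Enumerate every run of a sweep
#'
#' Expands the full Cartesian product of the sweep's factors times its
#' replicates, with one row per run and a deterministic seed per row.
#' Enumeration order is fixed: cost varies fastest, then delay, then payoff
#' pair, then investment; within each condition the replicate index varies
#' fastest of all. `config_index` is the zero-based index of the condition
#' in that order, and the seed is `derive_seed(base_seed, config_index,
#' replicate)`, so re-enumeration always reproduces the identical table.
#'
#' @param spec A `fairplay_sweep` specification.
#' @return A data frame with columns `config_index`, `replicate`, `P`, `R`,
#'   `p`, `c`, `d`, `control`, `seed`.
#' @examples
#' nrow(enumerate_sweep(sweep_set1(replicates = 1)))  # 1785 conditions
#' @export
enumerate_sweep <- function(spec) {
  stopifnot(inherits(spec, "fairplay_sweep"))
  np <- length(spec$payoff_R)
  conds <- expand.grid(c = spec$costs, d = spec$delays, pair = seq_len(np),
                       P = spec$investments, KEEP.OUT.ATTRS = FALSE)
  conds$config_index <- seq_len(nrow(conds)) - 1L
  k <- spec$replicates
  out <- conds[rep(seq_len(nrow(conds)), each = k), , drop = FALSE]
  out$replicate <- rep(seq_len(k) - 1L, times = nrow(conds))
  out$R <- spec$payoff_R[out$pair]
  out$p <- spec$payoff_p[out$pair]
  out$pair <- NULL
  out$control <- spec$control
  out$seed <- derive_seed(spec$base_seed, out$config_index, out$replicate)
  rownames(out) <- NULL
  out[, c("config_index", "replicate", "P", "R", "p", "c", "d",
          "control", "seed")]
}

#' Realize the parameters of one enumerated run
#'
#' @param row One row of [enumerate_sweep()] output.
#' @param base Base parameters supplying all non-swept fields.
#' @return A validated `fairplay_params` object.
#' @export
sweep_params <- function(row, base = fp_params()) {
  fp_update(base, R = row$R, p = row$p, c = row$c, d = as.integer(row$d),
            P = row$P, learn_fairness = !isTRUE(row$control))
}

#' Read a sweep specification from JSON
#'
#' @param source Path to a JSON file or a JSON string with fields
#'   `payoff_R`, `payoff_p`, and optionally `delays`, `costs`,
#'   `investments`, `replicates`, `base_seed`, `control`.
#' @return A `fairplay_sweep` specification.
#' @export
read_sweep <- function(source) {
  txt <- if (length(source) == 1L && grepl("^[[:space:]]*\\{", source)) {
    source
  } else {
    if (!file.exists(source)) stop("sweep file not found: ", source, call. = FALSE)
    paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  allowed <- names(formals(sweep_spec))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    stop("unknown sweep key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sweep_spec, x)
}
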