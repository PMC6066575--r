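# Small-population parameters for fast unit runs. Initial agents aged 5-20
# with short lifespans so all life-history events occur within ~100 steps.
tiny_params <- function(...) {
  args <- list(K = 100L, G = 10L, f = 12L, g = 6L, j = 5L, alpha = 2L,
               T = 40, l = 30, sd_l = 8, tau = 120L, burn_in = 40L,
               d = 3L, p = 0.3, R = 15, F0 = 0.3,
               n_init_groups = 4L, n_init_per_group = 8L,
               init_resource_range = c(10, 30), init_age_range = c(5L, 20L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fp_params, args)
}

# one-row agent constructor for scenario populations; always emits the same
# columns so rows can be rbind-ed
agent_row <- function(id, group_id = 0L, play_gene = FALSE, adult = TRUE,
                      age = 100L, resources = 0, bouts_played = 0L,
                      is_fair = FALSE, played_step = FALSE,
                      lifespan = 1e9L, last_repro_step = -1000000L,
                      parent_id = NA_integer_) {
  data.frame(id = id, group_id = group_id, play_gene = play_gene,
             adult = adult, age = age, resources = resources,
             bouts_played = bouts_played, is_fair = is_fair,
             played_step = played_step, lifespan = lifespan,
             last_repro_step = last_repro_step, parent_id = parent_id)
}

# brute-force binomial upper tail by explicit enumeration of all 2^d
# success/failure sequences; independent oracle for prob_reach_threshold
brute_force_tail <- function(d, p, k) {
  if (d == 0) return(as.numeric(k <= 0))
  total <- 0
  for (x in 0:(2^d - 1)) {
    successes <- sum(bitwAnd(x, bitwShiftL(1L, 0:(d - 1))) != 0)
    if (successes >= k) total <- total + p^successes * (1 - p)^(d - successes)
  }
  total
}
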