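# --- juvenile play -----------------------------------------------------------

juvenile_group <- function(genes, group_id = 0L) {
  n <- length(genes)
  rows <- lapply(seq_len(n), function(i) {
    agent_row(id = i, group_id = group_id, play_gene = genes[i],
              adult = FALSE, age = 1L)
  })
  # add one adult so the population is never considered extinct
  rows <- c(rows, list(agent_row(id = n + 1L, group_id = group_id)))
  new_population(do.call(rbind, rows))
}

test_that("two willing juveniles play one bout and both gain a bout count", {
  set.seed(1)
  pop <- juvenile_group(c(TRUE, TRUE))
  out <- play_phase(pop, tiny_params(c = 0))
  expect_equal(out$report$play_bouts, 1)
  expect_equal(out$report$play_deaths, 0)
  juv <- out$population$agents[!out$population$agents$adult, ]
  expect_identical(juv$bouts_played, c(1L, 1L))
})

test_that("certain per-bout mortality kills both participants of one bout", {
  set.seed(2)
  pop <- juvenile_group(c(TRUE, TRUE))
  out <- play_phase(pop, tiny_params(c = 1))
  expect_equal(out$report$play_bouts, 1)
  expect_equal(out$report$play_deaths, 2)
  expect_identical(sum(!out$population$agents$adult), 0L)
  expect_equal(out$population$counters$played_juveniles, 2)
})

test_that("a lone gene carrier finds no partner and pays no cost", {
  set.seed(3)
  pop <- juvenile_group(c(TRUE, FALSE, FALSE, FALSE))
  out <- play_phase(pop, tiny_params(c = 1))
  expect_equal(out$report$play_bouts, 0)
  expect_equal(out$report$play_deaths, 0)
  expect_true(all(out$population$agents$bouts_played == 0L))
})

test_that("gene-off juveniles never play and never die of play", {
  set.seed(4)
  for (i in 1:10) {
    pop <- juvenile_group(c(TRUE, TRUE, TRUE, FALSE, FALSE))
    out <- play_phase(pop, tiny_params(c = 1))
    juv <- out$population$agents[!out$population$agents$adult, ]
    off <- juv[!juv$play_gene, ]
    expect_identical(nrow(off), 2L)
    expect_true(all(off$bouts_played == 0L))
  }
})

test_that("no juvenile plays more than one bout per step", {
  set.seed(5)
  for (i in 1:20) {
    pop <- juvenile_group(rep(TRUE, 7))
    out <- play_phase(pop, tiny_params(c = 0))
    juv <- out$population$agents[!out$population$agents$adult, ]
    expect_true(all(juv$bouts_played <= 1L))
    # 7 willing juveniles support exactly 3 pairs
    expect_equal(out$report$play_bouts, 3)
    expect_identical(sum(juv$bouts_played), 6L)
  }
})

test_that("play happens only within a group", {
  set.seed(6)
  a <- agent_row(id = 1L, group_id = 0L, play_gene = TRUE, adult = FALSE,
                 age = 1L)
  b <- agent_row(id = 2L, group_id = 1L, play_gene = TRUE, adult = FALSE,
                 age = 1L)
  anchor <- agent_row(id = 3L, group_id = 0L)
  out <- play_phase(new_population(rbind(a, b, anchor)), tiny_params(c = 0))
  expect_equal(out$report$play_bouts, 0)
})

test_that("partner choice is uniform over eligible partners", {
  focal <- agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 1L)
  eligible <- do.call(rbind, lapply(2:5, function(i) {
    agent_row(id = i, play_gene = TRUE, adult = FALSE, age = 1L)
  }))
  decoy <- agent_row(id = 6L, play_gene = FALSE, adult = FALSE, age = 1L)
  pop <- new_population(rbind(focal, eligible, decoy))
  set.seed(7)
  picks <- replicate(4000, find_partner(pop, 1L))
  expect_true(all(picks %in% 2:5))  # the gene-off juvenile is never picked
  expect_gt(stats::chisq.test(table(picks))$p.value, 0.001)
})

test_that("find_partner returns NA without willing partners", {
  lone <- new_population(rbind(
    agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 1L),
    agent_row(id = 2L, group_id = 0L)
  ))
  expect_true(is.na(find_partner(lone, 1L)))
  allofff <- new_population(rbind(
    agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 1L),
    agent_row(id = 2L, play_gene = FALSE, adult = FALSE, age = 1L),
    agent_row(id = 3L, group_id = 0L)
  ))
  expect_true(is.na(find_partner(allofff, 1L)))
  # a partner that already played this step is ineligible
  played <- new_population(rbind(
    agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 1L),
    agent_row(id = 2L, play_gene = TRUE, adult = FALSE, age = 1L,
              played_step = TRUE),
    agent_row(id = 3L, group_id = 0L)
  ))
  expect_true(is.na(find_partner(played, 1L)))
})

# --- maturation --------------------------------------------------------------

test_that("juveniles mature at age j and learn fairness at the threshold", {
  pars <- tiny_params()  # j = 5, alpha = 2
  ready <- new_population(rbind(
    agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 5L,
              bouts_played = 2L),
    agent_row(id = 2L, play_gene = TRUE, adult = FALSE, age = 5L,
              bouts_played = 1L),
    agent_row(id = 3L, play_gene = FALSE, adult = FALSE, age = 5L,
              bouts_played = 0L),
    agent_row(id = 4L, play_gene = TRUE, adult = FALSE, age = 4L,
              bouts_played = 2L),
    agent_row(id = 5L)
  ))
  set.seed(8)
  out <- mature_phase(ready, pars)
  ag <- out$population$agents
  expect_equal(out$report$matured, 3)
  expect_true(ag$adult[ag$id == 1])
  expect_true(ag$is_fair[ag$id == 1])     # bouts >= alpha
  expect_false(ag$is_fair[ag$id == 2])    # below the learning threshold
  expect_false(ag$is_fair[ag$id == 3])    # no gene
  expect_false(ag$adult[ag$id == 4])      # under age
})

test_that("the control condition blocks fairness learning at maturation", {
  pars <- tiny_params(learn_fairness = FALSE)
  ready <- new_population(rbind(
    agent_row(id = 1L, play_gene = TRUE, adult = FALSE, age = 5L,
              bouts_played = 5L),
    agent_row(id = 2L)
  ))
  set.seed(9)
  out <- mature_phase(ready, pars)
  expect_false(out$population$agents$is_fair[1])
  expect_true(out$population$agents$adult[1])
})

test_that("juveniles maturing at the adult cap die instead", {
  pars <- tiny_params(K = 2L, f = 2L, g = 1L)
  pop <- new_population(rbind(
    agent_row(id = 1L), agent_row(id = 2L),
    agent_row(id = 3L, adult = FALSE, age = 5L),
    agent_row(id = 4L, adult = FALSE, age = 5L)
  ))
  set.seed(10)
  out <- mature_phase(pop, pars)
  expect_equal(out$report$matured, 0)
  expect_equal(out$report$cap_deaths, 2)
  expect_identical(pop_adult_count(out$population), 2L)
})

# --- foraging and pooling ----------------------------------------------------

test_that("foraging follows the success probability and noise model", {
  set.seed(11)
  expect_true(all(forage(1000, p = 0, R = 40) == 0))
  expect_true(all(forage(1000, p = 1, R = 40, sd_R = 0) == 40))
  draws <- forage(2e5, p = 0.0875, R = 40)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 3.5), 3 * se)  # expected payoff pR
  expect_true(all(draws >= 0))
})

test_that("pooling divides the current step's gains equally and conserves", {
  expect_equal(pool_and_divide(c(40, 0), fair = c(TRUE, TRUE)), c(20, 20))
  expect_equal(pool_and_divide(37.5, fair = TRUE), 37.5)  # pool of one
  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    gains <- forage(n, p = 0.5, R = 20)
    fair <- runif(n) < 0.5
    credits <- pool_and_divide(gains, fair)
    expect_equal(sum(credits), sum(gains), tolerance = 1e-12)
    expect_identical(credits[!fair], gains[!fair])
    if (sum(fair) > 0) expect_equal(diff(range(credits[fair])), 0)
  }
})

test_that("a fair adult alone in its group keeps its own gain", {
  pop <- new_population(rbind(
    agent_row(id = 1L, is_fair = TRUE, resources = 5),
    agent_row(id = 2L, group_id = 1L, is_fair = FALSE, resources = 5)
  ))
  pars <- tiny_params(p = 1)  # deterministic success
  set.seed(13)
  out <- forage_phase(pop, pars)
  expect_equal(out$report$foraged_total, out$report$credited_total,
               tolerance = 1e-12)
  expect_true(all(out$population$agents$resources > 5))
})

test_that("fair adults of one group end the step with identical credits", {
  rows <- do.call(rbind, lapply(1:8, function(i) {
    agent_row(id = i, is_fair = i <= 5, resources = 0)
  }))
  pars <- tiny_params(p = 0.5, R = 10)
  set.seed(14)
  out <- forage_phase(new_population(rows), pars)
  ag <- out$population$agents
  expect_equal(diff(range(ag$resources[ag$is_fair])), 0)
  expect_equal(sum(ag$resources), out$report$foraged_total, tolerance = 1e-9)
})

# --- reproduction ------------------------------------------------------------

test_that("reproduction needs the threshold and respects the delay", {
  pars <- tiny_params(T = 100, d = 3L)
  pars$P <- 0.5
  below <- new_population(rbind(agent_row(id = 1L, resources = 99.9)),
                          step = 10L)
  set.seed(15)
  expect_equal(reproduction_phase(below, pars)$report$births, 0)

  at <- new_population(rbind(agent_row(id = 1L, resources = 100)), step = 10L)
  out <- reproduction_phase(at, pars)
  expect_equal(out$report$births, 1)
  ag <- out$population$agents
  expect_equal(ag$resources[ag$adult], 50)
  expect_equal(ag$resources[!ag$adult], 50)
  expect_identical(ag$last_repro_step[ag$adult], 10L)

  # one offspring per event even with resources >= 2T
  rich <- new_population(rbind(agent_row(id = 1L, resources = 250)),
                         step = 10L)
  out2 <- reproduction_phase(rich, pars)
  expect_equal(out2$report$births, 1)
  expect_equal(sum(!out2$population$agents$adult), 1L)

  # an agent that reproduced d - 1 steps ago must wait
  waiting <- new_population(rbind(
    agent_row(id = 1L, resources = 200, last_repro_step = 8L)), step = 10L)
  expect_equal(reproduction_phase(waiting, pars)$report$births, 0)
  eligible <- new_population(rbind(
    agent_row(id = 1L, resources = 200, last_repro_step = 7L)), step = 10L)
  expect_equal(reproduction_phase(eligible, pars)$report$births, 1)
})

# --- aging and death ---------------------------------------------------------

test_that("an agent at age lifespan - 1 survives this step and dies next", {
  pars <- tiny_params()
  pop <- new_population(rbind(
    agent_row(id = 1L, age = 29L, lifespan = 30L),
    agent_row(id = 2L, age = 10L, lifespan = 30L)
  ))
  out1 <- age_phase(pop, pars)
  expect_equal(out1$report$lifespan_deaths, 0)
  out2 <- age_phase(out1$population, pars)
  expect_equal(out2$report$lifespan_deaths, 1)
  expect_identical(out2$population$agents$id, 2L)
})

test_that("dependent juveniles die with their lifespan-expired parent", {
  pars <- tiny_params()
  pop <- new_population(rbind(
    agent_row(id = 1L, age = 31L, lifespan = 30L),
    agent_row(id = 2L, adult = FALSE, age = 2L, parent_id = 1L),
    agent_row(id = 3L, adult = FALSE, age = 2L, parent_id = 4L),
    agent_row(id = 4L)
  ))
  out <- age_phase(pop, pars)
  expect_equal(out$report$lifespan_deaths, 1)
  expect_equal(out$report$parent_deaths, 1)
  expect_identical(sort(out$population$agents$id), c(3L, 4L))
})

# --- fission -----------------------------------------------------------------

test_that("a group at the fission size splits off g adults", {
  pars <- tiny_params(f = 12L, g = 6L, G = 10L)
  rows <- do.call(rbind, lapply(1:12, function(i) agent_row(id = i)))
  set.seed(16)
  out <- fission_phase(new_population(rows), pars)
  expect_equal(out$report$fissions, 1)
  expect_identical(pop_group_count(out$population), 2L)
  expect_identical(as.vector(table(out$population$agents$group_id)),
                   c(6L, 6L))
})

test_that("no fission below f or at the group cap", {
  pars <- tiny_params(f = 12L, g = 6L, G = 10L)
  rows <- do.call(rbind, lapply(1:11, function(i) agent_row(id = i)))
  set.seed(17)
  expect_equal(fission_phase(new_population(rows), pars)$report$fissions, 0)

  pars2 <- tiny_params(f = 12L, g = 6L, G = 2L, n_init_groups = 2L)
  rows2 <- rbind(
    do.call(rbind, lapply(1:12, function(i) agent_row(id = i, group_id = 0L))),
    agent_row(id = 13L, group_id = 1L)
  )
  expect_equal(fission_phase(new_population(rows2), pars2)$report$fissions, 0)
})

test_that("moved adults take their dependent juveniles along", {
  pars <- tiny_params(f = 4L, g = 2L, G = 10L)
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i) agent_row(id = i))),
    agent_row(id = 5L, adult = FALSE, age = 1L, parent_id = 1L),
    agent_row(id = 6L, adult = FALSE, age = 1L, parent_id = 2L),
    agent_row(id = 7L, adult = FALSE, age = 1L, parent_id = 3L),
    agent_row(id = 8L, adult = FALSE, age = 1L, parent_id = 4L)
  )
  set.seed(18)
  out <- fission_phase(new_population(rows), pars)
  ag <- out$population$agents
  expect_equal(out$report$fissions, 1)
  for (i in 1:4) {
    parent_group <- ag$group_id[ag$id == i]
    child_group <- ag$group_id[ag$id == i + 4L]
    expect_identical(parent_group, child_group)
  }
})

# --- whole steps and runs ----------------------------------------------------

test_that("selfish adults with no foraging success only age", {
  pars <- tiny_params(p = 0, r = 0)
  rows <- do.call(rbind, lapply(1:5, function(i) {
    agent_row(id = i, age = 50L, resources = 10)
  }))
  pop <- new_population(rows)
  set.seed(19)
  out <- step_population(pop, pars)
  ag <- out$population$agents
  expect_identical(ag$age, rep(51L, 5))
  expect_equal(ag$resources, rep(10, 5))
  expect_equal(out$report$births + out$report$play_bouts +
                 out$report$lifespan_deaths, 0)
})

test_that("stepping an extinct population errors", {
  juvs <- new_population(rbind(
    agent_row(id = 1L, adult = FALSE, age = 1L)
  ))
  expect_error(step_population(juvs, tiny_params()), "extinct")
})

test_that("identical parameters and seed reproduce a run bit for bit", {
  pars <- tiny_params(c = 0.01)
  a <- run_simulation(pars, seed = 123, record_trajectory = TRUE)
  b <- run_simulation(pars, seed = 123, record_trajectory = TRUE)
  expect_identical(a$population$agents, b$population$agents)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$gene_birth_frequency, b$gene_birth_frequency)
  d <- run_simulation(pars, seed = 124)
  expect_false(identical(a$population$agents, d$population$agents))
})

test_that("without mutation or initial carriers the gene never arises", {
  pars <- tiny_params(r = 0, F0 = 0)
  sim <- run_simulation(pars, seed = 20)
  expect_equal(as.numeric(sim$gene_birth_frequency), 0)
  expect_gt(sim$births_in_window, 0)
  expect_identical(sum(sim$population$agents$play_gene), 0L)
})
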