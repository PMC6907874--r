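test_that("the schedule has the full factorial structure", {
  for (pid in c(1, 4, 6)) {
    sched <- make_schedule(permutation_id = pid, seed = 100 + pid)
    expect_equal(nrow(sched), 288)
    cells <- table(sched$cost, sched$q)
    expect_true(all(cells == 48))
    expect_equal(sum(sched$hidden_jar == "pink"), 144)
    # jars and sides counterbalanced within every cell
    full <- table(sched$cost, sched$q, sched$hidden_jar, sched$pink_side)
    expect_true(all(full == 12))
    # cost blocked: one cost per 96-trial block, order by permutation id
    expect_true(all(tapply(sched$cost, sched$block,
                           function(x) length(unique(x))) == 1))
  }
  orders <- vapply(1:6, function(pid) {
    s <- make_schedule(pid, seed = 1)
    paste(unique(s$cost[order(s$trial)]), collapse = ",")
  }, character(1))
  expect_equal(length(unique(orders)), 6)
  expect_error(make_schedule(7), "1..6")
  # seed contract
  expect_identical(make_schedule(2, seed = 9), make_schedule(2, seed = 9))
})

test_that("degenerate agents hit the stopping extremes", {
  sched <- make_schedule(1, seed = 5)[1:30, ]
  base <- default_agent_params("cost_first")
  stopper <- list(id = "s1", models = list(cost_first = base))
  stopper$models$cost_first$choice_par[c("w_cost_zero", "w_cost_low",
                                         "w_cost_high")] <- 50
  sim <- simulate_agent(stopper, sched, seed = 1)
  expect_true(all(sim$trials$n_samples == 0))
  expect_true(all(sim$samples$choice == "stop"))
  # efficiency of never sampling is computable and equals gain(0)/max
  cc <- condition(sched$cost[1], sched$q[1])
  sub <- sim$trials[sim$trials$cost == cc$unit_cost & sim$trials$q == cc$q, ]
  expect_equal(efficiency(sub$n_samples, cc),
               5 / optimal_policy(cc)$max_gain)

  sampler <- list(id = "s2", models = list(cost_first = base))
  sampler$models$cost_first$choice_par[c("w_cost_zero", "w_cost_low",
                                         "w_cost_high", "w_ev_icpt")] <- -50
  sampler$models$cost_first$choice_par[c("w_nsamp", "w_totcost", "w_absci",
                                         "w_totev", "w_prevcorr",
                                         "w_prevn")] <- 0
  sim2 <- simulate_agent(sampler, sched, seed = 2)
  expect_true(all(sim2$trials$n_samples == 20))
  expect_true(all(sim2$samples$choice == "continue"))
  expect_equal(nrow(sim2$samples), 30 * 20)
})

test_that("simulated choices and judgments respect the generative model", {
  sched <- make_schedule(1, seed = 6)
  profile <- list(id = "a1", models = list(cost_first =
                                             default_agent_params("cost_first")))
  sim <- simulate_agent(profile, sched, seed = 3)
  expect_equal(nrow(sim$trials), 288)
  # every continue row carries a positive DT and a stage label
  cont <- sim$samples$choice == "continue"
  expect_true(all(sim$samples$dt[cont] > 0))
  expect_true(all(sim$samples$dt_stage[cont] %in% 1:2))
  expect_true(all(is.na(sim$samples$dt[!cont])))
  # judgment follows the majority color deterministically off ties
  for (i in sample(which(sim$trials$n_samples > 0), 40)) {
    tr <- sim$trials[i, ]
    beads <- sim$samples$bead[sim$samples$trial == tr$trial & cont]
    pinks <- sum(beads == "P")
    blues <- sum(beads == "B")
    if (pinks == blues) next
    won_jar <- if (pinks > blues) "pink" else "blue"
    expect_equal(tr$correct, as.integer(won_jar == tr$hidden_jar))
  }
  # seed contract
  sim_b <- simulate_agent(profile, sched, seed = 3)
  expect_identical(sim$samples, sim_b$samples)
})

test_that("populations carry AQ-linked strategy mixing and a truth manifest", {
  ds <- simulate_population(n_agents = 6, seed = 17)
  expect_equal(nrow(ds$participants), 6)
  expect_equal(nrow(ds$trials), 6 * 288)
  expect_equal(nrow(ds$manifest), 6)
  expect_true(all(c("pi_costfirst", "psec_zero", "alpha", "b0_1") %in%
                    names(ds$manifest)))
  expect_true(all(ds$participants$aq >= 0 & ds$participants$aq <= 150))
  # positive link: mixing weight increases with AQ
  expect_equal(order(ds$manifest$pi_costfirst), order(ds$manifest$aq))
  expect_true(all(ds$manifest$pi_costfirst >= 0 &
                    ds$manifest$pi_costfirst <= 1))
  # reproducibility
  ds2 <- simulate_population(n_agents = 6, seed = 17)
  expect_identical(ds$samples, ds2$samples)
  expect_error(simulate_population(n_agents = 1), "at least 2")
})
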