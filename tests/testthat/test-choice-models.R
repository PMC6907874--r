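test_that("decayed cumulative information follows the leaky count recursion", {
  ci <- 0
  for (b in c("P", "P", "B")) ci <- update_decayed_ci(ci, b, alpha = 1)
  expect_equal(ci, 1)
  expect_equal(update_decayed_ci(3.7, "B", alpha = 0), -1)
  expect_equal(update_decayed_ci(update_decayed_ci(0, "P", 0.5), "P", 0.5),
               1.5)
  expect_equal(update_decayed_ci(2, -1, 0.9), 0.8)
  expect_error(update_decayed_ci(0, "P", 1.2), "0, 1")
  expect_error(update_decayed_ci(0, "x", 1), "pink")
})

test_that("stage logits use the documented DV codings", {
  s <- choice_state(3, condition(0.1, 0.8), ci_decayed = -2,
                    prev_correct = 1, prev_n = 7)
  expect_equal(stage_logit(s, rep(0, 5), "cost"), 0)
  expect_equal(plogis(stage_logit(s, rep(0, 6), "evidence")), 0.5)
  # cost DVs: level indicator (low cost), j, j * c
  expect_equal(stage_logit(s, c(1, 2, 3, 4, 5), "cost"),
               2 + 4 * 3 + 5 * 0.3)
  # evidence DVs: 1, llr, |ci|, llr * |ci|, prev_correct, prev_n
  llr <- log(0.8 / 0.2)
  expect_equal(stage_logit(s, c(1, 1, 1, 1, 1, 1), "evidence"),
               1 + llr + 2 + llr * 2 + 1 + 7)
  expect_equal(plogis(log(3)), 0.75)  # logit ln 3 -> stop probability 3/4
  expect_error(stage_logit(s, rep(0, 4), "cost"), "length 5")
})

test_that("the registry enumerates the full sixteen-model space", {
  reg <- model_registry()
  expect_length(reg, 16)
  man <- model_manifest()
  expect_equal(sum(man$family == "two_stage"), 12)
  expect_true("Cost->C-cond,continue,Evidence" %in% man$name)
  expect_setequal(unique(man$order[man$family == "two_stage"]),
                  c("cost_first", "evidence_first"))
  # 2 x 2 x 3 crossing, 2 models per order x trigger x rule cell
  tab <- table(man$order[man$family == "two_stage"],
               man$trigger[man$family == "two_stage"],
               man$rule[man$family == "two_stage"])
  expect_true(all(tab == 1))
  # parameter counts: 11 stage weights + rule parameters + decay
  expect_equal(reg[["Cost->C-cond,continue,Evidence"]]$k_choice, 15)
  expect_equal(reg[["Cost->E-cond,stop,Evidence"]]$k_choice, 14)
  expect_equal(reg[["Evidence->flex,continue,Cost"]]$k_choice, 14)
  expect_equal(reg[["Cost only"]]$k_choice, 5)
  expect_equal(reg[["Evidence only w/o decay"]]$k_choice, 6)
  expect_equal(reg[["Cost + Evidence w/o decay"]]$k_choice, 10)
  expect_equal(reg[["Cost + Evidence"]]$k_choice, 11)
  expect_true(all(man$k_dt[man$family == "one_stage"] == 4))
  expect_true(all(man$k_dt[man$family == "two_stage"] == 8))
})

test_that("two-stage stop probabilities equal exhaustive tree enumeration", {
  # crafted probabilities via intercept-only states at j = 0
  spec <- model_registry()[["Cost->C-cond,continue,Evidence"]]
  st <- choice_state(0, condition(0, 0.6))
  par <- par_for(spec, w_cost_zero = qlogis(0.2), w_ev_icpt = qlogis(0.5),
                 psec_zero = 0)
  expect_equal(stop_probability(spec, par, st)$p_stop, 0.2)
  par["psec_zero"] <- 1
  expect_equal(stop_probability(spec, par, st)$p_stop, 0.2 + 0.8 * 0.5)
  spec_s <- model_registry()[["Cost->C-cond,stop,Evidence"]]
  par_s <- par_for(spec_s, w_cost_zero = qlogis(0.4), w_ev_icpt = 50,
                   psec_zero = 0.5)
  expect_equal(stop_probability(spec_s, par_s, st)$p_stop, 0.4,
               tolerance = 1e-9)
  par_s["psec_zero"] <- 0
  expect_equal(stop_probability(spec_s, par_s, st)$p_stop, 0.4)
  # flexible rule with gamma = 1, phi = 0 reproduces p_sec = p1
  spec_f <- model_registry()[["Cost->flex,continue,Evidence"]]
  par_f <- par_for(spec_f, w_cost_zero = qlogis(0.3), gamma = 1, phi = 0)
  expect_equal(stop_probability(spec_f, par_f, st)$p_sec, 0.3)

  set.seed(21)
  specs <- model_registry()
  for (rep in 1:200) {
    spec <- specs[[sample(5:16, 1)]]
    par <- random_par(spec)
    st <- random_state()
    sp <- stop_probability(spec, par, st)
    expect_equal(sp$p_stop,
                 enum_stop_probability(sp$p_stage1, sp$p_stage2, sp$p_sec,
                                       spec$trigger),
                 tolerance = 1e-13)
    expect_true(all(unlist(sp) >= 0 & unlist(sp) <= 1))
    if (spec$trigger == "continue") {
      expect_gte(sp$p_stop, sp$p_stage1 - 1e-12)
    } else {
      expect_lte(sp$p_stop, sp$p_stage1 + 1e-12)
    }
  }
})

test_that("choice likelihood counts the right terms and clamps loudly", {
  spec <- model_registry()[["Cost only"]]
  par0 <- par_for(spec)  # all-zero weights: p_stop = 0.5 at every state
  d1 <- make_manual_data("PB")  # 2 continues + 1 stop
  cd1 <- prepare_choice_data(d1$trials, d1$samples)
  expect_equal(choice_loglik(spec, par0, cd1), 3 * log(0.5))
  # a trial at the 20-sample cap contributes exactly 20 continue terms
  d2 <- make_manual_data(paste(rep("P", 20), collapse = ""))
  cd2 <- prepare_choice_data(d2$trials, d2$samples)
  expect_equal(cd2$n_states, 20L)
  expect_true(all(cd2$is_stop == 0L))
  expect_equal(choice_loglik(spec, par0, cd2), 20 * log(0.5))
  # conflicting deterministic prediction clamps at 1e-12 with a warning
  par_hard <- par_for(spec, w_cost_low = 50)
  expect_warning(ll <- choice_loglik(spec, par_hard, cd1), "clamped")
  expect_equal(as.numeric(ll), 2 * log(1e-12) + log(1 - 1e-12))
})

test_that("the C++ likelihood path agrees with the plain R path", {
  set.seed(5)
  ds <- simulate_single_model_population("cost_first", 1, seed = 8)
  cd <- prepare_choice_data(ds$trials, ds$samples,
                            participant = ds$participants$participant[1])
  for (spec in model_registry()[c(1, 2, 4, 5, 8, 11, 14, 16)]) {
    par <- random_par(spec)
    ll_cpp <- choice_loglik(spec, par, cd, engine = "cpp", keep_probs = TRUE)
    ll_r <- choice_loglik(spec, par, cd, engine = "r", keep_probs = TRUE)
    expect_equal(as.numeric(ll_cpp), as.numeric(ll_r), tolerance = 1e-10)
    expect_equal(attr(ll_cpp, "probs")$p_stop, attr(ll_r, "probs")$p_stop,
                 tolerance = 1e-12)
    # gradient-path objective agrees too
    pp <- beadsampling:::unpack_choice_par(spec, par)
    res <- beadsampling:::choice_nll_grad_cpp(
      as.numeric(par), spec$ix$wc - 1L, spec$ix$we - 1L, spec$ix$rule - 1L,
      spec$ix$alpha - 1L, beadsampling:::spec_codes(spec), cd$new_trial,
      cd$j, cd$cost_idx - 1L, cd$cost, cd$llr, cd$low_ev, cd$prev_correct,
      cd$prev_n, cd$is_stop, cd$bead_sign, FALSE)
    expect_equal(-res$nll, as.numeric(ll_cpp), tolerance = 1e-10)
  }
})

test_that("two-stage models nest their first-stage-only counterparts", {
  set.seed(6)
  ds <- simulate_single_model_population("cost_first", 1, seed = 9)
  cd <- prepare_choice_data(ds$trials, ds$samples,
                            participant = ds$participants$participant[1])
  cost_par <- c(w_cost_zero = -2.5, w_cost_low = -1.5, w_cost_high = -0.5,
                w_nsamp = 0.1, w_totcost = 0.2)
  spec1 <- model_registry()[["Cost only"]]
  ll1 <- choice_loglik(spec1, cost_par, cd)
  for (nm in c("Cost->C-cond,continue,Evidence", "Cost->E-cond,stop,Evidence")) {
    spec2 <- model_registry()[[nm]]
    par2 <- par_for(spec2)
    par2[names(cost_par)] <- cost_par
    par2[grepl("^psec", names(par2))] <- 0
    par2["w_ev_icpt"] <- rnorm(1)  # second stage never recruited
    expect_equal(choice_loglik(spec2, par2, cd), ll1, tolerance = 1e-10)
  }
})

test_that("with alpha = 1 the decayed CI is the plain signed count", {
  set.seed(3)
  signs <- sample(c(1, -1), 20, replace = TRUE)
  ci <- 0
  for (k in seq_along(signs)) {
    ci <- update_decayed_ci(ci, signs[k], alpha = 1)
    expect_equal(ci, sum(signs[seq_len(k)]))
  }
})

test_that("sampled stage paths reproduce the closed-form stop probability", {
  set.seed(9)
  for (trig in c("continue", "stop")) {
    nm <- sprintf("Cost->C-cond,%s,Evidence", trig)
    spec <- model_registry()[[nm]]
    sp <- list(p_stage1 = 0.35, p_stage2 = 0.6, p_sec = 0.5)
    sp$p_stop <- enum_stop_probability(sp$p_stage1, sp$p_stage2, sp$p_sec,
                                       trig)
    n_rep <- 2e4
    stops <- vapply(seq_len(n_rep), function(i) {
      beadsampling:::sample_stage_path(spec, sp)$stop
    }, logical(1))
    phat <- mean(stops)
    se <- sqrt(sp$p_stop * (1 - sp$p_stop) / n_rep)
    expect_lt(abs(phat - sp$p_stop), 2.6 * se)
  }
})
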