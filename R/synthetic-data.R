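# Synthetic task schedules and generative agents. The simulator inverts the
# choice and DT models: at every decision state the two-stage stop
# probability is decomposed into its stage path (first-stage outcome,
# second-thought recruitment, second-stage outcome), the path determines
# both the choice and which lognormal the decision time is drawn from, and
# the judgment follows the majority color with coin-flip ties.

.block_orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Generate a task schedule
#'
#' 288 trials in three 96-trial cost blocks (costs 0, 0.1, 0.4; block order
#' set by `permutation_id`), with the two evidence conditions randomly
#' mixed within block, 48 trials per cost x evidence cell, the
#' pink-dominant jar preselected on exactly half the trials of every cell,
#' and left/right jar positions counterbalanced.
#'
#' @param permutation_id block-order permutation, 1..6.
#' @param seed optional seed for the within-block shuffles.
#' @return data frame with columns `trial`, `block`, `permutation`, `cost`,
#'   `q`, `hidden_jar` (`"pink"`/`"blue"`), `pink_side` (`"left"`/`"right"`).
#' @export
make_schedule <- function(permutation_id = 1, seed = NULL) {
  if (!(permutation_id %in% 1:6)) stop("`permutation_id` must be in 1..6")
  order <- .block_orders[[permutation_id]]
  costs <- c(0, 0.1, 0.4)[order]
  with_local_seed(seed, {
    blocks <- lapply(seq_len(3), function(b) {
      cell <- expand.grid(q = c(0.6, 0.8), hidden_jar = c("pink", "blue"),
                          pink_side = c("left", "right"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      block <- cell[rep(seq_len(nrow(cell)), each = 12), ]  # 96 trials
      block <- block[sample.int(nrow(block)), ]
      block$block <- b
      block$cost <- costs[b]
      block
    })
    out <- do.call(rbind, blocks)
    out$trial <- seq_len(nrow(out))
    out$permutation <- permutation_id
    rownames(out) <- NULL
    out[, c("trial", "block", "permutation", "cost", "q", "hidden_jar",
            "pink_side")]
  })
}

#' Default generative parameters for a simulated agent
#'
#' Parameter sets for four representative generative processes. Values are
#' package choices tuned once so that simulated mean sample sizes decrease
#' with cost and evidence, stopping hazards stay in a realistic range, and
#' the two DT stages are separated enough to produce the characteristic
#' bimodal pooled log-DT distribution; they are not estimates from any real
#' dataset.
#'
#' @param strategy which generative process: the cost-first or
#'   evidence-first two-stage model (both continue-triggered with
#'   cost-conditional second thoughts), the stop-triggered cost-first
#'   variant, or the one-stage cost-only model.
#' @return list with `model` (registry name), `choice_par`, `dt_par`.
#' @export
default_agent_params <- function(strategy = c("cost_first", "evidence_first",
                                              "stop_triggered", "cost_only")) {
  strategy <- match.arg(strategy)
  dt8 <- c(b0_1 = 0.15, b1_1 = 0.35, b2_1 = 0.3, sigma_1 = 0.25,
           b0_2 = 0.45, b1_2 = 0.35, b2_2 = 0.3, sigma_2 = 0.3)
  switch(strategy,
    cost_first = list(
      model = "Cost->C-cond,continue,Evidence",
      choice_par = c(w_cost_zero = -4.2, w_cost_low = -3, w_cost_high = -1.8,
                     w_nsamp = 0.12, w_totcost = 0.3,
                     w_ev_icpt = -3.8, w_llr = 0, w_absci = 0.6, w_totev = 0.7,
                     w_prevcorr = 0.2, w_prevn = 0.01,
                     psec_zero = 0.25, psec_low = 0.45, psec_high = 0.6,
                     alpha = 0.92),
      dt_par = dt8),
    evidence_first = list(
      model = "Evidence->E-cond,continue,Cost",
      choice_par = c(w_cost_zero = -3.4, w_cost_low = -2, w_cost_high = -0.6,
                     w_nsamp = 0.12, w_totcost = 0.25,
                     w_ev_icpt = -5.6, w_llr = 0, w_absci = 0.5,
                     w_totev = 0.45, w_prevcorr = 0.2, w_prevn = 0.01,
                     psec_lowev = 0.55, psec_highev = 0.7,
                     alpha = 0.92),
      dt_par = dt8),
    stop_triggered = list(
      model = "Cost->C-cond,stop,Evidence",
      choice_par = c(w_cost_zero = -2.2, w_cost_low = -1.4, w_cost_high = -0.4,
                     w_nsamp = 0.18, w_totcost = 0.3,
                     w_ev_icpt = -3.5, w_llr = 0, w_absci = 0.6, w_totev = 0.7,
                     w_prevcorr = 0.2, w_prevn = 0.01,
                     psec_zero = 0.4, psec_low = 0.5, psec_high = 0.6,
                     alpha = 0.92),
      dt_par = dt8),
    cost_only = list(
      model = "Cost only",
      choice_par = c(w_cost_zero = -2.8, w_cost_low = -2, w_cost_high = -1,
                     w_nsamp = 0.15, w_totcost = 0.3),
      dt_par = c(b0_1 = 0.3, b1_1 = 0.4, b2_1 = 0.3, sigma_1 = 0.35))
  )
}

jitter_clamped <- function(x, sd, lower, upper) {
  pmin(pmax(x + rnorm(length(x), 0, sd), lower), upper)
}

#' Sample a population of agent profiles
#'
#' Each agent mixes a cost-first and an evidence-first two-stage process:
#' on every trial the process is drawn cost-first with probability
#' `pi_costfirst`, which is tied to the agent's (standardized) AQ score
#' through `logit(pi) = link_a + link_b * zAQ`, so a positive `link_b`
#' makes high-AQ agents near-pure cost-first and low-AQ agents more
#' balanced. Second-thought probabilities, the decay rate, stage-weight
#' intercepts and DT baselines vary across agents around the
#' [default_agent_params()] values.
#'
#' @param n number of agents.
#' @param aq_mean,aq_sd AQ score distribution (scores are rounded and
#'   clipped to the questionnaire range 0-150).
#' @param link_a,link_b strategy-mixing link coefficients.
#' @param seed optional seed.
#' @return list of agent profiles (id, aq, pi_costfirst, per-process
#'   parameters, per-agent seed).
#' @export
sample_agent_profiles <- function(n, aq_mean = 69.97, aq_sd = 10.48,
                                  link_a = 1, link_b = 1.5, seed = NULL) {
  with_local_seed(seed, {
    aq <- pmin(pmax(round(rnorm(n, aq_mean, aq_sd)), 0), 150)
    zaq <- (aq - aq_mean) / aq_sd
    pi_cf <- plogis(link_a + link_b * zaq)
    lapply(seq_len(n), function(i) {
      models <- list()
      for (strategy in c("cost_first", "evidence_first")) {
        base <- default_agent_params(strategy)
        cp <- base$choice_par
        psec_idx <- grepl("^psec", names(cp))
        conc <- 5
        cp[psec_idx] <- rbeta(sum(psec_idx), cp[psec_idx] * conc,
                              (1 - cp[psec_idx]) * conc)
        cp["alpha"] <- rbeta(1, 0.9 * 20, 0.1 * 20)
        icpt <- names(cp) %in% c("w_cost_zero", "w_cost_low", "w_cost_high",
                                 "w_ev_icpt")
        cp[icpt] <- cp[icpt] + rnorm(sum(icpt), 0, 0.35)
        cp["w_nsamp"] <- jitter_clamped(cp["w_nsamp"], 0.03, 0, 0.5)
        dp <- base$dt_par
        dp[c("b0_1", "b0_2")] <- jitter_clamped(dp[c("b0_1", "b0_2")], 0.08,
                                                0.02, 1.5)
        dp[c("sigma_1", "sigma_2")] <- jitter_clamped(
          dp[c("sigma_1", "sigma_2")], 0.03, 0.1, 1)
        models[[strategy]] <- list(model = base$model, choice_par = cp,
                                   dt_par = dp)
      }
      list(id = sprintf("agent%03d", i), aq = aq[i], pi_costfirst = pi_cf[i],
           models = models,
           seed = as.integer((i * 7919) %% 2147483587))
    })
  })
}

#' Simulate one agent on a schedule
#'
#' @param profile an agent profile: either an element of
#'   [sample_agent_profiles()] or a list with `id`, `models` (named list of
#'   `model`/`choice_par`/`dt_par` sets) and optionally `pi_costfirst` for
#'   trial-wise mixing of a `cost_first` and an `evidence_first` process.
#' @param schedule a [make_schedule()] data frame.
#' @param seed optional seed.
#' @param n_cap sampling cap, default 20.
#' @return list with `trials` and `samples` data frames for the agent. The
#'   samples table carries the ground-truth `dt_stage` of each continue
#'   choice (1 or 2); trials carry the generative `process` used.
#' @export
simulate_agent <- function(profile, schedule, seed = NULL, n_cap = 20L) {
  registry <- model_registry()
  specs <- lapply(profile$models, function(m) registry[[m$model]])
  with_local_seed(seed, {
    n_tr <- nrow(schedule)
    trials <- schedule
    trials$participant <- profile$id
    trials$n_samples <- NA_integer_
    trials$judgment <- NA_character_
    trials$correct <- NA_integer_
    trials$process <- NA_character_
    sample_rows <- vector("list", n_tr)
    prev_correct <- 0.5
    prev_n <- 0
    for (i in seq_len(n_tr)) {
      tr <- schedule[i, ]
      cond <- condition(tr$cost, tr$q)
      proc <- if (length(specs) == 1L) {
        names(specs)[1]
      } else if (runif(1) < profile$pi_costfirst) "cost_first" else "evidence_first"
      spec <- specs[[proc]]
      mp <- profile$models[[proc]]
      alpha <- unpack_choice_par(spec, mp$choice_par)$alpha
      ci <- 0
      pinks <- 0L
      rows <- list()
      j <- 0L
      stopped <- FALSE
      while (j < n_cap) {
        st <- choice_state(j, cond, ci_decayed = ci,
                           prev_correct = prev_correct, prev_n = prev_n)
        sp <- stop_probability(spec, mp$choice_par, st)
        path <- sample_stage_path(spec, sp)
        if (path$stop) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = profile$id, trial = tr$trial, j = j + 1L,
            bead = NA_character_, choice = "stop", dt = NA_real_,
            dt_stage = NA_integer_, stringsAsFactors = FALSE)
          stopped <- TRUE
          break
        }
        y <- expected_stage_dts(sp$p_stage1, sp$p_stage2, mp$dt_par,
                                if (spec$family == "two_stage") spec$trigger else NA)
        dt <- if (path$stage == 2L) {
          simulate_dt(y$y_cont2, mp$dt_par[["sigma_2"]], 1)
        } else {
          simulate_dt(y$y_cont1, mp$dt_par[["sigma_1"]], 1)
        }
        p_pink <- if (tr$hidden_jar == "pink") tr$q else 1 - tr$q
        bead <- if (runif(1) < p_pink) "P" else "B"
        if (bead == "P") pinks <- pinks + 1L
        j <- j + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          participant = profile$id, trial = tr$trial, j = j, bead = bead,
          choice = "continue", dt = dt, dt_stage = path$stage,
          stringsAsFactors = FALSE)
        ci <- update_decayed_ci(ci, bead, alpha)
      }
      blues <- j - pinks
      chosen <- if (pinks > blues) "pink" else if (pinks < blues) "blue" else
        sample(c("pink", "blue"), 1)
      hidden_side <- if (tr$hidden_jar == "pink") tr$pink_side else
        setdiff(c("left", "right"), tr$pink_side)
      chosen_side <- if (chosen == "pink") tr$pink_side else
        setdiff(c("left", "right"), tr$pink_side)
      trials$n_samples[i] <- j
      trials$judgment[i] <- chosen_side
      trials$correct[i] <- as.integer(chosen == tr$hidden_jar)
      trials$process[i] <- proc
      sample_rows[[i]] <- do.call(rbind, rows)
      prev_correct <- trials$correct[i]
      prev_n <- j
    }
    list(trials = trials, samples = do.call(rbind, sample_rows))
  })
}

# Draw the latent stage path of one decision given the stage probabilities.
# Returns stop (logical) and, for continue choices, the stage (1 or 2) in
# which the decision was finalized.
sample_stage_path <- function(spec, sp) {
  if (spec$family == "one_stage") {
    return(list(stop = runif(1) < sp$p_stop, stage = 1L))
  }
  stop1 <- runif(1) < sp$p_stage1
  if (spec$trigger == "continue") {
    if (stop1) return(list(stop = TRUE, stage = 1L))
    if (runif(1) >= sp$p_sec) return(list(stop = FALSE, stage = 1L))
    list(stop = runif(1) < sp$p_stage2, stage = 2L)
  } else {
    if (!stop1) return(list(stop = FALSE, stage = 1L))
    if (runif(1) >= sp$p_sec) return(list(stop = TRUE, stage = 1L))
    list(stop = runif(1) < sp$p_stage2, stage = 2L)
  }
}

#' Simulate a population of agents on the full task
#'
#' Draws `n_agents` AQ-linked agent profiles ([sample_agent_profiles()]),
#' gives each a block-order-counterbalanced schedule, and simulates every
#' trial. The returned dataset carries a ground-truth manifest (per-agent
#' generative parameters) for recovery studies.
#'
#' @inheritParams sample_agent_profiles
#' @param n_agents number of agents, default 104 (the canonical sample
#'   size of the task design emulated here).
#' @param seed integer seed governing all randomness.
#' @return list of class `"beads_dataset"` with `trials`, `samples`,
#'   `participants`, `manifest` (data frame of generative parameters) and
#'   `profiles`.
#' @export
simulate_population <- function(n_agents = 104, seed = 1, aq_mean = 69.97,
                                aq_sd = 10.48, link_a = 1, link_b = 1.5) {
  if (n_agents < 2) stop("need at least 2 agents")
  profiles <- sample_agent_profiles(n_agents, aq_mean, aq_sd, link_a, link_b,
                                    seed = seed)
  trials <- list()
  samples <- list()
  with_local_seed(seed + 104729, {
    age <- sample(18:28, n_agents, replace = TRUE)
    gender <- sample(c("f", "m"), n_agents, replace = TRUE)
  })
  for (i in seq_len(n_agents)) {
    sched <- make_schedule(permutation_id = ((i - 1L) %% 6L) + 1L,
                           seed = (seed * 131 + i) %% 2147483587)
    sim <- simulate_agent(profiles[[i]], sched,
                          seed = (seed * 524287 + i * 2654435761) %% 2147483587)
    trials[[i]] <- sim$trials
    samples[[i]] <- sim$samples
  }
  manifest <- do.call(rbind, lapply(profiles, function(p) {
    cp <- p$models$cost_first$choice_par
    dp <- p$models$cost_first$dt_par
    data.frame(participant = p$id, aq = p$aq, pi_costfirst = p$pi_costfirst,
               psec_zero = cp[["psec_zero"]], psec_low = cp[["psec_low"]],
               psec_high = cp[["psec_high"]], alpha = cp[["alpha"]],
               b0_1 = dp[["b0_1"]], b0_2 = dp[["b0_2"]],
               sigma_1 = dp[["sigma_1"]], sigma_2 = dp[["sigma_2"]],
               stringsAsFactors = FALSE)
  }))
  participants <- data.frame(
    participant = vapply(profiles, `[[`, character(1), "id"),
    aq = vapply(profiles, `[[`, numeric(1), "aq"),
    age = age, gender = gender, stringsAsFactors = FALSE)
  structure(list(trials = do.call(rbind, trials),
                 samples = do.call(rbind, samples),
                 participants = participants, manifest = manifest,
                 profiles = profiles, seed = seed),
            class = "beads_dataset")
}

#' @export
print.beads_dataset <- function(x, ...) {
  cat(sprintf("<beads_dataset: %d participants, %d trials, %d sampling choices>\n",
              nrow(x$participants), nrow(x$trials), nrow(x$samples)))
  invisible(x)
}

#' Simulate a homogeneous single-model population
#'
#' Convenience generator for recovery studies: every agent uses one fixed
#' generative model (no strategy mixing), with per-agent heterogeneity in
#' second-thought probabilities, decay and DT baselines.
#'
#' @param strategy passed to [default_agent_params()].
#' @param n_agents number of agents.
#' @param seed integer seed.
#' @return a `"beads_dataset"` (manifest columns restricted to the
#'   generative model's parameters).
#' @export
simulate_single_model_population <- function(strategy, n_agents, seed = 1) {
  base <- default_agent_params(strategy)
  with_local_seed(seed, {
    profiles <- lapply(seq_len(n_agents), function(i) {
      cp <- base$choice_par
      psec_idx <- grepl("^psec", names(cp))
      if (any(psec_idx)) {
        conc <- 5
        cp[psec_idx] <- rbeta(sum(psec_idx), cp[psec_idx] * conc,
                              (1 - cp[psec_idx]) * conc)
      }
      if ("alpha" %in% names(cp)) cp["alpha"] <- rbeta(1, 0.9 * 20, 0.1 * 20)
      icpt <- names(cp) %in% c("w_cost_zero", "w_cost_low", "w_cost_high",
                               "w_ev_icpt")
      cp[icpt] <- cp[icpt] + rnorm(sum(icpt), 0, 0.35)
      dp <- base$dt_par
      b0s <- grep("^b0", names(dp))
      dp[b0s] <- jitter_clamped(dp[b0s], 0.08, 0.02, 1.5)
      list(id = sprintf("%s%03d", gsub("_", "", strategy), i),
           aq = NA_real_, pi_costfirst = NA_real_,
           models = setNames(list(list(model = base$model, choice_par = cp,
                                       dt_par = dp)), strategy),
           seed = i)
    })
    NULL
  })
  trials <- list()
  samples <- list()
  for (i in seq_len(n_agents)) {
    sched <- make_schedule(permutation_id = ((i - 1L) %% 6L) + 1L,
                           seed = (seed * 257 + i) %% 2147483587)
    sim <- simulate_agent(profiles[[i]], sched,
                          seed = (seed * 65537 + i * 39916801) %% 2147483587)
    trials[[i]] <- sim$trials
    samples[[i]] <- sim$samples
  }
  manifest <- do.call(rbind, lapply(profiles, function(p) {
    m <- p$models[[1]]
    out <- data.frame(participant = p$id, model = m$model,
                      stringsAsFactors = FALSE)
    for (nm in names(m$choice_par)) out[[nm]] <- m$choice_par[[nm]]
    for (nm in names(m$dt_par)) out[[nm]] <- m$dt_par[[nm]]
    out
  }))
  participants <- data.frame(
    participant = vapply(profiles, `[[`, character(1), "id"),
    aq = NA_real_, stringsAsFactors = FALSE)
  structure(list(trials = do.call(rbind, trials),
                 samples = do.call(rbind, samples),
                 participants = participants, manifest = manifest,
                 profiles = profiles, seed = seed),
            class = "beads_dataset")
}
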