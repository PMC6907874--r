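# Decision-variable coding shared by all models.
#
# Cost-related DVs (5 weights): one intercept per cost level (no global
# intercept, which keeps the weight count at the canonical 11 for the
# two-stage models and avoids dummy-coding collinearity), the number of
# beads drawn so far j, and the total sampling cost j*c.
#
# Evidence-related DVs (6 weights): stage intercept, unit log evidence
# ln(q/(1-q)), absolute decayed cumulative information |CI|, total log
# evidence ln(q/(1-q))*|CI|, previous-trial correctness (0/1, 0.5 on the
# first trial), and previous-trial sample count.

.cost_par_names <- c("w_cost_zero", "w_cost_low", "w_cost_high",
                     "w_nsamp", "w_totcost")
.ev_par_names <- c("w_ev_icpt", "w_llr", "w_absci", "w_totev",
                   "w_prevcorr", "w_prevn")
.cost_levels <- c(0, 0.1, 0.4)

.rule_par_names <- list(
  cost_condition = c("psec_zero", "psec_low", "psec_high"),
  evidence_condition = c("psec_lowev", "psec_highev"),
  flexible = c("gamma", "phi")
)

.weight_bound <- 50  # implementation clip for nominally unbounded weights

cost_level_index <- function(cost) {
  idx <- match(cost, .cost_levels)
  if (anyNA(idx)) {
    stop("unit cost must be one of ", paste(.cost_levels, collapse = ", "))
  }
  idx
}

new_choice_spec <- function(name, family, order = NA_character_,
                            trigger = NA_character_, rule = NA_character_,
                            decay, use_cost = TRUE, use_ev = TRUE) {
  rule_par <- if (!is.na(rule)) .rule_par_names[[rule]] else character(0)
  if (family == "one_stage") {
    par_names <- c(if (use_cost) .cost_par_names,
                   if (use_ev && use_cost) .ev_par_names[-1],
                   if (use_ev && !use_cost) .ev_par_names,
                   if (decay) "alpha")
  } else {
    par_names <- c(.cost_par_names, .ev_par_names, rule_par, "alpha")
  }
  lower <- rep(-.weight_bound, length(par_names))
  upper <- rep(.weight_bound, length(par_names))
  prob_par <- par_names %in% c("psec_zero", "psec_low", "psec_high",
                               "psec_lowev", "psec_highev", "alpha")
  lower[prob_par] <- 0
  upper[prob_par] <- 1
  ix <- list(wc = match(.cost_par_names, par_names, nomatch = 0L),
             we = match(.ev_par_names, par_names, nomatch = 0L),
             rule = match(rule_par, par_names),
             alpha = match("alpha", par_names, nomatch = 0L))
  ix$wc_nz <- ix$wc > 0L
  ix$we_nz <- ix$we > 0L
  structure(list(
    name = name, family = family, order = order, trigger = trigger,
    rule = rule, decay = decay, use_cost = use_cost, use_ev = use_ev,
    par_names = par_names, lower = lower, upper = upper, ix = ix,
    k_choice = length(par_names),
    k_dt = if (family == "one_stage") 4L else 8L
  ), class = "choice_model_spec")
}

#' @export
print.choice_model_spec <- function(x, ...) {
  cat(sprintf("<choice model '%s': %s, %d choice + %d DT parameters>\n",
              x$name, gsub("_", "-", x$family), x$k_choice, x$k_dt))
  invisible(x)
}

#' The sixteen-model registry of sampling-choice models
#'
#' Enumerates the full model space: four one-stage models (stopping
#' probability a logistic function of cost DVs, evidence DVs, or both, the
#' latter with or without evidence decay) and twelve two-stage models, the
#' 2 x 2 x 3 crossing of stage order (cost-first vs. evidence-first), the
#' first-stage decision that can trigger an optional second stage (continue
#' vs. stop), and the rule governing the second-thought probability (set by
#' the cost condition, the evidence condition, or a flexible logit-linear
#' function of the first-stage stop probability). Two-stage model names read
#' `first->rule,trigger,second`, e.g. `"Cost->C-cond,continue,Evidence"`.
#'
#' @return a named list of 16 `choice_model_spec` objects.
#' @examples
#' length(model_registry())
#' model_manifest()[, c("name", "k_choice")]
#' @export
model_registry <- function() {
  specs <- list(
    new_choice_spec("Cost only", "one_stage", decay = FALSE,
                    use_cost = TRUE, use_ev = FALSE),
    new_choice_spec("Evidence only w/o decay", "one_stage", decay = FALSE,
                    use_cost = FALSE, use_ev = TRUE),
    new_choice_spec("Cost + Evidence w/o decay", "one_stage", decay = FALSE),
    new_choice_spec("Cost + Evidence", "one_stage", decay = TRUE)
  )
  rule_code <- c(cost_condition = "C-cond", evidence_condition = "E-cond",
                 flexible = "flex")
  for (order in c("cost_first", "evidence_first")) {
    first <- if (order == "cost_first") "Cost" else "Evidence"
    second <- if (order == "cost_first") "Evidence" else "Cost"
    for (rule in names(rule_code)) {
      for (trigger in c("continue", "stop")) {
        name <- sprintf("%s->%s,%s,%s", first, rule_code[[rule]], trigger,
                        second)
        specs <- c(specs, list(new_choice_spec(
          name, "two_stage", order = order, trigger = trigger, rule = rule,
          decay = TRUE)))
      }
    }
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname model_registry
#' @return `model_manifest()`: a data frame with one row per model (name,
#'   family, stage order, trigger, second-thought rule, decay flag,
#'   parameter counts and names), suitable for machine consumption.
#' @export
model_manifest <- function() {
  specs <- model_registry()
  data.frame(
    name = vapply(specs, `[[`, character(1), "name"),
    family = vapply(specs, `[[`, character(1), "family"),
    order = vapply(specs, `[[`, character(1), "order"),
    trigger = vapply(specs, `[[`, character(1), "trigger"),
    rule = vapply(specs, `[[`, character(1), "rule"),
    decay = vapply(specs, `[[`, logical(1), "decay"),
    k_choice = vapply(specs, `[[`, integer(1), "k_choice"),
    k_dt = vapply(specs, `[[`, integer(1), "k_dt"),
    par_names = vapply(specs, function(s) paste(s$par_names, collapse = ";"),
                       character(1)),
    row.names = NULL
  )
}

#' Decayed cumulative information update
#'
#' Cumulative information (CI) is the signed pink-minus-blue sample count,
#' optionally leaky: after each bead the running value is multiplied by the
#' decay rate `alpha` before the new bead's +/-1 contribution is added.
#' `alpha = 1` recovers the plain count; `alpha = 0` retains only the most
#' recent bead.
#'
#' @param ci current decayed CI (0 before the first bead).
#' @param bead `"P"`/`"pink"` or `"B"`/`"blue"`, or a +/-1 numeric sign.
#' @param alpha decay rate in \[0, 1\].
#' @return updated CI.
#' @examples
#' ci <- 0
#' for (b in c("P", "P", "B")) ci <- update_decayed_ci(ci, b, alpha = 1)
#' ci  # +1
#' @export
update_decayed_ci <- function(ci, bead, alpha) {
  if (!(alpha >= 0 && alpha <= 1)) stop("`alpha` must lie in [0, 1]")
  sign <- bead_sign(bead)
  alpha * ci + sign
}

bead_sign <- function(bead) {
  if (is.numeric(bead)) {
    if (!all(bead %in% c(-1, 1))) stop("numeric bead codes must be +/-1")
    return(bead)
  }
  key <- toupper(substr(as.character(bead), 1, 1))
  out <- ifelse(key == "P", 1, ifelse(key == "B", -1, NA_real_))
  if (anyNA(out)) stop("bead colors must be pink ('P') or blue ('B')")
  out
}

#' Decision state for a single sampling choice
#'
#' Bundles everything a choice model needs to evaluate one stop/continue
#' decision: the number of beads drawn so far, the condition, the decayed
#' cumulative information, and the previous-trial covariates.
#'
#' @param j beads drawn so far (0-based within trial).
#' @param condition a [condition()].
#' @param ci_decayed signed decayed pink-minus-blue count.
#' @param prev_correct previous-trial correctness, 0/1 (0.5 on trial 1).
#' @param prev_n previous-trial sample count (0 on trial 1).
#' @return list of class `"choice_state"`.
#' @export
choice_state <- function(j, condition, ci_decayed = 0, prev_correct = 0.5,
                         prev_n = 0) {
  condition <- as_condition(condition)
  structure(list(j = j, condition = condition, ci_decayed = ci_decayed,
                 prev_correct = prev_correct, prev_n = prev_n),
            class = "choice_state")
}

cost_dvs <- function(state) {
  lev <- numeric(3)
  lev[cost_level_index(state$condition$unit_cost)] <- 1
  c(lev, state$j, state$j * state$condition$unit_cost)
}

evidence_dvs <- function(state) {
  llr <- log(state$condition$q / (1 - state$condition$q))
  absci <- abs(state$ci_decayed)
  c(1, llr, absci, llr * absci, state$prev_correct, state$prev_n)
}

#' Linear predictor of one decision stage
#'
#' Computes `X = sum_k beta_k DV_k` for one stage. Cost DVs are the cost
#' level indicator, the count of beads drawn, and the total cost; evidence
#' DVs are an intercept, the unit log evidence, the absolute decayed
#' cumulative information, the total log evidence, and the previous-trial
#' correctness and sample count.
#'
#' @param state a [choice_state()].
#' @param weights numeric vector: length 5 for `dv_set = "cost"`, length 6
#'   for `dv_set = "evidence"`.
#' @param dv_set `"cost"` or `"evidence"`.
#' @return the scalar logit of stopping for the stage.
#' @examples
#' s <- choice_state(3, condition(0.1, 0.8), ci_decayed = 2)
#' plogis(stage_logit(s, rep(0, 5), "cost"))  # 0.5
#' @export
stage_logit <- function(state, weights, dv_set = c("cost", "evidence")) {
  dv_set <- match.arg(dv_set)
  dvs <- if (dv_set == "cost") cost_dvs(state) else evidence_dvs(state)
  if (length(weights) != length(dvs)) {
    stop(sprintf("`weights` must have length %d for the %s DV set",
                 length(dvs), dv_set))
  }
  sum(weights * dvs)
}

# Split a flat named parameter vector into the pieces the likelihood needs.
# `we` is always returned with length 6; one-stage cost+evidence models have
# no separate evidence intercept (the cost level indicators span it), so the
# intercept slot is fixed at 0 for them.
unpack_choice_par <- function(spec, par) {
  if (length(par) != spec$k_choice) {
    stop(sprintf("model '%s' expects %d choice parameters, got %d",
                 spec$name, spec$k_choice, length(par)))
  }
  par <- as.numeric(par)
  ix <- spec$ix
  wc <- numeric(5)
  we <- numeric(6)
  if (any(ix$wc_nz)) wc[ix$wc_nz] <- par[ix$wc[ix$wc_nz]]
  if (any(ix$we_nz)) we[ix$we_nz] <- par[ix$we[ix$we_nz]]
  rulep <- if (length(ix$rule)) par[ix$rule] else numeric(0)
  alpha <- if (ix$alpha > 0L) par[ix$alpha] else 1
  list(wc = wc, we = we, rulep = rulep, alpha = alpha)
}

#' Stop probability of a choice model at one decision state
#'
#' For one-stage models the stop probability is the logistic of the stage
#' linear predictor. Two-stage models combine the two stage probabilities
#' with a second-thought probability `p_sec`: when continuing triggers the
#' second stage, `p_stop = p1 + (1 - p1) p_sec p2`; when stopping triggers
#' it, `p_stop = p1 (1 - p_sec) + p1 p_sec p2`. Under the flexible rule
#' `logit(p_sec) = gamma logit(p1) + phi`.
#'
#' @param spec a `choice_model_spec` from [model_registry()].
#' @param par flat named parameter vector (`spec$par_names` order).
#' @param state a [choice_state()].
#' @return list with `p_stop`, `p_stage1`, and (two-stage) `p_stage2`,
#'   `p_sec` (`NA` for one-stage models).
#' @examples
#' spec <- model_registry()[["Cost->C-cond,continue,Evidence"]]
#' par <- setNames(rep(0, spec$k_choice), spec$par_names)
#' par[c("psec_zero", "psec_low", "psec_high")] <- 0.5
#' par["alpha"] <- 1
#' stop_probability(spec, par, choice_state(0, condition(0, 0.6)))
#' @export
stop_probability <- function(spec, par, state) {
  pp <- unpack_choice_par(spec, par)
  xc <- stage_logit(state, pp$wc, "cost")
  xe <- stage_logit(state, pp$we, "evidence")
  if (spec$family == "one_stage") {
    x <- (if (spec$use_cost) xc else 0) + (if (spec$use_ev) xe else 0)
    p1 <- plogis(x)
    return(list(p_stop = p1, p_stage1 = p1, p_stage2 = NA_real_,
                p_sec = NA_real_))
  }
  x1 <- if (spec$order == "cost_first") xc else xe
  x2 <- if (spec$order == "cost_first") xe else xc
  p1 <- plogis(x1)
  p2 <- plogis(x2)
  psec <- switch(spec$rule,
    cost_condition = pp$rulep[cost_level_index(state$condition$unit_cost)],
    evidence_condition = pp$rulep[if (state$condition$q == 0.6) 1L else 2L],
    flexible = plogis(pp$rulep[1] * x1 + pp$rulep[2])
  )
  p_stop <- if (spec$trigger == "continue") {
    p1 + (1 - p1) * psec * p2
  } else {
    p1 * (1 - psec) + p1 * psec * p2
  }
  list(p_stop = p_stop, p_stage1 = p1, p_stage2 = p2, p_sec = psec)
}

#' Build the per-choice table for likelihood evaluation
#'
#' Expands a participant's trials into one record per stop/continue decision
#' state: the state after `j` beads on each trial, for `j = 0 .. n_s - 1`
#' (continue choices) plus the stop choice at `j = n_s` unless the trial hit
#' the 20-bead cap, where the forced stop is not a choice and is excluded.
#'
#' @param trials trial-level data frame (one row per trial with columns
#'   `participant`, `trial`, `cost`, `q`, `n_samples`, `correct`).
#' @param samples sample-level data frame (one row per sampling choice with
#'   columns `participant`, `trial`, `j`, `bead`, `choice`, `dt`).
#' @param participant optional id to subset to.
#' @param n_cap sampling cap, default 20.
#' @return list of class `"choice_data"` of parallel per-state vectors.
#' @export
prepare_choice_data <- function(trials, samples, participant = NULL,
                                n_cap = 20L) {
  if (!is.null(participant)) {
    trials <- trials[trials$participant == participant, , drop = FALSE]
    samples <- samples[samples$participant == participant, , drop = FALSE]
  }
  if (length(unique(trials$participant)) != 1L) {
    stop("`prepare_choice_data()` expects trials from a single participant")
  }
  trials <- trials[order(trials$trial), , drop = FALSE]
  draws <- samples[samples$choice == "continue", , drop = FALSE]
  draws <- draws[order(draws$trial, draws$j), , drop = FALSE]
  sign_by_trial <- split(bead_sign(draws$bead), draws$trial)
  dt_by_trial <- split(draws$dt, draws$trial)

  n_tr <- nrow(trials)
  ns <- trials$n_samples
  n_states <- sum(ns + as.integer(ns < n_cap))
  out <- list(
    participant = trials$participant[1],
    trial = integer(n_states), new_trial = integer(n_states),
    j = integer(n_states), cost_idx = integer(n_states),
    cost = numeric(n_states), llr = numeric(n_states),
    low_ev = integer(n_states), prev_correct = numeric(n_states),
    prev_n = numeric(n_states), is_stop = integer(n_states),
    bead_sign = numeric(n_states), dt = numeric(n_states)
  )
  pos <- 0L
  prev_correct <- 0.5
  prev_n <- 0
  for (i in seq_len(n_tr)) {
    tr <- trials[i, ]
    key <- as.character(tr$trial)
    signs <- sign_by_trial[[key]]
    if (length(signs) != tr$n_samples) {
      stop(sprintf("trial %s: %d continue rows but n_samples = %d",
                   key, length(signs), tr$n_samples))
    }
    dts <- dt_by_trial[[key]]
    k <- tr$n_samples + as.integer(tr$n_samples < n_cap)
    idx <- pos + seq_len(k)
    out$trial[idx] <- tr$trial
    out$new_trial[idx] <- c(1L, rep(0L, k - 1L))
    out$j[idx] <- seq_len(k) - 1L
    out$cost_idx[idx] <- cost_level_index(tr$cost)
    out$cost[idx] <- tr$cost
    out$llr[idx] <- log(tr$q / (1 - tr$q))
    out$low_ev[idx] <- as.integer(tr$q == 0.6)
    out$prev_correct[idx] <- prev_correct
    out$prev_n[idx] <- prev_n
    stops <- c(rep(0L, tr$n_samples), if (tr$n_samples < n_cap) 1L)
    out$is_stop[idx] <- stops
    out$bead_sign[idx] <- c(signs, if (tr$n_samples < n_cap) 0)
    out$dt[idx] <- c(dts, if (tr$n_samples < n_cap) NA_real_)
    pos <- pos + k
    prev_correct <- as.numeric(tr$correct)
    prev_n <- tr$n_samples
  }
  out$n_states <- n_states
  class(out) <- "choice_data"
  out
}

#' @export
print.choice_data <- function(x, ...) {
  cat(sprintf("<choice data: participant %s, %d decision states (%d stops)>\n",
              x$participant, x$n_states, sum(x$is_stop)))
  invisible(x)
}

#' Choice log-likelihood of a model on one participant's data
#'
#' Sums `ln p_stop` over observed stop choices and `ln(1 - p_stop)` over
#' continue choices; the forced stop after 20 samples is never included.
#' Probabilities conflicting with the observed choice are clamped at 1e-12
#' before the log and a warning reports how many clamps occurred.
#'
#' @inheritParams stop_probability
#' @param data a `"choice_data"` object from [prepare_choice_data()].
#' @param engine `"cpp"` (fast path used by fitting) or `"r"` (plain
#'   reference loop over [stop_probability()]).
#' @param keep_probs if `TRUE`, attach per-state probability vectors
#'   (`p_stage1`, `p_stage2`, `p_sec`, `p_stop`) needed by the DT model.
#' @return the log-likelihood, with attribute `probs` when requested.
#' @export
choice_loglik <- function(spec, par, data, engine = c("cpp", "r"),
                          keep_probs = FALSE) {
  engine <- match.arg(engine)
  pp <- unpack_choice_par(spec, par)
  codes <- spec_codes(spec)
  if (engine == "cpp") {
    res <- choice_eval_cpp(pp$wc, pp$we, pp$rulep, pp$alpha, codes,
                           data$new_trial, data$j, data$cost_idx - 1L,
                           data$cost, data$llr, data$low_ev,
                           data$prev_correct, data$prev_n, data$is_stop,
                           data$bead_sign, keep_probs)
  } else {
    res <- choice_eval_r(spec, par, data, keep_probs)
  }
  if (res$n_clamped > 0L) {
    warning(sprintf("%d choice probabilities clamped at 1e-12", res$n_clamped))
  }
  out <- res$loglik
  if (keep_probs) {
    attr(out, "probs") <- list(p_stage1 = res$p1, p_stage2 = res$p2,
                               p_sec = res$psec, p_stop = res$pstop)
  }
  out
}

spec_codes <- function(spec) {
  c(family = if (spec$family == "one_stage") 1L else 2L,
    order = if (is.na(spec$order)) 0L else if (spec$order == "cost_first") 1L else 2L,
    trigger = if (is.na(spec$trigger)) 0L else if (spec$trigger == "continue") 1L else 2L,
    rule = if (is.na(spec$rule)) 0L else match(spec$rule, names(.rule_par_names)),
    use_cost = as.integer(spec$use_cost),
    use_ev = as.integer(spec$use_ev))
}

# Reference implementation: a plain R loop over stop_probability().
choice_eval_r <- function(spec, par, data, keep_probs = FALSE) {
  pp <- unpack_choice_par(spec, par)
  n <- data$n_states
  p1 <- p2 <- psec <- pstop <- rep(NA_real_, n)
  ll <- 0
  n_clamped <- 0L
  ci <- 0
  for (i in seq_len(n)) {
    if (data$new_trial[i] == 1L) ci <- 0
    st <- choice_state(data$j[i],
                       condition(data$cost[i], if (data$low_ev[i]) 0.6 else 0.8),
                       ci_decayed = ci, prev_correct = data$prev_correct[i],
                       prev_n = data$prev_n[i])
    sp <- stop_probability(spec, par, st)
    p1[i] <- sp$p_stage1; p2[i] <- sp$p_stage2
    psec[i] <- sp$p_sec; pstop[i] <- sp$p_stop
    pc <- if (data$is_stop[i] == 1L) sp$p_stop else 1 - sp$p_stop
    if (pc < 1e-12) {
      pc <- 1e-12
      n_clamped <- n_clamped + 1L
    }
    ll <- ll + log(pc)
    if (data$is_stop[i] == 0L) ci <- pp$alpha * ci + data$bead_sign[i]
  }
  list(loglik = ll, n_clamped = n_clamped, p1 = p1, p2 = p2, psec = psec,
       pstop = pstop)
}
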