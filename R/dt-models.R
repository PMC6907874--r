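# Decision-time (DT) model: each decision stage contributes a lognormal
# latency whose expected value depends on how (un)easy the stage's decision
# was. Only DTs for continuing sampling are modeled; the stop key press and
# the final judgment are bookkeeping. There is no separate non-decision
# constant: the stage baselines exp(b0) absorb it.

#' Expected stage decision times
#'
#' The expected DT of a stage decision is
#' `exp(b0 + b1 * (1 - p) + b2 * p * (1 - p))` for continuing (with `p` the
#' stage's stop probability) and the same expression with `p` in place of
#' `1 - p` for stopping; the quadratic term tracks choice difficulty. A
#' continue decision finalized in the second stage takes the first-stage
#' time plus a second-stage increment of the same form: the first-stage term
#' is the continue time when continuing triggers the second thought and the
#' stop time when stopping does.
#'
#' @param p_stage1,p_stage2 stage stop probabilities (vectorized).
#' @param dt_par named numeric vector: `b0_1`, `b1_1`, `b2_1`, `sigma_1`
#'   and, for two-stage models, `b0_2`, `b1_2`, `b2_2`, `sigma_2`.
#' @param trigger `"continue"`, `"stop"`, or `NA` for one-stage models.
#' @return list with `y_cont1`, `y_stop1`, and `y_cont2` (`NULL` for
#'   one-stage models), in seconds.
#' @examples
#' expected_stage_dts(0.2, NA, c(b0_1 = log(0.3), b1_1 = 1, b2_1 = 0,
#'                               sigma_1 = 0.3), NA)
#' @export
expected_stage_dts <- function(p_stage1, p_stage2, dt_par, trigger) {
  y_cont1 <- exp(dt_par[["b0_1"]] + dt_par[["b1_1"]] * (1 - p_stage1) +
                 dt_par[["b2_1"]] * p_stage1 * (1 - p_stage1))
  y_stop1 <- exp(dt_par[["b0_1"]] + dt_par[["b1_1"]] * p_stage1 +
                 dt_par[["b2_1"]] * p_stage1 * (1 - p_stage1))
  y_cont2 <- NULL
  if (!is.na(trigger) && length(trigger) == 1L && trigger %in% c("continue", "stop")) {
    base <- if (trigger == "continue") y_cont1 else y_stop1
    y_cont2 <- base + exp(dt_par[["b0_2"]] + dt_par[["b1_2"]] * (1 - p_stage2) +
                          dt_par[["b2_2"]] * p_stage2 * (1 - p_stage2))
  }
  list(y_cont1 = y_cont1, y_stop1 = y_stop1, y_cont2 = y_cont2)
}

#' Stage posteriors given a continue choice
#'
#' Probability that an observed continue choice was finalized in stage 1
#' versus stage 2. When continuing triggers the second thought,
#' `P(S1 | continue) = (1 - p_sec) / ((1 - p_sec) + p_sec (1 - p2))`; when
#' stopping triggers it,
#' `P(S1 | continue) = (1 - p1) / ((1 - p1) + p1 p_sec (1 - p2))`. The pair
#' always sums to 1.
#'
#' @inheritParams expected_stage_dts
#' @param p_sec second-thought probability (vectorized).
#' @param trigger `"continue"` or `"stop"`.
#' @return list with `p_s1` and `p_s2`.
#' @examples
#' stage_posteriors(0.2, 0.5, 1, "continue")  # continue forced into stage 2
#' @export
stage_posteriors <- function(p_stage1, p_stage2, p_sec, trigger) {
  trigger <- match.arg(trigger, c("continue", "stop"))
  if (trigger == "continue") {
    num <- 1 - p_sec
    den <- (1 - p_sec) + p_sec * (1 - p_stage2)
  } else {
    num <- 1 - p_stage1
    den <- (1 - p_stage1) + p_stage1 * p_sec * (1 - p_stage2)
  }
  if (any(den <= 0)) {
    stop("a continue choice is impossible at this state (zero denominator)")
  }
  p_s1 <- num / den
  list(p_s1 = p_s1, p_s2 = 1 - p_s1)
}

#' Decision-time log-likelihood
#'
#' One-stage models: the DT of a continue choice is lognormal with location
#' `ln y_cont1` and scale `sigma_1`. Two-stage models: a two-component
#' lognormal mixture over the stage in which the choice was finalized, with
#' weights from [stage_posteriors()].
#'
#' @param dt decision times in seconds (> 0), continue choices only.
#' @inheritParams stage_posteriors
#' @inheritParams expected_stage_dts
#' @param trigger `"continue"`, `"stop"`, or `NA` for one-stage models.
#' @return total log-likelihood over the supplied DTs.
#' @export
dt_loglik <- function(dt, p_stage1, p_stage2, p_sec, dt_par, trigger) {
  if (any(dt <= 0)) stop("decision times must be positive")
  y <- expected_stage_dts(p_stage1, p_stage2, dt_par, trigger)
  l1 <- dlnorm(dt, meanlog = log(y$y_cont1), sdlog = dt_par[["sigma_1"]],
               log = TRUE)
  if (is.null(y$y_cont2)) return(sum(l1))
  post <- stage_posteriors(p_stage1, p_stage2, p_sec, trigger)
  l2 <- dlnorm(dt, meanlog = log(y$y_cont2), sdlog = dt_par[["sigma_2"]],
               log = TRUE)
  # log of w1 * exp(l1) + w2 * exp(l2), stably
  hi <- pmax(l1, l2)
  sum(hi + log(post$p_s1 * exp(l1 - hi) + post$p_s2 * exp(l2 - hi)))
}

#' Joint choice and decision-time log-likelihood
#'
#' The joint likelihood of a sampling choice and its decision time
#' factorizes into the choice likelihood and the DT mixture likelihood, so
#' the joint log-likelihood of a participant's data is simply their sum.
#'
#' @param choice_ll,dt_ll log-likelihoods computed on the same participant
#'   and model.
#' @return their sum.
#' @export
joint_loglik <- function(choice_ll, dt_ll) {
  as.numeric(choice_ll) + as.numeric(dt_ll)
}

#' Simulate a decision time for a given stage path
#'
#' Draws a lognormal DT with location `ln Y` of the decision path
#' (stage-1 continue, or the two-stage continue total) and the path's scale.
#'
#' @param y expected DT of the path in seconds.
#' @param sigma lognormal scale of the path's stage.
#' @param n number of draws.
#' @return simulated decision times in seconds.
#' @export
simulate_dt <- function(y, sigma, n = length(y)) {
  if (any(sigma < 0)) stop("`sigma` must be non-negative")
  rlnorm(n, meanlog = log(y), sdlog = sigma)
}
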