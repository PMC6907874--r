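#' Task conditions
#'
#' A condition of the bead-sampling task is a pair of unit sampling cost
#' (points deducted per bead drawn) and dominant-bead proportion `q` (the
#' fraction of the majority color in the preselected jar). The task crosses
#' three costs \{0, 0.1, 0.4\} with two evidence levels \{0.6, 0.8\}.
#'
#' @param unit_cost points per sample, non-negative.
#' @param q dominant-bead proportion, strictly between 0.5 and 1.
#' @return `condition()` returns a list with class `"beads_condition"`;
#'   `task_conditions()` returns a data frame of the six canonical cells.
#' @examples
#' condition(0.4, 0.8)
#' task_conditions()
#' @export
condition <- function(unit_cost, q) {
  stopifnot(is.numeric(unit_cost), length(unit_cost) == 1L, unit_cost >= 0,
            is.numeric(q), length(q) == 1L)
  if (!(q > 0.5 && q < 1)) {
    stop("`q` must lie strictly between 0.5 and 1, got ", q)
  }
  structure(list(unit_cost = unit_cost, q = q), class = "beads_condition")
}

#' @rdname condition
#' @export
task_conditions <- function() {
  out <- expand.grid(unit_cost = c(0, 0.1, 0.4), q = c(0.6, 0.8),
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$unit_cost, out$q), , drop = FALSE]
}

#' @export
print.beads_condition <- function(x, ...) {
  cat(sprintf("<condition: cost = %g, q = %g>\n", x$unit_cost, x$q))
  invisible(x)
}

as_condition <- function(x) {
  if (inherits(x, "beads_condition")) return(x)
  if (is.list(x) && all(c("unit_cost", "q") %in% names(x))) {
    return(condition(x$unit_cost, x$q))
  }
  stop("cannot interpret input as a task condition")
}

#' Ideal-observer probability of a correct jar judgment
#'
#' For an observer who judges the jar by the majority color of `n` drawn
#' beads (ties resolved by a fair coin flip), the probability of a correct
#' judgment is the binomial upper tail in the majority count, plus half the
#' tie probability when `n` is even; with no samples the judgment is a guess.
#'
#' @param n number of bead samples, non-negative integer (vectorized).
#' @param q dominant-bead proportion in (0.5, 1).
#' @return probability in \[0.5, 1\], one per element of `n`.
#' @examples
#' expected_correct_prob(0:5, 0.6)
#' @seealso [expected_gain()], [optimal_policy()]
#' @export
expected_correct_prob <- function(n, q) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("`n` must contain non-negative integers")
  }
  if (length(q) != 1L || !(q > 0.5 && q < 1)) {
    stop("`q` must be a single value strictly between 0.5 and 1")
  }
  vapply(n, function(nn) {
    if (nn == 0L) {
      0.5
    } else if (nn %% 2L == 1L) {
      sum(dbinom(seq((nn + 1L) / 2L, nn), nn, q))
    } else {
      half <- nn / 2L
      tail <- if (half + 1L <= nn) sum(dbinom(seq(half + 1L, nn), nn, q)) else 0
      0.5 * dbinom(half, nn, q) + tail
    }
  }, numeric(1))
}

#' Expected gain of sampling n beads
#'
#' The trial pays `reward` points minus the accumulated sampling cost for a
#' correct judgment and nothing otherwise, so the expected gain at sample
#' size `n` is `(reward - n * unit_cost) * p(n | q)`.
#'
#' @param n sample size (vectorized, non-negative integers).
#' @param condition a [condition()] (or list with `unit_cost` and `q`).
#' @param reward maximal reward in points, default 10.
#' @return expected gain in points, one per element of `n`.
#' @examples
#' expected_gain(0:20, condition(0.4, 0.6))
#' @export
expected_gain <- function(n, condition, reward = 10) {
  condition <- as_condition(condition)
  (reward - n * condition$unit_cost) * expected_correct_prob(n, condition$q)
}

#' Optimal sampling policy for a condition
#'
#' Scans sample sizes 0..`n_max` and returns the full accuracy and
#' expected-gain profiles together with the optimal sample size. Ties in the
#' gain curve are broken toward the largest maximizing `n`: exact ties only
#' arise at zero cost, where accuracy (and hence gain) is identical for
#' 2k-1 and 2k draws, and the optimal zero-cost policy is to sample up to
#' the cap.
#'
#' @inheritParams expected_gain
#' @param n_max sampling cap, default 20.
#' @return a list of class `"optimality_profile"` with elements `condition`,
#'   `n`, `p_correct`, `expected_gain`, `n_opt`, `max_gain`.
#' @examples
#' optimal_policy(condition(0.4, 0.8))$n_opt
#' @export
optimal_policy <- function(condition, reward = 10, n_max = 20) {
  condition <- as_condition(condition)
  n <- 0:n_max
  p <- expected_correct_prob(n, condition$q)
  g <- (reward - n * condition$unit_cost) * p
  i_opt <- max(which(g >= max(g) - 1e-9))  # largest maximizing n
  structure(list(condition = condition, n = n, p_correct = p,
                 expected_gain = g, n_opt = n[i_opt], max_gain = g[i_opt]),
            class = "optimality_profile")
}

#' @export
print.optimality_profile <- function(x, ...) {
  cat(sprintf("<optimality profile: cost = %g, q = %g, n_opt = %d, max gain = %.4f>\n",
              x$condition$unit_cost, x$condition$q, x$n_opt, x$max_gain))
  invisible(x)
}

#' Sampling efficiency
#'
#' Efficiency is the expected gain for the sample sizes actually chosen,
#' divided by the maximum expected gain attainable in the condition, averaged
#' over trials. A policy that always samples the optimal number scores 1.
#'
#' @param n_s integer vector of per-trial sample sizes from one participant
#'   in one condition.
#' @inheritParams expected_gain
#' @return mean gain ratio in (0, 1\].
#' @examples
#' efficiency(c(3, 5, 7), condition(0.4, 0.8))
#' @export
efficiency <- function(n_s, condition, reward = 10) {
  if (length(n_s) == 0L) stop("`n_s` must contain at least one trial")
  prof <- optimal_policy(condition, reward = reward)
  mean(prof$expected_gain[n_s + 1L]) / prof$max_gain
}

#' Sampling bias and variability
#'
#' Sampling bias is the mean number of samples drawn minus the optimal
#' number for the condition; sampling variability is the standard deviation
#' of the drawn sample counts across trials.
#'
#' @inheritParams efficiency
#' @return list with elements `bias` and `sd` (the latter `NA` with a
#'   warning when fewer than two trials are supplied).
#' @examples
#' sampling_bias_and_variability(c(4, 6), condition(0.4, 0.8))
#' @export
sampling_bias_and_variability <- function(n_s, condition, reward = 10) {
  if (length(n_s) == 0L) stop("`n_s` must contain at least one trial")
  prof <- optimal_policy(condition, reward = reward)
  s <- if (length(n_s) >= 2L) {
    sd(n_s)
  } else {
    warning("sampling variability undefined with fewer than 2 trials")
    NA_real_
  }
  list(bias = mean(n_s) - prof$n_opt, sd = s)
}

#' Flag likely-noncompliant observations
#'
#' Applies the nonparametric boxplot rule to per-participant values within a
#' condition: values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR` are
#' flagged. Quartiles use the linear-interpolation convention
#' (`quantile(type = 7)`).
#'
#' @param x numeric vector of per-participant values (e.g. mean sample
#'   counts) within one condition; at least 4 values.
#' @param k fence multiplier, default 1.5.
#' @return logical vector, `TRUE` where flagged.
#' @examples
#' flag_noncompliant(c(5, 5, 5, 5, 5, 20))
#' @export
flag_noncompliant <- function(x, k = 1.5) {
  if (length(x) < 4L) stop("need at least 4 values for boxplot fences")
  qs <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  x < qs[1] - k * iqr | x > qs[2] + k * iqr
}
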