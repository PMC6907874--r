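#' Information criteria
#'
#' `AIC = 2k - 2 loglik`; the small-sample correction adds
#' `2k(k + 1)/(n - k - 1)`; `BIC = k ln(n) - 2 loglik`. For the
#' choice-plus-DT models the observation count `n` is the number of
#' decision times modeled for the participant.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return named vector with `aic`, `aicc`, `bic` (`aicc` is `NA` with a
#'   warning when `n <= k + 1`).
#' @examples
#' information_criteria(0, k = 15, n = 200)
#' @export
information_criteria <- function(loglik, k, n) {
  aic <- 2 * k - 2 * loglik
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else {
    warning("AICc undefined: n <= k + 1")
    NA_real_
  }
  c(aic = aic, aicc = aicc, bic = k * log(n) - 2 * loglik)
}

#' Fixed-effects model comparison table
#'
#' Per-participant criterion differences relative to each participant's
#' best (lowest-criterion) model, plus their sum across participants.
#'
#' @param evidence participants x models matrix of AICc (or BIC) values,
#'   e.g. from [aicc_matrix()].
#' @return list with `delta` (participants x models matrix of differences,
#'   each row containing at least one zero) and `summed` (per-model summed
#'   differences).
#' @export
delta_criterion <- function(evidence) {
  delta <- sweep(evidence, 1, apply(evidence, 1, min), `-`)
  list(delta = delta, summed = colSums(delta))
}

#' Group-level random-effects Bayesian model selection
#'
#' Treats the model identity of each participant as a random effect drawn
#' from a population distribution over models with Dirichlet-distributed
#' frequencies. A variational update iterates posterior model assignments
#' and Dirichlet pseudo-counts to convergence; exceedance probabilities
#' (probability that a model is the most frequent) are estimated by Monte
#' Carlo from the posterior Dirichlet, and protected exceedance
#' probabilities blend them with a uniform prior according to the Bayesian
#' omnibus risk (BOR), the posterior probability that model frequencies are
#' exactly uniform: `pEP = EP (1 - BOR) + BOR / K`.
#'
#' Log model evidence per participant and model is approximated as
#' `-AICc / 2` when an AICc matrix is supplied.
#'
#' @param log_evidence participants x models matrix of log model evidence.
#'   Supply `aicc = TRUE` to pass an AICc matrix instead.
#' @param aicc if `TRUE`, `log_evidence` holds AICc values and is converted
#'   via `-AICc / 2`.
#' @param alpha0 Dirichlet prior pseudo-count per model (uniform prior 1).
#' @param n_samples Monte Carlo samples for exceedance probabilities.
#' @param seed optional seed for the Monte Carlo step.
#' @param tol convergence tolerance of the variational update.
#' @return list of class `"bms_result"`: `dirichlet_alpha`,
#'   `model_frequencies`, `exceedance`, `protected_exceedance`, `bor`,
#'   `assignment` (participants x models posterior), `free_energy`.
#' @export
group_bms <- function(log_evidence, aicc = FALSE, alpha0 = 1,
                      n_samples = 1e6, seed = NULL, tol = 1e-6) {
  if (!is.matrix(log_evidence) || nrow(log_evidence) < 2 ||
      ncol(log_evidence) < 2) {
    stop("`log_evidence` must be a matrix with >= 2 participants and models")
  }
  if (any(!is.finite(log_evidence))) stop("non-finite model evidence")
  if (aicc) log_evidence <- -log_evidence / 2
  n <- nrow(log_evidence)
  K <- ncol(log_evidence)
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  for (iter in seq_len(500)) {
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    z <- w / rowSums(w)
    alpha_new <- a0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  z <- pmax(z, 1e-300)
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  # variational free energy of the random-effects model
  f1 <- sum(z * log_evidence) + sum(z %*% elog_r) +
    (lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elog_r)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog_r)) -
    sum(z * log(z))
  # exact evidence of the null model (frequencies fixed at 1/K)
  lse <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  f0 <- sum(apply(log_evidence, 1, function(r) lse(r - log(K))))
  bor <- 1 / (1 + exp(f1 - f0))
  freq <- alpha / sum(alpha)
  ep <- with_local_seed(seed, {
    g <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                n_samples, K)
    tabulate(max.col(g), nbins = K) / n_samples
  })
  pep <- ep * (1 - bor) + bor / K
  structure(list(dirichlet_alpha = setNames(alpha, colnames(log_evidence)),
                 model_frequencies = setNames(freq, colnames(log_evidence)),
                 exceedance = setNames(ep, colnames(log_evidence)),
                 protected_exceedance = setNames(pep, colnames(log_evidence)),
                 bor = bor, assignment = z, free_energy = c(f1 = f1, f0 = f0)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  k <- which.max(x$protected_exceedance)
  cat(sprintf("<BMS over %d models: BOR = %.3g; top model %s (freq %.3f, pEP %.3f)>\n",
              length(x$model_frequencies), x$bor,
              names(x$model_frequencies)[k] %||% k,
              x$model_frequencies[k], x$protected_exceedance[k]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_stage_models_by <- function(dimension, level) {
  man <- model_manifest()
  man <- man[man$family == "two_stage", ]
  man$name[man[[dimension]] == level]
}

#' Cost-evidence strategy index (and its siblings)
#'
#' For one participant, the mean AICc over the six cost-first two-stage
#' models minus the mean over the six evidence-first two-stage models.
#' Negative values indicate that cost-first models fit better, i.e. a
#' cost-first decision strategy. `dimension_index()` generalizes the
#' contrast to the other two model dimensions (trigger and second-thought
#' rule); only the stage-order contrast is the canonical strategy index.
#'
#' @param aicc named numeric vector (or one-row slice of [aicc_matrix()])
#'   holding the participant's AICc for all 12 two-stage models.
#' @return the index (points of AICc).
#' @export
strategy_index <- function(aicc) {
  dimension_index(aicc, "order", "cost_first", "evidence_first")
}

#' @rdname strategy_index
#' @param dimension `"order"`, `"trigger"`, or `"rule"`.
#' @param level_a,level_b the two family levels to contrast (mean AICc of
#'   `level_a` minus mean AICc of `level_b`).
#' @export
dimension_index <- function(aicc, dimension = c("order", "trigger", "rule"),
                            level_a, level_b) {
  dimension <- match.arg(dimension)
  ma <- two_stage_models_by(dimension, level_a)
  mb <- two_stage_models_by(dimension, level_b)
  if (length(ma) == 0L || length(mb) == 0L) stop("unknown family level")
  missing <- setdiff(c(ma, mb), names(aicc))
  if (length(missing)) {
    stop("missing fits for: ", paste(missing, collapse = ", "))
  }
  mean(aicc[ma]) - mean(aicc[mb])
}

#' Strategy indices for every participant of a fitted dataset
#'
#' @param fits a `"beads_fits"` object from [fit_all()] containing all 12
#'   two-stage models.
#' @return data frame with `participant` and `strategy_index`.
#' @export
strategy_index_table <- function(fits) {
  am <- aicc_matrix(fits)
  data.frame(participant = rownames(am),
             strategy_index = apply(am, 1, strategy_index),
             stringsAsFactors = FALSE)
}
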