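# Two-step maximum-likelihood estimation, per participant and model:
# choice parameters are fit first to the stop/continue sequence; DT
# parameters are then fit to the continue-choice decision times with the
# choice-derived stage probabilities (including the second-thought
# probability) frozen, so DTs never adjust choice parameters.

#' Fitting configuration
#'
#' @param n_restarts number of optimizer starts per fit (the first start is
#'   a fixed heuristic, the rest are randomized deterministically).
#' @param seed integer base seed; the effective seed of each fit is derived
#'   from it together with a participant-and-model hash, so refits are
#'   reproducible and independent of execution order.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param max_iter iteration cap per start.
#' @return list of class `"fit_config"`.
#' @export
fit_config <- function(n_restarts = 10L, seed = 1L, rel_tol = 1e-6,
                       max_iter = 400L) {
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 rel_tol = rel_tol, max_iter = as.integer(max_iter)),
            class = "fit_config")
}

fit_seed <- function(config, participant, model_name) {
  h <- sum(utf8ToInt(paste(participant, model_name, sep = "/")) *
             seq_along(utf8ToInt(paste(participant, model_name, sep = "/"))))
  as.integer((as.numeric(config$seed) * 48271 + h) %% 2147483587) + 1L
}

choice_start_base <- function(spec) {
  par <- setNames(numeric(spec$k_choice), spec$par_names)
  par[names(par) %in% c("w_cost_zero", "w_cost_low", "w_cost_high",
                        "w_ev_icpt")] <- -2
  par[names(par) == "w_nsamp"] <- 0.1
  par[grepl("^psec", names(par))] <- 0.5
  par[names(par) == "alpha"] <- 0.9
  par[names(par) == "gamma"] <- 1
  par
}

choice_start_random <- function(spec) {
  par <- choice_start_base(spec)
  w <- !grepl("^psec|^alpha$", names(par))
  par[w] <- par[w] + rnorm(sum(w), 0, 1)
  par[grepl("^psec", names(par))] <- runif(sum(grepl("^psec", names(par))),
                                           0.05, 0.95)
  par[names(par) == "alpha"] <- runif(1, 0.5, 1)
  par
}

run_restarts <- function(starts, objective, lower, upper, config,
                         gradient = NULL) {
  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, objective, gradient = gradient, lower = lower, upper = upper,
             control = list(rel.tol = config$rel_tol,
                            iter.max = config$max_iter,
                            eval.max = 4L * config$max_iter)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  list(best = best, n_ok = n_ok)
}

#' Fit the choice model of one participant
#'
#' Bounded multi-start quasi-Newton maximization of the choice
#' log-likelihood. Second-thought probabilities and the decay rate are
#' bounded to \[0, 1\]; nominally unbounded weights are clipped to +/-50 to
#' prevent overflow (an implementation bound, not a model bound).
#'
#' @param spec a `choice_model_spec` from [model_registry()].
#' @param data a `"choice_data"` object from [prepare_choice_data()].
#' @param config a [fit_config()].
#' @return list with `par`, `loglik`, `converged`, `n_restarts_used`,
#'   `seed`, and `probs` (per-state stage probabilities at the optimum, as
#'   required by the DT model).
#' @export
fit_choice <- function(spec, data, config = fit_config()) {
  if (sum(data$is_stop == 0L) < 1L) {
    stop("no free choices to fit")
  }
  codes <- spec_codes(spec)
  ixc <- spec$ix$wc - 1L
  ixe <- spec$ix$we - 1L
  ixr <- spec$ix$rule - 1L
  ixa <- spec$ix$alpha - 1L
  cost_idx0 <- data$cost_idx - 1L
  # objective and analytic gradient share one evaluation per point
  last_par <- NULL
  last <- NULL
  eval_point <- function(par) {
    if (is.null(last_par) || !identical(par, last_par)) {
      last <<- choice_nll_grad_cpp(par, ixc, ixe, ixr, ixa, codes,
                                   data$new_trial, data$j, cost_idx0,
                                   data$cost, data$llr, data$low_ev,
                                   data$prev_correct, data$prev_n,
                                   data$is_stop, data$bead_sign, TRUE)
      last_par <<- par
    }
    last
  }
  objective <- function(par) {
    v <- eval_point(par)$nll
    if (!is.finite(v)) 1e10 else v
  }
  gradient <- function(par) eval_point(par)$grad
  seed <- fit_seed(config, data$participant, spec$name)
  starts <- with_local_seed(seed, {
    c(list(choice_start_base(spec)),
      lapply(seq_len(max(0L, config$n_restarts - 1L)),
             function(i) choice_start_random(spec)))
  })
  res <- run_restarts(starts, objective, spec$lower, spec$upper, config,
                      gradient = gradient)
  par <- setNames(res$best$par, spec$par_names)
  ll <- choice_loglik(spec, par, data, engine = "cpp", keep_probs = TRUE)
  list(par = par, loglik = as.numeric(ll),
       converged = res$best$convergence == 0L,
       n_restarts_used = res$n_ok, seed = seed, probs = attr(ll, "probs"))
}

dt_par_info <- function(spec) {
  nm <- c("b0_1", "b1_1", "b2_1", "sigma_1")
  if (spec$family == "two_stage") nm <- c(nm, "b0_2", "b1_2", "b2_2", "sigma_2")
  lower <- setNames(rep(-.weight_bound, length(nm)), nm)
  upper <- setNames(rep(.weight_bound, length(nm)), nm)
  lower[grepl("^b0", nm)] <- 1e-4   # positivity bound on the stage baselines
  upper[grepl("^b0", nm)] <- 5
  lower[grepl("^sigma", nm)] <- 1e-3
  upper[grepl("^sigma", nm)] <- 5
  list(names = nm, lower = lower, upper = upper)
}

dt_start <- function(spec, dt, jitter = FALSE) {
  b0 <- min(max(log(median(dt) * if (spec$family == "two_stage") 0.8 else 1),
                0.01), 2)
  sig <- min(max(sd(log(dt)) * 0.8, 0.05), 2)
  par <- c(b0_1 = b0, b1_1 = 0, b2_1 = 0, sigma_1 = sig)
  if (spec$family == "two_stage") {
    par <- c(par, b0_2 = b0, b1_2 = 0, b2_2 = 0, sigma_2 = sig)
  }
  if (jitter) {
    par <- par + rnorm(length(par), 0, 0.25)
    info <- dt_par_info(spec)
    par <- pmin(pmax(par, info$lower + 1e-6), info$upper - 1e-6)
  }
  par
}

#' Fit the decision-time model of one participant
#'
#' Maximum-likelihood estimation of the stage DT parameters with the
#' choice-derived stage probabilities held fixed. Stage baselines `b0` and
#' scales `sigma` are bounded positive.
#'
#' @inheritParams fit_choice
#' @param choice_fit the result of [fit_choice()] for the same data.
#' @param dt decision times of the modeled continue choices (after outlier
#'   exclusion), in seconds.
#' @param state_idx indices into the per-state probability vectors of
#'   `choice_fit$probs` matching `dt`.
#' @return list with `par`, `loglik`, `converged`, `n_restarts_used`,
#'   `n_dt`.
#' @export
fit_dt <- function(spec, choice_fit, dt, state_idx, config = fit_config()) {
  if (length(dt) == 0L) stop("no modeled decision times")
  if (length(dt) != length(state_idx)) {
    stop("`dt` and `state_idx` must have equal length")
  }
  p1 <- choice_fit$probs$p_stage1[state_idx]
  p2 <- choice_fit$probs$p_stage2[state_idx]
  psec <- choice_fit$probs$p_sec[state_idx]
  trigger <- if (spec$family == "two_stage") spec$trigger else NA_character_
  info <- dt_par_info(spec)
  objective <- function(par) {
    names(par) <- info$names
    ll <- tryCatch(dt_loglik(dt, p1, p2, psec, par, trigger),
                   error = function(e) NaN)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  seed <- fit_seed(config, choice_fit$seed, paste0(spec$name, "/dt"))
  starts <- with_local_seed(seed, {
    c(list(dt_start(spec, dt)),
      lapply(seq_len(max(0L, min(config$n_restarts, 5L) - 1L)),
             function(i) dt_start(spec, dt, jitter = TRUE)))
  })
  res <- run_restarts(starts, objective, info$lower, info$upper, config)
  par <- setNames(res$best$par, info$names)
  list(par = par, loglik = -res$best$objective,
       converged = res$best$convergence == 0L,
       n_restarts_used = res$n_ok, n_dt = length(dt))
}

#' Fit one model (choice + DT) to one participant
#'
#' @inheritParams fit_choice
#' @param dt_include logical mask over the decision states of `data`
#'   marking which continue-choice DTs are modeled (after outlier
#'   exclusion); defaults to all continue states with a finite positive DT.
#' @return list of class `"fit_result"`: parameter estimates, component and
#'   joint log-likelihoods, parameter counts, `n_dt`, AICc and BIC.
#' @export
fit_participant <- function(spec, data, dt_include = NULL,
                            config = fit_config()) {
  cf <- fit_choice(spec, data, config)
  cont <- data$is_stop == 0L
  if (is.null(dt_include)) {
    dt_include <- cont & is.finite(data$dt) & data$dt > 0
  }
  dt_include <- dt_include & cont
  state_idx <- which(dt_include)
  df <- fit_dt(spec, cf, data$dt[state_idx], state_idx, config)
  k <- spec$k_choice + spec$k_dt
  n <- df$n_dt
  ic <- information_criteria(cf$loglik + df$loglik, k, n)
  structure(list(
    participant = data$participant, model = spec$name, spec = spec,
    choice_par = cf$par, dt_par = df$par,
    choice_loglik = cf$loglik, dt_loglik = df$loglik,
    joint_loglik = joint_loglik(cf$loglik, df$loglik),
    k_choice = spec$k_choice, k_dt = spec$k_dt, n_dt = n,
    aic = ic[["aic"]], aicc = ic[["aicc"]], bic = ic[["bic"]],
    converged = cf$converged && df$converged,
    n_restarts_used = cf$n_restarts_used, seed = cf$seed
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit: %s, participant %s | joint ll = %.2f, AICc = %.2f, n_dt = %d>\n",
              x$model, x$participant, x$joint_loglik, x$aicc, x$n_dt))
  invisible(x)
}

#' Fit a set of models to every participant of a dataset
#'
#' Runs the two-step fit for each participant x model cell. Decision-time
#' outliers are excluded beforehand with the boxplot rule on the pooled
#' log-transformed continue DTs of the whole dataset (see
#' [preprocess_dts()]). Per-model failures are recorded, not fatal.
#'
#' @param dataset a list with `trials` and `samples` data frames (see
#'   [simulate_population()] or [read_dataset()]).
#' @param registry list of model specs to fit, default the full 16-model
#'   [model_registry()].
#' @param config a [fit_config()].
#' @param participants optional subset of participant ids.
#' @param progress print one line per participant.
#' @return object of class `"beads_fits"`: nested list of
#'   [fit_participant()] results (`fits[[participant]][[model]]`) plus the
#'   exclusion info; use [fit_table()] or [aicc_matrix()] to tabulate.
#' @export
fit_all <- function(dataset, registry = model_registry(),
                    config = fit_config(), participants = NULL,
                    progress = FALSE) {
  trials <- dataset$trials
  samples <- dataset$samples
  if (is.null(participants)) participants <- unique(trials$participant)
  pool <- preprocess_dts(samples$dt[samples$choice == "continue"])
  fence <- pool$fences
  fits <- list()
  errors <- list()
  for (p in participants) {
    data <- prepare_choice_data(trials, samples, participant = p)
    keep <- data$is_stop == 0L & is.finite(data$dt) & data$dt > 0
    keep[keep] <- log(data$dt[keep]) >= fence[1] & log(data$dt[keep]) <= fence[2]
    fits[[as.character(p)]] <- list()
    for (spec in registry) {
      res <- tryCatch(fit_participant(spec, data, dt_include = keep,
                                      config = config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(p, spec$name, sep = "/")]] <- conditionMessage(res)
      } else {
        fits[[as.character(p)]][[spec$name]] <- res
      }
    }
    if (progress) {
      message(sprintf("participant %s: %d/%d models fit", p,
                      length(fits[[as.character(p)]]), length(registry)))
    }
  }
  structure(list(fits = fits, dt_fences = fence, errors = errors),
            class = "beads_fits")
}

#' @export
print.beads_fits <- function(x, ...) {
  cat(sprintf("<beads_fits: %d participants, %d fits, %d failures>\n",
              length(x$fits), sum(lengths(x$fits)), length(x$errors)))
  invisible(x)
}

#' Tabulate fit results
#'
#' @param fits a `"beads_fits"` object from [fit_all()].
#' @return `fit_table()`: data frame with one row per participant x model
#'   (log-likelihoods, parameter counts, `n_dt`, AICc, BIC).
#'   `aicc_matrix()`: participants x models matrix of AICc (or BIC) values.
#' @export
fit_table <- function(fits) {
  rows <- list()
  for (p in names(fits$fits)) {
    for (m in names(fits$fits[[p]])) {
      f <- fits$fits[[p]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, model = m, choice_loglik = f$choice_loglik,
        dt_loglik = f$dt_loglik, joint_loglik = f$joint_loglik,
        k = f$k_choice + f$k_dt, n_dt = f$n_dt, aicc = f$aicc, bic = f$bic,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname fit_table
#' @param criterion `"aicc"` or `"bic"`.
#' @export
aicc_matrix <- function(fits, criterion = c("aicc", "bic")) {
  criterion <- match.arg(criterion)
  tab <- fit_table(fits)
  models <- unique(tab$model)
  parts <- unique(tab$participant)
  out <- matrix(NA_real_, length(parts), length(models),
                dimnames = list(parts, models))
  for (i in seq_len(nrow(tab))) {
    out[tab$participant[i], tab$model[i]] <- tab[[criterion]][i]
  }
  out
}
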