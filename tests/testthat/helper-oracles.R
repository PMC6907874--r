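# Independent oracles used across the suite.

# Exhaustive decision-tree enumeration of the two-stage stop probability:
# stage-1 outcome x second-thought recruitment x stage-2 outcome.
enum_stop_probability <- function(p1, p2, psec, trigger) {
  p_stop <- 0
  for (s1 in c(TRUE, FALSE)) {
    pr1 <- if (s1) p1 else 1 - p1
    qualified <- if (trigger == "continue") !s1 else s1
    if (!qualified) {
      if (s1) p_stop <- p_stop + pr1
      next
    }
    # not recruited: first-stage decision stands
    if (s1) p_stop <- p_stop + pr1 * (1 - psec)
    # recruited: stage 2 decides
    for (s2 in c(TRUE, FALSE)) {
      pr2 <- if (s2) p2 else 1 - p2
      if (s2) p_stop <- p_stop + pr1 * psec * pr2
    }
  }
  p_stop
}

# Path probabilities P(stage-s final, continue) from the same tree.
enum_continue_paths <- function(p1, p2, psec, trigger) {
  if (trigger == "continue") {
    c(s1 = (1 - p1) * (1 - psec), s2 = (1 - p1) * psec * (1 - p2))
  } else {
    c(s1 = 1 - p1, s2 = p1 * psec * (1 - p2))
  }
}

# Monte-Carlo majority-judgment accuracy with coin-flip ties.
mc_correct_freq <- function(n, q, reps) {
  if (n == 0) return(0.5)
  pinks <- rbinom(reps, n, q)
  mean(ifelse(pinks * 2 > n, 1, ifelse(pinks * 2 < n, 0,
                                       rbinom(reps, 1, 0.5))))
}

# Brute-force dip statistic for tiny samples: direct minimization over
# unimodal piecewise-linear CDFs via LP feasibility checks (quadprog),
# bisecting the band half-width d for every candidate mode location. The
# mode (with its jump) may sit at any point of the real line; candidates
# are every data point plus a fine grid inside every inter-point gap and
# one position outside each end of the data.
dip_lp <- function(x, tol = 1e-8, n_tau = 15) {
  x <- sort(x)
  y <- unique(x)
  m <- length(y)
  if (m <= 1) return(0)
  Fv <- cumsum(tabulate(match(x, y), nbins = m)) / length(x)
  Flo <- c(0, Fv[-m])

  solve_feasible <- function(C, b) {
    tryCatch({
      quadprog::solve.QP(Dmat = diag(ncol(C)), dvec = rep(0, ncol(C)),
                         Amat = t(C), bvec = b, meq = 0)
      TRUE
    }, error = function(e) FALSE)
  }

  # slopes over the knot chain must be nondecreasing (convex, dir = 1) or
  # nonincreasing (concave, dir = -1)
  shape_rows <- function(xs, cols, n_var, dir) {
    rows <- list()
    if (length(xs) >= 3) {
      for (i in seq_len(length(xs) - 2)) {
        r <- numeric(n_var)
        d1 <- xs[i + 1] - xs[i]
        d2 <- xs[i + 2] - xs[i + 1]
        r[cols[i]] <- dir / d1
        r[cols[i + 1]] <- -dir / d1 - dir / d2
        r[cols[i + 2]] <- dir / d2
        rows[[length(rows) + 1L]] <- r
      }
    }
    rows
  }

  # Feasibility for a fixed mode position tau: variables are the CDF values
  # v_1..v_m at the data points plus the pre-jump (w) and post-jump (u)
  # values at tau. Left chain (points <= tau, ending in w) is convex; right
  # chain (starting at u, points > tau) is concave; the chain is monotone
  # and the bands are |G - F_n| <= d evaluated at interval endpoints.
  feasible <- function(d, tau) {
    kl <- sum(y < tau)          # data points strictly left of tau
    at <- match(TRUE, y == tau) # tau on a data point?
    n_var <- m + 2L
    iw <- m + 1L
    iu <- m + 2L
    rows <- list()
    b <- numeric(0)
    add <- function(r, bound) {
      rows[[length(rows) + 1L]] <<- r
      b[length(b) + 1L] <<- bound
    }
    unit <- function(i, s = 1) {
      r <- numeric(n_var)
      r[i] <- s
      r
    }
    # ECDF height just left of tau
    F_at_tau <- if (kl == 0) 0 else Fv[kl]
    for (jj in seq_len(m)) {
      lo <- Fv[jj] - d
      hi <- Flo[jj] + d
      if (!is.na(at) && jj == at) hi <- 1  # jump at this point: upper on w
      add(unit(jj), lo)
      add(unit(jj, -1), -hi)
    }
    add(unit(1), 0)
    add(unit(m, -1), -1)
    # bands at tau: pre-jump w <= F(tau-) + d, post-jump u >= F(tau) - d
    add(unit(iw, -1), -((if (!is.na(at)) Flo[at] else F_at_tau) + d))
    add(unit(iw), 0)
    add(unit(iu), (if (!is.na(at)) Fv[at] else F_at_tau) - d)
    add(unit(iu, -1), -1)
    # monotone chain: v_1..v_kl, w, u, v_{kl+1}..v_m (tau at a data point k:
    # v_k is the post-jump value, so u and v_k coincide there; keep both
    # with an equality through two inequalities)
    if (!is.na(at)) {
      add(unit(iu) - unit(at), 0)
      add(unit(at) - unit(iu), 0)
      left_cols <- c(seq_len(at - 1L), iw)
      left_xs <- c(y[seq_len(at - 1L)], tau)
      right_cols <- c(at, if (at < m) (at + 1L):m)
      right_xs <- y[at:m]
      chain <- c(seq_len(at - 1L), iw, at, if (at < m) (at + 1L):m)
    } else {
      left_cols <- c(seq_len(kl), iw)
      left_xs <- c(y[seq_len(kl)], tau)
      right_cols <- c(iu, if (kl < m) (kl + 1L):m)
      right_xs <- c(tau, if (kl < m) y[(kl + 1L):m])
      chain <- c(seq_len(kl), iw, iu, if (kl < m) (kl + 1L):m)
    }
    for (i in seq_len(length(chain) - 1)) {
      r <- numeric(n_var)
      r[chain[i]] <- -1
      r[chain[i + 1]] <- 1
      add(r, 0)
    }
    rows <- c(rows, shape_rows(left_xs, left_cols, n_var, 1),
              shape_rows(right_xs, right_cols, n_var, -1))
    b <- c(b, rep(0, length(rows) - length(b)))
    solve_feasible(do.call(rbind, rows), b)
  }

  span <- diff(range(y))
  taus <- y
  for (k in seq_len(m - 1)) {
    taus <- c(taus, y[k] + (y[k + 1] - y[k]) * seq_len(n_tau) / (n_tau + 1))
  }
  taus <- c(taus, y[1] - 0.1 * span - 1, y[m] + 0.1 * span + 1)
  best <- Inf
  for (tau in taus) {
    if (!feasible(0.5, tau)) next
    lo <- 0
    hi <- 0.5
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (feasible(mid, tau)) hi <- mid else lo <- mid
    }
    best <- min(best, hi)
  }
  best
}

# Hand-coded Benjamini-Hochberg step-up rule (independent of p.adjust).
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hand-built tiny dataset: one participant, explicit bead strings and DTs.
make_manual_data <- function(beads_per_trial, cost = 0.1, q = 0.8,
                             dts = NULL, participant = "p1") {
  n_tr <- length(beads_per_trial)
  trials <- data.frame(
    participant = participant, trial = seq_len(n_tr), block = 1L,
    permutation = 1L, cost = cost, q = q, hidden_jar = "pink",
    pink_side = "left",
    n_samples = vapply(beads_per_trial, nchar, integer(1)),
    judgment = "left", correct = 1L, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n_tr)) {
    bs <- strsplit(beads_per_trial[i], "")[[1]]
    ns <- length(bs)
    if (ns > 0) {
      dt <- if (is.null(dts)) runif(ns, 0.5, 2) else dts[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant, trial = i, j = seq_len(ns), bead = bs,
        choice = "continue", dt = dt, stringsAsFactors = FALSE)
    }
    if (ns < 20) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant, trial = i, j = ns + 1L,
        bead = NA_character_, choice = "stop", dt = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  list(trials = trials, samples = samples)
}

# Named parameter vector for a spec with chosen entries overridden.
par_for <- function(spec, ...) {
  par <- setNames(numeric(spec$k_choice), spec$par_names)
  if ("alpha" %in% spec$par_names) par["alpha"] <- 1
  over <- list(...)
  for (nm in names(over)) par[nm] <- over[[nm]]
  par
}

# Random but well-behaved parameter draw for a spec.
random_par <- function(spec) {
  par <- setNames(rnorm(spec$k_choice, 0, 0.5), spec$par_names)
  par[names(par) %in% c("w_cost_zero", "w_cost_low", "w_cost_high",
                        "w_ev_icpt")] <-
    rnorm(sum(names(par) %in% c("w_cost_zero", "w_cost_low", "w_cost_high",
                                "w_ev_icpt")), -2, 0.5)
  psec <- grepl("^psec", names(par))
  par[psec] <- runif(sum(psec), 0.05, 0.95)
  if ("alpha" %in% names(par)) par["alpha"] <- runif(1, 0.4, 1)
  if ("gamma" %in% names(par)) par["gamma"] <- runif(1, 0.3, 1.5)
  par
}

random_state <- function() {
  choice_state(sample(0:19, 1),
               condition(sample(c(0, 0.1, 0.4), 1), sample(c(0.6, 0.8), 1)),
               ci_decayed = runif(1, -6, 6),
               prev_correct = sample(c(0, 0.5, 1), 1),
               prev_n = sample(0:20, 1))
}
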