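#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double x) {
  // guard against overflow in exp for the clipped-weight regime
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Fast path of the choice likelihood. One element per decision state,
// states ordered within trial; `new_trial` resets the decayed cumulative
// information. `codes` = (family, order, trigger, rule, use_cost, use_ev)
// with family 1 = one-stage, 2 = two-stage; order 1 = cost-first,
// 2 = evidence-first; trigger 1 = continue, 2 = stop; rule 1 = cost
// condition, 2 = evidence condition, 3 = flexible.
// [[Rcpp::export]]
List choice_eval_cpp(NumericVector wc, NumericVector we, NumericVector rulep,
                     double alpha, IntegerVector codes,
                     IntegerVector new_trial, IntegerVector j,
                     IntegerVector cost_idx, NumericVector cost,
                     NumericVector llr, IntegerVector low_ev,
                     NumericVector prev_correct, NumericVector prev_n,
                     IntegerVector is_stop, NumericVector bead_sign,
                     bool keep_probs) {
  const int family = codes[0], order = codes[1], trigger = codes[2],
            rule = codes[3], use_cost = codes[4], use_ev = codes[5];
  const int n = j.size();
  double ll = 0.0, ci = 0.0;
  int n_clamped = 0;
  NumericVector P1, P2, PS, PSTOP;
  if (keep_probs) {
    P1 = NumericVector(n, NA_REAL);
    P2 = NumericVector(n, NA_REAL);
    PS = NumericVector(n, NA_REAL);
    PSTOP = NumericVector(n, NA_REAL);
  }
  for (int i = 0; i < n; ++i) {
    if (new_trial[i]) ci = 0.0;
    const double absci = std::fabs(ci);
    const double xc = wc[cost_idx[i]] + wc[3] * j[i] + wc[4] * j[i] * cost[i];
    const double xe = we[0] + we[1] * llr[i] + we[2] * absci +
                      we[3] * llr[i] * absci + we[4] * prev_correct[i] +
                      we[5] * prev_n[i];
    double p1, p2 = NA_REAL, psec = NA_REAL, pstop;
    if (family == 1) {
      double x = 0.0;
      if (use_cost) x += xc;
      if (use_ev) x += xe;
      p1 = pstop = logistic(x);
    } else {
      const double x1 = (order == 1) ? xc : xe;
      const double x2 = (order == 1) ? xe : xc;
      p1 = logistic(x1);
      p2 = logistic(x2);
      if (rule == 1) {
        psec = rulep[cost_idx[i]];
      } else if (rule == 2) {
        psec = rulep[low_ev[i] ? 0 : 1];
      } else {
        psec = logistic(rulep[0] * x1 + rulep[1]);
      }
      if (trigger == 1) {
        pstop = p1 + (1.0 - p1) * psec * p2;
      } else {
        pstop = p1 * (1.0 - psec) + p1 * psec * p2;
      }
    }
    double pc = is_stop[i] ? pstop : 1.0 - pstop;
    if (pc < 1e-12) {
      pc = 1e-12;
      ++n_clamped;
    }
    ll += std::log(pc);
    if (keep_probs) {
      P1[i] = p1;
      P2[i] = p2;
      PS[i] = psec;
      PSTOP[i] = pstop;
    }
    if (!is_stop[i]) ci = alpha * ci + bead_sign[i];
  }
  if (keep_probs) {
    return List::create(_["loglik"] = ll, _["n_clamped"] = n_clamped,
                        _["p1"] = P1, _["p2"] = P2, _["psec"] = PS,
                        _["pstop"] = PSTOP);
  }
  return List::create(_["loglik"] = ll, _["n_clamped"] = n_clamped);
}

// Objective and analytic gradient of the choice negative log-likelihood in
// the flat parameter layout of a model spec. ixc/ixe/ixrule/ixalpha are
// 0-based positions of the cost weights (5), evidence weights (6), rule
// parameters and decay rate inside `par`; -1 marks an absent parameter.
// The decayed-CI derivative with respect to alpha follows the recursion
// d ci'/d alpha = ci + alpha * d ci/d alpha alongside ci' = alpha ci + s.
// [[Rcpp::export]]
List choice_nll_grad_cpp(NumericVector par, IntegerVector ixc,
                         IntegerVector ixe, IntegerVector ixrule, int ixalpha,
                         IntegerVector codes, IntegerVector new_trial,
                         IntegerVector j, IntegerVector cost_idx,
                         NumericVector cost, NumericVector llr,
                         IntegerVector low_ev, NumericVector prev_correct,
                         NumericVector prev_n, IntegerVector is_stop,
                         NumericVector bead_sign, bool want_grad) {
  const int family = codes[0], order = codes[1], trigger = codes[2],
            rule = codes[3], use_cost = codes[4], use_ev = codes[5];
  const int n = j.size(), np = par.size();
  double wc[5] = {0, 0, 0, 0, 0}, we[6] = {0, 0, 0, 0, 0, 0};
  for (int k = 0; k < 5; ++k) if (ixc[k] >= 0) wc[k] = par[ixc[k]];
  for (int k = 0; k < 6; ++k) if (ixe[k] >= 0) we[k] = par[ixe[k]];
  const double alpha = (ixalpha >= 0) ? par[ixalpha] : 1.0;
  double g1 = 0.0, g2 = 0.0;  // flexible-rule parameters (gamma, phi)
  if (rule == 3) {
    g1 = par[ixrule[0]];
    g2 = par[ixrule[1]];
  }
  NumericVector grad(np);
  double nll = 0.0, ci = 0.0, dci = 0.0;
  int n_clamped = 0;
  for (int i = 0; i < n; ++i) {
    if (new_trial[i]) { ci = 0.0; dci = 0.0; }
    const double absci = std::fabs(ci);
    const double sgn = (ci > 0) - (ci < 0);
    const double xc = wc[cost_idx[i]] + wc[3] * j[i] + wc[4] * j[i] * cost[i];
    const double dve[6] = {1.0, llr[i], absci, llr[i] * absci,
                           prev_correct[i], prev_n[i]};
    double xe = 0.0;
    for (int k = 0; k < 6; ++k) xe += we[k] * dve[k];
    // d xe / d alpha through the decayed CI
    const double dxe_da = (we[2] + we[3] * llr[i]) * sgn * dci;
    double P, dPdxc = 0.0, dPdxe = 0.0, dPda = 0.0, dPds = 0.0;
    double s = 0.0, dsfac = 0.0, x1 = 0.0;
    if (family == 1) {
      double x = 0.0;
      if (use_cost) x += xc;
      if (use_ev) x += xe;
      P = logistic(x);
      const double dp = P * (1.0 - P);
      if (use_cost) dPdxc = dp;
      if (use_ev) { dPdxe = dp; dPda = dp * dxe_da; }
    } else {
      x1 = (order == 1) ? xc : xe;
      const double x2 = (order == 1) ? xe : xc;
      const double p1 = logistic(x1), p2 = logistic(x2);
      const double d1 = p1 * (1.0 - p1), d2 = p2 * (1.0 - p2);
      if (rule == 1) s = par[ixrule[cost_idx[i]]];
      else if (rule == 2) s = par[ixrule[low_ev[i] ? 0 : 1]];
      else s = logistic(g1 * x1 + g2);
      dsfac = (rule == 3) ? s * (1.0 - s) : 0.0;  // d s / d (g1*x1+g2)
      double dPdx1, dPdx2;
      if (trigger == 1) {
        P = p1 + (1.0 - p1) * s * p2;
        dPdx1 = d1 * (1.0 - s * p2) + (1.0 - p1) * p2 * dsfac * g1;
        dPdx2 = (1.0 - p1) * s * d2;
        dPds = (1.0 - p1) * p2;
      } else {
        P = p1 * (1.0 - s) + p1 * s * p2;
        dPdx1 = d1 * (1.0 - s * (1.0 - p2)) - p1 * (1.0 - p2) * dsfac * g1;
        dPdx2 = p1 * s * d2;
        dPds = -p1 * (1.0 - p2);
      }
      if (order == 1) { dPdxc = dPdx1; dPdxe = dPdx2; }
      else { dPdxc = dPdx2; dPdxe = dPdx1; }
      dPda = dPdxe * dxe_da;
    }
    double Pc = is_stop[i] ? P : 1.0 - P;
    if (Pc < 1e-12) {
      Pc = 1e-12;
      ++n_clamped;
      nll -= std::log(Pc);
    } else {
      nll -= std::log(Pc);
      if (want_grad) {
        const double coef = (is_stop[i] ? -1.0 : 1.0) / Pc;
        if (dPdxc != 0.0) {
          if (ixc[cost_idx[i]] >= 0) grad[ixc[cost_idx[i]]] += coef * dPdxc;
          if (ixc[3] >= 0) grad[ixc[3]] += coef * dPdxc * j[i];
          if (ixc[4] >= 0) grad[ixc[4]] += coef * dPdxc * j[i] * cost[i];
        }
        if (dPdxe != 0.0) {
          for (int k = 0; k < 6; ++k) {
            if (ixe[k] >= 0 && dve[k] != 0.0) {
              grad[ixe[k]] += coef * dPdxe * dve[k];
            }
          }
        }
        if (ixalpha >= 0 && dPda != 0.0) grad[ixalpha] += coef * dPda;
        if (family == 2) {
          if (rule == 1) {
            grad[ixrule[cost_idx[i]]] += coef * dPds;
          } else if (rule == 2) {
            grad[ixrule[low_ev[i] ? 0 : 1]] += coef * dPds;
          } else {
            grad[ixrule[0]] += coef * dPds * dsfac * x1;
            grad[ixrule[1]] += coef * dPds * dsfac;
          }
        }
      }
    }
    if (!is_stop[i]) {
      dci = ci + alpha * dci;
      ci = alpha * ci + bead_sign[i];
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad,
                      _["n_clamped"] = n_clamped);
}
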