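#' Decision-time preprocessing and outlier exclusion
#'
#' Only decision times of continue choices are analyzed. DTs are
#' log-transformed and points outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the
#' pooled log-DT distribution are excluded (boxplot rule,
#' linear-interpolation quartiles). Fences are computed on the pooled
#' distribution across all participants by default; `by` allows
#' per-group fences instead.
#'
#' @param dt positive decision times in seconds.
#' @param k fence multiplier, default 1.5.
#' @param by optional grouping factor of `length(dt)`; fences are then
#'   computed within each group.
#' @return list of class `"dt_pool"`: `log_dt`, logical `include` mask,
#'   `fences` (on the log scale; a matrix when `by` is used), and the
#'   exclusion count. Raw data are untouched.
#' @export
preprocess_dts <- function(dt, k = 1.5, by = NULL) {
  if (length(dt) == 0L) stop("no decision times supplied")
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("decision times must be positive and finite")
  }
  ldt <- log(dt)
  fence_of <- function(v) {
    qs <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    c(lower = qs[1] - k * (qs[2] - qs[1]), upper = qs[2] + k * (qs[2] - qs[1]))
  }
  if (is.null(by)) {
    fences <- fence_of(ldt)
    include <- ldt >= fences[1] & ldt <= fences[2]
  } else {
    by <- as.factor(by)
    fences <- t(vapply(levels(by), function(g) fence_of(ldt[by == g]),
                       numeric(2)))
    include <- ldt >= fences[by, 1] & ldt <= fences[by, 2]
  }
  structure(list(log_dt = ldt, include = include, fences = fences,
                 n_excluded = sum(!include)),
            class = "dt_pool")
}

#' @export
print.dt_pool <- function(x, ...) {
  cat(sprintf("<dt_pool: %d DTs, %d excluded by the boxplot rule>\n",
              length(x$log_dt), x$n_excluded))
  invisible(x)
}

#' Gaussian mixture fit to log decision times
#'
#' Fits a two-component unequal-variance Gaussian mixture to the included
#' log DTs by EM (via \pkg{mclust}), alongside a single-Gaussian fit for
#' comparison. Components are ordered by mean.
#'
#' @param pool a `"dt_pool"` from [preprocess_dts()], or a numeric vector
#'   of log DTs.
#' @param n_components number of mixture components, default 2.
#' @param seed optional seed (EM initialization is deterministic given the
#'   data, but a seed keeps any tie-breaking reproducible).
#' @return list with `weights`, `means`, `sds` (ordered by mean), `loglik`,
#'   `bic` for the mixture, and `bic_1` / `loglik_1` for the one-component
#'   fit; `bic` uses the `-2 loglik + k log n` (smaller is better)
#'   convention.
#' @export
fit_logdt_mixture <- function(pool, n_components = 2, seed = NULL) {
  ldt <- if (inherits(pool, "dt_pool")) pool$log_dt[pool$include] else pool
  if (length(ldt) < 10L) stop("need at least 10 points for the mixture fit")
  fit <- with_local_seed(seed, {
    mclust::Mclust(ldt, G = n_components, modelNames = "V", verbose = FALSE)
  })
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  n <- length(ldt)
  k_mix <- 3 * n_components - 1
  fit1 <- mclust::Mclust(ldt, G = 1, modelNames = "X", verbose = FALSE)
  list(weights = fit$parameters$pro[ord],
       means = as.numeric(fit$parameters$mean[ord]),
       sds = sqrt(fit$parameters$variance$sigmasq[ord]),
       loglik = fit$loglik,
       bic = -2 * fit$loglik + k_mix * log(n),
       loglik_1 = fit1$loglik,
       bic_1 = -2 * fit1$loglik + 2 * log(n))
}

#' Spearman correlations with false-discovery-rate correction
#'
#' Computes Spearman's rank correlation for each pair of vectors and
#' adjusts the p-values with the Benjamini-Hochberg step-up procedure
#' within the supplied comparison family.
#'
#' @param pairs list of two-element lists (or a single pair) of equal-length
#'   numeric vectors.
#' @return data frame with `rho`, `p_raw`, `p_fdr`, one row per pair.
#' @export
spearman_fdr <- function(pairs) {
  if (is.numeric(pairs[[1]])) pairs <- list(pairs)
  res <- lapply(pairs, function(pr) {
    x <- pr[[1]]
    y <- pr[[2]]
    if (length(x) != length(y) || length(x) < 3L) {
      stop("each pair needs equal-length vectors with >= 3 points")
    }
    if (sd(x) == 0 || sd(y) == 0) {
      stop("Spearman correlation undefined for a constant vector")
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    c(rho = unname(ct$estimate), p_raw = ct$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out
}

spearman_rho <- function(x, y) {
  suppressWarnings(cor(x, y, method = "spearman"))
}

# t-approximation p-value for a Spearman correlation against zero
rho_p_t <- function(rho, n) {
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  2 * pt(-abs(t), df = n - 2)
}

running_rho <- function(x, y, min_n) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  ms <- min_n:n
  rho <- vapply(ms, function(m) spearman_rho(xs[seq_len(m)], ys[seq_len(m)]),
                numeric(1))
  list(m = ms, rho = rho)
}

find_clusters <- function(sig, sgn, z) {
  runs <- rle(ifelse(sig, sgn, 0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      sign = integer(0), size = numeric(0)))
  }
  data.frame(
    start = starts[keep], end = ends[keep], sign = runs$values[keep],
    size = vapply(which(keep),
                  function(i) abs(sum(z[starts[i]:ends[i]])), numeric(1)))
}

#' Cluster-based permutation test on a running correlation curve
#'
#' Participants are ranked in ascending order of `index`; the Spearman
#' correlation between `index` and `y` is computed for the first `m`
#' participants as `m` grows from `min_n` to the full sample, giving a
#' correlation curve. Points significant at the uncorrected .05 level
#' (t-approximation against zero, or Monte Carlo against the overall
#' correlation when `reference = "overall"`) are grouped into clusters of
#' adjacent same-signed points; the cluster size is the absolute sum of the
#' Fisher-z transformed correlations. The null distribution of the maximum
#' cluster size is obtained by shuffling `index` across participants
#' (`reference = "zero"`) or shuffling the inclusion order
#' (`reference = "overall"`).
#'
#' @param index per-participant values defining the ranking (e.g. the
#'   cost-evidence strategy index).
#' @param y per-participant values to correlate (e.g. AQ scores).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param min_n smallest inclusion count of the curve, default 10.
#' @param alpha uncorrected pointwise significance level.
#' @param reference test the curve against zero or against the overall
#'   (full-sample) correlation.
#' @param seed optional seed for the permutations.
#' @return list of class `"correlation_curve"`: `m`, `rho`, `p_point`,
#'   `clusters` (with permutation p-values), `overall_rho`, `max_null`
#'   (permutation distribution of the maximum cluster size).
#' @export
cluster_permutation_curve <- function(index, y, n_perm = 10000, min_n = 10,
                                      alpha = 0.05,
                                      reference = c("zero", "overall"),
                                      seed = NULL) {
  reference <- match.arg(reference)
  if (length(index) != length(y)) stop("`index` and `y` must match in length")
  n <- length(index)
  if (n < min_n) stop("need at least `min_n` participants")
  if (n_perm < 100) stop("`n_perm` below 100 gives an unstable null")

  curve <- running_rho(index, y, min_n)
  fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

  with_local_seed(seed, {
    if (reference == "zero") {
      p_point <- rho_p_t(curve$rho, curve$m)
      sig <- p_point < alpha
      z <- fisher_z(curve$rho)
      clusters <- find_clusters(sig, sign(curve$rho), z)
      max_null <- vapply(seq_len(n_perm), function(b) {
        cb <- running_rho(index, y[sample.int(n)], min_n)
        pb <- rho_p_t(cb$rho, cb$m)
        cl <- find_clusters(pb < alpha, sign(cb$rho), fisher_z(cb$rho))
        if (nrow(cl)) max(cl$size) else 0
      }, numeric(1))
      overall <- spearman_rho(index, y)
    } else {
      # null curves: random inclusion order with index-y pairing intact
      overall <- spearman_rho(index, y)
      ord_curves <- matrix(NA_real_, n_perm, length(curve$m))
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        xs <- index[perm]
        ys <- y[perm]
        ord_curves[b, ] <- vapply(seq_along(curve$m), function(i) {
          m <- curve$m[i]
          spearman_rho(xs[seq_len(m)], ys[seq_len(m)])
        }, numeric(1))
      }
      # pointwise two-sided Monte Carlo p against the overall correlation
      p_of_curve <- function(rho_curve) {
        vapply(seq_along(rho_curve), function(i) {
          null_i <- ord_curves[, i]
          (1 + sum(abs(null_i - overall) >= abs(rho_curve[i] - overall))) /
            (n_perm + 1)
        }, numeric(1))
      }
      p_point <- p_of_curve(curve$rho)
      zdev <- fisher_z(curve$rho) - fisher_z(overall)
      clusters <- find_clusters(p_point < alpha, sign(zdev), zdev)
      max_null <- vapply(seq_len(n_perm), function(b) {
        rb <- ord_curves[b, ]
        pb <- p_of_curve(rb)
        zb <- fisher_z(rb) - fisher_z(overall)
        cl <- find_clusters(pb < alpha, sign(zb), zb)
        if (nrow(cl)) max(cl$size) else 0
      }, numeric(1))
    }
    if (nrow(clusters)) {
      clusters$p <- vapply(clusters$size,
                           function(s) (1 + sum(max_null >= s)) / (n_perm + 1),
                           numeric(1))
    } else {
      clusters$p <- numeric(0)
    }
    structure(list(m = curve$m, rho = curve$rho, p_point = p_point,
                   clusters = clusters, overall_rho = overall,
                   max_null = max_null, reference = reference,
                   n_perm = n_perm),
              class = "correlation_curve")
  })
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation curve vs %s: %d points, overall rho = %.3f, %d cluster(s)>\n",
              x$reference, length(x$m), x$overall_rho, nrow(x$clusters)))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: m = %d..%d, size = %.2f, p = %.4g\n", i,
                  x$m[x$clusters$start[i]], x$m[x$clusters$end[i]],
                  x$clusters$size[i], x$clusters$p[i]))
    }
  }
  invisible(x)
}
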