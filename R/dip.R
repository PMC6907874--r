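#' Hartigan's dip statistic and bootstrap multimodality test
#'
#' The dip is the smallest sup-norm distance between the empirical
#' distribution function of the data and the class of unimodal distribution
#' functions. `dip_stat()` computes the statistic by direct minimization
#' over candidate mode locations, using convex-minorant / concave-majorant
#' feasibility sweeps on the ECDF band (a quadratic-worst-case but in
#' practice near-linear variant of the classical algorithm). `dip_test()`
#' attaches a bootstrap p-value under the uniform null, the conventional
#' calibration for the test: `n_boot` uniform samples of the same size are
#' drawn and the p-value is the fraction with a dip at least as large.
#'
#' @param x numeric data (at least 4 points for the test).
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed optional integer seed for the bootstrap.
#' @return `dip_stat()`: the statistic (0 for constant or single-point
#'   data). `dip_test()`: list with `statistic`, `p_value`, `n`, `n_boot`.
#' @examples
#' dip_stat(c(0, 1))           # 0.25, maximally bimodal two-point sample
#' dip_test(rnorm(200), n_boot = 100, seed = 1)$p_value  # unimodal: large
#' @export
dip_stat <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0)
  dip_stat_cpp(sort(as.numeric(x)))
}

#' @rdname dip_stat
#' @export
dip_test <- function(x, n_boot = 1000, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("need at least 4 observations")
  d <- dip_stat(x)
  n <- length(x)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) dip_stat_cpp(sort(runif(n))),
           numeric(1))
  })
  structure(list(statistic = d,
                 p_value = (1 + sum(boots >= d)) / (n_boot + 1),
                 n = n, n_boot = n_boot),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.4g, bootstrap p = %.4g (n = %d, %d reps)\n",
              x$statistic, x$p_value, x$n, x$n_boot))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (when not
# NULL), restoring the caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
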