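dt8 <- c(b0_1 = 0.2, b1_1 = 0.4, b2_1 = 0.3, sigma_1 = 0.25,
         b0_2 = 0.5, b1_2 = 0.3, b2_2 = 0.2, sigma_2 = 0.3)

test_that("expected stage DTs follow the exponential difficulty form", {
  p4 <- c(b0_1 = log(0.3), b1_1 = 1, b2_1 = 0, sigma_1 = 0.3)
  y <- expected_stage_dts(0.2, NA, p4, NA)
  expect_equal(y$y_cont1, 0.3 * exp(0.8))
  expect_equal(y$y_stop1, 0.3 * exp(0.2))
  expect_null(y$y_cont2)
  # b1 = b2 = 0 collapses to exp(b0); p = 1/2 is symmetric
  p0 <- c(b0_1 = 0.7, b1_1 = 0, b2_1 = 0, sigma_1 = 0.2)
  y0 <- expected_stage_dts(0.83, NA, p0, NA)
  expect_equal(y0$y_cont1, exp(0.7))
  expect_equal(y0$y_cont1, y0$y_stop1)
  ysym <- expected_stage_dts(0.5, NA, p4, NA)
  expect_equal(ysym$y_cont1, ysym$y_stop1)
  # second-stage continue time adds a positive increment to the right base
  yc <- expected_stage_dts(0.3, 0.6, dt8, "continue")
  ys <- expected_stage_dts(0.3, 0.6, dt8, "stop")
  expect_gt(yc$y_cont2, yc$y_cont1)
  expect_gt(ys$y_cont2, ys$y_stop1)
  expect_equal(yc$y_cont2 - yc$y_cont1, ys$y_cont2 - ys$y_stop1)
})

test_that("stage posteriors given continue match their closed forms and sum to 1", {
  expect_equal(stage_posteriors(0.3, 0.6, 0, "continue"),
               list(p_s1 = 1, p_s2 = 0))
  expect_equal(stage_posteriors(0.3, 0.5, 1, "continue")$p_s1, 0)
  expect_equal(stage_posteriors(0, 0.5, 0.7, "stop"), list(p_s1 = 1, p_s2 = 0))
  set.seed(4)
  for (i in 1:50) {
    p1 <- runif(1)
    p2 <- runif(1, 0, 0.99)
    psec <- runif(1, 0, 0.99)
    for (trig in c("continue", "stop")) {
      ps <- stage_posteriors(p1, p2, psec, trig)
      expect_equal(ps$p_s1 + ps$p_s2, 1)
      # agree with path-probability enumeration
      paths <- enum_continue_paths(p1, p2, psec, trig)
      expect_equal(ps$p_s1, unname(paths["s1"] / sum(paths)),
                   tolerance = 1e-12)
    }
  }
  expect_error(stage_posteriors(0.3, 1, 1, "continue"), "impossible")
})

test_that("the DT likelihood is a proper lognormal mixture", {
  # single-component collapse and the closed-form density at the median
  y <- expected_stage_dts(0.4, 0.6, dt8, "continue")
  ll_mix <- dt_loglik(1.3, 0.4, 0.6, 0, dt8, "continue")
  expect_equal(ll_mix, dlnorm(1.3, log(y$y_cont1), dt8["sigma_1"],
                              log = TRUE), ignore_attr = TRUE)
  p1c <- c(b0_1 = 0.3, b1_1 = 0, b2_1 = 0, sigma_1 = 1)
  y1 <- exp(0.3)
  expect_equal(exp(dt_loglik(y1, 0.5, NA, NA, p1c, NA)),
               1 / (sqrt(2 * pi) * y1))
  # mixture density integrates to 1
  set.seed(12)
  for (i in 1:5) {
    p1 <- runif(1)
    p2 <- runif(1, 0, 0.95)
    psec <- runif(1, 0.05, 0.95)
    dens <- function(t) {
      vapply(t, function(ti) exp(dt_loglik(ti, p1, p2, psec, dt8,
                                           "continue")), numeric(1))
    }
    total <- integrate(dens, 0, Inf, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  expect_error(dt_loglik(-1, 0.5, 0.5, 0.5, dt8, "continue"), "positive")
})

test_that("the joint likelihood factorizes into choice and DT terms", {
  expect_equal(joint_loglik(-120.5, 0), -120.5)
  expect_equal(joint_loglik(-120.5, -300.25), -420.75)
  # direct evaluation of the joint mixture equals the product form
  set.seed(13)
  for (i in 1:1000) {
    p1 <- runif(1)
    p2 <- runif(1, 0, 0.95)
    psec <- runif(1, 0, 0.95)
    trig <- sample(c("continue", "stop"), 1)
    dt <- runif(1, 0.2, 5)
    paths <- enum_continue_paths(p1, p2, psec, trig)
    p_cont <- sum(paths)
    if (p_cont <= 0) next
    y <- expected_stage_dts(p1, p2, dt8, trig)
    direct <- paths["s1"] * dlnorm(dt, log(y$y_cont1), dt8["sigma_1"]) +
      paths["s2"] * dlnorm(dt, log(y$y_cont2), dt8["sigma_2"])
    product <- log(p_cont) + dt_loglik(dt, p1, p2, psec, dt8, trig)
    expect_equal(unname(log(direct)), unname(product), tolerance = 1e-10)
  }
})

test_that("simulated DTs have the path's lognormal location", {
  set.seed(14)
  expect_equal(simulate_dt(rep(1.7, 3), 0), rep(1.7, 3))
  draws <- simulate_dt(rep(2.2, 1e5), 0.4)
  expect_lt(abs(median(draws) - 2.2), 0.02)
  expect_lt(abs(sd(log(draws)) - 0.4), 0.01)
  # two separated paths produce a bimodal log-DT distribution
  two <- c(simulate_dt(rep(1, 2000), 0.2), simulate_dt(rep(4, 2000), 0.2))
  dt_res <- dip_test(log(two), n_boot = 200, seed = 5)
  expect_lt(dt_res$p_value, 0.05)
  one <- simulate_dt(rep(2, 4000), 0.25)
  expect_gt(dip_test(log(one), n_boot = 200, seed = 6)$p_value, 0.1)
})
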