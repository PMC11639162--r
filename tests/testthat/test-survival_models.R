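test_that("antisymmetric pooled data gives a zero balance effect", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  b <- c(0.5, -1, 2, 0.3, -0.7, 1.5)
  out <- survival_outcome(c(time, time), c(event, event))
  fit <- fit_cox(c(b, -b), out)
  expect_equal(fit$gamma, 0, tolerance = 1e-6)
})

test_that("Cox fit matches the brute-force Breslow partial likelihood", {
  # high-balance subjects tend to fail earlier; the interleaving keeps an
  # interior maximum (a fully separated arrangement has a monotone
  # partial likelihood whose supremum sits at +Inf)
  time <- 1:6
  event <- rep(1, 6)
  b <- c(1, 0, 1, 0, 1, 0)
  out <- survival_outcome(time, event)
  fit <- fit_cox(b, out, ties = "breslow")
  grid <- seq(-2, 4, by = 1e-3)
  oracle <- breslow_grid_mle(time, event, b, grid)
  expect_gt(fit$gamma, 0)
  expect_equal(fit$gamma, oracle$gamma, tolerance = 2e-3)
  expect_equal(fit$loglik,
               breslow_partial_loglik(fit$gamma, time, event, b),
               tolerance = 1e-8)
  # LRT statistic equals direct evaluation at gamma-hat and 0
  lrt <- 2 * (fit$loglik - fit$loglik_null)
  expect_equal(lrt,
               2 * (breslow_partial_loglik(fit$gamma, time, event, b) -
                      breslow_partial_loglik(0, time, event, b)),
               tolerance = 1e-8)
  expect_equal(fit$p_gamma, pchisq(lrt, 1, lower.tail = FALSE))
})

test_that("Cox partial likelihood depends on time only through ranks", {
  set.seed(3)
  n <- 80
  b <- rnorm(n)
  time <- rexp(n, exp(0.8 * b))
  event <- rbinom(n, 1, 0.8)
  out1 <- survival_outcome(time, event)
  out2 <- survival_outcome(time^2, event)  # strictly increasing transform
  f1 <- fit_cox(b, out1)
  f2 <- fit_cox(b, out2)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("negating the balance negates the effect in both models", {
  set.seed(4)
  n <- 120
  b <- rnorm(n)
  time <- rweibull(n, 1.4, exp(1 - 0.5 * b))
  event <- rbinom(n, 1, 0.85)
  out <- survival_outcome(time, event)
  fc1 <- fit_cox(b, out); fc2 <- fit_cox(-b, out)
  expect_equal(fc1$gamma, -fc2$gamma, tolerance = 1e-6)
  expect_equal(fc1$loglik, fc2$loglik, tolerance = 1e-8)
  fa1 <- fit_weibull_aft(b, out); fa2 <- fit_weibull_aft(-b, out)
  expect_equal(fa1$gamma_prime, -fa2$gamma_prime, tolerance = 1e-5)
  expect_equal(fa1$loglik, fa2$loglik, tolerance = 1e-6)
})

test_that("AFT fit is unbiased under a null balance effect", {
  set.seed(5)
  n <- 500
  b <- rnorm(n)
  time <- exp(2 + 0 * b + 0.5 * log(rexp(n)))
  out <- survival_outcome(time, rep(1, n))
  fit <- fit_weibull_aft(b, out)
  expect_lt(abs(fit$gamma_prime), 3 * fit$se_gamma)
  expect_equal(fit$intercept, 2, tolerance = 0.15)
  expect_equal(fit$scale, 0.5, tolerance = 0.1)
})

test_that("uncensored constant-balance AFT reduces to the Weibull MLE", {
  set.seed(6)
  time <- rweibull(200, shape = 1.7, scale = 5)
  out <- survival_outcome(time, rep(1, 200))
  fit <- fit_weibull_aft(rep(1, 200) * 0, out)  # constant balance
  oracle <- weibull_mle_oracle(time)
  # survreg parameterization: scale = 1/shape, exp(intercept) = Weibull scale
  expect_equal(1 / fit$scale, oracle$shape, tolerance = 1e-3)
  expect_equal(exp(fit$intercept), oracle$scale, tolerance = 1e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
  # fitted loglik dominates the truth's loglik
  truth_ll <- sum(dweibull(time, 1.7, 5, log = TRUE))
  expect_gte(fit$loglik, truth_ll - 1e-6)
})

test_that("degenerate inputs are handled per contract", {
  out0 <- survival_outcome(1:5, rep(0, 5))
  expect_error(fit_cox(rnorm(5), out0), "event")
  expect_error(fit_weibull_aft(rnorm(5), out0), "event")
  # monotone likelihood (perfect separation) is flagged, not fatal
  time <- c(1, 2, 3, 10, 11, 12)
  b <- c(5, 5, 5, -5, -5, -5)
  fit <- fit_cox(b, survival_outcome(time, rep(1, 6)))
  expect_false(is.null(fit$flag))
})

test_that("predicted survival curves obey the axioms", {
  set.seed(8)
  n <- 150
  b <- rnorm(n)
  time <- rweibull(n, 1.5, exp(0.5 - 0.6 * b))
  event <- rbinom(n, 1, 0.8)
  out <- survival_outcome(time, event)
  for (fit in list(fit_cox(b, out), fit_weibull_aft(b, out))) {
    qs <- quantile(b, c(0.25, 0.75), names = FALSE)
    cur <- predict_survival_curves(fit, qs)
    expect_equal(unique(cur$survival[cur$time == 0]), 1)
    for (lv in qs) {
      s <- cur$survival[cur$level == lv]
      expect_true(all(diff(s) <= 1e-12))
    }
    # hazard-increasing effect: high-balance curve lies below
    g <- if (inherits(fit, "cox_fit")) fit$gamma else -fit$gamma_prime
    s1 <- cur$survival[cur$level == qs[1]]
    s3 <- cur$survival[cur$level == qs[2]]
    if (g > 0) expect_true(all(s3 <= s1 + 1e-12))
  }
  # null AFT effect: curves at Q1 and Q3 coincide
  fa <- fit_weibull_aft(b, out)
  fa$gamma_prime <- 0
  cur0 <- predict_survival_curves(fa, c(-1, 1))
  expect_equal(cur0$survival[cur0$level == -1],
               cur0$survival[cur0$level == 1])
  expect_error(predict_survival_curves(fa, c(0, NA)), "finite")
})

test_that("fit summaries serialize to JSON", {
  set.seed(9)
  b <- rnorm(60)
  out <- survival_outcome(rexp(60, exp(0.5 * b)), rbinom(60, 1, 0.9))
  js <- fit_summary_json(fit_cox(b, out))
  parsed <- jsonlite::fromJSON(js)
  expect_named(parsed, c("gamma", "se_gamma", "beta", "loglik",
                         "loglik_null", "p_gamma", "ties", "flag",
                         "converged", "max_time", "model"),
               ignore.order = TRUE)
  expect_true(parsed$converged)
})
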