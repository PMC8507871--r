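test_that("parameter construction enforces positivity and ordering", {
  expect_s3_class(stock_params(), "resens_params")
  expect_error(resens_params(0.23, 0.12, 0.03, 0.066), "alpha_m")
  expect_error(resens_params(-0.1, 0.2, 0.03, 0.066), "alpha0")
  expect_error(resens_params(0.1, 0.2, 0.03, -1), "b")
  # equality alpha_m = alpha0 is the frozen-sensitivity limit and is allowed
  expect_silent(resens_params(0.12, 0.12, 0.03, 0))
})

test_that("alpha(t) follows the resensitization kinetics", {
  p <- stock_params()
  expect_equal(alpha_at(0, p), p$alpha0)               # starts hypoxic
  p0 <- resens_params(0.12, 0.23, 0.12 / 4.5, b = 0)
  expect_equal(alpha_at(c(0, 5, 50), p0), rep(0.12, 3))  # b = 0: constant

  # independent evaluation of the kinetics at t = 14 d
  w14 <- exp(-0.066 * 14^2 / 2)
  expect_equal(alpha_at(14, p), 0.12 * w14 + 0.23 * (1 - w14))
  expect_equal(alpha_at(14, p), 0.2298, tolerance = 1e-3)

  expect_error(alpha_at(-1, p), "non-negative")
})

test_that("beta(t) is tied to alpha(t) through the squared OER relation", {
  p <- stock_params()
  expect_equal(beta_at(0, p), p$beta0)
  # asymptotic limit beta_m = beta0 (alpha_m/alpha0)^2
  expect_equal(beta_at(1e6, p), p$beta0 * (p$alpha_m / p$alpha0)^2)
  # independent evaluation at t = 14 d
  expect_equal(beta_at(14, p), p$beta0 * (alpha_at(14, p) / 0.12)^2)
  expect_equal(beta_at(14, p), 0.0979, tolerance = 1e-3)
})

test_that("alpha is non-decreasing and bounded; the OER identity holds", {
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_params()
      t <- sort(runif(30, 0, 60))
      a <- alpha_at(t, p)
      expect_true(all(diff(a) >= -1e-12))
      expect_true(all(a >= p$alpha0 - 1e-12 & a <= p$alpha_m + 1e-12))
      expect_equal(beta_at(t, p) / p$beta0, (a / p$alpha0)^2)
      # alpha/beta = alpha0^2 / (beta0 alpha(t)) decreases when alpha_m > alpha0
      ab <- a / beta_at(t, p)
      if (p$alpha_m > p$alpha0) expect_true(all(diff(ab) <= 1e-12))
    }
  })
})

test_that("cumulative log survival accumulates per-fraction LQ kill", {
  p <- stock_params()
  # single fraction at t = 0 sees the initial sensitivities
  s1 <- fx_schedule(0, 5)
  expect_equal(cumulative_log_survival(s1, p),
               -(p$alpha0 * 5 + p$beta0 * 25))

  # b = 0 reduces to the classic LQ model: n equal fractions
  p0 <- resens_params(0.15, 0.25, 0.03, b = 0)
  s4 <- fx_schedule(c(0, 7, 14, 21), 6)
  expect_equal(cumulative_log_survival(s4, p0),
               -4 * (0.15 * 6 + 0.03 * 36))

  # clinical 2 x 14 Gy: independent sum of the two per-fraction terms
  a14 <- alpha_at(14, p); b14 <- beta_at(14, p)
  expected <- -((p$alpha0 * 14 + p$beta0 * 196) + (a14 * 14 + b14 * 196))
  expect_equal(cumulative_log_survival(sched_2f(), p), expected)
  expect_equal(expected, -29.3, tolerance = 1e-3)

  expect_error(cumulative_log_survival(sched_2f(), p, k = 3), "fraction index")
  expect_error(cumulative_log_survival(sched_2f(), p, k = 0), "fraction index")
})

test_that("log survival is additive over fractions and non-increasing in k", {
  withr::with_seed(12, {
    for (i in 1:10) {
      p <- random_params()
      s <- random_schedule()
      ls <- vapply(seq_len(nrow(s)), cumulative_log_survival,
                   numeric(1), schedule = s, params = p)
      expect_true(all(diff(ls) < 0))
      for (k in seq_len(nrow(s))[-1]) {
        term <- -(alpha_at(s$time_days[k], p) * s$dose_gy[k] +
                    beta_at(s$time_days[k], p) * s$dose_gy[k]^2)
        expect_equal(ls[k], ls[k - 1] + term)
      }
    }
  })
})

test_that("time-mean alpha/beta matches brute-force evaluation", {
  p <- stock_params()
  # degenerate cases: single fraction, or no resensitization
  expect_equal(time_mean_alpha_beta(fx_schedule(0, 10), p), 4.5)
  p0 <- resens_params(0.12, 0.23, 0.12 / 4.5, b = 0)
  expect_equal(time_mean_alpha_beta(sched_3f(), p0), 4.5)

  # 3 fractions at 0/14/28 d: mean of alpha(T_i)/beta(T_i) computed directly
  times <- c(0, 14, 28)
  brute <- mean(alpha_at(times, p) / beta_at(times, p))
  expect_equal(time_mean_alpha_beta(sched_3f(), p), brute)
  expect_equal(brute, 3.07, tolerance = 2e-3)
})
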