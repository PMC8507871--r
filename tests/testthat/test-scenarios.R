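test_that("the stock scenario grid covers schedules x resensitization rates", {
  specs <- stock_scenarios(seed = 1, n_samples = 300)
  expect_equal(nrow(specs), 8L)
  expect_equal(sort(unique(specs$b)), c(0.066, 1))
  expect_false(anyDuplicated(specs$label) > 0)

  m <- run_matrix(specs)
  expect_s3_class(m, "tcp_scenario_matrix")
  expect_equal(nrow(m), 8L)
  expect_true(all(m$population_tcp >= 0 & m$population_tcp <= 1))
  expect_error(run_matrix(specs[c(1, 1), ]), "unique")
})

test_that("paired cohorts make schedule contrasts consistent", {
  # scenarios sharing population, b and fraction times reuse the same cohort
  specs <- stock_scenarios(seed = 2, n_samples = 500)
  m <- run_matrix(specs)
  ind1 <- m$result[[which(m$label == "2F/14d b=0.066")]]$individuals
  # same draws as a direct population_tcp call with the same seed
  direct <- population_tcp(stock_population(2, 500), sched_2f(),
                           stock_kinetics(), 0.066)
  expect_identical(ind1$alpha0, direct$individuals$alpha0)
})

test_that("dose sweep is monotone under common random numbers", {
  pop <- small_pop(n = 1500, seed = 31)
  sw <- dose_sweep(sched_2f(), seq(10, 16, 0.5), pop, stock_kinetics(), 0.066)
  expect_s3_class(sw, "tcp_dose_sweep")
  expect_true(all(diff(sw$population_tcp) >= -1e-12))
  # extremes: negligible dose -> no control; huge dose -> certain control
  ends <- dose_sweep(sched_2f(), c(1e-3, 100), pop, stock_kinetics(), 0.066)
  expect_lt(ends$population_tcp[1], 1e-6)
  expect_equal(ends$population_tcp[2], 1)
  expect_error(dose_sweep(sched_2f(), numeric(0), pop, stock_kinetics(),
                          0.066), "non-empty")
})

test_that("iso-TCP dose inversion matches a dense grid scan", {
  pop <- small_pop(n = 1500, seed = 32)
  k <- stock_kinetics()
  target <- 0.5
  d_bisect <- find_iso_tcp_dose(sched_2f(), target, pop, k, 0.066,
                                bracket = c(10, 16), resolution = 0.1)
  # brute-force oracle: first grid dose reaching the target
  grid <- dose_sweep(sched_2f(), seq(10, 16, 0.1), pop, k, 0.066)
  d_grid <- grid$dose_gy[which(grid$population_tcp >= target)[1]]
  expect_lte(abs(d_bisect - d_grid), 0.1 + 1e-9)

  # target already met at the low edge returns the low edge
  expect_equal(
    find_iso_tcp_dose(sched_2f(), 0.01, pop, k, 0.066, bracket = c(14, 16)),
    14
  )
  expect_error(
    find_iso_tcp_dose(sched_2f(), 0.999999, pop, k, 0.066,
                      bracket = c(10, 11)),
    "bracket"
  )
})

test_that("frozen-sensitivity scenarios reduce to the plain LQ model", {
  pop <- small_pop(n = 800, seed = 33)
  hyp <- no_resensitization(pop, mode = "hypoxic")
  sen <- no_resensitization(pop, mode = "sensitive")
  expect_equal(nrow(hyp), 2L)
  # never reoxygenating is far worse than never having been hypoxic
  expect_true(all(hyp$population_tcp < 0.2))
  expect_true(all(sen$population_tcp > 0.9))

  # zero spread: the frozen population TCP is one individual's zm_tcp
  pop0 <- small_pop(n = 20, seed = 34, sd_alpha0 = 0, sd_beta0 = 0,
                    sd_alpha_m = 0)
  sen0 <- no_resensitization(pop0, mode = "sensitive")
  p_frozen <- resens_params(0.23, 0.23, 0.23 / 4.5, b = 0)
  expect_equal(
    sen0$population_tcp[sen0$label == "2F/14d"],
    zm_tcp(sched_2f(), p_frozen, stock_kinetics())
  )
})

test_that("sensitivity grid emits one paired point per perturbation", {
  pop <- small_pop(n = 600, seed = 35)
  base_only <- sensitivity_grid(pop, perturbations = tibble::tibble(
    parameter = character(0), value = numeric(0)
  ))
  expect_equal(nrow(base_only), 1L)
  m <- run_matrix(stock_scenarios(seed = 35, n_samples = 600))
  expect_equal(base_only$tcp_3f,
               m$population_tcp[m$label == "3F/28d b=0.066"])

  grid <- sensitivity_grid(pop)
  expect_equal(nrow(grid), nrow(default_perturbations()) + 1L)
  expect_error(
    sensitivity_grid(pop, perturbations = tibble::tibble(
      parameter = "mean_beta0", value = 0.01
    )),
    "limited"
  )
})
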