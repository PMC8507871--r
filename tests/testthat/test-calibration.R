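test_that("target and search-space constructors validate inputs", {
  expect_error(calibration_targets(tcp_2f_target = 1.2), "tcp_2f_target")
  expect_error(calibration_targets(tolerance = 0), "tolerance")
  expect_error(search_space(mean_alpha0 = c(0.3, 0.1)), "mean_alpha0")
})

test_that("a single-evaluation budget yields a one-row trace", {
  cal <- random_search(search_space(), calibration_targets(), budget = 1,
                       seed = 41, n_inner = 200, n_final = 200)
  expect_equal(nrow(cal$trace), 1L)
  expect_s3_class(tidy(cal), "tbl_df")
  expect_equal(glance(cal)$n_evals, 1L)
})

test_that("search is deterministic given seed, budget and space", {
  args <- list(search_space(), calibration_targets(), budget = 5,
               seed = 42, n_inner = 200, n_final = 200)
  cal1 <- do.call(random_search, args)
  cal2 <- do.call(random_search, args)
  expect_identical(cal1$trace, cal2$trace)
  expect_identical(cal1$score, cal2$score)
})

test_that("a space collapsed onto the calibrated point is accepted", {
  collapsed <- search_space(
    mean_alpha0 = c(0.12, 0.12), sd_alpha0 = c(0.02, 0.02),
    mean_alpha_m = c(0.23, 0.23), sd_alpha_m = c(0.02, 0.02),
    sd_beta0 = c(0.01, 0.01)
  )
  # targets at the configuration's own simulated TCPs (independent seed),
  # tolerance 0.03: the collapsed space must be accepted immediately
  k <- stock_kinetics()
  targets <- calibration_targets(
    tcp_2f_target = population_tcp(small_pop(4000, seed = 143), sched_2f(),
                                   k, 0.066)$population_tcp,
    tcp_3f_target = population_tcp(small_pop(4000, seed = 143), sched_3f(),
                                   k, 0.066)$population_tcp,
    tolerance = 0.03
  )
  cal <- random_search(collapsed, targets,
                       budget = 1, seed = 43, n_inner = 2000, n_final = 4000)
  expect_equal(cal$best$mean_alpha0, 0.12)
  expect_true(cal$accepted)
  # the final re-scoring reuses the search seed's cohort exactly
  direct2 <- population_tcp(small_pop(4000, seed = 43), sched_2f(),
                            stock_kinetics(), 0.066)$population_tcp
  expect_equal(cal$tcp_2f, direct2)
})

test_that("calibration round-trip recovers target TCPs on the TCP scale", {
  # simulate 'observed' control rates from a known population, then search a
  # narrow bracketing space; recovery is judged on the TCP scale only
  truth <- small_pop(n = 1500, seed = 44)
  k <- stock_kinetics()
  tcp2 <- population_tcp(truth, sched_2f(), k, 0.066)$population_tcp
  tcp3 <- population_tcp(truth, sched_3f(), k, 0.066)$population_tcp
  targets <- calibration_targets(tcp_2f_target = tcp2, tcp_3f_target = tcp3,
                                 tolerance = 0.02)
  space <- search_space(
    mean_alpha0 = c(0.10, 0.14), sd_alpha0 = c(0.01, 0.03),
    mean_alpha_m = c(0.20, 0.26), sd_alpha_m = c(0.01, 0.03),
    sd_beta0 = c(0.005, 0.015)
  )
  cal <- random_search(space, targets, budget = 150, seed = 44,
                       n_inner = 1000, n_final = 1500)
  expect_lte(abs(cal$tcp_2f - tcp2), 0.02)
  expect_lte(abs(cal$tcp_3f - tcp3), 0.02)
  expect_true(cal$accepted)
})

test_that("the objective profile is flatter along mean_alpha0 than mean_alpha_m", {
  base <- small_pop(n = 1200, seed = 45)
  # targets at the base configuration's own simulated values so the profile
  # minimum sits at the base point
  k <- stock_kinetics()
  targets <- calibration_targets(
    tcp_2f_target = population_tcp(base, sched_2f(), k, 0.066)$population_tcp,
    tcp_3f_target = population_tcp(base, sched_3f(), k, 0.066)$population_tcp
  )
  prof_m <- profile_objective("mean_alpha_m", c(0.21, 0.23, 0.25),
                              targets, base)
  expect_equal(nrow(prof_m), 3L)
  expect_equal(prof_m$value[which.min(prof_m$objective)], 0.23)

  prof_0 <- profile_objective("mean_alpha0", c(0.10, 0.12, 0.14),
                              targets, base)
  # +-0.02 around the calibrated point: alpha_m moves the TCPs more
  expect_lt(diff(range(prof_0$objective)), diff(range(prof_m$objective)))

  expect_error(profile_objective("b", 1, targets, base), "axis")
  prof_1 <- profile_objective("mean_alpha_m", 0.23, targets, base)
  expect_equal(nrow(prof_1), 1L)
})
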