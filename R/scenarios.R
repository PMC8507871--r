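#' Stock study configuration
#'
#' The shipped default configuration of the analysis: the calibrated
#' population (`alpha0 ~ N(0.12, 0.02)`, `alpha_m ~ N(0.23, 0.02)`,
#' `beta0 ~ N(0.12/4.5, 0.01)`, alpha/beta window 3.5-6 Gy), fixed kinetics
#' (`N0 = 1e8` cells, `lambda = 0.02` day^-1), slow resensitization
#' (`b = 0.066` day^-2), and the four schedules: the clinical two-fraction
#' (2 x 14 Gy, days 0/14) and three-fraction (3 x 11 Gy, days 0/14/28)
#' regimens plus their hypothetical 7-day-interval shortenings.
#'
#' @param seed Integer seed for the population sampling.
#' @param n_samples Individuals per cohort.
#' @return `stock_population()`: a [population_distribution()];
#'   `stock_kinetics()`: a [tumor_kinetics()]; `clinical_schedules()`: a
#'   named list of four [fx_schedule()]s.
#' @export
stock_population <- function(seed, n_samples = 10000) {
  population_distribution(n_samples = n_samples, seed = seed)
}

#' @rdname stock_population
#' @export
stock_kinetics <- function() tumor_kinetics(n0 = 1e8, lambda = 0.02)

#' @rdname stock_population
#' @export
clinical_schedules <- function() {
  list(
    `2F/14d` = fx_schedule(c(0, 14), 14),
    `3F/28d` = fx_schedule(c(0, 14, 28), 11),
    `2F/7d`  = fx_schedule(c(0, 7), 14),
    `3F/14d` = fx_schedule(c(0, 7, 14), 11)
  )
}

#' Scenario specifications for the eight-cell schedule-by-rate matrix
#'
#' One row per scenario: the four schedules of [clinical_schedules()] crossed
#' with slow (`b = 0.066` day^-2) and fast (`b = 1` day^-2) resensitization.
#'
#' @inheritParams stock_population
#' @return A tibble with columns `label`, `schedule` (list), `b`,
#'   `population` (list), `kinetics` (list).
#' @export
stock_scenarios <- function(seed, n_samples = 10000) {
  sch <- clinical_schedules()
  pop <- stock_population(seed, n_samples)
  kin <- stock_kinetics()
  grid <- tidyr::expand_grid(
    b = c(0.066, 1),
    schedule_name = names(sch)
  )
  tibble(
    label = paste0(grid$schedule_name, " b=", grid$b),
    schedule = unname(sch[grid$schedule_name]),
    b = grid$b,
    population = rep(list(pop), nrow(grid)),
    kinetics = rep(list(kin), nrow(grid))
  )
}

#' Run a batch of population-TCP scenarios
#'
#' Evaluates [population_tcp()] for every row of a scenario table.  Scenarios
#' sharing a population use common random numbers (the population's seed), so
#' cohorts are paired wherever the alpha/beta acceptance window coincides and
#' schedule contrasts are stabilised.
#'
#' @param specs A tibble as produced by [stock_scenarios()]: columns `label`
#'   (unique), `schedule`, `b`, `population`, `kinetics`.
#' @return A tibble of class `tcp_scenario_matrix` with one row per scenario:
#'   `label`, `population_tcp`, `se`, `n_samples`, `acceptance_rate`, and the
#'   full result object in the list column `result`.
#' @examples
#' \donttest{
#' run_matrix(stock_scenarios(seed = 1, n_samples = 2000))
#' }
#' @export
run_matrix <- function(specs) {
  if (!is.data.frame(specs) || nrow(specs) == 0L) {
    abort("`specs` must be a non-empty scenario table.")
  }
  if (anyDuplicated(specs$label)) {
    abort("Scenario labels must be unique within a batch.")
  }
  results <- pmap(
    list(specs$schedule, specs$b, specs$population, specs$kinetics),
    function(schedule, b, population, kinetics) {
      population_tcp(population, schedule, kinetics, b)
    }
  )
  out <- tibble(
    label = specs$label,
    population_tcp = map_dbl(results, "population_tcp"),
    se = map_dbl(results, "se"),
    n_samples = map_dbl(results, ~ nrow(.x$individuals)),
    acceptance_rate = map_dbl(results, "acceptance_rate"),
    result = results
  )
  class(out) <- c("tcp_scenario_matrix", class(out))
  out
}

#' Population TCP as a function of dose per fraction
#'
#' Substitutes each candidate equal dose per fraction into the fraction times
#' of `schedule_template` and computes the population TCP.  One cohort is
#' sampled once and reused across all doses (the alpha/beta window depends on
#' fraction times only), so the curve is a common-random-number pairing and
#' monotone non-decreasing up to floating-point noise.
#'
#' @param schedule_template An [fx_schedule()] whose times are kept.
#' @param doses Vector of doses per fraction, Gy, all positive.
#' @param pop A [population_distribution()].
#' @param kinetics A [tumor_kinetics()].
#' @param b Resensitization rate, day^-2.
#' @return A tibble of class `tcp_dose_sweep`: `dose_gy`, `population_tcp`,
#'   `se`.
#' @export
dose_sweep <- function(schedule_template, doses, pop, kinetics, b) {
  schedule_template <- as_fx_schedule(schedule_template)
  if (length(doses) == 0L || !is.numeric(doses)) {
    abort("`doses` must be a non-empty numeric vector.")
  }
  if (any(doses <= 0)) abort("All doses must be positive.")
  cohort <- sample_individuals(pop, schedule_template, b)
  rows <- map(doses, function(d) {
    res <- population_tcp(pop, with_dose(schedule_template, d), kinetics, b,
                          individuals = cohort)
    tibble(dose_gy = d, population_tcp = res$population_tcp, se = res$se)
  })
  out <- bind_rows(rows)
  class(out) <- c("tcp_dose_sweep", class(out))
  out
}

#' Dose per fraction achieving a target population TCP
#'
#' Inverse of [dose_sweep()]: bisection on the dose -> population TCP map for
#' an equal-dose-per-fraction schedule.  The map is made deterministic by
#' common random numbers (one cohort reused at every trial dose), so plain
#' bisection applies; the returned dose is reported at `resolution` (0.1 Gy
#' by default).
#'
#' @inheritParams dose_sweep
#' @param target_tcp Target population TCP in (0, 1).
#' @param bracket Dose bracket `c(low, high)` in Gy that must straddle the
#'   target.
#' @param resolution Dose resolution in Gy.
#' @return The dose per fraction in Gy.
#' @export
find_iso_tcp_dose <- function(schedule_template, target_tcp, pop, kinetics, b,
                              bracket = c(10, 16), resolution = 0.1) {
  schedule_template <- as_fx_schedule(schedule_template)
  check_number(target_tcp, "target_tcp", lower = 0, allow_equal = FALSE)
  if (target_tcp >= 1) abort("`target_tcp` must be in (0, 1).")
  cohort <- sample_individuals(pop, schedule_template, b)
  f <- function(d) {
    population_tcp(pop, with_dose(schedule_template, d), kinetics, b,
                   individuals = cohort)$population_tcp - target_tcp
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo >= 0) return(lo)      # target met already at the low edge
  if (f_hi < 0) {
    abort(sprintf(
      "Target TCP %.3f not achievable within the bracket [%g, %g] Gy.",
      target_tcp, lo, hi
    ))
  }
  while (hi - lo > resolution / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  round(hi / resolution) * resolution
}

#' Population TCP with resensitization switched off (anti-hypotheses)
#'
#' Evaluates the two `b = 0` counterfactuals on both clinical schedules:
#' `"hypoxic"` freezes sensitivities at their initial values (mean alpha
#' 0.12 Gy^-1), i.e. the tumor never reoxygenates; `"sensitive"` assumes no
#' initial hypoxia, freezing them at the fully oxygenated maxima (mean alpha
#' 0.23 Gy^-1, mean beta 0.23/4.5 Gy^-2).  Each individual's `alpha_m` is
#' tied to its `alpha0`, which is inert when `b = 0`.
#'
#' @param pop A [population_distribution()]; its SDs, window, `n_samples` and
#'   seed are reused for the frozen populations.
#' @param schedules Named list of schedules; defaults to the two clinical
#'   regimens.
#' @param kinetics A [tumor_kinetics()].
#' @param mode `"hypoxic"` or `"sensitive"`.
#' @return A tibble: `label`, `mode`, `population_tcp`, `se`.
#' @export
no_resensitization <- function(pop, schedules = clinical_schedules()[c("2F/14d", "3F/28d")],
                               kinetics = stock_kinetics(),
                               mode = c("hypoxic", "sensitive")) {
  mode <- match.arg(mode)
  mean_alpha <- switch(mode,
    hypoxic = pop$mean_alpha0,
    sensitive = pop$mean_alpha_m
  )
  frozen <- population_distribution(
    mean_alpha0 = mean_alpha, sd_alpha0 = pop$sd_alpha0,
    mean_alpha_m = mean_alpha, sd_alpha_m = 0,
    mean_beta0 = mean_alpha / 4.5, sd_beta0 = pop$sd_beta0,
    ab_window = pop$ab_window, n_samples = pop$n_samples, seed = pop$seed
  )
  rows <- map2(names(schedules), schedules, function(label, schedule) {
    cohort <- sample_individuals(frozen, schedule, b = 0, tie_alpha_m = TRUE)
    res <- population_tcp(frozen, schedule, kinetics, b = 0,
                          individuals = cohort)
    tibble(label = label, mode = mode,
           population_tcp = res$population_tcp, se = res$se)
  })
  bind_rows(rows)
}

#' Sensitivity of the paired clinical TCPs to population-parameter variation
#'
#' Re-evaluates the two clinical population TCPs (three-fraction and
#' two-fraction schedules, `b = 0.066` day^-2) under perturbed values of the
#' population means/SDs of `alpha0` and `alpha_m`, producing the
#' scatter-plot table of (TCP_3F, TCP_2F) pairs.
#'
#' @param base_pop A [population_distribution()] to perturb.
#' @param perturbations A tibble (or data frame) with columns `parameter`
#'   (one of `mean_alpha0`, `sd_alpha0`, `mean_alpha_m`, `sd_alpha_m`) and
#'   `value`; an empty table yields the single base point.
#' @param kinetics A [tumor_kinetics()].
#' @param b Resensitization rate, day^-2.
#' @return A tibble of class `tcp_sensitivity_grid`: `parameter`, `value`,
#'   `tcp_3f`, `tcp_2f`.
#' @export
sensitivity_grid <- function(base_pop, perturbations = default_perturbations(),
                             kinetics = stock_kinetics(), b = 0.066) {
  allowed <- c("mean_alpha0", "sd_alpha0", "mean_alpha_m", "sd_alpha_m")
  perturbations <- as_tibble(perturbations)
  if (nrow(perturbations) > 0 && !all(perturbations$parameter %in% allowed)) {
    abort(paste("Perturbed parameters are limited to:",
                paste(allowed, collapse = ", ")))
  }
  base_row <- tibble(parameter = "base", value = NA_real_)
  grid <- bind_rows(base_row, perturbations)
  sch <- clinical_schedules()
  rows <- pmap(grid, function(parameter, value) {
    pop <- base_pop
    if (parameter != "base") {
      pop[[parameter]] <- value
      if (parameter == "mean_alpha0") pop$mean_beta0 <- value / 4.5
    }
    tcp3 <- population_tcp(pop, sch[["3F/28d"]], kinetics, b)$population_tcp
    tcp2 <- population_tcp(pop, sch[["2F/14d"]], kinetics, b)$population_tcp
    tibble(parameter = parameter, value = value, tcp_3f = tcp3, tcp_2f = tcp2)
  })
  out <- bind_rows(rows)
  class(out) <- c("tcp_sensitivity_grid", class(out))
  out
}

#' @rdname sensitivity_grid
#' @export
default_perturbations <- function() {
  tibble(
    parameter = rep(c("mean_alpha0", "mean_alpha_m", "sd_alpha0", "sd_alpha_m"),
                    each = 2L),
    value = c(0.12 - 0.02, 0.12 + 0.02,
              0.23 - 0.02, 0.23 + 0.02,
              0.01, 0.03,
              0.01, 0.03)
  )
}
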