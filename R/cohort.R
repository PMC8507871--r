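#' Summarise an observed cohort outcome
#'
#' Failure and control rates (reported to 0.1% precision) with an exact
#' Clopper-Pearson 95% confidence interval on the failure rate.  Biochemical
#' (PSA) failure is equated with loss of local control, so
#' `control_rate = 1 - failure_rate`.
#'
#' @param n_patients Cohort size.
#' @param n_failures Number of failures, `0 <= n_failures <= n_patients`.
#' @return A one-row tibble of class `cohort_outcome`: `n_patients`,
#'   `n_failures`, `failure_rate`, `control_rate`, `ci_low`, `ci_high`
#'   (the CI bounds are on the failure rate).
#' @examples
#' summarize_cohort(107, 5)   # 4.7% failure, 95.3% control
#' summarize_cohort(103, 15)  # 14.6% failure, 85.4% control
#' @export
summarize_cohort <- function(n_patients, n_failures) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(n_failures, "n_failures", lower = 0)
  if (n_failures > n_patients) {
    abort("`n_failures` cannot exceed `n_patients`.")
  }
  ci <- binom.test(n_failures, n_patients)$conf.int
  out <- tibble(
    n_patients = as.integer(n_patients),
    n_failures = as.integer(n_failures),
    failure_rate = round(n_failures / n_patients, 3L),
    control_rate = round(1 - n_failures / n_patients, 3L),
    ci_low = ci[1L],
    ci_high = ci[2L]
  )
  class(out) <- c("cohort_outcome", class(out))
  out
}

#' Generate a synthetic patient cohort with Bernoulli outcomes
#'
#' Emulates the structure of the clinical registry data: `n_patients`
#' individuals are sampled from the population distribution (with the
#' alpha/beta acceptance window), each individual's [zm_tcp()] is computed,
#' and a failure is drawn as Bernoulli(1 - TCP).
#'
#' @param pop A [population_distribution()]; its `n_samples` is overridden by
#'   `n_patients`.
#' @param schedule An [fx_schedule()].
#' @param kinetics A [tumor_kinetics()].
#' @param b Resensitization rate, day^-2.
#' @param n_patients Cohort size (>= 1).
#' @param seed Integer seed; outcomes are reproducible given the seed.
#' @return A list with `outcome` (a [summarize_cohort()] tibble) and
#'   `patients` (tibble: `patient_id`, `alpha0`, `alpha_m`, `beta0`, `tcp`,
#'   `failed`).
#' @export
generate_cohort <- function(pop, schedule, kinetics, b, n_patients, seed) {
  check_number(n_patients, "n_patients", lower = 1)
  pop$n_samples <- as.integer(n_patients)
  pop$seed <- as.integer(seed)
  res <- population_tcp(pop, schedule, kinetics, b)
  failed <- withr::with_seed(seed + 1L, {
    rbinom(n_patients, 1L, 1 - res$individuals$tcp)
  })
  patients <- mutate(
    res$individuals,
    patient_id = dplyr::row_number(), failed = as.logical(failed),
    .before = 1L
  )
  list(
    outcome = summarize_cohort(n_patients, sum(failed)),
    patients = as_tibble(patients)
  )
}

#' Compare a simulated cohort outcome with a clinical one
#'
#' Two-sided exact binomial test of the observed clinical failure count
#' against the simulated failure probability, plus the failure-rate
#' difference (clinical minus simulated).
#'
#' @param simulated A `cohort_outcome` (or any one-row data frame with
#'   `n_patients`/`n_failures`) giving the simulated failure probability.
#' @param clinical A `cohort_outcome` with the observed counts.
#' @return A one-row tibble: `p_value`, `rate_difference`,
#'   `simulated_failure_rate`, `clinical_failure_rate`.
#' @export
compare_to_clinical <- function(simulated, clinical) {
  p_sim <- simulated$n_failures / simulated$n_patients
  p_cli <- clinical$n_failures / clinical$n_patients
  p_value <- if (p_sim <= 0 || p_sim >= 1) {
    # degenerate null: the exact test collapses to a point mass
    if (clinical$n_failures == round(p_sim * clinical$n_patients)) 1 else 0
  } else {
    binom.test(clinical$n_failures, clinical$n_patients, p = p_sim)$p.value
  }
  tibble(
    p_value = p_value,
    rate_difference = p_cli - p_sim,
    simulated_failure_rate = p_sim,
    clinical_failure_rate = p_cli
  )
}
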