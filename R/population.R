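#' Population distribution of radiosensitivity parameters
#'
#' Describes inter-patient variability: `alpha0`, `alpha_m` and `beta0` are
#' drawn independently from normal distributions, draws violating positivity
#' or the ordering `alpha_m >= alpha0` are resampled, and individuals whose
#' time-averaged alpha/beta ratio on the treated schedule falls outside
#' `ab_window` are rejected (and resampled until `n_samples` are accepted).
#' By default the mean of `beta0` is tied to the mean of `alpha0` through the
#' most probable prostate alpha/beta ratio of 4.5 Gy.
#'
#' @param mean_alpha0,sd_alpha0 Mean and SD of the initial linear sensitivity,
#'   Gy^-1.
#' @param mean_alpha_m,sd_alpha_m Mean and SD of the asymptotic linear
#'   sensitivity, Gy^-1.
#' @param mean_beta0,sd_beta0 Mean and SD of the initial quadratic
#'   sensitivity, Gy^-2; `mean_beta0` defaults to `mean_alpha0 / 4.5`.
#' @param ab_window Length-2 acceptance bounds (Gy) on the time-mean
#'   alpha/beta ratio; `c(0, Inf)` disables the filter.
#' @param n_samples Number of accepted individuals per cohort.
#' @param seed Integer seed controlling all sampling.
#' @return A list of class `population_distribution`.
#' @examples
#' population_distribution(seed = 1)
#' @export
population_distribution <- function(mean_alpha0 = 0.12, sd_alpha0 = 0.02,
                                    mean_alpha_m = 0.23, sd_alpha_m = 0.02,
                                    mean_beta0 = mean_alpha0 / 4.5,
                                    sd_beta0 = 0.01,
                                    ab_window = c(3.5, 6),
                                    n_samples = 10000,
                                    seed) {
  check_number(mean_alpha0, "mean_alpha0", lower = 0, allow_equal = FALSE)
  check_number(mean_alpha_m, "mean_alpha_m", lower = 0, allow_equal = FALSE)
  check_number(mean_beta0, "mean_beta0", lower = 0, allow_equal = FALSE)
  check_number(sd_alpha0, "sd_alpha0", lower = 0)
  check_number(sd_alpha_m, "sd_alpha_m", lower = 0)
  check_number(sd_beta0, "sd_beta0", lower = 0)
  check_number(n_samples, "n_samples", lower = 1)
  if (missing(seed)) abort("`seed` is required for reproducible sampling.")
  check_number(seed, "seed")
  if (length(ab_window) != 2L || !is.numeric(ab_window) ||
      ab_window[1L] <= 0 || ab_window[1L] >= ab_window[2L]) {
    abort("`ab_window` must be bounds `c(low, high)` with 0 < low < high.")
  }
  structure(
    list(
      mean_alpha0 = mean_alpha0, sd_alpha0 = sd_alpha0,
      mean_alpha_m = mean_alpha_m, sd_alpha_m = sd_alpha_m,
      mean_beta0 = mean_beta0, sd_beta0 = sd_beta0,
      ab_window = as.numeric(ab_window),
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    class = "population_distribution"
  )
}

#' @export
print.population_distribution <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<population_distribution>\n",
      "  alpha0  ~ N(%g, %g) Gy^-1\n",
      "  alpha_m ~ N(%g, %g) Gy^-1\n",
      "  beta0   ~ N(%g, %g) Gy^-2\n",
      "  alpha/beta window (%g, %g) Gy, n_samples %d, seed %d\n"
    ),
    x$mean_alpha0, x$sd_alpha0, x$mean_alpha_m, x$sd_alpha_m,
    x$mean_beta0, x$sd_beta0, x$ab_window[1L], x$ab_window[2L],
    x$n_samples, x$seed
  ))
  invisible(x)
}

# vectorized time-mean alpha/beta for a draw matrix on one schedule
time_mean_ab_vec <- function(times, alpha0, alpha_m, beta0, b) {
  w <- hypoxic_weight(times, b)
  A <- outer(alpha0, w) + outer(alpha_m, 1 - w)
  rowMeans(alpha0^2 / (beta0 * A))
}

#' Sample an accepted cohort of individual radiosensitivity parameters
#'
#' Draws `(alpha0, alpha_m, beta0)` triples from the population normals,
#' resamples violations of positivity and of `alpha_m >= alpha0`, and rejects
#' individuals whose [time_mean_alpha_beta()] on `schedule` lies outside the
#' population's `ab_window`, until `n_samples` individuals are accepted.
#' Deterministic for a fixed `pop$seed`.
#'
#' @param pop A [population_distribution()].
#' @param schedule The [fx_schedule()] on which the alpha/beta window is
#'   evaluated.
#' @param b Resensitization rate, day^-2.
#' @param tie_alpha_m If `TRUE`, `alpha_m` is set equal to each individual's
#'   `alpha0` instead of being drawn (frozen-sensitivity scenarios with
#'   `b = 0`).
#' @return A tibble with columns `alpha0`, `alpha_m`, `beta0`,
#'   `time_mean_ab`, and attributes `n_rejected` (window rejections) and
#'   `acceptance_rate`.
#' @export
sample_individuals <- function(pop, schedule, b, tie_alpha_m = FALSE) {
  schedule <- as_fx_schedule(schedule)
  check_number(b, "b", lower = 0)
  n <- pop$n_samples
  withr::with_seed(pop$seed, {
    kept <- list()
    n_acc <- 0L
    n_window_rejected <- 0L
    n_proposed <- 0L
    while (n_acc < n) {
      m <- max(1000L, 4L * (n - n_acc))
      alpha0 <- rnorm(m, pop$mean_alpha0, pop$sd_alpha0)
      alpha_m <- if (tie_alpha_m) alpha0 else rnorm(m, pop$mean_alpha_m, pop$sd_alpha_m)
      beta0 <- rnorm(m, pop$mean_beta0, pop$sd_beta0)
      # positivity/ordering violations are resampled, not clipped, so the
      # accepted distributions stay near-normal
      valid <- alpha0 > 0 & beta0 > 0 & alpha_m >= alpha0
      alpha0 <- alpha0[valid]; alpha_m <- alpha_m[valid]; beta0 <- beta0[valid]
      tm <- time_mean_ab_vec(schedule$time_days, alpha0, alpha_m, beta0, b)
      inside <- tm > pop$ab_window[1L] & tm < pop$ab_window[2L]
      n_window_rejected <- n_window_rejected + sum(!inside)
      n_proposed <- n_proposed + length(alpha0)
      kept[[length(kept) + 1L]] <- tibble(
        alpha0 = alpha0[inside], alpha_m = alpha_m[inside],
        beta0 = beta0[inside], time_mean_ab = tm[inside]
      )
      n_acc <- n_acc + sum(inside)
      if (n_proposed >= 1e4 && n_acc / n_proposed < 1e-3) {
        abort(paste0(
          "alpha/beta window acceptance rate below 1e-3: the window (",
          pop$ab_window[1L], ", ", pop$ab_window[2L],
          ") Gy is incompatible with the population distribution."
        ))
      }
    }
  })
  out <- dplyr::slice_head(bind_rows(kept), n = n)
  attr(out, "n_rejected") <- n_window_rejected
  attr(out, "acceptance_rate") <- n_acc / n_proposed
  out
}

#' Population tumor control probability
#'
#' Samples a cohort with [sample_individuals()], computes each individual's
#' [zm_tcp()], and summarises the cohort: the population TCP is the mean
#' individual TCP, which is also the expected cure fraction of the cohort.
#'
#' @inheritParams sample_individuals
#' @param kinetics A [tumor_kinetics()]; `n0` and `lambda` are common to all
#'   individuals.
#' @param individuals Optional pre-sampled cohort (a tibble from
#'   [sample_individuals()]); when supplied the sampling step is skipped so
#'   that scenario contrasts can share one cohort (common random numbers).
#' @return An object of class `population_tcp`: a list with the individuals
#'   tibble (including a `tcp` column), `population_tcp`, its Monte-Carlo
#'   standard error `se`, rejection diagnostics, and the inputs.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' pop <- population_distribution(n_samples = 500, seed = 42)
#' res <- population_tcp(pop, fx_schedule(c(0, 14), 14),
#'                       tumor_kinetics(1e8, 0.02), b = 0.066)
#' glance(res)
#' @export
population_tcp <- function(pop, schedule, kinetics, b, individuals = NULL) {
  schedule <- as_fx_schedule(schedule)
  if (is.null(individuals)) {
    individuals <- sample_individuals(pop, schedule, b)
  }
  n_rejected <- attr(individuals, "n_rejected") %||% NA_integer_
  acceptance_rate <- attr(individuals, "acceptance_rate") %||% NA_real_
  tcp <- zm_tcp_vec(
    schedule$time_days, schedule$dose_gy,
    individuals$alpha0, individuals$alpha_m, individuals$beta0, b,
    kinetics$n0, kinetics$lambda
  )
  individuals <- mutate(individuals, tcp = tcp)
  structure(
    list(
      individuals = individuals,
      population_tcp = mean(tcp),
      se = stats::sd(tcp) / sqrt(length(tcp)),
      n_rejected = n_rejected,
      acceptance_rate = acceptance_rate,
      schedule = schedule, b = b, pop = pop, kinetics = kinetics
    ),
    class = "population_tcp"
  )
}

#' @export
print.population_tcp <- function(x, ...) {
  cat(sprintf(
    "<population_tcp> %d fractions, b = %g day^-2: TCP = %.1f%% (se %.2f pp, n = %d)\n",
    n_fractions(x$schedule), x$b, 100 * x$population_tcp, 100 * x$se,
    nrow(x$individuals)
  ))
  invisible(x)
}

#' @rdname population_tcp
#' @param x A `population_tcp` object.
#' @param ... Unused.
#' @method tidy population_tcp
#' @export
tidy.population_tcp <- function(x, ...) as_tibble(x$individuals)

#' @rdname population_tcp
#' @method glance population_tcp
#' @export
glance.population_tcp <- function(x, ...) {
  tibble(
    population_tcp = x$population_tcp,
    se = x$se,
    n_samples = nrow(x$individuals),
    n_rejected = x$n_rejected,
    acceptance_rate = x$acceptance_rate,
    frac_tcp_below_0.05 = mean(x$individuals$tcp < 0.05),
    n_fractions = n_fractions(x$schedule),
    total_dose_gy = sum(x$schedule$dose_gy),
    treatment_days = max(x$schedule$time_days),
    b = x$b
  )
}

#' Histogram of the individual TCP distribution
#'
#' Bins the individual TCPs of a [population_tcp()] result over `[0, 1]`.
#' Also reports, as an attribute, the fraction of individuals with TCP below
#' 0.05 — the dichotomy diagnostic: a high population TCP can coexist with a
#' subgroup whose control probability is close to zero.
#'
#' @param result A `population_tcp` object.
#' @param n_bins Number of equal-width bins (>= 1).
#' @return A tibble with columns `bin_low`, `bin_high`, `count` and
#'   attribute `frac_below_0.05`; counts sum to the number of individuals.
#' @export
tcp_histogram <- function(result, n_bins = 50) {
  if (!inherits(result, "population_tcp") || nrow(result$individuals) == 0L) {
    abort("`result` must be a non-empty `population_tcp` object.")
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    abort("`n_bins` must be a positive count.")
  }
  n_bins <- as.integer(n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(findInterval(result$individuals$tcp, edges,
                           rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble(
    bin_low = edges[-(n_bins + 1L)], bin_high = edges[-1L], count = counts
  )
  attr(out, "frac_below_0.05") <- mean(result$individuals$tcp < 0.05)
  out
}
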