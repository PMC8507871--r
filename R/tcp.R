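#' Tumor kinetic parameters
#'
#' @param n0 Initial clonogen number (>= 1).  Fixed across individuals in the
#'   population analyses.
#' @param lambda Clonogen birth (repopulation) rate in day^-1 (>= 0); 0.02
#'   day^-1 corresponds to a slowly repopulating tumor such as prostate
#'   carcinoma.
#' @return A list of class `tumor_kinetics`.
#' @examples
#' tumor_kinetics(n0 = 1e8, lambda = 0.02)
#' @export
tumor_kinetics <- function(n0, lambda) {
  check_number(n0, "n0", lower = 1)
  check_number(lambda, "lambda", lower = 0)
  structure(list(n0 = n0, lambda = lambda), class = "tumor_kinetics")
}

#' @export
print.tumor_kinetics <- function(x, ...) {
  cat(sprintf("<tumor_kinetics> n0 = %g cells, lambda = %g day^-1\n",
              x$n0, x$lambda))
  invisible(x)
}

# Core Zaider-Minerbo evaluation, vectorized over individuals.
#
# Arguments are equal-length vectors of individual parameters; `times`/`doses`
# describe one schedule.  Everything is carried on the log scale: the
# single-cell failure probability is
#   z = S(T_n) e^{lambda T_n} / (1 + S(T_n) e^{lambda T_n} * SUM)
# with SUM = sum_k S^{-1}(T_{k-1}) (e^{-lambda T_{k-1}} - e^{-lambda T_k})
# over the n-1 inter-fraction intervals (empty for a single fraction), and
# TCP = exp(N0 * log1p(-z)).
zm_tcp_vec <- function(times, doses, alpha0, alpha_m, beta0, b, n0, lambda) {
  nf <- length(times)
  w <- hypoxic_weight(times, b)                       # length nf
  # individuals x fractions matrices
  A <- outer(alpha0, w) + outer(alpha_m, 1 - w)       # alpha(T_i)
  B <- (A / alpha0)^2 * beta0                          # beta(T_i), OER tie
  kill <- A * rep(doses, each = length(alpha0)) +
    B * rep(doses^2, each = length(alpha0))
  ls <- t(apply(-kill, 1L, cumsum))                   # log S after k fractions
  if (nf == 1L) ls <- matrix(ls, ncol = 1L)
  t_end <- times[nf]
  log_se <- ls[, nf] + lambda * t_end                 # log(S e^{lambda T})
  if (nf > 1L && lambda > 0) {
    k <- seq_len(nf - 1L)
    # log(e^{-lambda T_{k-1}} - e^{-lambda T_k}), all summands >= 0
    log_int <- -lambda * times[k] + log1p(-exp(-lambda * diff(times)))
    # log-sum-exp across intervals of  -ls[,k] + log_int
    lt <- sweep(-ls[, k, drop = FALSE], 2L, log_int, "+")
    m <- apply(lt, 1L, max)
    log_sum <- m + log(rowSums(exp(lt - m)))
    log_x <- log_se + log_sum                         # x = S e^{lambda T} SUM
    log_denom <- ifelse(log_x > 33, log_x, log1p(exp(log_x)))
  } else {
    log_denom <- 0
  }
  z <- exp(pmin(log_se - log_denom, 0))
  z <- pmin(pmax(z, 0), 1)
  exp(n0 * log1p(-z))
}

#' Individual tumor control probability (Zaider-Minerbo, fractionated)
#'
#' Extinction probability of the clonogen birth-death process at the end of a
#' fractionated treatment: cells proliferate at rate `lambda` between
#' fractions and are killed at fraction times according to the time-dependent
#' LQ survival of [cumulative_log_survival()].  For `lambda = 0` the formula
#' reduces to the Poisson-type closed form \eqn{(1 - S)^{N_0}}.
#'
#' @param schedule An [fx_schedule()].
#' @param params A [resens_params()].
#' @param kinetics A [tumor_kinetics()].
#' @return A probability in `[0, 1]`.
#' @examples
#' sched <- fx_schedule(c(0, 14), 14)
#' pars <- resens_params(0.12, 0.23, 0.12 / 4.5, 0.066)
#' zm_tcp(sched, pars, tumor_kinetics(1e8, 0.02))
#' @export
zm_tcp <- function(schedule, params, kinetics) {
  schedule <- as_fx_schedule(schedule)
  zm_tcp_vec(
    schedule$time_days, schedule$dose_gy,
    params$alpha0, params$alpha_m, params$beta0, params$b,
    kinetics$n0, kinetics$lambda
  )
}

#' Stochastic birth-death extinction frequency (simulation oracle)
#'
#' Exact stochastic simulation of the branching process underlying
#' [zm_tcp()], used as an independent cross-check: between fractions every
#' cell divides at rate `lambda` (a Yule pure-birth process, whose increment
#' over an interval has an exact negative-binomial law), and at each fraction
#' every living cell independently survives with that fraction's per-fraction
#' survival probability.  The returned frequency of all-cells-dead replicates
#' estimates the TCP at the end of treatment.
#'
#' @inheritParams zm_tcp
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; the result is reproducible for a fixed seed.
#' @return A one-row tibble with columns `extinct`, `reps`, `frequency` and
#'   the binomial standard error `se`.
#' @export
simulate_extinction <- function(schedule, params, kinetics, reps, seed) {
  schedule <- as_fx_schedule(schedule)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    abort("`reps` must be a positive count.")
  }
  if (kinetics$n0 > 1e3) {
    abort("`n0` too large to simulate cell-by-cell; use n0 <= 1000.")
  }
  reps <- as.integer(reps)
  kills <- fraction_log_kill(schedule, params)
  surv <- exp(-kills)                                  # per-fraction survival
  gaps <- diff(schedule$time_days)
  withr::with_seed(seed, {
    n_cells <- rep.int(as.integer(kinetics$n0), reps)
    for (i in seq_len(n_fractions(schedule))) {
      if (i > 1L && kinetics$lambda > 0) {
        alive <- n_cells > 0L
        # Yule growth: N(t + dt) = N + NegBin(N, e^{-lambda dt})
        n_cells[alive] <- n_cells[alive] +
          rnbinom(sum(alive), size = n_cells[alive],
                  prob = exp(-kinetics$lambda * gaps[i - 1L]))
      }
      alive <- n_cells > 0L
      n_cells[alive] <- rbinom(sum(alive), n_cells[alive], surv[i])
    }
    extinct <- sum(n_cells == 0L)
  })
  freq <- extinct / reps
  tibble(
    extinct = extinct, reps = reps, frequency = freq,
    se = sqrt(freq * (1 - freq) / reps)
  )
}
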