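#' Calibration targets: clinical control rates to reproduce
#'
#' @param tcp_2f_target,tcp_3f_target Target population TCPs in (0, 1); the
#'   defaults are the observed biochemical control rates of the two clinical
#'   cohorts (85.4% for 2 x 14 Gy / 14 d, 95.3% for 3 x 11 Gy / 28 d).
#' @param tolerance Acceptance tolerance on the worse of the two absolute
#'   TCP errors.
#' @return A list of class `calibration_targets`.
#' @export
calibration_targets <- function(tcp_2f_target = 0.854, tcp_3f_target = 0.953,
                                tolerance = 0.02) {
  for (nm in c("tcp_2f_target", "tcp_3f_target")) {
    v <- get(nm)
    check_number(v, nm, lower = 0, allow_equal = FALSE)
    if (v >= 1) abort(sprintf("`%s` must be in (0, 1).", nm))
  }
  check_number(tolerance, "tolerance", lower = 0, allow_equal = FALSE)
  structure(
    list(tcp_2f_target = tcp_2f_target, tcp_3f_target = tcp_3f_target,
         tolerance = tolerance),
    class = "calibration_targets"
  )
}

#' Search space for the population-parameter random search
#'
#' Uniform ranges for the five searched quantities.  `mean_beta0` is never
#' searched: it is always derived as `mean_alpha0 / 4.5`.  Kinetics, the
#' resensitization rate and the alpha/beta window are held fixed.
#'
#' @param mean_alpha0,sd_alpha0,mean_alpha_m,sd_alpha_m,sd_beta0 Length-2
#'   `c(low, high)` ranges.  Defaults bracket the calibrated point
#'   generously while staying radiobiologically plausible.
#' @param kinetics Fixed [tumor_kinetics()].
#' @param b Fixed resensitization rate, day^-2.
#' @param ab_window Fixed alpha/beta acceptance window, Gy.
#' @return A list of class `search_space`.
#' @export
search_space <- function(mean_alpha0 = c(0.05, 0.3), sd_alpha0 = c(0, 0.05),
                         mean_alpha_m = c(0.1, 0.5), sd_alpha_m = c(0, 0.05),
                         sd_beta0 = c(0, 0.03),
                         kinetics = stock_kinetics(), b = 0.066,
                         ab_window = c(3.5, 6)) {
  ranges <- list(
    mean_alpha0 = mean_alpha0, sd_alpha0 = sd_alpha0,
    mean_alpha_m = mean_alpha_m, sd_alpha_m = sd_alpha_m,
    sd_beta0 = sd_beta0
  )
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[1L] > r[2L]) {
      abort(sprintf("`%s` must be a range c(low, high) with low <= high.", nm))
    }
  }
  structure(
    c(ranges, list(kinetics = kinetics, b = b, ab_window = ab_window)),
    class = "search_space"
  )
}

# evaluate one candidate: paired population TCPs on the two clinical
# schedules and the max-abs-error score against the targets
score_candidate <- function(pop, targets, kinetics, b) {
  sch <- clinical_schedules()
  tcp2 <- population_tcp(pop, sch[["2F/14d"]], kinetics, b)$population_tcp
  tcp3 <- population_tcp(pop, sch[["3F/28d"]], kinetics, b)$population_tcp
  list(
    tcp_2f = tcp2, tcp_3f = tcp3,
    score = max(abs(tcp2 - targets$tcp_2f_target),
                abs(tcp3 - targets$tcp_3f_target))
  )
}

#' Random search for population parameters matching clinical control rates
#'
#' Uniformly samples candidate population distributions from `space`, scores
#' each by the worse of the two absolute errors between its simulated
#' population TCPs (both clinical schedules) and the targets, and returns the
#' best candidate.  All candidates share one sampling seed (common random
#' numbers), so the objective surface is deterministic given `seed`.
#' Candidates are scored with a reduced cohort (`n_inner`) for speed and the
#' best is re-scored at `n_final`.
#'
#' @param space A [search_space()].
#' @param targets A [calibration_targets()].
#' @param budget Number of candidate evaluations (>= 1).
#' @param seed Integer seed for both the candidate draws and the cohorts.
#' @param n_inner Cohort size during the search.
#' @param n_final Cohort size for re-scoring the best candidate.
#' @return A list of class `tcp_calibration`: `best` (the winning
#'   [population_distribution()]), `accepted` (did its final score meet the
#'   tolerance), `score`, `tcp_2f`, `tcp_3f`, and `trace` (one row per
#'   evaluation).  Supports [tidy()] (the trace) and [glance()].
#' @export
random_search <- function(space, targets, budget = 500, seed,
                          n_inner = 2000, n_final = 10000) {
  if (!is.numeric(budget) || length(budget) != 1L || budget < 1) {
    abort("`budget` must be >= 1 evaluation.")
  }
  if (missing(seed)) abort("`seed` is required.")
  budget <- as.integer(budget)
  draw <- function(range, u) range[1L] + u * (range[2L] - range[1L])
  u <- withr::with_seed(seed, matrix(runif(budget * 5L), budget, 5L))
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    cand <- list(
      mean_alpha0 = draw(space$mean_alpha0, u[i, 1L]),
      sd_alpha0 = draw(space$sd_alpha0, u[i, 2L]),
      mean_alpha_m = draw(space$mean_alpha_m, u[i, 3L]),
      sd_alpha_m = draw(space$sd_alpha_m, u[i, 4L]),
      sd_beta0 = draw(space$sd_beta0, u[i, 5L])
    )
    # resensitization means non-decreasing sensitivity; an inverted candidate
    # mean ordering would be resampled away almost surely, so skip it cheaply
    if (cand$mean_alpha_m < cand$mean_alpha0) {
      rows[[i]] <- tibble(
        eval = i, !!!cand, tcp_2f = NA_real_, tcp_3f = NA_real_,
        score = Inf
      )
      next
    }
    pop <- population_distribution(
      mean_alpha0 = cand$mean_alpha0, sd_alpha0 = cand$sd_alpha0,
      mean_alpha_m = cand$mean_alpha_m, sd_alpha_m = cand$sd_alpha_m,
      mean_beta0 = cand$mean_alpha0 / 4.5, sd_beta0 = cand$sd_beta0,
      ab_window = space$ab_window, n_samples = n_inner, seed = seed
    )
    sc <- tryCatch(
      score_candidate(pop, targets, space$kinetics, space$b),
      error = function(e) list(tcp_2f = NA_real_, tcp_3f = NA_real_,
                               score = Inf)
    )
    rows[[i]] <- tibble(
      eval = i, !!!cand,
      tcp_2f = sc$tcp_2f, tcp_3f = sc$tcp_3f, score = sc$score
    )
  }
  trace <- bind_rows(rows)
  best_i <- which.min(trace$score)
  if (!is.finite(trace$score[best_i])) {
    abort("No candidate in the search space could be evaluated.")
  }
  best_pop <- population_distribution(
    mean_alpha0 = trace$mean_alpha0[best_i],
    sd_alpha0 = trace$sd_alpha0[best_i],
    mean_alpha_m = trace$mean_alpha_m[best_i],
    sd_alpha_m = trace$sd_alpha_m[best_i],
    mean_beta0 = trace$mean_alpha0[best_i] / 4.5,
    sd_beta0 = trace$sd_beta0[best_i],
    ab_window = space$ab_window, n_samples = n_final, seed = seed
  )
  final <- score_candidate(best_pop, targets, space$kinetics, space$b)
  structure(
    list(
      best = best_pop, accepted = final$score <= targets$tolerance,
      score = final$score, tcp_2f = final$tcp_2f, tcp_3f = final$tcp_3f,
      trace = trace, targets = targets
    ),
    class = "tcp_calibration"
  )
}

#' @export
print.tcp_calibration <- function(x, ...) {
  cat(sprintf(
    "<tcp_calibration> %d evaluations, %s (score %.4f): TCP_2F %.1f%%, TCP_3F %.1f%%\n",
    nrow(x$trace), if (x$accepted) "accepted" else "best-so-far",
    x$score, 100 * x$tcp_2f, 100 * x$tcp_3f
  ))
  invisible(x)
}

#' @rdname random_search
#' @param x A `tcp_calibration` object.
#' @param ... Unused.
#' @method tidy tcp_calibration
#' @export
tidy.tcp_calibration <- function(x, ...) x$trace

#' @rdname random_search
#' @method glance tcp_calibration
#' @export
glance.tcp_calibration <- function(x, ...) {
  tibble(
    accepted = x$accepted, score = x$score,
    tcp_2f = x$tcp_2f, tcp_3f = x$tcp_3f,
    n_evals = nrow(x$trace),
    mean_alpha0 = x$best$mean_alpha0, sd_alpha0 = x$best$sd_alpha0,
    mean_alpha_m = x$best$mean_alpha_m, sd_alpha_m = x$best$sd_alpha_m,
    sd_beta0 = x$best$sd_beta0
  )
}

#' One-dimensional profile of the calibration objective
#'
#' Evaluates the calibration score along a grid of one searchable parameter,
#' all other parameters held at the calibrated point.  Documents which
#' directions of the parameter space are flat (poorly identified) and which
#' are steep.
#'
#' @param axis One of `mean_alpha0`, `sd_alpha0`, `mean_alpha_m`,
#'   `sd_alpha_m`, `sd_beta0`.
#' @param grid Numeric vector of values for `axis`.
#' @param targets A [calibration_targets()].
#' @param base_pop The [population_distribution()] providing the fixed
#'   parameters.
#' @param kinetics A [tumor_kinetics()].
#' @param b Resensitization rate, day^-2.
#' @return A tibble: `parameter`, `value`, `tcp_2f`, `tcp_3f`, `objective`.
#' @export
profile_objective <- function(axis, grid, targets = calibration_targets(),
                              base_pop, kinetics = stock_kinetics(),
                              b = 0.066) {
  allowed <- c("mean_alpha0", "sd_alpha0", "mean_alpha_m", "sd_alpha_m",
               "sd_beta0")
  if (!axis %in% allowed) {
    abort(paste("`axis` must be one of:", paste(allowed, collapse = ", ")))
  }
  rows <- map(grid, function(v) {
    pop <- base_pop
    pop[[axis]] <- v
    if (axis == "mean_alpha0") pop$mean_beta0 <- v / 4.5
    sc <- score_candidate(pop, targets, kinetics, b)
    tibble(parameter = axis, value = v,
           tcp_2f = sc$tcp_2f, tcp_3f = sc$tcp_3f, objective = sc$score)
  })
  bind_rows(rows)
}
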