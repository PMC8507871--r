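# shared fixtures: the calibrated study configuration at reduced cohort sizes
stock_params <- function() resens_params(0.12, 0.23, 0.12 / 4.5, 0.066)

sched_2f <- function() fx_schedule(c(0, 14), 14)
sched_3f <- function() fx_schedule(c(0, 14, 28), 11)

small_pop <- function(n = 2000, seed = 1, ...) {
  population_distribution(n_samples = n, seed = seed, ...)
}

# draw a random valid parameter set for property-style tests
random_params <- function() {
  alpha0 <- runif(1, 0.05, 0.3)
  resens_params(
    alpha0 = alpha0,
    alpha_m = alpha0 + runif(1, 0, 0.3),
    beta0 = runif(1, 0.01, 0.1),
    b = runif(1, 0, 1.5)
  )
}

random_schedule <- function(max_fractions = 5) {
  nf <- sample(max_fractions, 1)
  times <- c(0, sort(sample(1:40, nf - 1)))
  fx_schedule(times, runif(nf, 0.5, 8))
}
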