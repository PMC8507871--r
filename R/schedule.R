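#' Fractionation schedule
#'
#' A fractionation schedule is the ordered set of fraction delivery times and
#' the physical dose given at each fraction.  Times are measured in days from
#' the first fraction, so the first fraction is always at day 0 and the last
#' time equals the overall treatment time.
#'
#' @param time_days Numeric vector of fraction times in days, strictly
#'   increasing, starting at 0.
#' @param dose_gy Numeric vector of doses per fraction in Gy, all positive.
#'   A single value is recycled to every fraction.
#'
#' @return A tibble of class `fx_schedule` with columns `time_days` and
#'   `dose_gy`, one row per fraction.
#'
#' @examples
#' # the two clinical regimens: 2 x 14 Gy over two weeks, 3 x 11 Gy over four
#' fx_schedule(c(0, 14), 14)
#' fx_schedule(c(0, 14, 28), 11)
#' @export
fx_schedule <- function(time_days, dose_gy) {
  if (!is.numeric(time_days) || length(time_days) < 1L || anyNA(time_days)) {
    abort("`time_days` must be a non-empty numeric vector.")
  }
  if (length(dose_gy) == 1L) dose_gy <- rep(dose_gy, length(time_days))
  if (!is.numeric(dose_gy) || length(dose_gy) != length(time_days) ||
      anyNA(dose_gy)) {
    abort("`dose_gy` must match `time_days` in length (or be a single value).")
  }
  if (time_days[1L] != 0) {
    abort("The first fraction must be at `time_days = 0`.")
  }
  if (length(time_days) > 1L && any(diff(time_days) <= 0)) {
    abort("`time_days` must be strictly increasing.")
  }
  if (any(dose_gy <= 0)) {
    abort("All doses must be positive.")
  }
  new_tibble(
    list(time_days = as.numeric(time_days), dose_gy = as.numeric(dose_gy)),
    nrow = length(time_days),
    class = "fx_schedule"
  )
}

as_fx_schedule <- function(x) {
  if (inherits(x, "fx_schedule")) return(x)
  if (is.data.frame(x) && all(c("time_days", "dose_gy") %in% names(x))) {
    return(fx_schedule(x$time_days, x$dose_gy))
  }
  abort("Expected an `fx_schedule` (see `fx_schedule()`).")
}

n_fractions <- function(schedule) nrow(schedule)

#' Replace every dose of a schedule with a common dose per fraction
#'
#' Used by dose sweeps: the fraction times of `schedule` are kept and the dose
#' column is replaced by a single equal dose per fraction.
#'
#' @param schedule An [fx_schedule()].
#' @param dose_gy Single dose per fraction in Gy.
#' @return An [fx_schedule()].
#' @export
with_dose <- function(schedule, dose_gy) {
  schedule <- as_fx_schedule(schedule)
  check_number(dose_gy, "dose_gy", lower = 0, allow_equal = FALSE)
  fx_schedule(schedule$time_days, dose_gy)
}

#' Read or write a schedule as a small JSON/YAML record
#'
#' Schedules are serialized as `{times_days: [...], doses_gy: [...]}`.  The
#' format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_schedule()` returns an [fx_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  rec <- read_record(path)
  if (!all(c("times_days", "doses_gy") %in% names(rec))) {
    abort("Schedule record must have fields `times_days` and `doses_gy`.")
  }
  fx_schedule(unlist(rec$times_days), unlist(rec$doses_gy))
}

#' @param schedule An [fx_schedule()].
#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  schedule <- as_fx_schedule(schedule)
  write_record(
    list(times_days = schedule$time_days, doses_gy = schedule$dose_gy),
    path
  )
}

read_record <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_record <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
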