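#' Age-indexed schedule of annual probabilities or costs
#'
#' The basic container for every age-varying model input: one value per
#' integer age over at least 45..100. Probability-role schedules must lie in
#' \[0, 1\]; cost-role schedules must be non-negative.
#'
#' @param ages Integer vector of ages (must cover 45..100 without gaps).
#' @param values Numeric vector, one value per age.
#' @param role One of `"probability"` or `"cost"`.
#' @param name Optional label describing what the schedule measures.
#'
#' @return A data frame with columns `age` and `value`, class `age_schedule`,
#'   carrying `role` and `name` attributes.
#' @export
#' @examples
#' age_schedule(45:100, rep(0.01, 56), role = "probability")
age_schedule <- function(ages, values, role = c("probability", "cost"),
                         name = NULL) {
  role <- match.arg(role)
  ages <- as.integer(ages)
  if (anyNA(ages) || anyNA(values)) {
    stop("age_schedule: ages and values must not contain NA")
  }
  if (length(ages) != length(values)) {
    stop("age_schedule: ages and values must have equal length")
  }
  if (anyDuplicated(ages)) {
    stop("age_schedule: duplicated ages")
  }
  required <- 45:100
  if (!all(required %in% ages)) {
    stop("age_schedule: ages must cover 45..100 inclusive")
  }
  if (role == "probability" && (any(values < 0) || any(values > 1))) {
    stop("age_schedule: probability values must lie in [0, 1]")
  }
  if (role == "cost" && any(values < 0)) {
    stop("age_schedule: cost values must be non-negative")
  }
  ord <- order(ages)
  out <- data.frame(age = ages[ord], value = values[ord])
  class(out) <- c("age_schedule", "data.frame")
  attr(out, "role") <- role
  attr(out, "name") <- name %||% "unnamed"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Look up schedule values at given ages
#'
#' @param schedule An [age_schedule()].
#' @param ages Integer ages; ages beyond the tabulated range take the
#'   boundary value.
#' @return Numeric vector of values.
#' @export
schedule_at <- function(schedule, ages) {
  stopifnot(inherits(schedule, "age_schedule"))
  ages <- pmin(pmax(as.integer(ages), min(schedule$age)), max(schedule$age))
  schedule$value[match(ages, schedule$age)]
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule> %s (%s), ages %d..%d\n",
              attr(x, "name"), attr(x, "role"), min(x$age), max(x$age)))
  cat(sprintf("  value range: %.6g .. %.6g\n", min(x$value), max(x$value)))
  invisible(x)
}

# Constant-by-age-band schedule helper: breaks are lower bounds of bands.
banded_schedule <- function(breaks, band_values, role, name,
                            ages = 45:100) {
  idx <- findInterval(ages, breaks)
  age_schedule(ages, band_values[pmax(idx, 1L)], role = role, name = name)
}
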