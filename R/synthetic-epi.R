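#' Synthetic life table: Gompertz-Makeham other-cause mortality
#'
#' Emulates a CDC-style period life table with a Gompertz-Makeham hazard
#' \eqn{h(a) = \lambda + \alpha e^{\beta a}}: `makeham` is the age-independent
#' background hazard \eqn{\lambda}, `gompertz_coef` the senescent scale
#' \eqn{\alpha} and `gompertz_rate` the log-slope \eqn{\beta} per year of age.
#' The annual death probability is \eqn{1 - e^{-h(a)}}.
#'
#' Defaults are tuned so that truncated life expectancy at 45 (everyone dead
#' by 100) is about 36 years, the right magnitude for a US cohort.
#'
#' @param shape_params List with elements `makeham`, `gompertz_coef`,
#'   `gompertz_rate` (all per-year hazards / rates).
#' @param age_range Integer ages; must cover 45..100.
#' @return An [age_schedule()] of annual other-cause death probabilities,
#'   non-decreasing in age, each strictly inside (0, 1).
#' @export
generate_life_table <- function(shape_params = list(), age_range = 45:100) {
  p <- modifyList(list(makeham = 5e-4, gompertz_coef = 3.4e-5,
                       gompertz_rate = 0.092), shape_params)
  if (!all(45:100 %in% age_range)) {
    stop("generate_life_table: age_range must cover 45..100")
  }
  if (p$makeham < 0 || p$gompertz_coef < 0 || p$gompertz_rate < 0) {
    stop("generate_life_table: hazard parameters must be non-negative")
  }
  hazard <- p$makeham + p$gompertz_coef * exp(p$gompertz_rate * age_range)
  q <- 1 - exp(-hazard)
  if (any(q <= 0) || any(q >= 1)) {
    stop("generate_life_table: hazard produces probabilities outside (0, 1)")
  }
  if (is.unsorted(q)) {
    stop("generate_life_table: death probability must be non-decreasing in age")
  }
  age_schedule(age_range, q, role = "probability", name = "all_cause_mortality")
}

#' Truncated life expectancy implied by a mortality schedule
#'
#' Expected years lived from `from_age` up to (not beyond) `to_age`, with one
#' full year credited per year started alive. Used to sanity-check the
#' synthetic life table against the unscreened cohort's life-year total.
#'
#' @param mortality An [age_schedule()] of annual death probabilities.
#' @param from_age,to_age Integer age limits.
#' @return Expected years (scalar).
#' @export
life_expectancy <- function(mortality, from_age = 45, to_age = 100) {
  q <- schedule_at(mortality, from_age:(to_age - 1))
  surv <- cumprod(1 - q)
  # alive at start of each year: 1, S(1), ..., S(n-1)
  sum(c(1, surv[-length(surv)]))
}

#' Synthetic baseline colorectal cancer incidence
#'
#' Annual probability of clinical CRC onset in an unscreened population,
#' log-linear in age and constant after `plateau_age` -- the shape of
#' pre-screening-era registry incidence. Defaults rise from about 2.3e-4 at
#' 45 to about 5e-3 at the plateau, giving a lifetime risk near 5.2% under
#' competing life-table mortality.
#'
#' @param shape_params List with `rate_at_45` (annual probability at age 45),
#'   `log_slope` (per year of age) and `plateau_age`.
#' @return An [age_schedule()], monotone non-decreasing over 45..plateau.
#' @export
generate_crc_incidence <- function(shape_params = list()) {
  p <- modifyList(list(rate_at_45 = 2.25e-4, log_slope = 0.078,
                       plateau_age = 85), shape_params)
  ages <- 45:100
  i <- p$rate_at_45 * exp(p$log_slope * (pmin(ages, p$plateau_age) - 45))
  if (any(i < 0) || any(i > 0.05)) {
    stop("generate_crc_incidence: annual probabilities must lie in [0, 0.05]")
  }
  age_schedule(ages, i, role = "probability", name = "crc_incidence_baseline")
}

#' Cumulative incidence of a schedule under competing mortality
#'
#' Direct product-limit evaluation: applies the incidence schedule to a
#' cohort alive per the life table, with onset and death competing
#' (death applied first within a year, matching the model's cycle order).
#' This is the generator-level check that the incidence curve carries a
#' realistic lifetime risk; the full model recomputes incidence through the
#' polyp pathway.
#'
#' @param incidence,mortality [age_schedule()]s of annual probabilities.
#' @param from_age,to_age Age limits.
#' @return Scalar cumulative incidence (fraction of the starting cohort).
#' @export
cumulative_incidence <- function(incidence, mortality,
                                 from_age = 45, to_age = 100) {
  ages <- from_age:(to_age - 1)
  i <- schedule_at(incidence, ages)
  m <- schedule_at(mortality, ages)
  at_risk <- 1
  cum <- 0
  for (k in seq_along(ages)) {
    new_cases <- at_risk * (1 - m[k]) * i[k]
    cum <- cum + new_cases
    at_risk <- at_risk * (1 - m[k]) * (1 - i[k])
  }
  cum
}

#' Synthetic polyp onset schedule and prevalence calibration targets
#'
#' Emulates registry-style (CORI-like) adenoma prevalence that rises with
#' age. Returns (a) a low-risk polyp onset schedule, logistic in age, that
#' the natural-history calibration scales, and (b) the low-risk and
#' high-risk prevalence target curves the calibration aims at. High-risk
#' polyps are the rarer subset, so the HR target lies below the LR target at
#' every age.
#'
#' @param shape_params List with `onset_low`, `onset_high` (annual onset
#'   probability floor/ceiling), `onset_midage`, `onset_width` (logistic
#'   location/scale in years), `lr_prev_max` (low-risk prevalence plateau,
#'   reached by 75), `hr_prev_65` (high-risk prevalence at 65) and
#'   `hr_prev_cap` (ceiling of the high-risk curve).
#' @return List with `lr_onset`, `lr_prev_target`, `hr_prev_target`, all
#'   [age_schedule()]s.
#' @export
generate_polyp_schedules <- function(shape_params = list()) {
  p <- modifyList(list(onset_low = 0.012, onset_high = 0.030,
                       onset_midage = 60, onset_width = 8,
                       lr_prev_max = 0.36, hr_prev_65 = 0.06,
                       hr_prev_cap = 0.30), shape_params)
  ages <- 45:100
  logistic <- function(lo, hi, mid, width) {
    lo + (hi - lo) / (1 + exp(-(ages - mid) / width))
  }
  if (p$lr_prev_max < 0 || p$lr_prev_max >= 1 || p$hr_prev_65 < 0 ||
      p$hr_prev_cap < 0 || p$hr_prev_cap >= 1 || p$hr_prev_65 >= 1) {
    stop("generate_polyp_schedules: prevalence targets must lie in [0, 1)")
  }
  onset <- logistic(p$onset_low, p$onset_high, p$onset_midage, p$onset_width)
  # cohort enters lesion-free at 45: the low-risk stock fills roughly
  # linearly over the first decades, the rarer high-risk subset (fed by
  # progression out of the low-risk stock) quadratically
  lr_prev <- pmin(p$lr_prev_max * pmin((ages - 45) / 30, 1), 0.999)
  hr_prev <- pmin(p$hr_prev_65 * ((ages - 45) / 20)^2, p$hr_prev_cap, 0.999)
  if (any(lr_prev < 0) || any(lr_prev >= 1) || any(hr_prev < 0) ||
      any(hr_prev >= 1)) {
    stop("generate_polyp_schedules: prevalence targets must lie in [0, 1)")
  }
  list(
    lr_onset = age_schedule(ages, onset, role = "probability",
                            name = "lr_polyp_onset"),
    lr_prev_target = age_schedule(ages, lr_prev, role = "probability",
                                  name = "polyp_prevalence_lr"),
    hr_prev_target = age_schedule(ages, hr_prev, role = "probability",
                                  name = "polyp_prevalence_hr")
  )
}

#' Stage distributions at diagnosis and stage-specific cancer lethality
#'
#' Two distributions over SEER summary stages (local, regional, distant):
#' one for symptomatically presenting cancers and one for screen-detected
#' cancers, the latter shifted toward earlier stage, plus the annual
#' probability of cancer death in each stage (distant >> regional > local).
#'
#' @param shape_params List with `stage_sympt`, `stage_screen` (length-3
#'   simplex vectors, order local/regional/distant) and `cancer_death`
#'   (length-3 annual probabilities).
#' @return List with validated `stage_sympt`, `stage_screen`, `cancer_death`.
#' @export
generate_stage_inputs <- function(shape_params = list()) {
  p <- modifyList(list(
    stage_sympt = c(local = 0.40, regional = 0.35, distant = 0.25),
    stage_screen = c(local = 0.50, regional = 0.32, distant = 0.18),
    cancer_death = c(local = 0.02, regional = 0.10, distant = 0.40)
  ), shape_params)
  check_simplex <- function(v, what) {
    if (length(v) != 3 || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("generate_stage_inputs: %s must be a 3-vector summing to 1",
                   what))
    }
  }
  check_simplex(p$stage_sympt, "stage_sympt")
  check_simplex(p$stage_screen, "stage_screen")
  # screen-detected must be (weakly) earlier-stage: cumulative mass from
  # local onward never smaller than symptomatic
  cs <- cumsum(p$stage_screen)
  cy <- cumsum(p$stage_sympt)
  if (any(cs[1:2] < cy[1:2] - 1e-12)) {
    stop("generate_stage_inputs: screen-detected stage distribution must not be later-stage than symptomatic")
  }
  d <- p$cancer_death
  if (any(d < 0) || any(d > 1)) {
    stop("generate_stage_inputs: cancer death probabilities must lie in [0, 1]")
  }
  if (!(d[3] > d[2] && d[2] > d[1])) {
    stop("generate_stage_inputs: cancer lethality must satisfy distant > regional > local")
  }
  names(p$stage_sympt) <- names(p$stage_screen) <- names(p$cancer_death) <-
    c("local", "regional", "distant")
  p[c("stage_sympt", "stage_screen", "cancer_death")]
}

#' Assemble the full synthetic epidemiology bundle
#'
#' Bundles the life table, baseline incidence, polyp schedules and stage
#' inputs into the `epi` block of the parameter set. All generators are pure
#' functions of their parameters.
#'
#' @param life,incidence,polyps,stages Optional shape-parameter lists passed
#'   to the individual generators.
#' @return A named list (class `epi_tables`).
#' @export
default_epi_tables <- function(life = list(), incidence = list(),
                               polyps = list(), stages = list()) {
  pol <- generate_polyp_schedules(polyps)
  stg <- generate_stage_inputs(stages)
  out <- list(
    mortality = generate_life_table(life),
    incidence = generate_crc_incidence(incidence),
    lr_onset = pol$lr_onset,
    lr_prev_target = pol$lr_prev_target,
    hr_prev_target = pol$hr_prev_target,
    stage_sympt = stg$stage_sympt,
    stage_screen = stg$stage_screen,
    cancer_death = stg$cancer_death
  )
  class(out) <- "epi_tables"
  out
}
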