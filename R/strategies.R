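#' The six screening strategies
#'
#' Builds a strategy specification: one or more cohort components, each a
#' (weight, modality, interval) triple. Non-adherent fractions in the FIT,
#' colonoscopy and stool-DNA arms follow natural history; in the hybrid
#' arm every first-line non-adherer receives the blood test instead.
#'
#' @param name One of `"NH"`, `"FIT"`, `"Colonoscopy"`, `"S-DNA"`, `"LB"`,
#'   `"C-LB"`.
#' @param params A `crc_params` parameter set (supplies adherence and test
#'   intervals).
#' @return A list of class `strategy_spec` with fields `name` and
#'   `components` (list of `weight` / `modality` / `interval`).
#' @export
build_strategy <- function(name, params = default_parameters()) {
  valid <- c("NH", "FIT", "Colonoscopy", "S-DNA", "LB", "C-LB")
  if (!name %in% valid) {
    stop(sprintf("unknown strategy '%s'; valid names: %s", name,
                 paste(valid, collapse = ", ")))
  }
  adh <- params$policy$adherence
  lb_adh <- params$policy$lb_adherence
  iv <- params$policy$intervals
  comp <- function(weight, modality, interval = NA_real_) {
    list(weight = weight, modality = modality, interval = interval)
  }
  components <- switch(
    name,
    "NH" = list(comp(1, "none")),
    "FIT" = list(comp(adh, "fit", iv[["fit"]]), comp(1 - adh, "none")),
    "Colonoscopy" = list(comp(adh, "colonoscopy", iv[["colonoscopy"]]),
                         comp(1 - adh, "none")),
    "S-DNA" = list(comp(adh, "sdna", iv[["sdna"]]), comp(1 - adh, "none")),
    "LB" = list(comp(lb_adh, "lb", iv[["lb"]]),
                comp(1 - lb_adh, "none")),
    "C-LB" = list(comp(adh, "colonoscopy", iv[["colonoscopy"]]),
                  comp((1 - adh) * lb_adh, "lb", iv[["lb"]]),
                  comp((1 - adh) * (1 - lb_adh), "none"))
  )
  components <- Filter(function(cc) cc$weight > 0, components)
  structure(list(name = name, components = components,
                 start_age = params$policy$start_age,
                 stop_age = params$policy$stop_age),
            class = "strategy_spec")
}

#' Is routine screening due at this age?
#'
#' Deterministic cohort schedule: true iff the age lies on the interval grid
#' anchored at the start age and within the screening window.
#'
#' @param age Integer age.
#' @param interval Screening interval in years (>= 1).
#' @param start_age,stop_age Screening window bounds (inclusive).
#' @return Logical flag.
#' @export
screening_due <- function(age, interval, start_age = 45, stop_age = 75) {
  stopifnot(interval >= 1)
  age >= start_age & age <= stop_age &
    ((age - start_age) %% interval) == 0
}

event_names <- c(
  "tests", "screening_colonoscopies", "followup_colonoscopies",
  "surveillance_colonoscopies", "diagnostic_colonoscopies",
  "polypectomies", "false_positives", "complications",
  "screen_detected_cancers", "symptomatic_cancers"
)

empty_events <- function() {
  stats::setNames(numeric(length(event_names)), event_names)
}

#' Apply one screening event step to a cohort occupancy vector
#'
#' The adherent sub-cohort due for screening is tested: the test (or
#' screening colonoscopy) cost is charged for everyone not yet diagnosed or
#' under surveillance, and lesion-free screenees of the stool/blood tests
#' test falsely positive with one minus specificity, receiving a follow-up
#' colonoscopy with its cost and age-specific complication risk but no
#' state change. True-positive detection operates on the disease flows in
#' the transition step (programme sensitivity -- see
#' [nh_transition_matrix()]), so the event step never moves mass between
#' lesion states; person mass is conserved exactly.
#'
#' @param state_vector Named occupancy over [health_states()] (simplex).
#' @param age Integer age.
#' @param modality `"none"`, `"colonoscopy"`, `"fit"`, `"sdna"` or `"lb"`.
#' @param interval Screening interval in years.
#' @param params A `crc_params` parameter set.
#' @return List with `state` (updated occupancy), `events` (named event
#'   fractions) and `cost` (undiscounted USD accrued by the event step).
#' @export
apply_screening_cycle <- function(state_vector, age, modality, interval,
                                  params) {
  v <- state_vector
  events <- empty_events()
  cost <- 0
  pol <- params$policy
  if (modality == "none" ||
      !screening_due(age, interval, pol$start_age, pol$stop_age)) {
    return(list(state = v, events = events, cost = cost))
  }
  cs <- params$costs
  comp_p <- schedule_at(params$complications$prob, age)
  comp_c <- schedule_at(cs$complication, age)
  tested <- v[["healthy"]] + v[["lr_polyp"]] + v[["hr_polyp"]]
  events["tests"] <- tested

  if (modality == "colonoscopy") {
    events["screening_colonoscopies"] <- tested
    events["complications"] <- tested * comp_p
    cost <- tested * cs$colo_no_polypectomy + tested * comp_p * comp_c
  } else {
    perf <- params$tests[[modality]]
    fp <- v[["healthy"]] * (1 - perf$specificity)
    events["false_positives"] <- fp
    events["followup_colonoscopies"] <- fp
    events["complications"] <- fp * comp_p
    cost <- tested * cs[[modality]] +
      fp * (cs$colo_no_polypectomy + comp_p * comp_c)
  }
  list(state = v, events = events, cost = cost)
}

#' Apply one surveillance event step
#'
#' Mass at the end of a surveillance tunnel (tunnel year equals the
#' surveillance interval) receives a surveillance colonoscopy -- follow-up
#' adherence is 100% -- while surveillance is active (age at or below the
#' surveillance stop age, default 85). Polyps that re-developed during the
#' tunnel are re-detected with the colonoscopy's low-risk polyp sensitivity
#' and the tunnel restarts in the matching track with the polypectomy cost;
#' otherwise the person restarts the low-risk (5-year) track as
#' polyp-free surveillance. Beyond the stop age tunnels advance with no
#' further colonoscopies.
#'
#' @inheritParams apply_screening_cycle
#' @return List with `state`, `events`, `cost` as in
#'   [apply_screening_cycle()].
#' @export
surveillance_cycle <- function(state_vector, age, params) {
  v <- state_vector
  events <- empty_events()
  cost <- 0
  pol <- params$policy
  if (age > pol$surveillance_stop_age) {
    return(list(state = v, events = events, cost = cost))
  }
  L <- pol$lr_surveillance_interval
  H <- pol$hr_surveillance_interval
  lr_end <- paste0("lr_surv_", L)
  hr_end <- paste0("hr_surv_", H)
  fire_lr <- v[[lr_end]]
  fire_hr <- v[[hr_end]]
  if (fire_lr + fire_hr <= 0) {
    return(list(state = v, events = events, cost = cost))
  }
  cs <- params$costs
  comp_p <- schedule_at(params$complications$prob, age)
  comp_c <- schedule_at(cs$complication, age)
  o <- min(1, params$rates$onset_scale * schedule_at(params$epi$lr_onset, age))
  sl <- schedule_at(params$tests$colonoscopy$lr_sens, age)
  q_lr <- (1 - (1 - o)^L) * sl   # recurrent polyp present and re-detected
  q_hr <- (1 - (1 - o)^H) * sl

  v[[lr_end]] <- 0
  v[["lr_surv_0"]] <- v[["lr_surv_0"]] + fire_lr + fire_hr * (1 - q_hr)
  v[[hr_end]] <- 0
  v[["hr_surv_0"]] <- v[["hr_surv_0"]] + fire_hr * q_hr

  colos <- fire_lr + fire_hr
  polyps <- fire_lr * q_lr + fire_hr * q_hr
  events["surveillance_colonoscopies"] <- colos
  events["polypectomies"] <- polyps
  events["complications"] <- colos * comp_p
  cost <- polyps * cs$colo_polypectomy +
    (colos - polyps) * cs$colo_no_polypectomy +
    colos * comp_p * comp_c
  list(state = v, events = events, cost = cost)
}
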