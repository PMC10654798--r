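#' Discount factor
#'
#' @param year_index Years since model start (0 = age 45).
#' @param rate Annual discount rate (>= 0).
#' @return `(1 + rate)^(-year_index)`.
#' @export
discount_factor <- function(year_index, rate) {
  if (any(year_index < 0)) stop("discount_factor: year_index must be >= 0")
  if (any(rate < 0)) stop("discount_factor: rate must be >= 0")
  (1 + rate)^(-year_index)
}

# Run one homogeneous sub-cohort (single modality) from 45 to 100.
#
# Cycle order: (1) screening and surveillance events, (2) natural-history
# and death transitions, (3) accrual of life-years and costs. Life-years
# accrue at the post-event (= start-of-cycle) alive mass; first-year and
# continuing cancer costs on post-event occupancy; final-year cancer costs
# and the diagnostic colonoscopy at diagnosis on the transition flows.
run_component <- function(modality, interval, params) {
  pol <- params$policy
  states <- health_states(pol$lr_surveillance_interval,
                          pol$hr_surveillance_interval)
  n <- length(states)
  ages <- pol$start_age:(pol$max_age - 1)
  n_cyc <- length(ages)

  v <- stats::setNames(numeric(n), states)
  v[["healthy"]] <- 1

  y1 <- paste0("ca_", c("local", "regional", "distant"), "_y1")
  cont <- paste0("ca_", c("local", "regional", "distant"), "_cont")
  surv_states <- grep("_surv_", states, value = TRUE)
  undet <- c("healthy", "lr_polyp", "hr_polyp")
  cancer_cost <- params$costs$cancer
  colo_cost <- params$costs$colo_no_polypectomy

  occupancy <- matrix(0, n_cyc + 1, n, dimnames = list(NULL, states))
  cyc <- data.frame(age = ages, ly = 0, cost = 0, alive = 0,
                    inc_flow = 0, screen_flow = 0, crc_death_flow = 0)
  ev_mat <- matrix(0, n_cyc, length(event_names),
                   dimnames = list(NULL, event_names))
  inc_by_stage <- c(local = 0, regional = 0, distant = 0)

  base_cover <- if (modality == "none") {
    list(cancer = 0, lr = 0, hr = 0)
  } else if (modality == "colonoscopy") {
    list(cancer = params$tests$colonoscopy$cancer_detection_rate,
         lr = NA, hr = NA)  # age-specific, filled per cycle
  } else {
    perf <- params$tests[[modality]]
    list(cancer = perf$cancer_sens, lr = perf$lr_sens, hr = perf$hr_sens)
  }
  colo_det <- params$tests$colonoscopy$cancer_detection_rate
  no_cover <- list(cancer = 0, lr = 0, hr = 0)

  for (k in seq_len(n_cyc)) {
    a <- ages[k]
    scr <- apply_screening_cycle(v, a, modality, interval, params)
    sur <- surveillance_cycle(scr$state, a, params)
    v <- sur$state
    ev <- scr$events + sur$events
    cost <- scr$cost + sur$cost

    cover <- if (a <= pol$stop_age && modality != "none") {
      cv <- base_cover
      if (modality == "colonoscopy") {
        cv$lr <- schedule_at(params$tests$colonoscopy$lr_sens, a)
        cv$hr <- schedule_at(params$tests$colonoscopy$hr_sens, a)
      }
      cv
    } else no_cover
    surv_cover <- if (a <= pol$surveillance_stop_age) colo_det else 0
    M <- cycle_transition_matrix(a, params, cover, surv_cover)

    # phase-of-care costs on start-of-cycle occupancy
    cost <- cost + sum(v[y1] * cancer_cost[, "first_year"]) +
      sum(v[cont] * cancer_cost[, "continuing"])

    # transition flows: diagnoses and cancer deaths this cycle
    m_oth <- schedule_at(params$epi$mortality, a)
    i_eff <- params$rates$incidence_scale *
      schedule_at(params$epi$incidence, a)
    cd <- min(1, params$rates$direct_cancer_fraction * i_eff)
    ch <- min(1, params$rates$hr_cancer_mult * i_eff)
    flow_undet <- (1 - m_oth) *
      (cd * (v[["healthy"]] + v[["lr_polyp"]]) + ch * v[["hr_polyp"]])
    flow_surv <- (1 - m_oth) * cd * sum(v[surv_states])
    screen_flow <- cover$cancer * flow_undet + surv_cover * flow_surv
    sympt_flow <- (flow_undet + flow_surv) - screen_flow
    inc_flow <- flow_undet + flow_surv
    inc_by_stage <- inc_by_stage +
      screen_flow * params$epi$stage_screen +
      sympt_flow * params$epi$stage_sympt

    death_flow_stage <- (v[y1] + v[cont]) * M[y1, "dead_crc"]
    crc_death_flow <- sum(death_flow_stage)
    cost <- cost + sum(death_flow_stage * cancer_cost[, "final_year"])

    comp_p <- schedule_at(params$complications$prob, a)
    comp_c <- schedule_at(params$costs$complication, a)
    cost <- cost + inc_flow * (colo_cost + comp_p * comp_c)
    ev["diagnostic_colonoscopies"] <- inc_flow
    ev["complications"] <- ev["complications"] + inc_flow * comp_p
    ev["screen_detected_cancers"] <- screen_flow
    ev["symptomatic_cancers"] <- sympt_flow

    # polyp interception flows (programme polyp sensitivity): a detected
    # new polyp is removed and enters surveillance. Stool/blood positives
    # receive a follow-up colonoscopy with polypectomy; in the colonoscopy
    # arm only the polypectomy increment is charged here, the visit itself
    # being costed on the screening schedule.
    int_lr <- v[["healthy"]] * (1 - m_oth) * (1 - cd) *
      min(1, params$rates$onset_scale * schedule_at(params$epi$lr_onset, a)) *
      cover$lr
    int_hr <- v[["lr_polyp"]] * (1 - m_oth) * (1 - cd) *
      params$rates$lr_to_hr * cover$hr
    intercepted <- int_lr + int_hr
    if (intercepted > 0) {
      ev["polypectomies"] <- ev["polypectomies"] + intercepted
      if (modality == "colonoscopy") {
        cost <- cost + intercepted *
          (params$costs$colo_polypectomy - params$costs$colo_no_polypectomy)
      } else {
        ev["followup_colonoscopies"] <- ev["followup_colonoscopies"] +
          intercepted
        ev["complications"] <- ev["complications"] + intercepted * comp_p
        cost <- cost + intercepted *
          (params$costs$colo_polypectomy + comp_p * comp_c)
      }
    }

    alive <- 1 - v[["dead_crc"]] - v[["dead_other"]]
    occupancy[k, ] <- v
    cyc$ly[k] <- alive
    cyc$alive[k] <- alive
    cyc$cost[k] <- cost
    cyc$inc_flow[k] <- inc_flow
    cyc$screen_flow[k] <- screen_flow
    cyc$crc_death_flow[k] <- crc_death_flow
    ev_mat[k, ] <- ev

    v <- drop(v %*% M)
    names(v) <- states
  }
  occupancy[n_cyc + 1, ] <- v

  structure(list(
    trace_ages = c(ages, pol$max_age),
    cycles = cyc,
    occupancy = occupancy,
    events = ev_mat,
    inc_by_stage = inc_by_stage,
    lifetime_incidence = sum(cyc$inc_flow),
    crc_mortality = unname(v[["dead_crc"]]),
    policy = pol
  ), class = "cohort_trace")
}

# Weighted mixture of component traces (all accrual is linear in occupancy).
combine_traces <- function(traces, weights) {
  w <- weights / sum(weights)
  out <- traces[[1]]
  num <- c("ly", "cost", "alive", "inc_flow", "screen_flow", "crc_death_flow")
  out$cycles[num] <- out$cycles[num] * w[1]
  out$occupancy <- out$occupancy * w[1]
  out$events <- out$events * w[1]
  out$inc_by_stage <- out$inc_by_stage * w[1]
  out$lifetime_incidence <- out$lifetime_incidence * w[1]
  out$crc_mortality <- out$crc_mortality * w[1]
  for (j in seq_along(traces)[-1]) {
    tr <- traces[[j]]
    out$cycles[num] <- out$cycles[num] + tr$cycles[num] * w[j]
    out$occupancy <- out$occupancy + tr$occupancy * w[j]
    out$events <- out$events + tr$events * w[j]
    out$inc_by_stage <- out$inc_by_stage + tr$inc_by_stage * w[j]
    out$lifetime_incidence <- out$lifetime_incidence +
      tr$lifetime_incidence * w[j]
    out$crc_mortality <- out$crc_mortality + tr$crc_mortality * w[j]
  }
  out
}

#' Run the annual-cycle Markov cohort for one strategy
#'
#' Runs each strategy component (adherent / non-adherent sub-cohort) from
#' age 45 until death or age 100 and mixes the traces by component weight.
#'
#' @param spec A [build_strategy()] specification (or a strategy name).
#' @param params A `crc_params` parameter set (normally calibrated first
#'   with [calibrate_natural_history()]).
#' @param component_cache Optional environment used to share identical
#'   component runs across strategies (e.g. the natural-history component).
#' @return A `cohort_trace`: per-cycle occupancy, event ledger, life-years
#'   and undiscounted costs, plus lifetime incidence/mortality tallies.
#' @export
run_cohort <- function(spec, params, component_cache = NULL) {
  if (is.character(spec)) spec <- build_strategy(spec, params)
  stopifnot(inherits(spec, "strategy_spec"))
  traces <- lapply(spec$components, function(cc) {
    key <- paste0(cc$modality, ":", cc$interval)
    if (!is.null(component_cache) && !is.null(component_cache[[key]])) {
      return(component_cache[[key]])
    }
    tr <- run_component(cc$modality, cc$interval, params)
    if (!is.null(component_cache)) component_cache[[key]] <- tr
    tr
  })
  out <- combine_traces(traces, vapply(spec$components, `[[`, 0, "weight"))
  out$strategy <- spec$name
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s: ages %d..%d\n",
              x$strategy %||% "(component)", min(x$trace_ages),
              max(x$trace_ages)))
  cat(sprintf("  lifetime CRC incidence %.2f%%, CRC mortality %.2f%%\n",
              100 * x$lifetime_incidence, 100 * x$crc_mortality))
  cat(sprintf("  undiscounted life-years %.3f, undiscounted cost $%.0f\n",
              sum(x$cycles$ly), sum(x$cycles$cost)))
  invisible(x)
}

#' Summarize a cohort trace into per-person outcomes
#'
#' Applies discounting to the per-cycle accruals. Costs are always
#' discounted; the effectiveness measure is undiscounted life-years by
#' default (`discount_lyg = FALSE`), switchable to discounted life-years.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param rate Annual discount rate (default: the policy rate stored in the
#'   trace).
#' @param discount_lyg Logical; use discounted life-years as the
#'   effectiveness measure.
#' @return A list of class `outcomes`: `discounted_cost`, `discounted_lyg`,
#'   `undiscounted_lyg`, `effectiveness`, `lifetime_crc_incidence` (%),
#'   `crc_mortality` (%), `stage_distribution` of diagnosed cancers.
#' @export
accrue_outcomes <- function(trace, rate = NULL, discount_lyg = NULL) {
  rate <- rate %||% trace$policy$discount_rate
  discount_lyg <- discount_lyg %||% trace$policy$discount_lyg
  df <- discount_factor(seq_along(trace$cycles$age) - 1, rate)
  disc_cost <- sum(trace$cycles$cost * df)
  disc_lyg <- sum(trace$cycles$ly * df)
  undisc_lyg <- sum(trace$cycles$ly)
  stage <- trace$inc_by_stage
  stage <- if (sum(stage) > 0) stage / sum(stage) else stage
  structure(list(
    strategy = trace$strategy %||% NA_character_,
    discounted_cost = disc_cost,
    discounted_lyg = disc_lyg,
    undiscounted_lyg = undisc_lyg,
    effectiveness = if (discount_lyg) disc_lyg else undisc_lyg,
    lifetime_crc_incidence = 100 * trace$lifetime_incidence,
    crc_mortality = 100 * trace$crc_mortality,
    stage_distribution = stage
  ), class = "outcomes")
}

#' Run a set of strategies and tabulate per-strategy outcomes
#'
#' @param params A calibrated `crc_params` parameter set.
#' @param strategies Character vector of strategy names.
#' @return Data frame with one row per strategy: cost (discounted USD),
#'   effectiveness (life-years), incidence and mortality percentages.
#' @export
run_strategies <- function(params,
                           strategies = c("NH", "FIT", "Colonoscopy",
                                          "S-DNA", "C-LB", "LB")) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(strategies, function(nm) {
    out <- accrue_outcomes(run_cohort(nm, params, component_cache = cache))
    data.frame(strategy = nm,
               cost = out$discounted_cost,
               effectiveness = out$effectiveness,
               discounted_lyg = out$discounted_lyg,
               undiscounted_lyg = out$undiscounted_lyg,
               crc_incidence_pct = out$lifetime_crc_incidence,
               crc_mortality_pct = out$crc_mortality)
  })
  do.call(rbind, rows)
}
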