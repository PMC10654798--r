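#' @keywords internal
# Per-cycle transition matrix over the full state space.
#
# Other-cause death is applied first in every state; the survivors then
# undergo disease transitions. `cover` describes the screening programme
# active for this sub-cohort as interception probabilities on the disease
# flows ("programme sensitivity", the cohort-level annualization of test
# performance applied to natural-history incidence):
#   * cover$cancer -- an incident cancer arising from the undetected states
#     is screen-detected (screen-detected stage distribution) instead of
#     presenting symptomatically;
#   * cover$lr -- a newly arising low-risk polyp is detected and removed
#     (enters the low-risk surveillance tunnel) instead of joining the
#     undetected stock;
#   * cover$hr -- a polyp progressing to high risk is detected on entry to
#     the high-risk stock and enters the high-risk tunnel.
# A lesion missed at this single interception opportunity stays undetected
# (misses are treated as persistent, lesion-driven). `surv_sens` is the
# screen-detection probability for cancers arising from surveillance
# states while surveillance is active.
cycle_transition_matrix <- function(age, params,
                                    cover = list(cancer = 0, lr = 0, hr = 0),
                                    surv_sens = 0) {
  pol <- params$policy
  states <- health_states(pol$lr_surveillance_interval,
                          pol$hr_surveillance_interval)
  n <- length(states)
  L <- pol$lr_surveillance_interval
  H <- pol$hr_surveillance_interval
  e <- params$epi
  r <- params$rates

  m <- schedule_at(e$mortality, age)
  i_eff <- r$incidence_scale * schedule_at(e$incidence, age)
  cd <- min(1, r$direct_cancer_fraction * i_eff)
  ch <- min(1, r$hr_cancer_mult * i_eff)
  o <- min(1, r$onset_scale * schedule_at(e$lr_onset, age))
  lh <- r$lr_to_hr
  d <- pmin(1, r$death_scale * e$cancer_death)

  dist_cov <- cover$cancer * e$stage_screen +
    (1 - cover$cancer) * e$stage_sympt
  dist_surv <- surv_sens * e$stage_screen + (1 - surv_sens) * e$stage_sympt

  M <- matrix(0, n, n, dimnames = list(states, states))
  y1 <- paste0("ca_", c("local", "regional", "distant"), "_y1")
  cont <- paste0("ca_", c("local", "regional", "distant"), "_cont")
  alive <- 1 - m

  M["healthy", "dead_other"] <- m
  M["healthy", y1] <- alive * cd * dist_cov
  M["healthy", "lr_surv_0"] <- alive * (1 - cd) * o * cover$lr
  M["healthy", "lr_polyp"] <- alive * (1 - cd) * o * (1 - cover$lr)
  M["healthy", "healthy"] <- alive * (1 - cd) * (1 - o)

  M["lr_polyp", "dead_other"] <- m
  M["lr_polyp", y1] <- alive * cd * dist_cov
  M["lr_polyp", "hr_surv_0"] <- alive * (1 - cd) * lh * cover$hr
  M["lr_polyp", "hr_polyp"] <- alive * (1 - cd) * lh * (1 - cover$hr)
  M["lr_polyp", "lr_polyp"] <- alive * (1 - cd) * (1 - lh)

  M["hr_polyp", "dead_other"] <- m
  M["hr_polyp", y1] <- alive * ch * dist_cov
  M["hr_polyp", "hr_polyp"] <- alive * (1 - ch)

  advance <- function(prefix, K) {
    for (k in 0:K) {
      from <- paste0(prefix, k)
      M[from, "dead_other"] <<- m
      M[from, y1] <<- alive * cd * dist_surv
      to <- if (k < K) paste0(prefix, k + 1) else from
      M[from, to] <<- alive * (1 - cd)
    }
  }
  advance("lr_surv_", L)
  advance("hr_surv_", H)

  for (j in 1:3) {
    for (st in c(y1[j], cont[j])) {
      M[st, "dead_other"] <- m
      M[st, "dead_crc"] <- alive * d[j]
      M[st, cont[j]] <- M[st, cont[j]] + alive * (1 - d[j])
    }
  }
  M["dead_crc", "dead_crc"] <- 1
  M["dead_other", "dead_other"] <- 1
  M
}

#' Natural-history transition matrix at a given age
#'
#' The unscreened disease process: polyp onset and progression, cancer
#' onset with the symptomatic stage distribution (no screening, so no
#' screen-detected flows and no entries into surveillance states), cancer
#' death and other-cause death. Rows are source states, columns targets;
#' every row sums to one.
#'
#' @param age Integer age in 45..100.
#' @param params A `crc_params` parameter set (carries rates and
#'   epidemiology).
#' @return A row-stochastic square matrix over [health_states()].
#' @export
nh_transition_matrix <- function(age, params) {
  if (age < 45 || age > 100) stop("nh_transition_matrix: age must be in 45..100")
  cycle_transition_matrix(age, params, surv_sens = 0)
}

#' Calibrate natural-history rates to the synthetic epidemiology targets
#'
#' Sequential deterministic one-dimensional root finding: the polyp onset
#' scale is solved against the low-risk prevalence target at 65, the
#' LR-to-HR progression rate against the high-risk target at 65, the
#' incidence scale against lifetime CRC incidence, and the lethality scale
#' against lifetime CRC mortality, looping the blocks to settle
#' cross-dependence. Pure function of its inputs (fixed starting brackets,
#' no randomness), hence idempotent up to the root-finder tolerance.
#'
#' @param params A `crc_params` parameter set.
#' @param targets List with `lifetime_incidence` and `crc_mortality`
#'   (fractions) and optional `lr_prev` / `hr_prev` [age_schedule()]s
#'   (default: the prevalence targets in `params$epi`).
#' @param tolerances List with `incidence` (default 0.003), `mortality`
#'   (0.002) and `prevalence` (0.05, checked at ages 55/65/75).
#' @param outer_iter Maximum number of block sweeps; sweeping stops early
#'   once no rate moves by more than `rate_tol` (relative).
#' @param rate_tol Relative fixed-point tolerance on the calibrated rates.
#' @return The parameter set with calibrated `rates`, carrying a
#'   `calibration_report` attribute (data frame of target / achieved /
#'   residual). Signals an error with the residual table if any target is
#'   missed beyond tolerance.
#' @export
calibrate_natural_history <- function(params,
                                      targets = list(),
                                      tolerances = list(),
                                      outer_iter = 10, rate_tol = 5e-4) {
  targets <- modifyList(list(lifetime_incidence = 0.052,
                             crc_mortality = 0.016,
                             lr_prev = params$epi$lr_prev_target,
                             hr_prev = params$epi$hr_prev_target), targets)
  tolerances <- modifyList(list(incidence = 0.003, mortality = 0.002,
                                prevalence = 0.05), tolerances)

  zero_polyps <- all(schedule_at(targets$lr_prev, 45:100) == 0) &&
    all(schedule_at(targets$hr_prev, 45:100) == 0)
  if (targets$lifetime_incidence == 0 && zero_polyps) {
    params$rates$onset_scale <- 0
    params$rates$lr_to_hr <- 0
    params$rates$incidence_scale <- 0
    params$rates$death_scale <- 0
    attr(params, "calibration_report") <- data.frame(
      target = c("lifetime_incidence", "crc_mortality"),
      goal = c(0, 0), achieved = c(0, 0), residual = c(0, 0))
    return(params)
  }

  nh_summary <- function(p) {
    tr <- run_component("none", NA, p)
    alive <- 1 - tr$occupancy[, "dead_crc"] - tr$occupancy[, "dead_other"]
    list(
      incidence = tr$lifetime_incidence,
      mortality = tr$crc_mortality,
      lr_prev = tr$occupancy[, "lr_polyp"] / pmax(alive, 1e-12),
      hr_prev = tr$occupancy[, "hr_polyp"] / pmax(alive, 1e-12),
      ages = tr$trace_ages
    )
  }
  prev_at <- function(s, which, age) s[[which]][match(age, s$ages)]

  safe_root <- function(f, lower, upper, what) {
    out <- tryCatch(
      stats::uniroot(f, c(lower, upper), tol = 1e-8)$root,
      error = function(e) {
        stop(sprintf("calibration failure for %s: %s", what, conditionMessage(e)),
             call. = FALSE)
      })
    out
  }

  tgt_lr65 <- schedule_at(targets$lr_prev, 65)
  tgt_hr65 <- schedule_at(targets$hr_prev, 65)

  rate_vec <- function(p) unlist(p$rates[c("onset_scale", "lr_to_hr",
                                           "incidence_scale", "death_scale")])
  for (sweep in seq_len(outer_iter)) {
    before <- rate_vec(params)
    if (tgt_lr65 > 0) {
      params$rates$onset_scale <- safe_root(function(s) {
        p <- params; p$rates$onset_scale <- s
        prev_at(nh_summary(p), "lr_prev", 65) - tgt_lr65
      }, 1e-4, 25, "polyp onset scale")
    } else params$rates$onset_scale <- 0
    if (tgt_hr65 > 0 && params$rates$onset_scale > 0) {
      params$rates$lr_to_hr <- safe_root(function(lh) {
        p <- params; p$rates$lr_to_hr <- lh
        prev_at(nh_summary(p), "hr_prev", 65) - tgt_hr65
      }, 1e-5, 0.6, "LR-to-HR progression")
    } else if (tgt_hr65 == 0) params$rates$lr_to_hr <- 0

    if (targets$lifetime_incidence > 0) {
      params$rates$incidence_scale <- safe_root(function(s) {
        p <- params; p$rates$incidence_scale <- s
        nh_summary(p)$incidence - targets$lifetime_incidence
      }, 1e-4, 100, "incidence scale")
      params$rates$death_scale <- safe_root(function(s) {
        p <- params; p$rates$death_scale <- s
        nh_summary(p)$mortality - targets$crc_mortality
      }, 1e-4, 0.999 / max(params$epi$cancer_death), "lethality scale")
    } else {
      params$rates$incidence_scale <- 0
      params$rates$death_scale <- 0
    }
    after <- rate_vec(params)
    if (max(abs(after - before) / pmax(abs(before), 1e-12)) < rate_tol) break
  }

  s <- nh_summary(params)
  decade_ages <- intersect(c(55, 65, 75), s$ages)
  report <- rbind(
    data.frame(target = "lifetime_incidence",
               goal = targets$lifetime_incidence, achieved = s$incidence),
    data.frame(target = "crc_mortality",
               goal = targets$crc_mortality, achieved = s$mortality),
    data.frame(target = paste0("lr_prev_", decade_ages),
               goal = schedule_at(targets$lr_prev, decade_ages),
               achieved = prev_at(s, "lr_prev", decade_ages)),
    data.frame(target = paste0("hr_prev_", decade_ages),
               goal = schedule_at(targets$hr_prev, decade_ages),
               achieved = prev_at(s, "hr_prev", decade_ages))
  )
  report$residual <- report$achieved - report$goal
  tol <- c(tolerances$incidence, tolerances$mortality,
           rep(tolerances$prevalence, 2 * length(decade_ages)))
  report$within_tolerance <- abs(report$residual) <= tol
  attr(params, "calibration_report") <- report
  if (!all(report$within_tolerance)) {
    stop(paste(c("natural-history calibration did not reach its targets:",
                 utils::capture.output(print(report))), collapse = "\n"),
         call. = FALSE)
  }
  params
}
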