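# Internal: cost/effect pair for one strategy under a parameter set.
strategy_pair <- function(name, params, cache = NULL) {
  out <- accrue_outcomes(run_cohort(name, params, component_cache = cache))
  c(cost = out$discounted_cost, effect = out$effectiveness)
}

pairwise_icer <- function(a, b, params) {
  cache <- new.env(parent = emptyenv())
  pa <- strategy_pair(a, params, cache)
  pb <- strategy_pair(b, params, cache)
  de <- pb[["effect"]] - pa[["effect"]]
  dc <- pb[["cost"]] - pa[["cost"]]
  if (de <= 0) return(if (dc <= 0) -Inf else Inf)  # dominated / dominating
  dc / de
}

#' One-way sensitivity analysis for a single parameter
#'
#' Reruns the model at the lower and upper bound of one parameter, holding
#' all others at base case, and reports the ICER of strategy B against
#' strategy A at each bound. Negative lower bounds are clamped to zero.
#'
#' @param param_id Dotted parameter path (see [param_get()]), e.g.
#'   `"costs.lb"` or `"tests.lb.cancer_sens"`.
#' @param bounds Numeric length-2 vector `c(low, high)`; must bracket the
#'   base-case value.
#' @param comparison Character length-2 `c(A, B)` strategy names.
#' @param params A calibrated `crc_params` parameter set.
#' @return A one-row data frame (class `owsa_entry`): bounds, ICER at each
#'   bound, and the ICER range width used to order tornado diagrams.
#' @export
one_way_sa <- function(param_id, bounds, comparison, params) {
  stopifnot(length(bounds) == 2, length(comparison) == 2)
  base <- param_get(params, param_id)
  if (!is.numeric(base) || length(base) != 1) {
    stop(sprintf("one_way_sa: '%s' is not a scalar parameter", param_id))
  }
  bounds <- sort(pmax(bounds, 0))
  if (base < bounds[1] - 1e-12 || base > bounds[2] + 1e-12) {
    stop(sprintf("one_way_sa: bounds [%g, %g] do not bracket base value %g",
                 bounds[1], bounds[2], base))
  }
  icers <- vapply(bounds, function(b) {
    pairwise_icer(comparison[1], comparison[2],
                  param_set(params, param_id, b))
  }, 0)
  out <- data.frame(parameter = param_id, low = bounds[1], high = bounds[2],
                    icer_low = icers[1], icer_high = icers[2],
                    range = abs(icers[2] - icers[1]))
  class(out) <- c("owsa_entry", "data.frame")
  out
}

#' Tornado table over a list of parameters
#'
#' @param param_bounds Named list mapping parameter paths to
#'   `c(low, high)` bounds.
#' @inheritParams one_way_sa
#' @return Data frame of [one_way_sa()] rows sorted by decreasing ICER
#'   range.
#' @export
tornado_table <- function(param_bounds, comparison, params) {
  rows <- lapply(names(param_bounds), function(id) {
    one_way_sa(id, param_bounds[[id]], comparison, params)
  })
  out <- do.call(rbind, rows)
  out[order(-out$range), ]
}

#' Threshold price search
#'
#' Finds the parameter value (typically the liquid biopsy unit cost) at
#' which the ICER of strategy B versus strategy A crosses the
#' willingness-to-pay threshold, by bisection. The ICER is first sampled at
#' five points across the interval and the search refuses to run if it is
#' not monotone there.
#'
#' @param param_id Dotted parameter path of the price being varied.
#' @param comparison Character length-2 `c(A, B)` strategy names.
#' @param wtp Willingness-to-pay threshold (USD per life-year).
#' @param interval Numeric length-2 search interval.
#' @param tol Absolute tolerance on the price.
#' @param params A calibrated `crc_params` parameter set.
#' @return List with `price`, `already_cost_effective` (TRUE when the ICER
#'   stays below `wtp` over the whole interval, in which case `price` is
#'   the upper endpoint), `no_crossing` (TRUE when the ICER stays above
#'   `wtp`, `price` the lower endpoint) and the sampled `icer_grid`.
#' @export
threshold_price <- function(param_id, comparison, wtp, interval,
                            tol = 0.01, params = default_parameters()) {
  stopifnot(length(interval) == 2, tol > 0)
  interval <- sort(interval)
  f <- function(p) {
    pairwise_icer(comparison[1], comparison[2],
                  param_set(params, param_id, p)) - wtp
  }
  grid <- seq(interval[1], interval[2], length.out = 5)
  g <- vapply(grid, f, 0)
  finite <- g[is.finite(g)]
  if (length(finite) >= 2 && is.unsorted(finite) &&
      is.unsorted(rev(finite))) {
    stop(paste("threshold_price: ICER is not monotone over the interval;",
               "sampled values:", paste(signif(g + wtp, 6), collapse = ", ")))
  }
  if (all(g <= 0)) {
    return(list(price = interval[2], already_cost_effective = TRUE,
                no_crossing = FALSE, icer_grid = g + wtp))
  }
  if (all(g >= 0)) {
    return(list(price = interval[1], already_cost_effective = FALSE,
                no_crossing = TRUE, icer_grid = g + wtp))
  }
  root <- stats::uniroot(f, interval, tol = tol)$root
  list(price = root, already_cost_effective = FALSE, no_crossing = FALSE,
       icer_grid = g + wtp)
}

#' Scenario analysis: granting the blood test polyp sensitivity
#'
#' Recomputes the full frontier over a grid of high-risk and low-risk polyp
#' sensitivities for the liquid biopsy. A polyp-positive blood test leads to
#' a follow-up colonoscopy with polypectomy and surveillance entry, exactly
#' as for the stool tests.
#'
#' @param hr_grid,lr_grid Numeric vectors of sensitivities in \[0, 1\].
#' @param params A calibrated `crc_params` parameter set.
#' @param strategies Strategies included in each frontier.
#' @return Data frame with one row per grid point: the hybrid strategy's
#'   ICER (NA when dominated), its dominance status, and the cost-effective
#'   choice at the policy willingness-to-pay.
#' @export
scenario_lb_polyp <- function(hr_grid, lr_grid, params,
                              strategies = c("NH", "FIT", "Colonoscopy",
                                             "S-DNA", "C-LB", "LB")) {
  stopifnot(all(hr_grid >= 0 & hr_grid <= 1), all(lr_grid >= 0 & lr_grid <= 1))
  grid <- expand.grid(hr_sens = hr_grid, lr_sens = lr_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- param_set(params, "tests.lb.hr_sens", grid$hr_sens[g])
    p <- param_set(p, "tests.lb.lr_sens", grid$lr_sens[g])
    tab <- run_strategies(p, strategies)
    fr <- incremental_analysis(tab[c("strategy", "cost", "effectiveness")])
    clb <- fr[fr$strategy == "C-LB", ]
    data.frame(hr_sens = grid$hr_sens[g], lr_sens = grid$lr_sens[g],
               clb_cost = clb$cost, clb_effect = clb$effectiveness,
               clb_icer = clb$icer, clb_status = clb$status,
               choice = decide_cost_effective(fr, params$policy$wtp))
  })
  do.call(rbind, rows)
}

#' Scenario analysis: surveillance interval and screening end age
#'
#' Reruns the strategy set for each combination of low-risk surveillance
#' interval (years) and screening stop age, reporting outcomes and whether
#' the cost-effective choice changes from the base case.
#'
#' @param lr_intervals Integer vector of low-risk surveillance intervals.
#' @param end_ages Integer vector of screening stop ages.
#' @param params A calibrated `crc_params` parameter set.
#' @param strategies Strategies included.
#' @return List with `outcomes` (per-configuration strategy table including
#'   total surveillance colonoscopy burden) and `choices` (cost-effective
#'   strategy per configuration, with a flag against the base case).
#' @export
scenario_intervals_endage <- function(lr_intervals = c(5, 7, 10),
                                      end_ages = c(75, 85),
                                      params = default_parameters(),
                                      strategies = c("NH", "FIT",
                                                     "Colonoscopy", "S-DNA",
                                                     "C-LB", "LB")) {
  base_choice <- {
    tab <- run_strategies(params, strategies)
    decide_cost_effective(
      incremental_analysis(tab[c("strategy", "cost", "effectiveness")]),
      params$policy$wtp)
  }
  cfg <- expand.grid(lr_interval = lr_intervals, end_age = end_ages)
  outcomes <- list()
  choices <- list()
  for (g in seq_len(nrow(cfg))) {
    p <- param_set(params, "policy.lr_surveillance_interval",
                   cfg$lr_interval[g])
    p <- param_set(p, "policy.stop_age", cfg$end_age[g])
    cache <- new.env(parent = emptyenv())
    tab <- do.call(rbind, lapply(strategies, function(nm) {
      tr <- run_cohort(nm, p, component_cache = cache)
      out <- accrue_outcomes(tr)
      data.frame(lr_interval = cfg$lr_interval[g], end_age = cfg$end_age[g],
                 strategy = nm, cost = out$discounted_cost,
                 effectiveness = out$effectiveness,
                 surveillance_colonoscopies =
                   sum(tr$events[, "surveillance_colonoscopies"]),
                 total_colonoscopies =
                   sum(tr$events[, c("screening_colonoscopies",
                                     "followup_colonoscopies",
                                     "surveillance_colonoscopies",
                                     "diagnostic_colonoscopies")]))
    }))
    outcomes[[g]] <- tab
    fr <- incremental_analysis(tab[c("strategy", "cost", "effectiveness")])
    choices[[g]] <- data.frame(
      lr_interval = cfg$lr_interval[g], end_age = cfg$end_age[g],
      choice = decide_cost_effective(fr, params$policy$wtp))
  }
  choices <- do.call(rbind, choices)
  choices$same_as_base <- choices$choice == base_choice
  list(outcomes = do.call(rbind, outcomes), choices = choices,
       base_choice = base_choice)
}

#' Default probabilistic sensitivity distributions
#'
#' Beta distributions for probabilities (standard deviation one tenth of
#' the smaller of mean and one minus mean, keeping the moment-matched shape
#' parameters positive even for near-boundary means such as a 99.5%
#' specificity) and gamma distributions for unit costs (standard deviation
#' implied by the +/-25% cost bounds read as a 95% interval; the blood test
#' uses its published 0..949 price range).
#'
#' @param params A `crc_params` parameter set.
#' @return Named list of distribution specifications (`path`, `family`,
#'   `mean`, `sd`).
#' @export
default_psa_distributions <- function(params = default_parameters()) {
  prob <- function(path) {
    m <- param_get(params, path)
    list(path = path, family = "beta", mean = m,
         sd = 0.10 * min(m, 1 - m))
  }
  cost_pm25 <- function(path) {
    m <- param_get(params, path)
    list(path = path, family = "gamma", mean = m, sd = (0.5 * m) / (2 * 1.96))
  }
  specs <- list(
    prob("tests.colonoscopy.cancer_detection_rate"),
    prob("tests.fit.cancer_sens"), prob("tests.fit.hr_sens"),
    prob("tests.fit.lr_sens"), prob("tests.fit.specificity"),
    prob("tests.sdna.cancer_sens"), prob("tests.sdna.hr_sens"),
    prob("tests.sdna.lr_sens"), prob("tests.sdna.specificity"),
    prob("tests.lb.cancer_sens"), prob("tests.lb.specificity"),
    prob("policy.adherence"),
    cost_pm25("costs.colo_polypectomy"), cost_pm25("costs.colo_no_polypectomy"),
    cost_pm25("costs.fit"), cost_pm25("costs.sdna"),
    list(path = "costs.lb", family = "gamma",
         mean = param_get(params, "costs.lb"),
         sd = param_get(params, "costs.lb") / (2 * 1.96))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "path"))
}

#' Draw one coherent parameter set for probabilistic sensitivity analysis
#'
#' Moment-matched sampling: beta draws for quantities in \[0, 1\] (shape
#' parameters from mean and standard deviation), gamma draws for costs
#' (`shape = (mean/sd)^2`, `scale = sd^2/mean`), degenerate entries passed
#' through unchanged. Sampling the colonoscopy cancer detection rate
#' re-derives the complementary interval cancer rate so the pair still sums
#' to one. Consumes the current RNG stream; seed outside.
#'
#' @param distributions A [default_psa_distributions()]-style list.
#' @param params Base-case `crc_params` parameter set.
#' @return A new parameter set with sampled values.
#' @export
sample_psa_draw <- function(distributions, params) {
  for (spec in distributions) {
    value <- switch(
      spec$family,
      degenerate = spec$mean,
      beta = {
        m <- spec$mean; s <- spec$sd
        if (s == 0) m else {
          if (m * (1 - m) <= s^2) {
            stop(sprintf(
              "sample_psa_draw: infeasible beta moments for '%s' (mean %g, sd %g)",
              spec$path, m, s))
          }
          nu <- m * (1 - m) / s^2 - 1
          stats::rbeta(1, m * nu, (1 - m) * nu)
        }
      },
      gamma = {
        m <- spec$mean; s <- spec$sd
        if (s == 0 || m == 0) m else {
          stats::rgamma(1, shape = (m / s)^2, scale = s^2 / m)
        }
      },
      stop(sprintf("sample_psa_draw: unknown family '%s'", spec$family))
    )
    params <- param_set(params, spec$path, value)
    if (spec$path == "tests.colonoscopy.cancer_detection_rate") {
      params <- param_set(params, "tests.colonoscopy.interval_cancer_rate",
                          1 - value)
    }
  }
  params
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Samples all inputs simultaneously from their distributions, reruns every
#' strategy per iteration, and builds the cost-effectiveness acceptability
#' curve: at each willingness-to-pay value, the fraction of iterations in
#' which each strategy has the highest net monetary benefit
#' (effectiveness x WTP - cost). Fully reproducible for a fixed seed.
#'
#' @param n_iterations Number of Monte Carlo iterations (>= 1).
#' @param seed Integer RNG seed.
#' @param wtp_grid Willingness-to-pay grid (USD per life-year).
#' @param params A calibrated `crc_params` parameter set.
#' @param distributions Distribution set (default
#'   [default_psa_distributions()] of `params`).
#' @param strategies Strategy names.
#' @return A list of class `psa_result`: `n_iterations`, `seed`, `cost` and
#'   `effect` matrices (iteration x strategy), `ceac` (long data frame of
#'   wtp / strategy / probability), and `optimal_at` giving the modal
#'   optimal strategy at the policy WTP.
#' @export
run_psa <- function(n_iterations, seed, wtp_grid = c(5e4, 1e5, 1.5e5, 2e5),
                    params = default_parameters(),
                    distributions = NULL,
                    strategies = c("NH", "FIT", "Colonoscopy", "S-DNA",
                                   "C-LB", "LB")) {
  stopifnot(n_iterations >= 1)
  distributions <- distributions %||% default_psa_distributions(params)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  ns <- length(strategies)
  cost <- matrix(NA_real_, n_iterations, ns,
                 dimnames = list(NULL, strategies))
  effect <- cost
  for (it in seq_len(n_iterations)) {
    p <- sample_psa_draw(distributions, params)
    tab <- run_strategies(p, strategies)
    cost[it, ] <- tab$cost
    effect[it, ] <- tab$effectiveness
  }
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb <- effect * w - cost
    best <- strategies[max.col(nmb, ties.method = "first")]
    data.frame(wtp = w, strategy = strategies,
               probability = vapply(strategies,
                                    function(s) mean(best == s), 0),
               row.names = NULL)
  }))
  nmb_policy <- effect * params$policy$wtp - cost
  best_policy <- strategies[max.col(nmb_policy, ties.method = "first")]
  modal <- names(sort(table(best_policy), decreasing = TRUE))[1]
  structure(list(n_iterations = n_iterations, seed = seed,
                 strategies = strategies, cost = cost, effect = effect,
                 ceac = ceac, wtp_grid = wtp_grid,
                 optimal_at = list(wtp = params$policy$wtp, modal = modal,
                                   share = mean(best_policy == modal))),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %d\n", x$n_iterations,
              x$seed))
  cat(sprintf("  modal cost-effective strategy at $%s/LYG: %s (%.1f%% of iterations)\n",
              format(x$optimal_at$wtp, big.mark = " "), x$optimal_at$modal,
              100 * x$optimal_at$share))
  invisible(x)
}
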