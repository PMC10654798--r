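test_that("varying a parameter neither strategy uses leaves the ICER flat", {
  p <- calibrated_params()
  entry <- one_way_sa("costs.sdna", c(369, 615), c("NH", "LB"), p)
  expect_equal(entry$icer_low, entry$icer_high)
  expect_equal(entry$range, 0)
})

test_that("one-way bounds reproduce a rerun with the edited parameter set", {
  p <- calibrated_params()
  base <- param_get(p, "costs.colo_no_polypectomy")
  bounds <- c(0.75, 1.25) * base
  entry <- one_way_sa("costs.colo_no_polypectomy", bounds,
                      c("NH", "Colonoscopy"), p)
  # independent recomputation with the perturbed cost set
  manual <- vapply(bounds, function(b) {
    p2 <- param_set(p, "costs.colo_no_polypectomy", b)
    a <- accrue_outcomes(run_cohort("NH", p2))
    d <- accrue_outcomes(run_cohort("Colonoscopy", p2))
    (d$discounted_cost - a$discounted_cost) /
      (d$effectiveness - a$effectiveness)
  }, 0)
  expect_equal(c(entry$icer_low, entry$icer_high), manual)
  expect_gt(entry$range, 0)
  expect_error(one_way_sa("costs.nonexistent", c(0, 1), c("NH", "LB"), p),
               "unknown parameter path")
  expect_error(one_way_sa("costs.lb", c(1000, 2000), c("NH", "LB"), p),
               "bracket")
})

test_that("the blood-test ICER against no screening rises with its price", {
  p <- calibrated_params()
  icers <- vapply(c(0, 474.5, 949), function(price) {
    p2 <- param_set(p, "costs.lb", price)
    a <- accrue_outcomes(run_cohort("NH", p2))
    b <- accrue_outcomes(run_cohort("LB", p2))
    (b$discounted_cost - a$discounted_cost) /
      (b$effectiveness - a$effectiveness)
  }, 0)
  expect_true(all(diff(icers) > 0))
})

test_that("threshold search matches the closed-form linear solution", {
  p <- calibrated_params()
  # the model's ICER is linear in a unit cost: fit a + b * price from two
  # evaluations and solve for the crossing analytically
  icer_at <- function(price) {
    p2 <- param_set(p, "costs.lb", price)
    a <- accrue_outcomes(run_cohort("NH", p2))
    b <- accrue_outcomes(run_cohort("LB", p2))
    (b$discounted_cost - a$discounted_cost) /
      (b$effectiveness - a$effectiveness)
  }
  i0 <- icer_at(0); i1 <- icer_at(949)
  slope <- (i1 - i0) / 949
  analytic <- (1e5 - i0) / slope
  th <- threshold_price("costs.lb", c("NH", "LB"), 1e5, c(0, 949),
                        tol = 0.01, p)
  expect_false(th$already_cost_effective)
  expect_false(th$no_crossing)
  expect_equal(th$price, analytic, tolerance = 0.1 / analytic)
  # stability under tolerance halving
  th2 <- threshold_price("costs.lb", c("NH", "LB"), 1e5, c(0, 949),
                         tol = 0.005, p)
  expect_lt(abs(th2$price - th$price), 2 * 0.01)
})

test_that("threshold search flags intervals without a crossing", {
  p <- calibrated_params()
  th_lo <- threshold_price("costs.lb", c("NH", "LB"), 1e5, c(0, 20),
                           tol = 0.01, p)
  expect_true(th_lo$already_cost_effective)
  expect_equal(th_lo$price, 20)
  th_hi <- threshold_price("costs.lb", c("NH", "LB"), 1e5, c(600, 949),
                           tol = 0.01, p)
  expect_true(th_hi$no_crossing)
  expect_equal(th_hi$price, 600)
})

test_that("the base-case blood-test threshold price sits far below list price", {
  p <- calibrated_params()
  th <- threshold_price("costs.lb", c("NH", "LB"), 1e5, c(0, 949),
                        tol = 0.01, p)
  expect_lt(th$price, 300)
  expect_gt(th$price, 0)
})

test_that("granting the blood test polyp sensitivity is a no-op at zero", {
  p <- calibrated_params()
  tab <- run_strategies(p)
  fr <- incremental_analysis(tab[c("strategy", "cost", "effectiveness")])
  base_clb <- fr[fr$strategy == "C-LB", ]
  sc <- scenario_lb_polyp(0, 0, p)
  expect_equal(sc$clb_cost, base_clb$cost)
  expect_equal(sc$clb_effect, base_clb$effectiveness)
  expect_equal(sc$clb_icer, base_clb$icer)
})

test_that("the hybrid ICER falls monotonically in blood-test polyp sensitivity", {
  p <- calibrated_params()
  sc <- scenario_lb_polyp(c(0, 0.1, 0.3), 0.05, p)
  sc <- sc[order(sc$hr_sens), ]
  expect_true(all(diff(sc$clb_icer) < 0))
})

test_that("surveillance interval and end-age scenarios behave as expected", {
  p <- calibrated_params()
  sc <- scenario_intervals_endage(lr_intervals = c(5, 10),
                                  end_ages = c(75, 85), params = p,
                                  strategies = c("NH", "Colonoscopy"))
  out <- sc$outcomes
  base <- out[out$lr_interval == 5 & out$end_age == 75, ]
  base_direct <- run_strategies(p, c("NH", "Colonoscopy"))
  expect_equal(base$cost, base_direct$cost)
  expect_equal(base$effectiveness, base_direct$effectiveness)

  colo <- function(ivl, ea) out[out$lr_interval == ivl & out$end_age == ea &
                                  out$strategy == "Colonoscopy", ]
  # longer low-risk surveillance interval: fewer surveillance colonoscopies
  expect_lt(colo(10, 75)$surveillance_colonoscopies,
            colo(5, 75)$surveillance_colonoscopies)
  # extending screening to 85 cannot reduce life-years
  expect_gte(colo(5, 85)$effectiveness, colo(5, 75)$effectiveness)
  expect_true(all(sc$choices$choice %in% c("NH", "Colonoscopy")))
})

test_that("degenerate distributions reproduce the base case exactly", {
  p <- calibrated_params()
  dists <- lapply(default_psa_distributions(p), function(d) {
    d$family <- "degenerate"; d
  })
  drawn <- sample_psa_draw(dists, p)
  tab_base <- run_strategies(p, c("NH", "LB"))
  tab_drawn <- run_strategies(drawn, c("NH", "LB"))
  expect_identical(tab_base, tab_drawn)
  ps <- run_psa(5, seed = 3, params = p, distributions = dists,
                strategies = c("NH", "Colonoscopy", "LB"))
  at_wtp <- ps$ceac[ps$ceac$wtp == 1e5, ]
  expect_equal(at_wtp$probability[at_wtp$strategy == "Colonoscopy"], 1)
})

test_that("moment matching recovers the stated mean within Monte Carlo error", {
  p <- default_parameters()
  dist_beta <- list(list(path = "tests.lb.cancer_sens", family = "beta",
                         mean = 0.82, sd = 0.04))
  dist_gamma <- list(list(path = "costs.lb", family = "gamma",
                          mean = 949, sd = 242))
  set.seed(99)
  n <- 3000
  beta_draws <- vapply(seq_len(n), function(i) {
    param_get(sample_psa_draw(dist_beta, p), "tests.lb.cancer_sens")
  }, 0)
  gamma_draws <- vapply(seq_len(n), function(i) {
    param_get(sample_psa_draw(dist_gamma, p), "costs.lb")
  }, 0)
  expect_true(all(beta_draws >= 0 & beta_draws <= 1))
  expect_true(all(gamma_draws >= 0))
  expect_equal(mean(beta_draws), 0.82, tolerance = 3 * 0.04 / sqrt(n) / 0.82)
  expect_equal(mean(gamma_draws), 949, tolerance = 3 * 242 / sqrt(n) / 949)
  expect_equal(sd(gamma_draws), 242, tolerance = 0.1)
  expect_error(sample_psa_draw(list(list(path = "tests.lb.cancer_sens",
                                         family = "beta", mean = 0.5,
                                         sd = 0.6)), p),
               "infeasible beta moments.*tests.lb.cancer_sens")
})

test_that("acceptability curves are coherent and seed-reproducible", {
  p <- calibrated_params()
  ps1 <- run_psa(12, seed = 21, wtp_grid = c(0, 5e4, 1e5, 2e5), params = p,
                 strategies = c("NH", "Colonoscopy", "C-LB"))
  ps2 <- run_psa(12, seed = 21, wtp_grid = c(0, 5e4, 1e5, 2e5), params = p,
                 strategies = c("NH", "Colonoscopy", "C-LB"))
  expect_identical(ps1, ps2)
  sums <- tapply(ps1$ceac$probability, ps1$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ref <- ps1$ceac[ps1$ceac$strategy == "NH", ]
  ref <- ref[order(ref$wtp), ]
  expect_true(all(diff(ref$probability) <= 1e-12))
  # sampling the colonoscopy detection rate keeps the complementary pair
  set.seed(1)
  drawn <- sample_psa_draw(default_psa_distributions(p), p)
  expect_equal(drawn$tests$colonoscopy$cancer_detection_rate +
                 drawn$tests$colonoscopy$interval_cancer_rate, 1)
})

test_that("shrinking all spreads collapses the PSA onto the base case", {
  p <- calibrated_params()
  dists <- lapply(default_psa_distributions(p), function(d) {
    d$sd <- d$sd * 1e-4; d
  })
  set.seed(8)
  drawn <- sample_psa_draw(dists, p)
  tab_base <- run_strategies(p, c("NH", "LB"))
  tab_drawn <- run_strategies(drawn, c("NH", "LB"))
  expect_equal(tab_drawn$cost, tab_base$cost, tolerance = 1e-3)
  expect_equal(tab_drawn$effectiveness, tab_base$effectiveness,
               tolerance = 1e-6)
})
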