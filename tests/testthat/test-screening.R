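test_that("screening_due follows the interval grid within the window", {
  expect_true(screening_due(45, 10, 45, 75))
  expect_false(screening_due(76, 1, 45, 75))
  expect_false(screening_due(44, 1, 45, 75))
  # q3y grid: 45, 48, 51, ...
  due <- vapply(45:75, screening_due, TRUE, interval = 3)
  expect_identical(which(due) + 44L, seq(45L, 75L, 3L))
  expect_true(screening_due(51, 3, 45, 75))
  expect_false(screening_due(52, 3, 45, 75))
})

test_that("build_strategy encodes the six arms and rejects unknown names", {
  p <- default_parameters()
  nh <- build_strategy("NH", p)
  expect_length(nh$components, 1)
  expect_identical(nh$components[[1]]$modality, "none")

  fit <- build_strategy("FIT", p)
  expect_equal(fit$components[[1]]$weight, 0.606)
  expect_equal(fit$components[[1]]$interval, 1)

  clb <- build_strategy("C-LB", p)
  mods <- vapply(clb$components, `[[`, "", "modality")
  w <- vapply(clb$components, `[[`, 0, "weight")
  expect_identical(mods, c("colonoscopy", "lb"))
  expect_equal(w, c(0.606, 0.394))
  expect_equal(clb$components[[2]]$interval, 3)

  expect_error(build_strategy("MRI", p), "valid names")
})

test_that("event steps conserve person mass and stay non-negative", {
  p <- calibrated_params()
  states <- health_states()
  set.seed(42)
  for (rep in 1:20) {
    v <- stats::setNames(abs(rnorm(length(states))), states)
    v <- v / sum(v)
    a <- sample(45:85, 1)
    for (mod in c("none", "colonoscopy", "fit", "sdna", "lb")) {
      scr <- apply_screening_cycle(v, a, mod, 3, p)
      expect_equal(sum(scr$state), 1, tolerance = 1e-12)
      expect_true(all(scr$state >= 0))
      expect_true(all(scr$events >= 0))
      sur <- surveillance_cycle(scr$state, a, p)
      expect_equal(sum(sur$state), 1, tolerance = 1e-12)
      expect_true(all(sur$state >= 0))
    }
  }
})

test_that("a lesion-free cohort screened by blood test false-positives at 1 - specificity", {
  p <- default_parameters()
  states <- health_states()
  v <- stats::setNames(numeric(length(states)), states)
  v[["healthy"]] <- 1
  out <- apply_screening_cycle(v, 45, "lb", 3, p)
  expect_equal(unname(out$events[["false_positives"]]), 0.005)
  expect_equal(unname(out$events[["followup_colonoscopies"]]), 0.005)
  # the no-screening arm leaves the state untouched with zero events
  nh <- apply_screening_cycle(v, 45, "none", NA, p)
  expect_identical(nh$state, v)
  expect_true(all(nh$events == 0))
  expect_equal(nh$cost, 0)
})

test_that("zero-adherence strategies reproduce natural history exactly", {
  p <- calibrated_params()
  p$policy$adherence <- 0
  p$policy$lb_adherence <- 0
  nh <- run_cohort("NH", p)
  for (nm in c("FIT", "Colonoscopy", "S-DNA", "LB")) {
    tr <- run_cohort(nm, p)
    expect_equal(max(abs(tr$occupancy - nh$occupancy)), 0)
    expect_equal(max(abs(tr$cycles$cost - nh$cycles$cost)), 0)
  }
})

test_that("a null blood test is indistinguishable from no screening", {
  p <- calibrated_params()
  p$tests$lb <- list(cancer_sens = 0, hr_sens = 0, lr_sens = 0,
                     specificity = 1)
  p$costs$lb <- 0
  nh <- run_cohort("NH", p)
  lb <- run_cohort("LB", p)
  expect_lt(max(abs(lb$occupancy - nh$occupancy)), 1e-12)
  expect_lt(max(abs(lb$cycles$cost - nh$cycles$cost)), 1e-12)
  expect_lt(abs(accrue_outcomes(lb)$effectiveness -
                  accrue_outcomes(nh)$effectiveness), 1e-12)
})

test_that("raising any sensitivity never hurts life-years or cancer mortality", {
  p <- calibrated_params()
  grids <- list(
    c("tests.lb.cancer_sens", "LB"),
    c("tests.fit.hr_sens", "FIT"),
    c("tests.sdna.cancer_sens", "S-DNA"),
    c("tests.fit.lr_sens", "FIT")
  )
  for (g in grids) {
    path <- g[1]; strat <- g[2]
    vals <- c(0.2, 0.6, 0.95)
    runs <- lapply(vals, function(s) {
      accrue_outcomes(run_cohort(strat, param_set(p, path, s)))
    })
    lyg <- vapply(runs, `[[`, 0, "effectiveness")
    mort <- vapply(runs, `[[`, 0, "crc_mortality")
    expect_true(all(diff(lyg) >= -1e-12),
                label = paste("LYG monotone in", path))
    expect_true(all(diff(mort) <= 1e-12),
                label = paste("mortality anti-monotone in", path))
  }
})

test_that("surveillance tunnels advance yearly and fire at the interval end", {
  p <- default_parameters()
  states <- health_states()
  v <- stats::setNames(numeric(length(states)), states)
  v[["hr_surv_1"]] <- 1
  out <- surveillance_cycle(v, 60, p)
  expect_identical(out$state, v)  # mid-tunnel: no colonoscopy event
  expect_equal(unname(out$events[["surveillance_colonoscopies"]]), 0)
  M <- nh_transition_matrix(60, p)
  moved <- drop(v %*% M)
  expect_gt(moved[["hr_surv_2"]], 0.9)  # advanced one tunnel year

  v2 <- stats::setNames(numeric(length(states)), states)
  v2[["hr_surv_3"]] <- 0.4
  v2[["healthy"]] <- 0.6
  out2 <- surveillance_cycle(v2, 60, p)
  expect_equal(unname(out2$events[["surveillance_colonoscopies"]]), 0.4)
  expect_equal(out2$state[["hr_surv_3"]], 0)
  expect_equal(out2$state[["hr_surv_0"]] + out2$state[["lr_surv_0"]], 0.4)

  # beyond the surveillance stop age no colonoscopies occur
  out3 <- surveillance_cycle(v2, 86, p)
  expect_identical(out3$state, v2)
  expect_true(all(out3$events == 0))
})
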