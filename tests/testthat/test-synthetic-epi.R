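test_that("degenerate hazard gives a constant annual death probability", {
  lt <- generate_life_table(list(makeham = 0.01, gompertz_coef = 0,
                                 gompertz_rate = 0))
  expect_equal(unique(lt$value), 1 - exp(-0.01))
})

test_that("default life table is monotone with a realistic life expectancy", {
  lt <- generate_life_table()
  expect_true(all(diff(lt$value) >= 0))
  expect_true(all(lt$value > 0 & lt$value < 1))
  le45 <- life_expectancy(lt)
  expect_gt(le45, 33)
  expect_lt(le45, 40)
  expect_gt(schedule_at(lt, 100), schedule_at(lt, 45))
})

test_that("life table rejects bad hazards and age ranges", {
  expect_error(generate_life_table(list(makeham = 50)), "outside")
  expect_error(generate_life_table(age_range = 50:100), "45\\.\\.100")
  expect_error(generate_life_table(list(makeham = -0.1)), "non-negative")
})

test_that("null incidence curve produces a cancer-free natural history", {
  inc <- generate_crc_incidence(list(rate_at_45 = 0, log_slope = 0))
  expect_true(all(inc$value == 0))
  p <- default_parameters()
  p$epi$incidence <- inc
  p$rates$incidence_scale <- 1
  tr <- run_component("none", NA, p)
  expect_equal(tr$lifetime_incidence, 0)
  expect_equal(tr$crc_mortality, 0)
})

test_that("default incidence curve carries a ~5% lifetime risk and scales", {
  inc <- generate_crc_incidence()
  lt <- generate_life_table()
  expect_true(all(diff(schedule_at(inc, 45:85)) >= 0))
  cum <- cumulative_incidence(inc, lt)
  expect_gt(cum, 0.045)
  expect_lt(cum, 0.060)
  # doubling every value strictly increases cohort lifetime incidence
  p <- default_parameters()
  base <- run_component("none", NA, p)$lifetime_incidence
  p2 <- p
  p2$epi$incidence <- age_schedule(p$epi$incidence$age,
                                   pmin(2 * p$epi$incidence$value, 0.05),
                                   role = "probability")
  expect_gt(run_component("none", NA, p2)$lifetime_incidence, base)
  expect_error(generate_crc_incidence(list(rate_at_45 = 0.01,
                                           log_slope = 0.1)),
               "0.05")
})

test_that("zero polyp onset leaves the cohort polyp-free", {
  p <- default_parameters()
  p$rates$onset_scale <- 0
  tr <- run_component("none", NA, p)
  expect_true(all(tr$occupancy[, "lr_polyp"] == 0))
  expect_true(all(tr$occupancy[, "hr_polyp"] == 0))
})

test_that("high-risk prevalence target lies below low-risk at every age", {
  pol <- generate_polyp_schedules()
  ages <- 46:100
  expect_true(all(schedule_at(pol$hr_prev_target, ages) <
                    schedule_at(pol$lr_prev_target, ages)))
  expect_error(generate_polyp_schedules(list(lr_prev_max = 1.5)), "\\[0, 1\\)")
})

test_that("stage inputs are validated as a screen-shifted pair of simplices", {
  s <- generate_stage_inputs()
  expect_equal(sum(s$stage_sympt), 1, tolerance = 1e-9)
  expect_equal(sum(s$stage_screen), 1, tolerance = 1e-9)
  expect_gte(s$stage_screen[["local"]], s$stage_sympt[["local"]])
  expect_true(s$cancer_death[["distant"]] > s$cancer_death[["regional"]])
  expect_true(s$cancer_death[["regional"]] > s$cancer_death[["local"]])
  expect_error(generate_stage_inputs(list(stage_sympt = c(0.5, 0.5, 0.5))),
               "summing to 1")
  expect_error(generate_stage_inputs(
    list(stage_screen = c(local = 0.2, regional = 0.3, distant = 0.5))),
    "later-stage")
  expect_error(generate_stage_inputs(
    list(cancer_death = c(local = 0.3, regional = 0.2, distant = 0.1))),
    "distant > regional > local")
})

test_that("certain lethality in distant stage is absorbing within one cycle", {
  p <- default_parameters(default_epi_tables(
    stages = list(cancer_death = c(local = 0.02, regional = 0.10,
                                   distant = 1.0))))
  p$rates$death_scale <- 1
  tr <- run_component("none", NA, p)
  # nobody ever survives a year in the distant stage
  expect_true(all(tr$occupancy[, "ca_distant_cont"] == 0))
})

test_that("generators are pure functions of their parameters", {
  expect_identical(generate_life_table(), generate_life_table())
  expect_identical(generate_crc_incidence(), generate_crc_incidence())
  expect_identical(generate_polyp_schedules(), generate_polyp_schedules())
  expect_identical(default_epi_tables(), default_epi_tables())
})
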