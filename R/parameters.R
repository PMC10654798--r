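#' Default model parameter set
#'
#' Assembles the complete input bundle: synthetic epidemiology, natural
#' history rates (pre-calibration), test performance, costs (2022 USD) and
#' policy constants. Test performance and cost defaults are the published
#' base-case inputs: FIT 73.8/23.8/7.6 sensitivity (cancer/HR polyp/LR
#' polyp) with 96.4 specificity, stool DNA 92.3/42.4/17.2 with 89.8,
#' liquid biopsy 82.0 cancer sensitivity with 99.5 specificity and no polyp
#' detection, colonoscopy 92.8 cancer detection rate with the 7.2
#' complementary interval-cancer rate and age-banded polyp sensitivity.
#'
#' @param epi Optional `epi_tables` bundle (defaults to
#'   [default_epi_tables()]).
#' @return A nested named list of class `crc_params`.
#' @export
default_parameters <- function(epi = default_epi_tables()) {
  ages <- 45:100
  params <- list(
    epi = epi,
    rates = list(
      onset_scale = 1,            # calibrated: scales epi$lr_onset
      lr_to_hr = 0.05,            # calibrated: annual LR -> HR progression
      hr_cancer_mult = 20,        # HR-polyp cancer risk multiplier on baseline incidence
      direct_cancer_fraction = 0.15, # share of incidence risk bypassing the polyp pathway
      incidence_scale = 1,        # calibrated: scales baseline incidence
      death_scale = 1             # calibrated: scales stage lethality
    ),
    tests = list(
      colonoscopy = list(
        cancer_detection_rate = 0.928,
        interval_cancer_rate = 0.072,
        hr_sens = banded_schedule(c(45, 65, 80), c(0.95, 0.92, 0.89),
                                  "probability", "colonoscopy_hr_sens"),
        lr_sens = banded_schedule(c(45, 65, 80), c(0.85, 0.80, 0.75),
                                  "probability", "colonoscopy_lr_sens")
      ),
      fit = list(cancer_sens = 0.738, hr_sens = 0.238, lr_sens = 0.076,
                 specificity = 0.964),
      sdna = list(cancer_sens = 0.923, hr_sens = 0.424, lr_sens = 0.172,
                  specificity = 0.898),
      lb = list(cancer_sens = 0.820, hr_sens = 0, lr_sens = 0,
                specificity = 0.995)
    ),
    costs = list(
      colo_polypectomy = 1366,
      colo_no_polypectomy = 1119,
      fit = 52,
      sdna = 492,
      lb = 949,
      # 3 stages x 3 phases of care
      cancer = matrix(c(42347, 3941, 14158,
                        56019, 8188, 25270,
                        55705, 27586, 34464),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("local", "regional", "distant"),
                                      c("first_year", "continuing",
                                        "final_year"))),
      complication = age_schedule(
        ages, 6000 + 120 * (ages - 45), role = "cost",
        name = "colonoscopy_complication_cost")
    ),
    complications = list(
      prob = age_schedule(
        ages, pmin(0.001 * exp(0.045 * (ages - 45)), 0.02),
        role = "probability", name = "colonoscopy_complication_prob")
    ),
    policy = list(
      start_age = 45,
      stop_age = 75,
      surveillance_stop_age = 85,
      max_age = 100,
      adherence = 0.606,
      lb_adherence = 1.0,
      intervals = c(colonoscopy = 10, fit = 1, sdna = 3, lb = 3),
      hr_surveillance_interval = 3,
      lr_surveillance_interval = 5,
      discount_rate = 0.03,
      wtp = 1e5,
      discount_lyg = FALSE,  # published life-year totals are undiscounted
      half_cycle = FALSE
    )
  )
  class(params) <- "crc_params"
  params
}

#' @export
print.crc_params <- function(x, ...) {
  cat("<crc_params> Markov screening model parameter set\n")
  cat(sprintf("  ages %d..%d, screen stop %d, surveillance stop %d\n",
              x$policy$start_age, x$policy$max_age, x$policy$stop_age,
              x$policy$surveillance_stop_age))
  cat(sprintf("  adherence %.1f%%, discount %.1f%%, WTP $%s/LYG\n",
              100 * x$policy$adherence, 100 * x$policy$discount_rate,
              format(x$policy$wtp, big.mark = " ")))
  cat(sprintf("  calibration scales: onset %.3g, incidence %.3g, death %.3g, LR->HR %.3g\n",
              x$rates$onset_scale, x$rates$incidence_scale,
              x$rates$death_scale, x$rates$lr_to_hr))
  invisible(x)
}

#' Read a parameter by dotted path
#'
#' Addresses scalars inside the nested parameter list, e.g.
#' `param_get(params, "costs.lb")` or `param_get(params,
#' "tests.lb.cancer_sens")`.
#'
#' @param params A `crc_params` object.
#' @param path Dotted path string.
#' @return The value at the path.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop(sprintf("unknown parameter path: '%s' (failed at '%s')", path, k))
    }
    node <- node[[k]]
  }
  node
}

#' Set a parameter by dotted path
#'
#' @inheritParams param_get
#' @param value Replacement value.
#' @return The modified parameter set.
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  param_get(params, path)  # validates the path exists
  expr <- paste0("params", paste0("[['", keys, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  params
}

#' Health-state labels of the cohort model
#'
#' Order: healthy, undetected low-risk polyp, undetected high-risk polyp,
#' low-risk surveillance tunnel (year 0 = polypectomy year .. interval),
#' high-risk surveillance tunnel, six diagnosed-cancer states (first-year
#' and continuing, by stage), and the two absorbing death states.
#'
#' @param lr_interval,hr_interval Surveillance intervals in years; the
#'   tunnel has `interval + 1` positions so that surveillance colonoscopies
#'   recur exactly every `interval` years under the events-then-transitions
#'   cycle order.
#' @return Character vector of state names.
#' @export
health_states <- function(lr_interval = 5, hr_interval = 3) {
  stopifnot(lr_interval >= 1, hr_interval >= 1)
  c("healthy", "lr_polyp", "hr_polyp",
    paste0("lr_surv_", 0:lr_interval),
    paste0("hr_surv_", 0:hr_interval),
    "ca_local_y1", "ca_local_cont",
    "ca_regional_y1", "ca_regional_cont",
    "ca_distant_y1", "ca_distant_cont",
    "dead_crc", "dead_other")
}

# 32-bit polynomial rolling hash over the serialized configuration; used only
# to label output artifacts with the inputs they came from.
config_hash <- function(params) {
  bytes <- as.integer(charToRaw(paste(
    utils::capture.output(utils::str(params, digits.d = 12, list.len = 1e4)),
    collapse = "\n")))
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
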