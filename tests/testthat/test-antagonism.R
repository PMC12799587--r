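# Antagonism module: Gaddum dose ratios, Schild regression, Stephenson's
# matched-response method, and conformation affinity ratios.

blocked_at <- function(ctl, conc, dr, emax = NULL) {
  list(conc = conc,
       fit = one_site_at(ctl$logEC50 + log10(dr),
                         emax = if (is.null(emax)) ctl$Emax_pct else emax))
}

test_that("a dose ratio of 2 at [B] = KD returns the KD exactly", {
  ctl <- one_site_at(-8)
  ex <- shift_experiment(ctl, list(blocked_at(ctl, 1e-9, 2)),
                         antagonist_id = "ant", agonist_id = "ago")
  est <- gaddum_kd(ex)
  expect_lt(abs(est$logKd - (-9)), 1e-6)
  # and DR = 11 at 10x KD gives the same answer
  ex2 <- shift_experiment(ctl, list(blocked_at(ctl, 1e-8, 11)))
  expect_lt(abs(gaddum_kd(ex2)$logKd - (-9)), 1e-6)
})

test_that("no measurable shift yields a censored estimate, not a number", {
  ctl <- one_site_at(-8)
  ex <- shift_experiment(ctl, list(blocked_at(ctl, 1e-5, 1.05)),
                         antagonist_id = "ant")
  est <- gaddum_kd(ex)
  expect_true(is_censored(est))
  expect_equal(est$censored$direction, ">")
  expect_equal(est$censored$bound, -5)
})

test_that("a depressed plateau triggers the parallel-shift warning", {
  ctl <- one_site_at(-8, emax = 100)
  ex <- shift_experiment(ctl, list(blocked_at(ctl, 1e-8, 5, emax = 50)))
  expect_warning(gaddum_kd(ex), "parallel")
})

test_that("shift experiments validate their antagonist concentrations", {
  ctl <- one_site_at(-8)
  expect_error(shift_experiment(ctl, list(blocked_at(ctl, 0, 2))),
               "positive and distinct")
  expect_error(shift_experiment(ctl, list(blocked_at(ctl, 1e-9, 2),
                                          blocked_at(ctl, 1e-9, 3))),
               "positive and distinct")
})

test_that("exact Gaddum shifts give a Schild line with unit slope through the KD", {
  kd <- 10^-9.47
  ctl <- one_site_at(-8.07)
  concs <- c(1e-9, 1e-8, 1e-7)
  ex <- shift_experiment(ctl, lapply(concs, function(b)
    blocked_at(ctl, b, 1 + b / kd)), antagonist_id = "ant")
  sf <- suppressWarnings(schild_fit(ex))   # lm() flags the exact fit
  expect_lt(abs(sf$slope - 1), 1e-6)
  expect_lt(abs(sf$intercept_logKd - (-9.47)), 1e-6)
  expect_true(sf$competitive)
})

test_that("noisy Schild slopes stay within three standard errors of unity", {
  kd <- 1e-9
  conc <- 10^seq(-11, -5, by = 0.5)
  concs_b <- c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7)
  set.seed(21)
  fit_noisy <- function(le) {
    pct <- eq_one_site(conc, 100, 10^le) + matrix(rnorm(39, 0, 5), ncol = 3)
    fit_one_site(as_curve(conc, pct))
  }
  ctl <- fit_noisy(-8)
  ex <- shift_experiment(ctl, lapply(concs_b, function(b)
    list(conc = b, fit = fit_noisy(-8 + log10(1 + b / kd)))))
  sf <- schild_fit(ex)
  expect_lt(abs(sf$slope - 1), 3 * sf$se_slope)
})

test_that("a saturable shift produces a Schild slope below one", {
  ctl <- one_site_at(-8)
  concs_b <- c(1e-9, 1e-8, 1e-7, 1e-6)
  # dose ratio saturates instead of growing linearly in [B]
  ex <- shift_experiment(ctl, lapply(concs_b, function(b)
    blocked_at(ctl, b, 1 + 100 * b / (b + 1e-7))))
  sf <- schild_fit(ex)
  expect_lt(sf$slope, 0.8)
})

test_that("uninformative Schild points are excluded, and too few points stop", {
  ctl <- one_site_at(-8)
  ex <- shift_experiment(ctl, list(blocked_at(ctl, 1e-10, 1.0),
                                   blocked_at(ctl, 1e-9, 2),
                                   blocked_at(ctl, 1e-8, 11)))
  expect_warning(expect_error(schild_fit(ex), ">= 3"), "excluded")
})

test_that("Stephenson's equation evaluates matched readings directly", {
  r <- stephenson_eq(P = 1e-8, A1 = 3e-9, A2 = 3e-8, A3 = 1e-7)
  expect_equal(r$Y, 0.27)
  expect_equal(signif(r$Kd * 1e9, 3), 3.70)
  r2 <- stephenson_eq(P = 1e-9, A1 = 1e-9, A2 = 2e-9, A3 = 2e-9)
  expect_equal(r2$Y, 0.5)
  expect_equal(r2$Kd, 1e-9)
  expect_error(stephenson_eq(1e-9, 2e-9, 1e-9, 1e-9), "A2 > A1")
  expect_error(stephenson_eq(1e-9, 1e-9, 2e-9, 1e-12), "\\(0, 1\\)")
})

test_that("Stephenson's method recovers a partial agonist's KD from simulated plates", {
  full <- ground_truth("full", logKd_cce = -6.43, efficacy_cce = 1,
                       mode = "cce_agonist")
  part <- ground_truth("part", logKd_cce = -9, efficacy_cce = 0.05,
                       mode = "cce_agonist")
  cfg <- sim_config(list(full, part), receptor_expression = 40, noise_sd = 0)
  ctl <- fit_one_site(normalize_plate(simulate_functional_curve(cfg, "full")))
  comb <- normalize_plate(simulate_functional_curve(
    cfg, "full", fixed_antagonist = list(compound = "part", conc = 1e-8)))
  est <- stephenson_kd(ctl, comb, P = 1e-8)
  expect_lt(abs(est$logKd - (-9)), 0.1)
  # matched levels agree with each other on noiseless data
  expect_lt(est$se, 1e-2)
})

test_that("Stephenson's method refuses a plateau at the system maximum", {
  full <- ground_truth("full", logKd_cce = -6.43, efficacy_cce = 1,
                       mode = "cce_agonist")
  other <- ground_truth("other", logKd_cce = -8, efficacy_cce = 1,
                        mode = "cce_agonist")
  cfg <- sim_config(list(full, other), receptor_expression = 40, noise_sd = 0)
  ctl <- fit_one_site(normalize_plate(simulate_functional_curve(cfg, "full")))
  comb <- normalize_plate(simulate_functional_curve(
    cfg, "full", fixed_antagonist = list(compound = "other", conc = 1e-5)))
  expect_error(stephenson_kd(ctl, comb, P = 1e-5), "plateau")
  expect_error(stephenson_kd(ctl, comb, P = 0), "must be positive")
})

test_that("conformation log-ratios reproduce the printed values and censor correctly", {
  r <- conformation_ratio(-10.19, -6.64)
  expect_equal(r$log_ratio, 3.55)
  expect_null(r$censored)
  expect_equal(conformation_ratio(-7.21, -5.57)$log_ratio, 1.64)
  expect_equal(conformation_ratio(-8, -8)$log_ratio, 0)
  cens <- affinity_estimate(NA, method = "gaddum",
                            censored = list(direction = ">", bound = -5))
  point <- affinity_estimate(-8, method = "gaddum")
  up <- conformation_ratio(point, cens)
  expect_equal(up$censored, ">")
  expect_equal(up$log_ratio, 3)
  down <- conformation_ratio(cens, point)
  expect_equal(down$censored, "<")
  both <- conformation_ratio(cens, cens)
  expect_true(is.na(both$log_ratio))
})
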