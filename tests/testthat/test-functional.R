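# Functional module: normalisation, one-site / two-site / dip fits,
# nested model selection with guards, and grid-search oracles.

test_that("normalisation maps basal to 0 and the positive-control mean to 100", {
  conc <- 10^seq(-10, -6, by = 0.5)
  raw <- conc_series("cmp", conc, matrix(500 + 45 * 54, length(conc), 3),
                     controls = list(basal = c(490, 500, 510),
                                     positive = c(4990, 5000, 5010)),
                     meta = list(cell_line = "lineX"))
  nc <- normalize_plate(raw)
  expect_equal(unname(nc$response[1, 1]), 54, tolerance = 1e-12)
  expect_equal(nc$basal_pct, 0)
  raw$controls$positive <- NULL
  expect_error(normalize_plate(raw), "basal and positive")
  inv <- conc_series("cmp", conc, matrix(500, length(conc), 3),
                     controls = list(basal = rep(5000, 3), positive = rep(500, 3)))
  expect_error(normalize_plate(inv), "no assay window")
})

test_that("a noiseless one-site curve returns its parameters essentially exactly", {
  conc <- 10^seq(-10.5, -5.5, by = 0.5)
  fit <- fit_one_site(as_curve(conc, eq_one_site(conc, 106.2, 10^-8.07)))
  expect_lt(abs(fit$logEC50 - (-8.07)), 1e-4)
  expect_lt(abs(fit$Emax_pct - 106.2), 1e-2)
  expect_false(fit$unidentifiable)
})

test_that("a flat curve is flagged unidentifiable instead of given an EC50", {
  conc <- 10^seq(-10.5, -5.5, by = 0.5)
  fit <- fit_one_site(as_curve(conc, matrix(10, 11, 3)))
  expect_true(fit$unidentifiable)
})

test_that("the one-site fit matches a brute-force grid search on noisy 8-point data", {
  conc <- 10^seq(-10.5, -5.25, by = 0.75)
  set.seed(11)
  pct <- eq_one_site(conc, 60, 10^-8) + matrix(rnorm(16, 0, 4), ncol = 2)
  fit <- fit_one_site(as_curve(conc, pct))
  x <- rep(conc, 2); y <- as.vector(pct)
  oracle <- grid2(function(em, le) sum((y - eq_one_site(x, em, 10^le))^2),
                  seq(30, 100, length.out = 100), seq(-10.5, -5.25, length.out = 100))
  expect_lt(abs(fit$logEC50 - oracle$par[2]), 0.02)
})

test_that("a noiseless two-site curve returns both components and the split", {
  conc <- 10^seq(-11, -5, by = 0.5)
  pct <- eq_two_site(conc, 23.7, 23.3, 10^-9.27, 10^-7.24)
  fit <- fit_two_site_stim(as_curve(conc, pct))
  expect_lt(abs(fit$logEC1_50 - (-9.27)), 1e-3)
  expect_lt(abs(fit$logEC2_50 - (-7.24)), 1e-3)
  expect_lt(abs(fit$site1_pct - 23.3), 0.05)
  expect_lt(abs(fit$total_Emax_pct - 23.7), 0.05)
  expect_false(fit$collapsed)
})

test_that("the two-site model with a 100% first component reduces to one site", {
  A <- 10^seq(-11, -5, by = 0.5)
  expect_equal(eq_two_site(A, 50, 100, 1e-9, 1e-7),
               eq_one_site(A, 50, 1e-9), tolerance = 1e-12)
})

test_that("the two-site fit reaches the grid-search optimum on noisy data", {
  conc <- 10^seq(-11, -5, by = 0.5)
  set.seed(5)
  pct <- eq_two_site(conc, 40, 35, 10^-9.3, 10^-7) + matrix(rnorm(39, 0, 1.5), ncol = 3)
  fit <- fit_two_site_stim(as_curve(conc, pct))
  x <- rep(conc, 3); y <- as.vector(pct)
  oracle <- grid_two_site(x, y, -11, -5)
  expect_lte(fit$rss, oracle$rss * 1.01)
  expect_lt(abs(fit$logEC1_50 - oracle$par[1]), 0.02)
  expect_lt(abs(fit$logEC2_50 - oracle$par[2]), 0.02)
})

test_that("the richer model never fits worse than the one nested inside it", {
  conc <- 10^seq(-11, -5, by = 0.5)
  set.seed(8)
  pct <- eq_one_site(conc, 50, 1e-8) + matrix(rnorm(39, 0, 3), ncol = 3)
  one <- fit_one_site(as_curve(conc, pct))
  two <- fit_two_site_stim(as_curve(conc, pct))
  expect_lte(two$rss, one$rss * 1.001)
})

test_that("model selection keeps the simplest adequate model", {
  conc <- 10^seq(-11, -5, by = 0.5)
  set.seed(4)
  one_pct <- eq_one_site(conc, 60, 1e-8) + matrix(rnorm(39, 0, 2), ncol = 3)
  expect_equal(select_cr_model(as_curve(conc, one_pct))$chosen, "one_site")
  two_pct <- eq_two_site(conc, 40, 35, 10^-9.3, 10^-7) + matrix(rnorm(39, 0, 1.5), ncol = 3)
  expect_equal(select_cr_model(as_curve(conc, two_pct))$chosen, "two_site")
  flat_pct <- matrix(rnorm(39, 0, 2), ncol = 3)
  expect_equal(select_cr_model(as_curve(conc, flat_pct))$chosen, "flat")
})

test_that("a significant but unbalanced second site is conservatively reported as one site", {
  conc <- 10^seq(-11, -5, by = 0.5)
  set.seed(6)
  # second component carries only 5% of the total: below the 10% share guard
  pct <- eq_two_site(conc, 50, 95, 10^-9.5, 10^-6.5) +
    matrix(rnorm(13 * 9, 0, 0.8), ncol = 9)
  ch <- select_cr_model(as_curve(conc, pct))
  expect_equal(ch$chosen, "one_site")
  expect_lt(ch$p_value, 0.05)
  expect_match(ch$diagnostics, "guard")
})

test_that("a noiseless dip curve returns both limbs exactly", {
  conc <- 10^seq(-11, -5, by = 0.5)
  pct <- eq_dip(conc, 0, 75, 10^-8.6, 40, 10^-7.2)
  curve <- as_curve(conc, pct, control_pct = 75,
                    meta = list(fixed_reference = list(compound = "ref", conc = 3e-8)))
  fit <- fit_dip(curve)
  expect_lt(abs(fit$logIC50 - (-8.6)), 1e-4)
  expect_lt(abs(fit$logEC50 - (-7.2)), 1e-4)
  expect_lt(abs(fit$Smax_pct - 40), 0.01)
  expect_lt(fit$rss, 1e-6)
})

test_that("the dip fit requires a control level above basal", {
  conc <- 10^seq(-11, -5, by = 0.5)
  curve <- as_curve(conc, matrix(10, 13, 2))
  expect_error(fit_dip(curve), "control level")
  curve2 <- as_curve(conc, matrix(10, 13, 2), control_pct = -2)
  expect_error(fit_dip(curve2), "must exceed basal")
})

test_that("dip selection distinguishes composite, monotone and flat shapes", {
  conc <- 10^seq(-11, -5, by = 0.5)
  meta <- list(fixed_reference = list(compound = "ref", conc = 3e-8))
  set.seed(9)
  dip_pct <- eq_dip(conc, 0, 75, 10^-8.6, 40, 10^-7.2) +
    matrix(rnorm(13 * 6, 0, 2), ncol = 6)
  ch <- select_cr_model(as_curve(conc, dip_pct, control_pct = 75, meta = meta))
  expect_equal(ch$chosen, "dip")
  expect_lt(ch$p_value, 0.05)
  expect_lt(ch$p_value_second, 0.05)
  inh_pct <- 75 * (1 - conc / (conc + 1e-8)) + matrix(rnorm(13 * 6, 0, 2), ncol = 6)
  ch2 <- select_cr_model(as_curve(conc, inh_pct, control_pct = 75, meta = meta))
  expect_equal(ch2$chosen, "inhibition")
  flat_pct <- 75 + matrix(rnorm(13 * 6, 0, 2), ncol = 6)
  ch3 <- select_cr_model(as_curve(conc, flat_pct, control_pct = 75, meta = meta))
  expect_equal(ch3$chosen, "flat")
})

test_that("unseparated limbs are not called a dip", {
  conc <- 10^seq(-11, -5, by = 0.5)
  meta <- list(fixed_reference = list(compound = "ref", conc = 3e-8))
  set.seed(10)
  # stimulation begins below the inhibitory IC50: no observable trough
  pct <- eq_dip(conc, 0, 75, 10^-7, 40, 10^-7.2) +
    matrix(rnorm(13 * 6, 0, 2), ncol = 6)
  ch <- select_cr_model(as_curve(conc, pct, control_pct = 75, meta = meta))
  expect_false(ch$chosen == "dip")
})

test_that("the dip fit matches its grid-search oracle on noisy data", {
  conc <- 10^seq(-11, -5, by = 0.5)
  set.seed(13)
  pct <- eq_dip(conc, 0, 75, 10^-8.6, 40, 10^-7.2) +
    matrix(rnorm(13 * 3, 0, 2), ncol = 3)
  curve <- as_curve(conc, pct, control_pct = 75,
                    meta = list(fixed_reference = list(compound = "ref", conc = 3e-8)))
  fit <- fit_dip(curve, control_pct = 75, basal_pct = 0)
  x <- rep(conc, 3); y <- as.vector(pct)
  oracle <- grid_dip(x, y, 0, 75, -11, -5)
  expect_lt(abs(fit$logIC50 - oracle$par[1]), 0.02)
  expect_lt(abs(fit$logEC50 - oracle$par[2]), 0.02)
})
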