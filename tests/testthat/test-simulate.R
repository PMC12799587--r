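# Forward simulator: determinism, closed-form noiseless means, ground-truth
# invariants and panel structure.

test_that("ground truth declarations enforce their invariants", {
  expect_error(ground_truth("x", logKd_cce = -2, mode = "neutral"),
               "must lie in \\[-12, -3\\]")
  expect_error(ground_truth("x", logKd_cce = -8, efficacy_cce = 1.5,
                            mode = "cce_agonist"),
               "efficacies")
  expect_error(ground_truth("x", logKd_cce = -8, efficacy_cce = 0.2,
                            mode = "nonbinder"),
               "zero efficacy")
  expect_error(ground_truth("x", logKd_cce = -7, logKd_sce = -9,
                            efficacy_cce = 0.1, efficacy_sce = 0.1,
                            mode = "biphasic"),
               "logKd_sce > logKd_cce")
  gt <- ground_truth("x", logKd_cce = -9, logKd_sce = -7,
                     efficacy_cce = 0.01, efficacy_sce = 0.2, mode = "biphasic")
  expect_s3_class(gt, "ground_truth")
})

test_that("a fixed seed reproduces the study bundle bit for bit", {
  b1 <- make_study_fixture(seed = 3)
  b2 <- make_study_fixture(seed = 3)
  expect_identical(b1, b2)
  b3 <- make_study_fixture(seed = 4)
  expect_false(identical(b1$plates[[1]]$signal, b3$plates[[1]]$signal))
})

test_that("the study panel covers every qualitative compound class", {
  b <- make_study_fixture(seed = 1)
  modes <- vapply(b$ground_truth$wt, `[[`, "", "mode")
  expect_true(all(c("nonbinder", "neutral", "cce_agonist",
                    "sce_agonist", "biphasic") %in% modes))
  expect_equal(length(b$ground_truth$wt), 19)
  # every plate carries finite non-negative signals
  ok <- vapply(b$plates, function(p) all(is.finite(p$signal)) && all(p$signal >= 0), TRUE)
  expect_true(all(ok))
})

test_that("noiseless competition plates sit exactly on the inverse Cheng-Prusoff IC50", {
  gt <- ground_truth("cmp", logKd_cce = -9.29, mode = "neutral")
  cfg <- sim_config(gt, radioligand_conc = 0.71e-9,
                    radioligand_logKd = log10(0.42e-9), noise_sd = 0)
  plate <- simulate_binding_plate(cfg, "cmp", assay = "competition")
  fit <- fit_competition(plate)
  ic50_expected <- log10(10^-9.29 * (1 + 0.71 / 0.42))
  expect_lt(abs(fit$logIC50 - ic50_expected), 1e-5)
  est <- cheng_prusoff(fit, cfg$radioligand_conc, 10^cfg$radioligand_logKd)
  expect_lt(abs(est$logKd - (-9.29)), 1e-5)
})

test_that("noiseless saturation plates return the radioligand affinity", {
  gt <- ground_truth("cmp", logKd_cce = -8, mode = "neutral")
  cfg <- sim_config(gt, radioligand_logKd = log10(0.42e-9), noise_sd = 0)
  plate <- simulate_binding_plate(cfg, "cmp", assay = "saturation")
  fit <- fit_saturation(plate)
  expect_lt(abs(fit$logKd - log10(0.42e-9)), 1e-5)
})

test_that("nonbinders give flat plates in both assays", {
  gt <- ground_truth("none", mode = "nonbinder")
  cfg <- sim_config(gt, noise_sd = 0)
  comp <- simulate_binding_plate(cfg, "none", assay = "competition")
  expect_lt(diff(range(comp$signal)), 1e-9)
  fun <- simulate_functional_curve(cfg, "none")
  expect_true(all(fun$signal == 500))   # plate basal
})

test_that("neutral binders are functionally silent but compete for the radioligand", {
  gt <- ground_truth("neut", logKd_cce = -8.29, mode = "neutral")
  cfg <- sim_config(gt, noise_sd = 0)
  fun <- simulate_functional_curve(cfg, "neut")
  expect_true(all(fun$signal == 500))
  comp <- simulate_binding_plate(cfg, "neut", assay = "competition")
  expect_gt(diff(range(rowMeans(comp$signal))), 100)  # real inhibition curve
})

test_that("the noiseless functional mean follows the hyperbolic transducer", {
  gt <- ground_truth("b", logKd_cce = -9, logKd_sce = -7,
                     efficacy_cce = 0.01, efficacy_sce = 0.2, mode = "biphasic")
  cfg <- sim_config(gt, receptor_expression = 40, noise_sd = 0)
  s <- simulate_functional_curve(cfg, "b")
  A <- s$conc
  S <- 0.01 * 40 * (A / 1e-9) / (1 + A / 1e-9) +
       0.2  * 40 * (A / 1e-7) / (1 + A / 1e-7)
  expect_equal(unname(s$signal[, 1]), 500 + 4500 * S / (1 + S), tolerance = 1e-12)
})

test_that("raising receptor expression raises the plateau and left-shifts the EC50", {
  gt <- ground_truth("a", logKd_cce = -7.62, efficacy_cce = 0.003,
                     mode = "cce_agonist")
  fits <- lapply(c(40, 600), function(e) {
    cfg <- sim_config(gt, receptor_expression = e, noise_sd = 0)
    fit_one_site(normalize_plate(simulate_functional_curve(cfg, "a")))
  })
  expect_gt(fits[[2]]$Emax_pct, fits[[1]]$Emax_pct)
  expect_lt(fits[[2]]$logEC50, fits[[1]]$logEC50)
  # and the one-site observables match tau/(1+tau), KD/(1+tau) exactly
  tau <- 0.003 * 40; pos <- 40 / 41
  expect_lt(abs(fits[[1]]$logEC50 - (-7.62 - log10(1 + tau))), 1e-4)
  expect_lt(abs(fits[[1]]$Emax_pct - 100 * (tau / (1 + tau)) / pos), 1e-2)
})

test_that("the dip plate composes Gaddum inhibition with the compound's own agonism", {
  ref <- ground_truth("ref", logKd_cce = -6.43, efficacy_cce = 1, mode = "cce_agonist")
  cmp <- ground_truth("cmp", logKd_cce = -9, logKd_sce = -7,
                      efficacy_cce = 0, efficacy_sce = 0.05, mode = "sce_agonist")
  cfg <- sim_config(list(ref, cmp), receptor_expression = 40, noise_sd = 0)
  s <- simulate_functional_curve(cfg, "cmp",
                                 fixed_reference = list(compound = "ref", conc = 30e-9))
  A <- s$conc
  tau_r <- 40; K_r <- 10^-6.43
  ec50_ref <- K_r / (1 + tau_r)
  S_ctl <- tau_r * (30e-9 / K_r) / (1 + 30e-9 / K_r)
  control <- S_ctl / (1 + S_ctl)
  tau_s <- 0.05 * 40
  ic50 <- 1e-9 * (1 + 30e-9 / ec50_ref)
  stim <- (tau_s / (1 + tau_s)) * A / (A + 1e-7 / (1 + tau_s))
  frac <- control * (1 - A / (A + ic50)) + stim
  expect_equal(unname(s$signal[, 1]), 500 + 4500 * frac, tolerance = 1e-12)
  # the curve is non-monotone: it dips below the control level then recovers
  mid <- 500 + 4500 * control
  expect_lt(min(s$signal[, 1]), mid - 100)
  expect_gt(s$signal[length(A), 1], min(s$signal[, 1]) + 100)
})

test_that("dip and shift designs validate their fixed ligands", {
  neut <- ground_truth("neut", logKd_cce = -8, mode = "neutral")
  ago <- ground_truth("ago", logKd_cce = -7, efficacy_cce = 0.5, mode = "cce_agonist")
  cfg <- sim_config(list(neut, ago), noise_sd = 0)
  expect_error(simulate_functional_curve(cfg, "ago",
                 fixed_reference = list(compound = "neut", conc = 1e-8)),
               "lacks CCE agonism")
  expect_error(simulate_functional_curve(cfg, "ago",
                 fixed_antagonist = list(compound = "neut", conc = 0)),
               "must be positive")
  expect_error(simulate_functional_curve(cfg, "missing"), "unknown compound")
})

test_that("a fixed antagonist right-shifts the agonist curve by the Gaddum factor", {
  ago <- ground_truth("ago", logKd_cce = -8, efficacy_cce = 1, mode = "cce_agonist")
  ant <- ground_truth("ant", logKd_cce = -9, mode = "neutral")
  cfg <- sim_config(list(ago, ant), receptor_expression = 10, noise_sd = 0)
  ctl <- fit_one_site(normalize_plate(simulate_functional_curve(cfg, "ago")))
  blk <- fit_one_site(normalize_plate(simulate_functional_curve(
    cfg, "ago", fixed_antagonist = list(compound = "ant", conc = 1e-8))))
  dr_expected <- 1 + 1e-8 / 1e-9
  expect_lt(abs((blk$logEC50 - ctl$logEC50) - log10(dr_expected)), 1e-3)
  expect_lt(abs(blk$Emax_pct - ctl$Emax_pct), 0.5)  # parallel shift
})
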