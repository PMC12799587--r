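# Evidence rubric: the four criteria, pooling across lines, the
# classification decision order, and the wild-type/mutant contrast.

conc13 <- 10^seq(-11, -5, by = 0.5)

choice_one_site <- function(logEC50 = -7.54, emax = 54.2, seed = 31) {
  set.seed(seed)
  pct <- eq_one_site(conc13, emax, 10^logEC50) + matrix(rnorm(39, 0, 1), ncol = 3)
  select_cr_model(as_curve(conc13, pct))
}

choice_two_site <- function(seed = 32) {
  set.seed(seed)
  pct <- eq_two_site(conc13, 40, 35, 10^-9.3, 10^-7) + matrix(rnorm(39, 0, 1), ncol = 3)
  select_cr_model(as_curve(conc13, pct))
}

choice_flat <- function(seed = 33) {
  set.seed(seed)
  select_cr_model(as_curve(conc13, matrix(rnorm(39, 0, 1.5), ncol = 3)))
}

choice_dip <- function(seed = 34) {
  set.seed(seed)
  pct <- eq_dip(conc13, 0, 75, 10^-8.6, 40, 10^-7.2) + matrix(rnorm(39, 0, 2), ncol = 3)
  select_cr_model(as_curve(conc13, pct, control_pct = 75,
                           meta = list(fixed_reference = list(compound = "ref", conc = 3e-8))))
}

choice_inhibition <- function(seed = 35) {
  set.seed(seed)
  pct <- 75 * (1 - conc13 / (conc13 + 1e-8)) + matrix(rnorm(39, 0, 2), ncol = 3)
  select_cr_model(as_curve(conc13, pct, control_pct = 75,
                           meta = list(fixed_reference = list(compound = "ref", conc = 3e-8))))
}

aff <- function(logKd, method = "gaddum", se = 0.05)
  affinity_estimate(logKd, se = se, method = method)
aff_cens <- function(bound = -5)
  affinity_estimate(NA, method = "gaddum",
                    censored = list(direction = ">", bound = bound))

test_that("an EC50 far above the conformation KD is positive evidence with its gap", {
  prof <- evaluate_evidence(
    functional = list(own = choice_one_site(-7.54, 54.2)),
    shifts = list(cce = aff(-9.87, "stephenson"),
                  antagonist_vs_compound = aff(-7.37),
                  antagonist_vs_reference = aff(-9.47)),
    compound_id = "probe")
  expect_equal(prof$A$call, "positive")
  expect_equal(prof$A$gap, prof$A$logEC50 - (-9.87))
  expect_gt(prof$A$gap, 2)
  expect_equal(prof$B$call, "positive")
  expect_equal(prof$B$gap, 2.10)
  expect_equal(prof$C$call, "negative")
  expect_equal(prof$D$call, "indeterminate")
  expect_equal(classify_compound(prof)$classification, "sce_agonist")
})

test_that("an EC50 at the KD, or a sub-threshold gap, is negative evidence", {
  own <- choice_one_site(-7.19, 40)
  at_kd <- evaluate_evidence(functional = list(own = own),
                             shifts = list(cce = aff(own$candidates$one_site$logEC50)))
  expect_equal(at_kd$A$call, "negative")
  small_gap <- evaluate_evidence(functional = list(own = own),
                                 shifts = list(cce = aff(-8.00)))
  expect_equal(small_gap$A$call, "negative")   # gap ~0.8, below the 10-fold bar
  expect_equal(classify_compound(small_gap)$classification, "cce_agonist")
})

test_that("the gap criterion is monotone in the threshold and the gap", {
  own <- choice_one_site(-7.19, 40)
  gap_only <- function(cce_logkd, gap_A = 1.0) {
    evaluate_evidence(functional = list(own = own),
                      shifts = list(cce = aff(cce_logkd)),
                      thresholds = study_thresholds(gap_A = gap_A))$A$call
  }
  expect_equal(gap_only(-8.7), "positive")
  expect_equal(gap_only(-10.7), "positive")    # larger gap stays positive
  expect_equal(gap_only(-8.7, gap_A = 2.5), "negative")  # stricter bar flips it
})

test_that("unreliable or biphasic responses leave the gap criterion open", {
  tiny <- evaluate_evidence(functional = list(own = choice_one_site(-7, 8)),
                            shifts = list(cce = aff(-9)))
  expect_equal(tiny$A$call, "indeterminate")
  expect_match(tiny$A$reason, "too small")
  biph <- evaluate_evidence(functional = list(own = choice_two_site()),
                            shifts = list(cce = aff(-9.3)))
  expect_equal(biph$A$call, "indeterminate")
  no_aff <- evaluate_evidence(functional = list(own = choice_one_site(-7.54, 54)),
                              shifts = list(cce = aff_cens()))
  expect_equal(no_aff$A$call, "indeterminate")
})

test_that("antagonist resistance compares the two apparent antagonist KDs", {
  own <- choice_one_site(-7.54, 54)
  resist <- evaluate_evidence(functional = list(own = own),
                              shifts = list(antagonist_vs_compound = aff(-7.37),
                                            antagonist_vs_reference = aff(-9.47)))
  expect_equal(resist$B$call, "positive")
  same <- evaluate_evidence(functional = list(own = own),
                            shifts = list(antagonist_vs_compound = aff(-9.4),
                                          antagonist_vs_reference = aff(-9.47)))
  expect_equal(same$B$call, "negative")
  missing <- evaluate_evidence(functional = list(own = own))
  expect_equal(missing$B$call, "indeterminate")
})

test_that("a biphasic curve is the shape criterion and dominates classification", {
  prof <- evaluate_evidence(binding = list(cce = aff(-9.3, "competition_cheng_prusoff")),
                            functional = list(own = choice_two_site()),
                            shifts = list(antagonist_vs_compound = aff(-7.3),
                                          antagonist_vs_reference = aff(-9.5)),
                            compound_id = "x")
  expect_equal(prof$C$call, "positive")
  expect_equal(classify_compound(prof)$classification, "biphasic_agonist")
})

test_that("the dip design drives the inhibit-then-stimulate criterion", {
  own <- choice_one_site(-7.54, 54)
  pos <- evaluate_evidence(binding = list(cce = aff(-9.3, "competition_cheng_prusoff")),
                           functional = list(own = own, dip = choice_dip()))
  expect_equal(pos$D$call, "positive")
  expect_equal(classify_compound(pos)$classification, "sce_agonist")
  neg <- evaluate_evidence(binding = list(cce = aff(-9.3, "competition_cheng_prusoff")),
                           functional = list(own = own, dip = choice_inhibition()))
  expect_equal(neg$D$call, "negative")
  expect_equal(classify_compound(neg)$classification, "cce_agonist")
})

test_that("the classification walks its decision order", {
  # censored everywhere and flat: no receptor interaction
  none <- evaluate_evidence(binding = list(cce = aff_cens()),
                            functional = list(own = choice_flat()))
  expect_equal(classify_compound(none)$classification, "no_interaction")
  # binds but never stimulates: neutral antagonist
  neut <- evaluate_evidence(binding = list(cce = aff(-8.29, "competition_cheng_prusoff")),
                            functional = list(own = choice_flat()))
  expect_equal(classify_compound(neut)$classification, "neutral_antagonist")
  # fitted agonism with no affinity data at all is contradictory
  orphan <- evaluate_evidence(functional = list(own = choice_one_site(-7.5, 50)))
  expect_error(classify_compound(orphan), "contradictory")
})

test_that("pooling takes any positive over negatives and negatives over unknowns", {
  own <- choice_one_site(-7.54, 54)
  p_pos <- evaluate_evidence(functional = list(own = own),
                             shifts = list(cce = aff(-9.87)),
                             compound_id = "x", cell_line = "l1")
  p_neg <- evaluate_evidence(functional = list(own = own),
                             shifts = list(cce = aff(-8.0)),
                             compound_id = "x", cell_line = "l2")
  p_ind <- evaluate_evidence(functional = list(own = own),
                             compound_id = "x", cell_line = "l3")
  pooled <- pool_evidence(list(p_neg, p_pos, p_ind))
  expect_equal(pooled$A$call, "positive")
  expect_equal(pooled$cell_line, "pooled")
  pooled2 <- pool_evidence(list(p_ind, p_neg))
  expect_equal(pooled2$A$call, "negative")
  pooled3 <- pool_evidence(list(p_ind, p_ind))
  expect_equal(pooled3$A$call, "indeterminate")
  p_other <- evaluate_evidence(functional = list(own = own), compound_id = "y")
  expect_error(pool_evidence(list(p_pos, p_other)), "one compound")
})

test_that("the line contrast reports lost evidence only when it was positive", {
  own <- choice_one_site(-7.54, 54)
  wt <- classify_compound(evaluate_evidence(
    functional = list(own = own, dip = choice_dip()),
    shifts = list(cce = aff(-9.87),
                  antagonist_vs_compound = aff(-7.37),
                  antagonist_vs_reference = aff(-9.47)),
    compound_id = "x", cell_line = "wt"))
  mut <- classify_compound(evaluate_evidence(
    functional = list(own = choice_one_site(-9.57, 28), dip = choice_inhibition()),
    shifts = list(cce = aff(-9.57),
                  antagonist_vs_compound = aff(-9.3),
                  antagonist_vs_reference = aff(-9.8)),
    compound_id = "x", cell_line = "mut"))
  ct <- compare_lines(wt, mut)
  expect_setequal(ct$lost, c("A", "B", "D"))
  expect_equal(ct$gained, character(0))
  expect_true(ct$sce_lost)
  # identical profiles lose nothing
  ct0 <- compare_lines(wt, wt)
  expect_equal(ct0$lost, character(0))
  expect_false(ct0$sce_lost)
  expect_error(compare_lines(wt, classify_compound(evaluate_evidence(
    functional = list(own = own), shifts = list(cce = aff(-9)),
    compound_id = "y"))), "different compounds")
})
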