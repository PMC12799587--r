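# The seeded study fixture: a 19-compound beta1-adrenoceptor panel with
# published affinities and efficacies as ground truth, simulated in a
# low-expression (luciferase-reporter) line, a high-expression
# (SPAP-reporter) line, and a high-expression line carrying the
# TM4 triple-mutant receptor in which the secondary conformation is absent.

# stimulus scale tau from a response expressed as a fraction of system max
.tau_from_frac <- function(f) f / (1 - f)

# expression scalars are anchored on the reference full agonist
# (cimaterol): its KD/EC50 gap per line fixes tau = KD/EC50 - 1.
.fixture_expression <- function() {
  list(
    luc  = 10^(8.07 - 6.43) - 1,   # low-expression reporter line
    spap = 10^(9.26 - 6.43) - 1,   # high-expression reporter line
    mut_cal = 10^(8.33 - 6.76) - 1 # expression at which mutant-line efficacies were calibrated
  )
}

.pos_frac <- function(expr) expr / (1 + expr)

# percent-of-isoprenaline -> tau at a given expression scale
.tau_from_pct <- function(pct, expr) .tau_from_frac(pct / 100 * .pos_frac(expr))

#' Ground-truth panel for the wild-type receptor
#'
#' One entry per panel compound.  CCE affinities come from competition
#' binding; secondary-conformation components are anchored to the cell line
#' in which that compound's SCE behaviour is quantifiable (the
#' low-expression line for the monophasic SCE agonists, the high-expression
#' line for the classical biphasic beta-blockers); classic biphasic
#' parameters are inverted exactly through the transducer algebra.
#'
#' @return named list of [ground_truth()] objects.
#' @keywords internal
.fixture_ground_truth_wt <- function() {
  ex <- .fixture_expression()
  g <- list()

  # reference full agonist: efficacy 1 by construction of the expression scale
  g$cimaterol <- ground_truth("cimaterol", logKd_cce = -6.43,
                              efficacy_cce = 1, mode = "cce_agonist")

  # reference antagonist: binds both conformations, stimulates neither
  g$CGP20712A <- ground_truth("CGP20712A", logKd_cce = -8.80, logKd_sce = -7.37,
                              mode = "neutral")

  # SCE probe agonist: high-affinity CCE binding with zero CCE efficacy,
  # SCE component anchored to the low-expression line (54.2% at logEC50 -7.54)
  tau <- .tau_from_pct(54.2, ex$luc)
  g$CGP12177 <- ground_truth("CGP12177", logKd_cce = -9.29,
                             logKd_sce = -7.54 + log10(1 + tau),
                             efficacy_sce = tau / ex$luc, mode = "sce_agonist")

  # classical biphasic beta-blockers: exact inversion of the published
  # two-site curve through the transducer (anchor line in comments)
  biphasic_from_curve <- function(id, total, n_pct, logEC1, logEC2, expr) {
    f <- total / 100 * .pos_frac(expr)
    m1 <- f * n_pct / 100; m2 <- f - m1
    mix <- .two_site_to_mix(m1, 10^logEC1, m2, 10^logEC2)
    ground_truth(id, logKd_cce = log10(mix$K1), logKd_sce = log10(mix$K2),
                 efficacy_cce = mix$tau1 / expr, efficacy_sce = mix$tau2 / expr,
                 mode = "biphasic")
  }
  g$alprenolol <- biphasic_from_curve("alprenolol", 62.5, 56.7, -8.34, -6.44, ex$spap)
  g$oxprenolol <- biphasic_from_curve("oxprenolol", 79.8, 67.8, -8.41, -5.68, ex$spap)
  g$pindolol   <- biphasic_from_curve("pindolol",   62.7, 81.0, -8.75, -5.91, ex$spap)
  g$bucindolol <- biphasic_from_curve("bucindolol", 23.3, 23.7, -9.27, -7.24, ex$luc)

  # novel SCE agonists: CCE affinity from binding; SCE component anchored to
  # the low-expression line; a small CCE efficacy reproduces the
  # expression-dependent emergence of the first component
  sce_biphasic <- function(id, logKd_cce, pct_luc, logEC50_luc, e_cce = 2e-4) {
    tau <- .tau_from_pct(pct_luc, ex$luc)
    ground_truth(id, logKd_cce = logKd_cce,
                 logKd_sce = logEC50_luc + log10(1 + tau),
                 efficacy_cce = e_cce, efficacy_sce = tau / ex$luc,
                 mode = "biphasic")
  }
  g$VL01 <- sce_biphasic("VL01", -9.45, 19.7, -6.78)
  g$VL04 <- sce_biphasic("VL04", -8.64, 23.7, -6.12)
  # VL09's binding and functional CCE affinities disagree; the functional
  # value keeps the high-expression components resolvably separated
  g$VL09 <- sce_biphasic("VL09", -8.84, 23.9, -6.89, e_cce = 2.75e-4)

  # weak SCE agonist without measurable CCE efficacy (high-expression anchor)
  tau <- .tau_from_pct(26.5, ex$spap)
  g$VL07 <- ground_truth("VL07", logKd_cce = -8.21,
                         logKd_sce = -6.55 + log10(1 + tau),
                         efficacy_sce = tau / ex$spap, mode = "sce_agonist")

  # conventional CCE partial agonists (high-expression anchor)
  cce_partial <- function(id, logKd_cce, pct_spap) {
    tau <- .tau_from_pct(pct_spap, ex$spap)
    ground_truth(id, logKd_cce = logKd_cce, efficacy_cce = tau / ex$spap,
                 mode = "cce_agonist")
  }
  g$VL05 <- cce_partial("VL05", -7.62, 62.3)
  g$VL06 <- cce_partial("VL06", -5.95, 53.6)
  g$VL10 <- cce_partial("VL10", -6.73, 66.9)

  # neutral antagonist at both conformations
  g$VL03 <- ground_truth("VL03", logKd_cce = -8.29, logKd_sce = -6.38,
                         mode = "neutral")

  # compounds with no measurable receptor interaction
  for (id in c("VL08", "VL11", "VL12", "VL13")) {
    g[[id]] <- ground_truth(id, mode = "nonbinder")
  }
  g
}

#' Ground-truth panel for the TM4 triple-mutant receptor
#'
#' The secondary conformation is absent: SCE affinities and efficacies are
#' removed, and the former SCE agonists reappear as conventional
#' catecholamine-conformation partial agonists with EC50 tracking their KD.
#'
#' @return named list of [ground_truth()] objects.
#' @keywords internal
.fixture_ground_truth_mut <- function() {
  ex <- .fixture_expression()
  cal <- ex$mut_cal
  g <- list()
  g$cimaterol <- ground_truth("cimaterol", logKd_cce = -6.76,
                              efficacy_cce = 1, mode = "cce_agonist")
  g$CGP20712A <- ground_truth("CGP20712A", logKd_cce = -9.50, mode = "neutral")
  mut_partial <- function(id, logKd_cce, pct) {
    tau <- .tau_from_pct(pct, cal)
    ground_truth(id, logKd_cce = logKd_cce, efficacy_cce = tau / cal,
                 mode = "cce_agonist")
  }
  g$CGP12177 <- mut_partial("CGP12177", -9.57, 27.9)
  g$VL01 <- mut_partial("VL01", -9.56, 30.4)
  g$VL04 <- mut_partial("VL04", -8.76, 26.7)
  g$VL09 <- mut_partial("VL09", -8.61, 35.6)
  g
}

.FIXTURE_COMPOUNDS <- c("alprenolol", "bucindolol", "CGP12177", "cimaterol",
                        "oxprenolol", "pindolol", "CGP20712A",
                        paste0("VL", sprintf("%02d", c(1, 3:13))))
.MUT_COMPOUNDS <- c("cimaterol", "CGP20712A", "CGP12177", "VL01", "VL04", "VL09")

# fixed-ligand concentration for a shift experiment: ten-fold over the KD,
# capped at the top of the dilution range
.shift_conc <- function(logKd, mult = 10) {
  if (is.na(logKd)) return(1e-5)
  min(10^logKd * mult, 1e-5)
}

#' Build the deterministic multi-compound study fixture
#'
#' Simulates the complete study around a 19-compound beta-ligand panel:
#' competition-binding plates and a saturation plate per binding line,
#' concentration-response curves for every compound in a low- and a
#' high-expression functional line, reference-agonist shift experiments for
#' functional CCE affinities (routed to Gaddum or Stephenson analysis
#' downstream), reference-antagonist shifts of each monophasic agonist
#' response, shifts of the SCE probe agonist's response for SCE affinities,
#' fixed-reference "dip" plates, and the full mutant-receptor arm for the
#' wild-type versus TM4-mutant contrast.  Bit-identical across runs at a
#' fixed seed.
#'
#' @param seed integer seed driving every random draw.
#' @param noise_sd replicate noise as a fraction of the assay window
#'   (default 0.05).
#' @return an object of class `study_bundle`: `configs` (per line),
#'   `ground_truth` (`wt` and `mut` panels), `plates` (named list of
#'   [conc_series()]), `design` (roster data frame), and the roles of the
#'   reference ligands.
#' @export
make_study_fixture <- function(seed = 1L, noise_sd = 0.05) {
  ex <- .fixture_expression()
  gt_wt <- .fixture_ground_truth_wt()
  gt_mut <- .fixture_ground_truth_mut()

  configs <- list(
    luc = sim_config(gt_wt, radioligand_conc = 0.71e-9,
                     radioligand_logKd = log10(0.15e-9),
                     receptor_expression = ex$luc, noise_sd = noise_sd,
                     seed = seed, cell_line = "b1_luc"),
    spap = sim_config(gt_wt, radioligand_conc = 0.71e-9,
                      radioligand_logKd = log10(0.42e-9),
                      receptor_expression = ex$spap, noise_sd = noise_sd,
                      seed = seed, cell_line = "b1_spap"),
    mut = sim_config(gt_mut, radioligand_conc = 0.71e-9,
                     radioligand_logKd = log10(0.272e-9),
                     receptor_expression = ex$mut_cal, noise_sd = noise_sd,
                     seed = seed, cell_line = "b1_mut")
  )

  design <- list()
  add <- function(line, design_type, compound, fixed_compound = NA, fixed_conc = NA) {
    design[[length(design) + 1]] <<- data.frame(
      line = line, design = design_type, compound = compound,
      fixed_compound = fixed_compound, fixed_conc = fixed_conc,
      stringsAsFactors = FALSE)
  }

  kd_cce <- function(panel, id) panel[[id]]$logKd_cce

  # --- binding -------------------------------------------------------------
  for (cmp in .FIXTURE_COMPOUNDS) add("spap", "binding_competition", cmp)
  for (cmp in .MUT_COMPOUNDS) add("mut", "binding_competition", cmp)
  for (ln in c("luc", "spap", "mut")) add(ln, "binding_saturation", "radioligand")

  # --- functional curves, compound alone ------------------------------------
  for (cmp in .FIXTURE_COMPOUNDS) {
    add("luc", "functional_alone", cmp)
    add("spap", "functional_alone", cmp)
  }
  for (cmp in .MUT_COMPOUNDS) add("mut", "functional_alone", cmp)

  # --- reference-agonist shifts (functional CCE affinity) -------------------
  ref_shift <- function(line, panel, cmp, mults) {
    for (m in mults) add(line, "cce_shift", "cimaterol", cmp,
                         .shift_conc(kd_cce(panel, cmp), m))
  }
  for (ln in c("luc", "spap")) {
    ref_shift(ln, gt_wt, "CGP20712A", c(3, 10, 30))
  }
  ref_shift("luc", gt_wt, "VL03", 10)
  ref_shift("spap", gt_wt, "VL03", c(3, 10, 30, 100))
  for (cmp in c("CGP12177", "VL01", "VL04", "VL09", "VL05", "VL06", "VL10")) {
    ref_shift("luc", gt_wt, cmp, 10)
    ref_shift("spap", gt_wt, cmp, 10)
  }
  for (cmp in c("VL08", "VL11", "VL12", "VL13")) {
    ref_shift("spap", gt_wt, cmp, 10)     # top concentration; expect no shift
  }
  ref_shift("mut", gt_mut, "CGP20712A", c(3, 10, 30))
  for (cmp in c("CGP12177", "VL01", "VL04", "VL09")) ref_shift("mut", gt_mut, cmp, 10)

  # fixed concentration overrides matching the published designs
  design <- do.call(rbind, design)
  design$fixed_conc[design$design == "cce_shift" &
                    design$fixed_compound == "CGP12177" &
                    design$line %in% c("luc", "spap")] <- 30e-9

  more <- list()
  add2 <- function(line, design_type, compound, fixed_compound = NA, fixed_conc = NA) {
    more[[length(more) + 1]] <<- data.frame(
      line = line, design = design_type, compound = compound,
      fixed_compound = fixed_compound, fixed_conc = fixed_conc,
      stringsAsFactors = FALSE)
  }

  # --- reference-antagonist shifts of monophasic agonist responses ----------
  # antagonist concentrations are scaled to each agonist's potency so that
  # the Gaddum-shifted EC50 stays inside the dilution range
  add2("luc", "antagonist_shift", "CGP12177", "CGP20712A", 1e-6)
  add2("luc", "antagonist_shift", "VL01", "CGP20712A", 3e-7)
  add2("luc", "antagonist_shift", "VL04", "CGP20712A", 1e-7)
  add2("luc", "antagonist_shift", "VL09", "CGP20712A", 1e-7)
  add2("spap", "antagonist_shift", "CGP12177", "CGP20712A", 1e-6)
  add2("spap", "antagonist_shift", "VL05", "CGP20712A", 1e-7)
  add2("spap", "antagonist_shift", "VL06", "CGP20712A", 3e-9)
  add2("spap", "antagonist_shift", "VL10", "CGP20712A", 1e-8)
  for (cmp in c("CGP12177", "VL01", "VL04", "VL09")) {
    add2("mut", "antagonist_shift", cmp, "CGP20712A", 1e-8)
  }

  # --- shifts of the SCE probe agonist's response (SCE affinity) ------------
  for (cmp in c("CGP20712A", "VL03", "VL07", "VL01", "VL05", "VL11")) {
    kd_s <- gt_wt[[cmp]]$logKd_sce
    add2("luc", "sce_shift", "CGP12177", cmp, .shift_conc(kd_s))
  }

  # --- dip design: compound vs fixed reference agonist ----------------------
  for (cmp in c("CGP12177", "VL01", "VL04", "VL09", "VL03", "VL05", "VL10",
                "VL08", "VL13")) {
    add2("luc", "dip", cmp, "cimaterol", 30e-9)
  }

  design <- rbind(design, do.call(rbind, more))
  design$plate_id <- sprintf("P%03d", seq_len(nrow(design)))

  # concentration-response plates pool the study's n separate triplicate
  # experiments per compound and line (3n wells per concentration);
  # resolving small biphasic components takes that replication, while
  # shift plates only track the dominant component and keep the config
  # default
  study_n <- list(
    luc = c(alprenolol = 8, bucindolol = 7, CGP12177 = 25, cimaterol = 19,
            oxprenolol = 8, pindolol = 8, VL01 = 16, VL04 = 13, VL05 = 18,
            VL06 = 8, VL09 = 17, VL10 = 20, CGP20712A = 5, VL03 = 5,
            VL07 = 5, VL08 = 5, VL11 = 5, VL12 = 5, VL13 = 5),
    spap = c(alprenolol = 8, bucindolol = 9, CGP12177 = 17, cimaterol = 20,
             oxprenolol = 7, pindolol = 11, VL01 = 14, VL04 = 18, VL05 = 13,
             VL06 = 15, VL07 = 12, VL09 = 13, VL10 = 19, CGP20712A = 5,
             VL03 = 5, VL08 = 5, VL11 = 5, VL12 = 5, VL13 = 5),
    mut = c(cimaterol = 9, CGP12177 = 9, VL01 = 16, VL04 = 16, VL09 = 9,
            CGP20712A = 5)
  )
  design$n_reps <- NA_integer_
  fa <- design$design == "functional_alone"
  design$n_reps[fa] <- vapply(which(fa), function(i) {
    n <- study_n[[design$line[i]]][design$compound[i]]
    if (is.na(n)) NA_integer_ else as.integer(3 * n)
  }, 0L)
  # shift and dip analyses likewise pool several separate triplicate
  # experiments (six, the study's typical n for these analyses)
  design$n_reps[design$design %in% c("cce_shift", "sce_shift",
                                     "antagonist_shift", "dip")] <- 18L

  plates <- vector("list", nrow(design))
  names(plates) <- design$plate_id
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    cfg <- configs[[d$line]]
    if (!is.na(d$n_reps)) cfg$n_replicates <- d$n_reps
    plates[[i]] <- switch(
      d$design,
      binding_competition = simulate_binding_plate(cfg, d$compound, "competition"),
      binding_saturation = simulate_binding_plate(cfg, d$compound, "saturation"),
      functional_alone = simulate_functional_curve(cfg, d$compound),
      cce_shift = ,
      sce_shift = ,
      antagonist_shift = simulate_functional_curve(
        cfg, d$compound,
        fixed_antagonist = list(compound = d$fixed_compound, conc = d$fixed_conc)),
      dip = simulate_functional_curve(
        cfg, d$compound,
        fixed_reference = list(compound = d$fixed_compound, conc = d$fixed_conc)),
      stop("unknown design: ", d$design)
    )
    plates[[i]]$meta$plate_id <- d$plate_id
    plates[[i]]$meta$design <- d$design
  }

  structure(
    list(configs = configs, ground_truth = list(wt = gt_wt, mut = gt_mut),
         plates = plates, design = design, seed = seed,
         reference_agonist = "cimaterol", sce_probe = "CGP12177",
         reference_antagonist = "CGP20712A",
         wt_lines = c("luc", "spap"), mut_lines = "mut"),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> seed %d: %d plates across %d cell lines, %d compounds\n",
              x$seed, length(x$plates), length(x$configs),
              length(x$ground_truth$wt)))
  invisible(x)
}
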