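#' Declare a compound's two-conformation ground truth
#'
#' The generative parameters for one compound in the simulator: its affinity
#' for the catecholamine conformation ensemble (CCE, the classical
#' intrahelical site through which catecholamines act) and for the secondary
#' conformation ensemble (SCE, the lower-affinity, antagonist-resistant
#' conformation), together with an intrinsic efficacy at each.  `mode`
#' summarises the qualitative behaviour and controls the simulated curve
#' shape.
#'
#' @param compound_id compound name.
#' @param logKd_cce,logKd_sce log10 molar affinities; `NA` when the compound
#'   does not bind that conformation.  When present they must lie in
#'   `[-12, -3]`.
#' @param efficacy_cce,efficacy_sce intrinsic efficacies in `[0, 1]`
#'   (fraction of the system maximal stimulus per unit receptor-expression
#'   scale).
#' @param mode one of `"neutral"`, `"cce_agonist"`, `"sce_agonist"`,
#'   `"biphasic"`, `"nonbinder"`.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(compound_id,
                         logKd_cce = NA_real_, logKd_sce = NA_real_,
                         efficacy_cce = 0, efficacy_sce = 0,
                         mode = c("neutral", "cce_agonist", "sce_agonist",
                                  "biphasic", "nonbinder")) {
  mode <- match.arg(mode)
  chk <- function(k) is.na(k) || (k >= -12 && k <= -3)
  if (!chk(logKd_cce) || !chk(logKd_sce)) stop("logKd values must lie in [-12, -3]")
  if (efficacy_cce < 0 || efficacy_cce > 1 || efficacy_sce < 0 || efficacy_sce > 1)
    stop("efficacies must lie in [0, 1]")
  if (mode == "nonbinder") {
    if (efficacy_cce != 0 || efficacy_sce != 0)
      stop("a nonbinder has zero efficacy at both conformations")
    if ((!is.na(logKd_cce) && logKd_cce < -5) || (!is.na(logKd_sce) && logKd_sce < -5))
      stop("a nonbinder's logKd fields must be absent or >= -5")
  }
  if (mode == "biphasic") {
    if (is.na(logKd_sce) || is.na(logKd_cce) || logKd_sce <= logKd_cce)
      stop("biphasic compounds must have logKd_sce > logKd_cce (lower SCE affinity)")
  }
  structure(
    list(compound_id = compound_id, logKd_cce = logKd_cce, logKd_sce = logKd_sce,
         efficacy_cce = efficacy_cce, efficacy_sce = efficacy_sce, mode = mode),
    class = "ground_truth"
  )
}

#' Simulation configuration for one cell line
#'
#' Bundles a ground-truth panel with the assay conditions of one cell line:
#' the radioligand concentration and affinity used in binding plates, a
#' receptor-expression scale factor (the amplification difference between a
#' low-expression luciferase-reporter line and a high-expression
#' secreted-phosphatase-reporter line), the replicate noise level, and the
#' test-compound concentration grid.
#'
#' @param ground_truth list of [ground_truth()] objects.
#' @param radioligand_conc fixed radioligand concentration (molar) for
#'   competition plates.
#' @param radioligand_logKd radioligand affinity, log10 molar.
#' @param receptor_expression positive amplification scale; an agonist's
#'   stimulus is `efficacy * receptor_expression * occupancy`.
#' @param noise_sd replicate noise SD as a fraction of the positive-control
#'   window (default 0.05).
#' @param n_replicates wells per concentration (default 3).
#' @param seed integer seed; identical (config, seed) pairs give
#'   bit-identical datasets.
#' @param concentration_grid strictly increasing molar grid for test
#'   compounds (default half-log series 1e-11 to 1e-5).
#' @param cell_line label carried into every simulated series.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(ground_truth, radioligand_conc = 0.71e-9,
                       radioligand_logKd = log10(0.42e-9),
                       receptor_expression = 1, noise_sd = 0.05,
                       n_replicates = 3L, seed = 1L,
                       concentration_grid = 10^seq(-11, -5, by = 0.5),
                       cell_line = "line1") {
  if (inherits(ground_truth, "ground_truth")) ground_truth <- list(ground_truth)
  ids <- vapply(ground_truth, `[[`, "", "compound_id")
  if (anyDuplicated(ids)) stop("duplicate compound ids in ground truth")
  names(ground_truth) <- ids
  if (radioligand_conc <= 0) stop("radioligand concentration must be positive")
  if (receptor_expression <= 0) stop("receptor_expression must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(concentration_grid <= 0) || is.unsorted(concentration_grid, strictly = TRUE))
    stop("concentration_grid must be strictly increasing and positive")
  structure(
    list(ground_truth = ground_truth, radioligand_conc = radioligand_conc,
         radioligand_logKd = radioligand_logKd,
         receptor_expression = receptor_expression, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         concentration_grid = concentration_grid, cell_line = cell_line),
    class = "sim_config"
  )
}

.gt_get <- function(config, compound) {
  gt <- config$ground_truth[[compound]]
  if (is.null(gt)) stop("unknown compound id: ", compound)
  gt
}

# tau values (efficacy x expression) for a compound under a config
.gt_tau <- function(gt, expr) {
  list(tau_c = gt$efficacy_cce * expr, tau_s = gt$efficacy_sce * expr,
       Kc = if (is.na(gt$logKd_cce)) NA_real_ else 10^gt$logKd_cce,
       Ks = if (is.na(gt$logKd_sce)) NA_real_ else 10^gt$logKd_sce)
}

# Noiseless response fraction (of the system maximum) for a compound alone,
# optionally in the presence of a fixed second ligand that is treated
# mechanistically: competition at each conformation plus any stimulus of its
# own.  This is the hyperbolic-transducer model R = S / (1 + S).
.response_fraction <- function(config, compound, A,
                               fixed = NULL, fixed_conc = NULL) {
  gt <- .gt_get(config, compound)
  p <- .gt_tau(gt, config$receptor_expression)
  bc <- bs <- 0; tb_c <- tb_s <- 0
  if (!is.null(fixed)) {
    gtb <- .gt_get(config, fixed)
    pb <- .gt_tau(gtb, config$receptor_expression)
    if (!is.na(pb$Kc)) bc <- fixed_conc / pb$Kc
    if (!is.na(pb$Ks)) bs <- fixed_conc / pb$Ks
    tb_c <- pb$tau_c; tb_s <- pb$tau_s
  }
  xc <- if (!is.na(p$Kc)) A / p$Kc else rep(0, length(A))
  xs <- if (!is.na(p$Ks)) A / p$Ks else rep(0, length(A))
  use_c <- gt$mode %in% c("cce_agonist", "biphasic") && p$tau_c > 0
  use_s <- gt$mode %in% c("sce_agonist", "biphasic") && p$tau_s > 0
  S_c <- (ifelse(use_c, p$tau_c, 0) * xc + tb_c * bc) / (1 + xc + bc)
  S_s <- (ifelse(use_s, p$tau_s, 0) * xs + tb_s * bs) / (1 + xs + bs)
  S <- S_c + S_s
  S / (1 + S)
}

# response fraction of a single fixed ligand alone at one concentration
.own_fraction <- function(config, compound, conc) {
  .response_fraction(config, compound, conc)
}

# fraction of system max produced by the positive control (10 uM
# isoprenaline, a full agonist at a saturating concentration)
.positive_fraction <- function(config) {
  e <- config$receptor_expression
  e / (1 + e)
}

# raw-signal constants for simulated reporter plates
.PLATE_BASAL <- 500
.PLATE_WINDOW <- 4500

.emit_raw <- function(frac_matrix, config, seed_label) {
  pos <- .positive_fraction(config)
  window <- .PLATE_WINDOW * pos
  mu <- .PLATE_BASAL + .PLATE_WINDOW * frac_matrix
  if (config$noise_sd > 0) {
    noise <- .with_seed(.mix_seed(config$seed, seed_label), {
      matrix(stats::rnorm(length(mu), 0, config$noise_sd * window), nrow = nrow(mu))
    })
    mu <- mu + noise
  }
  pmax(mu, 0)
}

#' Simulate a radioligand binding plate
#'
#' Forward model of whole-cell radioligand binding.  In `"competition"` mode
#' the plate carries total-binding wells, nonspecific-binding wells, and a
#' competitor dilution series whose noiseless expectation is
#' `100 * (1 - c / (c + IC50))` percent of specific binding, with the IC50
#' derived from the compound's CCE affinity by the inverse Cheng-Prusoff
#' relation `IC50 = KD * (1 + L / KD_L)`.  In `"saturation"` mode the
#' radioligand itself is diluted and the plate carries matched total and
#' nonspecific wells at every radioligand concentration.
#'
#' @param config a [sim_config()].
#' @param compound compound id present in the config's ground truth
#'   (ignored in saturation mode, where the radioligand is the subject).
#' @param assay `"competition"` or `"saturation"`.
#' @param n_control_wells wells for each of total and nonspecific binding
#'   (default 6).
#' @return a [conc_series()] with binding controls and metadata.
#' @export
simulate_binding_plate <- function(config, compound,
                                   assay = c("competition", "saturation"),
                                   n_control_wells = 6L) {
  assay <- match.arg(assay)
  if (config$radioligand_conc <= 0) stop("radioligand concentration must be positive")
  L <- config$radioligand_conc
  KdL <- 10^config$radioligand_logKd
  Bmax <- 1000
  noise <- function(n, label, sd) {
    if (config$noise_sd == 0) return(rep(0, n))
    .with_seed(.mix_seed(config$seed, label), stats::rnorm(n, 0, sd))
  }

  if (assay == "saturation") {
    conc <- 10^seq(log10(8e-12), log10(8.9e-9), length.out = 8)
    ns_coef <- 0.2 * Bmax / max(conc)
    sb <- eq_saturation(conc, Bmax, KdL)
    nsb <- ns_coef * conc
    nrep <- config$n_replicates
    tot <- matrix(rep(sb + nsb, nrep), ncol = nrep) +
      matrix(noise(length(conc) * nrep, paste0("sat_tot_", config$cell_line),
                   config$noise_sd * Bmax), ncol = nrep)
    nsm <- matrix(rep(nsb, nrep), ncol = nrep) +
      matrix(noise(length(conc) * nrep, paste0("sat_nsb_", config$cell_line),
                   config$noise_sd * Bmax), ncol = nrep)
    return(conc_series(
      compound_id = "radioligand", conc = conc, signal = pmax(tot, 0),
      controls = list(nonspecific = pmax(nsm, 0)),
      meta = list(assay = "binding_saturation", cell_line = config$cell_line,
                  radioligand_logKd = config$radioligand_logKd)
    ))
  }

  gt <- .gt_get(config, compound)
  B0 <- eq_saturation(L, Bmax, KdL)     # specific binding without competitor
  ns <- 0.1 * B0                        # nonspecific level at this L
  conc <- config$concentration_grid
  if (is.na(gt$logKd_cce)) {
    frac <- rep(1, length(conc))        # no competition: flat
  } else {
    ic50 <- 10^gt$logKd_cce * (1 + L / KdL)
    frac <- 1 - conc / (conc + ic50)
  }
  nrep <- config$n_replicates
  mu <- matrix(rep(ns + B0 * frac, nrep), ncol = nrep)
  sd_w <- config$noise_sd * B0
  sig <- mu + matrix(noise(length(mu), paste0("cmp_", compound, "_", config$cell_line), sd_w),
                     ncol = nrep)
  tot <- ns + B0 + noise(n_control_wells, paste0("cmp_tot_", compound, "_", config$cell_line), sd_w)
  nsb <- ns + noise(n_control_wells, paste0("cmp_nsb_", compound, "_", config$cell_line), sd_w)
  conc_series(
    compound_id = compound, conc = conc, signal = pmax(sig, 0),
    controls = list(total = pmax(tot, 0), nonspecific = pmax(nsb, 0)),
    meta = list(assay = "binding_competition", cell_line = config$cell_line,
                radioligand_conc = L, radioligand_logKd = config$radioligand_logKd)
  )
}

#' Simulate a reporter-gene functional plate
#'
#' Forward model of a concentration-response experiment.  The curve shape
#' follows the compound's mode: neutral antagonists and nonbinders are flat
#' at basal; conventional (CCE) and secondary-conformation (SCE) agonists
#' follow the one-site curve with `Emax = tau/(1+tau)` and
#' `EC50 = KD/(1+tau)` where `tau = efficacy * receptor_expression`;
#' biphasic compounds follow the exact two-site curve implied by the sum of
#' the two conformation stimuli.  A fixed antagonist right-shifts each
#' component by the competitive (Gaddum) factor `1 + [B]/KD` of the
#' conformation it binds, and contributes its own stimulus if it has one
#' (the design used for Stephenson partial-agonist analysis).  With
#' `fixed_reference` set, the plate is the "dip" design: the test compound
#' is diluted against a fixed reference-agonist response and the noiseless
#' mean follows the inhibit-then-stimulate composite, with the inhibitory
#' IC50 at the Gaddum-shifted CCE KD and the stimulatory limb equal to the
#' compound's own agonist component.
#'
#' @param config a [sim_config()].
#' @param compound the compound being diluted.
#' @param fixed_reference `NULL` or `list(compound =, conc =)`: a fixed
#'   reference agonist (dip design).
#' @param fixed_antagonist `NULL` or `list(compound =, conc =)`: a fixed
#'   antagonist / partial agonist competing with `compound`.
#' @return a [conc_series()] with `basal` and `positive` controls; dip
#'   plates also carry `reference` wells (fixed reference agonist alone).
#' @export
simulate_functional_curve <- function(config, compound,
                                      fixed_reference = NULL,
                                      fixed_antagonist = NULL) {
  gt <- .gt_get(config, compound)
  conc <- config$concentration_grid
  nrep <- config$n_replicates
  p <- .gt_tau(gt, config$receptor_expression)

  if (!is.null(fixed_reference)) {
    ref <- .gt_get(config, fixed_reference$compound)
    Cref <- fixed_reference$conc
    if (Cref <= 0) stop("reference concentration must be positive")
    pref <- .gt_tau(ref, config$receptor_expression)
    if (!(ref$mode %in% c("cce_agonist", "biphasic")) || pref$tau_c <= 0)
      stop("fixed_reference compound lacks CCE agonism")
    ref_obs <- .one_site_observable(pref$tau_c, pref$Kc)
    control <- .response_fraction(config, fixed_reference$compound, Cref)
    # inhibitory limb: Gaddum-shifted CCE KD of the test compound
    if (!is.na(p$Kc)) {
      ic50 <- p$Kc * (1 + Cref / ref_obs$ec50)
      inhib <- control * (1 - conc / (conc + ic50))
    } else {
      inhib <- rep(control, length(conc))
    }
    # stimulatory limb: the compound's own agonist component
    stim <- rep(0, length(conc))
    if (gt$mode %in% c("sce_agonist", "biphasic") && p$tau_s > 0) {
      ob <- .one_site_observable(p$tau_s, p$Ks)
      stim <- ob$emax * conc / (conc + ob$ec50)
    } else if (gt$mode == "cce_agonist" && p$tau_c > 0) {
      ob <- .one_site_observable(p$tau_c, p$Kc)
      stim <- ob$emax * conc / (conc + ob$ec50)
    }
    frac <- pmax(inhib + stim, 0)
    mu <- matrix(rep(frac, nrep), ncol = nrep)
    sig <- .emit_raw(mu, config, paste0("dip_", compound, "_", config$cell_line))
    ctrl <- .controls_raw(config, label = paste0("dipctl_", compound),
                          reference = control)
    return(conc_series(
      compound_id = compound, conc = conc, signal = sig, controls = ctrl,
      meta = list(assay = "functional", cell_line = config$cell_line,
                  fixed_reference = fixed_reference)
    ))
  }

  if (!is.null(fixed_antagonist)) {
    if (fixed_antagonist$conc <= 0) stop("antagonist concentration must be positive")
    .gt_get(config, fixed_antagonist$compound)  # must exist; a nonbinder simply has no effect
    frac <- .response_fraction(config, compound, conc,
                               fixed = fixed_antagonist$compound,
                               fixed_conc = fixed_antagonist$conc)
  } else {
    frac <- .response_fraction(config, compound, conc)
  }
  mu <- matrix(rep(frac, nrep), ncol = nrep)
  sig <- .emit_raw(mu, config, paste0(
    "fun_", compound, "_",
    if (is.null(fixed_antagonist)) "alone" else
      paste0(fixed_antagonist$compound, "_", signif(fixed_antagonist$conc, 3)),
    "_", config$cell_line))
  ctrl <- .controls_raw(config, label = paste0("functl_", compound))
  conc_series(
    compound_id = compound, conc = conc, signal = sig, controls = ctrl,
    meta = list(assay = "functional", cell_line = config$cell_line,
                fixed_antagonist = fixed_antagonist)
  )
}

# basal / positive (and optionally fixed-reference) control wells, raw units
.controls_raw <- function(config, label, reference = NULL,
                          n_wells = max(6L, config$n_replicates)) {
  pos <- .positive_fraction(config)
  window <- .PLATE_WINDOW * pos
  mk <- function(frac, sub) {
    mu <- rep(.PLATE_BASAL + .PLATE_WINDOW * frac, n_wells)
    if (config$noise_sd > 0) {
      mu <- mu + .with_seed(.mix_seed(config$seed, paste0(label, sub, config$cell_line)),
                            stats::rnorm(n_wells, 0, config$noise_sd * window))
    }
    pmax(mu, 0)
  }
  out <- list(basal = mk(0, "_bas_"), positive = mk(pos, "_pos_"))
  if (!is.null(reference)) out$reference <- mk(reference, "_ref_")
  out
}
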