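#' Normalise a reporter-gene plate to percent of the positive control
#'
#' Converts raw reporter signals to the percent-of-isoprenaline scale used
#' throughout the analysis:
#' `100 * (well - mean basal) / (mean positive - mean basal)`.  The
#' transformation is affine and order-preserving; basal maps to 0 and the
#' positive-control mean to 100.  Metadata (cell line, fixed ligands) is
#' preserved, and any fixed-reference control wells are normalised onto the
#' same scale (`control_pct`).
#'
#' @param raw a [conc_series()] with `basal` and `positive` controls
#'   (>= 3 wells each).
#' @return an object of class `normalized_curve` with fields `compound_id`,
#'   `conc`, `response` (percent matrix), `basal_pct`, `control_pct`
#'   (NA unless the plate has fixed-reference wells) and `meta`.
#' @export
normalize_plate <- function(raw) {
  stopifnot(inherits(raw, "conc_series"))
  bas <- raw$controls$basal; pos <- raw$controls$positive
  if (is.null(bas) || is.null(pos)) stop("normalisation requires basal and positive controls")
  if (length(bas) < 3 || length(pos) < 3) stop("controls need at least 3 wells each")
  window <- mean(pos) - mean(bas)
  if (window <= 0) stop("no assay window (positive <= basal)")
  to_pct <- function(v) 100 * (v - mean(bas)) / window
  control_pct <- if (!is.null(raw$controls$reference)) mean(to_pct(raw$controls$reference)) else NA_real_
  structure(
    list(compound_id = raw$compound_id, conc = raw$conc,
         response = to_pct(as.matrix(raw$signal)),
         basal_pct = 0, control_pct = control_pct, meta = raw$meta),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %s: %d concentrations, top response %.1f%% of positive control\n",
              x$compound_id, length(x$conc), max(rowMeans(x$response))))
  invisible(x)
}

#' Fit a one-site sigmoid concentration-response curve
#'
#' Least squares on the percent scale for `Response = Emax * A / (EC50 + A)`
#' with log10 EC50 parameterisation.  A flat curve (no fitted span) is
#' flagged `unidentifiable` rather than given a meaningless EC50.
#'
#' @param curve a [normalized_curve()] with at least 5 distinct
#'   concentrations.
#' @return an object of class `one_site_fit` with `logEC50`, `Emax_pct`,
#'   `se_logEC50`, `rss`, `n_points`, plus `unidentifiable` and
#'   `nonmonotone` diagnostic flags.
#' @export
fit_one_site <- function(curve) {
  stopifnot(inherits(curve, "normalized_curve"))
  if (length(unique(curve$conc)) < 5) stop("need at least 5 distinct concentrations")
  st <- .stack_reps(curve$conc, curve$response)
  mr <- rowMeans(curve$response)
  fn <- function(par, x) eq_one_site(x, par[1], 10^par[2])
  emax0 <- max(mr)
  i50 <- which.min(abs(mr - emax0 / 2))
  starts <- lapply(c(-10, -8, -6), function(l) c(emax = max(emax0, 1), logEC50 = l))
  fit <- .ls_fit(fn, start = c(emax = max(emax0, 1), logEC50 = log10(curve$conc[i50])),
                 lower = c(0, .LOG_LO), upper = c(500, .LOG_HI),
                 x = st$x, y = st$y, starts = starts)
  # flat-curve diagnostics: compare to the constant model
  rss_flat <- sum((st$y - mean(st$y))^2)
  unident <- fit$par[1] < 1e-6 || fit$rss >= rss_flat * (1 - 1e-9)
  nonmono <- {
    n <- length(mr)
    top <- mean(mr[max(1, n - 1):n]); peak <- max(mr)
    peak - top > 4 * stats::sd(st$y - fn(fit$par, st$x)) && peak > 5
  }
  structure(
    list(logEC50 = unname(fit$par[2]), Emax_pct = unname(fit$par[1]),
         se_logEC50 = unname(fit$se[2]), se_Emax = unname(fit$se[1]),
         rss = fit$rss, n_points = fit$n,
         unidentifiable = unident, nonmonotone = nonmono,
         compound_id = curve$compound_id, cell_line = curve$meta$cell_line),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> %s: logEC50 %.3f +/- %.3f, Emax %.1f%%%s\n",
              x$compound_id, x$logEC50, x$se_logEC50, x$Emax_pct,
              if (isTRUE(x$unidentifiable)) " [flat: EC50 unidentifiable]" else ""))
  invisible(x)
}

#' Fit a two-site stimulatory concentration-response curve
#'
#' The free-total two-site model
#' `Response = T * [N/100 * A/(A+EC1) + (1-N/100) * A/(A+EC2)]` with the
#' constraint `logEC1 < logEC2` (component 1 is the higher-potency site).
#' The objective is multimodal, so the fit is launched from a deterministic
#' lattice of split points across the concentration range and the best
#' minimum kept.  A fit that collapses onto a single site (components
#' closer than 0.1 log or a component share under 1%) is flagged
#' `collapsed` rather than silently accepted.
#'
#' @param curve a [normalized_curve()] with at least 7 distinct
#'   concentrations.
#' @return an object of class `two_site_fit` with `logEC1_50`, `logEC2_50`,
#'   `site1_pct`, `total_Emax_pct`, `rss`, `n_points`, `collapsed`.
#' @export
fit_two_site_stim <- function(curve) {
  stopifnot(inherits(curve, "normalized_curve"))
  if (length(unique(curve$conc)) < 7) stop("need at least 7 distinct concentrations")
  st <- .stack_reps(curve$conc, curve$response)
  mr <- rowMeans(curve$response)
  top <- max(mr, 1)
  lo <- log10(min(curve$conc)); hi <- log10(max(curve$conc))
  # parameters: total, n_pct, logEC1, dlog (>0, logEC2 = logEC1 + dlog)
  fn <- function(par, x) eq_two_site(x, par[1], par[2], 10^par[3], 10^(par[3] + par[4]))
  splits <- seq(lo + 0.5, hi - 1, length.out = 5)
  starts <- list()
  for (s1 in splits) for (dl in c(1, 2, 3)) for (np in c(20, 50)) {
    starts <- c(starts, list(c(total = top, n_pct = np, logEC1 = s1, dlog = dl)))
  }
  fit <- .ls_fit(fn, start = starts[[1]],
                 lower = c(0, 0, .LOG_LO, 0.01), upper = c(500, 100, .LOG_HI, 8),
                 x = st$x, y = st$y, starts = starts[-1])
  p <- fit$par
  collapsed <- p[4] < 0.1 || p[2] < 1 || p[2] > 99 || p[1] * min(p[2], 100 - p[2]) / 100 < 0.5
  structure(
    list(logEC1_50 = unname(p[3]), logEC2_50 = unname(p[3] + p[4]),
         site1_pct = unname(p[2]), total_Emax_pct = unname(p[1]),
         se_logEC1 = unname(fit$se[3]),
         rss = fit$rss, n_points = fit$n, collapsed = collapsed,
         compound_id = curve$compound_id, cell_line = curve$meta$cell_line),
    class = "two_site_fit"
  )
}

#' @export
print.two_site_fit <- function(x, ...) {
  cat(sprintf("<two_site_fit> %s: logEC1 %.3f, logEC2 %.3f, site1 %.1f%%, total %.1f%%%s\n",
              x$compound_id, x$logEC1_50, x$logEC2_50, x$site1_pct, x$total_Emax_pct,
              if (isTRUE(x$collapsed)) " [collapsed to one site]" else ""))
  invisible(x)
}

#' Fit the inhibit-then-stimulate composite ("dip") curve
#'
#' For a test compound diluted against a fixed reference-agonist response:
#' `Response = basal + (control - basal) * (1 - A/(A+IC50)) + Smax * A/(A+EC50)`.
#' `basal` and `control` are fixed to their measured plate values (the
#' model treats them as knowns); `logIC50`, `Smax` and `logEC50` are free.
#' A genuine dip requires the inhibitory limb at lower concentrations than
#' the stimulatory one (`logIC50 < logEC50`).
#'
#' @param curve a [normalized_curve()] from a fixed-reference plate
#'   (`control_pct` available) with at least 7 concentrations.
#' @param control_pct,basal_pct optional overrides of the measured levels.
#' @return an object of class `dip_fit` with `basal_pct`, `control_pct`,
#'   `logIC50`, `logEC50`, `Smax_pct`, `rss`, `n_points`.
#' @export
fit_dip <- function(curve, control_pct = NULL, basal_pct = NULL) {
  stopifnot(inherits(curve, "normalized_curve"))
  if (length(unique(curve$conc)) < 7) stop("need at least 7 distinct concentrations")
  control <- if (!is.null(control_pct)) control_pct else curve$control_pct
  basal <- if (!is.null(basal_pct)) basal_pct else curve$basal_pct
  if (!is.finite(control)) stop("dip fit requires the fixed-reference control level")
  if (control <= basal) stop("control response must exceed basal")
  st <- .stack_reps(curve$conc, curve$response)
  lo <- log10(min(curve$conc)); hi <- log10(max(curve$conc))
  fn <- function(par, x) eq_dip(x, basal, control, 10^par[1], par[2], 10^par[3])
  starts <- list()
  for (li in seq(lo + 0.5, hi - 2, length.out = 3)) for (le in c(li + 1, li + 2.5)) {
    starts <- c(starts, list(c(logIC50 = li, smax = max(st$y) / 2, logEC50 = le)))
  }
  fit <- .ls_fit(fn, start = starts[[1]],
                 lower = c(.LOG_LO, 0, .LOG_LO), upper = c(.LOG_HI, 500, .LOG_HI),
                 x = st$x, y = st$y, starts = starts[-1])
  structure(
    list(basal_pct = basal, control_pct = control,
         logIC50 = unname(fit$par[1]), logEC50 = unname(fit$par[3]),
         Smax_pct = unname(fit$par[2]),
         se_logIC50 = unname(fit$se[1]), se_logEC50 = unname(fit$se[3]),
         rss = fit$rss, n_points = fit$n,
         compound_id = curve$compound_id, cell_line = curve$meta$cell_line),
    class = "dip_fit"
  )
}

#' @export
print.dip_fit <- function(x, ...) {
  cat(sprintf("<dip_fit> %s: logIC50 %.3f, logEC50 %.3f, Smax %.1f%% (control %.1f%%)\n",
              x$compound_id, x$logIC50, x$logEC50, x$Smax_pct, x$control_pct))
  invisible(x)
}

#' Choose the concentration-response model for a curve
#'
#' Nested model comparison standing in for "best described by": for an
#' ordinary agonist plate, flat vs one-site vs two-site via the
#' extra-sum-of-squares F-test at `alpha`, with a separation guard before a
#' two-site call is accepted (components at least `guard_sep` log units
#' apart, each at least `guard_frac` of the total span, and both inside the
#' tested concentration range); when the guard
#' fails a significant F-test is reported as one-site with the diagnostic
#' attached (conservative).  For a fixed-reference ("dip" design) plate the
#' candidates are inhibition-only, stimulation-only and the full composite,
#' and the dip is accepted only when both limbs are F-significant, both sit
#' inside the tested concentration range, and the inhibitory limb lies at
#' least `dip_sep` log units below the stimulatory one.
#'
#' @param curve a [normalized_curve()].
#' @param alpha significance level for the extra-sum-of-squares F-tests.
#' @param guard_sep,guard_frac two-site acceptance guard (log10 separation,
#'   minimum component share of the total).
#' @param dip_sep required log10 separation between dip limbs.
#' @return an object of class `model_choice`: `chosen` (one of `"flat"`,
#'   `"one_site"`, `"two_site"`, `"dip"`, `"inhibition"`), `p_value`,
#'   `test_statistic`, `candidates` (the fitted objects), `diagnostics`.
#' @export
select_cr_model <- function(curve, alpha = 0.05, guard_sep = 1, guard_frac = 0.10,
                            dip_sep = 0.5) {
  stopifnot(inherits(curve, "normalized_curve"))
  st <- .stack_reps(curve$conc, curve$response)
  n <- length(st$y)
  has_ref <- !is.null(curve$meta$fixed_reference) && is.finite(curve$control_pct)

  if (!has_ref) {
    rss_flat <- sum((st$y - mean(st$y))^2); df_flat <- n - 1
    one <- fit_one_site(curve)
    two <- tryCatch(fit_two_site_stim(curve), error = function(e) NULL)
    t1 <- .ess_f_test(rss_flat, df_flat, one$rss, n - 2)
    if (t1$p >= alpha || one$unidentifiable) {
      return(.model_choice("flat", t1, list(one_site = one, two_site = two),
                           diagnostics = "no significant response"))
    }
    if (is.null(two)) {
      return(.model_choice("one_site", t1, list(one_site = one)))
    }
    t2 <- .ess_f_test(one$rss, n - 2, two$rss, n - 4)
    sep <- two$logEC2_50 - two$logEC1_50
    # both components must also lie inside the tested concentration range:
    # a component EC50 beyond the dilution series is not identifiable from it
    in_range <- two$logEC1_50 >= log10(min(curve$conc)) &&
      two$logEC2_50 <= log10(max(curve$conc))
    guard_ok <- !two$collapsed && sep >= guard_sep && in_range &&
      min(two$site1_pct, 100 - two$site1_pct) >= guard_frac * 100
    if (t2$p < alpha && guard_ok) {
      return(.model_choice("two_site", t2, list(one_site = one, two_site = two)))
    }
    diag <- if (t2$p < alpha) "F-test significant but separation guard failed" else NA_character_
    return(.model_choice("one_site", t2, list(one_site = one, two_site = two),
                         diagnostics = diag))
  }

  # fixed-reference (dip) pathway
  control <- curve$control_pct; basal <- curve$basal_pct
  dip <- fit_dip(curve)
  # monotone inhibition to a free floor: a partial agonist suppresses the
  # reference response down to its own plateau without any dip, so the
  # composite must beat this shape -- not just inhibition to basal --
  # before a dip is called
  fn_inh <- function(par, x) par[2] + (control - par[2]) * (1 - x / (x + 10^par[1]))
  lo <- log10(min(curve$conc)); hi <- log10(max(curve$conc))
  inh <- .ls_fit(fn_inh, start = c(logIC50 = (lo + hi) / 2, floor = basal),
                 lower = c(.LOG_LO, 0), upper = c(.LOG_HI, max(control, 1)),
                 x = st$x, y = st$y,
                 starts = lapply(seq(lo, hi, length.out = 4),
                                 function(l) c(logIC50 = l, floor = basal)))
  # stimulation-only: reference response retained, own stimulation added
  fn_stim <- function(par, x) control + par[1] * x / (x + 10^par[2])
  stim <- .ls_fit(fn_stim, start = c(smax = max(st$y) - control, logEC50 = (lo + hi) / 2),
                  lower = c(0, .LOG_LO), upper = c(500, .LOG_HI), x = st$x, y = st$y,
                  starts = lapply(seq(lo, hi, length.out = 4),
                                  function(l) c(smax = 10, logEC50 = l)))
  rss_flat <- sum((st$y - control)^2)
  t_stim <- .ess_f_test(inh$rss, n - 2, dip$rss, n - 3)   # does the stim limb help?
  t_inh <- .ess_f_test(stim$rss, n - 2, dip$rss, n - 3)   # does the inhib limb help?
  separated <- dip$logIC50 <= dip$logEC50 - dip_sep
  # both limbs must sit inside the tested range; a limb placed beyond the
  # dilution series is an extrapolation artefact, not an observed dip
  limbs_in_range <- dip$logIC50 >= lo && dip$logEC50 <= hi
  if (t_stim$p < alpha && t_inh$p < alpha && separated && limbs_in_range) {
    return(.model_choice("dip", t_stim,
                         list(dip = dip, rss_inhibition = inh$rss, rss_stimulation = stim$rss),
                         p2 = t_inh$p))
  }
  # otherwise report the better monotone description
  t_any_inh <- .ess_f_test(rss_flat, n, inh$rss, n - 2)
  if (inh$rss <= stim$rss && t_any_inh$p < alpha) {
    return(.model_choice("inhibition", t_any_inh,
                         list(dip = dip, logIC50 = unname(inh$par[1])),
                         diagnostics = "monotone inhibition of the reference response"))
  }
  t_any_stim <- .ess_f_test(rss_flat, n, stim$rss, n - 2)
  if (t_any_stim$p < alpha) {
    return(.model_choice("one_site", t_any_stim, list(dip = dip),
                         diagnostics = "stimulation without a significant inhibitory limb"))
  }
  .model_choice("flat", t_any_stim, list(dip = dip),
                diagnostics = "no significant change from the reference response")
}

.model_choice <- function(chosen, test, candidates, diagnostics = NA_character_, p2 = NA_real_) {
  structure(
    list(chosen = chosen, test_statistic = test$statistic, p_value = test$p,
         p_value_second = p2, candidates = candidates, diagnostics = diagnostics),
    class = "model_choice"
  )
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("<model_choice> %s (F = %.3g, p = %.3g)%s\n", x$chosen,
              x$test_statistic, x$p_value,
              if (!is.na(x$diagnostics)) paste0(" - ", x$diagnostics) else ""))
  invisible(x)
}
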