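#' Bundle agonist curve fits with and without a fixed antagonist
#'
#' @param agonist_fit_control [fit_one_site()] result for the agonist alone.
#' @param agonist_fits_blocked list of `list(conc = molar, fit = one_site_fit)`
#'   for each fixed antagonist concentration (all positive and distinct).
#' @param antagonist_id,agonist_id,cell_line provenance labels.
#' @return an object of class `shift_experiment`.
#' @export
shift_experiment <- function(agonist_fit_control, agonist_fits_blocked,
                             antagonist_id = NA_character_,
                             agonist_id = NA_character_,
                             cell_line = NA_character_) {
  stopifnot(inherits(agonist_fit_control, "one_site_fit"))
  concs <- vapply(agonist_fits_blocked, `[[`, 0, "conc")
  if (any(concs <= 0) || anyDuplicated(concs)) stop("antagonist concentrations must be positive and distinct")
  structure(
    list(agonist_fit_control = agonist_fit_control,
         agonist_fits_blocked = agonist_fits_blocked,
         antagonist_id = antagonist_id, agonist_id = agonist_id,
         cell_line = cell_line),
    class = "shift_experiment"
  )
}

# dose ratios for each blocked curve
.dose_ratios <- function(experiment) {
  ctl <- experiment$agonist_fit_control
  vapply(experiment$agonist_fits_blocked,
         function(b) 10^(b$fit$logEC50 - ctl$logEC50), 0)
}

#' Antagonist affinity from the Gaddum dose-ratio equation
#'
#' For each fixed antagonist concentration `[B]`, the dose ratio
#' `DR = EC50(blocked) / EC50(control)` gives `KD = [B] / (DR - 1)`.
#' Per-concentration log KDs are averaged.  A shift smaller than `dr_min`
#' (default 1.2, within typical EC50 error at triplicate noise) carries no
#' information and yields a censored "no shift at [B]" estimate.  Blocked
#' curves whose plateau differs from the control by more than
#' `emax_tol` (relative) violate the parallel-shift assumption; the
#' estimate is still computed but a warning is raised.
#'
#' @param experiment a [shift_experiment()].
#' @param dr_min minimum dose ratio treated as a real shift.
#' @param emax_tol relative plateau-difference tolerance for the
#'   parallel-shift check.
#' @return an [affinity_estimate()] with method `"gaddum"` (censored when no
#'   shift was measurable).
#' @export
gaddum_kd <- function(experiment, dr_min = 1.2, emax_tol = 0.25) {
  stopifnot(inherits(experiment, "shift_experiment"))
  ctl <- experiment$agonist_fit_control
  dr <- .dose_ratios(experiment)
  concs <- vapply(experiment$agonist_fits_blocked, `[[`, 0, "conc")
  emax_b <- vapply(experiment$agonist_fits_blocked, function(b) b$fit$Emax_pct, 0)
  if (ctl$Emax_pct > 0 && any(abs(emax_b - ctl$Emax_pct) / ctl$Emax_pct > emax_tol)) {
    warning("blocked plateau differs from control beyond tolerance; parallel-shift assumption questionable")
  }
  ok <- dr > dr_min
  if (!any(ok)) {
    return(affinity_estimate(
      NA, method = "gaddum", n = length(dr),
      censored = list(direction = ">", bound = log10(max(concs))),
      compound_id = experiment$antagonist_id, cell_line = experiment$cell_line,
      agonist_id = experiment$agonist_id))
  }
  logk <- log10(concs[ok] / (dr[ok] - 1))
  affinity_estimate(mean(logk),
                    se = if (sum(ok) > 1) stats::sd(logk) / sqrt(sum(ok)) else NA_real_,
                    method = "gaddum", n = sum(ok),
                    compound_id = experiment$antagonist_id,
                    cell_line = experiment$cell_line,
                    agonist_id = experiment$agonist_id)
}

#' Schild regression
#'
#' Ordinary least-squares line through `(log10 [B], log10(DR - 1))` over at
#' least three antagonist concentrations.  Simple competitive antagonism
#' predicts unit slope, and the x-intercept estimates log KD.  Points with
#' `DR <= 1` carry no information and are excluded with a warning.
#'
#' @param experiment a [shift_experiment()] with >= 3 blocked curves.
#' @return an object of class `schild_fit`: `slope`, `se_slope`,
#'   `intercept_logKd`, `r_squared`, `n_points`, `competitive` (is 1 inside
#'   the slope's 95% interval).
#' @export
schild_fit <- function(experiment) {
  stopifnot(inherits(experiment, "shift_experiment"))
  dr <- .dose_ratios(experiment)
  concs <- vapply(experiment$agonist_fits_blocked, `[[`, 0, "conc")
  ok <- dr > 1
  if (any(!ok)) warning(sum(!ok), " point(s) with DR <= 1 excluded from the Schild plot")
  if (sum(ok) < 3) stop("Schild regression needs >= 3 antagonist concentrations with DR > 1")
  x <- log10(concs[ok]); y <- log10(dr[ok] - 1)
  m <- stats::lm(y ~ x)
  cf <- stats::coef(m)
  se_slope <- sqrt(stats::vcov(m)[2, 2])
  slope <- unname(cf[2])
  ci_half <- stats::qt(0.975, df = m$df.residual) * se_slope
  structure(
    list(slope = slope, se_slope = se_slope,
         intercept_logKd = unname(-cf[1] / cf[2]),
         r_squared = summary(m)$r.squared, n_points = sum(ok),
         competitive = is.finite(ci_half) && abs(slope - 1) <= ci_half ||
           (m$df.residual == 0 && abs(slope - 1) < 1e-6),
         antagonist_id = experiment$antagonist_id,
         cell_line = experiment$cell_line),
    class = "schild_fit"
  )
}

#' @export
print.schild_fit <- function(x, ...) {
  cat(sprintf("<schild_fit> %s: slope %.3f +/- %.3f, logKd %.3f (r2 %.3f, n=%d)%s\n",
              x$antagonist_id, x$slope, x$se_slope, x$intercept_logKd,
              x$r_squared, x$n_points,
              if (isTRUE(x$competitive)) " [competitive]" else ""))
  invisible(x)
}

#' Partial-agonist affinity by Stephenson's matched-response method
#'
#' With a fixed concentration `[P]` of a partial agonist present, matched
#' response levels above the partial agonist's own plateau are compared
#' between the full-agonist control curve and the combined curve:
#' `A1` is the control-curve concentration producing the plateau response,
#' `A2` the control-curve concentration at the matched level and `A3` the
#' combined-curve concentration at the same level; then
#' `Y = (A2 - A1) / A3` and `KD = Y * [P] / (1 - Y)`.  Five evenly spaced
#' levels between the plateau plus 5% of the control span and 90% of the
#' control Emax are read off the fitted curves by inverse interpolation and
#' the per-level log KDs averaged.
#'
#' @param control_curve [fit_one_site()] result for the full agonist alone.
#' @param combined_curve [normalized_curve()] measured in the presence of
#'   the fixed partial agonist.
#' @param P fixed partial-agonist concentration (molar).
#' @param n_levels number of matched response levels (default 5).
#' @return an [affinity_estimate()] with method `"stephenson"`.
#' @export
stephenson_kd <- function(control_curve, combined_curve, P, n_levels = 5L) {
  stopifnot(inherits(control_curve, "one_site_fit"),
            inherits(combined_curve, "normalized_curve"))
  if (P <= 0) stop("partial-agonist concentration must be positive")
  # fit the combined curve with a floating baseline (the plateau)
  st <- .stack_reps(combined_curve$conc, combined_curve$response)
  fn <- function(par, x) par[1] + (par[2] - par[1]) * x / (x + 10^par[3])
  lo <- log10(min(combined_curve$conc)); hi <- log10(max(combined_curve$conc))
  cfit <- .ls_fit(fn, start = c(b0 = min(rowMeans(combined_curve$response)),
                                emax = max(st$y), logEC50 = (lo + hi) / 2),
                  lower = c(-20, 0, .LOG_LO), upper = c(200, 500, .LOG_HI),
                  x = st$x, y = st$y,
                  starts = lapply(seq(lo, hi, length.out = 4),
                                  function(l) c(b0 = 5, emax = max(st$y), logEC50 = l)))
  plateau <- unname(cfit$par[1])
  emax_ctl <- control_curve$Emax_pct
  if (plateau >= emax_ctl) stop("fixed ligand's plateau reaches the full agonist's maximum; not a partial agonist here")
  lev_lo <- plateau + 0.05 * emax_ctl
  lev_hi <- 0.90 * emax_ctl
  if (lev_lo >= lev_hi) stop("no response level lies between the plateau and 90% of the control maximum")
  levels <- seq(lev_lo, lev_hi, length.out = n_levels)
  inv_ctl <- function(r) 10^control_curve$logEC50 * r / (emax_ctl - r)
  inv_cmb <- function(r) {
    b0 <- cfit$par[1]; em <- cfit$par[2]; ec <- 10^cfit$par[3]
    ec * (r - b0) / (em - r)
  }
  A1 <- inv_ctl(max(plateau, 1e-6))
  logk <- c()
  for (r in levels) {
    A2 <- inv_ctl(r); A3 <- inv_cmb(r)
    if (!is.finite(A2) || !is.finite(A3) || A3 <= 0 || A2 <= A1) next
    Y <- (A2 - A1) / A3
    if (Y <= 0 || Y >= 1) next
    logk <- c(logk, log10(Y * P / (1 - Y)))
  }
  if (!length(logk)) stop("no matched-response level satisfied the Stephenson preconditions")
  affinity_estimate(mean(logk),
                    se = if (length(logk) > 1) stats::sd(logk) / sqrt(length(logk)) else NA_real_,
                    method = "stephenson", n = length(logk),
                    compound_id = combined_curve$meta$fixed_antagonist$compound %||% NA_character_,
                    cell_line = combined_curve$meta$cell_line,
                    agonist_id = combined_curve$compound_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stephenson's equation on explicit matched concentrations
#'
#' Direct evaluation of `KD = Y * [P] / (1 - Y)` with `Y = (A2 - A1)/A3`,
#' for checking individual matched-response readings.
#'
#' @param P,A1,A2,A3 concentrations (molar); `A1 < A2`, all positive.
#' @return list with `Y` and `Kd` (molar).
#' @export
stephenson_eq <- function(P, A1, A2, A3) {
  if (any(c(P, A1, A2, A3) <= 0) || A2 <= A1) stop("need positive concentrations with A2 > A1")
  Y <- (A2 - A1) / A3
  if (Y <= 0 || Y >= 1) stop("Y must lie in (0, 1)")
  list(Y = Y, Kd = Y * P / (1 - Y))
}

#' Log ratio of affinities between the two conformations
#'
#' `logKd_sce - logKd_cce`, the log10 fold-difference in affinity between
#' the secondary and catecholamine conformations; positive values mean
#' higher affinity at the catecholamine conformation.  If the SCE estimate
#' is censored (no shift at the top concentration) a one-sided bound is
#' returned, e.g. "> 3".
#'
#' @param kd_cce,kd_sce [affinity_estimate()]s (or bare log10 values) for
#'   the two conformations.
#' @return a list with `log_ratio` and `censored` (`NULL` or direction).
#' @export
conformation_ratio <- function(kd_cce, kd_sce) {
  val <- function(x) if (inherits(x, "affinity_estimate")) x else
    affinity_estimate(x, method = "gaddum")
  a <- val(kd_cce); b <- val(kd_sce)
  if (is_censored(a) && is_censored(b)) {
    return(list(log_ratio = NA_real_, censored = "both censored"))
  }
  if (is_censored(b)) {
    return(list(log_ratio = b$censored$bound - a$logKd, censored = ">"))
  }
  if (is_censored(a)) {
    return(list(log_ratio = b$logKd - a$censored$bound, censored = "<"))
  }
  list(log_ratio = b$logKd - a$logKd, censored = NULL)
}
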