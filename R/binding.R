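#' Fit radioligand saturation binding
#'
#' Least-squares fit of the one-site saturation model
#' `SB = A * Bmax / (A + KD)` to specific binding (total minus the mean
#' matched nonspecific binding) over a radioligand dilution series.  The
#' affinity is optimised as log10 KD inside `[-13, -2]`; standard errors
#' come from the curvature of the residual surface.
#'
#' @param data a [conc_series()] whose `signal` holds total-binding wells
#'   and whose `controls$nonspecific` is a matrix matched to `conc`.
#' @return an object of class `saturation_fit` with fields `Bmax`, `logKd`,
#'   `se_logKd`, `rss`, `n_points`.
#' @export
fit_saturation <- function(data) {
  stopifnot(inherits(data, "conc_series"))
  nsb <- data$controls$nonspecific
  if (is.null(nsb)) stop("saturation fit requires matched nonspecific-binding wells")
  nsb <- as.matrix(nsb)
  if (nrow(nsb) != length(data$conc)) stop("nonspecific wells must match the dilution series")
  if (length(unique(data$conc)) < 4) stop("need at least 4 distinct radioligand concentrations")
  sb <- sweep(as.matrix(data$signal), 1, rowMeans(nsb))
  if (all(colSums(sb > 0) == 0) || max(sb) <= 0)
    stop("specific binding is non-positive everywhere; nothing to fit")
  st <- .stack_reps(data$conc, sb)
  bmax0 <- max(st$y)
  fn <- function(par, x) eq_saturation(x, par[1], 10^par[2])
  fit <- .ls_fit(fn,
                 start = c(Bmax = bmax0, logKd = log10(stats::median(data$conc))),
                 lower = c(1e-9, .LOG_LO), upper = c(bmax0 * 100, .LOG_HI),
                 x = st$x, y = st$y)
  structure(
    list(Bmax = unname(fit$par[1]), logKd = unname(fit$par[2]),
         se_logKd = unname(fit$se[2]), rss = fit$rss, n_points = fit$n,
         compound_id = data$compound_id, cell_line = data$meta$cell_line),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> Bmax %.1f, logKd %.3f +/- %.3f (KD %.3g nM, n=%d wells)\n",
              x$Bmax, x$logKd, x$se_logKd, 10^x$logKd * 1e9, x$n_points))
  invisible(x)
}

#' Fit competition binding on the percent-specific-binding scale
#'
#' Wells are converted per plate to percent uninhibited specific binding,
#' `100 * (well - mean nonspecific) / (mean total - mean nonspecific)`, and
#' the sigmoid `100 - 100 * A / (A + IC50) + NS` is fitted with log10 IC50
#' and the nonspecific floor `NS` free.  If no concentration inhibits at
#' least half of the specific binding the result is censored: a one-sided
#' bound `logIC50 > log10(top concentration)` is reported instead of a
#' point estimate (no extrapolation).
#'
#' @param data a [conc_series()] with `total` and `nonspecific` control
#'   wells (>= 3 each) and a competitor dilution series spanning >= 3 log
#'   units.
#' @return an object of class `competition_fit` with fields `logIC50`,
#'   `se_logIC50`, `ns_level`, `rss`, `n_points`, and `censored`
#'   (`NULL` or a one-sided bound).
#' @export
fit_competition <- function(data) {
  stopifnot(inherits(data, "conc_series"))
  tot <- data$controls$total; nsb <- data$controls$nonspecific
  if (is.null(tot) || is.null(nsb)) stop("competition fit requires total and nonspecific controls")
  if (length(tot) < 3 || length(nsb) < 3) stop("controls need at least 3 wells each")
  span <- log10(max(data$conc)) - log10(min(data$conc))
  if (span < 3) stop("competitor series must span at least 3 log units")
  window <- mean(tot) - mean(nsb)
  if (window <= 0) stop("no specific-binding window (total <= nonspecific)")
  pct <- 100 * (as.matrix(data$signal) - mean(nsb)) / window
  st <- .stack_reps(data$conc, pct)

  # censoring: does any concentration inhibit >= 50% of specific binding?
  mean_pct <- rowMeans(pct)
  if (min(mean_pct) > 50) {
    return(structure(
      list(logIC50 = NA_real_, se_logIC50 = NA_real_, ns_level = NA_real_,
           rss = NA_real_, n_points = length(st$y),
           censored = list(direction = ">", bound = log10(max(data$conc))),
           compound_id = data$compound_id, cell_line = data$meta$cell_line),
      class = "competition_fit"
    ))
  }

  fn <- function(par, x) eq_competition(x, 10^par[1], par[2])
  # start near the concentration closest to 50% inhibition
  i50 <- which.min(abs(mean_pct - 50))
  fit <- .ls_fit(fn, start = c(logIC50 = log10(data$conc[i50]), ns = 0),
                 lower = c(.LOG_LO, -20), upper = c(.LOG_HI, 100),
                 x = st$x, y = st$y)
  structure(
    list(logIC50 = unname(fit$par[1]), se_logIC50 = unname(fit$se[1]),
         ns_level = max(unname(fit$par[2]), 0), rss = fit$rss, n_points = fit$n,
         censored = NULL,
         compound_id = data$compound_id, cell_line = data$meta$cell_line),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  if (!is.null(x$censored)) {
    cat(sprintf("<competition_fit> %s: no 50%% inhibition up to %.3g M (logIC50 > %.2f)\n",
                x$compound_id, 10^x$censored$bound, x$censored$bound))
  } else {
    cat(sprintf("<competition_fit> %s: logIC50 %.3f +/- %.3f (n=%d wells)\n",
                x$compound_id, x$logIC50, x$se_logIC50, x$n_points))
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of a competition IC50 to a KD
#'
#' `KD = IC50 / (1 + L / KD_L)` where `L` is the fixed radioligand
#' concentration and `KD_L` its affinity.  Censoring propagates: a bound on
#' the IC50 becomes the corresponding bound on the KD.
#'
#' @param ic50 competitor IC50 (molar), or a [fit_competition()] result.
#' @param radioligand_conc fixed radioligand concentration (molar).
#' @param radioligand_Kd radioligand dissociation constant (molar).
#' @param se optional SE of log10 IC50, carried through unchanged (the
#'   correction is a constant shift on the log scale).
#' @param n replicate count for provenance.
#' @param compound_id,cell_line provenance labels.
#' @return an [affinity_estimate()] with method `"competition_cheng_prusoff"`.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_Kd,
                          se = NA_real_, n = 1L,
                          compound_id = NA_character_, cell_line = NA_character_) {
  if (radioligand_conc <= 0 || radioligand_Kd <= 0) stop("non-positive radioligand input")
  shift <- log10(1 + radioligand_conc / radioligand_Kd)
  if (inherits(ic50, "competition_fit")) {
    fit <- ic50
    cid <- if (is.na(compound_id)) fit$compound_id else compound_id
    cl <- if (is.na(cell_line)) fit$cell_line else cell_line
    if (!is.null(fit$censored)) {
      return(affinity_estimate(NA, method = "competition_cheng_prusoff", n = n,
                               censored = list(direction = fit$censored$direction,
                                               bound = fit$censored$bound - shift),
                               compound_id = cid, cell_line = cl))
    }
    return(affinity_estimate(fit$logIC50 - shift, se = fit$se_logIC50,
                             method = "competition_cheng_prusoff", n = n,
                             compound_id = cid, cell_line = cl))
  }
  if (ic50 <= 0) stop("non-positive IC50")
  affinity_estimate(log10(ic50) - shift, se = se,
                    method = "competition_cheng_prusoff", n = n,
                    compound_id = compound_id, cell_line = cell_line)
}

#' Selectivity ratio between two receptors
#'
#' Fold-difference in linear KD between two log10 affinities:
#' `10^(logKd_a - logKd_b)`.  A value above 1 means the compound has higher
#' affinity (lower KD) at the receptor supplying `logKd_b`; e.g. a
#' beta2-selective antagonist's beta1-over-beta2 ratio of 603 means 603-fold
#' higher affinity at the beta2 receptor.
#'
#' @param logKd_a,logKd_b log10 molar point estimates (censored estimates
#'   are rejected).
#' @return the fold ratio (numeric).
#' @export
selectivity_ratio <- function(logKd_a, logKd_b) {
  grab <- function(x) {
    if (inherits(x, "affinity_estimate")) {
      if (is_censored(x)) stop("selectivity ratio is undefined for censored estimates")
      x$logKd
    } else x
  }
  a <- grab(logKd_a); b <- grab(logKd_b)
  if (!is.finite(a) || !is.finite(b)) stop("selectivity ratio needs point estimates")
  10^(a - b)
}
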