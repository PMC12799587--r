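#' Assay record: a compound's concentration series with plate controls
#'
#' The universal container for one simulated or imported plate experiment:
#' a strictly increasing set of in-well concentrations (molar), a matrix of
#' replicate signals (rows = concentrations, columns = replicates), the plate
#' controls the assay type requires, and free-form metadata (cell line,
#' radioligand concentration, any fixed reference agonist or fixed
#' antagonist).
#'
#' Controls by assay type:
#' * binding competition: `total` and `nonspecific`, numeric vectors of at
#'   least 3 wells each (fixed radioligand concentration);
#' * binding saturation: `nonspecific`, a matrix matched row-for-row to
#'   `conc` (the radioligand dilution series); `signal` holds total binding;
#' * functional: `basal` and `positive` (10 uM isoprenaline) vectors, plus
#'   optionally `reference` (fixed reference agonist alone) for dip designs.
#'
#' @param compound_id compound identifier.
#' @param conc strictly increasing positive concentrations (molar).
#' @param signal numeric matrix (or vector) of replicate signals per
#'   concentration.
#' @param controls named list of control readings (see above).
#' @param meta named list of metadata.
#' @return an object of class `conc_series`.
#' @export
conc_series <- function(compound_id, conc, signal, controls = list(), meta = list()) {
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc <= 0)) stop("concentrations must be positive and finite")
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = length(conc))
  signal <- as.matrix(signal)
  if (nrow(signal) != length(conc)) stop("signal must have one row per concentration")
  if (is.unsorted(conc, strictly = TRUE)) {
    o <- order(conc)
    if (anyDuplicated(conc)) stop("duplicate concentrations")
    conc <- conc[o]; signal <- signal[o, , drop = FALSE]
    for (nm in names(controls)) {
      if (is.matrix(controls[[nm]]) && nrow(controls[[nm]]) == length(conc)) {
        controls[[nm]] <- controls[[nm]][o, , drop = FALSE]
      }
    }
  }
  if (any(!is.finite(signal))) stop("signals must be finite")
  structure(
    list(compound_id = compound_id, conc = conc, signal = signal,
         controls = controls, meta = meta),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> %s: %d concentrations (%.3g to %.3g M), %d replicate(s)\n",
              x$compound_id, length(x$conc), min(x$conc), max(x$conc), ncol(x$signal)))
  if (length(x$controls)) cat("  controls:", paste(names(x$controls), collapse = ", "), "\n")
  if (!is.null(x$meta$cell_line)) cat("  cell line:", x$meta$cell_line, "\n")
  invisible(x)
}

#' Affinity estimate with provenance
#'
#' A log10 KD (molar) with its standard error, the method that produced it
#' (saturation or competition binding, Gaddum dose-ratio, Schild regression,
#' or Stephenson's partial-agonist method) and, for experiments where no
#' shift / no inhibition was measurable, a one-sided censoring bound instead
#' of a point value (e.g. "no shift at 10 uM").
#'
#' @param logKd log10 molar point estimate (NA when censored).
#' @param se standard error in log10 units (optional).
#' @param method one of `"saturation"`, `"competition_cheng_prusoff"`,
#'   `"gaddum"`, `"schild"`, `"stephenson"`.
#' @param n number of replicate experiments or curves behind the estimate.
#' @param censored `NULL` for a point estimate, otherwise
#'   `list(direction = ">" or "<", bound = log10 molar)`.
#' @param compound_id,cell_line,agonist_id optional provenance labels.
#' @return an object of class `affinity_estimate`.
#' @export
affinity_estimate <- function(logKd, se = NA_real_, method, n = 1L, censored = NULL,
                              compound_id = NA_character_, cell_line = NA_character_,
                              agonist_id = NA_character_) {
  method <- match.arg(method, c("saturation", "competition_cheng_prusoff",
                                "gaddum", "schild", "stephenson"))
  if (!is.null(censored)) {
    stopifnot(censored$direction %in% c(">", "<"), is.finite(censored$bound))
    logKd <- NA_real_
  } else if (!is.finite(logKd)) {
    stop("point estimate requires a finite logKd (or supply a censoring bound)")
  }
  structure(
    list(logKd = logKd, se = se, method = method, n = as.integer(n),
         censored = censored, compound_id = compound_id,
         cell_line = cell_line, agonist_id = agonist_id),
    class = "affinity_estimate"
  )
}

#' @export
print.affinity_estimate <- function(x, ...) {
  if (!is.null(x$censored)) {
    cat(sprintf("<affinity_estimate> %s: logKd %s %.2f (%s, censored, n=%d)\n",
                x$compound_id, x$censored$direction, x$censored$bound, x$method, x$n))
  } else {
    cat(sprintf("<affinity_estimate> %s: logKd %.3f +/- %s (%s, n=%d)\n",
                x$compound_id, x$logKd,
                ifelse(is.finite(x$se), sprintf("%.3f", x$se), "NA"), x$method, x$n))
  }
  invisible(x)
}

#' Is an affinity estimate censored?
#' @param x an `affinity_estimate`.
#' @return logical.
#' @export
is_censored <- function(x) !is.null(x$censored)

# one row per estimate, for results tables
.affinity_row <- function(x) {
  data.frame(
    compound = x$compound_id, cell_line = x$cell_line, agonist = x$agonist_id,
    method = x$method, logKd = x$logKd, se = x$se, n = x$n,
    censor_dir = if (is.null(x$censored)) NA_character_ else x$censored$direction,
    censor_bound = if (is.null(x$censored)) NA_real_ else x$censored$bound,
    stringsAsFactors = FALSE
  )
}
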