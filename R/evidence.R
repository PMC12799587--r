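#' Thresholds for the secondary-conformation evidence rubric
#'
#' The four criteria are qualitative in origin ("substantially higher
#' concentrations", "relatively resistant"); these are the quantitative
#' stand-ins, all configurable:
#'
#' * `gap_A`: log10 units by which an agonist EC50 must exceed the CCE KD
#'   (criterion A).  Default 1.0 (10-fold): observed positive cases have
#'   gaps of about 2 or more and negative cases 0.8 or less, so 1.0
#'   separates them with margin on both sides.
#' * `gap_B`: log10 units by which the reference antagonist's apparent KD
#'   against the test agonist must exceed its KD against the reference
#'   CCE agonist (criterion B).  Default 1.0.
#' * `emax_floor`: minimum response (percent of positive control) for a
#'   monophasic curve to support criterion A; smaller responses give too
#'   unreliable an EC50 to anchor a KD comparison.  Default 15.
#' * `alpha`: significance level for all model-selection F-tests.
#' * `guard_sep`, `guard_frac`: two-site acceptance guard (see
#'   [select_cr_model()]).
#' * `dip_sep`: required log10 separation between the inhibitory and
#'   stimulatory limbs of a dip curve (criterion D).
#' * `dr_min`: minimum Gaddum dose ratio treated as a real shift.
#'
#' @param gap_A,gap_B,emax_floor,alpha,guard_sep,guard_frac,dip_sep,dr_min
#'   see above.
#' @return a named list of thresholds.
#' @export
study_thresholds <- function(gap_A = 1.0, gap_B = 1.0, emax_floor = 15,
                             alpha = 0.05, guard_sep = 1.0, guard_frac = 0.10,
                             dip_sep = 0.5, dr_min = 1.2) {
  list(gap_A = gap_A, gap_B = gap_B, emax_floor = emax_floor, alpha = alpha,
       guard_sep = guard_sep, guard_frac = guard_frac, dip_sep = dip_sep,
       dr_min = dr_min)
}

.call <- function(call, ...) {
  stopifnot(call %in% c("positive", "negative", "indeterminate"))
  c(list(call = call), list(...))
}

#' Evaluate the four secondary-conformation evidence criteria
#'
#' Applies the A-D rubric to one compound in one cell line:
#'
#' * **A** - the compound's own agonist EC50 lies substantially above
#'   (higher concentration than) its catecholamine-conformation KD.
#'   Evaluated only for a reliable monophasic response (Emax at or above
#'   `emax_floor`); a biphasic curve is already criterion C and its first
#'   component sits at the CCE affinity, so A is indeterminate there.
#'   Positive when `logEC50 - logKd_cce >= gap_A` and the gap exceeds twice
#'   its pooled standard error.
#' * **B** - inhibiting the compound's agonist response needs substantially
#'   more reference antagonist than inhibiting the reference CCE agonist's
#'   response: apparent antagonist KD difference at or above `gap_B`.
#' * **C** - the compound's own concentration-response curve is best
#'   described by two stimulatory sites ([select_cr_model()] chose
#'   `two_site`).
#' * **D** - against a fixed reference agonist the compound first inhibits
#'   and then stimulates, with both limbs significant and separated (the
#'   dip design chose `dip`).
#'
#' Missing or censored inputs make the affected call `indeterminate`,
#' never negative.
#'
#' @param binding list with optional entries `cce` and `sce`
#'   ([affinity_estimate()]s from competition binding).
#' @param functional list with `own` (the [select_cr_model()] result for
#'   the compound alone) and optionally `dip` (the fixed-reference design
#'   choice).
#' @param shifts list with optional entries `cce` (functional CCE affinity
#'   from Gaddum/Stephenson against the reference agonist),
#'   `antagonist_vs_compound`, `antagonist_vs_reference` (reference
#'   antagonist KDs), and `sce` (affinity against the SCE probe agonist).
#' @param compound_id,cell_line labels.
#' @param thresholds a [study_thresholds()] list.
#' @return an object of class `evidence_profile`; every call carries the
#'   numbers it was made from.
#' @export
evaluate_evidence <- function(binding = list(), functional = list(), shifts = list(),
                              compound_id = NA_character_, cell_line = NA_character_,
                              thresholds = study_thresholds()) {
  own <- functional$own
  chosen <- if (!is.null(own)) own$chosen else NA_character_

  pt <- function(est) !is.null(est) && inherits(est, "affinity_estimate") && !is_censored(est)

  # best CCE affinity: functional (Stephenson/Gaddum) preferred over binding
  cce <- if (pt(shifts$cce)) shifts$cce else if (pt(binding$cce)) binding$cce else NULL

  # ---- criterion A -------------------------------------------------------
  if (is.null(own) || !chosen %in% c("one_site", "two_site")) {
    A <- .call("indeterminate", reason = "no fitted agonist response")
  } else if (chosen == "two_site") {
    A <- .call("indeterminate", reason = "biphasic response; shape assessed under criterion C")
  } else {
    fit <- own$candidates$one_site
    if (fit$Emax_pct < thresholds$emax_floor) {
      A <- .call("indeterminate", reason = sprintf(
        "response too small to anchor an EC50 (Emax %.1f%% < %g%%)",
        fit$Emax_pct, thresholds$emax_floor))
    } else if (is.null(cce)) {
      A <- .call("indeterminate", reason = "no point estimate of CCE affinity")
    } else {
      gap <- fit$logEC50 - cce$logKd
      se <- sqrt(sum(c(fit$se_logEC50, cce$se)^2, na.rm = TRUE))
      ok <- gap >= thresholds$gap_A && gap > 2 * se
      A <- .call(if (ok) "positive" else "negative",
                 gap = gap, se = se, logEC50 = fit$logEC50, logKd_cce = cce$logKd,
                 affinity_method = cce$method)
    }
  }

  # ---- criterion B -------------------------------------------------------
  kb_c <- shifts$antagonist_vs_compound
  kb_r <- shifts$antagonist_vs_reference
  if (!pt(kb_c) || !pt(kb_r)) {
    B <- .call("indeterminate", reason = "antagonist KD not measured against this agonist")
  } else {
    gap <- kb_c$logKd - kb_r$logKd
    B <- .call(if (gap >= thresholds$gap_B) "positive" else "negative",
               gap = gap, logKd_vs_compound = kb_c$logKd,
               logKd_vs_reference = kb_r$logKd)
  }

  # ---- criterion C -------------------------------------------------------
  if (is.null(own)) {
    C <- .call("indeterminate", reason = "no concentration-response curve")
  } else if (chosen == "two_site") {
    two <- own$candidates$two_site
    C <- .call("positive", p_value = own$p_value,
               logEC1 = two$logEC1_50, logEC2 = two$logEC2_50,
               site1_pct = two$site1_pct)
  } else {
    C <- .call("negative", p_value = own$p_value, model = chosen)
  }

  # ---- criterion D -------------------------------------------------------
  dipm <- functional$dip
  if (is.null(dipm)) {
    D <- .call("indeterminate", reason = "no fixed-reference-agonist experiment")
  } else if (dipm$chosen == "dip") {
    dip <- dipm$candidates$dip
    D <- .call("positive", logIC50 = dip$logIC50, logEC50 = dip$logEC50,
               Smax_pct = dip$Smax_pct, p_stim = dipm$p_value,
               p_inhib = dipm$p_value_second)
  } else {
    D <- .call("negative", model = dipm$chosen)
  }

  # a monophasic call also needs a reliably non-zero span (Emax at least
  # three standard errors) before it counts as agonism; the nested F-test
  # alone admits too many noise-level "responses" across a large panel
  agonism <- !is.null(own) && chosen %in% c("one_site", "two_site")
  if (agonism && chosen == "one_site") {
    os <- own$candidates$one_site
    if (!is.null(os) && is.finite(os$se_Emax %||% NA_real_)) {
      agonism <- os$Emax_pct >= 3 * os$se_Emax
    }
  }
  affin <- list(binding$cce, binding$sce, shifts$cce, shifts$sce)
  affinity_present <- any(vapply(affin, pt, TRUE))
  any_measured <- any(vapply(affin, function(e) !is.null(e), TRUE))

  structure(
    list(compound_id = compound_id, cell_line = cell_line,
         A = A, B = B, C = C, D = D,
         agonism = agonism, affinity_present = affinity_present,
         affinity_measured = any_measured,
         binding = binding, shifts = shifts,
         classification = NA_character_),
    class = "evidence_profile"
  )
}

#' Pool evidence profiles for one compound across cell lines
#'
#' A criterion letter is positive if it is positive in any line, negative if
#' computed and never positive, and indeterminate if never computable;
#' agonism and measurable affinity likewise accumulate.
#'
#' @param profiles list of [evaluate_evidence()] results for one compound.
#' @return a pooled `evidence_profile` (cell_line `"pooled"`).
#' @export
pool_evidence <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- unique(vapply(profiles, `[[`, "", "compound_id"))
  if (length(ids) != 1) stop("profiles to pool must belong to one compound")
  pool_call <- function(letter) {
    calls <- vapply(profiles, function(p) p[[letter]]$call, "")
    if (any(calls == "positive")) {
      return(profiles[[which(calls == "positive")[1]]][[letter]])
    }
    if (any(calls == "negative")) {
      return(profiles[[which(calls == "negative")[1]]][[letter]])
    }
    profiles[[1]][[letter]]
  }
  out <- profiles[[1]]
  out$cell_line <- "pooled"
  for (l in c("A", "B", "C", "D")) out[[l]] <- pool_call(l)
  out$agonism <- any(vapply(profiles, `[[`, TRUE, "agonism"))
  out$affinity_present <- any(vapply(profiles, `[[`, TRUE, "affinity_present"))
  out$affinity_measured <- any(vapply(profiles, `[[`, TRUE, "affinity_measured"))
  out$classification <- NA_character_
  out
}

#' Classify a compound from its evidence profile
#'
#' Decision order: no receptor interaction (affinity censored everywhere
#' and no agonism) -> neutral antagonist (binds, never stimulates) ->
#' biphasic agonist (criterion C positive) -> secondary-conformation
#' agonist (A and B positive together, or D positive) -> conventional
#' (catecholamine-conformation) agonist.
#'
#' @param profile an [evaluate_evidence()] / [pool_evidence()] result.
#' @return the profile with `classification` filled in; one of
#'   `"no_interaction"`, `"neutral_antagonist"`, `"biphasic_agonist"`,
#'   `"sce_agonist"`, `"cce_agonist"`.
#' @export
classify_compound <- function(profile) {
  stopifnot(inherits(profile, "evidence_profile"))
  pos <- function(l) profile[[l]]$call == "positive"
  cls <- if (!profile$affinity_present && !profile$agonism) {
    "no_interaction"
  } else if (!profile$agonism) {
    "neutral_antagonist"
  } else if (!profile$affinity_present && !profile$affinity_measured) {
    stop("contradictory profile: fitted agonism for a compound with no measured affinity data")
  } else if (pos("C")) {
    "biphasic_agonist"
  } else if ((pos("A") && pos("B")) || pos("D")) {
    "sce_agonist"
  } else {
    "cce_agonist"
  }
  profile$classification <- cls
  profile
}

#' @export
print.evidence_profile <- function(x, ...) {
  letters <- paste0(vapply(c("A", "B", "C", "D"), function(l) {
    switch(x[[l]]$call, positive = l, negative = "-", indeterminate = "?")
  }, ""))
  cat(sprintf("<evidence_profile> %s [%s]: %s%s\n", x$compound_id, x$cell_line,
              paste(letters, collapse = ""),
              if (!is.na(x$classification)) paste0(" -> ", x$classification) else ""))
  invisible(x)
}

#' Compare wild-type and mutant-receptor evidence profiles
#'
#' Reports, per criterion, whether evidence present at the wild-type
#' receptor was lost (positive became negative) or gained in a second cell
#' line, and raises the headline flag `sce_lost` when at least one
#' criterion was lost while the compound still behaves as a conventional
#' ligand (a catecholamine-conformation agonist or neutral antagonist) at
#' the mutant.
#'
#' @param profile_wt,profile_mut classified [evidence_profile()]s for the
#'   same compound in the two lines.
#' @return a list of class `loss_of_evidence`: `compound_id`, per-letter
#'   `lost` / `gained`, `sce_lost`, and both classifications.
#' @export
compare_lines <- function(profile_wt, profile_mut) {
  stopifnot(inherits(profile_wt, "evidence_profile"),
            inherits(profile_mut, "evidence_profile"))
  if (!identical(profile_wt$compound_id, profile_mut$compound_id))
    stop("profiles belong to different compounds")
  lost <- gained <- character()
  for (l in c("A", "B", "C", "D")) {
    wt <- profile_wt[[l]]$call; mu <- profile_mut[[l]]$call
    if (wt == "positive" && mu == "negative") lost <- c(lost, l)
    if (wt != "positive" && mu == "positive") gained <- c(gained, l)
  }
  cce_retained <- profile_mut$classification %in% c("cce_agonist", "neutral_antagonist")
  structure(
    list(compound_id = profile_wt$compound_id, lost = lost, gained = gained,
         sce_lost = length(lost) > 0 && cce_retained,
         classification_wt = profile_wt$classification,
         classification_mut = profile_mut$classification),
    class = "loss_of_evidence"
  )
}

#' @export
print.loss_of_evidence <- function(x, ...) {
  cat(sprintf("<loss_of_evidence> %s: lost {%s}, gained {%s}%s (%s -> %s)\n",
              x$compound_id, paste(x$lost, collapse = ""),
              paste(x$gained, collapse = ""),
              if (x$sce_lost) " [SCE lost]" else "",
              x$classification_wt, x$classification_mut))
  invisible(x)
}
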