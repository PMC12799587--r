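# Study-level analysis: from a bag of plates to affinities, fits, evidence
# profiles and classifications.

# infer the experimental design of a series from its metadata
.infer_design <- function(s, reference_agonist, sce_probe) {
  if (!is.null(s$meta$design)) return(s$meta$design)
  assay <- s$meta$assay %||% "functional"
  if (assay != "functional") return(assay)
  if (!is.null(s$meta$fixed_reference)) return("dip")
  fa <- s$meta$fixed_antagonist
  if (is.null(fa)) return("functional_alone")
  if (identical(s$compound_id, reference_agonist)) return("cce_shift")
  if (identical(s$compound_id, sce_probe)) return("sce_shift")
  "antagonist_shift"
}

# predicted percent response of a compound alone at one concentration,
# from its selected concentration-response model
.predict_own_pct <- function(choice, conc) {
  if (is.null(choice)) return(0)
  if (choice$chosen == "one_site") {
    f <- choice$candidates$one_site
    return(eq_one_site(conc, f$Emax_pct, 10^f$logEC50))
  }
  if (choice$chosen == "two_site") {
    f <- choice$candidates$two_site
    return(eq_two_site(conc, f$total_Emax_pct, f$site1_pct,
                       10^f$logEC1_50, 10^f$logEC2_50))
  }
  0
}

#' Analyse a complete set of study plates
#'
#' Runs the full pipeline over a list of [conc_series()] plates (typically
#' a [make_study_fixture()] bundle's plates, or plates imported with
#' [read_plate_csv()]): competition/saturation binding fits with
#' Cheng-Prusoff conversion, per-compound concentration-response model
#' selection, Gaddum/Schild/Stephenson shift analyses, the A-D evidence
#' rubric per cell line, pooled classification over the wild-type lines,
#' and the wild-type versus mutant loss-of-evidence contrast.
#'
#' @param plates named list of [conc_series()].
#' @param thresholds a [study_thresholds()] list.
#' @param reference_agonist,sce_probe,reference_antagonist the roles the
#'   rubric needs: the full agonist of the catecholamine conformation, the
#'   probe agonist of the secondary conformation, and the antagonist used
#'   for resistance comparisons.
#' @param wt_lines,mut_lines cell-line labels carrying the wild-type and
#'   mutant receptor (mutant optional).
#' @return a list of class `study_results`: `affinities` (tidy table),
#'   `fits` (per-curve model rows), `profiles` (per line), `pooled`
#'   (classified pooled profiles), `classification` (summary table),
#'   `contrast` (loss-of-evidence reports), `schild` (regression table),
#'   `saturation` (radioligand fits), `log` (character vector).
#' @export
analyze_plates <- function(plates, thresholds = study_thresholds(),
                           reference_agonist = "cimaterol",
                           sce_probe = "CGP12177",
                           reference_antagonist = "CGP20712A",
                           wt_lines = NULL, mut_lines = character()) {
  logline <- character()
  say <- function(...) logline <<- c(logline, sprintf(...))

  for (i in seq_along(plates)) {
    plates[[i]]$meta$design <- .infer_design(plates[[i]], reference_agonist, sce_probe)
  }
  lines_of <- vapply(plates, function(s) s$meta$cell_line %||% NA_character_, "")
  designs <- vapply(plates, function(s) s$meta$design, "")
  all_lines <- unique(lines_of)
  if (is.null(wt_lines)) wt_lines <- setdiff(all_lines, mut_lines)

  aff_rows <- list()
  keep <- function(est) { aff_rows[[length(aff_rows) + 1]] <<- .affinity_row(est); est }

  # ---- binding ------------------------------------------------------------
  binding_est <- list()   # [[line]][[compound]]
  sat_fits <- list()
  for (i in which(designs == "binding_competition")) {
    s <- plates[[i]]
    fit <- fit_competition(s)
    est <- cheng_prusoff(fit, s$meta$radioligand_conc, 10^s$meta$radioligand_logKd)
    binding_est[[lines_of[i]]][[s$compound_id]] <- keep(est)
  }
  for (i in which(designs == "binding_saturation")) {
    sat_fits[[lines_of[i]]] <- fit_saturation(plates[[i]])
  }

  # ---- functional curves, compound alone -----------------------------------
  choices <- list()   # [[line]][[compound]] -> model_choice
  fit_rows <- list()
  for (i in which(designs == "functional_alone")) {
    s <- plates[[i]]
    nc <- normalize_plate(s)
    ch <- select_cr_model(nc, alpha = thresholds$alpha,
                          guard_sep = thresholds$guard_sep,
                          guard_frac = thresholds$guard_frac,
                          dip_sep = thresholds$dip_sep)
    choices[[lines_of[i]]][[s$compound_id]] <- ch
    fit_rows[[length(fit_rows) + 1]] <- .fit_row(s, ch)
    say("model %s/%s: %s (p=%.3g)", lines_of[i], s$compound_id, ch$chosen, ch$p_value)
  }

  one_site_of <- function(line, compound) {
    ch <- choices[[line]][[compound]]
    if (is.null(ch)) return(NULL)
    ch$candidates$one_site %||% NULL
  }

  # ---- shift experiments ----------------------------------------------------
  shift_groups <- function(design_type) {
    idx <- which(designs == design_type)
    if (!length(idx)) return(list())
    key <- vapply(idx, function(i) {
      paste(lines_of[i], plates[[i]]$meta$fixed_antagonist$compound, sep = "\r")
    }, "")
    split(idx, key)
  }

  analyze_shift <- function(idx, agonist_id) {
    line <- lines_of[idx[1]]
    test_cmp <- plates[[idx[1]]]$meta$fixed_antagonist$compound
    ctl <- one_site_of(line, agonist_id)
    if (is.null(ctl) || isTRUE(ctl$unidentifiable)) return(NULL)
    concs <- vapply(idx, function(i) plates[[i]]$meta$fixed_antagonist$conc, 0)
    own <- max(vapply(concs, function(b)
      .predict_own_pct(choices[[line]][[test_cmp]], b), 0))
    normed <- lapply(idx, function(i) normalize_plate(plates[[i]]))
    if (own > 10) {
      # the fixed ligand is itself a partial agonist here: Stephenson route
      ests <- list()
      for (j in seq_along(idx)) {
        e <- tryCatch(stephenson_kd(ctl, normed[[j]], concs[j]),
                      error = function(e) {
                        say("stephenson %s/%s vs %s at %.3g M failed: %s",
                            line, test_cmp, agonist_id, concs[j], conditionMessage(e))
                        NULL
                      })
        if (!is.null(e)) ests[[length(ests) + 1]] <- e
      }
      if (!length(ests)) return(NULL)
      lk <- vapply(ests, `[[`, 0, "logKd")
      est <- affinity_estimate(mean(lk),
                               se = if (length(lk) > 1) stats::sd(lk) / sqrt(length(lk)) else ests[[1]]$se,
                               method = "stephenson", n = length(lk),
                               compound_id = test_cmp, cell_line = line,
                               agonist_id = agonist_id)
      return(list(est = keep(est), experiment = NULL))
    }
    blocked <- lapply(seq_along(idx), function(j)
      list(conc = concs[j], fit = fit_one_site(normed[[j]])))
    exper <- shift_experiment(ctl, blocked, antagonist_id = test_cmp,
                              agonist_id = agonist_id, cell_line = line)
    est <- withCallingHandlers(
      gaddum_kd(exper, dr_min = thresholds$dr_min),
      warning = function(w) { say("gaddum %s/%s: %s", line, test_cmp, conditionMessage(w))
        invokeRestart("muffleWarning") })
    list(est = keep(est), experiment = exper)
  }

  cce_func <- list(); sce_func <- list(); ant_vs <- list()
  schild_rows <- list()
  for (grp in shift_groups("cce_shift")) {
    res <- analyze_shift(grp, reference_agonist)
    if (is.null(res)) next
    line <- res$est$cell_line; cmp <- res$est$compound_id
    cce_func[[line]][[cmp]] <- res$est
    if (!is.null(res$experiment) && length(grp) >= 3 && !is_censored(res$est)) {
      sf <- tryCatch(schild_fit(res$experiment), error = function(e) NULL,
                     warning = function(w) NULL)
      if (!is.null(sf)) {
        schild_rows[[length(schild_rows) + 1]] <- data.frame(
          compound = cmp, cell_line = line, slope = sf$slope,
          se_slope = sf$se_slope, intercept_logKd = sf$intercept_logKd,
          r_squared = sf$r_squared, n = sf$n_points,
          competitive = sf$competitive, stringsAsFactors = FALSE)
      }
    }
  }
  for (grp in shift_groups("sce_shift")) {
    res <- analyze_shift(grp, sce_probe)
    if (is.null(res)) next
    sce_func[[res$est$cell_line]][[res$est$compound_id]] <- res$est
  }
  for (i in which(designs == "antagonist_shift")) {
    s <- plates[[i]]
    line <- lines_of[i]
    agonist <- s$compound_id
    fa <- s$meta$fixed_antagonist
    ctl <- one_site_of(line, agonist)
    if (is.null(ctl)) next
    blocked <- list(list(conc = fa$conc, fit = fit_one_site(normalize_plate(s))))
    exper <- shift_experiment(ctl, blocked, antagonist_id = fa$compound,
                              agonist_id = agonist, cell_line = line)
    est <- suppressWarnings(gaddum_kd(exper, dr_min = thresholds$dr_min))
    ant_vs[[line]][[agonist]] <- keep(est)
  }

  # ---- dip designs ----------------------------------------------------------
  dips <- list()
  for (i in which(designs == "dip")) {
    s <- plates[[i]]
    nc <- normalize_plate(s)
    ch <- select_cr_model(nc, alpha = thresholds$alpha,
                          guard_sep = thresholds$guard_sep,
                          guard_frac = thresholds$guard_frac,
                          dip_sep = thresholds$dip_sep)
    dips[[lines_of[i]]][[s$compound_id]] <- ch
    fit_rows[[length(fit_rows) + 1]] <- .fit_row(s, ch)
    say("dip %s/%s: %s", lines_of[i], s$compound_id, ch$chosen)
  }

  # ---- evidence -------------------------------------------------------------
  genotype_of <- function(line) if (line %in% mut_lines) "mut" else "wt"
  pick_point <- function(lst) {
    for (e in lst) if (!is.null(e) && !is_censored(e)) return(e)
    for (e in lst) if (!is.null(e)) return(e)
    NULL
  }
  lookup_geno <- function(table, line, compound) {
    geno <- genotype_of(line)
    same <- table[[line]][[compound]]
    others <- lapply(setdiff(names(table), line), function(l) {
      if (genotype_of(l) == geno) table[[l]][[compound]] else NULL
    })
    pick_point(c(list(same), others))
  }

  compounds <- unique(vapply(plates, `[[`, "", "compound_id"))
  compounds <- setdiff(compounds, "radioligand")
  func_lines <- unique(lines_of[designs == "functional_alone"])

  profiles <- list()
  for (cmp in compounds) {
    for (line in func_lines) {
      if (is.null(choices[[line]][[cmp]])) next
      prof <- evaluate_evidence(
        binding = list(cce = lookup_geno(binding_est, line, cmp),
                       sce = NULL),
        functional = list(own = choices[[line]][[cmp]],
                          dip = dips[[line]][[cmp]]),
        shifts = list(cce = lookup_geno(cce_func, line, cmp),
                      sce = lookup_geno(sce_func, line, cmp),
                      antagonist_vs_compound = ant_vs[[line]][[cmp]],
                      antagonist_vs_reference = cce_func[[line]][[reference_antagonist]]),
        compound_id = cmp, cell_line = line, thresholds = thresholds)
      profiles[[line]][[cmp]] <- prof
    }
  }

  pooled <- list(); mut_profiles <- list(); contrast <- list()
  for (cmp in compounds) {
    wt_p <- Filter(Negate(is.null), lapply(intersect(wt_lines, names(profiles)),
                                           function(l) profiles[[l]][[cmp]]))
    if (length(wt_p)) {
      pooled[[cmp]] <- classify_compound(pool_evidence(wt_p))
    }
    mu_p <- Filter(Negate(is.null), lapply(intersect(mut_lines, names(profiles)),
                                           function(l) profiles[[l]][[cmp]]))
    if (length(mu_p)) {
      mut_profiles[[cmp]] <- classify_compound(if (length(mu_p) > 1)
        pool_evidence(mu_p) else mu_p[[1]])
      if (!is.null(pooled[[cmp]])) {
        contrast[[cmp]] <- compare_lines(pooled[[cmp]], mut_profiles[[cmp]])
      }
    }
  }

  classification <- do.call(rbind, lapply(names(pooled), function(cmp) {
    p <- pooled[[cmp]]
    calls <- vapply(c("A", "B", "C", "D"), function(l) p[[l]]$call, "")
    data.frame(
      compound = cmp,
      A = calls[1], B = calls[2], C = calls[3], D = calls[4],
      evidence = paste0(c("A", "B", "C", "D")[calls == "positive"], collapse = ""),
      gap_A = if (!is.null(p$A$gap)) p$A$gap else NA_real_,
      gap_B = if (!is.null(p$B$gap)) p$B$gap else NA_real_,
      classification = p$classification, stringsAsFactors = FALSE)
  }))

  structure(
    list(affinities = do.call(rbind, aff_rows), fits = do.call(rbind, fit_rows),
         profiles = profiles, pooled = pooled, mut_profiles = mut_profiles,
         classification = classification, contrast = contrast,
         schild = if (length(schild_rows)) do.call(rbind, schild_rows) else NULL,
         saturation = sat_fits,
         binding = binding_est, cce_func = cce_func, sce_func = sce_func,
         ant_vs = ant_vs, choices = choices, dips = dips,
         thresholds = thresholds, log = logline),
    class = "study_results"
  )
}

.fit_row <- function(s, ch) {
  row <- data.frame(cell_line = s$meta$cell_line %||% NA, compound = s$compound_id,
                    design = s$meta$design, model = ch$chosen,
                    p_model = ch$p_value, logEC50 = NA_real_, Emax_pct = NA_real_,
                    logEC1_50 = NA_real_, logEC2_50 = NA_real_, site1_pct = NA_real_,
                    logIC50 = NA_real_, Smax_pct = NA_real_, stringsAsFactors = FALSE)
  if (ch$chosen == "one_site" && !is.null(ch$candidates$one_site)) {
    row$logEC50 <- ch$candidates$one_site$logEC50
    row$Emax_pct <- ch$candidates$one_site$Emax_pct
  }
  if (ch$chosen == "two_site" && !is.null(ch$candidates$two_site)) {
    tw <- ch$candidates$two_site
    row$logEC1_50 <- tw$logEC1_50; row$logEC2_50 <- tw$logEC2_50
    row$site1_pct <- tw$site1_pct; row$Emax_pct <- tw$total_Emax_pct
  }
  if (ch$chosen == "dip" && !is.null(ch$candidates$dip)) {
    dp <- ch$candidates$dip
    row$logIC50 <- dp$logIC50; row$logEC50 <- dp$logEC50; row$Smax_pct <- dp$Smax_pct
  }
  row
}

#' Analyse a simulated study bundle
#'
#' Convenience wrapper running [analyze_plates()] with the bundle's own
#' reference-ligand roles and line genotypes.
#'
#' @param bundle a [make_study_fixture()] result.
#' @param thresholds a [study_thresholds()] list.
#' @return a `study_results` list.
#' @export
analyze_study <- function(bundle, thresholds = study_thresholds()) {
  stopifnot(inherits(bundle, "study_bundle"))
  lines <- vapply(bundle$configs, `[[`, "", "cell_line")
  analyze_plates(bundle$plates, thresholds = thresholds,
                 reference_agonist = bundle$reference_agonist,
                 sce_probe = bundle$sce_probe,
                 reference_antagonist = bundle$reference_antagonist,
                 wt_lines = unname(lines[bundle$wt_lines]),
                 mut_lines = unname(lines[bundle$mut_lines]))
}

#' Run the pipeline from a configuration
#'
#' Drives the whole analysis from a flat `key = value` configuration file
#' (or an equivalent named list): either `mode = simulate` with a `seed`,
#' or `plates_csv = <path>` pointing at plate data written in the
#' [write_plate_csv()] dialect.  Threshold keys (`gap_A`, `gap_B`,
#' `emax_floor`, `alpha`, `dip_sep`, `dr_min`, `guard_sep`, `guard_frac`)
#' override the defaults and are recorded in the log.  Results are written
#' to `out_dir` as tab-separated tables (`affinities.tsv`, `fits.tsv`,
#' `classification.tsv`, `schild.tsv`), a per-compound audit report
#' (`audit.txt`) and a run log (`run.log`).
#'
#' @param config path to a key = value file, or a named list.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return the `study_results` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_flat_config(config)
  get <- function(key, default = NULL) config[[key]] %||% default
  thr_keys <- c("gap_A", "gap_B", "emax_floor", "alpha", "guard_sep",
                "guard_frac", "dip_sep", "dr_min")
  thr <- study_thresholds()
  overridden <- character()
  for (k in thr_keys) {
    if (!is.null(config[[k]])) {
      thr[[k]] <- as.numeric(config[[k]])
      overridden <- c(overridden, sprintf("%s=%s", k, config[[k]]))
    }
  }
  mode <- get("mode", if (is.null(get("plates_csv"))) "simulate" else "csv")
  seed <- as.integer(get("seed", 1L))
  if (identical(mode, "simulate")) {
    bundle <- make_study_fixture(seed = seed,
                                 noise_sd = as.numeric(get("noise_sd", 0.05)))
    res <- analyze_study(bundle, thresholds = thr)
  } else {
    plates <- read_plate_csv(get("plates_csv"))
    res <- analyze_plates(plates, thresholds = thr,
                          reference_agonist = get("reference_agonist", "cimaterol"),
                          sce_probe = get("sce_probe", "CGP12177"),
                          reference_antagonist = get("reference_antagonist", "CGP20712A"),
                          mut_lines = strsplit(get("mut_lines", ""), ",")[[1]])
  }
  res$log <- c(sprintf("mode=%s seed=%d", mode, seed),
               if (length(overridden)) paste("threshold overrides:",
                                             paste(overridden, collapse = " ")),
               sprintf("thresholds: %s",
                       paste(sprintf("%s=%g", names(thr), unlist(thr)), collapse = " ")),
               res$log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) if (!is.null(df)) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(res$affinities, "affinities.tsv")
    wt(res$fits, "fits.tsv")
    wt(res$classification, "classification.tsv")
    wt(res$schild, "schild.tsv")
    writeLines(res$log, file.path(out_dir, "run.log"))
    writeLines(audit_report(res), file.path(out_dir, "audit.txt"))
  }
  invisible(res)
}

#' Parse a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Human-readable per-compound audit report
#'
#' @param results a `study_results` object.
#' @return character vector of report lines.
#' @export
audit_report <- function(results) {
  out <- character()
  for (cmp in names(results$pooled)) {
    p <- results$pooled[[cmp]]
    out <- c(out, sprintf("== %s: %s ==", cmp, p$classification))
    for (l in c("A", "B", "C", "D")) {
      cl <- p[[l]]
      detail <- if (!is.null(cl$gap)) sprintf(" gap=%.2f", cl$gap)
                else if (!is.null(cl$reason)) paste0(" (", cl$reason, ")")
                else ""
      out <- c(out, sprintf("  %s: %s%s", l, cl$call, detail))
    }
    if (!is.null(results$contrast[[cmp]])) {
      ct <- results$contrast[[cmp]]
      out <- c(out, sprintf("  wt vs mutant: lost {%s}%s",
                            paste(ct$lost, collapse = ""),
                            if (ct$sce_lost) " [SCE lost]" else ""))
    }
  }
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d affinity estimates, %d curves, %d classified compounds\n",
              nrow(x$affinities), nrow(x$fits),
              if (is.null(x$classification)) 0 else nrow(x$classification)))
  if (!is.null(x$classification)) print(x$classification[, c("compound", "evidence", "classification")])
  invisible(x)
}
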