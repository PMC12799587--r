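#' Plate CSV dialect
#'
#' Plates are exchanged as one CSV row per well with the columns:
#'
#' | column | content |
#' |---|---|
#' | `plate_id` | plate identifier; (`plate_id`, `well`) is unique |
#' | `well` | well label (A1..H12) |
#' | `compound_id` | compound in the well (or the radioligand) |
#' | `role` | `test`, `total`, `nsb`, `basal`, `positive`, `reference` |
#' | `conc_M` | final in-well concentration, molar (test wells and binding dilution series) |
#' | `replicate` | replicate index within the concentration |
#' | `signal` | raw plate-reader signal |
#' | `assay` | `binding_saturation`, `binding_competition`, `functional` |
#' | `cell_line` | cell line label |
#' | `fixed_reference_id`, `fixed_reference_conc_M` | fixed reference agonist, if any |
#' | `fixed_antagonist_id`, `fixed_antagonist_conc_M` | fixed antagonist, if any |
#' | `radioligand_conc_M`, `radioligand_logKd` | binding-plate radioligand metadata |
#'
#' Concentrations are stored in molar; en-dash/minus variants and `nM`/`uM`
#' suffixes in numeric fields are normalised on read.
#'
#' @name plate-csv
NULL

.CSV_COLS <- c("plate_id", "well", "compound_id", "role", "conc_M", "replicate",
               "signal", "assay", "cell_line", "fixed_reference_id",
               "fixed_reference_conc_M", "fixed_antagonist_id",
               "fixed_antagonist_conc_M", "radioligand_conc_M", "radioligand_logKd")

# normalise unicode minus signs and optional concentration unit suffixes
.parse_num <- function(x) {
  x <- gsub("−|–", "-", trimws(as.character(x)))
  mult <- rep(1, length(x))
  pick <- function(pat, m) {
    hit <- grepl(pat, x, ignore.case = FALSE)
    mult[hit] <<- m
    x[hit] <<- sub(pat, "", x[hit])
  }
  pick("nM$", 1e-9); pick("(uM|µM)$", 1e-6); pick("mM$", 1e-3); pick("M$", 1)
  suppressWarnings(as.numeric(x)) * mult
}

.well_labels <- function(n) {
  if (n > 96) stop("more than 96 wells on one plate")
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[seq_len(n)]
}

#' Write concentration series to a plate CSV
#'
#' @param series a [conc_series()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(series, path) {
  if (inherits(series, "conc_series")) series <- list(series)
  rows <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    pid <- s$meta$plate_id %||% sprintf("P%03d", i)
    add_block <- function(role, conc, values) {
      values <- as.matrix(values)
      df <- data.frame(
        plate_id = pid, well = NA_character_, compound_id = s$compound_id,
        role = role,
        conc_M = if (is.null(conc)) NA_real_ else rep(conc, times = ncol(values)),
        replicate = rep(seq_len(ncol(values)), each = nrow(values)),
        signal = as.vector(values),
        assay = s$meta$assay %||% "functional",
        cell_line = s$meta$cell_line %||% NA_character_,
        fixed_reference_id = s$meta$fixed_reference$compound %||% NA_character_,
        fixed_reference_conc_M = s$meta$fixed_reference$conc %||% NA_real_,
        fixed_antagonist_id = s$meta$fixed_antagonist$compound %||% NA_character_,
        fixed_antagonist_conc_M = s$meta$fixed_antagonist$conc %||% NA_real_,
        radioligand_conc_M = s$meta$radioligand_conc %||% NA_real_,
        radioligand_logKd = s$meta$radioligand_logKd %||% NA_real_,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <<- df
    }
    add_block("test", s$conc, s$signal)
    for (nm in names(s$controls)) {
      role <- c(total = "total", nonspecific = "nsb", basal = "basal",
                positive = "positive", reference = "reference")[[nm]]
      ctrl <- s$controls[[nm]]
      if (is.matrix(ctrl) && nrow(ctrl) == length(s$conc)) {
        add_block(role, s$conc, ctrl)
      } else {
        add_block(role, NULL, matrix(ctrl, nrow = 1))
      }
    }
    # assign wells within the plate
    k <- sum(vapply(rows[vapply(rows, function(r) r$plate_id[1] == pid, TRUE)], nrow, 0L))
    idx <- which(vapply(rows, function(r) r$plate_id[1] == pid, TRUE))
    nall <- 0
    for (j in idx) nall <- nall + nrow(rows[[j]])
    labels <- .well_labels(nall)
    off <- 0
    for (j in idx) {
      rows[[j]]$well <- labels[off + seq_len(nrow(rows[[j]]))]
      off <- off + nrow(rows[[j]])
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out[, .CSV_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plate CSV into concentration series
#'
#' Rows are validated (required columns, unique wells per plate, numeric
#' signals; offending line numbers are reported) and grouped back into one
#' [conc_series()] per plate.
#'
#' @param path CSV file in the dialect of [write_plate_csv()].
#' @return named list of [conc_series()], one per plate.
#' @export
read_plate_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.CSV_COLS, names(raw))
  if (length(missing_cols)) stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  raw$conc_M <- .parse_num(raw$conc_M)
  raw$signal_num <- .parse_num(raw$signal)
  bad <- which(!is.finite(raw$signal_num))
  if (length(bad)) stop("non-numeric signal at line(s): ", paste(bad + 1, collapse = ", "))
  raw$replicate <- as.integer(raw$replicate)
  key <- paste(raw$plate_id, raw$well)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate well: ", d)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(gsub("−", "-", x)))
  out <- list()
  for (pid in unique(raw$plate_id)) {
    p <- raw[raw$plate_id == pid, ]
    test <- p[p$role == "test", ]
    if (!nrow(test)) stop("plate ", pid, " has no test wells")
    conc <- sort(unique(test$conc_M))
    if (any(!is.finite(conc))) stop("plate ", pid, ": test wells need concentrations")
    nrep <- max(test$replicate)
    sig <- matrix(NA_real_, length(conc), nrep)
    for (r in seq_len(nrow(test))) {
      i <- match(test$conc_M[r], conc)
      sig[i, test$replicate[r]] <- test$signal_num[r]
    }
    controls <- list()
    for (role in c("total", "nsb", "basal", "positive", "reference")) {
      cr <- p[p$role == role, ]
      if (!nrow(cr)) next
      nm <- c(total = "total", nsb = "nonspecific", basal = "basal",
              positive = "positive", reference = "reference")[[role]]
      if (any(is.finite(cr$conc_M))) {
        m <- matrix(NA_real_, length(conc), max(cr$replicate))
        for (r in seq_len(nrow(cr))) {
          m[match(cr$conc_M[r], conc), cr$replicate[r]] <- cr$signal_num[r]
        }
        controls[[nm]] <- m
      } else {
        controls[[nm]] <- cr$signal_num
      }
    }
    meta <- list(
      plate_id = pid, assay = test$assay[1], cell_line = test$cell_line[1],
      radioligand_conc = num_or_na(test$radioligand_conc_M[1]),
      radioligand_logKd = num_or_na(test$radioligand_logKd[1])
    )
    if (nzchar(test$fixed_reference_id[1] %||% "") && !is.na(test$fixed_reference_id[1])) {
      meta$fixed_reference <- list(compound = test$fixed_reference_id[1],
                                   conc = num_or_na(test$fixed_reference_conc_M[1]))
    }
    if (nzchar(test$fixed_antagonist_id[1] %||% "") && !is.na(test$fixed_antagonist_id[1])) {
      meta$fixed_antagonist <- list(compound = test$fixed_antagonist_id[1],
                                    conc = num_or_na(test$fixed_antagonist_conc_M[1]))
    }
    if (is.na(meta$radioligand_conc)) meta$radioligand_conc <- NULL
    if (is.na(meta$radioligand_logKd)) meta$radioligand_logKd <- NULL
    out[[pid]] <- conc_series(test$compound_id[1], conc, sig, controls, meta)
  }
  out
}
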