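# cohort container, CSV I/O, validation, timepoint assignment

.enum_levels <- list(
  exposure_group   = c("WT", "IDH1", "IDH2"),
  sex              = c("female", "male"),
  aml_history      = c("de_novo", "secondary", "therapy_related"),
  cytogenetic_risk = c("favorable", "intermediate", "adverse")
)

.mandatory_cols <- c("patient_id", "exposure_group", "age", "sex", "os_time", "os_event")

.numeric_cols <- c("age", "wbc", "platelets", "hemoglobin", "cv_risk_factor_count",
                   "anthracycline_dose", "os_time", "cr_time", "rfs_time")
.logical_cols <- c("cad", "valvular_disease", "heart_failure", "acei_arb",
                   "beta_blocker", "mra", "intensive_induction", "cr_achieved",
                   "os_event", "rfs_event")

.all_cols <- c("patient_id", "exposure_group", "age", "sex", "aml_history",
               "wbc", "platelets", "hemoglobin", "cytogenetic_risk",
               "cad", "valvular_disease", "heart_failure", "cv_risk_factor_count",
               "acei_arb", "beta_blocker", "mra", "anthracycline_dose",
               "intensive_induction", "cr_achieved",
               "echo_months", "echo_lvef",
               "os_time", "os_event", "cr_time", "rfs_time", "rfs_event")

#' Validate a cohort table
#'
#' Checks the patient-level invariants: adults only (age >= 18), nonnegative
#' survival times, LVEF values in (0, 100], echo month/value vectors of equal
#' length, known enum tokens, unique patient identifiers, and relapse-free
#' survival fields only for patients with documented complete remission.
#'
#' @param cohort a cohort data frame (as returned by [read_cohort()] or
#'   [generate_cohort()]).
#' @return The cohort, invisibly, if valid; otherwise an error whose message
#'   names every offending row.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.mandatory_cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cohort)
  problems <- character(0)
  note <- function(i, msg) {
    id <- cohort$patient_id[i]
    problems <<- c(problems, sprintf("row %d (patient %s): %s", i, id, msg))
  }

  dup <- duplicated(cohort$patient_id)
  if (any(dup)) {
    for (i in which(dup)) note(i, "duplicate patient_id")
  }

  for (i in seq_len(n)) {
    if (is.na(cohort$age[i]) || cohort$age[i] < 18)
      note(i, sprintf("age %s violates the adult-cohort requirement (>= 18)",
                      format(cohort$age[i])))
    for (col in intersect(names(.enum_levels), names(cohort))) {
      v <- cohort[[col]][i]
      if (!is.na(v) && !(v %in% .enum_levels[[col]]))
        note(i, sprintf("unknown %s token '%s'", col, v))
    }
    if (is.na(cohort$os_time[i]) || cohort$os_time[i] < 0)
      note(i, "os_time must be a nonnegative number of months")
    if ("rfs_time" %in% names(cohort) && !is.na(cohort$rfs_time[i])) {
      if (cohort$rfs_time[i] < 0) note(i, "rfs_time must be >= 0")
      cr <- if ("cr_achieved" %in% names(cohort)) cohort$cr_achieved[i] else NA
      if (!isTRUE(cr)) note(i, "rfs_time present but cr_achieved is not TRUE")
    }
    if ("cv_risk_factor_count" %in% names(cohort)) {
      cv <- cohort$cv_risk_factor_count[i]
      if (!is.na(cv) && (cv < 0 || cv > 4 || cv != round(cv)))
        note(i, sprintf("cv_risk_factor_count %s outside 0-4", format(cv)))
    }
    mo <- cohort$echo_months[[i]]
    ef <- cohort$echo_lvef[[i]]
    if (length(mo) != length(ef))
      note(i, sprintf("echo_months (%d) and echo_lvef (%d) differ in length",
                      length(mo), length(ef)))
    bad <- ef[!is.na(ef) & (ef <= 0 | ef > 100)]
    if (length(bad) > 0)
      note(i, sprintf("lvef value(s) %s outside (0, 100]",
                      paste(format(bad), collapse = ", ")))
  }

  if (length(problems) > 0) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(cohort)
}

.parse_numeric <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0)
    stop(sprintf("column %s: non-numeric value '%s' in row %d", col, x[bad[1]], bad[1]))
  out[x == ""] <- NA_real_
  out
}

.parse_logical <- function(x, col) {
  z <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[z %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[z %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!(z %in% c("", "NA", "TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")))
  if (length(bad) > 0)
    stop(sprintf("column %s: unreadable logical '%s' in row %d", col, x[bad[1]], bad[1]))
  out
}

.parse_echo_list <- function(x) {
  lapply(x, function(cell) {
    cell <- trimws(cell %||% "")
    if (is.na(cell) || cell == "") return(numeric(0))
    as.numeric(strsplit(cell, ";", fixed = TRUE)[[1]])
  })
}

#' Read a patient-level cohort CSV
#'
#' One row per patient. The repeated echocardiography series is encoded as two
#' parallel semicolon-separated columns, `echo_months` and `echo_lvef`; blank
#' cells become missing values. A schema (named character vector or path to a
#' JSON file mapping standard names to the file's column names) allows reading
#' files with nonstandard headers.
#'
#' @param path path to the CSV file.
#' @param schema optional column mapping, `c(standard_name = "file_column")`,
#'   or the path of a JSON file holding such a mapping.
#' @return A validated cohort data frame with list-columns `echo_months` and
#'   `echo_lvef`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1 && file.exists(schema))
      schema <- unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
    for (std in names(schema)) {
      if (schema[[std]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[std]]] <- std
      }
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  cohort <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (col in setdiff(.all_cols, "patient_id")) {
    if (col %in% c("echo_months", "echo_lvef")) {
      cohort[[col]] <- .parse_echo_list(if (col %in% names(raw)) raw[[col]] else rep("", n))
    } else if (!(col %in% names(raw))) {
      cohort[[col]] <- if (col %in% .numeric_cols) NA_real_
                       else if (col %in% .logical_cols) NA
                       else NA_character_
    } else if (col %in% .numeric_cols) {
      cohort[[col]] <- .parse_numeric(raw[[col]], col)
    } else if (col %in% .logical_cols) {
      cohort[[col]] <- .parse_logical(raw[[col]], col)
    } else {
      x <- raw[[col]]
      x[x == ""] <- NA_character_
      cohort[[col]] <- x
    }
  }
  validate_cohort(cohort)
  class(cohort) <- c("aml_cohort", "data.frame")
  cohort
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: echo series are collapsed to semicolon-separated
#' cells and missing values become empty cells, so that a write/read round trip
#' preserves the data up to floating-point formatting.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort[setdiff(names(cohort), c("echo_months", "echo_lvef"))])
  fmt <- function(v) vapply(v, function(x) paste(format(x, digits = 15, trim = TRUE),
                                                 collapse = ";"), character(1))
  out$echo_months <- fmt(cohort$echo_months)
  out$echo_lvef <- fmt(cohort$echo_lvef)
  out <- out[, intersect(.all_cols, names(out))]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Echo timepoint windows
#'
#' Four half-open month intervals `[lo, hi)` on the months-from-diagnosis axis
#' labelling the pre-therapy timepoint `t0` and three on-therapy timepoints
#' `t1`-`t3`. Windows must be disjoint and ordered.
#'
#' @param t0,t1,t2,t3 length-2 numeric vectors `c(lo, hi)`.
#' @return An object of class `timepoint_windows`.
#' @export
timepoint_windows <- function(t0 = c(-6, 0.5), t1 = c(0.5, 4),
                              t2 = c(4, 8), t3 = c(8, 14)) {
  w <- list(t0 = t0, t1 = t1, t2 = t2, t3 = t3)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || !is.numeric(w[[nm]]) || w[[nm]][1] >= w[[nm]][2])
      stop("window ", nm, " must be a numeric c(lo, hi) with lo < hi")
  }
  for (k in 1:3) {
    if (w[[k]][2] > w[[k + 1]][1])
      stop("windows must be pairwise disjoint and ordered t0 < t1 < t2 < t3")
  }
  structure(w, class = "timepoint_windows")
}

#' @rdname timepoint_windows
#' @export
default_windows <- function() timepoint_windows()

#' Assign echo measurements to timepoints
#'
#' Maps a patient's echo series onto the `t0`-`t3` windows. At most one LVEF
#' value is retained per window; measurements outside every window are dropped.
#' With `rule = "closest_to_window_center"` the measurement nearest the window
#' midpoint wins; with `"latest_in_window"` the latest one wins. Ties are broken
#' in favour of the earlier measurement, so the assignment is deterministic.
#'
#' @param months numeric vector of measurement times (months from diagnosis).
#' @param lvef numeric vector of LVEF percentages, parallel to `months`.
#' @param windows a [timepoint_windows()] object.
#' @param rule tie-break rule for multiple measurements in one window.
#' @return A named numeric vector with a subset of names `t0`-`t3`.
#' @export
assign_timepoints <- function(months, lvef,
                              windows = default_windows(),
                              rule = c("closest_to_window_center", "latest_in_window")) {
  rule <- match.arg(rule)
  stopifnot(inherits(windows, "timepoint_windows"), length(months) == length(lvef))
  out <- numeric(0)
  keep <- !is.na(months) & !is.na(lvef)
  months <- months[keep]; lvef <- lvef[keep]
  for (tp in names(windows)) {
    lo <- windows[[tp]][1]; hi <- windows[[tp]][2]
    idx <- which(months >= lo & months < hi)
    if (length(idx) == 0) next
    if (rule == "closest_to_window_center") {
      center <- (lo + hi) / 2
      d <- abs(months[idx] - center)
      # among equally close candidates keep the earliest
      cand <- idx[d == min(d)]
      pick <- cand[which.min(months[cand])]
    } else {
      mx <- max(months[idx])
      pick <- idx[months[idx] == mx][1]
    }
    out[tp] <- lvef[pick]
  }
  out
}

#' Timepoint LVEF matrix for a cohort
#'
#' Applies [assign_timepoints()] to every patient and returns a data frame
#' with one row per patient and columns `patient_id`, `t0`..`t3` (`NA` where a
#' patient contributed no measurement to a window). Panels may be unbalanced.
#'
#' @inheritParams assign_timepoints
#' @param cohort cohort data frame.
#' @return Data frame with columns `patient_id`, `t0`, `t1`, `t2`, `t3`.
#' @export
timepoint_matrix <- function(cohort, windows = default_windows(),
                             rule = c("closest_to_window_center", "latest_in_window")) {
  rule <- match.arg(rule)
  tps <- names(windows)
  m <- matrix(NA_real_, nrow = nrow(cohort), ncol = length(tps),
              dimnames = list(NULL, tps))
  for (i in seq_len(nrow(cohort))) {
    a <- assign_timepoints(cohort$echo_months[[i]], cohort$echo_lvef[[i]],
                           windows, rule)
    m[i, names(a)] <- a
  }
  cbind(data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE),
        as.data.frame(m))
}
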