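# Window arithmetic uses fixed-length units throughout the package:
# "month" = 30 days, "year" = 365 days. The exclusion gap is 5 months
# (150 days) and the observation window 2 years (730 days), half-open
# [anchor - 880, anchor - 150).
GAP_DAYS <- 150L
WINDOW_DAYS <- 730L

#' Clean a raw consultation note
#'
#' Minimal syntactic normalisation that keeps potential signal: every
#' character outside `a-z A-Z 0-9 + - / \` is replaced by a space, runs of
#' spaces are collapsed, the result is trimmed and lowercased. Downstream
#' tokenization is split-on-space.
#'
#' @param raw character vector of raw notes.
#' @return character vector of cleaned notes.
#' @export
clean_note <- function(raw) {
  x <- gsub("[^a-zA-Z0-9+/\\\\-]", " ", raw)
  x <- gsub(" +", " ", x)
  tolower(trimws(x))
}

#' Tokenize cleaned notes
#'
#' @param cleaned character vector as returned by [clean_note()].
#' @return list of character vectors (empty vector for empty notes).
#' @export
tokenize_note <- function(cleaned) {
  out <- strsplit(cleaned, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

has_d75 <- function(icpc) {
  # prefix match on the first three characters of any code on the consult
  vapply(strsplit(icpc, " ", fixed = TRUE),
         function(cc) any(substr(cc, 1L, 3L) == "D75"), logical(1))
}

#' Label every patient in a cohort
#'
#' A patient is a case (label 1) iff any consultation carries a code whose
#' first three characters are `D75`; the anchor is the date of the earliest
#' such consultation. Controls (label 0) are anchored at their last visit.
#'
#' @param cohort an `emr_cohort`.
#' @return data.table (patient_id, label, anchor_date); patients without
#'   any consultation are dropped (exclusion signal).
#' @export
label_cohort <- function(cohort) {
  cons <- cohort$consultations
  if (nrow(cons) == 0)
    return(data.table::data.table(patient_id = character(0),
                                  label = integer(0),
                                  anchor_date = as.Date(character(0))))
  d75 <- has_d75(cons$icpc)
  dt <- data.table::data.table(patient_id = cons$patient_id,
                               date = cons$date, d75 = d75)
  lab <- dt[, list(
    label = as.integer(any(d75)),
    anchor_date = if (any(d75)) min(date[d75]) else max(date)
  ), by = "patient_id"]
  lab
}

#' Label a single patient record
#'
#' @param record a patient record as returned by [patient_record()].
#' @return list(label, anchor_date).
#' @export
label_patient <- function(record) {
  cons <- record$consultations
  if (is.null(cons) || nrow(cons) == 0)
    stop("record has no consultations: patient is excluded", call. = FALSE)
  d75 <- has_d75(cons$icpc)
  if (any(d75)) list(label = 1L, anchor_date = min(cons$date[d75]))
  else list(label = 0L, anchor_date = max(cons$date))
}

#' Extract one patient's observation window
#'
#' Retains exactly the consultations dated in
#' `[anchor - 880, anchor - 150)` days (two years of data ending five
#' months before the anchor, half-open on the right).
#'
#' @param record a patient record ([patient_record()]).
#' @param anchor_date the patient's anchor date.
#' @return list with `window_start`, `window_end`, `age_at_anchor` (years,
#'   365-day convention) and the retained `consultations`.
#' @export
extract_window <- function(record, anchor_date) {
  w_end <- anchor_date - GAP_DAYS
  w_start <- w_end - WINDOW_DAYS
  cons <- record$consultations
  keep <- cons$date >= w_start & cons$date < w_end
  list(
    patient_id = record$patient_id,
    window_start = w_start,
    window_end = w_end,
    age_at_anchor = as.numeric(anchor_date - record$birth_date) / 365,
    consultations = cons[keep, , drop = FALSE]
  )
}

#' Inclusion rule for a labelled window
#'
#' Included iff the patient is over 30 at the anchor and the window holds
#' any data on the required features: a non-empty cleaned note or at least
#' one occurrence of a tracked ICPC code.
#'
#' @param age_at_anchor age in years at the anchor date.
#' @param notes_clean cleaned notes of the window's consultations.
#' @param icpc space-separated code strings of the window's consultations.
#' @return logical.
#' @export
include_patient <- function(age_at_anchor, notes_clean, icpc) {
  if (!(age_at_anchor > 30)) return(FALSE)
  if (any(nzchar(notes_clean))) return(TRUE)
  codes <- unlist(strsplit(icpc, " ", fixed = TRUE), use.names = FALSE)
  any(substr(codes, 1L, 3L) %in% icpc_feature_codes())
}

#' Build labelled observation windows for a whole cohort
#'
#' Runs labelling, window extraction, note cleaning and the inclusion rule
#' over every patient. Under-30 patients are retained in the object (marked
#' `included = FALSE`) because their notes may feed the embedding corpus;
#' consultations outside the window never leave this function.
#'
#' @param cohort an `emr_cohort`.
#' @return a `labelled_windows` object: list of data.tables `patients`
#'   (patient_id, label, anchor_date, window_start, window_end,
#'   age_at_anchor, gender, included) and `consultations` (the
#'   window-filtered consults with a `note_clean` column).
#' @export
build_windows <- function(cohort) {
  lab <- label_cohort(cohort)
  pts <- data.table::copy(cohort$patients)
  data.table::setkeyv(pts, "patient_id")
  lab <- merge(lab, pts, by = "patient_id")
  lab[, "window_end" := anchor_date - GAP_DAYS]
  lab[, "window_start" := window_end - WINDOW_DAYS]
  lab[, "age_at_anchor" := as.numeric(anchor_date - birth_date) / 365]

  cons <- merge(cohort$consultations,
                lab[, c("patient_id", "window_start", "window_end")],
                by = "patient_id")
  cons <- cons[cons$date >= cons$window_start & cons$date < cons$window_end]
  cons[, "note_clean" := clean_note(note)]
  cons <- cons[, c("patient_id", "date", "icpc", "note_clean")]

  # inclusion: age gate + any tracked code or non-empty note in the window
  any_note <- cons[nzchar(note_clean), list(has_note = TRUE), by = "patient_id"]
  code_dt <- cons[nzchar(icpc),
                  list(code = substr(unlist(strsplit(icpc, " ", fixed = TRUE)),
                                     1L, 3L)),
                  by = "patient_id"]
  any_code <- code_dt[code %in% icpc_feature_codes(),
                      list(has_code = TRUE), by = "patient_id"]
  lab[, "has_note" := lab$patient_id %in% any_note$patient_id]
  lab[, "has_code" := lab$patient_id %in% any_code$patient_id]
  lab[, "included" := age_at_anchor > 30 & (has_note | has_code)]
  out <- list(
    patients = lab[, c("patient_id", "label", "anchor_date", "window_start",
                       "window_end", "age_at_anchor", "gender", "included")],
    consultations = cons
  )
  class(out) <- "labelled_windows"
  out
}

#' @export
print.labelled_windows <- function(x, ...) {
  p <- x$patients
  cat(sprintf(
    "<labelled_windows> %d patients (%d included), %d cases, %d window consultations\n",
    nrow(p), sum(p$included), sum(p$label), nrow(x$consultations)))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Randomly assigns included patients to training (60%), validation (20%)
#' and test (20%) parts, stratified by label: within each class, part sizes
#' are exact up to integer rounding, so class prevalence is preserved within
#' one patient in every part.
#'
#' @param windows a `labelled_windows` object.
#' @param seed integer seed; the assignment is deterministic given it.
#' @param proportions numeric length-3 vector summing to 1.
#' @return a data.table (patient_id, label, part) with
#'   `part in c("train", "validation", "test")`; the seed is attached as an
#'   attribute.
#' @export
split_data <- function(windows, seed, proportions = c(0.6, 0.2, 0.2)) {
  stopifnot(length(proportions) == 3L, abs(sum(proportions) - 1) < 1e-9)
  p <- windows$patients[windows$patients$included]
  counts <- table(factor(p$label, levels = c(0L, 1L)))
  if (any(counts < 5L))
    stop("stratification requires at least 5 patients per class", call. = FALSE)
  parts <- c("train", "validation", "test")
  with_seed(seed, {
    assign_class <- function(ids) {
      n <- length(ids)
      n_train <- round(n * proportions[1])
      n_val <- round(n * proportions[2])
      n_test <- n - n_train - n_val
      lab <- rep(parts, c(n_train, n_val, n_test))
      data.table::data.table(patient_id = ids, part = sample(lab))
    }
    out <- data.table::rbindlist(lapply(split(p$patient_id, p$label),
                                        assign_class))
  })
  out <- merge(out, p[, c("patient_id", "label")], by = "patient_id")
  data.table::setorderv(out, "patient_id")
  data.table::setattr(out, "seed", as.integer(seed))
  out
}
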