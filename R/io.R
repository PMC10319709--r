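#' Write a cohort as JSON Lines
#'
#' One patient per line:
#' `{"patient_id":..., "birth_date":"YYYY-MM-DD", "gender":...,
#'   "consultations":[{"date":..., "icpc":[...], "text":...}, ...]}`.
#' This is also the reader format for user-supplied real data.
#'
#' @param cohort an `emr_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  esc <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    gsub('"', '\\"', x, fixed = TRUE)
  }
  cons <- cohort$consultations
  code_json <- vapply(strsplit(cons$icpc, " ", fixed = TRUE), function(cc) {
    cc <- cc[nzchar(cc)]
    if (length(cc) == 0) "[]"
    else paste0("[", paste0('"', esc(cc), '"', collapse = ","), "]")
  }, character(1))
  cons_json <- sprintf('{"date":"%s","icpc":%s,"text":"%s"}',
                       format(cons$date), code_json, esc(cons$note))
  by_pat <- data.table::data.table(patient_id = cons$patient_id, j = cons_json)
  by_pat <- by_pat[, list(body = paste(j, collapse = ",")), by = "patient_id"]
  data.table::setkeyv(by_pat, "patient_id")
  p <- cohort$patients
  body <- by_pat[p$patient_id]$body
  body[is.na(body)] <- ""
  lines <- sprintf(
    '{"patient_id":"%s","birth_date":"%s","gender":"%s","consultations":[%s]}',
    esc(p$patient_id), format(p$birth_date), esc(p$gender), body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines cohort
#'
#' @param path file written by [write_cohort()] (or real data in the same
#'   schema).
#' @return an `emr_cohort`.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  patients <- data.table::data.table(
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    birth_date = as.Date(vapply(recs, `[[`, character(1), "birth_date")),
    gender = vapply(recs, `[[`, character(1), "gender")
  )
  cons_list <- lapply(recs, function(r) {
    cc <- r$consultations
    if (is.null(cc) || length(cc) == 0 || NROW(cc) == 0) return(NULL)
    icpc <- cc$icpc
    if (is.list(icpc))
      icpc <- vapply(icpc, function(v) paste(v, collapse = " "), character(1))
    data.table::data.table(
      patient_id = r$patient_id,
      date = as.Date(cc$date),
      icpc = icpc,
      note = cc$text
    )
  })
  consultations <- data.table::rbindlist(cons_list)
  if (nrow(consultations) == 0)
    consultations <- data.table::data.table(
      patient_id = character(0), date = as.Date(character(0)),
      icpc = character(0), note = character(0))
  data.table::setorderv(consultations, c("patient_id", "date"))
  out <- list(patients = patients, consultations = consultations)
  class(out) <- "emr_cohort"
  out
}

#' Persist an embedding matrix as plain text
#'
#' Writes one `token v1 v2 ... vd` line per vocabulary entry plus a JSON
#' sidecar (`<path>.json`) with the training hyperparameters.
#'
#' @param embedding an `embedding_matrix` from [train_sgns()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  w <- embedding$W
  lines <- paste(rownames(w),
                 apply(w, 1L, function(v) paste(sprintf("%.17g", v),
                                                collapse = " ")))
  writeLines(lines, path, useBytes = TRUE)
  jsonlite::write_json(embedding$params, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding()]
#'
#' @param path text file of `token v1 ... vd` lines.
#' @return an `embedding_matrix` (context vectors are not persisted).
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- lapply(strsplit(lines, " ", fixed = TRUE),
                  function(p) p[nzchar(p)])
  tokens <- vapply(parts, `[[`, character(1), 1L)
  w <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(w) <- tokens
  params <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) params <- jsonlite::fromJSON(sidecar)
  out <- list(W = w, C = NULL, dim = ncol(w), params = params)
  class(out) <- "embedding_matrix"
  out
}
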