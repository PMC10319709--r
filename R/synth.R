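#' The eleven tracked ICPC symptom codes
#'
#' Symptom codes used as structured predictors: constipation (D12),
#' diarrhoea (D11), changed bowel habit (D18), abdominal pain (D01),
#' abdominal bloating (D25), rectal blood loss (D16), weight loss (T08),
#' loss of appetite (T03), anaemia (B80, B82) and thrombophlebitis (K94).
#' The order is fixed and defines the layout of the tabular feature block.
#'
#' @return character vector of 11 three-character ICPC codes.
#' @export
icpc_feature_codes <- function() {
  c("D12", "D11", "D18", "D01", "D25", "D16", "T08", "T03", "B80", "B82", "K94")
}

#' Default note-length distribution
#'
#' Probability mass function over note lengths 1..15 words with its mode at
#' 7 words (P = 0.120), a discretized gamma(shape 5.3, rate 0.6). Matches the
#' flat, long-tailed word-count profile of short GP consultation notes.
#'
#' @return numeric vector of length 15 summing to 1.
#' @export
default_note_length_pmf <- function() {
  p <- stats::dgamma(1:15, shape = 5.3, rate = 0.6)
  p / sum(p)
}

#' Default age-bracket mixture by case status
#'
#' Proportions of patients in the brackets [30,60), [60,70), [70,80) and
#' [80,Inf), separately for non-cases and cases. CRC patients skew strongly
#' older, which is itself predictive signal for the tabular model.
#'
#' @return 2 x 4 numeric matrix with rows `control`, `case`.
#' @export
default_age_mixture <- function() {
  m <- rbind(
    control = c(0.6862, 0.1388, 0.0804, 0.0946),
    case    = c(0.2348, 0.2495, 0.2569, 0.2588)
  )
  colnames(m) <- c("30_60", "60_70", "70_80", "80_plus")
  m / rowSums(m)
}

#' Configuration for the synthetic EMR generator
#'
#' Bundles every knob of the cohort simulator. Defaults are the study
#' conditions the package targets: a CRC prevalence of 0.89%, notes of 1-15
#' words with mode 7, Zipfian background vocabulary, a small set of signal
#' tokens over-represented (on the odds scale) in cases' pre-diagnosis
#' windows, and elevated rates of the 11 tracked ICPC codes in those same
#' windows.
#'
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param n_patients number of patients.
#' @param prevalence probability a patient is a CRC case (receives a D75
#'   diagnosis code).
#' @param vocab_size number of background token types.
#' @param n_signal_tokens number of dedicated signal token types.
#' @param signal_strength odds multiplier (>= 1) for emitting a signal token
#'   inside a case's observation window; 1 means no planted text signal.
#' @param icpc_effect rate multiplier (>= 1) for the tracked ICPC codes inside
#'   a case's observation window; 1 means no planted code signal.
#' @param note_length_pmf probability vector over note lengths 1..15; must
#'   sum to 1 and peak at length 7.
#' @param consults_per_patient_mean named vector `c(control=, case=)`: mean
#'   consultations per patient over the whole record.
#' @param consults_per_patient_sd matching standard deviations (negative
#'   binomial overdispersion).
#' @param date_range two `Date`s bounding all consultation dates.
#' @param age_mixture 2 x 4 matrix as [default_age_mixture()].
#' @param under30_frac fraction of patients aged 18-30; they are excluded
#'   from prediction but their notes feed the embedding corpus.
#' @param empty_note_frac fraction of consultations with an empty note.
#' @param typo_rate per-token probability of an adjacent-character swap.
#' @param bigram_rate probability that a window signal token is followed by
#'   its partner signal token, planting learnable bigrams.
#' @param signal_base_mass total baseline probability mass of signal tokens
#'   in any note (cases and controls alike).
#' @param code_rate mean number of ICPC codes per consultation.
#' @param tracked_code_share share of baseline code mass on the 11 tracked
#'   codes.
#' @param gender_female named vector of P(female) by status.
#' @param gender_other probability of the third gender category.
#' @param zipf_exponent exponent of the Zipfian background token law.
#' @param max_consults upper cap on consultations per patient.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 10000L,
                         prevalence = 0.0089,
                         vocab_size = 2000L,
                         n_signal_tokens = 20L,
                         signal_strength = 6,
                         icpc_effect = 2.5,
                         note_length_pmf = default_note_length_pmf(),
                         consults_per_patient_mean = c(control = 59, case = 76),
                         consults_per_patient_sd = c(control = 69, case = 90),
                         date_range = as.Date(c("1995-01-01", "2015-12-31")),
                         age_mixture = default_age_mixture(),
                         under30_frac = 0.05,
                         empty_note_frac = 0.10,
                         typo_rate = 0.02,
                         bigram_rate = 0.30,
                         signal_base_mass = 0.04,
                         code_rate = 0.6,
                         tracked_code_share = 0.15,
                         gender_female = c(control = 0.5505, case = 0.5176),
                         gender_other = 0.005,
                         zipf_exponent = 1.05,
                         max_consults = 500L) {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    prevalence = prevalence, vocab_size = as.integer(vocab_size),
    n_signal_tokens = as.integer(n_signal_tokens),
    signal_strength = signal_strength, icpc_effect = icpc_effect,
    note_length_pmf = note_length_pmf,
    consults_per_patient_mean = consults_per_patient_mean,
    consults_per_patient_sd = consults_per_patient_sd,
    date_range = date_range, age_mixture = age_mixture,
    under30_frac = under30_frac, empty_note_frac = empty_note_frac,
    typo_rate = typo_rate, bigram_rate = bigram_rate,
    signal_base_mass = signal_base_mass, code_rate = code_rate,
    tracked_code_share = tracked_code_share,
    gender_female = gender_female, gender_other = gender_other,
    zipf_exponent = zipf_exponent, max_consults = as.integer(max_consults)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!(cfg$prevalence >= 0 && cfg$prevalence < 1))
    stop("`prevalence` must lie in [0, 1)", call. = FALSE)
  pmf <- cfg$note_length_pmf
  if (length(pmf) != 15L || any(pmf < 0) || abs(sum(pmf) - 1) > 1e-9)
    stop("`note_length_pmf` must be a length-15 probability vector summing to 1",
         call. = FALSE)
  if (which.max(pmf) != 7L)
    stop("`note_length_pmf` must have its mode at length 7", call. = FALSE)
  if (cfg$signal_strength < 1) stop("`signal_strength` must be >= 1", call. = FALSE)
  if (cfg$icpc_effect < 1) stop("`icpc_effect` must be >= 1", call. = FALSE)
  if (cfg$vocab_size < 1 || cfg$n_signal_tokens < 1)
    stop("vocabulary sizes must be positive", call. = FALSE)
  stopifnot_prob(cfg$under30_frac, "under30_frac")
  stopifnot_prob(cfg$empty_note_frac, "empty_note_frac")
  stopifnot_prob(cfg$typo_rate, "typo_rate")
  stopifnot_prob(cfg$bigram_rate, "bigram_rate")
  if (cfg$signal_base_mass <= 0 || cfg$signal_base_mass >= 0.5)
    stop("`signal_base_mass` must lie in (0, 0.5)", call. = FALSE)
  invisible(cfg)
}

zipf_probs <- function(v, s) {
  p <- (1:v)^(-s)
  p / sum(p)
}

signal_token_names <- function(k) sprintf("sig%02d", seq_len(k))
background_token_names <- function(v) sprintf("w%04d", seq_len(v))

# Boosted per-token signal probability on the odds scale.
signal_emission_probs <- function(cfg) {
  p0 <- cfg$signal_base_mass
  o1 <- cfg$signal_strength * p0 / (1 - p0)
  c(control = p0, case_window = o1 / (1 + o1))
}

#' Draw note lengths from the configured distribution
#'
#' @param n number of draws.
#' @param pmf probability vector over lengths 1..15.
#' @return integer vector of word counts in 1..15.
#' @export
sample_note_length <- function(n = 1L, pmf = default_note_length_pmf()) {
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-9)
    stop("`pmf` must be a probability vector summing to 1", call. = FALSE)
  sample.int(length(pmf), size = n, replace = TRUE, prob = pmf)
}

# Vectorized token emission for many notes at once. `lengths` gives words
# per note, `in_window` whether each note sits in a case's signal-bearing
# window. Returns tokens plus their note ids.
draw_note_tokens <- function(lengths, in_window, cfg) {
  stopifnot(length(lengths) == length(in_window))
  total <- sum(lengths)
  if (total == 0L)
    return(list(token = character(0), note_id = integer(0)))
  note_id <- rep(seq_along(lengths), lengths)
  flagged <- rep(in_window, lengths)
  ps <- signal_emission_probs(cfg)
  is_sig <- stats::runif(total) < ifelse(flagged, ps[["case_window"]], ps[["control"]])

  sig_idx <- integer(total)
  n_sig <- sum(is_sig)
  if (n_sig > 0)
    sig_idx[is_sig] <- sample.int(cfg$n_signal_tokens, n_sig, replace = TRUE)

  # Plant learnable bigrams: a window signal token is sometimes followed by
  # its fixed partner token.
  if (cfg$bigram_rate > 0 && n_sig > 0) {
    lead <- which(is_sig & flagged)
    lead <- lead[lead < total & note_id[pmin(lead + 1L, total)] == note_id[lead]]
    if (length(lead) > 0) {
      lead <- lead[stats::runif(length(lead)) < cfg$bigram_rate]
      if (length(lead) > 0) {
        partner <- (sig_idx[lead] %% cfg$n_signal_tokens) + 1L
        sig_idx[lead + 1L] <- partner
        is_sig[lead + 1L] <- TRUE
      }
    }
  }

  token <- character(total)
  n_bg <- sum(!is_sig)
  if (n_bg > 0) {
    bg <- sample.int(cfg$vocab_size, n_bg, replace = TRUE,
                     prob = zipf_probs(cfg$vocab_size, cfg$zipf_exponent))
    token[!is_sig] <- background_token_names(cfg$vocab_size)[bg]
  }
  if (any(is_sig))
    token[is_sig] <- signal_token_names(cfg$n_signal_tokens)[sig_idx[is_sig]]

  # Adjacent-character swaps emulate typing noise in GP notes.
  if (cfg$typo_rate > 0) {
    nc <- nchar(token)
    hit <- which(stats::runif(total) < cfg$typo_rate & nc >= 3L)
    if (length(hit) > 0) {
      j <- 1L + floor(stats::runif(length(hit)) * (nc[hit] - 1L))
      tk <- token[hit]
      token[hit] <- paste0(
        substr(tk, 1L, j - 1L),
        substr(tk, j + 1L, j + 1L),
        substr(tk, j, j),
        substr(tk, j + 2L, nc[hit])
      )
    }
  }
  list(token = token, note_id = note_id)
}

#' Draw the tokens of a single synthetic note
#'
#' @param length number of words (>= 1).
#' @param in_case_window logical; if `TRUE` the emission uses the
#'   signal-boosted odds of a case's observation window.
#' @param config a [synth_config()].
#' @return character vector of `length` tokens.
#' @export
sample_note_tokens <- function(length, in_case_window = FALSE,
                               config = synth_config()) {
  if (length < 1L) stop("`length` must be >= 1", call. = FALSE)
  draw_note_tokens(as.integer(length), isTRUE(in_case_window), config)$token
}

icpc_background_pool <- function() {
  chapters <- c("A", "K", "L", "N", "P", "R", "S", "U", "W", "X", "Y", "Z")
  pool <- as.vector(outer(chapters, sprintf("%02d", c(1:5, 70:74, 85, 95)),
                          paste0))
  setdiff(pool, c(icpc_feature_codes(), "D75"))[1:60]
}

# Codes for many consultations at once. Tracked-code counts are Poisson with
# rate boosted by `icpc_effect` inside case windows; background codes are
# unaffected, so the multiplier acts on the tracked rate exactly.
draw_icpc_codes <- function(n_consults, in_window, cfg) {
  rate_trk <- cfg$code_rate * cfg$tracked_code_share
  rate_bg <- cfg$code_rate * (1 - cfg$tracked_code_share)
  n_trk <- stats::rpois(n_consults, rate_trk * ifelse(in_window, cfg$icpc_effect, 1))
  n_bg <- stats::rpois(n_consults, rate_bg)

  trk_codes <- icpc_feature_codes()
  trk_w <- 1 / seq_along(trk_codes)
  bg_pool <- icpc_background_pool()
  bg_w <- 1 / seq_along(bg_pool)

  out <- character(n_consults)
  tot_trk <- sum(n_trk)
  tot_bg <- sum(n_bg)
  trk_draw <- if (tot_trk > 0)
    trk_codes[sample.int(length(trk_codes), tot_trk, TRUE, prob = trk_w)] else character(0)
  bg_draw <- if (tot_bg > 0)
    bg_pool[sample.int(length(bg_pool), tot_bg, TRUE, prob = bg_w)] else character(0)

  dt <- data.table::data.table(
    cid = c(rep(seq_len(n_consults), n_trk), rep(seq_len(n_consults), n_bg)),
    code = c(trk_draw, bg_draw)
  )
  if (nrow(dt) > 0) {
    joined <- dt[, list(codes = paste(code, collapse = " ")), by = "cid"]
    out[joined$cid] <- joined$codes
  }
  out
}

#' Generate a synthetic primary-care cohort
#'
#' Simulates `config$n_patients` patient records: demographics, a
#' registration period, ICPC-coded consultations and short noisy notes.
#' Cases receive exactly one D75 (colorectal malignancy) code at their
#' anchor date; inside their observation window (2 years ending 5 months
#' before the anchor) signal tokens are emitted with odds multiplied by
#' `signal_strength` and tracked ICPC codes at `icpc_effect` times the
#' baseline rate. The cohort is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a [synth_config()].
#' @return an `emr_cohort`: list with data.tables `patients`
#'   (patient_id, birth_date, gender) and `consultations`
#'   (patient_id, date, icpc, note), plus a `planted` attribute recording
#'   the simulated truth (case flag and anchor date) for validation.
#' @export
generate_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  empty <- function() {
    out <- list(
      patients = data.table::data.table(
        patient_id = character(0), birth_date = as.Date(character(0)),
        gender = character(0)),
      consultations = data.table::data.table(
        patient_id = character(0), date = as.Date(character(0)),
        icpc = character(0), note = character(0))
    )
    class(out) <- "emr_cohort"
    attr(out, "planted") <- data.table::data.table(
      patient_id = character(0), is_case = logical(0),
      anchor_date = as.Date(character(0)))
    out
  }
  if (config$n_patients <= 0L) return(empty())

  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("p%06d", seq_len(n))
    is_case <- stats::runif(n) < config$prevalence
    status <- ifelse(is_case, "case", "control")
    under30 <- stats::runif(n) < config$under30_frac

    # registration span: 4-20 years, always long enough to host a window
    d0 <- as.numeric(config$date_range[1])
    d1 <- as.numeric(config$date_range[2])
    span <- floor(stats::runif(n, 1460, min(7300, d1 - d0)))
    reg_start <- floor(stats::runif(n, d0, d1 - span))
    reg_end <- reg_start + span

    mu <- config$consults_per_patient_mean[status]
    sdv <- config$consults_per_patient_sd[status]
    size <- mu^2 / pmax(sdv^2 - mu, 1e-8)
    n_cons <- pmin(pmax(stats::rnbinom(n, size = size, mu = mu), 1L),
                   config$max_consults)

    # case anchor: uniform over dates with a full window of history
    anchor <- rep(NA_real_, n)
    if (any(is_case))
      anchor[is_case] <- floor(stats::runif(sum(is_case),
                                            reg_start[is_case] + 880,
                                            reg_end[is_case] + 1))

    cons <- data.table::data.table(
      patient_id = rep(pid, n_cons),
      date = floor(stats::runif(sum(n_cons),
                                rep(reg_start, n_cons),
                                rep(reg_end, n_cons) + 1)),
      anchor = rep(anchor, n_cons)
    )
    cons[, "in_window" := !is.na(anchor) & date >= anchor - 880 & date < anchor - 150]

    # notes
    n_all <- nrow(cons)
    has_note <- stats::runif(n_all) >= config$empty_note_frac
    len <- integer(n_all)
    len[has_note] <- sample_note_length(sum(has_note), config$note_length_pmf)
    toks <- draw_note_tokens(len, cons$in_window, config)
    note <- character(n_all)
    if (length(toks$token) > 0) {
      ndt <- data.table::data.table(nid = toks$note_id, tok = toks$token)
      pasted <- ndt[, list(txt = paste(tok, collapse = " ")), by = "nid"]
      note[pasted$nid] <- pasted$txt
    }
    cons[, "note" := note]
    cons[, "icpc" := draw_icpc_codes(n_all, cons$in_window, config)]

    # the diagnosis consultation: one D75 at the anchor date
    if (any(is_case)) {
      d75 <- data.table::data.table(
        patient_id = pid[is_case],
        date = anchor[is_case],
        anchor = anchor[is_case],
        in_window = FALSE,
        note = "",
        icpc = "D75"
      )
      cons <- data.table::rbindlist(list(cons, d75), use.names = TRUE)
    }
    cons[, "date" := as.Date(date, origin = "1970-01-01")]
    data.table::setorderv(cons, c("patient_id", "date"))

    # demographics: age at the anchor (cases) or last visit (controls)
    last_visit <- cons[, list(last = max(date)), by = "patient_id"]
    data.table::setkeyv(last_visit, "patient_id")
    anchor_date <- as.Date(ifelse(is_case, anchor,
                                  as.numeric(last_visit[pid]$last)),
                           origin = "1970-01-01")
    mix <- config$age_mixture
    bracket_lo <- c(30, 60, 70, 80)
    bracket_hi <- c(60, 70, 80, 95)
    age <- numeric(n)
    for (st in c("control", "case")) {
      sel <- which(status == st & !under30)
      if (length(sel) == 0) next
      br <- sample.int(4L, length(sel), replace = TRUE, prob = mix[st, ])
      age[sel] <- stats::runif(length(sel), bracket_lo[br], bracket_hi[br])
    }
    if (any(under30)) age[under30] <- stats::runif(sum(under30), 18, 30)
    birth_date <- anchor_date - round(age * 365)

    pf <- config$gender_female[status]
    u <- stats::runif(n)
    gender <- ifelse(u < pf, "female",
                     ifelse(u < pf + config$gender_other, "other", "male"))

    out <- list(
      patients = data.table::data.table(
        patient_id = pid, birth_date = birth_date, gender = gender),
      consultations = cons[, c("patient_id", "date", "icpc", "note")]
    )
    class(out) <- "emr_cohort"
    attr(out, "planted") <- data.table::data.table(
      patient_id = pid, is_case = is_case, anchor_date = anchor_date)
    out
  })
}

#' @export
print.emr_cohort <- function(x, ...) {
  planted <- attr(x, "planted")
  cat(sprintf("<emr_cohort> %d patients, %d consultations",
              nrow(x$patients), nrow(x$consultations)))
  if (!is.null(planted) && nrow(planted) > 0)
    cat(sprintf(", %d planted cases (%.2f%%)",
                sum(planted$is_case), 100 * mean(planted$is_case)))
  cat("\n")
  invisible(x)
}

#' Extract one patient's record from a cohort
#'
#' @param cohort an `emr_cohort`.
#' @param patient_id id to extract.
#' @return a list with `patient_id`, `birth_date`, `gender` and a
#'   `consultations` data.frame (date, icpc, note), time-ordered.
#' @export
patient_record <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id", call. = FALSE)
  cons <- cohort$consultations[cohort$consultations$patient_id == patient_id]
  list(
    patient_id = patient_id,
    birth_date = cohort$patients$birth_date[i],
    gender = cohort$patients$gender[i],
    consultations = as.data.frame(cons[, c("date", "icpc", "note")])
  )
}

#' Baseline characteristics of the reference study population
#'
#' Printed counts and percentages of the primary-care population whose
#' structure the synthetic generator's defaults emulate: 60,641 patients of
#' whom 541 (0.89%) had colorectal cancer, with gender and age-bracket
#' composition by case status. Percentages are as printed (gender and age
#' within case status; totals across the whole population).
#'
#' @return data.frame with columns `group`, `non_crc_n`, `non_crc_pct`,
#'   `crc_n`, `crc_pct`; note counts attached as attribute `notes`.
#' @export
reference_population <- function() {
  df <- data.frame(
    group = c("total", "female", "age_30_60", "age_60_70", "age_70_80",
              "age_80_plus"),
    non_crc_n = c(60100, 33087, 41242, 8342, 4831, 5685),
    non_crc_pct = c(99.11, 55.05, 68.62, 13.88, 8.04, 9.46),
    crc_n = c(541, 280, 127, 135, 139, 140),
    crc_pct = c(0.89, 51.76, 23.48, 24.95, 25.69, 25.88),
    stringsAsFactors = FALSE
  )
  attr(df, "notes") <- data.frame(
    status = c("non_crc", "crc"),
    total_notes = c(3556133, 41339),
    mean_per_patient = c(59, 76),
    sd_per_patient = c(69, 90)
  )
  df
}
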