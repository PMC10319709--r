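test_that("note cleaning applies the character rule", {
  expect_equal(
    clean_note("Lage rugklachten bij vastzitten cl. Advies trainen met hartslameter."),
    "lage rugklachten bij vastzitten cl advies trainen met hartslameter")
  expect_equal(clean_note(""), "")
  expect_equal(clean_note("T8!!  pijn??  +/-"), "t8 pijn +/-")
  # backslash is in the allowed set; unicode punctuation is not
  expect_equal(clean_note("a\\b —x"), "a\\b x")
  expect_equal(tokenize_note("a b  c")[[1]], c("a", "b", "c"))
  expect_equal(tokenize_note("")[[1]], character(0))
})

test_that("labelling uses the first D75-prefixed code, else the last visit", {
  rec <- list(
    patient_id = "x", birth_date = as.Date("1950-01-01"), gender = "female",
    consultations = data.frame(
      date = as.Date(c("2001-01-01", "2002-06-01", "2003-01-01")),
      icpc = c("K94", "D75", "D75.01"),
      note = c("", "", "")))
  lab <- label_patient(rec)
  expect_equal(lab$label, 1L)
  expect_equal(lab$anchor_date, as.Date("2002-06-01"))
  # subcode suffix on the first occurrence also counts (prefix match)
  rec$consultations$icpc <- c("K94", "D75.01", "A01")
  expect_equal(label_patient(rec)$anchor_date, as.Date("2002-06-01"))
  # no D75 -> control anchored at last visit
  rec$consultations$icpc <- c("K94", "A01", "")
  lab0 <- label_patient(rec)
  expect_equal(lab0$label, 0L)
  expect_equal(lab0$anchor_date, as.Date("2003-01-01"))
  # single consultation carrying D75
  rec1 <- rec
  rec1$consultations <- rec$consultations[2, ]
  rec1$consultations$icpc <- "D75"
  expect_equal(label_patient(rec1),
               list(label = 1L, anchor_date = as.Date("2002-06-01")))
  rec$consultations <- rec$consultations[0, ]
  expect_error(label_patient(rec), "excluded")
})

test_that("window extraction is half-open with the 150-day gap", {
  anchor <- as.Date("2010-01-01")
  rec <- list(
    patient_id = "x", birth_date = as.Date("1950-01-01"), gender = "male",
    consultations = data.frame(
      date = anchor - c(150, 151, 880, 881, 10),
      icpc = "", note = "n"))
  w <- extract_window(rec, anchor)
  expect_equal(w$window_end, anchor - 150)
  expect_equal(w$window_start, anchor - 880)
  expect_equal(as.numeric(w$window_end - w$window_start), 730)
  kept <- w$consultations$date
  expect_true((anchor - 151) %in% kept)   # just inside the right edge
  expect_true((anchor - 880) %in% kept)   # closed left edge
  expect_false((anchor - 150) %in% kept)  # half-open right edge
  expect_false((anchor - 881) %in% kept)
  expect_false((anchor - 10) %in% kept)   # exclusion gap
  # all consultations after the gap start -> empty window
  rec$consultations <- data.frame(date = anchor - c(5, 30), icpc = "",
                                  note = "n")
  expect_equal(nrow(extract_window(rec, anchor)$consultations), 0L)
})

test_that("inclusion requires age over 30 plus any tracked data", {
  expect_false(include_patient(29, "moe", "D12"))
  expect_true(include_patient(45, "moe", ""))
  expect_true(include_patient(45, "", "D12"))
  expect_true(include_patient(45, "", "A01 D12.02"))  # prefix match
  expect_false(include_patient(45, c("", ""), c("", "A01")))
  expect_false(include_patient(30, "moe", "D12"))  # strictly over 30
})

test_that("cohort labelling recovers the planted case set exactly", {
  co <- tiny_cohort(seed = 31, n = 2000, prevalence = 0.03)
  planted <- attr(co, "planted")
  lab <- label_cohort(co)
  m <- merge(planted, lab, by = "patient_id")
  expect_equal(nrow(m), 2000L)
  expect_equal(m$label == 1L, m$is_case)
  expect_equal(m$anchor_date.x, m$anchor_date.y)
})

test_that("no window consultation leaks outside its bounds", {
  co <- tiny_cohort(seed = 17, n = 500, prevalence = 0.05)
  w <- build_windows(co)
  m <- merge(w$consultations, w$patients, by = "patient_id")
  expect_true(all(m$date >= m$window_start & m$date < m$window_end))
})

test_that("stratified split is exact, disjoint and deterministic", {
  co <- tiny_cohort(seed = 13, n = 1200, prevalence = 0.05, under30_frac = 0)
  w <- build_windows(co)
  s1 <- split_data(w, seed = 99)
  s2 <- split_data(w, seed = 99)
  expect_identical(s1$part, s2$part)
  expect_false(identical(s1$part, split_data(w, seed = 100)$part))
  # union is the included set, parts disjoint by construction
  inc <- sort(w$patients$patient_id[w$patients$included])
  expect_identical(sort(s1$patient_id), inc)
  expect_equal(anyDuplicated(s1$patient_id), 0L)
  # per-class allocation exact to rounding
  for (lab in 0:1) {
    n <- sum(s1$label == lab)
    parts <- table(s1$part[s1$label == lab])
    expect_equal(as.integer(parts[["train"]]), round(n * 0.6))
    expect_equal(as.integer(parts[["validation"]]), round(n * 0.2))
  }
})

test_that("split errors when a class is too small to stratify", {
  co <- tiny_cohort(seed = 1, n = 300, prevalence = 0)
  w <- build_windows(co)
  expect_error(split_data(w, seed = 1), "5 patients per class")
})

test_that("a synthetic 1000/10 cohort splits 600/200/200 with 6/2/2 cases", {
  # construct windows directly so the class sizes are exact
  p <- data.table::data.table(
    patient_id = sprintf("q%04d", 1:1000),
    label = rep(c(1L, 0L), c(10, 990)),
    anchor_date = as.Date("2010-01-01"),
    window_start = as.Date("2007-08-04"),
    window_end = as.Date("2009-08-04"),
    age_at_anchor = 50, gender = "female", included = TRUE)
  w <- structure(list(patients = p,
                      consultations = data.table::data.table()),
                 class = "labelled_windows")
  s <- split_data(w, seed = 4)
  expect_equal(as.integer(table(s$part)[c("train", "validation", "test")]),
               c(600L, 200L, 200L))
  expect_equal(as.integer(table(s$part[s$label == 1])[c("train", "validation", "test")]),
               c(6L, 2L, 2L))
})
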