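#' Read long-format admission records
#'
#' Reads a delimited table with one row per admission and columns
#' `record_id`, `patient_id`, `sex`, `age`, `admission_date` and `codes`
#' (a `codes_sep`-separated list of ICD-10 codes of any precision).
#' Codes are normalised to 3-character categories and de-duplicated per
#' record; the unit of analysis is the disease category per admission, so a
#' record listing `E11.2` and `E11.9` carries `E11` once.
#'
#' Malformed rows (unparseable age or date, no parseable code) are dropped
#' and reported, with their row numbers, in the `row_errors` attribute;
#' codes that fail normalisation are kept out of the record but tallied in
#' the `code_errors` attribute. A missing required column or a duplicated
#' `record_id` is a fatal error.
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter (default `","`).
#' @param codes_sep delimiter inside the `codes` field (default `";"`).
#' @return an `admission_records` data.table with columns `record_id`,
#'   `patient_id`, `sex`, `age`, `admission_date`, and list-column `codes`
#'   holding the sorted set of 3-character categories of each record.
#' @export
read_records <- function(path, sep = ",", codes_sep = ";") {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          header = TRUE, data.table = TRUE)
  required <- c("record_id", "patient_id", "sex", "age", "admission_date",
                "codes")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- dt$record_id[duplicated(dt$record_id)]
  if (length(dup) > 0) {
    stop("duplicate record_id(s): ", paste(unique(dup), collapse = ", "))
  }
  as_admission_records(dt, codes_sep = codes_sep)
}

#' Build admission records from an in-memory table
#'
#' Same validation and normalisation as [read_records()] applied to a
#' data.frame already in memory (columns as documented there); `codes` may
#' be a delimited character column or a list of character vectors.
#'
#' @param x data.frame of raw rows.
#' @param codes_sep delimiter inside a character `codes` column.
#' @return an `admission_records` data.table; see [read_records()].
#' @export
as_admission_records <- function(x, codes_sep = ";") {
  dt <- data.table::as.data.table(x)
  n <- nrow(dt)
  age <- suppressWarnings(as.integer(dt$age))
  date <- as.Date(as.character(dt$admission_date), format = "%Y-%m-%d")
  sex <- tolower(as.character(dt$sex))
  sex_ok <- sex %in% c("male", "female")

  raw_codes <- if (is.list(dt$codes)) {
    lapply(dt$codes, as.character)
  } else {
    strsplit(as.character(dt$codes), codes_sep, fixed = TRUE)
  }
  raw_codes <- lapply(raw_codes, function(v) trimws(v[nzchar(trimws(v))]))

  norm <- normalize_icd10(unlist(c(list(character(0)), raw_codes)))
  idx <- rep.int(seq_len(n), lengths(raw_codes))
  code_errors <- unique(norm$raw[!norm$valid])
  codes <- lapply(split(norm$code3[norm$valid], factor(idx[norm$valid],
                                                      levels = seq_len(n))),
                  function(v) sort(unique(v)))
  if (n == 0) codes <- list()

  problems <- character(0)
  bad_age <- which(is.na(age) | age < 0)
  bad_date <- which(is.na(date))
  bad_sex <- which(!sex_ok)
  bad_codes <- which(lengths(codes) == 0)
  if (length(bad_age)) problems <- c(problems, paste0("row ", bad_age, ": unparseable or negative age"))
  if (length(bad_date)) problems <- c(problems, paste0("row ", bad_date, ": unparseable admission_date"))
  if (length(bad_sex)) problems <- c(problems, paste0("row ", bad_sex, ": sex not male/female"))
  if (length(bad_codes)) problems <- c(problems, paste0("row ", bad_codes, ": no parseable ICD-10 code"))
  drop <- sort(unique(c(bad_age, bad_date, bad_sex, bad_codes)))

  out <- data.table::data.table(
    record_id = as.character(dt$record_id),
    patient_id = as.character(dt$patient_id),
    sex = sex, age = age, admission_date = date, codes = codes
  )
  if (length(drop)) out <- out[-drop]
  data.table::setattr(out, "row_errors", problems)
  data.table::setattr(out, "code_errors", code_errors)
  data.table::setattr(out, "class",
                      c("admission_records", class(data.table::data.table())))
  out[]
}

#' Restrict records to ICD-10 Chapters 1-14
#'
#' Removes from each record every category whose chapter lies outside 1-14;
#' records whose categories all fall in Chapters 15-22 are rejected.
#' Idempotent. Rejection counts are reported in the `scope_report`
#' attribute.
#'
#' @param records an `admission_records` table with normalised codes.
#' @return the filtered `admission_records`; attribute `scope_report` is a
#'   list with `n_in`, `n_kept`, `n_rejected_out_of_scope`,
#'   `n_codes_dropped`.
#' @export
filter_scope <- function(records) {
  codes <- records$codes
  kept_codes <- lapply(codes, function(v) v[icd10_chapter(v) <= 14L])
  n_dropped <- sum(lengths(codes) - lengths(kept_codes))
  keep <- lengths(kept_codes) > 0
  out <- records[keep]
  data.table::set(out, j = "codes", value = list(kept_codes[keep]))
  data.table::setattr(out, "scope_report", list(
    n_in = nrow(records), n_kept = sum(keep),
    n_rejected_out_of_scope = sum(!keep), n_codes_dropped = n_dropped
  ))
  data.table::setattr(out, "class", class(records))
  out[]
}

#' Select each patient's baseline record
#'
#' Keeps exactly one record per `patient_id`: the earliest
#' `admission_date`, with ties broken by the lexicographically smallest
#' `record_id` so the selection is deterministic.
#'
#' @param records an `admission_records` table.
#' @return the baseline subset, one row per patient.
#' @export
select_baseline <- function(records) {
  ord <- order(records$patient_id, records$admission_date, records$record_id)
  out <- records[ord][!duplicated(patient_id)]
  data.table::setattr(out, "class", class(records))
  out[]
}

#' Age bands of the middle-aged cohort
#' @return character vector of the four 5-year band labels.
#' @export
age_bands <- function() c("40-44", "45-49", "50-54", "55-59")

# Band label for an integer age; bands are inclusive on both ends.
age_band_of <- function(age) {
  cut(age, breaks = c(39.5, 44.5, 49.5, 54.5, 59.5), labels = age_bands())
}

#' Stratify a cohort by sex and/or age band
#'
#' Ages must already lie in 40-59 (the inclusion filter); records outside
#' that range are dropped here with a warning. Strata are disjoint and
#' exhaustive over the retained cohort; bands are inclusive on both ends.
#'
#' @param records an `admission_records` table (baseline, in-scope).
#' @param scheme one of `"all"` (single stratum), `"sex"` (two strata), or
#'   `"sex_age"` (eight strata).
#' @return named list of `admission_records` strata; each carries
#'   attributes `sex` and `age_band` describing the stratum.
#' @export
stratify <- function(records, scheme = c("sex_age", "sex", "all")) {
  scheme <- match.arg(scheme)
  in_range <- records$age >= 40L & records$age <= 59L
  if (any(!in_range)) {
    warning(sum(!in_range), " record(s) outside ages 40-59 dropped")
    records <- records[in_range]
  }
  stratum <- function(rows, sex, band) {
    data.table::setattr(rows, "sex", sex)
    data.table::setattr(rows, "age_band", band)
    data.table::setattr(rows, "class",
                        c("admission_records", class(data.table::data.table())))
    rows[]
  }
  if (scheme == "all") {
    return(list(all = stratum(data.table::copy(records), "all", "40-59")))
  }
  if (scheme == "sex") {
    return(stats::setNames(lapply(c("male", "female"), function(s) {
      stratum(records[records$sex == s], s, "40-59")
    }), c("male", "female")))
  }
  out <- list()
  for (s in c("male", "female")) {
    for (b in age_bands()) {
      rows <- records[records$sex == s & age_band_of(records$age) == b]
      out[[paste(s, b, sep = "_")]] <- stratum(rows, s, b)
    }
  }
  out
}
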