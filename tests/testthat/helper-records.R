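# Build an admission_records table from a list of code sets (and optional
# per-record fields), bypassing file IO.
make_records <- function(codes, sex = "male", age = 45,
                         patient_id = NULL, record_id = NULL,
                         date = "2010-01-01") {
  n <- length(codes)
  df <- data.frame(
    record_id = if (is.null(record_id)) sprintf("r%03d", seq_len(n)) else record_id,
    patient_id = if (is.null(patient_id)) sprintf("p%03d", seq_len(n)) else patient_id,
    sex = rep_len(sex, n), age = rep_len(age, n),
    admission_date = rep_len(date, n),
    stringsAsFactors = FALSE
  )
  df$codes <- lapply(codes, as.character)
  as_admission_records(df)
}

# A stratum carrying explicit sex/age_band attributes.
make_stratum <- function(codes, sex = "male", age_band = "40-59", ...) {
  rec <- make_records(codes, sex = sex, ...)
  data.table::setattr(rec, "sex", sex)
  data.table::setattr(rec, "age_band", age_band)
  rec
}

# Minimal mm_network from a bare edge list (frequencies default to 1).
make_network <- function(x, y, frequency = 1, label = "toy",
                         nodes = NULL) {
  edges <- data.frame(x = pmin(x, y), y = pmax(x, y),
                      frequency = rep_len(frequency, length(x)),
                      stringsAsFactors = FALSE)
  multimorbnet:::new_mm_network(
    nodes = if (is.null(nodes)) sort(unique(c(edges$x, edges$y))) else nodes,
    edges = edges, operation = "complete", label = label
  )
}

# Deterministic pool of valid in-scope code labels for synthetic edges.
code_pool <- function(n) {
  grid <- as.vector(outer(sprintf("%02d", 0:99),
                          c("A", "C", "E", "F", "G", "I", "J", "K", "L",
                            "M", "N"),
                          function(d, l) paste0(l, d)))
  grid <- grid[!is.na(icd10_chapter(grid)) & icd10_chapter(grid) <= 14]
  stopifnot(length(grid) >= n)
  grid[seq_len(n)]
}
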