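#' Multimorbidity profile of a stratum
#'
#' Descriptive counts per stratum: distinct diseases observed, total
#' diagnoses (distinct 3-character categories summed over records), and the
#' single (1 disease) / multimorbidity (>= 2) / complex multimorbidity
#' (>= 4) decomposition of records. Percentages are of the stratum record
#' count, kept at full precision; round only at presentation with
#' [round_half_up()].
#'
#' @param stratum an `admission_records` stratum (baseline, in-scope).
#' @return object of class `mm_profile`: a list with `n_records`,
#'   `n_diseases`, `n_diagnoses`, `diagnoses_per_capita`, `n_single`,
#'   `n_multi`, `n_complex`, `pct_single`, `pct_multi`, `pct_complex`,
#'   `sex`, `age_band`.
#' @export
mm_profile <- function(stratum) {
  k <- lengths(stratum$codes)
  n <- nrow(stratum)
  out <- list(
    sex = attr(stratum, "sex") %||% "all",
    age_band = attr(stratum, "age_band") %||% "40-59",
    n_records = n,
    n_diseases = length(unique(unlist(stratum$codes))),
    n_diagnoses = sum(k),
    diagnoses_per_capita = if (n > 0) sum(k) / n else NA_real_,
    n_single = sum(k == 1L),
    n_multi = sum(k >= 2L),
    n_complex = sum(k >= 4L),
    pct_single = if (n > 0) pct_of(sum(k == 1L), n) else NA_real_,
    pct_multi = if (n > 0) pct_of(sum(k >= 2L), n) else NA_real_,
    pct_complex = if (n > 0) pct_of(sum(k >= 4L), n) else NA_real_
  )
  structure(out, class = "mm_profile")
}

#' @export
print.mm_profile <- function(x, ...) {
  cat(sprintf("Multimorbidity profile [%s, %s]\n", x$sex, x$age_band))
  cat(sprintf("  records: %d  diseases: %d  diagnoses: %d (%.2f/capita)\n",
              x$n_records, x$n_diseases, x$n_diagnoses,
              x$diagnoses_per_capita))
  cat(sprintf("  single: %d (%.2f%%)  multimorbidity: %d (%.2f%%)  complex: %d (%.2f%%)\n",
              x$n_single, round_half_up(x$pct_single),
              x$n_multi, round_half_up(x$pct_multi),
              x$n_complex, round_half_up(x$pct_complex)))
  invisible(x)
}

#' Profile table over a list of strata
#'
#' @param strata named list of strata as returned by [stratify()].
#' @return data.frame, one row per stratum, with the [mm_profile()] fields.
#' @export
profile_table <- function(strata) {
  rows <- lapply(names(strata), function(nm) {
    p <- mm_profile(strata[[nm]])
    data.frame(stratum = nm, sex = p$sex, age_band = p$age_band,
               n_records = p$n_records, n_diseases = p$n_diseases,
               n_diagnoses = p$n_diagnoses,
               diagnoses_per_capita = p$diagnoses_per_capita,
               n_single = p$n_single, n_multi = p$n_multi,
               n_complex = p$n_complex, pct_single = p$pct_single,
               pct_multi = p$pct_multi, pct_complex = p$pct_complex,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold ratio between two prevalences
#'
#' The male-to-female (or any A-to-B) fold value reported alongside paired
#' percentages or pattern counts, e.g. 58.51 vs 55.33 -> 1.06.
#'
#' @param p_a,p_b numeric; `p_b` must be non-zero.
#' @return the ratio `p_a / p_b` at full precision; report it rounded
#'   half-up to 2 decimals.
#' @examples
#' round_half_up(prevalence_ratio(58.51, 55.33))  # 1.06
#' @export
prevalence_ratio <- function(p_a, p_b) {
  if (any(p_b == 0)) stop("prevalence_ratio undefined for zero denominator")
  p_a / p_b
}
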