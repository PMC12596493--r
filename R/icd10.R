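#' ICD-10 chapter table
#'
#' The 22 top-level ICD-10 chapters with their 3-character category ranges.
#' Chapter membership is decided by lexicographic comparison of the
#' 3-character category against the range bounds, which is exact because a
#' category is always a letter followed by two digits.
#'
#' @return data.frame with columns `chapter`, `from`, `to`, `label`.
#' @export
icd10_chapter_table <- function() {
  data.frame(
    chapter = 1:22,
    from = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
             "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
             "S00", "V01", "Z00", "U00"),
    to = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
           "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
           "T98", "Y98", "Z99", "U99"),
    label = c("Infectious and parasitic diseases", "Neoplasms",
              "Blood and immune disorders",
              "Endocrine, nutritional and metabolic diseases",
              "Mental and behavioural disorders", "Nervous system",
              "Eye and adnexa", "Ear and mastoid process", "Circulatory system",
              "Respiratory system", "Digestive system",
              "Skin and subcutaneous tissue",
              "Musculoskeletal system and connective tissue",
              "Genitourinary system", "Pregnancy and childbirth",
              "Perinatal conditions", "Congenital malformations",
              "Symptoms and abnormal findings", "Injury and poisoning",
              "External causes", "Factors influencing health status",
              "Codes for special purposes"),
    stringsAsFactors = FALSE
  )
}

#' Chapter of a 3-character ICD-10 category
#'
#' @param code3 character vector of 3-character categories (e.g. `"I10"`).
#' @return integer vector of chapter numbers (1-22); `NA` for strings that
#'   are not valid categories.
#' @examples
#' icd10_chapter(c("E11", "I10", "S72"))
#' @export
icd10_chapter <- function(code3) {
  tab <- icd10_chapter_table()
  out <- rep(NA_integer_, length(code3))
  ok <- grepl("^[A-Z][0-9]{2}$", code3)
  for (k in seq_len(nrow(tab))) {
    in_k <- ok & code3 >= tab$from[k] & code3 <= tab$to[k]
    out[in_k] <- tab$chapter[k]
  }
  out
}

#' Normalise raw ICD-10 codes to 3-character categories
#'
#' Truncates any-precision ICD-10 codes (e.g. `"E11.9"`) to their
#' 3-character category and assigns the standard chapter. Strings whose
#' first three characters do not form a valid category are returned with
#' `NA` fields and flagged in the `valid` column.
#'
#' @param raw character vector of ICD-10 code strings.
#' @return data.frame with columns `raw`, `code3`, `chapter`, `valid`.
#' @examples
#' normalize_icd10(c("E11.9", "I10", "S72.0", "bad"))
#' @export
normalize_icd10 <- function(raw) {
  code3 <- toupper(substr(trimws(raw), 1, 3))
  valid <- grepl("^[A-Z][0-9]{2}$", code3)
  chapter <- icd10_chapter(code3)
  valid <- valid & !is.na(chapter)
  data.frame(raw = raw, code3 = ifelse(valid, code3, NA_character_),
             chapter = ifelse(valid, chapter, NA_integer_),
             valid = valid, stringsAsFactors = FALSE)
}
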