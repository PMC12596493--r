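test_that("raw rows parse into records with normalised code sets", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,patient_id,sex,age,admission_date,codes",
    "r1,p1,male,45,2010-01-02,I10;E11",
    "r2,p2,female,52,2011-06-30,E11.9;E11.2;K29",
    "r3,p3,male,41,2012-01-01,"
  ), tmp)
  rec <- read_records(tmp)
  expect_s3_class(rec, "admission_records")
  expect_equal(nrow(rec), 2)            # empty-codes row rejected
  expect_equal(rec$codes[[1]], c("E11", "I10"))
  # subcategories of one 3-character category count once
  expect_equal(rec$codes[[2]], c("E11", "K29"))
  expect_match(attr(rec, "row_errors"), "row 3", all = FALSE)
})

test_that("missing columns and duplicate record ids are fatal", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,patient_id,sex,age,codes",
               "r1,p1,male,45,I10"), tmp)
  expect_error(read_records(tmp), "admission_date")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,patient_id,sex,age,admission_date,codes",
               "r1,p1,male,45,2010-01-02,I10",
               "r1,p2,male,46,2010-01-03,E11"), tmp2)
  expect_error(read_records(tmp2), "r1")
})

test_that("codes normalise to 3-character categories with standard chapters", {
  norm <- normalize_icd10(c("E11.9", "I10", "S72.0", "bad", "Z51"))
  expect_equal(norm$code3[1:3], c("E11", "I10", "S72"))
  expect_equal(norm$chapter[1:3], c(4L, 9L, 19L))
  expect_false(norm$valid[4])
  expect_equal(norm$chapter[5], 21L)
  # projection: normalising a 3-character category is the identity
  twice <- normalize_icd10(norm$code3[1:3])
  expect_equal(twice$code3, norm$code3[1:3])
  expect_equal(twice$chapter, norm$chapter[1:3])
})

test_that("chapter boundaries follow the standard letter ranges", {
  expect_equal(icd10_chapter(c("A00", "B99", "C00", "D48", "D50", "D89")),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(icd10_chapter(c("H59", "H60", "N99", "O00", "T98", "V01",
                               "U07")),
               c(7L, 8L, 14L, 15L, 19L, 20L, 22L))
})

test_that("scope filter drops Chapter 15-22 codes and rejects empty records", {
  rec <- make_records(list(c("I10", "S72"), c("S72", "Z51"),
                           c("E11", "K29")))
  out <- filter_scope(rec)
  expect_equal(nrow(out), 2)
  expect_equal(out$codes[[1]], "I10")
  expect_equal(out$codes[[2]], c("E11", "K29"))
  rep <- attr(out, "scope_report")
  expect_equal(rep$n_rejected_out_of_scope, 1)
  # idempotence
  again <- filter_scope(out)
  expect_equal(again$codes, out$codes)
  expect_equal(nrow(again), nrow(out))
})

test_that("baseline selection keeps the earliest record per patient, ties by id", {
  rec <- make_records(
    list("I10", "E11", "K29", "N40"),
    patient_id = c("p1", "p1", "p2", "p2"),
    record_id = c("rB", "rA", "r2", "r1"),
    date = c("2009-05-01", "2011-03-02", "2010-01-01", "2010-01-01")
  )
  base <- select_baseline(rec)
  expect_equal(nrow(base), 2)
  expect_equal(sort(base$record_id), c("r1", "rB"))  # earliest; tie -> min id
  # single-record patient kept unchanged
  one <- make_records(list("I10"))
  expect_equal(select_baseline(one)$record_id, one$record_id)
})

test_that("sex-age strata partition the cohort with inclusive band bounds", {
  set.seed(7)
  ages <- sample(40:59, 200, replace = TRUE)
  sexes <- sample(c("male", "female"), 200, replace = TRUE)
  rec <- make_records(replicate(200, "I10", simplify = FALSE),
                      sex = sexes, age = ages)
  strata <- stratify(rec, "sex_age")
  expect_length(strata, 8)
  expect_equal(sum(vapply(strata, nrow, integer(1))), 200)
  # inclusive bounds
  r44 <- make_records(list("I10"), sex = "male", age = 44)
  expect_equal(nrow(stratify(r44, "sex_age")[["male_40-44"]]), 1)
  r59 <- make_records(list("I10"), sex = "female", age = 59)
  expect_equal(nrow(stratify(r59, "sex_age")[["female_55-59"]]), 1)
  # "all" is the identity partition
  expect_equal(nrow(stratify(rec, "all")$all), 200)
})
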