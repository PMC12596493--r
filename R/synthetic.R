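# Synthetic inpatient cohort generator: multi-stratum cohorts with known
# disease marginals, planted pairwise odds ratios (Plackett-style exact
# 2x2 joints; planted pairs are disease-disjoint so each joint is sampled
# exactly), independent background diseases, and a ground-truth manifest.

#' 2x2 joint cell probabilities with given marginals and odds ratio
#'
#' Solves the Plackett equation for `p11`: the root of
#' `psi * (p_x - p11) * (p_y - p11) = p11 * (1 - p_x - p_y + p11)` lying in
#' the Frechet interval `[max(0, p_x + p_y - 1), min(p_x, p_y)]`. The
#' returned cells sum to 1 and their cross-product ratio equals `psi`.
#'
#' @param p_x,p_y marginal probabilities in (0, 1).
#' @param psi target odds ratio, > 0.
#' @return named numeric vector `c(p11, p10, p01, p00)`.
#' @examples
#' joint_from_or(0.5, 0.5, 1)   # independence: p11 = 0.25
#' @export
joint_from_or <- function(p_x, p_y, psi) {
  stopifnot(p_x > 0, p_x < 1, p_y > 0, p_y < 1, psi > 0)
  if (abs(psi - 1) < 1e-12) {
    p11 <- p_x * p_y
  } else {
    # (psi - 1) p11^2 - [1 + (p_x + p_y)(psi - 1)] p11 + psi p_x p_y = 0
    aa <- psi - 1
    bb <- -(1 + (p_x + p_y) * (psi - 1))
    cc <- psi * p_x * p_y
    disc <- bb^2 - 4 * aa * cc
    if (disc < 0) stop("no admissible joint for p_x=", p_x, " p_y=", p_y,
                       " psi=", psi)
    roots <- (-bb + c(-1, 1) * sqrt(disc)) / (2 * aa)
    lo <- max(0, p_x + p_y - 1)
    hi <- min(p_x, p_y)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("no admissible joint for p_x=", p_x, " p_y=", p_y,
                       " psi=", psi)
    p11 <- min(max(roots[ok][1], lo), hi)
  }
  cells <- c(p11 = p11, p10 = p_x - p11, p01 = p_y - p11,
             p00 = 1 - p_x - p_y + p11)
  if (any(cells < -1e-12)) stop("inadmissible joint: negative cell")
  pmax(cells, 0)
}

#' Synthetic study configuration
#'
#' Defaults emulate the statistical shape of a middle-aged inpatient
#' study: eight sex-by-age strata with record counts matching a large
#' Chinese provincial inpatient cohort, a catalog of 3-character ICD-10
#' categories spread over Chapters 1-14 with decreasing marginal
#' prevalences, and planted disease-pair associations (sex-shared,
#' male-only and female-only) with specified odds ratios; all remaining
#' pairs are independent.
#'
#' @param strata data.frame with columns `sex`, `age_band`, `n_records`.
#' @param catalog data.frame with columns `code3`, `prevalence`.
#' @param planted_pairs data.frame with columns `x`, `y`, `target_or`,
#'   `scope` (`both_sexes`, `male_only`, `female_only`); pairs must be
#'   disease-disjoint.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(strata = NULL, catalog = NULL,
                         planted_pairs = NULL) {
  if (is.null(strata)) {
    strata <- data.frame(
      sex = rep(c("male", "female"), each = 4),
      age_band = rep(age_bands(), 2),
      n_records = c(30167, 31655, 25402, 16110,
                    20956, 24751, 21550, 13542)
    )
  }
  if (is.null(catalog)) catalog <- default_catalog()
  if (is.null(planted_pairs)) planted_pairs <- default_planted_pairs(catalog)
  validate_synth_config(strata, catalog, planted_pairs)
  structure(list(strata = strata, catalog = catalog,
                 planted_pairs = planted_pairs), class = "synth_config")
}

validate_synth_config <- function(strata, catalog, planted_pairs) {
  stopifnot(all(c("sex", "age_band", "n_records") %in% names(strata)),
            all(strata$sex %in% c("male", "female")),
            all(strata$n_records >= 0),
            all(c("code3", "prevalence") %in% names(catalog)),
            all(catalog$prevalence > 0), all(catalog$prevalence < 1),
            !anyDuplicated(catalog$code3))
  if (nrow(planted_pairs) > 0) {
    stopifnot(all(c("x", "y", "target_or", "scope") %in% names(planted_pairs)),
              all(planted_pairs$target_or > 0),
              all(planted_pairs$scope %in%
                    c("both_sexes", "male_only", "female_only")),
              all(c(planted_pairs$x, planted_pairs$y) %in% catalog$code3))
    support <- c(planted_pairs$x, planted_pairs$y)
    if (anyDuplicated(support)) {
      stop("planted pairs must be disease-disjoint")
    }
  }
  invisible(TRUE)
}

# Catalog of 150 in-scope categories: the first codes of each Chapter 1-14
# letter block, cycled, with a power-law prevalence profile calibrated so
# the expected diagnoses per record is around 2.3 (middle-aged inpatient
# scale).
default_catalog <- function(n_diseases = 150) {
  starts <- c("A", "C", "D5", "E", "F", "G", "H0", "H6", "I", "J", "K",
              "L", "M", "N")
  codes <- character(0)
  i <- 0
  while (length(codes) < n_diseases) {
    blk <- starts[(i %% length(starts)) + 1]
    num <- i %/% length(starts)
    code <- if (nchar(blk) == 2) {
      paste0(substr(blk, 1, 1), as.integer(substr(blk, 2, 2)) + num %/% 10,
             num %% 10)
    } else {
      sprintf("%s%02d", blk, num)
    }
    if (!is.na(icd10_chapter(code)) && icd10_chapter(code) <= 14 &&
        !(code %in% codes)) {
      codes <- c(codes, code)
    }
    i <- i + 1
  }
  prev <- 0.18 / (seq_len(n_diseases))^0.7
  prev <- pmax(prev, 5e-4)
  data.frame(code3 = codes, prevalence = prev, stringsAsFactors = FALSE)
}

# Planted pattern sets: 8 sex-shared pairs (psi 2/4/8), 5 male-only and
# 5 female-only pairs (psi 6), drawn from mid-prevalence catalog entries
# so both power and contrast are realistic.
default_planted_pairs <- function(catalog) {
  pool <- catalog$code3[catalog$prevalence >= 0.01 &
                          catalog$prevalence <= 0.15]
  pool <- pool[seq_len(36)]
  x <- pool[seq(1, 36, by = 2)]
  y <- pool[seq(2, 36, by = 2)]
  data.frame(
    x = x, y = y,
    target_or = c(rep(c(2, 4, 8), length.out = 8), rep(6, 10)),
    scope = c(rep("both_sexes", 8), rep("male_only", 5),
              rep("female_only", 5)),
    stringsAsFactors = FALSE
  )
}

# Does a planted pair apply in a stratum of the given sex?
pair_active <- function(scope, sex) {
  scope == "both_sexes" | (scope == "male_only" & sex == "male") |
    (scope == "female_only" & sex == "female")
}

#' Generate a synthetic cohort with ground truth
#'
#' Per stratum, each record's disease set is drawn as: every active
#' planted pair sampled jointly from its exact 2x2 cells (pairs are
#' disease-disjoint, so joint sampling is exact), every other catalog
#' disease as an independent Bernoulli at its marginal prevalence.
#' Records with an empty disease set are redrawn (ingest rejects empty
#' code sets); the redraw count is reported so the induced slight marginal
#' bias is visible. Ages are uniform within the band, admission dates
#' constant, one record per synthetic patient. Byte-identical output for
#' identical `config` and `seed`.
#'
#' @param config a [synth_config()].
#' @param seed integer RNG seed.
#' @return list with `records` (an `admission_records` table) and
#'   `ground_truth` (list with `planted` — per sex, the pair table with
#'   its exact joint cells and expected OR — and `n_redrawn`).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  catalog <- config$catalog
  planted <- config$planted_pairs
  band_lo <- c("40-44" = 40L, "45-49" = 45L, "50-54" = 50L, "55-59" = 55L)

  all_rows <- list()
  n_redrawn <- 0L
  pid0 <- 0L
  for (si in seq_len(nrow(config$strata))) {
    sex <- config$strata$sex[si]
    band <- config$strata$age_band[si]
    n <- config$strata$n_records[si]
    if (n == 0) next
    active <- planted[pair_active(planted$scope, sex), , drop = FALSE]
    planted_dis <- c(active$x, active$y)
    bg <- catalog[!(catalog$code3 %in% planted_dis), , drop = FALSE]
    # inactive planted diseases still occur at their marginals,
    # independently, so male-only pairs exist (as nodes) in female strata
    inactive_dis <- setdiff(c(planted$x, planted$y), planted_dis)
    bg <- rbind(bg, catalog[catalog$code3 %in% inactive_dis, , drop = FALSE])

    draw <- function(nn) {
      has <- matrix(FALSE, nrow = nn, ncol = nrow(catalog),
                    dimnames = list(NULL, catalog$code3))
      for (k in seq_len(nrow(active))) {
        px <- catalog$prevalence[catalog$code3 == active$x[k]]
        py <- catalog$prevalence[catalog$code3 == active$y[k]]
        cells <- joint_from_or(px, py, active$target_or[k])
        cell <- sample.int(4, nn, replace = TRUE, prob = cells)
        has[, active$x[k]] <- cell %in% c(1L, 2L)
        has[, active$y[k]] <- cell %in% c(1L, 3L)
      }
      for (k in seq_len(nrow(bg))) {
        has[, bg$code3[k]] <- stats::runif(nn) < bg$prevalence[k]
      }
      has
    }
    has <- draw(n)
    empty <- which(rowSums(has) == 0)
    while (length(empty) > 0) {
      n_redrawn <- n_redrawn + length(empty)
      has[empty, ] <- draw(length(empty))
      empty <- empty[rowSums(has[empty, , drop = FALSE]) == 0]
    }
    nz <- which(has, arr.ind = TRUE)
    codes <- lapply(split(catalog$code3[nz[, 2]],
                          factor(nz[, 1], levels = seq_len(n))), sort)
    ids <- sprintf("p%07d", pid0 + seq_len(n))
    pid0 <- pid0 + n
    all_rows[[length(all_rows) + 1]] <- data.table::data.table(
      record_id = paste0("r_", ids),
      patient_id = ids,
      sex = sex,
      age = band_lo[[band]] + sample.int(5, n, replace = TRUE) - 1L,
      admission_date = as.Date("2010-01-01"),
      codes = codes
    )
  }
  records <- data.table::rbindlist(all_rows)
  data.table::setattr(records, "class",
                      c("admission_records", class(data.table::data.table())))

  gt <- lapply(c("male", "female"), function(sex) planted_truth(config, sex))
  names(gt) <- c("male", "female")
  list(records = records[],
       ground_truth = list(planted = gt, pairs = planted,
                           n_redrawn = n_redrawn, seed = as.integer(seed)))
}

#' Exact planted-pair truth in a sex stratum
#'
#' For every pair planted in strata of the given sex: the nominal 2x2
#' joint cells implied by the marginals and target OR, and the exact
#' cells of emitted records after the empty-record redraw. The redraw
#' conditions each record on carrying at least one disease, which
#' reweights the neither-disease cell by `1 - q`, where `q` is the
#' probability that every *other* catalog disease is absent; the
#' conditional odds ratio is therefore `target_or * (1 - q)`, slightly
#' below target. Both are reported so calibration checks can use the
#' exact sampling distribution.
#'
#' @param config a [synth_config()].
#' @param sex `"male"` or `"female"`.
#' @return the active planted-pair table with nominal cells (`p11` ..
#'   `p00`), conditional cells (`p11_c` .. `p00_c`), and
#'   `or_conditional`.
#' @export
planted_truth <- function(config, sex) {
  catalog <- config$catalog
  planted <- config$planted_pairs
  active <- planted[pair_active(planted$scope, sex), , drop = FALSE]
  if (nrow(active) == 0) return(active)
  prev_of <- function(code) catalog$prevalence[catalog$code3 == code]
  cells <- t(vapply(seq_len(nrow(active)), function(k) {
    joint_from_or(prev_of(active$x[k]), prev_of(active$y[k]),
                  active$target_or[k])
  }, numeric(4)))
  colnames(cells) <- c("p11", "p10", "p01", "p00")
  # q_k: P(no disease outside pair k) = prod over independent diseases of
  # (1 - p) times prod over other active pairs of their p00
  bg_codes <- setdiff(catalog$code3, c(active$x, active$y))
  q_bg <- prod(1 - catalog$prevalence[catalog$code3 %in% bg_codes])
  cond <- t(vapply(seq_len(nrow(active)), function(k) {
    q <- q_bg * prod(cells[-k, "p00"])
    w <- c(1, 1, 1, 1 - q)
    cw <- cells[k, ] * w
    cw / sum(cw)
  }, numeric(4)))
  colnames(cond) <- c("p11_c", "p10_c", "p01_c", "p00_c")
  out <- cbind(active, as.data.frame(cells), as.data.frame(cond))
  out$or_conditional <- out$p11_c * out$p00_c / (out$p10_c * out$p01_c)
  rownames(out) <- NULL
  out
}

#' Write a cohort fixture (records + ground-truth manifest)
#'
#' Emits the delimited format [read_records()] consumes plus, when ground
#' truth is supplied, a JSON manifest of the planted pairs.
#'
#' @param records an `admission_records` table.
#' @param path output path for the cohort CSV.
#' @param ground_truth optional ground-truth list from [generate_cohort()];
#'   written to `paste0(path, ".truth.json")`.
#' @return invisibly, the cohort path.
#' @export
write_cohort <- function(records, path, ground_truth = NULL) {
  flat <- data.table::data.table(
    record_id = records$record_id, patient_id = records$patient_id,
    sex = records$sex, age = records$age,
    admission_date = format(records$admission_date, "%Y-%m-%d"),
    codes = vapply(records$codes, paste, character(1), collapse = ";")
  )
  data.table::fwrite(flat, path)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
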