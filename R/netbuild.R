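#' Edge-selection criteria for a multimorbidity network
#'
#' The three criteria an unordered disease pair (a "multimorbidity
#' pattern") must meet to become an edge:
#' \enumerate{
#'   \item odds ratio strictly greater than `or_floor` (default 1);
#'   \item two-sided p-value strictly below `alpha / N`, where `N` is the
#'     number of candidate patterns in the stratum with OR > `or_floor`
#'     (Bonferroni correction over the OR > 1 patterns);
#'   \item pattern prevalence (co-occurrence count over stratum record
#'     count) strictly greater than `prevalence_floor` (default 1/10 000).
#' }
#' All inequalities are strict.
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param or_floor odds-ratio floor (default 1).
#' @param prevalence_floor minimum pattern prevalence (default 1e-4).
#' @return list of class `network_criteria`.
#' @export
network_criteria <- function(alpha = 0.05, or_floor = 1,
                             prevalence_floor = 1 / 10000) {
  stopifnot(alpha > 0, alpha < 1, or_floor > 0, prevalence_floor >= 0)
  structure(list(alpha = alpha, or_floor = or_floor,
                 prevalence_floor = prevalence_floor),
            class = "network_criteria")
}

#' 2x2 contingency table for a disease pair
#'
#' Cell `a` counts records carrying both diseases, `b` only `x`, `c` only
#' `y`, `d` neither; `a + b + c + d` equals the stratum record count.
#'
#' @param stratum an `admission_records` stratum.
#' @param x,y distinct 3-character categories, both observed in the stratum.
#' @return list with integers `a`, `b`, `c`, `d`, `n`.
#' @export
pair_contingency <- function(stratum, x, y) {
  stopifnot(x != y)
  has_x <- vapply(stratum$codes, function(v) x %in% v, logical(1))
  has_y <- vapply(stratum$codes, function(v) y %in% v, logical(1))
  if (!any(has_x)) stop("disease not observed in stratum: ", x)
  if (!any(has_y)) stop("disease not observed in stratum: ", y)
  a <- sum(has_x & has_y)
  list(a = a, b = sum(has_x) - a, c = sum(has_y) - a,
       d = nrow(stratum) - sum(has_x) - sum(has_y) + a, n = nrow(stratum))
}

#' Odds ratio and p-value for 2x2 tables
#'
#' Maximum-likelihood association estimate for the single-binary-predictor
#' logistic model of disease `y` on disease `x`. On a 2x2 table the model
#' is saturated, so the MLE of the odds ratio is exactly the cross-product
#' ratio `a*d / (b*c)` and the Wald standard error of the log odds ratio is
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. The p-value is the two-sided
#' likelihood-ratio test of zero log-odds, whose deviance has the closed
#' form of the G-test of independence, `G^2 = 2 * sum(O * log(O / E))`
#' with `E` the margin-product expectations; the Wald test is also
#' reported (`p_wald`) but is not used for edge selection because it is
#' anti-conservative by orders of magnitude in the far tail when the
#' expected co-occurrence count is small, which breaks family-wise error
#' control under Bonferroni correction. Tables with an empty `b` or `c`
#' cell (separation) yield a non-finite estimate and are flagged unusable;
#' a table with `a = 0` has OR 0 and can never be accepted.
#'
#' Vectorised over the four cells.
#'
#' @param a,b,c,d non-negative cell counts (both-x-only-y-only-neither).
#' @return data.frame with columns `or`, `log_or`, `se`, `p`
#'   (likelihood-ratio), `p_wald`, `usable` (`TRUE` when all four cells
#'   are positive, so OR and p are finite).
#' @examples
#' estimate_association(30, 20, 10, 940)  # OR = 141
#' @export
estimate_association <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  usable <- a > 0 & b > 0 & c > 0 & d > 0
  or <- rep(NA_real_, length(a))
  or[usable] <- (a[usable] * d[usable]) / (b[usable] * c[usable])
  or[!usable & a == 0 & b > 0 & c > 0] <- 0    # no co-occurrence: OR 0
  log_or <- ifelse(usable, log(or), NA_real_)
  se <- ifelse(usable, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  p_wald <- ifelse(usable, 2 * stats::pnorm(-abs(log_or / se)), NA_real_)
  # likelihood-ratio deviance: G^2 = 2 * sum(O * log(O / E)), clamped at 0
  # against floating-point underflow near independence
  n <- a + b + c + d
  g2 <- 2 * (a * log(a * n / ((a + b) * (a + c))) +
               b * log(b * n / ((a + b) * (b + d))) +
               c * log(c * n / ((c + d) * (a + c))) +
               d * log(d * n / ((c + d) * (b + d))))
  p <- ifelse(usable,
              stats::pchisq(pmax(g2, 0), df = 1, lower.tail = FALSE),
              NA_real_)
  data.frame(or = or, log_or = log_or, se = se, p = p, p_wald = p_wald,
             usable = usable)
}

#' Bonferroni significance threshold
#'
#' `alpha / N`, where `N` counts the candidate patterns with a finite
#' odds ratio above the floor.
#'
#' @param or vector of candidate odds ratios (finite or `NA`).
#' @param alpha family-wise level.
#' @param or_floor odds-ratio floor defining `N` (default 1).
#' @return list with `n_bonferroni` and `threshold` (`NA` when `N` is 0).
#' @export
bonferroni_threshold <- function(or, alpha = 0.05, or_floor = 1) {
  n <- sum(!is.na(or) & is.finite(or) & or > or_floor)
  list(n_bonferroni = n,
       threshold = if (n > 0) alpha / n else NA_real_)
}

# All unordered pairs with co-occurrence count >= 1, via a sparse record x
# disease incidence matrix. Pairs with a = 0 have OR 0 and are never
# candidates for acceptance nor for the Bonferroni count.
co_occurrence_pairs <- function(stratum) {
  diseases <- sort(unique(unlist(stratum$codes)))
  n <- nrow(stratum)
  if (length(diseases) == 0 || n == 0) {
    return(list(diseases = diseases, n = n,
                pairs = data.frame(x = character(0), y = character(0),
                                   a = integer(0), b = integer(0),
                                   c = integer(0), d = integer(0))))
  }
  j <- match(unlist(stratum$codes), diseases)
  i <- rep.int(seq_len(n), lengths(stratum$codes))
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n, length(diseases)))
  margin <- Matrix::colSums(m)
  co <- Matrix::crossprod(m)
  ut <- methods::as(Matrix::triu(co, k = 1), "TsparseMatrix")
  xi <- ut@i + 1L
  yi <- ut@j + 1L
  a <- as.integer(ut@x)
  keep <- a > 0L
  xi <- xi[keep]; yi <- yi[keep]; a <- a[keep]
  list(diseases = diseases, n = n, pairs = data.frame(
    x = diseases[xi], y = diseases[yi], a = a,
    b = as.integer(margin[xi]) - a, c = as.integer(margin[yi]) - a,
    d = n - as.integer(margin[xi]) - as.integer(margin[yi]) + a,
    stringsAsFactors = FALSE
  ))
}

#' Build the complete multimorbidity network of a stratum
#'
#' Enumerates all co-occurring unordered disease pairs, estimates each
#' pair's odds ratio and likelihood-ratio p-value
#' ([estimate_association()]), computes
#' the stratum's own Bonferroni threshold ([bonferroni_threshold()]), and
#' accepts as edges exactly the pairs meeting all three
#' [network_criteria()]. Nodes are all diseases observed in the stratum,
#' including those left isolated.
#'
#' @param stratum an `admission_records` stratum (baseline, in-scope).
#' @param criteria a [network_criteria()] object.
#' @param label stratum label for provenance (defaults to sex/age
#'   attributes).
#' @return object of class `mm_network`: list with `nodes` (character),
#'   `edges` (accepted pairs with `x`, `y`, `a`, `b`, `c`, `d`, `or`, `p`,
#'   `frequency`, `prevalence`), `candidates` (all evaluated pairs plus
#'   `accepted` and `reason`), `criteria` (echoed, plus realised
#'   `n_bonferroni` and `threshold`), `stratum_label`, `n_records`,
#'   `total_pattern_frequency`, `operation = "complete"`.
#' @export
build_network <- function(stratum, criteria = network_criteria(),
                          label = NULL) {
  stopifnot(inherits(criteria, "network_criteria"))
  if (is.null(label)) {
    label <- paste(attr(stratum, "sex") %||% "all",
                   attr(stratum, "age_band") %||% "40-59", sep = "_")
  }
  cp <- co_occurrence_pairs(stratum)
  pairs <- cp$pairs
  est <- estimate_association(pairs$a, pairs$b, pairs$c, pairs$d)
  # N is fixed at the count of patterns with OR > 1 (not or_floor), so the
  # significance threshold does not loosen when the floor is tightened.
  bon <- bonferroni_threshold(est$or, alpha = criteria$alpha, or_floor = 1)
  prevalence <- pairs$a / cp$n

  pass_or <- est$usable & est$or > criteria$or_floor
  pass_p <- pass_or & !is.na(bon$threshold) & est$p < bon$threshold
  pass_prev <- prevalence > criteria$prevalence_floor
  accepted <- pass_or & pass_p & pass_prev

  reason <- rep("", nrow(pairs))
  reason[!est$usable] <- "degenerate_table"
  reason[est$usable & !pass_or] <- "or_not_above_floor"
  reason[pass_or & !pass_p] <- "p_above_bonferroni"
  reason[pass_or & pass_p & !pass_prev] <- "prevalence_below_floor"
  reason[accepted] <- "accepted"

  candidates <- cbind(pairs,
                      data.frame(or = est$or, p = est$p,
                                 prevalence = prevalence,
                                 accepted = accepted, reason = reason,
                                 stringsAsFactors = FALSE))
  edges <- candidates[accepted, c("x", "y", "a", "b", "c", "d", "or", "p",
                                  "prevalence"), drop = FALSE]
  edges$frequency <- edges$a
  rownames(edges) <- NULL

  structure(list(
    nodes = cp$diseases,
    edges = edges,
    candidates = candidates,
    criteria = c(unclass(criteria), bon),
    stratum_label = label,
    n_records = cp$n,
    total_pattern_frequency = sum(edges$frequency),
    operation = "complete"
  ), class = "mm_network")
}

#' @export
print.mm_network <- function(x, ...) {
  cat(sprintf("Multimorbidity network [%s, %s]\n", x$stratum_label,
              x$operation))
  cat(sprintf("  nodes: %d  edges: %d  total pattern frequency: %d\n",
              length(x$nodes), nrow(x$edges),
              as.integer(x$total_pattern_frequency)))
  if (!is.null(x$criteria$n_bonferroni)) {
    cat(sprintf("  criteria: OR > %g, p < %g/%d, prevalence > %g\n",
                x$criteria$or_floor, x$criteria$alpha,
                x$criteria$n_bonferroni, x$criteria$prevalence_floor))
  }
  invisible(x)
}

# Internal constructor for derived networks (algebra, hub subgraphs).
new_mm_network <- function(nodes, edges, operation, label,
                           n_records = NA_integer_, criteria = NULL,
                           parents = NULL) {
  freq <- if ("frequency" %in% names(edges)) sum(edges$frequency) else NA_real_
  structure(list(nodes = nodes, edges = edges, candidates = NULL,
                 criteria = criteria, stratum_label = label,
                 n_records = n_records,
                 total_pattern_frequency = freq,
                 operation = operation, parents = parents),
            class = "mm_network")
}
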