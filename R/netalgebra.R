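# Second- and third-level networks: edge-set algebra between the male and
# female complete networks, and independent per-age-band rebuilds. Edge
# identity is the unordered code pair only; the association statistics play
# no role in matching.

#' Sex-overlapped network (edge intersection)
#'
#' Edges present in both networks; per-side statistics are retained
#' side-by-side with `_left` / `_right` suffixes. The node set is the set
#' of endpoints of the surviving edges, not the union of parent node sets.
#' Symmetric in its arguments up to the suffix labelling.
#'
#' @param left,right `mm_network` objects sharing the code namespace.
#' @return an `mm_network` with `operation = "overlapped"`. `frequency` is
#'   the left-side pattern frequency (`frequency_left` and
#'   `frequency_right` are both retained).
#' @export
net_overlap <- function(left, right) {
  kl <- pair_key(left$edges$x, left$edges$y)
  kr <- pair_key(right$edges$x, right$edges$y)
  shared <- intersect(kl, kr)
  le <- left$edges[match(shared, kl), , drop = FALSE]
  re <- right$edges[match(shared, kr), , drop = FALSE]
  stat_cols <- setdiff(names(le), c("x", "y"))
  edges <- le[, c("x", "y"), drop = FALSE]
  for (cc in stat_cols) {
    edges[[paste0(cc, "_left")]] <- le[[cc]]
    if (cc %in% names(re)) edges[[paste0(cc, "_right")]] <- re[[cc]]
  }
  edges$frequency <- if ("frequency" %in% names(le)) le$frequency else NA
  rownames(edges) <- NULL
  new_mm_network(
    nodes = sort(unique(c(edges$x, edges$y))), edges = edges,
    operation = "overlapped",
    label = paste(left$stratum_label, right$stratum_label, sep = "&"),
    parents = c(left$stratum_label, right$stratum_label)
  )
}

#' Sex-specific network (edge difference)
#'
#' Edges of `left` absent from `right`; statistics carried over from
#' `left`. Node set = endpoints of the surviving edges. Not symmetric.
#'
#' @inheritParams net_overlap
#' @return an `mm_network` with `operation = "specific"`.
#' @export
net_specific <- function(left, right) {
  kl <- pair_key(left$edges$x, left$edges$y)
  kr <- pair_key(right$edges$x, right$edges$y)
  edges <- left$edges[!(kl %in% kr), , drop = FALSE]
  rownames(edges) <- NULL
  new_mm_network(
    nodes = sort(unique(c(edges$x, edges$y))), edges = edges,
    operation = "specific",
    label = paste0(left$stratum_label, "_specific"),
    criteria = left$criteria,
    parents = c(left$stratum_label, right$stratum_label)
  )
}

#' Age-band networks within one sex
#'
#' Builds one complete network per 5-year age band, each on its own
#' stratum with its own Bonferroni count; band networks are mutually
#' independent and need not nest.
#'
#' @param records an `admission_records` cohort (baseline, in-scope).
#' @param sex `"male"` or `"female"`.
#' @param criteria a [network_criteria()] object.
#' @return named list of `mm_network`, one per band in [age_bands()].
#' @export
decompose_by_age <- function(records, sex, criteria = network_criteria()) {
  stopifnot(sex %in% c("male", "female"))
  strata <- stratify(records[records$sex == sex], scheme = "sex_age")
  strata <- strata[paste(sex, age_bands(), sep = "_")]
  out <- lapply(strata, build_network, criteria = criteria)
  stats::setNames(out, age_bands())
}
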