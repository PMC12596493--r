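# ICD-10 chapter aggregation of accepted pattern frequencies, and the
# rank-trajectory surface across age bands.

#' Chapter-level pattern frequencies of a network
#'
#' Attributes each accepted edge's pattern frequency to the ICD-10 chapter
#' of each of its two endpoints. Under `"dual"` attribution (default) a
#' cross-chapter edge credits both chapters with its full frequency and a
#' within-chapter edge is credited once, so percentages over chapters can
#' sum above 100; under `"half"` a cross-chapter edge credits half its
#' frequency to each side. The percentage denominator is the network's
#' total pattern frequency in both modes. Ranks are assigned by descending
#' percentage, ties broken by ascending chapter number.
#'
#' @param net an `mm_network`.
#' @param attribution `"dual"` or `"half"`.
#' @return data.frame with columns `chapter`, `freq`, `pct`, `rank`, one
#'   row per chapter present in the network's edges, ordered by rank.
#' @export
chapter_frequencies <- function(net, attribution = c("dual", "half")) {
  attribution <- match.arg(attribution)
  edges <- net$edges
  if (nrow(edges) == 0) {
    return(data.frame(chapter = integer(0), freq = numeric(0),
                      pct = numeric(0), rank = integer(0)))
  }
  chx <- icd10_chapter(edges$x)
  chy <- icd10_chapter(edges$y)
  stopifnot(all(chx <= 14L), all(chy <= 14L))
  total <- sum(edges$frequency)
  cross <- chx != chy
  w <- if (attribution == "dual") 1 else 0.5
  chap <- c(chx, chy[cross])
  freq <- c(ifelse(cross, w * edges$frequency, edges$frequency),
            w * edges$frequency[cross])
  agg <- tapply(freq, chap, sum)
  out <- data.frame(chapter = as.integer(names(agg)),
                    freq = as.numeric(agg))
  out$pct <- pct_of(out$freq, total)
  ord <- order(-out$pct, out$chapter)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Chapter rank trajectories across age bands
#'
#' Per band, ranks chapters by [chapter_frequencies()]; a chapter absent
#' from a band's network gets `NA` rank there (not the worst rank). The
#' long format suits line charts of rank against age.
#'
#' @param nets_by_age named list of `mm_network`, one per age band.
#' @param attribution passed to [chapter_frequencies()].
#' @return data.frame with columns `age_band`, `chapter`, `freq`, `pct`,
#'   `rank`; bands with an empty network contribute rows with `NA` rank
#'   for every in-scope chapter.
#' @export
rank_trajectories <- function(nets_by_age, attribution = c("dual", "half")) {
  attribution <- match.arg(attribution)
  stopifnot(length(nets_by_age) >= 2, !is.null(names(nets_by_age)))
  chapters_seen <- sort(unique(unlist(lapply(nets_by_age, function(nn) {
    chapter_frequencies(nn, attribution)$chapter
  }))))
  if (length(chapters_seen) == 0) chapters_seen <- integer(0)
  rows <- lapply(names(nets_by_age), function(band) {
    cf <- chapter_frequencies(nets_by_age[[band]], attribution)
    base <- data.frame(age_band = band, chapter = chapters_seen,
                       stringsAsFactors = FALSE)
    merge(base, cf, by = "chapter", all.x = TRUE)[, c("age_band", "chapter",
                                                      "freq", "pct", "rank")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_band, out$chapter), , drop = FALSE]
  rownames(out) <- NULL
  out
}
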