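# End-to-end orchestration: cohort -> profiles -> three network levels ->
# hubs/coverage -> chapter rankings, plus network export.

#' Run the full multimorbidity-network pipeline
#'
#' Applies the analysis sequence to a cohort: baseline selection, Chapter
#' 1-14 scope filter, stratification, per-stratum multimorbidity profiles,
#' complete networks (overall, per sex, per sex-age band), sex-specific
#' and sex-overlapped networks, hub diseases with hub / hub-associated
#' networks and coverage, and chapter frequency rankings with age-band
#' rank trajectories. Also audits the decomposition identity
#' `|complete| = |specific| + |overlapped|` for each sex.
#'
#' @param records an `admission_records` cohort (raw admissions are fine:
#'   baseline selection and scope filtering are applied here).
#' @param criteria a [network_criteria()] object.
#' @param hub_k number of hub diseases per network (default 10).
#' @param attribution chapter attribution mode, see [chapter_frequencies()].
#' @param out_dir optional directory; when given, summary tables, edge
#'   lists and JSON reports are written under it.
#' @return list with `profiles` (master summary data.frame, one row per
#'   stratum: overall, per sex, per sex-age), `networks` (named list of
#'   `mm_network`), `hubs`, `coverage`, `metrics`, `chapters`,
#'   `trajectories`, `identity_checks`, `filter_report`.
#' @export
run_pipeline <- function(records, criteria = network_criteria(),
                         hub_k = 10, attribution = "dual", out_dir = NULL) {
  records <- select_baseline(records)
  records <- filter_scope(records)
  filter_report <- attr(records, "scope_report")

  strata <- c(stratify(records, "all"), stratify(records, "sex"),
              stratify(records, "sex_age"))
  profiles <- profile_table(strata)

  networks <- lapply(strata, build_network, criteria = criteria)
  networks[["male_specific"]] <- net_specific(networks$male, networks$female)
  networks[["female_specific"]] <- net_specific(networks$female,
                                                networks$male)
  networks[["sex_overlapped"]] <- net_overlap(networks$male,
                                              networks$female)

  identity_checks <- data.frame(
    sex = c("male", "female"),
    complete = c(nrow(networks$male$edges), nrow(networks$female$edges)),
    specific = c(nrow(networks$male_specific$edges),
                 nrow(networks$female_specific$edges)),
    overlapped = nrow(networks$sex_overlapped$edges)
  )
  identity_checks$holds <-
    identity_checks$complete ==
    identity_checks$specific + identity_checks$overlapped

  complete_names <- names(strata)
  metrics <- list(); hubs <- list(); cov <- list()
  for (nm in complete_names) {
    net <- networks[[nm]]
    if (nrow(net$edges) == 0) next
    m <- node_metrics(net)
    # short-hub-list warnings are expected for sparse strata; the realised
    # hub count is visible in the hubs element
    h <- withCallingHandlers(
      top_hubs(net, k = hub_k, metrics = m),
      warning = function(w) {
        if (grepl("returning all", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    hn <- hub_network(net, h)
    han <- hub_associated_network(net, h)
    metrics[[nm]] <- m
    hubs[[nm]] <- h
    cov[[nm]] <- list(hub = coverage(hn, net),
                      hub_associated = coverage(han, net))
    networks[[paste0(nm, "_hub")]] <- hn
    networks[[paste0(nm, "_hub_associated")]] <- han
  }

  chapters <- lapply(networks[c("male_specific", "female_specific")],
                     chapter_frequencies, attribution = attribution)
  trajectories <- list(
    male = rank_trajectories(
      stats::setNames(networks[paste0("male_", age_bands())], age_bands()),
      attribution = attribution),
    female = rank_trajectories(
      stats::setNames(networks[paste0("female_", age_bands())], age_bands()),
      attribution = attribution)
  )

  # master summary: Table-1-shaped row per stratum
  summary_rows <- lapply(complete_names, function(nm) {
    net <- networks[[nm]]
    p <- profiles[profiles$stratum == nm, ]
    han_cov <- if (!is.null(cov[[nm]])) cov[[nm]]$hub_associated else NULL
    data.frame(
      stratum = nm,
      n_records = p$n_records, n_diseases = p$n_diseases,
      n_diagnoses = p$n_diagnoses,
      n_single = p$n_single, pct_single = round_half_up(p$pct_single),
      n_multi = p$n_multi, pct_multi = round_half_up(p$pct_multi),
      n_complex = p$n_complex, pct_complex = round_half_up(p$pct_complex),
      net_nodes = length(net$nodes), net_edges = nrow(net$edges),
      net_freq = net$total_pattern_frequency,
      bonferroni_n = net$criteria$n_bonferroni %||% NA_integer_,
      hub_assoc_nodes = if (is.null(han_cov)) NA else han_cov$node_count,
      hub_assoc_node_pct = if (is.null(han_cov)) NA else
        round_half_up(han_cov$node_pct),
      hub_assoc_edges = if (is.null(han_cov)) NA else han_cov$edge_count,
      hub_assoc_edge_pct = if (is.null(han_cov)) NA else
        round_half_up(han_cov$edge_pct),
      hub_assoc_freq = if (is.null(han_cov)) NA else han_cov$freq_total,
      hub_assoc_freq_pct = if (is.null(han_cov)) NA else
        round_half_up(han_cov$freq_pct),
      stringsAsFactors = FALSE
    )
  })
  master <- do.call(rbind, summary_rows)

  out <- list(profiles = profiles, master = master, networks = networks,
              metrics = metrics, hubs = hubs, coverage = cov,
              chapters = chapters, trajectories = trajectories,
              identity_checks = identity_checks,
              filter_report = filter_report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(master, file.path(out_dir, "master_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(profiles, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(networks)) {
      export_network(networks[[nm]],
                     file.path(out_dir, paste0("network_", nm, ".tsv")),
                     format = "tsv")
    }
    jsonlite::write_json(
      list(criteria = unclass(criteria), identity_checks = identity_checks,
           hubs = hubs, coverage = cov, filter_report = filter_report),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Export a network as TSV or GraphML
#'
#' TSV carries the full edge table (round-trips losslessly through
#' [utils::read.delim()]); GraphML carries node and edge attributes for
#' network tools.
#'
#' @param net an `mm_network`.
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
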