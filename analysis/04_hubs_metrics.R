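#!/usr/bin/env Rscript
# Node metrics and hub diseases: the seven centrality metrics per network,
# top-10 hubs by degree, and the coverage of the hub-associated networks
# (share of nodes, patterns and pattern frequency they retain).

library(multimorbnet)

res <- readRDS("results/pipeline.rds")

metrics <- do.call(rbind, lapply(names(res$metrics), function(nm) {
  cbind(network = nm, res$metrics[[nm]])
}))
write.table(metrics, "results/node_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

hubs <- do.call(rbind, lapply(names(res$hubs), function(nm) {
  data.frame(network = nm, rank = seq_along(res$hubs[[nm]]),
             node = as.character(res$hubs[[nm]]))
}))
write.table(hubs, "results/hubs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cov <- do.call(rbind, lapply(names(res$coverage), function(nm) {
  cv <- res$coverage[[nm]]$hub_associated
  data.frame(network = nm,
             nodes = cv$node_count, node_pct = round_half_up(cv$node_pct),
             edges = cv$edge_count, edge_pct = round_half_up(cv$edge_pct),
             freq = cv$freq_total, freq_pct = round_half_up(cv$freq_pct))
}))
write.table(cov, "results/hub_associated_coverage.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

print(cov)
cat("wrote results/node_metrics.tsv, results/hubs.tsv,",
    "results/hub_associated_coverage.tsv\n")
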