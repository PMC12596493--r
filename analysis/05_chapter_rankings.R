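#!/usr/bin/env Rscript
# ICD-10 chapter involvement: chapter frequency percentages of the
# sex-specific networks (dual attribution) and chapter rank trajectories
# across the four age bands for each sex.

library(multimorbnet)

res <- readRDS("results/pipeline.rds")

ch <- do.call(rbind, lapply(names(res$chapters), function(nm) {
  cbind(network = nm, res$chapters[[nm]])
}))
write.table(ch, "results/chapter_frequencies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (sex in c("male", "female")) {
  tr <- res$trajectories[[sex]]
  write.table(tr, sprintf("results/chapter_ranks_%s.tsv", sex),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

print(head(ch[order(ch$network, ch$rank), ], 10))
cat("wrote results/chapter_frequencies.tsv and per-sex rank trajectories\n")
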