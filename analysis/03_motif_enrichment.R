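#!/usr/bin/env Rscript
# Step 3: motif census and enrichment, sizes 3-6, against 1000
# degree-preserving shuffled networks (z > 2 and empirical p < 0.005), plus
# the per-node annotation report. Everything lands under results/reports/.

suppressPackageStartupMessages(library(pathmotif))

model <- read_celldesigner_sbml("results/dc_synthetic_map.xml")
res <- run_pipeline(model, sizes = 3:6,
                    config = randomization_config(n_random = 1000, seed = 1))

paths <- write_reports(res$census, res$enrichment, res$annotations,
                       "results/reports")
jsonlite::write_json(res$manifest, "results/reports/run_manifest.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Analysed %d-node / %d-edge graph.\n",
            n_nodes(res$network), n_edges(res$network)))
for (k in 3:6) {
  ek <- res$enrichment[res$enrichment$size == k, ]
  cat(sprintf("size %d: %d classes observed, %d significant\n",
              k, nrow(ek), sum(ek$significant)))
}
sig <- res$enrichment[res$enrichment$significant, ]
if (nrow(sig)) {
  cat("Top over-represented classes:\n")
  top <- head(sig[order(-sig$z_score), ], 5)
  print(as.data.frame(top[, c("size", "family", "count_real", "mean_random",
                              "z_score", "p_value")]), row.names = FALSE)
} else {
  cat("No class exceeded the significance criterion on this synthetic map.\n")
}
cat("Reports written to", paste(paths, collapse = ", "), "\n")
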