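#!/usr/bin/env Rscript

# Simulate the study inputs: a 9-sample developmental count matrix with four
# stage-associated co-expression modules (egg / third-instar larva / pupa /
# adult), and a 338-node interaction network with 30 regulatory genes
# planted in five dense clusters.  Writes the TSV inputs the later steps
# consume plus the planted truth for evaluation.

suppressPackageStartupMessages(library(coexreg))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 1L)
print(cfg)
sim <- generate_count_matrix(cfg)
write_matrix_tsv(sim$counts, file.path(outdir, "counts.tsv"))
utils::write.table(sim$design$design, file.path(outdir, "design.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

net_cfg <- synthetic_network_config(seed = 1L)
net <- generate_interaction_network(net_cfg)
write_edges(net$edges, file.path(outdir, "network.tsv"))
write_labels(net$regulatory, file.path(outdir, "regulatory_labels.txt"))

truth <- list(
  module = as.list(sim$truth$module),
  module_stage = as.list(sim$truth$module_stage),
  planted_clusters = net$truth$clusters,
  regulatory_in_clusters = net$truth$regulatory_in_clusters)
jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d genes x %d samples; network: %d nodes, %d edges, %d regulatory\n",
            nrow(sim$counts), ncol(sim$counts),
            length(net$nodes), nrow(net$edges), length(net$regulatory)))
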