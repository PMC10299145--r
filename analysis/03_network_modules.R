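#!/usr/bin/env Rscript

# Build the signed weighted co-expression network, detect and refine
# modules, correlate eigengenes with developmental stages, and extract hub
# genes (kME >= 0.80).

suppressPackageStartupMessages(library(coexreg))

expr <- as.matrix(read.delim("results/expression_selected.tsv", row.names = 1,
                             check.names = FALSE))
design <- read_design("results/data/design.tsv")

st <- pick_soft_threshold(expr)
print(st)
write.table(st$table, "results/soft_threshold.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

adj <- signed_adjacency(expr, st$power)
tom <- tom_similarity(adj)
assignment <- detect_modules(1 - tom, min_module_size = 30)
labels <- merge_close_modules(expr, assignment, merge_cut_height = 0.25)
labels <- prune_modules(expr, labels)
print(table(labels))

me <- module_eigengenes(expr, labels)
mtc <- module_trait_correlation(me, design$indicator)
print(mtc)
key <- select_key_modules(mtc, "larva3", alpha = 0.05)
cat("modules positively associated with the larval stage:",
    if (length(key)) paste(key, collapse = ", ") else "(none)", "\n")

kme <- module_membership(expr, me)
hubs <- select_hub_genes(kme, labels, threshold = 0.80)
cat("hub genes per module:",
    paste(names(hubs), lengths(hubs), sep = "=", collapse = ", "), "\n")

write_matrix_tsv(round(me, 6), "results/eigengenes.tsv")
write.table(data.frame(gene = names(labels), module = unname(labels)),
            "results/modules.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(module = rownames(mtc$r), round(mtc$r, 4),
                       check.names = FALSE),
            "results/module_trait_r.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_labels(unique(unlist(hubs)), "results/hub_genes.txt")
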