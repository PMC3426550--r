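#!/usr/bin/env Rscript
# Stage 3: aggregate replicates, test control vs query, score interactions.
#
# Per strain and screen group: one-pass >2 SD outlier rejection, Welch test
# of control vs query colony sizes, fitness relative to the border-control
# median, epsilon under the multiplicative model, and stringent hit calling
# (>= 40 px, p <= 0.01, epsilon <= -0.12 or >= 0.2).

suppressPackageStartupMessages({library(data.table); library(sgaepsilon)})
bundle <- read_screen_bundle("results/sim/layout.tsv",
                             "results/sim/colonies_normalized.tsv")
truth <- fread("results/sim/sim_truth.tsv")
dubious <- unique(truth[dubious == TRUE, strain_id])

sc <- score_screens(bundle$colonies, bundle$layout, sga_thresholds(),
                    dubious_strains = dubious)
write_results(sc$records, "results/interactions.tsv")
fwrite(sc$query_fitness, "results/query_fitness.tsv", sep = "\t")
fwrite(clustergram_table(sc$records), "results/clustergram.tsv", sep = "\t")

message(sprintf("query fitness: %s",
                paste(sprintf("%s=%.3f", sc$query_fitness$query,
                              sc$query_fitness$Wq), collapse = ", ")))
hits <- sc$records[stringent_flag == TRUE]
message(sprintf("%d stringent interactions over %d scored strain x query pairs",
                nrow(hits), nrow(sc$records)))
verified <- hits[dubious_flag == FALSE, uniqueN(array_gene)]
message(sprintf("%d unique genes in the verified stringent set (dubious ORFs removed)",
                verified))
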