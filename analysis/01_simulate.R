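#!/usr/bin/env Rscript
# Stage 1: generate a full-design synthetic screen set.
#
# Design: 4292 array strains in duplicate on 7 x 1536-colony plates with a
# two-colony border-control perimeter; 5 replicate control screens and 3
# replicate screens for each of 3 deletion queries (relative fitness 0.95,
# 0.96 and 0.89).  Interactions are planted so downstream stages have
# structure to find: 120 aggravating strains (epsilon -0.30) and 80
# alleviating strains (epsilon +0.30), each planted in 1-3 of the queries so
# the per-query hit sets overlap but do not coincide.

suppressPackageStartupMessages({library(data.table); library(sgaepsilon)})
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
seed <- 42L

queries <- c("scs3d", "yft2d", "scs3d_yft2d")
set.seed(seed)
agg_ids <- sprintf("STR%04d", 1:120)
all_ids <- sprintf("STR%04d", 201:280)
pick <- function(ids, eps) rbindlist(lapply(ids, function(s) {
  qs <- sample(queries, sample(1:3, 1))
  data.table(strain_id = s, query_name = qs, epsilon = eps)
}))
planted <- rbind(pick(agg_ids, -0.30), pick(all_ids, +0.30))

# the dubious-ORF strains mirror their neighbor's effect by construction, so
# planting effects on the neighbors gives the reproducibility QC real signal
nb <- sga_sim_config(seed = seed)$dubious_pairs$neighbor_id
nb_eff <- CJ(strain_id = nb, query_name = queries)[
  , epsilon := rep(pmax(pmin(rnorm(length(nb), 0, 0.25), 0.6), -0.6),
                   each = length(queries))]
planted <- rbind(planted, nb_eff)

cfg <- sga_sim_config(planted_effects = planted, seed = seed)
sim <- simulate_screen_set(cfg)

write_layout(sim$layout, "results/sim/layout.tsv")
write_colony_table(sim$colonies, "results/sim/colonies.tsv")
write_truth(sim$truth, "results/sim/sim")

message(sprintf("simulated %d colonies on %d plate instances (%d screens)",
                nrow(sim$colonies),
                nrow(unique(sim$colonies[, .(screen_id, plate_id)])),
                length(unique(sim$colonies$screen_id))))
message(sprintf("planted %d aggravating and %d alleviating strains (%d strain x query effects)",
                length(agg_ids), length(all_ids), nrow(planted)))
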