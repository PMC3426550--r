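#!/usr/bin/env Rscript
# Stage 4: distributional and reproducibility QC.
#
# Gaussian fit of the binned epsilon distribution (bin 0.025), cross-query
# overlap of relaxed-criteria hit sets (pixel + p gates only), recovery of
# the planted interactions, and the dubious-ORF neighbor correlation.

suppressPackageStartupMessages({library(data.table); library(sgaepsilon)})
rec <- read_results("results/interactions.tsv")
truth <- fread("results/sim/sim_truth.tsv")

gfit <- fit_epsilon_gaussian(rec[dead_flag == FALSE & dubious_flag == FALSE, epsilon])
fwrite(gfit$histogram, "results/epsilon_histogram.tsv", sep = "\t")
message(sprintf("epsilon fit: center %.4f +/- %.1e, sigma %.3f, adjusted r2 %.3f",
                gfit$center, gfit$center_se, gfit$sigma, gfit$adjusted_r2))

ovl <- query_overlap(relaxed_hit_sets(rec))
fwrite(ovl$regions, "results/overlap_regions.tsv", sep = "\t")
message(sprintf("relaxed-criteria hits per query: %s; %d genes shared in >= 2 screens",
                paste(names(ovl$per_query), ovl$per_query, sep = "=", collapse = ", "),
                ovl$shared_ge[["ge2"]]))

## planted-effect recovery at the stringent criteria (strain level);
## restricted to effects large enough to clear the epsilon cutoffs
planted <- truth[abs(true_epsilon) >= 0.25 & dubious == FALSE]
per_strain <- rec[array_gene %in% planted$strain_id][
  truth, true_epsilon := i.true_epsilon,
  on = c(array_gene = "strain_id", query = "query_name")][
  , .(hit = any(stringent_flag & sign(epsilon) == sign(true_epsilon) &
                  true_epsilon != 0)), by = array_gene]
message(sprintf("stringent recovery of planted strains: %.0f%% (%d / %d)",
                100 * mean(per_strain$hit), sum(per_strain$hit), nrow(per_strain)))

## dubious ORFs mirror their neighbors
dub <- unique(truth[dubious == TRUE, .(strain_id, neighbor_id)])
qs <- unique(rec$query)
idx <- CJ(i = seq_len(nrow(dub)), query = qs, sorted = FALSE)
e_db <- rec[data.table(array_gene = dub$strain_id[idx$i], query = idx$query),
            on = c("array_gene", "query"), epsilon]
e_nb <- rec[data.table(array_gene = dub$neighbor_id[idx$i], query = idx$query),
            on = c("array_gene", "query"), epsilon]
r <- correlate_epsilon_vectors(e_db, e_nb, "pearson")
message(sprintf("dubious-ORF vs neighbor epsilon correlation: Pearson r = %.2f over %d values",
                r, length(e_db)))

fwrite(data.table(metric = c("fit_center", "fit_center_se", "fit_sigma",
                             "fit_adjusted_r2", "shared_ge2",
                             "planted_recovery", "dubious_neighbor_r"),
                  value = c(gfit$center, gfit$center_se, gfit$sigma,
                            gfit$adjusted_r2, ovl$shared_ge[["ge2"]],
                            mean(per_strain$hit), r)),
       "results/qc_report.tsv", sep = "\t")
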