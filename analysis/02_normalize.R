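#!/usr/bin/env Rscript
# Stage 2: plate-level normalization and replicate-CV quality control.
#
# Every plate is rescaled so its inner-perimeter border-control median maps
# onto the experimental median (the median of all 98 plate medians), then
# per-strain replicate CVs are summarized per screen group.

suppressPackageStartupMessages({library(data.table); library(sgaepsilon)})
bundle <- read_screen_bundle("results/sim/layout.tsv", "results/sim/colonies.tsv")

nr <- normalize_screens(bundle$colonies, bundle$layout)
write_colony_table(nr$colonies, "results/sim/colonies_normalized.tsv")
fwrite(nr$stats$plate_medians, "results/sim/plate_medians.tsv", sep = "\t")

cv <- cv_summary(nr$colonies, bundle$layout)
fwrite(cv$per_strain, "results/sim/cv_per_strain.tsv", sep = "\t")
fwrite(data.table(mean_cv = cv$mean_cv, sd_cv = cv$sd_cv,
                  fraction_below = cv$fraction_below,
                  cv_threshold = cv$cv_threshold),
       "results/sim/cv_summary.tsv", sep = "\t")

message(sprintf("experimental median: %.1f px over %d plates",
                nr$stats$experimental_median, nrow(nr$stats$plate_medians)))
message(sprintf("replicate CV %.1f%% +/- %.1f%%; %.1f%% of strain x group pairs below %.1f%%",
                100 * cv$mean_cv, 100 * cv$sd_cv, 100 * cv$fraction_below,
                100 * cv$cv_threshold))
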