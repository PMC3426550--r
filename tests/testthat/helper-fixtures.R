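## small simulation configs used across test files
library(data.table)

tiny_config <- function(n_strains = 60, seed = 7, ...) {
  sga_sim_config(n_array_strains = n_strains, n_dubious_pairs = 0L,
                 seed = seed, ...)
}

noiseless_config <- function(n_strains = 20, seed = 1, ...) {
  sga_sim_config(n_array_strains = n_strains, noise_cv = 0,
                 plate_effect_sd = 0, outlier_rate = 0,
                 n_dubious_pairs = 0L, seed = seed, ...)
}

## a minimal two-plate bundle with hand-set raw sizes, for normalization
## arithmetic: plate medians 200 (P1) and 486 (P2) -> experimental median 343
two_plate_bundle <- function() {
  lay <- make_layout(4, n_rows = 6, n_cols = 6)  # 2 plates x 4 interior positions
  colonies <- data.table::as.data.table(lay$positions)
  data.table::setnames(colonies, "plate", "plate_id")
  colonies[, `:=`(screen_id = "control_r1", query_name = "control",
                  replicate = 1L)]
  colonies[, raw_size := data.table::fifelse(plate_id == "P1", 200, 486)]
  colonies[plate_id == "P1" & ring == "interior", raw_size := 400]
  colonies[plate_id == "P2" & ring == "interior", raw_size := 486]
  colonies[, ring := NULL]
  list(layout = lay, colonies = colonies)
}
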