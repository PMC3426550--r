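#' Per-query hit sets at the relaxed (pixel + p) criteria
#'
#' Membership for the cross-screen overlap comparison uses only the
#' pixel-difference and p-value gates — the epsilon cutoffs are applied
#' afterwards, when the stringent set is compiled.  Dead strains are
#' excluded; dubious ORFs are kept (they are part of the reproducibility
#' story).
#'
#' @param records interaction records from [score_screens()].
#' @param thresholds an [sga_thresholds()] object.
#' @return named list of character vectors, one per query.
#' @export
relaxed_hit_sets <- function(records, thresholds = sga_thresholds()) {
  rec <- data.table::as.data.table(records)
  rec <- rec[dead_flag == FALSE & abs(delta_pixels) >= thresholds$delta_px &
               p_value <= thresholds$p_max]
  split(rec$array_gene, rec$query)
}

#' Run the whole screen-analysis pipeline on a simulated screen set
#'
#' Chains the stages: simulate, normalize to the inner-perimeter control
#' medians, summarize replicate CVs, aggregate/score every query against the
#' control screens, fit the epsilon distribution, and compute the
#' relaxed-criteria overlap across queries.
#'
#' @param config an [sga_sim_config()].
#' @param thresholds an [sga_thresholds()].
#' @param gaussian_bin histogram bin width for the epsilon fit.
#' @return list with `sim`, `normalized` (colonies + stats), `cv`,
#'   `scores`, `gaussian_fit` (on non-dead, non-dubious epsilon scores) and
#'   `overlap`.
#' @export
run_sga_pipeline <- function(config = sga_sim_config(),
                             thresholds = sga_thresholds(),
                             gaussian_bin = 0.025) {
  sim <- simulate_screen_set(config)
  norm <- normalize_screens(sim$colonies, sim$layout)
  cv <- cv_summary(norm$colonies, sim$layout)
  dub <- sim$truth$strains[dubious == TRUE, strain_id]
  scores <- score_screens(norm$colonies, sim$layout, thresholds,
                          dubious_strains = dub)
  eps <- scores$records[dead_flag == FALSE & dubious_flag == FALSE, epsilon]
  gfit <- fit_epsilon_gaussian(eps, bin_size = gaussian_bin)
  ovl <- if (nrow(scores$query_fitness) >= 2L)
    query_overlap(relaxed_hit_sets(scores$records, thresholds)) else NULL
  list(sim = sim, normalized = norm, cv = cv, scores = scores,
       gaussian_fit = gfit, overlap = ovl)
}

#' Parameter-recovery experiment with planted interactions
#'
#' Plants aggravating (`eps_neg`) effects in `n_planted` strains and
#' alleviating (`eps_pos`) effects in another `n_planted` strains — for every
#' query, since a gene's hit status is compiled across screens — runs the
#' pipeline, and measures, per sign: the strain-level stringent recall (a
#' planted strain counts as recovered when it passes the stringent criteria
#' with the correct epsilon sign in at least one query screen) and the mean
#' bias of the epsilon estimate over all planted (strain, query) pairs.
#'
#' @param config base [sga_sim_config()]; planted effects are added to it.
#' @param thresholds an [sga_thresholds()].
#' @param n_planted strains per sign.
#' @param eps_neg,eps_pos planted epsilon values.
#' @param replicate_scale multiply the number of control and query replicate
#'   screens (use 10 for a tight bias measurement).
#' @return list with `recall_neg`, `recall_pos`, `bias` (mean estimated
#'   minus true epsilon over planted pairs), `records` (planted strains'
#'   interaction records joined to the truth) and `pipeline` result.
#' @export
recovery_experiment <- function(config = sga_sim_config(),
                                thresholds = sga_thresholds(),
                                n_planted = 100L, eps_neg = -0.30,
                                eps_pos = 0.30, replicate_scale = 1L) {
  if (2L * n_planted + 2L * nrow(config$dubious_pairs) > config$n_array_strains)
    stop("not enough strains to plant effects outside the dubious tail")
  neg_ids <- config$strain_ids[seq_len(n_planted)]
  pos_ids <- config$strain_ids[n_planted + seq_len(n_planted)]
  planted <- data.table::rbindlist(lapply(names(config$queries), function(q)
    data.table::data.table(strain_id = c(neg_ids, pos_ids), query_name = q,
                           epsilon = rep(c(eps_neg, eps_pos), each = n_planted))))
  cfg <- sga_sim_config(
    n_array_strains = config$n_array_strains,
    n_control_screens = config$n_control_screens * replicate_scale,
    queries = config$queries,
    n_replicates_per_query = config$n_replicates_per_query * replicate_scale,
    baseline_colony_size = config$baseline_colony_size,
    noise_cv = config$noise_cv, plate_effect_sd = config$plate_effect_sd,
    planted_effects = planted, outlier_rate = config$outlier_rate,
    outlier_multiplier = config$outlier_multiplier,
    n_dubious_pairs = nrow(config$dubious_pairs), seed = config$seed)

  res <- run_sga_pipeline(cfg, thresholds)
  rec <- res$scores$records[array_gene %in% c(neg_ids, pos_ids)]
  rec[res$sim$truth$effects, true_epsilon := i.true_epsilon,
      on = c(array_gene = "strain_id", query = "query_name")]

  recovered <- rec[, .(hit = any(stringent_flag & sign(epsilon) == sign(true_epsilon))),
                   by = array_gene]
  recall_neg <- recovered[array_gene %in% neg_ids, mean(hit)]
  recall_pos <- recovered[array_gene %in% pos_ids, mean(hit)]
  bias <- rec[, mean(epsilon - true_epsilon)]
  list(recall_neg = recall_neg, recall_pos = recall_pos, bias = bias,
       records = rec, pipeline = res)
}
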