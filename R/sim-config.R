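#' Configuration for the synthetic screen generator
#'
#' Captures the screen design and noise model used by [simulate_screen_set()].
#' Defaults reproduce the study design the pipeline targets: 4292 array
#' strains in duplicate on 1536-colony plates, five replicate control screens
#' of a neutral query, and three replicate screens for each of three deletion
#' queries whose relative fitnesses are close to wild type.
#'
#' The per-colony noise model is multiplicative log-normal with coefficient
#' of variation `noise_cv` (colony areas are positive and right-skewed); each
#' (screen, plate) additionally receives one multiplicative log-normal plate
#' effect with log-scale sd `plate_effect_sd`, which is what the
#' inner-perimeter normalization must remove.  Both log-normals are
#' mean-corrected so expected colony size equals its target exactly.
#'
#' @param n_array_strains number of distinct array strains.
#' @param n_control_screens replicate screens of the neutral control query.
#' @param queries named numeric vector of query relative fitness values
#'   (names are query identifiers).
#' @param n_replicates_per_query replicate screens per query.
#' @param baseline_colony_size expected wild-type colony area in pixels.
#' @param noise_cv per-colony coefficient of variation.
#' @param plate_effect_sd log-scale sd of the per-(screen, plate)
#'   multiplicative effect.
#' @param planted_effects optional `data.frame` with columns `strain_id`,
#'   `query_name`, `epsilon`: true genetic-interaction effects to plant.
#' @param planted_fitness optional named numeric vector of array single-mutant
#'   fitness values (default 1 for every strain).
#' @param outlier_rate fraction of colonies replaced by gross outliers.
#' @param outlier_multiplier fold-change applied (multiplied or divided, at
#'   random) to outlier colonies.
#' @param n_dubious_pairs number of (dubious ORF, neighbor) strain pairs to
#'   flag; the last `2 * n_dubious_pairs` strains are paired consecutively and
#'   a dubious strain inherits its neighbor's planted effect unless one is
#'   planted for it explicitly.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return An object of class `sga_sim_config` (a validated list).
#' @export
sga_sim_config <- function(n_array_strains = 4292L,
                           n_control_screens = 5L,
                           queries = c("scs3d" = 0.95, "yft2d" = 0.96,
                                       "scs3d_yft2d" = 0.89),
                           n_replicates_per_query = 3L,
                           baseline_colony_size = 343,
                           noise_cv = 0.12,
                           plate_effect_sd = 0.10,
                           planted_effects = NULL,
                           planted_fitness = NULL,
                           outlier_rate = 0.01,
                           outlier_multiplier = 3,
                           n_dubious_pairs = 40L,
                           seed = 1L) {
  if (length(queries) < 1L || is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be a non-empty named numeric vector of relative fitness values")
  if (any(queries < 0)) stop("query fitness values must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (plate_effect_sd < 0) stop("plate_effect_sd must be >= 0")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must lie in [0, 1]")
  if (baseline_colony_size <= 0) stop("baseline_colony_size must be > 0")
  n_array_strains <- as.integer(n_array_strains)
  strain_ids <- sprintf("STR%04d", seq_len(n_array_strains))

  wx <- stats::setNames(rep(1, n_array_strains), strain_ids)
  if (!is.null(planted_fitness)) {
    unknown <- setdiff(names(planted_fitness), strain_ids)
    if (length(unknown))
      stop("planted_fitness names unknown strain(s): ", paste(utils::head(unknown, 3), collapse = ", "))
    if (any(planted_fitness < 0)) stop("planted fitness values must be >= 0")
    wx[names(planted_fitness)] <- planted_fitness
  }

  if (!is.null(planted_effects)) {
    planted_effects <- data.table::as.data.table(planted_effects)
    need <- c("strain_id", "query_name", "epsilon")
    if (!all(need %in% names(planted_effects)))
      stop("planted_effects needs columns strain_id, query_name, epsilon")
    unknown <- setdiff(planted_effects$strain_id, strain_ids)
    if (length(unknown))
      stop("planted_effects references unknown strain(s): ", paste(utils::head(unknown, 3), collapse = ", "))
    unknown_q <- setdiff(planted_effects$query_name, names(queries))
    if (length(unknown_q))
      stop("planted_effects references unknown query(s): ", paste(unknown_q, collapse = ", "))
  }

  n_dubious_pairs <- as.integer(n_dubious_pairs)
  if (2L * n_dubious_pairs > n_array_strains)
    stop("n_dubious_pairs too large for the number of array strains")
  dubious <- if (n_dubious_pairs > 0L) {
    tail_ids <- strain_ids[(n_array_strains - 2L * n_dubious_pairs + 1L):n_array_strains]
    data.table::data.table(strain_id  = tail_ids[seq(1L, length(tail_ids), by = 2L)],
                           neighbor_id = tail_ids[seq(2L, length(tail_ids), by = 2L)])
  } else data.table::data.table(strain_id = character(), neighbor_id = character())

  structure(list(n_array_strains = n_array_strains,
                 strain_ids = strain_ids,
                 n_control_screens = as.integer(n_control_screens),
                 queries = queries,
                 n_replicates_per_query = as.integer(n_replicates_per_query),
                 baseline_colony_size = baseline_colony_size,
                 noise_cv = noise_cv,
                 plate_effect_sd = plate_effect_sd,
                 planted_effects = planted_effects,
                 planted_fitness = wx,
                 outlier_rate = outlier_rate,
                 outlier_multiplier = outlier_multiplier,
                 dubious_pairs = dubious,
                 seed = as.integer(seed)),
            class = "sga_sim_config")
}
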