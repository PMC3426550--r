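#' Simulate a complete set of control and query colony-array screens
#'
#' Generates one colony record for every position of every plate of every
#' replicate screen.  Control screens cross the array with a neutral query:
#' the expected size of an array strain's colony is
#' `baseline * Wx` (its single-mutant fitness) and of a border-control colony
#' `baseline`.  Query screens cross the array with a deletion query of
#' relative fitness `Wq`: array-strain colonies have expected size
#' `baseline * (Wx * Wq + epsilon)` under the multiplicative model with a
#' planted interaction `epsilon` (0 unless planted), and every border-control
#' position carries the query's fitness, `baseline * Wq` — which is exactly
#' how query fitness is later re-measured from inner-perimeter medians.
#'
#' Noise: per-colony multiplicative log-normal with CV `noise_cv`; one
#' multiplicative log-normal plate effect per (screen, plate); a fraction
#' `outlier_rate` of colonies multiplied or divided by `outlier_multiplier`.
#'
#' @param config an [sga_sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{layout}{the [make_layout()] result used for every screen,}
#'     \item{colonies}{a `data.table` with columns `screen_id`, `query_name`
#'       (`"control"` for control screens), `replicate`, `plate_id`, `row`,
#'       `col`, `strain_id`, `raw_size`,}
#'     \item{truth}{a list with `effects` (per strain x query: `Wx`, `Wq`,
#'       `true_epsilon`, `expected_size`), `strains` (per-strain `Wx`,
#'       dubious flag and neighbor), `queries`, `outliers` (coordinates and
#'       factors of injected outliers) and `seed`.}
#'   }
#' @examples
#' cfg <- sga_sim_config(n_array_strains = 20, seed = 7)
#' sim <- simulate_screen_set(cfg)
#' nrow(sim$colonies)  # positions x plates x screens
#' @export
simulate_screen_set <- function(config) {
  stopifnot(inherits(config, "sga_sim_config"))
  layout <- make_layout(config$n_array_strains,
                        control_strain_id = "his3d::kanMX")

  queries <- config$queries
  wx <- config$planted_fitness

  ## planted effects, with dubious strains mirroring their neighbor
  eff <- data.table::CJ(strain_id = config$strain_ids, query_name = names(queries))
  eff[, `:=`(Wx = wx[strain_id], Wq = queries[query_name], true_epsilon = 0)]
  if (!is.null(config$planted_effects)) {
    pe <- config$planted_effects
    eff[pe, true_epsilon := i.epsilon, on = c("strain_id", "query_name")]
  }
  if (nrow(config$dubious_pairs)) {
    dp <- config$dubious_pairs
    explicit <- if (!is.null(config$planted_effects))
      config$planted_effects[, paste(strain_id, query_name)] else character()
    nb <- eff[dp, on = c(strain_id = "neighbor_id"),
              .(dubious = i.strain_id, query_name, true_epsilon)]
    nb <- nb[!paste(dubious, query_name) %in% explicit]
    eff[nb, true_epsilon := i.true_epsilon,
        on = c(strain_id = "dubious", "query_name")]
  }
  eff[, expected_fitness := Wx * Wq + true_epsilon]
  if (any(eff$expected_fitness < 0))
    stop("planted effect yields negative expected fitness for ",
         eff[expected_fitness < 0][1L, paste(strain_id, "/", query_name)])
  eff[, expected_size := config$baseline_colony_size * expected_fitness]

  ## screen roster: control replicates, then each query's replicates
  screens <- data.table::rbindlist(list(
    data.table::data.table(query_name = "control",
                           replicate = seq_len(config$n_control_screens),
                           Wq = 1),
    data.table::CJ(query_name = names(queries),
                   replicate = seq_len(config$n_replicates_per_query))[
                     , Wq := queries[query_name]][]
  ), fill = TRUE)
  screens[, screen_id := paste0(query_name, "_r", replicate)]

  pos <- layout$positions
  colonies <- screens[, {
    dt <- data.table::copy(pos)
    dt[, `:=`(screen_id = screen_id, query_name = query_name, replicate = replicate)]
    dt
  }, by = seq_len(nrow(screens))][, seq_len := NULL]
  data.table::setnames(colonies, "plate", "plate_id")

  ## expected size per colony
  base <- config$baseline_colony_size
  colonies[, expected := base]                                   # control strain, control screen
  colonies[query_name != "control" & strain_id == layout$control_strain_id,
           expected := base * queries[query_name]]
  is_array <- colonies$strain_id != layout$control_strain_id
  colonies[eff, on = c("strain_id", "query_name"), expected := i.expected_size]
  colonies[is_array & query_name == "control", expected := base * wx[strain_id]]

  ## draw sizes (restore RNG state afterwards)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- nrow(colonies)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)

  plate_key <- colonies[, .N, by = .(screen_id, plate_id)][, N := NULL]
  ps <- config$plate_effect_sd
  plate_key[, plate_factor := if (ps > 0)
    stats::rlnorm(.N, -ps^2 / 2, ps) else 1]
  colonies[plate_key, plate_factor := i.plate_factor, on = c("screen_id", "plate_id")]

  colonies[, raw_size := expected * plate_factor * noise]

  ## gross outliers
  outliers <- data.table::data.table(screen_id = character(), plate_id = character(),
                                     row = integer(), col = integer(), factor = numeric())
  if (config$outlier_rate > 0) {
    hit <- which(stats::runif(n) < config$outlier_rate)
    if (length(hit)) {
      fac <- ifelse(stats::runif(length(hit)) < 0.5,
                    config$outlier_multiplier, 1 / config$outlier_multiplier)
      colonies[hit, raw_size := raw_size * fac]
      outliers <- colonies[hit, .(screen_id, plate_id, row, col)][, factor := fac][]
      data.table::setorder(outliers, screen_id, plate_id, row, col)
    }
  }

  colonies <- colonies[, .(screen_id, query_name, replicate, plate_id, row, col,
                           strain_id, raw_size)]
  data.table::setorder(colonies, screen_id, plate_id, row, col)

  strains <- data.table::data.table(strain_id = config$strain_ids,
                                    Wx = wx[config$strain_ids],
                                    dubious = FALSE, neighbor_id = NA_character_)
  if (nrow(config$dubious_pairs)) {
    strains[config$dubious_pairs, `:=`(dubious = TRUE, neighbor_id = i.neighbor_id),
            on = "strain_id"]
  }

  truth <- list(effects = eff[, .(strain_id, query_name, Wx, Wq, true_epsilon, expected_size)],
                strains = strains,
                queries = data.table::data.table(query_name = names(queries), Wq = queries),
                outliers = outliers,
                seed = config$seed)
  list(layout = layout, colonies = colonies, truth = truth)
}
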