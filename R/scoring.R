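#' Aggregate a strain's replicate colonies with one-pass outlier rejection
#'
#' Computes the mean and sample standard deviation of the sizes, removes
#' values more than 2 standard deviations from the mean, and recomputes the
#' mean and standard deviation once on the survivors.  The filter is applied
#' a single time, not iterated.  Values at the mean always survive, so the
#' kept set is never empty.
#'
#' @param sizes numeric vector of (normalized) colony sizes, length >= 2.
#' @return list with `n_raw`, `n_kept`, `mean`, `sd`, `cv`.
#' @examples
#' aggregate_strain(c(100, 100, 100, 100, 100, 200))  # 200 rejected
#' @export
aggregate_strain <- function(sizes) {
  if (length(sizes) < 2L)
    stop("insufficient replicates: need >= 2 colony sizes")
  m0 <- mean(sizes); s0 <- stats::sd(sizes)
  keep <- if (s0 > 0) abs(sizes - m0) <= 2 * s0 else rep(TRUE, length(sizes))
  kept <- sizes[keep]
  list(n_raw = length(sizes), n_kept = length(kept),
       mean = mean(kept), sd = if (length(kept) > 1L) stats::sd(kept) else 0,
       cv = if (mean(kept) > 0 && length(kept) > 1L) stats::sd(kept) / mean(kept) else NA_real_)
}

## vectorized two-pass filter over a grouped colony table
.aggregate_groups <- function(dt, value = "normalized_size", by) {
  first <- dt[, .(.m = mean(get(value)), .s = stats::sd(get(value))), by = by]
  dt2 <- dt[first, on = by]
  dt2 <- dt2[.s == 0 | abs(get(value) - .m) <= 2 * .s]
  out <- dt2[, .(n_kept = .N, mean = mean(get(value)),
                 sd = if (.N > 1L) stats::sd(get(value)) else 0), by = by]
  raw <- dt[, .(n_raw = .N), by = by]
  out <- out[raw, on = by]
  out[, cv := data.table::fifelse(mean > 0 & n_kept > 1L, sd / mean, NA_real_)]
  out
}

#' Welch two-sample t-test of colony sizes
#'
#' Two-tailed unequal-variance t-test with Welch–Satterthwaite degrees of
#' freedom, computed from the group summary statistics.  Degenerate inputs
#' follow a documented convention: if both groups have zero variance the
#' p-value is 1 when the means are equal and 0 when they differ.
#'
#' @param control_sizes,query_sizes numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(control_sizes, query_sizes) {
  if (length(control_sizes) < 2L || length(query_sizes) < 2L)
    stop("insufficient replicates: need >= 2 sizes per group")
  res <- .welch_stats(mean(control_sizes), stats::sd(control_sizes), length(control_sizes),
                      mean(query_sizes), stats::sd(query_sizes), length(query_sizes))
  as.list(res)
}

## vectorized Welch test from summary statistics
.welch_stats <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen, na.rm = TRUE)) {
    eq <- degen & (m1 == m2)
    t[degen] <- 0; df[degen] <- NA_real_
    p[degen & eq] <- 1; p[degen & !eq] <- 0
    t[degen & !eq] <- Inf * sign((m1 - m2)[degen & !eq])
  }
  data.table::data.table(t = t, df = df, p = p)
}

#' Fitness of a strain relative to the border-control median
#'
#' `W = strain_mean / control_his3_median`, the ratio of a strain's mean
#' colony size to the median border-control colony size from the control
#' screens.  The wild-type reference has fitness 1 by construction.
#'
#' @param strain_mean mean (normalized) colony size in pixels.
#' @param control_his3_median median border-control size in pixels (> 0).
#' @return fitness W (dimensionless, >= 0).
#' @export
fitness_of <- function(strain_mean, control_his3_median) {
  if (any(control_his3_median <= 0)) stop("control median must be > 0")
  strain_mean / control_his3_median
}

#' Genetic-interaction score under the multiplicative model
#'
#' `epsilon = W_obs - Wx * Wq`: the deviation of the observed double- (or
#' triple-) mutant fitness from the product of the component fitnesses.  For
#' digenic scoring `Wq` is the single-mutant query fitness; for trigenic
#' scoring it is the double-mutant query fitness — the formula is the same.
#' Negative scores are aggravating, positive scores alleviating.
#'
#' @param W_obs observed combined-mutant fitness.
#' @param Wx array single-mutant fitness.
#' @param Wq query fitness.
#' @return epsilon (dimensionless).
#' @examples
#' epsilon_score(0.78, 0.48, 0.89)  # strong alleviating interaction
#' @export
epsilon_score <- function(W_obs, Wx, Wq) {
  if (any(c(W_obs, Wx, Wq) < 0)) stop("fitness values must be >= 0")
  W_obs - Wx * Wq
}

#' Hit-calling thresholds
#'
#' The stringent criteria: at least `delta_px` pixels mean colony-size
#' difference between control and query screens, Welch p-value at most
#' `p_max`, and epsilon at or beyond `eps_lo` (aggravating) or `eps_hi`
#' (alleviating).  Values exactly at a threshold are included.
#' `dead_fitness_floor` flags array strains whose control-screen fitness is
#' below the floor; they are excluded from hit calling.
#'
#' @param delta_px pixel-difference threshold (default 40).
#' @param p_max p-value threshold (default 0.01).
#' @param eps_lo,eps_hi epsilon cutoffs (defaults -0.12 and 0.2).
#' @param dead_fitness_floor minimum control fitness (default 0.05).
#' @export
sga_thresholds <- function(delta_px = 40, p_max = 0.01, eps_lo = -0.12,
                           eps_hi = 0.2, dead_fitness_floor = 0.05) {
  stopifnot(delta_px >= 0, p_max > 0, p_max <= 1, eps_lo < 0, eps_hi > 0)
  structure(list(delta_px = delta_px, p_max = p_max, eps_lo = eps_lo,
                 eps_hi = eps_hi, dead_fitness_floor = dead_fitness_floor),
            class = "sga_thresholds")
}

#' Classify interactions and apply the stringent hit criteria
#'
#' Class is `"aggravating"` if epsilon is at or below `eps_lo`,
#' `"alleviating"` if at or above `eps_hi`, `"none"` otherwise.  The
#' stringent flag requires all three criteria jointly: an absolute mean
#' colony-size difference of at least `delta_px` pixels, a Welch p-value of
#' at most `p_max`, and a non-`"none"` class.  Records exactly at a
#' threshold are included.
#'
#' @param delta_pixels signed mean size difference (control minus query).
#' @param p_value Welch two-tailed p-value.
#' @param epsilon genetic-interaction score.
#' @param thresholds an [sga_thresholds()] object.
#' @return list of vectors `class` and `stringent_flag`.
#' @examples
#' classify_interaction(50, 0.005, -0.15)  # aggravating, stringent
#' classify_interaction(39, 0.001, -0.50)  # pixel rule fails
#' @export
classify_interaction <- function(delta_pixels, p_value, epsilon,
                                 thresholds = sga_thresholds()) {
  th <- thresholds
  class <- data.table::fifelse(epsilon <= th$eps_lo, "aggravating",
           data.table::fifelse(epsilon >= th$eps_hi, "alleviating", "none"))
  stringent <- abs(delta_pixels) >= th$delta_px & p_value <= th$p_max &
    class != "none"
  list(class = class, stringent_flag = stringent)
}

#' Score one query screen against the control screens
#'
#' Joins per-strain aggregated statistics from the control and query screen
#' groups, computes the signed pixel difference (control minus query), the
#' Welch p-value, fitness values and epsilon, classifies each interaction
#' (aggravating / alleviating / none by the epsilon cutoffs) and flags
#' stringent hits meeting all three criteria.  Strains marked dubious are
#' scored and retained (for reproducibility QC) but flagged so they can be
#' excluded from the verified hit set; strains below the dead-fitness floor
#' are excluded from hit calling.  A Benjamini-Hochberg adjusted p-value
#' column is appended for information; it plays no part in hit calling.
#'
#' @param control_stats,query_stats `data.table`s from the aggregation step
#'   with columns `strain_id`, `n_raw`, `n_kept`, `mean`, `sd`.
#' @param Wq query fitness.
#' @param W_control_median border-control median from the control screens
#'   (fitness denominator).
#' @param thresholds an [sga_thresholds()] object.
#' @param query_name label stored in the `query` column.
#' @param dubious_strains character vector of dubious-ORF strain ids.
#' @return `data.table` of interaction records, one row per strain present
#'   on both sides with >= 2 kept colonies each.
#' @export
score_interactions <- function(control_stats, query_stats, Wq, W_control_median,
                               thresholds = sga_thresholds(),
                               query_name = "query",
                               dubious_strains = character()) {
  ctl <- data.table::as.data.table(control_stats)
  qry <- data.table::as.data.table(query_stats)
  rec <- ctl[qry, on = "strain_id", nomatch = NULL,
             .(strain_id, n_control = n_kept, mean_control = mean, sd_control = sd,
               n_query = i.n_kept, mean_query = i.mean, sd_query = i.sd)]
  rec <- rec[n_control >= 2L & n_query >= 2L]
  wt <- .welch_stats(rec$mean_control, rec$sd_control, rec$n_control,
                     rec$mean_query, rec$sd_query, rec$n_query)
  ## plate normalization pins query plates to the control scale via the
  ## inner-perimeter controls, which themselves carry the query deletion —
  ## so it divides the query's global fitness out of every query colony.
  ## The separately measured Wq re-introduces it into the observed fitness.
  rec[, `:=`(delta_pixels = mean_control - mean_query, p_value = wt$p,
             Wx = fitness_of(mean_control, W_control_median),
             Wq = Wq,
             W_observed = Wq * fitness_of(mean_query, W_control_median))]
  rec[, epsilon := W_observed - Wx * Wq]
  cls <- classify_interaction(rec$delta_pixels, rec$p_value, rec$epsilon, thresholds)
  rec[, class := cls$class]
  rec[, dead_flag := Wx < thresholds$dead_fitness_floor]
  rec[, dubious_flag := strain_id %in% dubious_strains]
  rec[, stringent_flag := cls$stringent_flag & !dead_flag]
  rec[, bh_q := stats::p.adjust(p_value, method = "BH")]
  rec[, `:=`(array_gene = strain_id, query = query_name)]
  data.table::setorder(rec, array_gene)
  rec[, .(array_gene, query, n_control, n_query, mean_control, mean_query,
          delta_pixels, p_value, Wx, Wq, W_observed, epsilon, class,
          stringent_flag, bh_q, dubious_flag, dead_flag)]
}

#' Score every query of a normalized screen bundle
#'
#' The full scoring stage: aggregates each array strain's normalized interior
#' colonies per screen group with one-pass outlier rejection
#' ([aggregate_strain()] semantics), measures query fitness from the
#' inner-perimeter control medians (query screens versus control screens),
#' takes the fitness denominator as the median normalized inner-perimeter
#' border-control size over the control screens, and calls
#' [score_interactions()] for each query.
#'
#' @param colonies normalized colony `data.table`.
#' @param layout matching `sga_layout`.
#' @param thresholds an [sga_thresholds()] object.
#' @param dubious_strains character vector of dubious-ORF strain ids.
#' @return list: `records` (all queries' interaction records), `query_fitness`
#'   (`data.table` of query, Wq), `W_control_median`, `strain_stats`
#'   (per strain x group aggregates), `n_skipped` (strains missing or with
#'   <2 kept colonies on a side).
#' @export
score_screens <- function(colonies, layout, thresholds = sga_thresholds(),
                          dubious_strains = character()) {
  colonies <- data.table::as.data.table(colonies)
  if (!"normalized_size" %in% names(colonies))
    stop("normalized sizes absent: run normalize_screens() first")
  pos <- layout$positions
  ctl_strain <- layout$control_strain_id

  inner <- colonies[pos[ring == "inner_control"],
                    on = c(plate_id = "plate", "row", "col"), nomatch = NULL]
  inner <- inner[strain_id == ctl_strain]
  ## fitness denominator: median normalized border-control size, control screens
  ctl_inner_median <- stats::median(inner[query_name == "control", normalized_size])
  ## query fitness is measured on *raw* inner-perimeter sizes: normalization
  ## pins every plate's inner-control median to the experimental median, so
  ## only the unnormalized medians still carry the query's growth defect
  ctl_raw_median <- stats::median(inner[query_name == "control", raw_size])
  qmed <- inner[query_name != "control",
                .(Wq = stats::median(raw_size) / ctl_raw_median),
                by = .(query = query_name)]

  interior <- colonies[pos[ring == "interior"],
                       on = c(plate_id = "plate", "row", "col"), nomatch = NULL]
  interior <- interior[strain_id != ctl_strain]
  stats_all <- .aggregate_groups(interior, "normalized_size",
                                 by = c("strain_id", "query_name"))

  ctl_stats <- stats_all[query_name == "control"]
  records <- data.table::rbindlist(lapply(qmed$query, function(q) {
    score_interactions(ctl_stats, stats_all[query_name == q],
                       Wq = qmed[query == q, Wq],
                       W_control_median = ctl_inner_median,
                       thresholds = thresholds, query_name = q,
                       dubious_strains = dubious_strains)
  }))
  n_universe <- length(unique(interior$strain_id))
  n_scored <- length(unique(records$array_gene))
  list(records = records, query_fitness = qmed,
       W_control_median = ctl_inner_median,
       strain_stats = stats_all,
       n_skipped = n_universe - n_scored)
}

#' Wide epsilon matrix for clustergram rendering
#'
#' Rows are array genes, one column of epsilon values per query — the
#' heatmap-ready table downstream clustering tools consume.
#'
#' @param records interaction records from [score_screens()].
#' @param stringent_only keep only genes with a stringent hit in >= 1 query.
#' @param drop_dubious drop genes flagged as dubious ORFs.
#' @return `data.table`, first column `array_gene`.
#' @export
clustergram_table <- function(records, stringent_only = TRUE, drop_dubious = TRUE) {
  rec <- data.table::as.data.table(records)
  if (drop_dubious) rec <- rec[dubious_flag == FALSE]
  keep <- if (stringent_only) rec[stringent_flag == TRUE, unique(array_gene)]
          else rec[, unique(array_gene)]
  wide <- data.table::dcast(rec[array_gene %in% keep],
                            array_gene ~ query, value.var = "epsilon")
  data.table::setorder(wide, array_gene)
  wide
}
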