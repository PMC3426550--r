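#' Normalize colony sizes to the inner-perimeter control medians
#'
#' The second ring of border-control colonies on each plate (the "inner
#' perimeter") competes for nutrients the way interior colonies do, so its
#' median size is a reliable per-plate growth reference.  For every plate of
#' every screen the plate median is the median raw size of its inner-perimeter
#' control colonies; the experimental median pools all screens (control and
#' query) in the bundle, either as the median of the per-plate medians
#' (default) or of all inner-perimeter colonies pooled.  Then
#'
#'   `normalized_size = raw_size * experimental_median / plate_median`
#'
#' for every colony of the plate, including outer-ring colonies (which are
#' normalized but excluded from all downstream statistics).
#'
#' @param colonies colony `data.table` with `raw_size`.
#' @param layout matching `sga_layout`.
#' @param experimental_median `"plate_medians"` (median of per-plate medians,
#'   default) or `"pooled"` (median over all inner-perimeter control
#'   colonies).
#' @param reference_median optional fixed experimental median in pixels.  When
#'   supplied it replaces the computed experimental median, so normalized
#'   sizes are expressed on a fixed reference scale (the original study used
#'   a fixed 343-pixel reference) and become exactly invariant to any
#'   per-plate rescaling of the raw sizes.
#' @return A list: `colonies` (input plus `normalized_size`) and `stats`, an
#'   `sga_norm_stats` object with `plate_medians` (per screen x plate),
#'   `experimental_median` and `method`.
#' @export
normalize_screens <- function(colonies, layout,
                              experimental_median = c("plate_medians", "pooled"),
                              reference_median = NULL) {
  experimental_median <- match.arg(experimental_median)
  colonies <- data.table::copy(data.table::as.data.table(colonies))
  pos <- layout$positions
  colonies[pos, ring := i.ring, on = c(plate_id = "plate", "row", "col")]
  if (anyNA(colonies$ring))
    stop("consistency error: colony positions missing from the layout")

  inner <- colonies[ring == "inner_control" & strain_id == layout$control_strain_id]
  pm <- inner[, .(plate_median = stats::median(raw_size), n_inner = .N),
              by = .(screen_id, plate_id)]
  all_plates <- unique(colonies[, .(screen_id, plate_id)])
  missing <- all_plates[!pm, on = c("screen_id", "plate_id")]
  if (nrow(missing))
    stop("normalization error: no inner-perimeter control colonies on plate ",
         missing$plate_id[1L], " of screen ", missing$screen_id[1L])
  bad <- pm[plate_median <= 0]
  if (nrow(bad))
    stop("normalization error: plate median is zero on plate ", bad$plate_id[1L],
         " of screen ", bad$screen_id[1L])

  exp_med <- if (!is.null(reference_median)) {
    stopifnot(is.numeric(reference_median), reference_median > 0)
    reference_median
  } else if (experimental_median == "plate_medians")
    stats::median(pm$plate_median) else stats::median(inner$raw_size)

  colonies[pm, plate_median := i.plate_median, on = c("screen_id", "plate_id")]
  colonies[, normalized_size := raw_size * exp_med / plate_median]
  colonies[, c("plate_median", "ring") := NULL]

  stats <- structure(list(plate_medians = pm, experimental_median = exp_med,
                          method = experimental_median),
                     class = "sga_norm_stats")
  list(colonies = colonies, stats = stats)
}

#' @export
print.sga_norm_stats <- function(x, ...) {
  cat(sprintf("Normalization over %d plate instances; experimental median %.1f px (%s)\n",
              nrow(x$plate_medians), x$experimental_median, x$method))
  invisible(x)
}

#' Per-strain replicate coefficient of variation summary
#'
#' For every array strain and screen group (the pooled control screens, or
#' one group per query) the CV is the sample standard deviation over the
#' strain's normalized interior colonies divided by their mean.  Strains with
#' zero mean are flagged and excluded (counted in `n_undefined`).
#'
#' @param colonies colony `data.table` with `normalized_size`.
#' @param layout matching `sga_layout`.
#' @param cv_threshold reporting threshold on the CV (default 0.225).
#' @return An `sga_cv_summary`: list with `per_strain` (`strain_id`, `group`,
#'   `n`, `mean`, `sd`, `cv`), `mean_cv`, `sd_cv`, `fraction_below`
#'   (fraction of strain x group CVs below `cv_threshold`), `cv_threshold`,
#'   `n_undefined`.
#' @export
cv_summary <- function(colonies, layout, cv_threshold = 0.225) {
  colonies <- data.table::as.data.table(colonies)
  if (!"normalized_size" %in% names(colonies))
    stop("normalized sizes absent: run normalize_screens() first")
  pos <- layout$positions
  interior <- colonies[pos[ring == "interior"],
                       on = c(plate_id = "plate", "row", "col"), nomatch = NULL]
  interior <- interior[strain_id != layout$control_strain_id]
  per <- interior[, .(n = .N, mean = mean(normalized_size),
                      sd = stats::sd(normalized_size)),
                  by = .(strain_id, group = query_name)]
  per <- per[n >= 2L]
  n_undef <- sum(per$mean == 0)
  if (n_undef) warning(n_undef, " strain/group CV(s) undefined (zero mean), excluded")
  per <- per[mean > 0][, cv := sd / mean]
  structure(list(per_strain = per,
                 mean_cv = mean(per$cv), sd_cv = stats::sd(per$cv),
                 fraction_below = mean(per$cv < cv_threshold),
                 cv_threshold = cv_threshold, n_undefined = n_undef),
            class = "sga_cv_summary")
}

#' @export
print.sga_cv_summary <- function(x, ...) {
  cat(sprintf("Replicate CV over %d strain x group pairs: %.1f%% +/- %.1f%%; %.1f%% below %.1f%%\n",
              nrow(x$per_strain), 100 * x$mean_cv, 100 * x$sd_cv,
              100 * x$fraction_below, 100 * x$cv_threshold))
  invisible(x)
}
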