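## Tab-separated readers/writers for every tabular artifact of the pipeline.
## All files are UTF-8 TSV with a header row; '#'-prefixed comment lines are
## permitted and skipped on read.  Coordinates are 1-based, row 1 = top.
## All writers are deterministic: identical inputs give byte-identical files.

.fread_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("format error in ", what, " file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  dt
}

.fwrite_tsv <- function(dt, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA", eol = "\n")
}

#' Write / read an array layout as TSV
#'
#' One row per plate position with columns `plate`, `row`, `col`,
#' `strain_id`, `ring`.  Grid dimensions and the control strain are
#' reconstructed from the table on read.
#'
#' @param layout an `sga_layout`.
#' @param path file path.
#' @return `read_layout()` returns an `sga_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sga_layout"))
  .fwrite_tsv(layout$positions, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  pos <- .fread_tsv(path, c("plate", "row", "col", "strain_id", "ring"), "layout")
  valid_rings <- c("outer_control", "inner_control", "interior")
  if (!all(pos$ring %in% valid_rings))
    stop("format error in layout: unknown ring label(s) ",
         paste(setdiff(unique(pos$ring), valid_rings), collapse = ", "))
  n_rows <- max(pos$row); n_cols <- max(pos$col)
  control <- unique(pos[ring == "outer_control", strain_id])
  if (length(control) != 1L)
    stop("layout error: outer perimeter must hold exactly one control strain")
  strain_ids <- sort(setdiff(unique(pos$strain_id), control))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 plates = unique(pos$plate), control_strain_id = control,
                 strain_ids = strain_ids,
                 interior_capacity = (n_rows - 4L) * (n_cols - 4L),
                 positions = pos),
            class = "sga_layout")
}

#' Write / read a colony-size table as TSV
#'
#' Columns: `screen_id`, `query_name`, `replicate`, `plate_id`, `row`, `col`,
#' `strain_id`, `raw_size` and, when present, `normalized_size`.
#'
#' @param colonies colony `data.table`.
#' @param path file path.
#' @export
write_colony_table <- function(colonies, path) {
  keep <- intersect(c("screen_id", "query_name", "replicate", "plate_id", "row",
                      "col", "strain_id", "raw_size", "normalized_size"),
                    names(colonies))
  out <- data.table::as.data.table(colonies)[, keep, with = FALSE]
  data.table::setorder(out, screen_id, plate_id, row, col)
  .fwrite_tsv(out, path)
  invisible(path)
}

#' @rdname write_colony_table
#' @export
read_colony_table <- function(path) {
  dt <- .fread_tsv(path, c("screen_id", "query_name", "replicate", "plate_id",
                           "row", "col", "strain_id", "raw_size"), "colony")
  if (!is.numeric(dt$raw_size))
    stop("parse error in colony file: non-numeric raw_size (first offending line ",
         which(is.na(suppressWarnings(as.numeric(dt$raw_size))))[1L] + 1L, ")")
  if (any(dt$raw_size < 0)) stop("colony table error: negative raw_size")
  key <- dt[, .N, by = .(screen_id, replicate, plate_id, row, col)][N > 1L]
  if (nrow(key))
    stop("format error: duplicate colony key at screen ", key$screen_id[1L],
         " replicate ", key$replicate[1L], " plate ", key$plate_id[1L],
         " (", key$row[1L], ",", key$col[1L], ")")
  dt
}

#' Read and cross-validate a layout + colony-table bundle
#'
#' Every colony must sit on a position present in the layout, with the
#' strain identity the layout assigns to that position.
#'
#' @param layout_path,colony_path file paths.
#' @return `list(layout, colonies)`.
#' @export
read_screen_bundle <- function(layout_path, colony_path) {
  layout <- read_layout(layout_path)
  colonies <- read_colony_table(colony_path)
  chk <- colonies[!layout$positions, on = c(plate_id = "plate", "row", "col")]
  if (nrow(chk))
    stop("consistency error: colony at plate ", chk$plate_id[1L], " (",
         chk$row[1L], ",", chk$col[1L], ") has no matching layout position")
  merged <- layout$positions[colonies, on = c(plate = "plate_id", "row", "col")]
  bad <- merged[strain_id != i.strain_id]
  if (nrow(bad))
    stop("consistency error: strain mismatch at plate ", bad$plate[1L], " (",
         bad$row[1L], ",", bad$col[1L], "): layout says ", bad$strain_id[1L],
         ", colony table says ", bad$i.strain_id[1L])
  list(layout = layout, colonies = colonies)
}

#' Write interaction records as a TSV hit table
#'
#' One row per (array gene, query), sorted by query then gene.  Epsilon is
#' serialized to 4 decimals and p-values in scientific notation with 3
#' significant digits, so round trips preserve the reported precision.
#'
#' @param records interaction `data.table` from [score_screens()].
#' @param path output file path.
#' @export
write_results <- function(records, path) {
  cols <- c("array_gene", "query", "n_control", "n_query", "mean_control",
            "mean_query", "delta_pixels", "p_value", "Wx", "Wq", "W_observed",
            "epsilon", "class", "stringent_flag")
  extra <- intersect(c("bh_q", "dubious_flag", "dead_flag"), names(records))
  out <- data.table::as.data.table(records)
  missing <- setdiff(cols, names(out))
  if (length(missing))
    stop("records not scored: missing column(s) ", paste(missing, collapse = ", "))
  out <- out[, c(cols, extra), with = FALSE]
  data.table::setorder(out, query, array_gene)
  num3 <- c("mean_control", "mean_query", "delta_pixels")
  for (cc in num3) data.table::set(out, j = cc, value = sprintf("%.2f", out[[cc]]))
  for (cc in intersect(c("Wx", "Wq", "W_observed", "epsilon"), names(out)))
    data.table::set(out, j = cc, value = sprintf("%.4f", out[[cc]]))
  for (cc in intersect(c("p_value", "bh_q"), names(out)))
    data.table::set(out, j = cc, value = sprintf("%.3e", out[[cc]]))
  .fwrite_tsv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  dt <- .fread_tsv(path, c("array_gene", "query", "epsilon", "p_value",
                           "class", "stringent_flag"), "results")
  dt
}

#' Write the simulation ground truth
#'
#' Two files: `<stem>_truth.tsv` (strain x query: `Wx`, `Wq`, `true_epsilon`,
#' `expected_size`, dubious flag) and `<stem>_outliers.tsv` (coordinates and
#' fold-factors of injected outlier colonies).
#'
#' @param truth the `truth` element of [simulate_screen_set()].
#' @param stem output path stem.
#' @export
write_truth <- function(truth, stem) {
  eff <- data.table::copy(truth$effects)
  eff[truth$strains, `:=`(dubious = i.dubious, neighbor_id = i.neighbor_id),
      on = "strain_id"]
  data.table::setorder(eff, query_name, strain_id)
  .fwrite_tsv(eff, paste0(stem, "_truth.tsv"))
  .fwrite_tsv(truth$outliers, paste0(stem, "_outliers.tsv"))
  invisible(stem)
}

#' Read a gene-to-term annotation map
#'
#' Expects a 2- or 3-column TSV: `gene`, `term` and optionally `term_name`.
#' The background universe defaults to all annotated genes; pass `universe`
#' to widen it (every annotated gene must belong to it).
#'
#' @param path annotation TSV.
#' @param universe optional character vector of background genes.
#' @return An object of class `sga_annotations`: list with `gene2term`
#'   (`data.table` of gene, term), `term_names` (named character) and
#'   `universe`.
#' @export
read_annotations <- function(path, universe = NULL) {
  dt <- .fread_tsv(path, c("gene", "term"), "annotation")
  dt <- unique(dt[, .(gene, term,
                      term_name = if ("term_name" %in% names(dt)) term_name else term)])
  if (is.null(universe)) universe <- sort(unique(dt$gene))
  outside <- setdiff(dt$gene, universe)
  if (length(outside))
    stop("annotation error: gene(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  term_names <- dt[, .(term_name = term_name[1L]), by = term]
  structure(list(gene2term = dt[, .(gene, term)],
                 term_names = stats::setNames(term_names$term_name, term_names$term),
                 universe = universe),
            class = "sga_annotations")
}
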