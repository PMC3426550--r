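#' Build a colony-array plate layout with a two-colony control perimeter
#'
#' Lays out `n_array_strains` deletion strains, in duplicate, on plates of
#' `n_rows` x `n_cols` colonies (1536-format by default).  The outermost ring
#' of every plate and the ring just inside it hold the border-control strain;
#' only the second ("inner perimeter") ring competes for nutrients like an
#' interior colony and is later used as the normalization reference.  Array
#' strains fill interior positions in row-major order, both duplicate copies
#' consecutively, so both copies of a strain always land on the same plate.
#' Interior positions left over on the last plate are filled with the control
#' strain.
#'
#' Under the default 32 x 48 geometry each plate has 156 outer-ring and 148
#' inner-ring control positions and 1232 interior positions (616 strains per
#' plate in duplicate).
#'
#' @param n_array_strains number of distinct array strains (>= 1).
#' @param n_rows,n_cols plate grid dimensions; must leave at least one
#'   interior row and column inside the two-colony perimeter.
#' @param control_strain_id identifier used for every border-control colony.
#' @return An object of class `sga_layout`: a list with `n_rows`, `n_cols`,
#'   `plates` (character vector of plate ids), `control_strain_id`, and
#'   `positions`, a `data.table` with columns `plate`, `row`, `col`,
#'   `strain_id`, `ring` (one of `"outer_control"`, `"inner_control"`,
#'   `"interior"`).
#' @examples
#' lay <- make_layout(100)
#' table(lay$positions$ring) / length(lay$plates)
#' @export
make_layout <- function(n_array_strains, n_rows = 32L, n_cols = 48L,
                        control_strain_id = "his3d::kanMX") {
  n_array_strains <- as.integer(n_array_strains)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_array_strains) || n_array_strains < 1L)
    stop("n_array_strains must be a positive integer (empty array)")
  if (n_rows < 5L || n_cols < 5L)
    stop("grid too small: a two-colony perimeter plus interior needs at least 5 rows and 5 columns")

  interior_rows <- (n_rows - 4L) ; interior_cols <- (n_cols - 4L)
  interior_capacity <- interior_rows * interior_cols
  if (interior_capacity < 2L)
    stop("grid too small: fewer than 2 interior positions inside the perimeter")
  if (interior_capacity %% 2L == 1L) interior_capacity_strains <- (interior_capacity - 1L) %/% 2L
  else interior_capacity_strains <- interior_capacity %/% 2L

  n_plates <- ceiling(2L * n_array_strains / interior_capacity)
  # odd interior capacity could force a strain to straddle plates; keep both
  # copies on one plate by capping strains per plate instead
  n_plates <- max(n_plates, ceiling(n_array_strains / interior_capacity_strains))
  plates <- sprintf("P%d", seq_len(n_plates))

  row_idx <- seq_len(n_rows); col_idx <- seq_len(n_cols)
  grid <- data.table::CJ(row = row_idx, col = col_idx)  # row-major after ordering
  data.table::setorder(grid, row, col)
  ring <- rep("interior", nrow(grid))
  outer <- grid$row == 1L | grid$row == n_rows | grid$col == 1L | grid$col == n_cols
  inner <- !outer & (grid$row == 2L | grid$row == n_rows - 1L |
                     grid$col == 2L | grid$col == n_cols - 1L)
  ring[outer] <- "outer_control"
  ring[inner] <- "inner_control"

  strain_ids <- sprintf("STR%04d", seq_len(n_array_strains))
  per_plate <- interior_capacity_strains

  positions <- data.table::rbindlist(lapply(seq_len(n_plates), function(p) {
    dt <- data.table::data.table(plate = plates[p], row = grid$row, col = grid$col,
                                 ring = ring, strain_id = control_strain_id)
    first <- (p - 1L) * per_plate + 1L
    last  <- min(p * per_plate, n_array_strains)
    if (first <= last) {
      ids <- strain_ids[first:last]
      fill <- rep(ids, each = 2L)                      # duplicate copies, consecutive
      idx_int <- which(dt$ring == "interior")
      dt$strain_id[idx_int[seq_along(fill)]] <- fill
    }
    dt
  }))
  data.table::setcolorder(positions, c("plate", "row", "col", "strain_id", "ring"))

  structure(list(n_rows = n_rows, n_cols = n_cols, plates = plates,
                 control_strain_id = control_strain_id,
                 strain_ids = strain_ids,
                 interior_capacity = interior_capacity,
                 positions = positions),
            class = "sga_layout")
}

#' @export
print.sga_layout <- function(x, ...) {
  cat(sprintf("SGA array layout: %d plate(s) of %d x %d colonies\n",
              length(x$plates), x$n_rows, x$n_cols))
  cat(sprintf("  array strains: %d (in duplicate), control strain: %s\n",
              length(x$strain_ids), x$control_strain_id))
  cnt <- table(x$positions$ring) / length(x$plates)
  cat(sprintf("  per plate: %s interior, %s inner-perimeter, %s outer-perimeter\n",
              cnt[["interior"]], cnt[["inner_control"]], cnt[["outer_control"]]))
  invisible(x)
}
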