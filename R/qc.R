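#' Gaussian fit of the epsilon-score histogram
#'
#' Bins the epsilon values (left-closed, right-open bins anchored at 0) and
#' fits `amplitude * exp(-(x - center)^2 / (2 * sigma^2))` to the bin counts
#' at the bin midpoints by nonlinear least squares, initialized from the
#' sample mean, sample SD and maximum count.  A screen with no systematic
#' bias in the multiplicative model gives a fit centered near 0.
#'
#' @param epsilons numeric vector of epsilon scores.
#' @param bin_size histogram bin width (default 0.025).
#' @return An `sga_gaussian_fit`: list with `center`, `center_se`, `sigma`,
#'   `amplitude`, `adjusted_r2` (3 fitted parameters), `bin_size`, `n`, and
#'   `histogram` (`data.table` of `mid`, `count`, `fitted`).
#' @export
fit_epsilon_gaussian <- function(epsilons, bin_size = 0.025) {
  stopifnot(bin_size > 0)
  epsilons <- epsilons[is.finite(epsilons)]
  idx <- floor(epsilons / bin_size)              # left-closed, right-open, anchored at 0
  tab <- table(idx)
  full <- seq(min(idx), max(idx))
  count <- as.numeric(tab[as.character(full)])
  count[is.na(count)] <- 0
  mid <- (full + 0.5) * bin_size
  if (sum(count > 0) < 5L)
    stop("degenerate histogram: need >= 5 non-empty bins for a Gaussian fit")

  core <- .fit_gaussian_bins(mid, count,
                             start = list(A = max(count), mu = mean(epsilons),
                                          sg = stats::sd(epsilons)))
  structure(c(core, list(bin_size = bin_size, n = length(epsilons))),
            class = "sga_gaussian_fit")
}

## nonlinear least-squares Gaussian fit to bin counts at bin midpoints;
## adjusted r2 uses p = 3 fitted parameters
.fit_gaussian_bins <- function(mid, count, start) {
  fit <- minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * sg^2)),
                           start = start,
                           data = data.frame(mid = mid, count = count),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  fitted <- stats::fitted(fit)
  n_bins <- length(count); p <- 3L
  r2 <- 1 - sum((count - fitted)^2) / sum((count - mean(count))^2)
  adj_r2 <- 1 - (1 - r2) * (n_bins - 1) / (n_bins - p - 1)
  list(center = unname(cf["mu"]), center_se = unname(se["mu"]),
       sigma = abs(unname(cf["sg"])), amplitude = unname(cf["A"]),
       adjusted_r2 = adj_r2,
       histogram = data.table::data.table(mid = mid, count = count,
                                          fitted = fitted))
}

#' @export
print.sga_gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit of %d epsilon scores (bin %.3f): center %.4f +/- %.1e, sigma %.3f, adj r2 %.3f\n",
              x$n, x$bin_size, x$center, x$center_se, x$sigma, x$adjusted_r2))
  invisible(x)
}

#' Overlap of hit sets across query screens
#'
#' Exact Venn region counts and shared-in-at-least-k counts for any number
#' of queries.  The counts are invariant to the order the queries are given.
#'
#' @param hit_sets named list of character vectors (gene sets per query).
#' @return An `sga_overlap`: list with `per_query` (set sizes), `pairwise`
#'   (matrix of intersection counts), `regions` (`data.table` of membership
#'   signature and count), `shared_ge` (named vector: genes present in >= k
#'   queries for k = 1..number of queries) and `shared_genes_ge2`.
#' @export
query_overlap <- function(hit_sets) {
  if (length(hit_sets) < 2L) stop("need >= 2 hit sets")
  if (is.null(names(hit_sets))) names(hit_sets) <- paste0("q", seq_along(hit_sets))
  qs <- names(hit_sets)
  genes <- sort(unique(unlist(hit_sets)))
  member <- vapply(hit_sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, qs))
  k <- rowSums(member)
  sig <- apply(member, 1L, function(m) paste(qs[m], collapse = "&"))
  regions <- data.table::data.table(signature = sig)[, .(count = .N), by = signature]
  data.table::setorder(regions, signature)
  pairwise <- outer(qs, qs, Vectorize(function(a, b)
    length(intersect(hit_sets[[a]], hit_sets[[b]]))))
  dimnames(pairwise) <- list(qs, qs)
  shared_ge <- vapply(seq_along(qs), function(j) sum(k >= j), integer(1L))
  names(shared_ge) <- paste0("ge", seq_along(qs))
  structure(list(per_query = vapply(hit_sets, function(s) length(unique(s)), integer(1L)),
                 pairwise = pairwise, regions = regions,
                 shared_ge = shared_ge,
                 shared_genes_ge2 = genes[k >= 2L]),
            class = "sga_overlap")
}

#' @export
print.sga_overlap <- function(x, ...) {
  cat("Hit-set overlap across", length(x$per_query), "queries\n")
  cat("  per query:", paste(names(x$per_query), x$per_query, sep = "=", collapse = ", "), "\n")
  cat("  shared in >=2 screens:", x$shared_ge[["ge2"]], "\n")
  invisible(x)
}

#' Correlation between two epsilon vectors
#'
#' Pearson or Spearman correlation of paired interaction scores, e.g. a
#' dubious-ORF deletion versus its overlapping verified neighbor across
#' queries.  Spearman uses average ranks on ties.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
correlate_epsilon_vectors <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need >= 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in an input vector")
  stats::cor(x, y, method = method)
}

#' Overlap with an external hit list at matched criteria
#'
#' The fraction of external hits, restricted to the strains scoreable in this
#' screen, that this screen also calls:
#' `|own ∩ external ∩ scoreable| / |external ∩ scoreable|`.
#'
#' @param own_hits,external_hits,scoreable character gene sets from the same
#'   identifier space.
#' @return list with `fraction`, `n_scoreable` (external hits scoreable
#'   here) and `n_shared`.
#' @export
external_overlap <- function(own_hits, external_hits, scoreable) {
  ext <- intersect(external_hits, scoreable)
  if (length(ext) == 0L)
    stop("no external hits are scoreable in this screen: fraction undefined")
  shared <- intersect(own_hits, ext)
  list(fraction = length(shared) / length(ext),
       n_scoreable = length(ext), n_shared = length(shared))
}
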