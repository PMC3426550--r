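#' Hypergeometric over-representation of annotation terms in a hit set
#'
#' For each term with at least one annotated gene in the universe, tests
#' whether the hit set contains more term-annotated genes than expected when
#' drawing `n = |hits|` genes without replacement from the `N`-gene universe
#' containing `K` term-annotated genes: the upper-tail probability
#' `P(X >= k)` of the hypergeometric distribution.  One-sided
#' over-representation only; genes annotated to several terms count once per
#' term.  A Benjamini-Hochberg column is appended for information — the
#' primary value is the raw hypergeometric p.
#'
#' @param hits character vector of hit genes (must lie in the universe).
#' @param annotations an `sga_annotations` from [read_annotations()], or a
#'   `data.frame` with columns `gene`, `term`.
#' @param universe background gene set; defaults to the annotation universe.
#' @return `data.table` sorted by `p_hyper` with columns `term`, `term_name`,
#'   `N`, `K`, `n`, `k`, `p_hyper`, `fold` (`(k/n) / (K/N)`), `bh_q`.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                   term = c("T1", "T1", "T1", "T2"))
#' hypergeom_enrichment(c("g1", "g2"), ann, universe = paste0("g", 1:10))
#' @export
hypergeom_enrichment <- function(hits, annotations, universe = NULL) {
  if (inherits(annotations, "sga_annotations")) {
    g2t <- annotations$gene2term
    term_names <- annotations$term_names
    if (is.null(universe)) universe <- annotations$universe
  } else {
    g2t <- data.table::as.data.table(annotations)[, .(gene, term)]
    term_names <- NULL
    if (is.null(universe)) universe <- sort(unique(g2t$gene))
  }
  hits <- unique(hits)
  if (length(setdiff(hits, universe)))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 3), collapse = ", "))
  if (length(hits) == 0L) {
    warning("empty hit set: no enrichment computed")
    return(data.table::data.table(term = character(), term_name = character(),
                                  N = integer(), K = integer(), n = integer(),
                                  k = integer(), p_hyper = numeric(),
                                  fold = numeric(), bh_q = numeric()))
  }
  g2t <- unique(g2t[gene %in% universe])
  N <- length(universe); n <- length(hits)
  tab <- g2t[, .(K = .N, k = sum(gene %in% hits)), by = term]
  tab <- tab[K > 0L]
  tab[, `:=`(N = N, n = n,
             p_hyper = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
             fold = (k / n) / (K / N))]
  tab[, bh_q := stats::p.adjust(p_hyper, method = "BH")]
  tab[, term_name := if (!is.null(term_names)) unname(term_names[term]) else term]
  data.table::setorder(tab, p_hyper, term)
  tab[, .(term, term_name, N, K, n, k, p_hyper, fold, bh_q)]
}

#' Spearman comparison of term-frequency profiles
#'
#' Rank-correlates the frequency of annotation terms among hit genes with
#' their genome-wide frequency, over the `top_k` terms by genome frequency
#' after removing the terms in `exclude` (ubiquitous compartments such as
#' cytoplasm and nucleus are conventionally excluded).  Average ranks are
#' used on ties.
#'
#' @param freq_hits,freq_genome named numeric vectors: term -> frequency.
#' @param top_k number of top genome terms to compare (default 18).
#' @param exclude character vector of terms to drop before truncation.
#' @return Spearman rank correlation over the selected terms.
#' @export
component_profile_spearman <- function(freq_hits, freq_genome, top_k = 18L,
                                       exclude = character()) {
  fg <- freq_genome[!names(freq_genome) %in% exclude]
  fg <- fg[order(-fg, names(fg))]
  sel <- utils::head(names(fg), top_k)
  sel <- sel[sel %in% names(freq_hits)]
  if (length(sel) < 3L)
    stop("fewer than 3 shared terms after exclusion and truncation")
  stats::cor(freq_hits[sel], freq_genome[sel], method = "spearman")
}
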