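#' Shared/unique species counts for a pair of assemblages
#'
#' For two presence-absence vectors, `a` is the number of species present at
#' both sites, `b` those only at the first, `c` those only at the second.
#' All incidence-based similarity indices here are functions of (a, b, c).
#'
#' @param x,y binary incidence vectors over the same species set.
#' @return list with integer components `a`, `b`, `c`.
#' @export
pair_counts <- function(x, y) {
  if (length(x) != length(y)) stopf("incidence vectors differ in length")
  x <- as.logical(x); y <- as.logical(y)
  list(a = sum(x & y), b = sum(x & !y), c = sum(!x & y))
}

#' Jaccard similarity from pair counts
#'
#' J = a / (a + b + c): the fraction of the pooled species list shared by the
#' two sites. 1 means identical assemblages, 0 means none shared.
#'
#' @param counts a list with components `a`, `b`, `c` (see [pair_counts()]).
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(counts) {
  tot <- counts$a + counts$b + counts$c
  if (tot == 0) stopf("Jaccard undefined: both assemblages empty")
  counts$a / tot
}

#' Simpson similarity from pair counts
#'
#' a / (a + min(b, c)): insensitive to richness differences, so a species-poor
#' site nested inside a species-rich one scores 1. Used to separate true
#' turnover from nestedness.
#'
#' @inheritParams jaccard
#' @return similarity in \[0, 1\]; always >= the Jaccard value.
#' @export
simpson <- function(counts) {
  den <- counts$a + min(counts$b, counts$c)
  if (den == 0) stopf("Simpson undefined: smaller assemblage empty")
  counts$a / den
}

#' Pairwise similarity matrix from an occurrence matrix
#'
#' Computes the chosen incidence-based index for every site pair. The shared
#' counts come from one cross-product of the binary matrix, so the 164-site
#' scale (13,366 pairs) is immediate.
#'
#' @param occ an [occurrence_matrix()].
#' @param index `"jaccard"` or `"simpson"`.
#' @return a [pairwise_matrix()] of kind `"similarity"`, unit diagonal.
#' @export
similarity_matrix <- function(occ, index = c("jaccard", "simpson")) {
  index <- match.arg(index)
  if (!inherits(occ, "occurrence_matrix")) occ <- occurrence_matrix(occ)
  m <- unclass(occ)
  storage.mode(m) <- "double"
  shared <- tcrossprod(m)            # a: shared species per pair
  rich <- rowSums(m)                 # a + b (row) and a + c (col)
  only_i <- outer(rich, rep(1, length(rich))) - shared
  only_j <- t(only_i)
  sim <- switch(index,
    jaccard = shared / (shared + only_i + only_j),
    simpson = shared / (shared + pmin(only_i, only_j))
  )
  # empty assemblages are rejected upstream, so denominators are positive
  pairwise_matrix(sim, kind = "similarity", site_ids = rownames(occ))
}
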