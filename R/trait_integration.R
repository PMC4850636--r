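# Cross-trait integration: composite Score = sum over traits of -log10(p_i).
#
# Genes with multiple strong associations accumulate large scores. An
# association removed by the FDR filter (or never tested) contributes 0 for
# that trait rather than deleting the gene outright; a gene contributing 0 in
# every trait drops out of the ranking.

#' Combine per-trait gene p-values into composite scores
#'
#' The contribution of (gene, trait) is `-log10(max(p, p_floor))` when the gene
#' was tested for that trait and, if filters are supplied, not removed;
#' otherwise 0. The score is the sum over all supplied traits.
#'
#' @param per_trait named list (by trait) of [map_trait()] result data.frames
#'   over a common gene universe.
#' @param filters optional named list (by trait) of [apply_filter()] results
#'   covering the same (gene, trait) pairs.
#' @param p_floor lower clamp so degenerate p-values keep scores finite.
#' @return data.frame (class `gene_scores`): `gene`, one `contrib_<trait>`
#'   column per trait, `n_traits_contributing`, `score`. Genes scoring 0 in
#'   every trait are dropped. Unranked; see [rank_genes()].
#' @export
score_genes <- function(per_trait, filters = NULL, p_floor = 1e-300) {
  .assert(is.list(per_trait) && length(per_trait) >= 1L && !is.null(names(per_trait)),
          "per_trait must be a named list of map_trait() results")
  traits <- names(per_trait)
  universe <- sort(per_trait[[1]]$gene)
  for (t in traits) {
    .assert(identical(sort(per_trait[[t]]$gene), universe),
            "inconsistent gene universe in trait '%s'", t)
  }
  if (!is.null(filters)) {
    .assert(all(names(filters) %in% traits), "filters name unknown trait(s)")
    for (t in names(filters)) {
      .assert(identical(sort(filters[[t]]$gene), universe),
              "filter gene universe differs for trait '%s'", t)
    }
  }
  contrib <- matrix(0, nrow = length(universe), ncol = length(traits),
                    dimnames = list(universe, traits))
  for (t in traits) {
    r <- per_trait[[t]]
    i <- match(r$gene, universe)
    ok <- !r$untested
    if (!is.null(filters) && t %in% names(filters)) {
      f <- filters[[t]]
      removed <- f$removed[match(r$gene, f$gene)]
      ok <- ok & !removed
    }
    contrib[i[ok], t] <- -log10(pmax(r$p_orig[ok], p_floor))
  }
  score <- rowSums(contrib)
  keep <- score > 0
  out <- data.frame(gene = universe[keep], stringsAsFactors = FALSE)
  for (t in traits) out[[paste0("contrib_", t)]] <- contrib[keep, t]
  out$n_traits_contributing <- rowSums(contrib[keep, , drop = FALSE] > 0)
  out$score <- score[keep]
  structure(out, class = c("gene_scores", "data.frame"))
}

#' Rank genes by descending composite score
#'
#' Ties are broken lexicographically by gene name; ranks 1..m are assigned
#' after sorting.
#'
#' @param scores output of [score_genes()].
#' @return The same data.frame sorted by descending score with a `rank` column.
#' @export
rank_genes <- function(scores) {
  .assert(is.data.frame(scores) && nrow(scores) > 0L, "no genes to rank")
  o <- order(-scores$score, scores$gene)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
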