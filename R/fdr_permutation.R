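# Gene-wise permutation FDR filter.
#
# The strain -> phenotype assignment is permuted B times and the genome-wide
# scan re-run on each permuted trait, giving every gene B null gene-level
# p-values. The gene's FDR p-value is k/B where k counts permuted p-values
# strictly smaller than the original; associations with FDR p > alpha are
# removed. This is formally a per-gene permutation p-value; the field's name
# for this construction ("gene-wise FDR p-value") is kept.

#' Run B phenotype-label permutations genome-wide
#'
#' Draws B independent uniform random permutations of the strain-to-value
#' assignment (seeded; the identity permutation is not excluded) and re-maps
#' the genome on each. All genes within a trait share the same B permutations,
#' and the permutation index matrix is kept on the result so any gene's FDR
#' p-value can be recomputed independently.
#'
#' @param genotypes a [genotype_matrix].
#' @param annotation a [gene_annotation].
#' @param trait_values named numeric vector (strain -> value), or a
#'   [phenotype_table] with `trait`.
#' @param B number of permutations (1,000 by default).
#' @param seed integer seed; mandatory so runs are reproducible.
#' @param config an [hb_config()].
#' @param trait trait name when `trait_values` is a phenotype table.
#' @param blocks optional pre-enumerated blocks (same genotypes/config).
#' @return An object of class `permutation_run`: `trait`, `B`, `seed`,
#'   `perm` (matrix of permuted positions, available strains x B), `strains`,
#'   `permuted_p` (genes x B matrix of gene-level p-values; a gene untested
#'   under a permutation contributes p = 1).
#' @export
run_permutations <- function(genotypes, annotation, trait_values, B = 1000L,
                             seed, config = hb_config(), trait = NULL,
                             blocks = NULL) {
  .assert(.is_count(B), "B must be a positive integer")
  .assert(.is_count(seed, min = 0L), "seed must be a non-negative integer")
  gm <- validate_genotype_matrix(genotypes)
  if (inherits(trait_values, "phenotype_table")) {
    .assert(!is.null(trait), "supply `trait` when passing a phenotype_table")
    trait_values <- trait_vector(trait_values, trait)
  }
  trait_name <- if (is.null(trait)) "trait" else trait
  v <- rep(NA_real_, length(gm$strains))
  names(v) <- gm$strains
  v[names(trait_values)] <- trait_values
  avail <- which(!is.na(v))
  .assert(length(avail) >= 3L, "fewer than 3 phenotyped strains")
  if (is.null(blocks)) {
    blocks <- enumerate_blocks(gm, config$window_size, config$min_group_size)
  }
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) sample.int(length(avail)),
                 integer(length(avail)))
  run <- .permutation_core(gm, annotation, v, avail, perm, blocks, config)
  structure(list(trait = trait_name, B = as.integer(B), seed = as.integer(seed),
                 perm = perm, strains = gm$strains[avail],
                 permuted_p = run),
            class = "permutation_run")
}

# shared scan machinery: apply the permutation columns to the value vector and
# return the genes x B matrix of gene-level min-p values
.permutation_core <- function(gm, annotation, v, avail, perm, blocks, config) {
  B <- ncol(perm)
  V <- matrix(NA_real_, nrow = length(v), ncol = B)
  vals <- v[avail]
  for (b in seq_len(B)) V[avail, b] <- vals[perm[, b]]
  bp <- .blocks_p_matrix(blocks, V, config$p_floor)
  gidx <- .gene_block_index(annotation, blocks, config$flank_bp)
  out <- matrix(1, nrow = nrow(annotation), ncol = B,
                dimnames = list(annotation$gene, NULL))
  for (i in seq_len(nrow(annotation))) {
    idx <- gidx[[i]]
    idx <- idx[!is.na(bp$p[idx, 1L])]
    if (length(idx)) out[i, ] <- .col_mins(bp$p[idx, , drop = FALSE])
  }
  out
}

#' @export
print.permutation_run <- function(x, ...) {
  cat(sprintf("permutation_run: trait '%s', B = %d, seed = %d, %d genes x %d strains\n",
              x$trait, x$B, x$seed, nrow(x$permuted_p), length(x$strains)))
  invisible(x)
}

#' Gene-wise FDR p-value for one gene
#'
#' `k` counts permuted p-values strictly smaller than the original (ties favor
#' retention), `fdr_p = k / B`, and the association is removed when
#' `fdr_p > alpha`. At the defaults (B = 1000, alpha = 0.005) a gene beaten by
#' exactly five permutations is retained and one beaten by six is removed.
#'
#' @param p_orig original gene-level p-value.
#' @param permuted_p numeric vector of B permuted gene-level p-values.
#' @param alpha removal threshold in (0, 1).
#' @return A list of class `fdr_result`: `k`, `B`, `fdr_p`, `removed`, `alpha`.
#' @export
gene_fdr <- function(p_orig, permuted_p, alpha = 0.005) {
  .assert(length(permuted_p) >= 1L, "permuted_p must have at least one entry")
  .assert(.is_number(p_orig) && p_orig >= 0 && p_orig <= 1,
          "p_orig must be in [0, 1]")
  .assert(.is_number(alpha) && alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  B <- length(permuted_p)
  k <- sum(permuted_p < p_orig)
  fdr_p <- k / B
  structure(list(k = as.integer(k), B = as.integer(B), fdr_p = fdr_p,
                 removed = fdr_p > alpha, alpha = alpha),
            class = "fdr_result")
}

#' Apply the gene-wise FDR filter to a trait's mapping results
#'
#' @param results data.frame from [map_trait()].
#' @param run a `permutation_run` for the same trait/panel.
#' @param alpha removal threshold (0.005 by default).
#' @return data.frame with one row per gene: `gene`, `trait`, `p_orig`, `k`,
#'   `B`, `fdr_p`, `removed`, `reason` (`""`, or `"untested"` for genes with no
#'   overlapping blocks, which pass through as removed).
#' @export
apply_filter <- function(results, run, alpha = 0.005) {
  .assert(inherits(run, "permutation_run"), "run must be a permutation_run")
  miss <- setdiff(results$gene, rownames(run$permuted_p))
  .assert(length(miss) == 0L, "gene(s) missing from the permutation run: %s",
          paste(miss, collapse = ", "))
  B <- run$B
  M <- run$permuted_p[results$gene, , drop = FALSE]
  # k = #{b : p_b < p_orig}, strict: ties do not count against the gene
  k <- as.integer(rowSums(M < results$p_orig))
  fdr_p <- k / B
  out <- data.frame(gene = results$gene, trait = results$trait,
                    p_orig = results$p_orig, k = k, B = B, fdr_p = fdr_p,
                    removed = fdr_p > alpha, reason = "",
                    stringsAsFactors = FALSE)
  un <- which(results$untested)
  if (length(un)) {
    out$k[un] <- NA_integer_
    out$fdr_p[un] <- NA_real_
    out$removed[un] <- TRUE
    out$reason[un] <- "untested"
  }
  rownames(out) <- NULL
  out
}
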