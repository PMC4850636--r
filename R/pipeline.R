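# End-to-end driver: map every trait, permute, filter, integrate, rank.
# Blocks are enumerated once and the original scan shares the block loop with
# its B permutations (the original trait rides along as column 0), which keeps
# the full demo tractable on one CPU.

#' Run the full mapping / FDR / integration pipeline
#'
#' For each trait: the genome is scanned once on the observed values and B
#' times on permuted strain-to-value assignments (all traits drawing from one
#' seeded generator in trait order, so a run is reproducible end-to-end); the
#' gene-wise FDR filter is applied; finally per-trait results are integrated
#' into unfiltered and FDR-filtered composite rankings.
#'
#' @param genotypes a [genotype_matrix].
#' @param annotation a [gene_annotation].
#' @param phenotypes a [phenotype_table].
#' @param config an [hb_config()].
#' @param B permutations per trait.
#' @param alpha FDR removal threshold.
#' @param seed integer seed (mandatory).
#' @param traits traits to analyse (default: all in `phenotypes`).
#' @return A list of class `hb_result`: `results` (per-trait [map_trait()]
#'   tables), `runs` (per-trait `permutation_run`s), `filters` (per-trait
#'   [apply_filter()] tables), `unfiltered` and `filtered` ranked score tables,
#'   plus the parameters used.
#' @export
hb_pipeline <- function(genotypes, annotation, phenotypes, config = hb_config(),
                        B = 1000L, alpha = 0.005, seed,
                        traits = trait_names(phenotypes)) {
  .assert(.is_count(B), "B must be a positive integer")
  .assert(.is_count(seed, min = 0L), "seed must be a non-negative integer")
  .assert(length(traits) >= 1L, "no traits to analyse")
  gm <- validate_genotype_matrix(genotypes)
  blocks <- enumerate_blocks(gm, config$window_size, config$min_group_size)
  gidx <- .gene_block_index(annotation, blocks, config$flank_bp)
  set.seed(seed)
  results <- list(); runs <- list(); filters <- list()
  for (t in traits) {
    tv <- trait_vector(phenotypes, t)
    miss <- setdiff(names(tv), gm$strains)
    .assert(length(miss) == 0L,
            "phenotyped strain(s) absent from the genotype panel: %s",
            paste(miss, collapse = ", "))
    v <- rep(NA_real_, length(gm$strains))
    names(v) <- gm$strains
    v[names(tv)] <- tv
    avail <- which(!is.na(v))
    .assert(length(avail) >= 3L, "fewer than 3 phenotyped strains for trait '%s'", t)
    perm <- vapply(seq_len(B), function(b) sample.int(length(avail)),
                   integer(length(avail)))
    # column 1 = observed assignment, columns 2..B+1 = permutations
    V <- matrix(NA_real_, nrow = length(v), ncol = B + 1L)
    V[, 1L] <- v
    vals <- v[avail]
    for (b in seq_len(B)) V[avail, b + 1L] <- vals[perm[, b]]
    bp <- .blocks_p_matrix(blocks, V, config$p_floor)
    ngene <- nrow(annotation)
    p_orig <- rep(NA_real_, ngene)
    best <- rep(NA_integer_, ngene)
    ntest <- integer(ngene)
    permuted <- matrix(1, nrow = ngene, ncol = B,
                       dimnames = list(annotation$gene, NULL))
    for (i in seq_len(ngene)) {
      idx <- gidx[[i]]
      idx <- idx[!is.na(bp$p[idx, 1L])]
      ntest[i] <- length(idx)
      if (length(idx)) {
        j <- idx[which.min(bp$p[idx, 1L])]  # first minimum = left-most block
        best[i] <- j
        p_orig[i] <- bp$p[j, 1L]
        permuted[i, ] <- .col_mins(bp$p[idx, -1L, drop = FALSE])
      }
    }
    res <- data.frame(gene = annotation$gene, trait = t, p_orig = p_orig,
                      best_block = best, n_blocks_tested = ntest,
                      untested = ntest == 0L, stringsAsFactors = FALSE)
    run <- structure(list(trait = t, B = as.integer(B), seed = as.integer(seed),
                          perm = perm, strains = gm$strains[avail],
                          permuted_p = permuted),
                     class = "permutation_run")
    results[[t]] <- res
    runs[[t]] <- run
    filters[[t]] <- apply_filter(res, run, alpha)
  }
  unfiltered <- rank_genes(score_genes(results, p_floor = config$p_floor))
  filtered_scores <- score_genes(results, filters, p_floor = config$p_floor)
  filtered <- if (nrow(filtered_scores) > 0L) rank_genes(filtered_scores) else filtered_scores
  structure(list(results = results, runs = runs, filters = filters,
                 unfiltered = unfiltered, filtered = filtered,
                 config = config, B = as.integer(B), alpha = alpha,
                 seed = as.integer(seed), traits = traits,
                 n_blocks = length(blocks)),
            class = "hb_result")
}

#' @export
print.hb_result <- function(x, ...) {
  cat(sprintf("hb_result: %d traits, %d blocks, B = %d, alpha = %g, seed = %d\n",
              length(x$traits), x$n_blocks, x$B, x$alpha, x$seed))
  if (nrow(x$filtered) > 0L) {
    top <- utils::head(x$filtered, 5L)
    cat("top FDR-filtered genes:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %d. %s (Score %.1f)\n", top$rank[i], top$gene[i], top$score[i]))
    }
  } else {
    cat("no gene survived FDR filtering\n")
  }
  invisible(x)
}
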