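# Haplotype-block enumeration and block/gene association testing.
#
# A haplotype block is a window of `window_size` consecutive SNPs on one
# chromosome; the distinct allele strings over the window partition the
# strains into haplotype groups. Each partition is tested against strain-level
# trait means by one-way fixed-effects ANOVA, and a gene's p-value is the
# minimum over blocks whose span overlaps the (flanked) gene interval —
# deliberately uncorrected within gene, because min-p inflation across
# polymorphic genes is what the permutation FDR stage corrects.

#' Mapping configuration
#'
#' @param window_size SNPs per sliding window (stride 1).
#' @param min_group_size a candidate block is kept only if at least one
#'   haplotype group has this many strains.
#' @param flank_bp flank added on both sides of a gene interval when collecting
#'   overlapping blocks; the default 10 kb admits proximal regulatory variation.
#' @param p_floor smallest representable p-value; perfect-separation blocks
#'   (within-group SS = 0) are clamped here so -log10(p) stays finite.
#' @return A list of class `hb_config`.
#' @export
hb_config <- function(window_size = 3L, min_group_size = 2L,
                      flank_bp = 10000L, p_floor = 1e-300) {
  .assert(.is_count(window_size), "window_size must be a positive integer")
  .assert(.is_count(min_group_size), "min_group_size must be a positive integer")
  .assert(.is_count(flank_bp, min = 0L), "flank_bp must be a non-negative integer")
  .assert(.is_number(p_floor) && p_floor > 0 && p_floor < 1, "p_floor must be in (0, 1)")
  structure(list(window_size = as.integer(window_size),
                 min_group_size = as.integer(min_group_size),
                 flank_bp = as.integer(flank_bp), p_floor = p_floor),
            class = "hb_config")
}

# one-way fixed-effects ANOVA of every column of V across integer groups g.
# g: group index 1..ng per row of V (no NAs); V: n x K matrix.
# Returns F, p, dfs and degeneracy flags, vectorised over columns.
.anova_core <- function(g, V, p_floor = 1e-300) {
  V <- as.matrix(V)
  n <- length(g)
  ng <- max(g)
  sizes <- tabulate(g, ng)
  S <- rowsum(V, g, reorder = TRUE)              # ng x K group sums
  tot <- colSums(S)
  ssb <- colSums(S * S / sizes) - tot * tot / n
  sst <- colSums(V * V) - tot * tot / n
  ssw <- pmax(sst - ssb, 0)
  df1 <- ng - 1L
  df2 <- n - ng
  # scale-aware zero tests: sst ~ 0 means a constant trait
  scale2 <- pmax(colSums(V * V) / n, 1)
  const <- sst <= 1e-12 * n * scale2
  degenerate <- !const & ssw <= 1e-12 * pmax(sst, .Machine$double.xmin)
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  f[const] <- 0
  p[const] <- 1
  p <- pmax(p, p_floor)
  list(f = f, p = p, df_between = df1, df_within = df2,
       degenerate = degenerate, constant = const)
}

#' Enumerate candidate haplotype blocks
#'
#' Slides a window of `window_size` consecutive sites (stride 1) along each
#' chromosome. Strains with any missing call in the window sit that block out.
#' A candidate is kept only if at least two haplotype groups remain, at least
#' one group has `min_group_size` strains, and a downstream ANOVA would have
#' at least one within-group degree of freedom. Adjacent windows inducing an
#' identical strain partition are deduplicated (left-most kept): the minimum
#' over a gene's blocks is unchanged and redundant tests are avoided.
#'
#' @param genotypes a [genotype_matrix].
#' @param window_size,min_group_size see [hb_config()].
#' @return A list of class `haplotype_blocks`; each element records the
#'   chromosome, the site index range, the bp span `[span_start, span_end)`
#'   (0-based half-open), the per-strain group index (`NA` = not tested) and
#'   the group count.
#' @export
enumerate_blocks <- function(genotypes, window_size = 3L, min_group_size = 2L) {
  gm <- validate_genotype_matrix(genotypes)
  w <- as.integer(window_size)
  .assert(.is_count(w), "window_size must be a positive integer")
  n <- length(gm$strains)
  blocks <- vector("list", max(nrow(gm$sites), 1L))
  nb <- 0L
  for (chrom in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chrom)
    if (length(idx) < w) next
    last_key <- ""
    for (j in seq_len(length(idx) - w + 1L)) {
      cols <- idx[j:(j + w - 1L)]
      sub <- gm$calls[, cols, drop = FALSE]
      tested <- rowSums(is.na(sub)) == 0L
      nt <- sum(tested)
      if (nt < 3L) { last_key <- ""; next }
      hap <- do.call(paste0, lapply(seq_len(w), function(k) sub[tested, k]))
      gi <- match(hap, unique(hap))
      ng <- max(gi)
      if (ng < 2L || nt - ng < 1L || max(tabulate(gi, ng)) < min_group_size) {
        last_key <- ""
        next
      }
      key <- paste(paste(which(tested), collapse = ","),
                   paste(gi, collapse = ""), sep = "|")
      if (identical(key, last_key)) next
      last_key <- key
      groups <- rep(NA_integer_, n)
      groups[tested] <- gi
      nb <- nb + 1L
      blocks[[nb]] <- list(
        chrom = chrom,
        first_site = cols[1], last_site = cols[w],
        span_start = gm$sites$pos0[cols[1]],
        span_end = gm$sites$pos0[cols[w]] + 1L,
        groups = groups, n_groups = ng, n_tested = nt
      )
    }
  }
  structure(blocks[seq_len(nb)], class = "haplotype_blocks",
            strains = gm$strains, window_size = w)
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat(sprintf("haplotype_blocks: %d candidate blocks (window_size = %d, %d strains)\n",
              length(x), attr(x, "window_size"), length(attr(x, "strains"))))
  invisible(x)
}

# regroup a block's partition after intersecting with strains that have a
# phenotype value; returns NULL when < 2 groups or df_within < 1 remain
.block_grouping <- function(block, avail) {
  tested <- !is.na(block$groups) & avail
  gi <- block$groups[tested]
  gi <- match(gi, unique(gi))
  ng <- if (length(gi)) max(gi) else 0L
  if (ng < 2L || length(gi) - ng < 1L) return(NULL)
  list(rows = which(tested), g = gi, n_groups = ng)
}

#' Test one block against one trait by one-way ANOVA
#'
#' Strain-level trait means are compared across the block's haplotype groups
#' with a one-way fixed-effects ANOVA; the p-value is the upper tail of the F
#' distribution. If all values are identical the block carries F = 0, p = 1.
#' Perfect separation (within-group SS = 0 with between-group SS > 0) is
#' clamped to `p_floor` and flagged degenerate.
#'
#' @param block one element of [enumerate_blocks()] output.
#' @param trait_values named numeric vector, strain -> value.
#' @param p_floor see [hb_config()].
#' @return A list of class `block_association`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `degenerate`, `n_tested`, `n_groups`.
#' @export
block_association <- function(block, trait_values, p_floor = 1e-300) {
  strains <- names(trait_values)
  .assert(!is.null(strains) && all(nzchar(strains)),
          "trait_values must be a named vector (names = strains)")
  # caller aligns trait_values to the panel order used at enumeration time
  .assert(length(trait_values) == length(block$groups),
          "trait_values length (%d) must match the panel size (%d)",
          length(trait_values), length(block$groups))
  avail <- !is.na(trait_values)
  grp <- .block_grouping(block, avail)
  if (is.null(grp)) {
    stop("block skipped: fewer than 2 haplotype groups after intersecting with phenotyped strains",
         call. = FALSE)
  }
  core <- .anova_core(grp$g, matrix(trait_values[grp$rows], ncol = 1L), p_floor)
  structure(list(f_statistic = core$f[1], p_value = core$p[1],
                 df_between = core$df_between, df_within = core$df_within,
                 degenerate = core$degenerate[1], constant = core$constant[1],
                 n_tested = length(grp$rows), n_groups = grp$n_groups),
            class = "block_association")
}

# p-values for all blocks x all columns of V (n_strains x K, NA rows = strains
# without a phenotype value; the NA pattern must be identical across columns).
# Returns list(p = matrix blocks x K, f = numeric (first column), skipped).
.blocks_p_matrix <- function(blocks, V, p_floor = 1e-300) {
  V <- as.matrix(V)
  avail <- !is.na(V[, 1L])
  nbl <- length(blocks)
  P <- matrix(NA_real_, nrow = nbl, ncol = ncol(V))
  f1 <- rep(NA_real_, nbl)
  deg <- rep(FALSE, nbl)
  skipped <- 0L
  for (b in seq_len(nbl)) {
    grp <- .block_grouping(blocks[[b]], avail)
    if (is.null(grp)) { skipped <- skipped + 1L; next }
    core <- .anova_core(grp$g, V[grp$rows, , drop = FALSE], p_floor)
    P[b, ] <- core$p
    f1[b] <- core$f[1]
    deg[b] <- core$degenerate[1]
  }
  list(p = P, f = f1, degenerate = deg, skipped = skipped)
}

# indices of blocks whose bp span overlaps each flanked gene interval
.gene_block_index <- function(annotation, blocks, flank_bp) {
  bchrom <- vapply(blocks, `[[`, character(1), "chrom")
  bs <- vapply(blocks, `[[`, numeric(1), "span_start")
  be <- vapply(blocks, `[[`, numeric(1), "span_end")
  lapply(seq_len(nrow(annotation)), function(i) {
    which(bchrom == annotation$chrom[i] &
            bs < annotation$end[i] + flank_bp &
            be > annotation$start[i] - flank_bp)
  })
}

#' Aggregate block associations to a gene-level p-value
#'
#' The gene-level p-value is the minimum block p-value over blocks whose span
#' overlaps `[start - flank, end + flank)`. Ties are broken toward the
#' left-most block. A gene overlapped by zero tested blocks is returned in an
#' explicit untested state (`p_orig = NA`, `untested = TRUE`), never a silent
#' p = 1.
#'
#' @param gene one row of a [gene_annotation].
#' @param blocks a `haplotype_blocks` list.
#' @param block_p numeric vector of block p-values aligned with `blocks`
#'   (`NA` = skipped for this trait).
#' @param flank flank in bp.
#' @return A one-row data.frame: `gene`, `p_orig`, `best_block`,
#'   `n_blocks_tested`, `untested`.
#' @export
gene_pvalue <- function(gene, blocks, block_p, flank = 10000L) {
  idx <- .gene_block_index(gene, blocks, flank)[[1]]
  idx <- idx[!is.na(block_p[idx])]
  if (length(idx) == 0L) {
    return(data.frame(gene = gene$gene, p_orig = NA_real_, best_block = NA_integer_,
                      n_blocks_tested = 0L, untested = TRUE, stringsAsFactors = FALSE))
  }
  best <- idx[which.min(block_p[idx])]   # which.min takes the first (left-most) minimum
  data.frame(gene = gene$gene, p_orig = block_p[best], best_block = best,
             n_blocks_tested = length(idx), untested = FALSE, stringsAsFactors = FALSE)
}

#' Map one trait genome-wide
#'
#' Enumerates blocks once, tests every block against the trait and aggregates
#' to gene-level minimum p-values. Strains present in `trait_values` must all
#' exist in the genotype panel (exact, case-sensitive names); genotyped strains
#' without a value for this trait sit the analysis out.
#'
#' @param genotypes a [genotype_matrix].
#' @param annotation a [gene_annotation].
#' @param trait_values named numeric vector (strain -> strain-level mean), or a
#'   [phenotype_table] together with `trait`.
#' @param config an [hb_config()].
#' @param trait trait name when `trait_values` is a phenotype table.
#' @param blocks optional pre-enumerated `haplotype_blocks` (must come from the
#'   same genotypes/config) to avoid recomputation.
#' @return data.frame with one row per gene: `gene`, `trait`, `p_orig`,
#'   `best_block`, `n_blocks_tested`, `untested`. Blocks skipped for this trait
#'   are counted in the `skipped_blocks` attribute.
#' @export
map_trait <- function(genotypes, annotation, trait_values, config = hb_config(),
                      trait = NULL, blocks = NULL) {
  gm <- validate_genotype_matrix(genotypes)
  .assert(inherits(annotation, "gene_annotation"), "annotation must be a gene_annotation")
  .assert(nrow(annotation) > 0L, "no genes in annotation")
  if (inherits(trait_values, "phenotype_table")) {
    .assert(!is.null(trait), "supply `trait` when passing a phenotype_table")
    trait_values <- trait_vector(trait_values, trait)
  }
  trait_name <- if (is.null(trait)) "trait" else trait
  miss <- setdiff(names(trait_values), gm$strains)
  .assert(length(miss) == 0L,
          "phenotyped strain(s) absent from the genotype panel: %s",
          paste(miss, collapse = ", "))
  v <- rep(NA_real_, length(gm$strains))
  names(v) <- gm$strains
  v[names(trait_values)] <- trait_values
  .assert(sum(!is.na(v)) >= 3L,
          "fewer than 3 strains shared between genotypes and this trait")
  if (is.null(blocks)) {
    blocks <- enumerate_blocks(gm, config$window_size, config$min_group_size)
  }
  bp <- .blocks_p_matrix(blocks, matrix(v, ncol = 1L), config$p_floor)
  if (bp$skipped > 0L) {
    message(sprintf("map_trait(%s): %d block(s) skipped after phenotype intersection",
                    trait_name, bp$skipped))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i) {
    gene_pvalue(annotation[i, , drop = FALSE], blocks, bp$p[, 1L], config$flank_bp)
  }))
  res <- data.frame(gene = res$gene, trait = trait_name, res[-1],
                    stringsAsFactors = FALSE)
  attr(res, "skipped_blocks") <- bp$skipped
  attr(res, "n_blocks") <- length(blocks)
  res
}
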