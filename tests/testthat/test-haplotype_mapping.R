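test_that("sliding windows produce one candidate per window position", {
  # 4 sites, w = 3 -> 2 windows; partitions crafted to differ so no dedup
  gm <- gm_from_strings(c("0001", "0000", "0000", "1111", "1110", "1110"))
  blocks <- enumerate_blocks(gm, window_size = 3, min_group_size = 1)
  expect_length(blocks, 2L)
  expect_identical(vapply(blocks, `[[`, integer(1), "first_site"), c(1L, 2L))
  # bp spans are 0-based half-open over the window's SNP positions
  expect_identical(blocks[[1]]$span_start, 99L)
  expect_identical(blocks[[1]]$span_end, 300L)
})

test_that("monomorphic windows are discarded", {
  gm <- gm_from_strings(c("000", "000", "000", "000"))
  expect_length(enumerate_blocks(gm, 3, 1), 0L)
})

test_that("a window partitions strains into haplotype groups {3,2,1}", {
  gm <- gm_from_strings(c("000", "000", "000", "111", "111", "110"))
  blocks <- enumerate_blocks(gm, 3, min_group_size = 3)
  expect_length(blocks, 1L)
  b <- blocks[[1]]
  expect_identical(b$n_groups, 3L)
  expect_identical(sort(tabulate(b$groups), decreasing = TRUE), c(3L, 2L, 1L))
  expect_identical(b$n_tested - b$n_groups, 3L)  # df_within = 3 >= 1 -> kept
  # min_group_size above the largest group kills the candidate
  expect_length(enumerate_blocks(gm, 3, min_group_size = 4), 0L)
})

test_that("strains with missing calls sit the block out", {
  gm <- gm_from_strings(c("000", "0.0", "111", "111", "000"))
  blocks <- enumerate_blocks(gm, 3, 1)
  expect_length(blocks, 1L)
  expect_true(is.na(blocks[[1]]$groups[2]))
  expect_identical(blocks[[1]]$n_tested, 4L)
})

test_that("adjacent windows with identical partitions are deduplicated", {
  # all 4 columns induce the same {1,2,3 | 4,5,6} split -> windows 1-3 and 2-4
  # share a partition; only the left-most survives
  gm <- gm_from_strings(c("0000", "0000", "0000", "1111", "1111", "1111"))
  blocks <- enumerate_blocks(gm, 3, 1)
  expect_length(blocks, 1L)
  expect_identical(blocks[[1]]$first_site, 1L)
})

test_that("block ANOVA agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(6:24, 1)
    ng <- sample(2:4, 1)
    g <- sample(rep_len(seq_len(ng), n))
    v <- rnorm(n)
    core <- hbcgm:::.anova_core(g, matrix(v, ncol = 1))
    oracle <- oracle_anova(v, g)
    expect_equal(core$f[1], oracle$f, tolerance = 1e-10)
    expect_equal(core$p[1], oracle$p, tolerance = 1e-10)
    expect_identical(core$df_between, oracle$df1)
    expect_identical(core$df_within, oracle$df2)
  }
})

test_that("block_association handles degenerate inputs per the stated rules", {
  gm <- gm_from_strings(c("000", "000", "000", "111", "111", "111"))
  b <- enumerate_blocks(gm, 3, 1)[[1]]
  v <- c(s01 = 2, s02 = 2, s03 = 2, s04 = 2, s05 = 2, s06 = 2)
  a <- block_association(b, v)
  expect_identical(a$f_statistic, 0)
  expect_identical(a$p_value, 1)

  # perfect separation: within SS = 0, between SS > 0 -> p clamped, flagged
  v2 <- c(s01 = 1, s02 = 1, s03 = 1, s04 = 2, s05 = 2, s06 = 2)
  a2 <- block_association(b, v2, p_floor = 1e-300)
  expect_identical(a2$p_value, 1e-300)
  expect_true(a2$degenerate)

  # ordinary two-group case against the oracle
  v3 <- c(s01 = 1.0, s02 = 1.2, s03 = 0.8, s04 = 3.0, s05 = 3.2, s06 = 2.8)
  a3 <- block_association(b, v3)
  o3 <- oracle_anova(unname(v3), c(1, 1, 1, 2, 2, 2))
  expect_equal(a3$f_statistic, o3$f, tolerance = 1e-10)
  expect_equal(a3$p_value, o3$p, tolerance = 1e-10)

  # intersection with phenotyped strains can collapse the partition
  v4 <- c(s01 = 1, s02 = 2, s03 = 3, s04 = NA, s05 = NA, s06 = NA)
  expect_error(block_association(b, v4), "fewer than 2 haplotype groups")
})

test_that("gene_pvalue takes the minimum over overlapping blocks", {
  blocks <- structure(list(
    list(chrom = "chr1", span_start = 100L, span_end = 130L),
    list(chrom = "chr1", span_start = 200L, span_end = 230L),
    list(chrom = "chr1", span_start = 300L, span_end = 330L),
    list(chrom = "chr2", span_start = 100L, span_end = 130L)
  ), class = "haplotype_blocks")
  gene <- gene_annotation("g1", "chr1", 50, 400)
  r <- gene_pvalue(gene, blocks, c(0.2, 0.01, 0.5, 1e-9), flank = 0)
  expect_identical(r$p_orig, 0.01)       # chr2 block never considered
  expect_identical(r$best_block, 2L)
  expect_identical(r$n_blocks_tested, 3L)
  expect_false(r$untested)

  # ties break to the left-most block
  r2 <- gene_pvalue(gene, blocks, c(0.01, 0.01, 0.5, 1), flank = 0)
  expect_identical(r2$best_block, 1L)

  # zero overlap -> explicit untested sentinel, never a silent p = 1
  far <- gene_annotation("g2", "chr1", 5000, 6000)
  r3 <- gene_pvalue(far, blocks, c(0.2, 0.01, 0.5, 1), flank = 10)
  expect_true(r3$untested)
  expect_true(is.na(r3$p_orig))
  expect_identical(r3$n_blocks_tested, 0L)

  # the flank pulls nearby blocks in
  r4 <- gene_pvalue(far, blocks, c(0.2, 0.01, 0.5, 1), flank = 10000)
  expect_false(r4$untested)
})

test_that("map_trait is deterministic and invariant to gene record order", {
  sim <- small_sim(11)
  tv <- trait_vector(sim$phenotypes, "tolerance")
  r1 <- map_trait(sim$genotypes, sim$annotation, tv)
  r2 <- map_trait(sim$genotypes, sim$annotation, tv)
  expect_identical(r1, r2)

  shuffled <- sim$annotation[c(3, 1, 2), , drop = FALSE]
  class(shuffled) <- class(sim$annotation)
  r3 <- map_trait(sim$genotypes, shuffled, tv)
  expect_identical(r3$p_orig[match(r1$gene, r3$gene)], r1$p_orig)
})

test_that("a planted 2-sigma effect is detected in >= 95 of 100 replicates", {
  hits <- 0L
  beats_null <- 0L
  for (r in 1:100) {
    sim <- small_sim(1000 + r, n_genes = 2)
    res <- map_trait(sim$genotypes, sim$annotation,
                     trait_vector(sim$phenotypes, "tolerance"))
    p_causal <- res$p_orig[res$gene == "gene_causal"]
    if (p_causal < 0.05) hits <- hits + 1L
    if (p_causal < res$p_orig[res$gene == "g01"]) beats_null <- beats_null + 1L
  }
  expect_gte(hits, 95L)
  expect_gt(beats_null, 50L)  # the causal gene attains the smaller p
})

test_that("null block p-values are uniform and min-p inflates with block count", {
  # one panel, many independent null traits ride along as matrix columns
  genes <- data.frame(name = c("small5", "big200"), n_blocks = c(5L, 200L))
  sim <- simulate_panel(sim_config(seed = 77, genes = genes,
                                   causal_gene = "small5", effect_size = 0))
  blocks <- enumerate_blocks(sim$genotypes)
  set.seed(78)
  V <- matrix(rnorm(24 * 500), nrow = 24)
  rownames(V) <- sim$genotypes$strains
  bp <- hbcgm:::.blocks_p_matrix(blocks, V)
  ks <- suppressWarnings(stats::ks.test(as.vector(bp$p[, 1:20]), "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  gidx <- hbcgm:::.gene_block_index(sim$annotation, blocks, 0L)
  min_small <- apply(bp$p[gidx[[1]], ], 2, min)
  min_big <- apply(bp$p[gidx[[2]], ], 2, min)
  # stochastically smaller min-p for the polymorphic gene: the inflation the
  # FDR filter exists to correct
  expect_lt(median(min_big), median(min_small))
  expect_gt(mean(min_big < min_small), 0.9)
})
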