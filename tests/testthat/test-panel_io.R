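test_that("TSV genotype round-trip is lossless and sites are sorted", {
  gm <- gm_from_strings(c("01", "10", "11"), strains = c("A", "B", "C"))
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  back <- load_genotypes(path, "tsv")
  expect_identical(back$strains, gm$strains)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$sites$pos0, gm$sites$pos0)
  expect_identical(length(back$calls), 6L)

  # unsorted rows are re-sorted with a warning
  lines <- readLines(path)
  expect_warning(load_genotypes(write_tsv_fixture(lines[c(1, 3, 2)]), "tsv"),
                 "re-sorting")
})

test_that("TSV loader rejects malformed input", {
  ok <- c("chrom\tpos\tid\tref\talt\tA\tB\tC",
          "chr1\t100\tsnp1\tA\tG\t0\t1\t.")
  expect_s3_class(load_genotypes(write_tsv_fixture(ok), "tsv"), "genotype_matrix")

  dup <- sub("A\tB\tC", "A\tA\tC", ok[1])
  expect_error(load_genotypes(write_tsv_fixture(c(dup, ok[2])), "tsv"),
               "duplicate strain")
  short <- c(ok, "chr1\t200\tsnp2\tA\tG\t0\t1")
  expect_error(load_genotypes(write_tsv_fixture(short), "tsv"), "line 3")
  badcall <- c(ok, "chr1\t200\tsnp2\tA\tG\t0\t2\t1")
  expect_error(load_genotypes(write_tsv_fixture(badcall), "tsv"), "malformed genotype call")
  duppos <- c(ok, "chr1\t100\tsnp2\tA\tG\t0\t1\t1")
  expect_error(load_genotypes(write_tsv_fixture(duppos), "tsv"), "duplicate position")
})

test_that("panel must have at least 3 uniquely named strains", {
  expect_error(gm_from_strings(c("01", "10")), "at least 3 strains")
  expect_error(gm_from_strings(c("01", "10", "11"), strains = c("A", "A", "B")),
               "duplicate strain")
})

test_that("VCF loader maps genotypes and agrees with the TSV loader", {
  skip_if_not_installed("VariantAnnotation")
  body <- c(
    "chr1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "chr1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1|1\t./.\t0/0",
    "chr1\t300\tsnp3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t1/1\t1/1"  # multi-allelic
  )
  path <- write_vcf_fixture(body, c("A", "B", "C"))
  expect_warning(vg <- load_genotypes(path, "vcf"), "non-biallelic")
  expect_identical(nrow(vg$sites), 2L)              # multi-allelic skipped
  expect_identical(vg$calls[, 1], c(A = 0L, B = 1L, C = NA))  # 0/1 -> missing
  expect_identical(vg$calls[, 2], c(A = 1L, B = NA, C = 0L))

  tsv <- c("chrom\tpos\tid\tref\talt\tA\tB\tC",
           "chr1\t100\tsnp1\tA\tG\t0\t1\t.",
           "chr1\t200\tsnp2\tC\tT\t1\t.\t0")
  tg <- load_genotypes(write_tsv_fixture(tsv), "tsv")
  expect_identical(unname(tg$calls), unname(vg$calls))
  expect_identical(tg$sites$pos0, vg$sites$pos0)
  expect_identical(tg$strains, vg$strains)
})

test_that("phenotype CSV loading handles absent and malformed cells", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("strain,tolerance,mech_oih",
               "A,1.5,20",
               "B,,30",
               "C,2.5,40"), path)
  pt <- load_phenotypes(path)
  expect_identical(trait_names(pt), c("tolerance", "mech_oih"))
  expect_identical(names(trait_vector(pt, "tolerance")), c("A", "C"))
  expect_identical(names(trait_vector(pt, "mech_oih")), c("A", "B", "C"))

  writeLines(c("strain,tolerance", "A,1.5", "B,abc"), path)
  expect_error(load_phenotypes(path), "strain 'B'.*'abc'")

  # round-trip through the writer
  sim <- small_sim(3)
  p2 <- tempfile(fileext = ".csv")
  write_phenotypes(sim$phenotypes, p2)
  back <- load_phenotypes(p2)
  expect_equal(as.data.frame(back), as.data.frame(sim$phenotypes),
               tolerance = 1e-12)
  expect_length(trait_names(back), 6L)
})

test_that("a phenotyped strain absent from the genotype panel is an error, not a drop", {
  sim <- small_sim(4)
  tv <- trait_vector(sim$phenotypes, "tolerance")
  names(tv)[1] <- "not_a_strain"
  expect_error(map_trait(sim$genotypes, sim$annotation, tv),
               "absent from the genotype panel.*not_a_strain")
})

test_that("BED annotation loading validates records", {
  skip_if_not_installed("rtracklayer")
  path <- tempfile(fileext = ".bed")
  writeLines("chr4\t100\t200\tMpdz", path)
  ann <- load_gene_annotation(path)
  expect_identical(ann$gene, "Mpdz")
  expect_identical(ann$start, 100L)
  expect_identical(ann$end, 200L)      # 0-based half-open preserved

  writeLines(c("chr4\t100\t200\tMpdz", "chr5\t10\t20\tMpdz"), path)
  expect_error(load_gene_annotation(path), "duplicate gene")

  writeLines(character(0), path)
  empty <- load_gene_annotation(path)
  expect_identical(nrow(empty), 0L)
  sim <- small_sim(5)
  expect_error(map_trait(sim$genotypes, empty,
                         trait_vector(sim$phenotypes, "tolerance")),
               "no genes")

  expect_error(gene_annotation("g1", "chr1", 200, 100), "start >= end")

  # writer round-trip
  p2 <- tempfile(fileext = ".bed")
  write_gene_annotation(sim$annotation, p2)
  expect_equal(as.data.frame(load_gene_annotation(p2)),
               as.data.frame(sim$annotation))
})

test_that("rank tables round-trip scores at full precision", {
  scores <- rank_genes(structure(
    data.frame(gene = c("b_gene", "a_gene", "c_gene"),
               score = c(12.0, 12.0, 4 * pi), stringsAsFactors = FALSE),
    class = c("gene_scores", "data.frame")))
  expect_identical(scores$gene, c("c_gene", "a_gene", "b_gene"))
  path <- tempfile(fileext = ".tsv")
  write_rank_table(scores, path)
  back <- read_rank_table(path)
  expect_identical(back$rank, 1:3)
  expect_identical(back$score_full, scores$score)   # full precision
  expect_identical(back$Score, c("12.6", "12.0", "12.0"))

  one <- rank_genes(structure(
    data.frame(gene = "g", score = 12.0, stringsAsFactors = FALSE),
    class = c("gene_scores", "data.frame")))
  write_rank_table(one, path)
  expect_identical(read_rank_table(path)$rank, 1L)
  expect_error(write_rank_table(one[0, ], path), "at least one gene")
})
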