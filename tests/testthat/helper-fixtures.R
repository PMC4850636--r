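# Programmatic fixtures: small genotype matrices built from haplotype strings,
# plus writers for the on-disk dialects.

# haps: character vector, one allele string per strain ("0"/"1" per site)
gm_from_strings <- function(haps, chrom = "chr1", pos = NULL,
                            strains = sprintf("s%02d", seq_along(haps))) {
  n_sites <- nchar(haps[1])
  calls <- t(vapply(strsplit(haps, ""), function(x) {
    v <- suppressWarnings(as.integer(x))  # "." -> NA
    v
  }, integer(n_sites)))
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n_sites)
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos0 = pos - 1L,
                             id = sprintf("snp%d", seq_len(n_sites)),
                             ref = "A", alt = "G", stringsAsFactors = FALSE),
                  strains)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
)

write_vcf_fixture <- function(body, samples, path = tempfile(fileext = ".vcf")) {
  head <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c(vcf_header, head, body), path)
  path
}

# a small mapped panel shared by several tests: 3 genes x 5 blocks
small_sim <- function(seed, effect_size = 2, n_genes = 3, n_blocks = 5,
                      causal_traits = c("tolerance", "mech_oih", "weight_change")) {
  genes <- data.frame(
    name = c(sprintf("g%02d", seq_len(n_genes - 1)), "gene_causal"),
    n_blocks = rep(n_blocks, n_genes), stringsAsFactors = FALSE
  )
  simulate_panel(sim_config(seed = seed, genes = genes,
                            effect_size = effect_size,
                            causal_traits = causal_traits))
}
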