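# On-disk formats and validated in-memory containers.
#
# Internal coordinate convention: 0-based half-open everywhere. SNP sites carry
# `pos0` (0-based position of the base); TSV/VCF positions are 1-based on disk
# and converted at the boundary only. Gene annotations use BED-native 0-based
# half-open [start, end).

#' Construct a validated genotype matrix
#'
#' A genotype matrix holds biallelic SNP calls for a panel of inbred strains.
#' Because inbred strains are homozygous, a call is a single allele code:
#' `0` (reference), `1` (alternate) or `NA` (missing). Strains are rows, sites
#' are columns.
#'
#' @param calls integer matrix, strains x sites, values in \{0, 1, NA\}.
#' @param sites data.frame with columns `chrom`, `pos0` (0-based position),
#'   `id`, `ref`, `alt`; one row per site, same order as `calls` columns.
#' @param strains character vector of unique strain names (rows of `calls`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, strains) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  rownames(calls) <- strains
  gm <- structure(
    list(strains = as.character(strains), sites = as.data.frame(sites), calls = calls),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: at least 3 uniquely named strains, sites
#' sorted by (chromosome, position) with unique positions per chromosome, and
#' every call in \{0, 1, NA\}. Sites are re-sorted with a warning if needed.
#'
#' @param gm a `genotype_matrix`.
#' @return The validated (possibly re-sorted) object, invisibly classed.
#' @export
validate_genotype_matrix <- function(gm) {
  s <- gm$strains
  .assert(length(s) >= 3L, "panel must contain at least 3 strains, got %d", length(s))
  .assert(all(nzchar(s)), "strain names must be non-empty")
  .assert(!anyDuplicated(s), "duplicate strain name: %s", s[duplicated(s)][1])
  st <- gm$sites
  need <- c("chrom", "pos0", "id", "ref", "alt")
  .assert(all(need %in% names(st)), "sites table must have columns %s",
          paste(need, collapse = ", "))
  .assert(nrow(st) == ncol(gm$calls), "sites (%d) and call columns (%d) differ",
          nrow(st), ncol(gm$calls))
  .assert(nrow(gm$calls) == length(s), "strains (%d) and call rows (%d) differ",
          length(s), nrow(gm$calls))
  o <- order(st$chrom, st$pos0)
  if (!identical(o, seq_len(nrow(st)))) {
    warning("genotype sites were not sorted by (chromosome, position); re-sorting")
    gm$sites <- st[o, , drop = FALSE]
    rownames(gm$sites) <- NULL
    gm$calls <- gm$calls[, o, drop = FALSE]
    st <- gm$sites
  }
  dup <- duplicated(paste(st$chrom, st$pos0))
  .assert(!any(dup), "duplicate position within chromosome %s at %d",
          st$chrom[dup][1], if (any(dup)) st$pos0[dup][1] + 1L else 0L)
  v <- gm$calls
  bad <- !(is.na(v) | v == 0L | v == 1L)
  .assert(!any(bad), "genotype calls must be 0, 1 or missing; found %s",
          paste(unique(v[bad]), collapse = ","))
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d sites on %d chromosome(s); %d missing calls\n",
              length(x$strains), nrow(x$sites),
              length(unique(x$sites$chrom)), sum(is.na(x$calls))))
  invisible(x)
}

#' Read a genotype matrix
#'
#' Two dialects are supported. The project TSV dialect has a header row
#' `chrom pos id ref alt <strain...>` followed by one row per site; calls are
#' `0`, `1` or `.` (missing); positions are 1-based. VCF input (4.x, plain
#' text) consumes biallelic SNP records only: `0/0` becomes 0, `1/1` becomes 1,
#' and missing or heterozygous genotypes become missing (inbred panels carry no
#' heterozygous state). Multi-allelic or non-SNP records are skipped with a
#' warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A validated [genotype_matrix].
#' @export
load_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  .assert(file.exists(path), "genotype file not found: %s", path)
  switch(format, tsv = .read_geno_tsv(path), vcf = .read_geno_vcf(path))
}

.read_geno_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 1L, "empty genotype file: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fixed <- c("chrom", "pos", "id", "ref", "alt")
  .assert(length(header) > 5L && identical(header[1:5], fixed),
          "genotype TSV header must start with '%s'", paste(fixed, collapse = "\t"))
  strains <- header[-(1:5)]
  .assert(!anyDuplicated(strains), "duplicate strain column: %s",
          strains[duplicated(strains)][1])
  n <- length(strains)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = n, ncol = length(rows))
  chrom <- character(length(rows)); pos <- integer(length(rows))
  id <- character(length(rows)); ref <- character(length(rows)); alt <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    .assert(length(r) == 5L + n, "malformed genotype row at line %d: expected %d fields, got %d",
            i + 1L, 5L + n, length(r))
    p <- suppressWarnings(as.integer(r[2]))
    .assert(!is.na(p) && p >= 1L, "malformed position at line %d: '%s'", i + 1L, r[2])
    chrom[i] <- r[1]; pos[i] <- p; id[i] <- r[3]; ref[i] <- r[4]; alt[i] <- r[5]
    g <- r[-(1:5)]
    bad <- !(g %in% c("0", "1", "."))
    .assert(!any(bad), "malformed genotype call '%s' at line %d", g[bad][1], i + 1L)
    gi <- suppressWarnings(as.integer(g))
    calls[, i] <- gi
  }
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos0 = pos - 1L, id = id,
                             ref = ref, alt = alt, stringsAsFactors = FALSE),
                  strains)
}

.read_geno_vcf <- function(path) {
  .assert(requireNamespace("VariantAnnotation", quietly = TRUE),
          "package 'VariantAnnotation' is required to read VCF input")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  keep <- n_alt == 1L & nchar(ref) == 1L
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))
  keep <- keep & !is.na(alt1) & nchar(alt1) == 1L
  if (any(!keep)) {
    warning(sprintf("skipped %d non-biallelic-SNP VCF record(s)", sum(!keep)))
  }
  .assert(any(keep), "no biallelic SNP records in VCF: %s", path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  strains <- colnames(gt)
  .assert(!anyDuplicated(strains), "duplicate strain column: %s",
          strains[duplicated(strains)][1])
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt %in% c("0/0", "0|0", "0")] <- 0L
  code[gt %in% c("1/1", "1|1", "1")] <- 1L
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(gt)))
  genotype_matrix(t(code),
                  data.frame(chrom = as.character(rr$seqnames[keep]),
                             pos0 = as.integer(rr$start[keep]) - 1L,
                             id = ids, ref = ref[keep], alt = alt1[keep],
                             stringsAsFactors = FALSE),
                  strains)
}

#' Write a genotype matrix in the project TSV dialect
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  st <- gm$sites
  g <- t(gm$calls)
  g[is.na(g)] <- "."
  out <- cbind(st$chrom, st$pos0 + 1L, st$id, st$ref, st$alt, g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chrom", "pos", "id", "ref", "alt", gm$strains), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Construct a strain-level phenotype table
#'
#' @param df data.frame with a `strain` column and one numeric column per trait.
#'   `NA` marks a strain with no value for that trait (dropped from that
#'   trait's analysis only).
#' @return An object of class `phenotype_table` (a data.frame).
#' @export
phenotype_table <- function(df) {
  .assert(is.data.frame(df) && "strain" %in% names(df),
          "phenotype table needs a 'strain' column")
  df$strain <- as.character(df$strain)
  .assert(!anyDuplicated(df$strain), "duplicate strain in phenotype table: %s",
          df$strain[duplicated(df$strain)][1])
  traits <- setdiff(names(df), "strain")
  .assert(length(traits) >= 1L, "phenotype table has no trait columns")
  for (t in traits) {
    .assert(is.numeric(df[[t]]), "trait column '%s' is not numeric", t)
    .assert(all(is.finite(df[[t]]) | is.na(df[[t]])),
            "non-finite value in trait '%s'", t)
  }
  structure(df, class = c("phenotype_table", "data.frame"))
}

#' List the trait columns of a phenotype table
#' @param pt a [phenotype_table].
#' @return Character vector of trait names.
#' @export
trait_names <- function(pt) setdiff(names(pt), "strain")

#' Extract one trait as a named strain vector
#'
#' Strains with a missing cell are dropped (absent, not imputed).
#'
#' @param pt a [phenotype_table].
#' @param trait trait column name.
#' @return Named numeric vector, names are strains.
#' @export
trait_vector <- function(pt, trait) {
  .assert(trait %in% trait_names(pt), "unknown trait '%s'", trait)
  v <- pt[[trait]]
  names(v) <- pt$strain
  v[!is.na(v)]
}

#' Read a CSV phenotype table
#'
#' Expects a `strain` column plus one column per trait; empty cells become
#' absent values. A non-numeric cell is a parse error naming the cell.
#'
#' @param path CSV file path.
#' @return A [phenotype_table].
#' @export
load_phenotypes <- function(path) {
  .assert(file.exists(path), "phenotype file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  .assert("strain" %in% names(df), "phenotype CSV needs a 'strain' column")
  for (t in setdiff(names(df), "strain")) {
    raw <- df[[t]]
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    .assert(length(bad) == 0L,
            "non-numeric phenotype cell for trait '%s', strain '%s': '%s'",
            t, if (length(bad)) df$strain[bad[1]] else "", if (length(bad)) raw[bad[1]] else "")
    df[[t]] <- num
  }
  phenotype_table(df)
}

#' Write a phenotype table as CSV
#' @param pt a [phenotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pt, path) {
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' Coordinates are 0-based half-open (BED-native). Gene names must be unique
#' and every interval non-empty.
#'
#' @param gene character vector of gene names.
#' @param chrom chromosome per gene.
#' @param start,end 0-based half-open interval per gene.
#' @return An object of class `gene_annotation` (a data.frame).
#' @export
gene_annotation <- function(gene, chrom, start, end) {
  df <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  .assert(!anyDuplicated(df$gene), "duplicate gene name: %s",
          df$gene[duplicated(df$gene)][1])
  bad <- df$start >= df$end
  .assert(!any(bad), "gene '%s' has start >= end (%d >= %d)",
          df$gene[bad][1], if (any(bad)) df$start[bad][1] else 0L,
          if (any(bad)) df$end[bad][1] else 0L)
  structure(df, class = c("gene_annotation", "data.frame"))
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk, which matches the internal convention; the
#' name field is the gene name. An empty file yields an empty annotation
#' (downstream mapping then fails with a "no genes" error).
#'
#' @param path BED file path.
#' @return A [gene_annotation].
#' @export
load_gene_annotation <- function(path) {
  .assert(file.exists(path), "annotation file not found: %s", path)
  lines <- readLines(path)
  if (!any(nzchar(trimws(lines)))) {
    return(structure(data.frame(gene = character(), chrom = character(),
                                start = integer(), end = integer(),
                                stringsAsFactors = FALSE),
                     class = c("gene_annotation", "data.frame")))
  }
  .assert(requireNamespace("rtracklayer", quietly = TRUE),
          "package 'rtracklayer' is required to read BED input")
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  .assert("name" %in% names(df) && all(nzchar(df$name)),
          "BED name field (column 4) must carry the gene name")
  # rtracklayer converts BED to 1-based closed; undo at the boundary
  gene_annotation(df$name, as.character(df$seqnames), df$start - 1L, df$end)
}

#' Write gene intervals as BED
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(ann[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ranked gene table
#'
#' Emits one row per gene sorted by rank with, when per-trait details are
#' supplied, columns `p_<trait>`, `fdr_p_<trait>` and `removed_<trait>`.
#' `Score` is the display column rounded to 1 decimal; `score_full` keeps full
#' precision for machine round-trips.
#'
#' @param scores ranked gene scores from [rank_genes()].
#' @param path output path.
#' @param results optional named list (by trait) of [map_trait()] results.
#' @param filters optional named list (by trait) of [apply_filter()] results.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(scores, path, results = NULL, filters = NULL) {
  .assert(is.data.frame(scores) && nrow(scores) > 0L, "rank table needs at least one gene")
  out <- data.frame(gene = scores$gene, stringsAsFactors = FALSE)
  if (!is.null(results)) {
    for (t in names(results)) {
      r <- results[[t]]
      out[[paste0("p_", t)]] <-
        sprintf("%.17g", r$p_orig[match(scores$gene, r$gene)])
      if (!is.null(filters) && t %in% names(filters)) {
        f <- filters[[t]]
        i <- match(scores$gene, f$gene)
        out[[paste0("fdr_p_", t)]] <- sprintf("%.17g", f$fdr_p[i])
        out[[paste0("removed_", t)]] <- f$removed[i]
      }
    }
  }
  out$Score <- sprintf("%.1f", scores$score)
  out$score_full <- sprintf("%.17g", scores$score)
  out$rank <- scores$rank
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a ranked gene table
#' @param path TSV written by [write_rank_table()].
#' @return data.frame with `gene`, numeric `score_full` and `rank`.
#' @export
read_rank_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(Score = "character"))
  df$score_full <- as.numeric(df$score_full)
  df
}
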