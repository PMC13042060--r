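#' Write a dosage matrix as VCF 4.2
#'
#' Donors become sample columns; genotypes are emitted as unphased GT calls
#' (`0/0`, `0/1`, `1/1`) on 1-based coordinates. REF/ALT are placeholder
#' A/G alleles since the generator models dosages, not sequences.
#'
#' @param geno List with `dosage` (donors x SNPs) and `snps` tibble
#'   (snp_id, chrom, pos, maf), as from [generate_genotypes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  dos <- geno$dosage
  snps <- geno$snps
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(sub("^chr", "", snps$chrom[i]), snps$pos[i], snps$snp_id[i],
            "A", "G", ".", "PASS", ".", "GT", gt[dos[, i] + 1L]),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strivar",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Parses with \pkg{vcfR} and converts GT fields to alternate-allele dosages.
#'
#' @param path VCF file path.
#' @return List with `dosage` (donors x SNPs integer matrix) and `snps`
#'   tibble (snp_id, chrom, pos).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt),
                                       dimnames = list(rownames(gt), colnames(gt)))
  fix <- vcfR::getFIX(v)
  list(
    dosage = t(dos),
    snps = tibble::tibble(snp_id = unname(fix[, "ID"]),
                          chrom = unname(fix[, "CHROM"]),
                          pos = as.integer(fix[, "POS"]))
  )
}

#' Write a generated cohort to plain-text files
#'
#' Emits `donors.tsv`, `samples.tsv` (long counts), `genes.tsv`,
#' `genotypes.vcf` (if genotypes supplied), per-(cell type, region)
#' pseudobulk TSVs (genes x donors), and `truth.json` carrying every
#' generating parameter.
#'
#' @param dir Output directory (created if absent).
#' @param donors,truth Cohort pieces from [generate_cohort()].
#' @param samples Optional counts tibble.
#' @param geno Optional genotypes.
#' @param pb_set Optional pseudobulk set.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dir, donors, truth, samples = NULL, geno = NULL,
                         pb_set = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(donors, file.path(dir, "donors.tsv"))
  if (!is.null(samples)) readr::write_tsv(samples, file.path(dir, "samples.tsv"))
  if (!is.null(truth$config$genes)) {
    readr::write_tsv(truth$config$genes$genes, file.path(dir, "genes.tsv"))
  }
  if (!is.null(geno)) write_vcf(geno, file.path(dir, "genotypes.vcf"))
  if (!is.null(pb_set)) {
    for (i in seq_len(nrow(pb_set))) {
      pb <- pb_set$pb[[i]]
      tab <- tibble::as_tibble(t(pb$counts), rownames = "gene_id")
      readr::write_tsv(tab, file.path(dir, sprintf(
        "pseudobulk_%s_%s.tsv", pb$cell_type, pb$region)))
    }
  }
  tr <- truth
  tr$u <- as.data.frame(tr$u)
  tr$bio_age_offset <- as.data.frame(tr$bio_age_offset)
  tr$config$celltypes <- lapply(tr$config$celltypes, unclass)
  if (!is.null(tr$config$genes)) {
    tr$config$genes <- list(
      genes = tr$config$genes$genes,
      age_l2fc = as.data.frame(tr$config$genes$age_l2fc),
      eqtl_beta = as.data.frame(tr$config$genes$eqtl_beta),
      snps = tr$config$genes$snps
    )
  }
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read sparse nucleus-level counts in Matrix Market format
#'
#' Thin wrapper over [Matrix::readMM()] attaching feature and barcode names
#' from companion TSVs (one id per line, no header).
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param features_path,barcodes_path Companion TSV paths.
#' @return A `dgCMatrix` with genes as rows and barcodes as columns.
#' @export
read_counts_mtx <- function(mtx_path, features_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  rownames(m) <- readr::read_tsv(features_path, col_names = "id",
                                 show_col_types = FALSE)$id
  colnames(m) <- readr::read_tsv(barcodes_path, col_names = "id",
                                 show_col_types = FALSE)$id
  m
}
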