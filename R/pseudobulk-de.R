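#' Aggregate nucleus-level counts into pseudobulk
#'
#' Sums UMI counts over nuclei per (donor, cell type, region); donors
#' contributing fewer than `min_cells` nuclei to a group are excluded and
#' logged. Nucleus order is irrelevant.
#'
#' @param counts Sparse genes-by-barcodes matrix (e.g. from
#'   [read_counts_mtx()]).
#' @param assignments Tibble with columns `barcode`, `donor_id`,
#'   `cell_type`, `region` covering the matrix columns.
#' @param min_cells Minimum nuclei per donor per group (default 10).
#' @return List: `pb_set` (a `pseudobulk_set`) and `excluded` tibble
#'   (donor_id, cell_type, region, n_cells).
#' @export
aggregate_pseudobulk <- function(counts, assignments, min_cells = 10) {
  missing <- setdiff(colnames(counts), assignments$barcode)
  if (length(missing)) {
    abort(sprintf("%d barcodes in the matrix lack assignments (e.g. %s).",
                  length(missing), missing[1]))
  }
  asg <- assignments[match(colnames(counts), assignments$barcode), ]
  grp <- paste(asg$donor_id, asg$cell_type, asg$region, sep = "\r")
  glev <- unique(grp)
  ind <- Matrix::sparseMatrix(i = seq_along(grp),
                              j = match(grp, glev),
                              x = 1, dims = c(length(grp), length(glev)))
  agg <- as.matrix(counts %*% ind)  # genes x groups
  meta <- do.call(rbind, strsplit(glev, "\r"))
  meta <- tibble::tibble(donor_id = meta[, 1], cell_type = meta[, 2],
                         region = meta[, 3],
                         n_cells = as.integer(table(grp)[glev]))
  keep <- meta$n_cells >= min_cells
  excluded <- meta[!keep, ]
  meta <- meta[keep, ]
  agg <- agg[, keep, drop = FALSE]
  groups <- dplyr::distinct(meta, .data$cell_type, .data$region)
  pbs <- purrr::pmap(groups, function(cell_type, region) {
    sel <- meta$cell_type == cell_type & meta$region == region
    m <- t(agg[, sel, drop = FALSE])
    rownames(m) <- meta$donor_id[sel]
    new_pseudobulk(m, rowSums(m),
                   setNames(meta$n_cells[sel], meta$donor_id[sel]),
                   cell_type, region, meta$donor_id[sel])
  })
  pb_set <- structure(
    tibble::tibble(cell_type = groups$cell_type, region = groups$region,
                   pb = pbs),
    class = c("pseudobulk_set", "tbl_df", "tbl", "data.frame"))
  list(pb_set = pb_set, excluded = excluded)
}

#' Library-size normalization to log2 counts-per-million
#'
#' `log2(count * 1e6 / library_size + 1)`, the working expression scale for
#' differential expression, clocks and eQTL mapping.
#'
#' @param counts Donors-by-genes count matrix (or a `pseudobulk` object,
#'   whose library sizes are used and whose `log2cpm` slot is refreshed).
#' @param library_size Per-donor library sizes (ignored for `pseudobulk`
#'   input; defaults to row sums).
#' @return Matrix of log2 CPM values (or the updated `pseudobulk`).
#' @export
normalize_log2cpm <- function(counts, library_size = NULL) {
  if (inherits(counts, "pseudobulk")) {
    counts$log2cpm <- normalize_log2cpm(counts$counts, counts$library_size)
    return(counts)
  }
  ls <- library_size %||% rowSums(counts)
  if (any(ls <= 0)) abort("library sizes must be positive.")
  log2(sweep(counts, 1, ls, "/") * 1e6 + 1)
}

#' Differential expression on age and sex per cell type
#'
#' Per gene, a linear model of log2 CPM on age (decades, centered at 60),
#' sex, and any declared covariates, weighted by the log of the donor's
#' cell count for that cell type (deeper pseudobulk profiles are less
#' noisy). Genes expressed in fewer than `min_expr_frac` of donors are
#' skipped; BH correction is applied within (cell type, region, test).
#'
#' @param pb A `pseudobulk` object (or `pseudobulk_set`, mapped over).
#' @param donors Donor tibble (donor_id, age, sex, ...).
#' @param covariates Optional extra covariate columns of `donors`.
#' @param min_expr_frac Minimum fraction of donors with nonzero counts
#'   (default 0.25).
#' @param min_donors Minimum donors (default 20).
#' @param gene_meta Optional tibble (gene_id, chrom_class) to annotate.
#' @return Tibble of `DEResult` rows: gene_id, cell_type, region, test
#'   (`"age"`/`"sex"`), estimate (log2FC per decade, or male-vs-female
#'   log2FC), std_error, statistic, p_value, q_value, n_donors,
#'   chrom_class.
#' @export
fit_age_sex_de <- function(pb, donors, covariates = NULL,
                           min_expr_frac = 0.25, min_donors = 20,
                           gene_meta = NULL) {
  if (inherits(pb, "pseudobulk_set")) {
    return(purrr::map_dfr(pb$pb, fit_age_sex_de, donors = donors,
                          covariates = covariates,
                          min_expr_frac = min_expr_frac,
                          min_donors = min_donors, gene_meta = gene_meta))
  }
  dn <- donors[match(pb$donors, donors$donor_id), ]
  if (nrow(dn) < min_donors) {
    abort(sprintf("only %d donors (< %d).", nrow(dn), min_donors))
  }
  Y <- pb$log2cpm
  expressed <- colMeans(pb$counts > 0) >= min_expr_frac
  Y <- Y[, expressed, drop = FALSE]
  has_sex <- length(unique(dn$sex)) > 1
  X <- cbind(`(Intercept)` = 1, age_decade = age_decades(dn$age))
  if (has_sex) X <- cbind(X, sexM = as.numeric(dn$sex == "M"))
  for (cv in covariates) X <- cbind(X, dn[[cv]])
  if (!is.null(covariates)) {
    colnames(X)[(ncol(X) - length(covariates) + 1):ncol(X)] <- covariates
  }
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design.")
  w <- log(pmax(pb$cell_count[pb$donors], 2))
  sw <- sqrt(w)
  Xw <- X * sw
  Yw <- Y * sw
  XtXi <- solve(crossprod(Xw))
  B <- XtXi %*% crossprod(Xw, Yw)           # p x genes
  res <- Yw - Xw %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  tests <- intersect(c("age_decade", "sexM"), colnames(X))
  out <- purrr::map_dfr(tests, function(term) {
    j <- match(term, colnames(X))
    se <- sqrt(sigma2 * XtXi[j, j])
    est <- B[j, ]
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), df)
    tibble::tibble(
      gene_id = colnames(Y), cell_type = pb$cell_type, region = pb$region,
      test = if (term == "age_decade") "age" else "sex",
      estimate = unname(est), std_error = unname(se),
      statistic = unname(tstat), p_value = unname(p),
      q_value = bh_adjust(unname(p)), n_donors = nrow(dn)
    )
  })
  if (!is.null(gene_meta)) {
    out <- dplyr::left_join(out,
                            dplyr::select(gene_meta, "gene_id", "chrom_class"),
                            by = "gene_id")
  }
  out
}

#' Cross-cell-type correlation of age (or sex) effect profiles
#'
#' For each pair of cell types, Spearman rho and rho-squared of gene-level
#' effect sizes over the union of genes significant (q below `q_thresh`) in
#' at least one member of the pair; an all-genes variant is reported
#' alongside for sensitivity.
#'
#' @param de Combined DE tibble from [fit_age_sex_de()].
#' @param test Which test's effects to correlate (default `"age"`).
#' @param q_thresh Significance threshold for the union rule (default 0.05).
#' @param min_genes Minimum genes per pair (default 50); pairs below it get
#'   NA.
#' @return Tibble: cell_type_a, cell_type_b, n_genes, rho, rho2,
#'   rho_all_genes.
#' @export
cross_celltype_effect_correlation <- function(de, test = "age",
                                              q_thresh = 0.05,
                                              min_genes = 50) {
  d <- dplyr::filter(de, .data$test == !!test)
  cts <- unique(d$cell_type)
  if (length(cts) < 2) abort("need at least two cell types.")
  wide_b <- tidyr::pivot_wider(d, id_cols = "gene_id",
                               names_from = "cell_type",
                               values_from = "estimate")
  wide_q <- tidyr::pivot_wider(d, id_cols = "gene_id",
                               names_from = "cell_type",
                               values_from = "q_value")
  pairs <- utils::combn(cts, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    b1 <- wide_b[[pr[1]]]; b2 <- wide_b[[pr[2]]]
    q1 <- wide_q[[pr[1]]]; q2 <- wide_q[[pr[2]]]
    shared <- complete.cases(b1, b2)
    sig <- shared & (pmin(q1, q2, na.rm = TRUE) < q_thresh) &
      !is.na(q1) & !is.na(q2)
    sig[is.na(sig)] <- FALSE
    rho_all <- if (sum(shared) >= min_genes) {
      cor(b1[shared], b2[shared], method = "spearman")
    } else NA_real_
    rho <- if (sum(sig) >= min_genes) {
      cor(b1[sig], b2[sig], method = "spearman")
    } else NA_real_
    tibble::tibble(cell_type_a = pr[1], cell_type_b = pr[2],
                   n_genes = sum(sig), rho = rho, rho2 = rho^2,
                   rho_all_genes = rho_all)
  })
}

#' Build the gene-by-cell-type age-effect profile matrix
#'
#' Rows are genes significant (q below `q_thresh`) in at least one cell
#' type; entries are per-decade log2FCs; genes untested in a cell type are
#' imputed as 0 and recorded in the mask.
#'
#' @param de Combined DE tibble.
#' @param test Test to profile (default `"age"`).
#' @param q_thresh Inclusion threshold (default 0.05).
#' @return List: `beta` (genes x cell types), `mask` (TRUE where imputed),
#'   `sig` (logical significance matrix).
#' @export
build_effect_profiles <- function(de, test = "age", q_thresh = 0.05) {
  d <- dplyr::filter(de, .data$test == !!test)
  wide_b <- tidyr::pivot_wider(d, id_cols = "gene_id",
                               names_from = "cell_type",
                               values_from = "estimate")
  wide_q <- tidyr::pivot_wider(d, id_cols = "gene_id",
                               names_from = "cell_type",
                               values_from = "q_value")
  B <- as.matrix(wide_b[, -1]); rownames(B) <- wide_b$gene_id
  Q <- as.matrix(wide_q[, -1]); rownames(Q) <- wide_q$gene_id
  sig <- !is.na(Q) & Q < q_thresh
  keep <- rowSums(sig) >= 1
  B <- B[keep, , drop = FALSE]
  sig <- sig[keep, , drop = FALSE]
  mask <- is.na(B)
  B[mask] <- 0
  list(beta = B, mask = mask, sig = sig)
}

#' k-means clustering of gene age-effect profiles
#'
#' Groups genes by their patterns of age-associated expression change
#' across cell types, with 50 restarts and a fixed seed for
#' reproducibility.
#'
#' @param beta Genes-by-cell-types effect matrix (e.g.
#'   `build_effect_profiles()$beta`).
#' @param k Number of clusters (default 8).
#' @param seed RNG seed.
#' @param n_start Restarts (default 50).
#' @return List: `cluster` (named integer vector), `centers`,
#'   `tot_withinss`, `size`.
#' @export
cluster_age_profiles <- function(beta, k = 8, seed = 1L, n_start = 50) {
  if (k > nrow(beta)) abort("k exceeds the number of genes.")
  km <- with_seed(seed, kmeans(beta, centers = k, nstart = n_start,
                               iter.max = 100))
  list(cluster = setNames(km$cluster, rownames(beta)), centers = km$centers,
       tot_withinss = km$tot.withinss, size = km$size)
}

#' Moment-based transcriptome-wide impact of age
#'
#' The observed squared effect of each gene overstates the true squared
#' effect by its squared standard error; averaging `estimate^2 - SE^2`
#' over genes therefore gives an unbiased moment estimate of the mean
#' squared TRUE differential-expression effect — a power-robust summary of
#' how strongly age reshapes a cell type's transcriptome. The SE comes from
#' a gene-level bootstrap.
#'
#' @param de DE tibble for one (cell type, region, test) stratum, or a
#'   combined tibble (grouped internally by cell type, region, test).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Tibble: cell_type, region, test, twi, twi_se, n_genes.
#' @export
estimate_transcriptome_impact <- function(de, n_boot = 1000, seed = 1L) {
  if (any(is.na(de$std_error))) abort("missing standard errors.")
  strata <- dplyr::distinct(de, .data$cell_type, .data$region, .data$test)
  seeds <- derive_seeds(seed, nrow(strata))
  purrr::pmap_dfr(
    cbind(strata, .seed = seeds),
    function(cell_type, region, test, .seed) {
      d <- de[de$cell_type == cell_type & de$region == region &
                de$test == test, ]
      if (nrow(d) < 100) {
        warn(sprintf("%s/%s/%s: only %d genes; impact estimate unstable.",
                     cell_type, region, test, nrow(d)))
      }
      contrib <- d$estimate^2 - d$std_error^2
      boots <- with_seed(.seed, vapply(seq_len(n_boot), function(b) {
        mean(contrib[sample.int(length(contrib), replace = TRUE)])
      }, numeric(1)))
      tibble::tibble(cell_type = cell_type, region = region, test = test,
                     twi = mean(contrib), twi_se = sd(boots),
                     n_genes = nrow(d))
    })
}

#' Export a GSEA-compatible ranking file
#'
#' Writes gene rankings (by the signed test statistic) in `.rnk` format so
#' enrichment can be run in external tools.
#'
#' @param de DE tibble for a single stratum.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(de, path) {
  d <- dplyr::arrange(de, dplyr::desc(.data$statistic))
  readr::write_tsv(dplyr::select(d, "gene_id", "statistic"), path,
                   col_names = FALSE)
  invisible(path)
}
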