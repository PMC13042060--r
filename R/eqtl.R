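#' Rank-based inverse normal transform
#'
#' Maps values through the Blom offset `(rank - 3/8) / (n + 1/4)` into
#' standard-normal quantiles; ties receive average ranks. The standard
#' variance-stabilizing step before cis-eQTL regression.
#'
#' @param values Numeric vector (>= 3 values, not all identical).
#' @return Transformed vector, in input order.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("need >= 3 non-missing values.")
  if (length(unique(values[ok])) == 1) abort("all values identical.")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

# Residualize columns of M on covariate matrix C (with intercept).
residualize <- function(M, C) {
  C <- cbind(1, C)
  M - C %*% solve(crossprod(C), crossprod(C, M))
}

#' Map cis-eQTLs per cell type
#'
#' Per gene and cell type: inverse-normal-transformed log2 CPM is regressed
#' on SNP dosage with age and sex (plus declared covariates) as nuisance
#' terms; the lead SNP is the minimum-p SNP within `window` bp of the TSS;
#' the gene-level p is the Bonferroni-corrected minimum (min p times the
#' number of cis SNPs, capped at 1); BH across genes within the cell type
#' calls eGenes at `fdr`. Genes without cis SNPs are reported as NA rows.
#'
#' @param pb A `pseudobulk` object (or `pseudobulk_set`, mapped over).
#' @param geno Genotypes (list with `dosage`, `snps`) from
#'   [generate_genotypes()] or [read_vcf_dosage()].
#' @param genes Gene table with gene_id, chrom, tss.
#' @param donors Donor tibble with age and sex.
#' @param window Cis window half-width in bp (default 1e6).
#' @param maf_min Minimum MAF among analyzed donors (default 0.05).
#' @param fdr eGene FDR (default 0.01).
#' @param min_expr_frac Minimum expressed fraction (default 0.25).
#' @return Tibble: gene_id, cell_type, region, lead_snp, n_cis_snps, beta
#'   (standardized per-allele effect), std_error, p_lead, p_gene
#'   (Bonferroni), q_value (BH across genes), egene.
#' @export
map_cis_eqtls <- function(pb, geno, genes, donors, window = 1e6,
                          maf_min = 0.05, fdr = 0.01,
                          min_expr_frac = 0.25) {
  if (inherits(pb, "pseudobulk_set")) {
    return(purrr::map_dfr(pb$pb, map_cis_eqtls, geno = geno, genes = genes,
                          donors = donors, window = window,
                          maf_min = maf_min, fdr = fdr,
                          min_expr_frac = min_expr_frac))
  }
  shared <- intersect(pb$donors, rownames(geno$dosage))
  if (length(shared) < 40) abort("need >= 40 donors with genotype and expression.")
  dn <- donors[match(shared, donors$donor_id), ]
  Y <- pb$log2cpm[shared, , drop = FALSE]
  expressed <- colMeans(pb$counts[shared, , drop = FALSE] > 0) >= min_expr_frac
  D <- geno$dosage[shared, , drop = FALSE]
  maf <- colMeans(D) / 2
  maf <- pmin(maf, 1 - maf)
  D <- D[, maf >= maf_min & apply(D, 2, sd) > 0, drop = FALSE]
  snps <- geno$snps[match(colnames(D), geno$snps$snp_id), ]
  C <- cbind(age_decades(dn$age))
  if (length(unique(dn$sex)) > 1) C <- cbind(C, as.numeric(dn$sex == "M"))
  n <- length(shared)
  df <- n - ncol(C) - 2  # intercept + dosage
  Dr <- residualize(D, C)
  res <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    base <- tibble::tibble(
      gene_id = g$gene_id, cell_type = pb$cell_type, region = pb$region,
      lead_snp = NA_character_, n_cis_snps = 0L, beta = NA_real_,
      std_error = NA_real_, p_lead = NA_real_, p_gene = NA_real_)
    if (!g$gene_id %in% colnames(Y) || !expressed[g$gene_id]) return(base)
    cis <- which(snps$chrom == g$chrom & abs(snps$pos - g$tss) <= window)
    if (!length(cis)) return(base)
    yr <- residualize(inverse_normal_transform(Y[, g$gene_id]), C)
    beta <- se <- p <- numeric(length(cis))
    for (i in seq_along(cis)) {
      x <- Dr[, cis[i]]
      sxx <- sum(x^2)
      b <- sum(x * yr) / sxx
      rss <- sum((yr - b * x)^2)
      s <- sqrt(rss / df / sxx)
      beta[i] <- b; se[i] <- s
      p[i] <- 2 * pt(-abs(b / s), df)
    }
    lead <- which.min(p)
    base$lead_snp <- snps$snp_id[cis[lead]]
    base$n_cis_snps <- length(cis)
    base$beta <- beta[lead]; base$std_error <- se[lead]
    base$p_lead <- p[lead]
    base$p_gene <- min(1, p[lead] * length(cis))
    base
  })
  ok <- !is.na(res$p_gene)
  res$q_value <- NA_real_
  res$q_value[ok] <- bh_adjust(res$p_gene[ok])
  res$egene <- !is.na(res$q_value) & res$q_value < fdr
  res
}

#' Build the eQTL-by-cell-type effect matrix
#'
#' For each eGene (significant in at least one cell type), the lead SNP is
#' taken from the cell type with the smallest gene-level p and its
#' standardized per-allele effect recomputed in EVERY cell type; rows are
#' sign-oriented so the majority effect direction is positive; cell types
#' where the effect cannot be computed (too few donors, monomorphic SNP)
#' are imputed 0 and masked.
#'
#' @param results Combined tibble from [map_cis_eqtls()] over cell types.
#' @param pb_set The `pseudobulk_set` used for mapping.
#' @param geno Genotypes.
#' @param donors Donor tibble.
#' @return List: `beta` (eGenes x cell types, oriented), `mask`,
#'   `lead` tibble (gene_id, lead_snp, source cell type), `flipped`
#'   logical vector, `sig` significance matrix.
#' @export
build_effect_matrix <- function(results, pb_set, geno, donors) {
  eg <- dplyr::filter(results, .data$egene)
  if (!nrow(eg)) abort("no eGenes to assemble.")
  lead <- eg |>
    dplyr::slice_min(.data$p_gene, n = 1, by = "gene_id",
                     with_ties = FALSE) |>
    dplyr::select("gene_id", "lead_snp", source_cell_type = "cell_type")
  cts <- unique(results$cell_type)
  B <- matrix(NA_real_, nrow(lead), length(cts),
              dimnames = list(lead$gene_id, cts))
  for (ct in cts) {
    pb <- pb_get(pb_set, ct)
    shared <- intersect(pb$donors, rownames(geno$dosage))
    dn <- donors[match(shared, donors$donor_id), ]
    C <- cbind(age_decades(dn$age))
    if (length(unique(dn$sex)) > 1) C <- cbind(C, as.numeric(dn$sex == "M"))
    for (i in seq_len(nrow(lead))) {
      gid <- lead$gene_id[i]; snp <- lead$lead_snp[i]
      if (!gid %in% colnames(pb$log2cpm) ||
          !snp %in% colnames(geno$dosage)) next
      x <- geno$dosage[shared, snp]
      if (sd(x) == 0) next
      yv <- pb$log2cpm[shared, gid]
      if (length(unique(yv)) < 3) next
      yr <- residualize(inverse_normal_transform(yv), C)
      xr <- residualize(matrix(x, ncol = 1), C)
      B[i, ct] <- sum(xr * yr) / sum(xr^2)
    }
  }
  mask <- is.na(B)
  B[mask] <- 0
  oriented <- orient_effects(B)
  flipped <- rowSums(oriented != B & (B != 0 | oriented != 0)) > 0
  B <- oriented
  sig_tbl <- results |>
    dplyr::filter(.data$gene_id %in% lead$gene_id) |>
    dplyr::mutate(sig = .data$egene)
  sig <- matrix(FALSE, nrow(lead), length(cts),
                dimnames = dimnames(B))
  sig[cbind(match(sig_tbl$gene_id, lead$gene_id),
            match(sig_tbl$cell_type, cts))] <- sig_tbl$sig
  list(beta = B, mask = mask, lead = lead, flipped = flipped, sig = sig)
}

#' Sign-orient an effect matrix by majority direction
#'
#' Flips rows so the most common effect direction is positive. Only
#' substantial entries vote (at least `rel_thresh` of the row's largest
#' |effect|), so that noise-level effects in unaffected cell types cannot
#' outvote a single strong effect; exact ties are broken by the sign of the
#' row sum. Applying the orientation twice changes nothing.
#'
#' @param beta Numeric matrix (rows = eQTLs).
#' @param rel_thresh Voting threshold relative to the row maximum |effect|
#'   (default 0.25).
#' @return Matrix with oriented rows.
#' @export
orient_effects <- function(beta, rel_thresh = 0.25) {
  flip <- apply(beta, 1, function(b) {
    m <- max(abs(b))
    if (m == 0) return(FALSE)
    v <- b[abs(b) >= rel_thresh * m]
    neg <- sum(v < 0); pos <- sum(v > 0)
    if (neg != pos) neg > pos else sum(b) < 0
  })
  beta[flip, ] <- -beta[flip, , drop = FALSE]
  beta
}

#' k-means clustering of eQTL effect patterns
#'
#' Groups eQTLs by their pattern of per-allele effects across cell types
#' (50 restarts, fixed seed) and summarizes each cluster's dominant cell
#' types and the shared-vs-specific split.
#'
#' @param beta Oriented eQTLs-by-cell-types matrix.
#' @param k Number of clusters (default 13).
#' @param seed RNG seed.
#' @param n_start Restarts (default 50).
#' @param specific_thresh A cluster is "specific" when fewer than this
#'   fraction of cell types carry at least half the cluster's maximum mean
#'   effect (default 0.5).
#' @return List: `cluster`, `centers`, `tot_withinss`, `summary` tibble
#'   (cluster, n, dominant cell types, specific flag), `fraction_specific`.
#' @export
cluster_eqtls <- function(beta, k = 13, seed = 1L, n_start = 50,
                          specific_thresh = 0.5) {
  if (k > nrow(beta)) abort("k exceeds the number of eQTLs.")
  km <- with_seed(seed, kmeans(beta, centers = k, nstart = n_start,
                               iter.max = 100))
  summ <- purrr::map_dfr(seq_len(k), function(cl) {
    ctr <- km$centers[cl, ]
    dom <- names(ctr)[abs(ctr) >= 0.5 * max(abs(ctr))]
    tibble::tibble(cluster = cl, n = sum(km$cluster == cl),
                   dominant = paste(dom, collapse = ","),
                   specific = length(dom) < specific_thresh * ncol(beta))
  })
  list(cluster = setNames(km$cluster, rownames(beta)),
       centers = km$centers, tot_withinss = km$tot.withinss,
       summary = summ,
       fraction_specific = sum(summ$n[summ$specific]) / nrow(beta))
}

#' Pairwise sharing of eQTL effects between cell types
#'
#' Spearman rho-squared of per-allele effects over the union of eQTLs
#' significant in at least one member of each cell-type pair.
#'
#' @param effects Output of [build_effect_matrix()] (needs `beta` and
#'   `sig`).
#' @param min_eqtls Minimum qualifying eQTLs per pair (default 30).
#' @return Tibble: cell_type_a, cell_type_b, n_eqtls, rho, rho2.
#' @export
pairwise_sharing <- function(effects, min_eqtls = 30) {
  B <- effects$beta; S <- effects$sig
  cts <- colnames(B)
  pairs <- utils::combn(cts, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    qual <- (S[, pr[1]] | S[, pr[2]]) &
      !effects$mask[, pr[1]] & !effects$mask[, pr[2]]
    if (sum(qual) < min_eqtls) {
      return(tibble::tibble(cell_type_a = pr[1], cell_type_b = pr[2],
                            n_eqtls = sum(qual), rho = NA_real_,
                            rho2 = NA_real_))
    }
    rho <- cor(B[qual, pr[1]], B[qual, pr[2]], method = "spearman")
    tibble::tibble(cell_type_a = pr[1], cell_type_b = pr[2],
                   n_eqtls = sum(qual), rho = rho, rho2 = rho^2)
  })
}

#' Association between gene constraint and eQTL effect size
#'
#' Tests whether loss-of-function-intolerant genes carry smaller cis
#' effects: Spearman correlation of |effect| (fold-change scale) with the
#' constraint score across eGenes, plus a two-group Wilcoxon on a binary
#' constrained/unconstrained split.
#'
#' @param egene_effects Tibble with gene_id and `abs_beta` (per-allele
#'   |log2FC|; a fold-change-scale magnitude).
#' @param constraint Tibble with gene_id and `score` (higher = more
#'   constrained) and optionally `constrained` (logical); if absent, the
#'   upper score quartile is used.
#' @return Tibble: n_genes, rho, p_spearman, p_wilcoxon,
#'   median_constrained, median_unconstrained.
#' @export
constraint_effect_association <- function(egene_effects, constraint) {
  d <- dplyr::inner_join(egene_effects, constraint, by = "gene_id")
  if (nrow(d) < 50) abort("need constraint scores for >= 50 eGenes.")
  if (length(unique(d$score)) == 1) abort("constraint scores are constant.")
  ct <- suppressWarnings(cor.test(d$abs_beta, d$score, method = "spearman",
                                  exact = FALSE))
  if (!"constrained" %in% names(d)) {
    d$constrained <- d$score >= quantile(d$score, 0.75)
  }
  wt <- wilcox.test(d$abs_beta[d$constrained], d$abs_beta[!d$constrained])
  tibble::tibble(
    n_genes = nrow(d), rho = unname(ct$estimate), p_spearman = ct$p.value,
    p_wilcoxon = wt$p.value,
    median_constrained = median(d$abs_beta[d$constrained]),
    median_unconstrained = median(d$abs_beta[!d$constrained])
  )
}
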