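#' Specify one cell type for the synthetic cohort generator
#'
#' Each cell type is described on the logit scale of its expected fraction of
#' all nuclei in a sample. A donor-level latent propensity (variance `tau2`)
#' is shared across all of a donor's regions; sample-level noise (variance
#' `sigma2`) is drawn independently per sample. The age slope is in log-odds
#' per decade of age, centered at age 60.
#'
#' @param name Cell-type label.
#' @param baseline_logit Baseline logit fraction at age 60; either a single
#'   number (all regions) or a named vector with one entry per region.
#' @param age_slope Log-odds change per decade of age (default 0).
#' @param tau2 Donor-level propensity variance, shared across regions (>= 0).
#' @param sigma2 Sample-level noise variance (>= 0).
#' @param class Coarse class label (`"neuron"`, `"glia"`, `"other"`, ...),
#'   used to build denominators such as "fraction of all neurons".
#' @return A `celltype_spec` list.
#' @export
celltype_spec <- function(name, baseline_logit, age_slope = 0,
                          tau2 = 0, sigma2 = 0, class = "other") {
  if (tau2 < 0 || sigma2 < 0) abort("`tau2` and `sigma2` must be >= 0.")
  structure(
    list(name = name, baseline_logit = baseline_logit, age_slope = age_slope,
         tau2 = tau2, sigma2 = sigma2, class = class),
    class = "celltype_spec"
  )
}

#' Specify the gene panel for synthetic pseudobulk expression
#'
#' Builds a gene table plus per-cell-type effect matrices. Genes are laid out
#' along one chromosome with evenly spaced transcription start sites so that
#' cis windows are well defined. A subset of genes receives age effects
#' (log2 fold change per decade, possibly cell-type-specific), sex effects
#' confined to sex-chromosome genes (Y genes are silent in XX donors; X genes
#' model X-inactivation escape, i.e. higher expression in XX donors), and
#' cis-eQTL effects tied to nearby SNPs.
#'
#' @param celltypes Character vector of cell-type names.
#' @param n_genes Number of genes.
#' @param prop_age Proportion of genes with a nonzero age effect.
#' @param age_l2fc_sd SD of the per-decade log2FC for age-affected genes.
#' @param age_pattern `"shared"` (same effect in all cell types),
#'   `"independent"` (each cell type its own draw), or a numeric matrix of
#'   correlations... use `"groups"` with `age_groups` to give blocks of cell
#'   types identical profiles.
#' @param age_groups Optional list of character vectors; cell types within a
#'   group share identical age profiles, groups are independent. Overrides
#'   `age_pattern`.
#' @param n_y,n_x Numbers of Y- and X-chromosome genes (sex effects live only
#'   there).
#' @param sex_log2fc Magnitude of the male-vs-female log2FC on sex-chromosome
#'   genes (applied +ve on Y genes, -ve on X-escape genes).
#' @param baseline_mean,baseline_sd Mean/SD of baseline log2 CPM.
#' @param n_eqtl Number of genes given a cis-eQTL.
#' @param eqtl_beta_sd SD of eQTL effects (log2 expression per alt allele).
#' @param eqtl_pattern `"shared"`, `"independent"`, or a list of character
#'   vectors naming the cell types in which each eQTL class acts (recycled).
#' @param seed RNG seed for the spec itself.
#' @return A `gene_spec` list: `genes` tibble (gene_id, chrom, tss,
#'   chrom_class, baseline_log2cpm, sex_log2fc, eqtl_snp), `age_l2fc` and
#'   `eqtl_beta` gene-by-cell-type matrices, and a `snps` tibble.
#' @export
gene_spec <- function(celltypes, n_genes = 500, prop_age = 0.4,
                      age_l2fc_sd = 0.1, age_pattern = "shared",
                      age_groups = NULL, n_y = 10, n_x = 10, sex_log2fc = 1,
                      baseline_mean = 5, baseline_sd = 1.5,
                      n_eqtl = 100, eqtl_beta_sd = 0.5,
                      eqtl_pattern = "shared", seed = 1L) {
  if (n_y + n_x > n_genes) abort("n_y + n_x exceeds n_genes.")
  with_seed(seed, {
    nc <- length(celltypes)
    gene_id <- sprintf("G%04d", seq_len(n_genes))
    chrom_class <- rep("autosome", n_genes)
    if (n_y > 0) chrom_class[seq_len(n_y)] <- "Y"
    if (n_x > 0) chrom_class[n_y + seq_len(n_x)] <- "X"
    sexfc <- numeric(n_genes)
    sexfc[chrom_class == "Y"] <- sex_log2fc
    sexfc[chrom_class == "X"] <- -sex_log2fc

    age_l2fc <- matrix(0, n_genes, nc, dimnames = list(gene_id, celltypes))
    idx_age <- which(runif(n_genes) < prop_age)
    if (length(idx_age)) {
      if (!is.null(age_groups)) {
        for (grp in age_groups) {
          draw <- rnorm(length(idx_age), 0, age_l2fc_sd)
          for (ct in intersect(grp, celltypes)) age_l2fc[idx_age, ct] <- draw
        }
      } else if (identical(age_pattern, "shared")) {
        draw <- rnorm(length(idx_age), 0, age_l2fc_sd)
        age_l2fc[idx_age, ] <- draw
      } else {
        age_l2fc[idx_age, ] <- rnorm(length(idx_age) * nc, 0, age_l2fc_sd)
      }
    }

    eqtl_beta <- matrix(0, n_genes, nc, dimnames = list(gene_id, celltypes))
    eqtl_snp <- rep(NA_character_, n_genes)
    n_eqtl <- min(n_eqtl, n_genes)
    idx_eq <- if (n_eqtl > 0) sort(sample.int(n_genes, n_eqtl)) else integer()
    snps <- tibble::tibble(snp_id = character(), chrom = character(),
                           pos = integer(), maf = numeric())
    if (length(idx_eq)) {
      snp_id <- sprintf("rs%05d", seq_along(idx_eq))
      eqtl_snp[idx_eq] <- snp_id
      if (is.character(eqtl_pattern) && length(eqtl_pattern) == 1) {
        pat <- if (identical(eqtl_pattern, "shared")) list(celltypes) else
          as.list(rep_len(celltypes, length(idx_eq)))
      } else pat <- eqtl_pattern
      pat <- rep_len(pat, length(idx_eq))
      for (i in seq_along(idx_eq)) {
        b <- rnorm(1, 0, eqtl_beta_sd)
        cts <- intersect(pat[[i]], celltypes)
        eqtl_beta[idx_eq[i], cts] <- b
      }
      snps <- tibble::tibble(
        snp_id = snp_id, chrom = "chr1",
        pos = as.integer(idx_eq * 100000L + 1000L),
        maf = runif(length(idx_eq), 0.1, 0.5)
      )
    }

    genes <- tibble::tibble(
      gene_id = gene_id, chrom = "chr1",
      tss = as.integer(seq_len(n_genes) * 100000L),
      chrom_class = chrom_class,
      baseline_log2cpm = pmax(1, rnorm(n_genes, baseline_mean, baseline_sd)),
      sex_log2fc = sexfc, eqtl_snp = eqtl_snp
    )
    structure(list(genes = genes, age_l2fc = age_l2fc, eqtl_beta = eqtl_beta,
                   snps = snps, celltypes = celltypes),
              class = "gene_spec")
  })
}

#' Configure a synthetic multi-region snRNA-seq cohort
#'
#' Bundles everything the generators need: cohort demographics, village
#' layout, per-cell-type abundance models, the gene panel, nuclei-count
#' distribution, and noise levels. The defaults emulate the study conditions
#' the analyses assume: ~150 donors aged 27-90 (ages above 89 capped at 90),
#' five brain regions, ~20-donor villages, donor-level glial propensities
#' shared across regions, an OPC abundance decline of -0.096 log-odds per
#' decade, and ~5,000 nuclei per sample.
#'
#' @param n_donors Number of donors.
#' @param age_range Min/max age in years (uniform draw; capped at 90).
#' @param male_fraction Proportion of male donors.
#' @param regions Region labels.
#' @param village_size Donors per pooled village.
#' @param nuclei_mean,nuclei_size Negative-binomial mean and size for total
#'   nuclei per sample.
#' @param celltypes List of [celltype_spec()] objects (a remainder class
#'   absorbs the leftover probability mass).
#' @param genes A [gene_spec()] object, or `NULL` to skip expression.
#' @param nb_dispersion Negative-binomial dispersion of pseudobulk counts
#'   (0 gives noise-free expected counts).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param bio_age_sd SD (years) of a donor-level latent "biological age"
#'   offset added to chronological age in the expression model; 0 disables.
#' @param bio_age_shared If `TRUE` the offset is shared by all cell types of
#'   a donor; if `FALSE` each cell type draws its own.
#' @param doublet_rate Proportion of barcodes that are doublets (used by the
#'   village QC simulators).
#' @param seed Master RNG seed; every generator derives its own stream from
#'   it, so each is individually reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_donors = 150, age_range = c(27, 90),
                          male_fraction = 0.62,
                          regions = c("CaH", "Pu", "NAC", "ic", "DFC"),
                          village_size = 20,
                          nuclei_mean = 5000, nuclei_size = 10,
                          celltypes = default_celltypes(),
                          genes = NULL,
                          nb_dispersion = 0.2,
                          libsize_meanlog = 15, libsize_sdlog = 0.3,
                          bio_age_sd = 0, bio_age_shared = TRUE,
                          doublet_rate = 0.01,
                          seed = 1L) {
  if (n_donors <= 0) abort("`n_donors` must be positive.")
  if (age_range[1] >= age_range[2]) abort("`age_range` must satisfy min < max.")
  stopifnot_scalar_prob(male_fraction, "male_fraction")
  stopifnot_scalar_prob(doublet_rate, "doublet_rate")
  if (village_size < 1) abort("`village_size` must be >= 1.")
  names(celltypes) <- vapply(celltypes, `[[`, "", "name")
  structure(
    list(n_donors = as.integer(n_donors), age_range = age_range,
         male_fraction = male_fraction, regions = regions,
         village_size = as.integer(village_size),
         nuclei_mean = nuclei_mean, nuclei_size = nuclei_size,
         celltypes = celltypes, genes = genes,
         nb_dispersion = nb_dispersion,
         libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
         bio_age_sd = bio_age_sd, bio_age_shared = bio_age_shared,
         doublet_rate = doublet_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default cell-type panel for the synthetic striatal cohort
#'
#' Baseline fractions (at age 60) chosen to resemble adult human striatal
#' gray matter, with the internal capsule dominated by oligodendrocytes and
#' DFC carrying more interneurons; OPCs carry the canonical age decline.
#'
#' @return Named list of [celltype_spec()] objects.
#' @export
default_celltypes <- function() {
  l <- function(p) qlogis(p)
  cts <- list(
    celltype_spec("oligodendrocyte",
                  c(CaH = l(0.22), Pu = l(0.25), NAC = l(0.18),
                    ic = l(0.70), DFC = l(0.20)),
                  tau2 = 0.03, sigma2 = 0.03, class = "glia"),
    celltype_spec("astrocyte",
                  c(CaH = l(0.15), Pu = l(0.15), NAC = l(0.16),
                    ic = l(0.12), DFC = l(0.17)),
                  tau2 = 0.025, sigma2 = 0.035, class = "glia"),
    celltype_spec("microglia",
                  c(CaH = l(0.05), Pu = l(0.05), NAC = l(0.05),
                    ic = l(0.06), DFC = l(0.05)),
                  tau2 = 0.045, sigma2 = 0.055, class = "glia"),
    celltype_spec("OPC",
                  c(CaH = l(0.03), Pu = l(0.03), NAC = l(0.03),
                    ic = l(0.035), DFC = l(0.03)),
                  age_slope = -0.096, tau2 = 0.04, sigma2 = 0.02,
                  class = "glia"),
    celltype_spec("D1_MSN",
                  c(CaH = l(0.155), Pu = l(0.13), NAC = l(0.13),
                    ic = l(0.01), DFC = l(0.001)),
                  tau2 = 0.01, sigma2 = 0.01, class = "neuron"),
    celltype_spec("D2_MSN",
                  c(CaH = l(0.126), Pu = l(0.13), NAC = l(0.127),
                    ic = l(0.01), DFC = l(0.001)),
                  tau2 = 0.01, sigma2 = 0.01, class = "neuron"),
    celltype_spec("TAC3_PLPP4",
                  c(CaH = l(0.006), Pu = l(0.006), NAC = l(0.006),
                    ic = l(0.001), DFC = l(0.002)),
                  age_slope = -0.047, tau2 = 0.05, sigma2 = 0.04,
                  class = "neuron"),
    celltype_spec("PTHLH_PVALB",
                  c(CaH = l(0.008), Pu = l(0.008), NAC = l(0.007),
                    ic = l(0.001), DFC = l(0.002)),
                  tau2 = 0.05, sigma2 = 0.04, class = "neuron"),
    celltype_spec("cortical_excitatory",
                  c(CaH = l(0.001), Pu = l(0.001), NAC = l(0.001),
                    ic = l(0.001), DFC = l(0.25)),
                  tau2 = 0.01, sigma2 = 0.01, class = "neuron")
  )
  setNames(cts, vapply(cts, `[[`, "", "name"))
}
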