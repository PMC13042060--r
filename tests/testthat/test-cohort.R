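test_that("cohort generation honors demographics and is deterministic", {
  cfg <- cohort_config(n_donors = 40, male_fraction = 1, seed = 5)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$donors), 40)
  expect_true(all(ch$donors$sex == "M"))
  expect_true(all(ch$donors$age >= 27 & ch$donors$age <= 90))
  expect_equal(length(unique(ch$donors$village_id)), 2)

  ch2 <- generate_cohort(cfg)
  expect_identical(ch$donors, ch2$donors)
  expect_identical(ch$truth$u, ch2$truth$u)

  expect_error(generate_cohort(cohort_config(n_donors = 0)), "positive")
})

test_that("ages are uniform on the configured range", {
  cfg <- cohort_config(n_donors = 1000, age_range = c(27, 90), seed = 11)
  ch <- generate_cohort(cfg)
  se <- (90 - 27) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(ch$donors$age) - 58.5), 3 * se)
})

test_that("cell counts close compositionally and track baselines exactly when noiseless", {
  cfg <- one_ct_config(baseline = qlogis(0.1), age_slope = 0,
                       tau2 = 0, sigma2 = 0, n_donors = 60,
                       nuclei_mean = 20000, seed = 3)
  ch <- generate_cohort(cfg)
  cc <- generate_cell_counts(ch$donors, ch$truth, cfg)
  # closure: per-sample counts (incl. remainder) sum to total nuclei
  sums <- dplyr::summarise(cc, s = sum(count), n = total_nuclei[1],
                           .by = c(donor_id, region))
  expect_true(all(sums$s == sums$n))
  # with all variance off the only scatter is multinomial sampling
  fr <- dplyr::filter(cc, cell_type == "OPC")
  phat <- sum(fr$count) / sum(fr$total_nuclei)
  se <- sqrt(0.1 * 0.9 / sum(fr$total_nuclei))
  expect_lt(abs(phat - 0.1), 4 * se)
})

test_that("generated age slope is recovered by logistic regression at large n", {
  cfg <- one_ct_config(age_slope = -0.096, tau2 = 0, sigma2 = 0,
                       n_donors = 500, regions = "CaH", seed = 7)
  obs <- sim_abundance(cfg)
  g <- glm(cbind(k, n - k) ~ I((age - 60) / 10), binomial, data = obs)
  est <- coef(g)[2]
  se <- summary(g)$coefficients[2, 2]
  expect_lt(abs(est - (-0.096)), 3 * se)
})

test_that("donor propensities shared across regions give the expected cross-region correlation", {
  # tau2 > 0, sigma2 = 0: donor logit fractions should correlate ~1 across
  # regions; with sigma2 > 0 the correlation drops toward tau2/(tau2+sigma2)
  cfg <- one_ct_config(age_slope = 0, tau2 = 0.2, sigma2 = 0,
                       n_donors = 300, nuclei_mean = 30000, seed = 13)
  obs <- sim_abundance(cfg)
  w <- tidyr::pivot_wider(
    dplyr::mutate(obs, lf = qlogis(pmin(pmax(k / n, 1e-6), 1 - 1e-6))),
    id_cols = donor_id, names_from = region, values_from = lf)
  expect_gt(cor(w$CaH, w$Pu)^2, 0.97)

  cfg2 <- one_ct_config(age_slope = 0, tau2 = 0.1, sigma2 = 0.1,
                        n_donors = 2000, nuclei_mean = 30000, seed = 17)
  obs2 <- sim_abundance(cfg2)
  w2 <- tidyr::pivot_wider(
    dplyr::mutate(obs2, lf = qlogis(k / n)),
    id_cols = donor_id, names_from = region, values_from = lf)
  r <- cor(w2$CaH, w2$Pu)
  expect_lt(abs(r - 0.5), 0.06)  # tau2/(tau2+sigma2) = 0.5
})

test_that("sharing calibration hits the target fraction-scale r-squared", {
  cal <- calibrate_sharing(0.29, qlogis(0.05), n_nuclei = 5000,
                           total_var = 0.1)
  expect_equal(cal$r2, 0.29, tolerance = 1e-6)
  expect_gt(cal$tau2, 0)
  expect_lt(cal$tau2, 0.1)
  # Monte-Carlo agreement at large n
  cfg <- cohort_config(
    n_donors = 4000, regions = c("CaH", "DFC"), nuclei_mean = 5000,
    celltypes = list(celltype_spec("microglia", qlogis(0.05),
                                   tau2 = cal$tau2, sigma2 = cal$sigma2,
                                   class = "glia")),
    seed = 19)
  ch <- generate_cohort(cfg)
  cc <- generate_cell_counts(ch$donors, ch$truth, cfg)
  w <- tidyr::pivot_wider(
    dplyr::mutate(dplyr::filter(cc, cell_type == "microglia"),
                  f = count / total_nuclei),
    id_cols = donor_id, names_from = region, values_from = f)
  expect_lt(abs(cor(w$CaH, w$DFC)^2 - 0.29), 0.04)
})

test_that("genotypes follow Hardy-Weinberg and survive a VCF round trip", {
  donors <- tibble::tibble(donor_id = sprintf("D%05d", 1:10000))
  snps <- tibble::tibble(snp_id = c("rs1", "rs2"), chrom = "chr1",
                         pos = c(100L, 200L), maf = c(0.5, 0.2))
  geno <- generate_genotypes(donors, snps)
  tab <- table(factor(geno$dosage[, "rs1"], levels = 0:2)) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(tab[["0"]] - 0.25), 3 * se)
  expect_lt(abs(tab[["1"]] - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))
  expect_lt(abs(tab[["2"]] - 0.25), 3 * se)

  # maf -> 0 limit: all dosages homozygous reference
  g0 <- generate_genotypes(donors[1:50, ],
                           tibble::tibble(snp_id = "rsX", chrom = "chr1",
                                          pos = 1L, maf = 1e-12))
  expect_true(all(g0$dosage == 0))
  expect_error(
    generate_genotypes(donors, tibble::tibble(snp_id = "b", chrom = "1",
                                              pos = 1L, maf = 0.6)),
    "MAF")

  path <- withr::local_tempfile(fileext = ".vcf")
  small <- list(dosage = geno$dosage[1:25, , drop = FALSE], snps = snps)
  write_vcf(small, path)
  back <- read_vcf_dosage(path)
  expect_equal(back$dosage[rownames(small$dosage), colnames(small$dosage)],
               small$dosage)
})

test_that("pseudobulk expression encodes age, sex, and eQTL effects as specified", {
  cts <- c("D1_MSN", "astrocyte")
  gs <- gene_spec(cts, n_genes = 60, prop_age = 0, n_y = 5, n_x = 5,
                  n_eqtl = 10, eqtl_beta_sd = 0.6, baseline_mean = 10,
                  baseline_sd = 0, seed = 2)
  cfg <- cohort_config(n_donors = 80, regions = "CaH",
                       celltypes = default_celltypes()[cts], genes = gs,
                       nb_dispersion = 0, libsize_sdlog = 0, seed = 23)
  ch <- generate_cohort(cfg)
  geno <- generate_genotypes(ch$donors, cfg)
  pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg, geno = geno)
  pb <- pb_get(pbs, "D1_MSN")
  # Y genes silent in XX donors
  females <- ch$donors$donor_id[ch$donors$sex == "F"]
  ygenes <- gs$genes$gene_id[gs$genes$chrom_class == "Y"]
  expect_true(all(pb$counts[females, ygenes] == 0))
  # with zero age effects, per-gene age slopes center on zero
  auto <- gs$genes$gene_id[gs$genes$chrom_class == "autosome" &
                             is.na(gs$genes$eqtl_snp)]
  slopes <- apply(pb$log2cpm[, auto], 2, function(y)
    coef(lm(y ~ age_decades(ch$donors$age)))[2])
  expect_lt(abs(mean(slopes)), 0.01)
  # eQTL effect visible: expression separates by dosage for a strong eQTL
  eqg <- which(!is.na(gs$genes$eqtl_snp) &
                 abs(gs$eqtl_beta[, "D1_MSN"]) > 0.4)[1]
  gid <- gs$genes$gene_id[eqg]
  dos <- geno$dosage[ch$donors$donor_id, gs$genes$eqtl_snp[eqg]]
  b <- coef(lm(pb$log2cpm[, gid] ~ dos))[2]
  expect_lt(abs(unname(b) - gs$eqtl_beta[eqg, "D1_MSN"]), 0.05)
})

test_that("noise-free pseudobulk reproduces the generating age log2FC", {
  cts <- "astrocyte"
  gs <- gene_spec(cts, n_genes = 20, prop_age = 1, age_l2fc_sd = 0.1,
                  n_y = 0, n_x = 0, n_eqtl = 0, baseline_mean = 12,
                  baseline_sd = 0, seed = 4)
  cfg <- cohort_config(n_donors = 60, regions = "CaH",
                       celltypes = default_celltypes()[cts], genes = gs,
                       nb_dispersion = 0, libsize_sdlog = 0, seed = 29)
  ch <- generate_cohort(cfg)
  pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
  pb <- pb_get(pbs, "astrocyte")
  dec <- age_decades(ch$donors$age)
  for (j in c(1, 7, 20)) {
    slope <- coef(lm(pb$log2cpm[, j] ~ dec))[2]
    expect_equal(unname(slope), unname(gs$age_l2fc[j, cts]),
                 tolerance = 1e-3)
  }
})

test_that("a written cohort round-trips through plain-text files", {
  dir <- withr::local_tempdir()
  cfg <- one_ct_config(n_donors = 12, regions = "CaH", seed = 31,
                       nuclei_mean = 500)
  ch <- generate_cohort(cfg)
  cc <- generate_cell_counts(ch$donors, ch$truth, cfg)
  write_cohort(dir, ch$donors, ch$truth, samples = cc)
  don2 <- readr::read_tsv(file.path(dir, "donors.tsv"),
                          show_col_types = FALSE)
  expect_equal(don2$donor_id, ch$donors$donor_id)
  expect_equal(don2$age, ch$donors$age)
  cc2 <- readr::read_tsv(file.path(dir, "samples.tsv"),
                         show_col_types = FALSE)
  expect_equal(cc2$count, cc$count)
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("sparse counts aggregate to pseudobulk by addition, order-invariantly", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 1, 2, 1), j = c(1, 1, 2, 2, 3), x = c(1, 2, 3, 4, 9),
    dims = c(2, 3), dimnames = list(c("g1", "g2"), c("b1", "b2", "b3")))
  asg <- tibble::tibble(barcode = c("b1", "b2", "b3"),
                        donor_id = c("d1", "d1", "d2"),
                        cell_type = "T", region = "CaH")
  out <- aggregate_pseudobulk(m, asg, min_cells = 1)
  pb <- out$pb_set$pb[[1]]
  expect_equal(unname(pb$counts["d1", ]), c(4, 6))
  expect_equal(unname(pb$counts["d2", ]), c(9, 0))
  # permuted columns give identical pseudobulk
  out2 <- aggregate_pseudobulk(m[, c(3, 1, 2)], asg, min_cells = 1)
  expect_equal(out2$pb_set$pb[[1]]$counts[c("d1", "d2"), ],
               pb$counts[c("d1", "d2"), ])
  # min_cells excludes and logs
  out3 <- aggregate_pseudobulk(m, asg, min_cells = 2)
  expect_equal(out3$excluded$donor_id, "d2")
  expect_false("d2" %in% out3$pb_set$pb[[1]]$donors)
  expect_error(aggregate_pseudobulk(m[, 1:2], asg[2:3, ], min_cells = 1),
               "assignments")
})
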