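test_that("log2 CPM normalization follows the stated arithmetic", {
  m <- matrix(c(0, 1000), 1, 2, dimnames = list("d1", c("g1", "g2")))
  out <- normalize_log2cpm(m, library_size = 1e6)
  expect_equal(out[1, "g1"], 0)
  expect_equal(out[1, "g2"], log2(1001))
  # doubling counts and library leaves CPM unchanged
  expect_equal(normalize_log2cpm(2 * m, library_size = 2e6), out)
  expect_error(normalize_log2cpm(m, library_size = 0), "positive")
})

test_that("DE effect estimates equal the weighted-least-squares oracle", {
  cfg <- expr_config(celltypes = "astrocyte", n_genes = 60, n_donors = 60,
                     seed = 61)
  ch <- generate_cohort(cfg)
  pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
  pb <- pb_get(pbs, "astrocyte")
  de <- fit_age_sex_de(pb, ch$donors)
  # per-gene lm oracle with the same weights
  w <- log(pmax(pb$cell_count[pb$donors], 2))
  dn <- ch$donors[match(pb$donors, ch$donors$donor_id), ]
  dec <- age_decades(dn$age); male <- as.numeric(dn$sex == "M")
  for (g in unique(de$gene_id)[c(1, 11, 29)]) {
    ref <- lm(pb$log2cpm[, g] ~ dec + male, weights = w)
    row <- de[de$gene_id == g & de$test == "age", ]
    expect_equal(row$estimate, unname(coef(ref)["dec"]), tolerance = 1e-10)
    expect_equal(row$std_error,
                 unname(summary(ref)$coefficients["dec", 2]),
                 tolerance = 1e-10)
  }
})

test_that("a noiseless age-linear gene is recovered exactly with tiny p", {
  cfg <- expr_config(celltypes = "astrocyte", n_genes = 30, n_donors = 50,
                     seed = 67, prop_age = 1, age_l2fc_sd = 0.1,
                     baseline_mean = 12, baseline_sd = 0, n_y = 0, n_x = 0)
  cfg$nb_dispersion <- 0
  cfg$libsize_sdlog <- 0
  ch <- generate_cohort(cfg)
  pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
  de <- fit_age_sex_de(pb_get(pbs, "astrocyte"), ch$donors)
  age_rows <- de[de$test == "age", ]
  truth <- cfg$genes$age_l2fc[age_rows$gene_id, "astrocyte"]
  expect_equal(age_rows$estimate, unname(truth), tolerance = 2e-3)
  expect_true(all(age_rows$p_value[abs(truth) > 0.05] < 1e-12))
})

test_that("sex differential expression is confined to sex-chromosome genes", {
  # pooled over seeds: the autosomal share of q<0.05 sex hits is bounded by
  # the nominal 5% FDR (allowing Monte-Carlo slack around that expectation)
  hits <- purrr::map_dfr(1:4, function(s) {
    cfg <- expr_config(celltypes = "astrocyte", n_genes = 300,
                       n_donors = 120, seed = 70 + s, prop_age = 0,
                       n_y = 15, n_x = 15, sex_log2fc = 1.5)
    ch <- generate_cohort(cfg)
    pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
    de <- fit_age_sex_de(pb_get(pbs, "astrocyte"), ch$donors,
                         gene_meta = cfg$genes$genes)
    de[de$test == "sex" & de$q_value < 0.05, ]
  })
  expect_gt(nrow(hits), 40)
  expect_lte(mean(hits$chrom_class == "autosome"), 0.10)
})

test_that("cross-cell-type effect correlations separate shared from independent profiles", {
  cts <- c("D1_MSN", "D2_MSN", "astrocyte")
  gs <- gene_spec(cts, n_genes = 250, prop_age = 0.6, age_l2fc_sd = 0.15,
                  age_groups = list(c("D1_MSN", "D2_MSN"), "astrocyte"),
                  n_eqtl = 0, seed = 73)
  cfg <- cohort_config(n_donors = 130, regions = "CaH",
                       celltypes = default_celltypes()[cts], genes = gs,
                       seed = 73)
  ch <- generate_cohort(cfg)
  pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
  de <- fit_age_sex_de(pbs, ch$donors)
  cc <- cross_celltype_effect_correlation(de)
  r_msn <- cc$rho2[cc$cell_type_a == "D1_MSN" & cc$cell_type_b == "D2_MSN"]
  r_mix <- cc$rho2[cc$cell_type_b == "astrocyte" &
                     cc$cell_type_a == "D1_MSN"]
  expect_gt(r_msn, 0.8)
  expect_lt(r_mix, 0.1)
  # self-correlation and symmetry
  self <- cross_celltype_effect_correlation(
    dplyr::bind_rows(de, dplyr::mutate(de, cell_type = paste0(cell_type,
                                                              "_copy"))))
  expect_equal(self$rho2[self$cell_type_b == "D1_MSN_copy" &
                           self$cell_type_a == "D1_MSN"], 1)
})

test_that("k-means profile clustering recovers planted blocks and behaves canonically", {
  set.seed(5)
  up <- matrix(rnorm(60 * 3, mean = rep(c(0.3, 0.3, 0.3), each = 60),
                     sd = 0.02), 60, 3)
  down <- matrix(rnorm(60 * 3, mean = rep(c(-0.3, 0, 0), each = 60),
                       sd = 0.02), 60, 3)
  mat <- rbind(up, down)
  rownames(mat) <- sprintf("g%03d", 1:120)
  colnames(mat) <- c("MSN", "astro", "micro")
  cl <- cluster_age_profiles(mat, k = 2, seed = 9)
  truth <- rep(1:2, each = 60)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  # k = 1: centroid equals the column means
  c1 <- cluster_age_profiles(mat, k = 1, seed = 9)
  expect_equal(as.numeric(c1$centers), unname(colMeans(mat)))
  # determinism under a fixed seed
  cl2 <- cluster_age_profiles(mat, k = 2, seed = 9)
  expect_identical(cl$cluster, cl2$cluster)
  # Lloyd objective is non-increasing in the iteration budget
  wss <- sapply(1:5, function(it) {
    set.seed(33)
    suppressWarnings(kmeans(mat, 4, iter.max = it, nstart = 1,
                            algorithm = "Lloyd"))$tot.withinss
  })
  expect_true(all(diff(wss) <= 1e-9))
  expect_error(cluster_age_profiles(mat, k = 500), "exceeds")
})

test_that("effect-profile matrix includes only union-significant genes with a mask", {
  de <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    cell_type = rep(c("A", "B"), each = 3),
    region = "CaH", test = "age",
    estimate = c(0.5, 0.01, NA, 0.4, 0.02, 0.3),
    std_error = 0.1, statistic = 1, p_value = 0.5,
    q_value = c(0.001, 0.9, NA, 0.002, 0.8, 0.01), n_donors = 50)
  prof <- build_effect_profiles(de)
  expect_setequal(rownames(prof$beta), c("g1", "g3"))
  expect_true(prof$mask["g3", "A"])   # untested imputed as 0, masked
  expect_equal(prof$beta["g3", "A"], 0)
})

test_that("the moment TWI estimator is unbiased for the mean squared true effect", {
  # beta ~ N(0, 0.05^2) and known SEs: E[betahat^2 - se^2] = 0.0025
  ests <- sapply(1:60, function(s) {
    set.seed(s)
    ng <- 400
    beta <- rnorm(ng, 0, 0.05)
    se <- runif(ng, 0.02, 0.08)
    de <- tibble::tibble(gene_id = sprintf("g%d", 1:ng), cell_type = "A",
                         region = "CaH", test = "age",
                         estimate = beta + rnorm(ng, 0, se),
                         std_error = se, statistic = 0, p_value = 1,
                         q_value = 1, n_donors = 100)
    estimate_transcriptome_impact(de, n_boot = 50, seed = s)$twi
  })
  expect_lt(abs(mean(ests) - 0.0025), 4e-4)
  # null: estimate within 3 bootstrap SE of zero
  set.seed(99)
  ng <- 500
  se <- runif(ng, 0.02, 0.08)
  de0 <- tibble::tibble(gene_id = sprintf("g%d", 1:ng), cell_type = "A",
                        region = "CaH", test = "age",
                        estimate = rnorm(ng, 0, se), std_error = se,
                        statistic = 0, p_value = 1, q_value = 1,
                        n_donors = 100)
  out0 <- estimate_transcriptome_impact(de0, n_boot = 500, seed = 1)
  expect_lt(abs(out0$twi), 3 * out0$twi_se)
  expect_error(
    estimate_transcriptome_impact(dplyr::mutate(de0,
                                                std_error = NA_real_)),
    "standard errors")
})

test_that("cell types with larger true effects rank higher in transcriptome impact", {
  wins <- sapply(1:12, function(s) {
    gs_big <- gene_spec("D1_MSN", n_genes = 150, prop_age = 0.5,
                        age_l2fc_sd = 0.2, n_eqtl = 0, seed = s)
    gs_small <- gene_spec("TAC3_PLPP4", n_genes = 150, prop_age = 0.5,
                          age_l2fc_sd = 0.05, n_eqtl = 0, seed = s)
    mk <- function(gsx, ct) {
      cfg <- cohort_config(n_donors = 80, regions = "CaH",
                           celltypes = default_celltypes()[ct],
                           genes = gsx, seed = s)
      ch <- generate_cohort(cfg)
      pbs <- generate_pseudobulk(ch$donors, ch$truth, cfg)
      de <- fit_age_sex_de(pb_get(pbs, ct), ch$donors)
      estimate_transcriptome_impact(de[de$test == "age", ],
                                    n_boot = 50, seed = s)$twi
    }
    mk(gs_big, "D1_MSN") > mk(gs_small, "TAC3_PLPP4")
  })
  expect_gte(mean(wins), 0.95)
})
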