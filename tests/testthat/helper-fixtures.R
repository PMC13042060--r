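# Shared fixture builders. Everything is generated in code at test time.

# Single-cell-type cohort configuration for abundance tests.
one_ct_config <- function(name = "OPC", baseline = qlogis(0.03),
                          age_slope = -0.096, tau2 = 0.04, sigma2 = 0.02,
                          n_donors = 150, regions = c("CaH", "Pu"),
                          nuclei_mean = 5000, seed = 1L, ...) {
  cohort_config(
    n_donors = n_donors, regions = regions, nuclei_mean = nuclei_mean,
    celltypes = list(celltype_spec(name, baseline, age_slope = age_slope,
                                   tau2 = tau2, sigma2 = sigma2,
                                   class = "glia")),
    seed = seed, ...
  )
}

# Generate abundance observations for a single cell type in one call.
sim_abundance <- function(cfg, cell_type = names(cfg$celltypes)[1],
                          denominator = "all_nuclei") {
  ch <- generate_cohort(cfg)
  cc <- generate_cell_counts(ch$donors, ch$truth, cfg)
  abundance_observations(cc, ch$donors, cell_type,
                         denominator = denominator,
                         celltypes = cfg$celltypes)
}

# Independent grid-search beta-binomial MLE (iterative refinement), used as
# the optimizer oracle on tiny instances with design X = [1, x].
bb_grid_mle <- function(k, n, x, n_rounds = 6, grid_n = 21) {
  ll <- function(b0, b1, rho) {
    mu <- plogis(b0 + b1 * x)
    s <- (1 - rho) / rho
    a <- mu * s; b <- (1 - mu) * s
    sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  r0 <- c(-5, 5); r1 <- c(-3, 3); rr <- c(1e-4, 0.5)
  best <- c(NA, NA, NA, -Inf)
  for (round in seq_len(n_rounds)) {
    g0 <- seq(r0[1], r0[2], length.out = grid_n)
    g1 <- seq(r1[1], r1[2], length.out = grid_n)
    gr <- exp(seq(log(rr[1]), log(rr[2]), length.out = grid_n))
    for (b0 in g0) for (b1 in g1) for (rho in gr) {
      v <- ll(b0, b1, rho)
      if (v > best[4]) best <- c(b0, b1, rho, v)
    }
    w0 <- diff(r0) / (grid_n - 1); w1 <- diff(r1) / (grid_n - 1)
    r0 <- best[1] + c(-w0, w0); r1 <- best[2] + c(-w1, w1)
    lr <- log(rr); wr <- diff(lr) / (grid_n - 1)
    rr <- exp(log(best[3]) + c(-wr, wr))
  }
  list(b0 = best[1], b1 = best[2], rho = best[3], logLik = best[4])
}

# Small expression cohort for DE/clock/eQTL tests.
expr_config <- function(celltypes = c("D1_MSN", "astrocyte"),
                        n_genes = 200, n_donors = 100, seed = 1L,
                        gene_seed = seed, ...) {
  gs <- gene_spec(celltypes, n_genes = n_genes, n_eqtl = 0,
                  seed = gene_seed, ...)
  cohort_config(
    n_donors = n_donors, regions = "CaH",
    celltypes = default_celltypes()[celltypes],
    genes = gs, seed = seed
  )
}
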