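#' Generate the donor table and truth record for a synthetic cohort
#'
#' Draws donor ages uniformly on `age_range` (capped at 90, mirroring the
#' convention that precise ages above 89 are unavailable), sexes as
#' Bernoulli(`male_fraction`), assigns donors to villages of `village_size`,
#' and draws each donor's latent cell-type propensities
#' `u[i, g] ~ Normal(0, tau2_g)`, identical across regions. Everything needed
#' to regenerate downstream observables is kept in the truth record.
#'
#' @param config A [cohort_config()].
#' @return A list with `donors` (tibble: donor_id, age, sex, village_id) and
#'   `truth` (list: config, donors, `u` matrix, biological-age offsets, seed).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  seeds <- derive_seeds(config$seed, 4L)
  with_seed(seeds[1], {
    n <- config$n_donors
    age <- pmin(runif(n, config$age_range[1], config$age_range[2]), 90)
    sex <- ifelse(runif(n) < config$male_fraction, "M", "F")
    village <- sprintf("V%02d", ((seq_len(n) - 1L) %/% config$village_size) + 1L)
    donors <- tibble::tibble(
      donor_id = sprintf("D%04d", seq_len(n)),
      age = age, sex = sex, village_id = village
    )
    cts <- config$celltypes
    u <- vapply(cts, function(ct) rnorm(n, 0, sqrt(ct$tau2)), numeric(n))
    if (is.null(dim(u))) u <- matrix(u, nrow = n)
    dimnames(u) <- list(donors$donor_id, names(cts))
    bio <- if (config$bio_age_sd > 0) {
      if (config$bio_age_shared) {
        matrix(rnorm(n, 0, config$bio_age_sd), n, length(cts),
               dimnames = dimnames(u))
      } else {
        matrix(rnorm(n * length(cts), 0, config$bio_age_sd), n, length(cts),
               dimnames = dimnames(u))
      }
    } else {
      matrix(0, n, length(cts), dimnames = dimnames(u))
    }
    truth <- list(config = config, donors = donors, u = u,
                  bio_age_offset = bio, seed = config$seed)
    list(donors = donors, truth = truth)
  })
}

ct_baseline <- function(ct, region) {
  b <- ct$baseline_logit
  if (is.null(names(b))) return(b[[1]])
  if (!region %in% names(b)) {
    abort(sprintf("cell type '%s' has no baseline for region '%s'.",
                  ct$name, region))
  }
  b[[region]]
}

#' Generate per-sample cell-type counts
#'
#' For each donor-by-region sample, the total nucleus count is negative
#' binomial; each cell type's expected fraction is inverse-logit of
#' `baseline(region) + slope * (age - 60)/10 + u[donor] + e[sample]` with
#' `e ~ Normal(0, sigma2)`; counts are a single multinomial draw over the
#' named cell types plus an explicit remainder class, which guarantees
#' compositional closure while keeping each type's marginal logit equal to
#' its linear predictor.
#'
#' @param donors Donor tibble from [generate_cohort()].
#' @param truth Truth record from [generate_cohort()].
#' @param config The same [cohort_config()].
#' @return Tibble with columns donor_id, region, cell_type, count,
#'   total_nuclei (long format; includes an `"other"` remainder type).
#' @export
generate_cell_counts <- function(donors, truth, config) {
  if (!all(donors$donor_id %in% rownames(truth$u))) {
    abort("truth record is missing latent propensities for some donors.")
  }
  seeds <- derive_seeds(config$seed, 4L)
  with_seed(seeds[2], {
    cts <- config$celltypes
    nct <- length(cts)
    nd <- nrow(donors)
    slope <- vapply(cts, `[[`, numeric(1), "age_slope")
    sig <- sqrt(vapply(cts, `[[`, numeric(1), "sigma2"))
    u <- truth$u[donors$donor_id, , drop = FALSE]
    dec <- age_decades(donors$age)
    out <- vector("list", length(config$regions))
    for (ri in seq_along(config$regions)) {
      r <- config$regions[ri]
      base <- vapply(cts, ct_baseline, numeric(1), region = r)
      e <- matrix(rnorm(nd * nct, 0, rep(sig, each = nd)), nd, nct)
      eta <- matrix(base, nd, nct, byrow = TRUE) + outer(dec, slope) + u + e
      p <- plogis(eta)
      rest <- 1 - rowSums(p)
      bad <- rest < 0.01  # guard degenerate configs; keep a remainder sliver
      if (any(bad)) {
        p[bad, ] <- p[bad, , drop = FALSE] * (0.99 / rowSums(p)[bad])
        rest[bad] <- 0.01
      }
      n_tot <- pmax(1L, rnbinom(nd, size = config$nuclei_size,
                                mu = config$nuclei_mean))
      cnt <- vapply(seq_len(nd), function(i) {
        as.integer(rmultinom(1, n_tot[i], c(p[i, ], rest[i])))
      }, integer(nct + 1L))
      out[[ri]] <- tibble::tibble(
        donor_id = rep(donors$donor_id, each = nct + 1L),
        region = r,
        cell_type = rep(c(names(cts), "other"), nd),
        count = as.integer(cnt),
        total_nuclei = rep(n_tot, each = nct + 1L)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Build abundance observations with a chosen denominator
#'
#' Converts long per-sample counts into the (k, N) pairs the beta-binomial
#' abundance model consumes. The denominator can be all nuclei, all members
#' of a coarse class (e.g. all neurons), or an explicit set of cell types
#' (e.g. MSNs only).
#'
#' @param counts Long counts tibble from [generate_cell_counts()] (columns
#'   donor_id, region, cell_type, count, total_nuclei).
#' @param donors Donor tibble (donor_id, age, sex, ...).
#' @param numerator Cell type whose abundance is modeled.
#' @param denominator `"all_nuclei"`, a class name prefixed `"class:"`
#'   (e.g. `"class:neuron"`), or a character vector of cell types.
#' @param celltypes Cell-type spec list (needed for class denominators);
#'   defaults to none.
#' @return Tibble: donor_id, region, k, n, age, sex.
#' @export
abundance_observations <- function(counts, donors, numerator,
                                   denominator = "all_nuclei",
                                   celltypes = NULL) {
  num <- counts |>
    dplyr::filter(.data$cell_type == numerator) |>
    dplyr::select("donor_id", "region", k = "count", "total_nuclei")
  if (identical(denominator, "all_nuclei")) {
    den <- dplyr::mutate(num, n = .data$total_nuclei)
  } else {
    if (length(denominator) == 1 && startsWith(denominator, "class:")) {
      cls <- sub("^class:", "", denominator)
      if (is.null(celltypes)) abort("class denominators need `celltypes`.")
      types <- names(celltypes)[vapply(celltypes, `[[`, "", "class") == cls]
    } else {
      types <- denominator
    }
    if (!numerator %in% types) types <- c(types, numerator)
    den_tbl <- counts |>
      dplyr::filter(.data$cell_type %in% types) |>
      dplyr::summarise(n = sum(.data$count),
                       .by = c("donor_id", "region"))
    den <- dplyr::left_join(num, den_tbl, by = c("donor_id", "region"))
  }
  den |>
    dplyr::select("donor_id", "region", "k", "n") |>
    dplyr::left_join(dplyr::select(donors, "donor_id", "age", "sex"),
                     by = "donor_id") |>
    dplyr::filter(.data$n > 0)
}

#' Generate donor genotypes at specified SNPs
#'
#' Dosages (count of alternate alleles, 0/1/2) are drawn from Hardy-Weinberg
#' proportions at each SNP's minor-allele frequency; SNPs are independent.
#'
#' @param donors Donor tibble.
#' @param config A [cohort_config()] whose `genes` element carries a `snps`
#'   table, or a tibble of SNPs (snp_id, chrom, pos, maf) passed directly.
#' @return List: `dosage` (donors-by-SNPs integer matrix) and `snps` tibble.
#' @export
generate_genotypes <- function(donors, config) {
  snps <- if (inherits(config, "cohort_config")) config$genes$snps else config
  if (is.null(snps) || nrow(snps) == 0) abort("no SNPs specified.")
  if (any(snps$maf <= 0 | snps$maf > 0.5)) abort("MAF must lie in (0, 0.5].")
  seed <- if (inherits(config, "cohort_config"))
    derive_seeds(config$seed, 4L)[4] else 9601L
  with_seed(seed, {
    n <- nrow(donors)
    dos <- vapply(snps$maf, function(m) {
      probs <- c((1 - m)^2, 2 * m * (1 - m), m^2)
      sample(0:2, n, replace = TRUE, prob = probs)
    }, integer(n))
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = n)
    dimnames(dos) <- list(donors$donor_id, snps$snp_id)
    list(dosage = dos, snps = snps)
  })
}

#' Generate pseudobulk expression per cell type and region
#'
#' For donor i, gene j, cell type c the expected log2 CPM is
#' `baseline_j + age_l2fc[j,c] * (age_i + bio_offset_i - 60)/10 +
#' sex_log2fc_j * I(male) + eqtl_beta[j,c] * dosage_i`; Y-chromosome genes
#' are silent in XX donors and X-escape genes are elevated in XX donors.
#' Observed counts are negative binomial around `libsize * 2^log2cpm / 1e6`
#' with a log-normal library size per pseudobulk sample; dispersion 0 yields
#' the noise-free expectation.
#'
#' @param donors,truth,config As returned by [generate_cohort()].
#' @param geno Optional genotype list from [generate_genotypes()] (required
#'   when the gene panel contains eQTLs).
#' @param samples Optional counts tibble from [generate_cell_counts()]; if
#'   given, per-donor cell counts are taken from it, otherwise a nominal 500.
#' @param regions Regions to generate (default: all in the config).
#' @param celltypes Cell types to generate (default: all in the config).
#' @return A `pseudobulk_set`: tibble with columns cell_type, region and a
#'   list-column `pb` of `pseudobulk` objects (counts, log2cpm, library_size,
#'   cell_count, donors).
#' @export
generate_pseudobulk <- function(donors, truth, config, geno = NULL,
                                samples = NULL, regions = config$regions,
                                celltypes = names(config$celltypes)) {
  gs <- config$genes
  if (is.null(gs)) abort("config has no gene panel; supply `genes = gene_spec(...)`.")
  if (any(!is.na(gs$genes$eqtl_snp)) && is.null(geno)) {
    abort("gene panel has eQTLs; supply `geno = generate_genotypes(...)`.")
  }
  if (!is.null(geno)) {
    miss <- setdiff(na.omit(gs$genes$eqtl_snp), colnames(geno$dosage))
    if (length(miss)) abort(sprintf("gene panel references unknown SNPs: %s",
                                    paste(head(miss, 3), collapse = ", ")))
  }
  seeds <- derive_seeds(config$seed, 4L)
  with_seed(seeds[3], {
    nd <- nrow(donors)
    ng <- nrow(gs$genes)
    male <- donors$sex == "M"
    grid <- expand.grid(cell_type = celltypes, region = regions,
                        stringsAsFactors = FALSE)
    pbs <- vector("list", nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      ct <- grid$cell_type[gi]; rg <- grid$region[gi]
      eff_age <- donors$age + truth$bio_age_offset[donors$donor_id, ct]
      l2 <- matrix(rep(gs$genes$baseline_log2cpm, each = nd), nd, ng,
                   dimnames = list(donors$donor_id, gs$genes$gene_id))
      l2 <- l2 + outer(age_decades(eff_age), gs$age_l2fc[, ct])
      l2 <- l2 + outer(as.numeric(male), gs$genes$sex_log2fc)
      if (!is.null(geno)) {
        has_eq <- which(!is.na(gs$genes$eqtl_snp))
        if (length(has_eq)) {
          dos <- geno$dosage[donors$donor_id, gs$genes$eqtl_snp[has_eq],
                             drop = FALSE]
          l2[, has_eq] <- l2[, has_eq] +
            dos * matrix(rep(gs$eqtl_beta[has_eq, ct], each = nd),
                         nd, length(has_eq))
        }
      }
      lib <- rlnorm(nd, config$libsize_meanlog, config$libsize_sdlog)
      mu <- lib * 2^l2 / 1e6
      y_genes <- gs$genes$chrom_class == "Y"
      if (any(y_genes)) mu[!male, y_genes] <- 0
      counts <- if (config$nb_dispersion > 0) {
        matrix(rnbinom(nd * ng, size = 1 / config$nb_dispersion, mu = mu),
               nd, ng, dimnames = dimnames(l2))
      } else mu
      cell_count <- if (!is.null(samples)) {
        cc <- samples |>
          dplyr::filter(.data$cell_type == ct, .data$region == rg)
        setNames(cc$count, cc$donor_id)[donors$donor_id]
      } else setNames(rep(500L, nd), donors$donor_id)
      pbs[[gi]] <- new_pseudobulk(counts, lib, cell_count, ct, rg,
                                  donors$donor_id)
    }
    structure(tibble::tibble(cell_type = grid$cell_type,
                             region = grid$region, pb = pbs),
              class = c("pseudobulk_set", "tbl_df", "tbl", "data.frame"))
  })
}

new_pseudobulk <- function(counts, library_size, cell_count, cell_type,
                           region, donor_ids) {
  structure(
    list(counts = counts, library_size = library_size,
         cell_count = cell_count, cell_type = cell_type, region = region,
         donors = donor_ids,
         log2cpm = log2(sweep(counts, 1, library_size, "/") * 1e6 + 1)),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %s / %s: %d donors x %d genes\n",
              x$cell_type, x$region, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Extract one pseudobulk object from a pseudobulk set
#' @param pb_set A `pseudobulk_set`.
#' @param cell_type,region Selector; `region = NULL` takes the first match.
#' @return A `pseudobulk` object.
#' @export
pb_get <- function(pb_set, cell_type, region = NULL) {
  keep <- pb_set$cell_type == cell_type
  if (!is.null(region)) keep <- keep & pb_set$region == region
  i <- which(keep)
  if (!length(i)) abort("no matching pseudobulk entry.")
  pb_set$pb[[i[1]]]
}

# --- Gauss-Hermite machinery for sharing calibration -----------------------

gh_rule <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  # nodes/weights for E[g(Z)], Z ~ N(0,1)
  list(x = sqrt(2) * e$values, w = (e$vectors[1, ]^2))
}

fraction_moments <- function(baseline_logit, tau2, sigma2, n_nuclei,
                             rule = gh_rule(40)) {
  v <- tau2 + sigma2
  x <- rule$x; w <- rule$w
  f1 <- plogis(baseline_logit + sqrt(v) * x)
  m1 <- sum(w * f1)
  m2 <- sum(w * f1^2)
  # E[f(X) f(Y)] with corr(X, Y) = tau2 / v
  a <- sqrt(v); c_ <- if (a > 0) tau2 / a else 0
  d <- sqrt(max(v - c_^2, 0))
  fx <- plogis(baseline_logit + a * x)          # over z1
  cross <- 0
  for (j in seq_along(x)) {
    fy <- plogis(baseline_logit + c_ * x[j] + d * x)  # over z2 at z1 = x[j]
    cross <- cross + w[j] * fx[j] * sum(w * fy)
  }
  var_p <- m2 - m1^2
  binom <- sum(w * f1 * (1 - f1)) / n_nuclei
  list(mean = m1, var_obs = var_p + binom, cov_regions = cross - m1^2)
}

#' Calibrate cross-region sharing to a target fraction-scale r-squared
#'
#' The squared Pearson correlation of a cell type's observed fractions
#' between two regions is determined by the donor-shared propensity variance
#' tau2, the sample noise sigma2, the baseline fraction, and binomial
#' sampling noise at the sample's nucleus count. Given a target r-squared
#' (the quantity reported for glial abundances between caudate and DFC),
#' this solves for tau2 (holding tau2 + sigma2 fixed at `total_var`) so that
#' the generator's TRUE squared correlation of observed fractions equals the
#' target, using Gauss-Hermite quadrature over the bivariate latent logits.
#'
#' @param target_r2 Desired squared Pearson correlation of observed fractions.
#' @param baseline_logit Baseline logit fraction.
#' @param n_nuclei Nuclei per sample (binomial denominator).
#' @param total_var Total latent logit variance tau2 + sigma2.
#' @return List with `tau2`, `sigma2`, and the achieved `r2`.
#' @export
calibrate_sharing <- function(target_r2, baseline_logit, n_nuclei = 5000,
                              total_var = 0.1) {
  stopifnot_scalar_prob(target_r2, "target_r2")
  rule <- gh_rule(40)
  f <- function(tau2) {
    mom <- fraction_moments(baseline_logit, tau2, total_var - tau2,
                            n_nuclei, rule)
    (mom$cov_regions / mom$var_obs)^2 - target_r2
  }
  sol <- stats::uniroot(f, c(1e-8, total_var - 1e-8), tol = 1e-10)
  tau2 <- sol$root
  list(tau2 = tau2, sigma2 = total_var - tau2,
       r2 = f(tau2) + target_r2)
}
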