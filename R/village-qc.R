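#' Expected genotypic-doublet fraction of a village
#'
#' In a pool of donors with nucleus proportions `p`, a random pair of nuclei
#' comes from two different donors with probability `1 - sum(p^2)`; only such
#' heterotypic ("genotypic") doublets are detectable from mixed genotypes.
#'
#' @param proportions Numeric vector of per-donor nucleus proportions
#'   (must sum to 1 within 1e-6).
#' @return The expected fraction of doublets that are genotypic.
#' @export
expected_genotypic_doublet_fraction <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be non-negative.")
  if (abs(sum(proportions) - 1) > 1e-6) {
    abort("proportions must sum to 1 (tolerance 1e-6).")
  }
  1 - sum(proportions^2)
}

#' Infer the total doublet rate from genotypic-doublet counts
#'
#' Genotypic doublets are the detectable subset of all doublets; dividing
#' the observed genotypic-doublet rate by the expected genotypic fraction
#' recovers the total rate (genotypic plus same-donor).
#'
#' @param n_genotypic Number of barcodes called genotypic doublets.
#' @param n_barcodes Total number of barcodes.
#' @param proportions Village composition (see
#'   [expected_genotypic_doublet_fraction()]).
#' @return Estimated total doublet rate.
#' @export
infer_total_doublet_rate <- function(n_genotypic, n_barcodes, proportions) {
  if (n_genotypic > n_barcodes) abort("n_genotypic cannot exceed n_barcodes.")
  ef <- expected_genotypic_doublet_fraction(proportions)
  if (ef == 0) abort("single-donor village: genotypic doublets unobservable.")
  (n_genotypic / n_barcodes) / ef
}

#' Flag clusters enriched for genotypic doublets
#'
#' Clusters whose nuclei look like mixtures of other cell types tend to be
#' doublet-driven; they reveal themselves by containing far more genotypic
#' doublets than the dataset-wide rate predicts. Each cluster gets a
#' one-sided binomial test against the global genotypic-doublet rate; BH
#' correction is applied across clusters, and a cluster is flagged when its
#' q-value falls below `alpha` AND its observed doublet fraction is at least
#' twice the global rate (so huge clusters with trivial excess escape).
#'
#' @param assignments Tibble with per-nucleus columns `cluster` and
#'   `genotypic_doublet` (0/1 or logical).
#' @param alpha Significance level on the BH q-value (default 0.05).
#' @param min_enrichment Required fold-enrichment over the global rate
#'   (default 2).
#' @return Tibble: cluster_id, n_nuclei, n_genotypic_doublets,
#'   observed_fraction, expected_fraction, p_value, q_value, flagged.
#' @export
flag_doublet_clusters <- function(assignments, alpha = 0.05,
                                  min_enrichment = 2) {
  if (!nrow(assignments)) abort("empty assignment table.")
  base_rate <- mean(as.numeric(assignments$genotypic_doublet))
  stats <- assignments |>
    dplyr::summarise(
      n_nuclei = dplyr::n(),
      n_genotypic_doublets = sum(as.numeric(.data$genotypic_doublet)),
      .by = "cluster"
    ) |>
    dplyr::rename(cluster_id = "cluster") |>
    dplyr::mutate(
      observed_fraction = .data$n_genotypic_doublets / .data$n_nuclei,
      expected_fraction = base_rate,
      p_value = pbinom(.data$n_genotypic_doublets - 1, .data$n_nuclei,
                       base_rate, lower.tail = FALSE)
    )
  stats$q_value <- bh_adjust(stats$p_value, nrow(stats))
  stats$flagged <- stats$q_value < alpha &
    stats$observed_fraction >= min_enrichment * base_rate
  stats
}

#' Exclude low-quality or compositionally abnormal samples
#'
#' Two data-driven rules: (1) samples whose total nucleus count falls below
#' `min_nuclei` are excluded for low ascertainment; (2) within each region,
#' cell-type proportions are centered-log-ratio transformed (pseudocount 0.5
#' on zero counts) and each coordinate converted to a robust z-score
#' (median/MAD); samples whose maximum |z| exceeds `z_thresh` are excluded
#' as compositional outliers. Every exclusion carries a machine-readable
#' reason.
#'
#' @param samples Long counts tibble (donor_id, region, cell_type, count,
#'   total_nuclei).
#' @param min_nuclei Minimum total nuclei per sample (default 500).
#' @param z_thresh Robust-z threshold (default 4).
#' @return List with `kept` and `excluded` tibbles; `excluded` has columns
#'   donor_id, region, reason (`"low_ascertainment"` or
#'   `"abnormal_composition"`), max_abs_z.
#' @export
exclude_outlier_samples <- function(samples, min_nuclei = 500, z_thresh = 4) {
  if (any(samples$count < 0)) abort("negative cell counts.")
  wide <- samples |>
    tidyr::pivot_wider(id_cols = c("donor_id", "region", "total_nuclei"),
                       names_from = "cell_type", values_from = "count",
                       values_fill = 0L)
  low <- wide$total_nuclei < min_nuclei
  ct_cols <- setdiff(names(wide), c("donor_id", "region", "total_nuclei"))
  cnt <- as.matrix(wide[, ct_cols])
  cnt[cnt == 0] <- 0.5
  clr <- log(cnt / wide$total_nuclei)
  clr <- clr - rowMeans(clr)
  maxz <- rep(NA_real_, nrow(wide))
  for (r in unique(wide$region)) {
    i <- which(wide$region == r & !low)
    if (length(i) < 3) abort(sprintf("region '%s' has < 3 usable samples.", r))
    med <- apply(clr[i, , drop = FALSE], 2, median)
    madv <- apply(clr[i, , drop = FALSE], 2, mad)
    madv[madv == 0] <- Inf  # constant coordinate carries no outlier signal
    z <- abs(sweep(sweep(clr[i, , drop = FALSE], 2, med), 2, madv, "/"))
    maxz[i] <- apply(z, 1, max)
  }
  out <- wide |>
    dplyr::select("donor_id", "region", "total_nuclei") |>
    dplyr::mutate(
      max_abs_z = maxz,
      reason = dplyr::case_when(
        low ~ "low_ascertainment",
        maxz > z_thresh ~ "abnormal_composition",
        TRUE ~ NA_character_
      )
    )
  excluded <- dplyr::filter(out, !is.na(.data$reason))
  kept <- dplyr::filter(out, is.na(.data$reason)) |>
    dplyr::select("donor_id", "region")
  if (!nrow(kept)) abort("all samples excluded; check thresholds.")
  list(
    kept = dplyr::semi_join(samples, kept, by = c("donor_id", "region")),
    excluded = dplyr::select(excluded, "donor_id", "region", "reason",
                             "max_abs_z")
  )
}

#' Simulate barcode doublet status in a pooled village
#'
#' Utility for checking the doublet accounting: draws each barcode as a
#' doublet with probability `doublet_rate`, assigns the contributing donors
#' by the village composition, and marks a doublet genotypic when its two
#' donors differ.
#'
#' @param n_barcodes Number of barcodes.
#' @param proportions Village composition.
#' @param doublet_rate True total doublet rate.
#' @return Tibble: barcode, is_doublet, genotypic_doublet.
#' @export
simulate_village_doublets <- function(n_barcodes, proportions, doublet_rate) {
  stopifnot_scalar_prob(doublet_rate, "doublet_rate")
  nd <- length(proportions)
  is_dbl <- runif(n_barcodes) < doublet_rate
  d1 <- sample.int(nd, n_barcodes, replace = TRUE, prob = proportions)
  d2 <- sample.int(nd, n_barcodes, replace = TRUE, prob = proportions)
  tibble::tibble(
    barcode = sprintf("BC%06d", seq_len(n_barcodes)),
    is_doublet = is_dbl,
    genotypic_doublet = is_dbl & d1 != d2
  )
}
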