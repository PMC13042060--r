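#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Standard step-up BH with enforced monotonicity. The family size is
#' declared explicitly (it may exceed the number of p-values supplied, e.g.
#' when a fixed 44-test or 498-test family is only partially materialized).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param family_size Total number of tests in the declared family; must be
#'   at least `length(pvalues)`. Defaults to `length(pvalues)`.
#' @return Vector of BH q-values, in input order.
#' @export
bh_adjust <- function(pvalues, family_size = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  if (family_size < length(pvalues)) {
    abort("`family_size` must be >= the number of p-values.")
  }
  p.adjust(pvalues, method = "BH", n = family_size)
}

#' Cross-region correlation of donor-level values
#'
#' Spearman correlation of a per-donor quantity (e.g. a cell type's fraction
#' or fraction residual) between every pair of regions, using donors sampled
#' in both members of a pair, with BH correction across a declared family.
#' Pairs with fewer than `min_pairs` shared donors are reported as NA rather
#' than dropped.
#'
#' @param df Tibble with columns `donor_id`, `region`, and `value`.
#' @param family_size BH family size (e.g. 498 for the glial/interneuron
#'   cross-region family); defaults to the number of pairs.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_pairs Minimum shared donors per pair (default 5).
#' @return Tibble: region_a, region_b, n_shared, rho, p_value, q_value.
#' @export
cross_region_correlation <- function(df, family_size = NULL,
                                     method = "spearman", min_pairs = 5) {
  wide <- tidyr::pivot_wider(df, id_cols = "donor_id",
                             names_from = "region", values_from = "value")
  regions <- setdiff(names(wide), "donor_id")
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    ok <- complete.cases(x, y)
    if (sum(ok) < min_pairs) {
      return(tibble::tibble(region_a = pr[1], region_b = pr[2],
                            n_shared = sum(ok), rho = NA_real_,
                            p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                    exact = FALSE))
    tibble::tibble(region_a = pr[1], region_b = pr[2], n_shared = sum(ok),
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  fam <- family_size %||% nrow(res)
  res$q_value <- NA_real_
  ok <- !is.na(res$p_value)
  res$q_value[ok] <- bh_adjust(res$p_value[ok], max(fam, sum(ok)))
  res
}

#' Fractional decline implied by a log-odds slope over a span
#'
#' For a rare cell type the odds approximate the fraction, so a per-decade
#' log-odds slope `beta` sustained over `span` decades implies a fractional
#' decline of `1 - exp(beta * span)`. The exact decline on the fraction
#' scale is also reported when a baseline logit is supplied.
#'
#' @param beta_age Log-odds slope per decade.
#' @param span_decades Span in decades (e.g. 5 for age 30 to 80).
#' @param baseline_logit Optional baseline logit at the span's start for the
#'   exact fraction-scale decline.
#' @return Tibble: beta_age, span_decades, decline (odds-scale
#'   approximation), decline_exact (NA without a baseline).
#' @export
decline_over_span <- function(beta_age, span_decades, baseline_logit = NULL) {
  if (any(span_decades <= 0)) abort("`span_decades` must be positive.")
  decline <- 1 - exp(beta_age * span_decades)
  exact <- if (is.null(baseline_logit)) NA_real_ else {
    1 - plogis(baseline_logit + beta_age * span_decades) / plogis(baseline_logit)
  }
  tibble::tibble(beta_age = beta_age, span_decades = span_decades,
                 decline = decline, decline_exact = exact)
}

#' Conservative pairwise fold-difference from shared cross-region variation
#'
#' Focuses on the component of inter-individual variation that is shared
#' between two regions: the shared donor-level variance is estimated as the
#' sample covariance of the two regions' natural-log fractions (clipped at
#' zero). For two independent donors whose shared components are
#' Normal(0, s2), the median fold-difference between them is
#' `exp(median |X - Y|) = exp(0.9539 * sqrt(s2))`. A parametric bootstrap
#' (bivariate normal at the estimated moments) supplies the CI.
#'
#' @param log_frac_a,log_frac_b Paired per-donor natural-log fractions in
#'   the two regions (same donor order).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf_level CI level (default 0.95).
#' @return Tibble: shared_variance, median_fold, conf_low, conf_high,
#'   negative_covariance flag.
#' @export
pairwise_fold_difference <- function(log_frac_a, log_frac_b, n_boot = 1000,
                                     conf_level = 0.95) {
  ok <- complete.cases(log_frac_a, log_frac_b)
  x <- log_frac_a[ok]; y <- log_frac_b[ok]
  if (length(x) < 10) abort("need >= 10 paired donors.")
  cv <- cov(x, y)
  neg <- cv < 0
  fold_of <- function(s2) exp(0.9539 * sqrt(max(s2, 0)))
  if (neg) {
    warn("negative cross-region covariance; returning fold 1.0.")
    return(tibble::tibble(shared_variance = 0, median_fold = 1,
                          conf_low = NA_real_, conf_high = NA_real_,
                          negative_covariance = TRUE))
  }
  Sig <- matrix(c(var(x), cv, cv, var(y)), 2)
  n <- length(x)
  ch <- chol(Sig)
  boots <- vapply(seq_len(n_boot), function(b) {
    z <- matrix(rnorm(2 * n), n, 2) %*% ch
    fold_of(cov(z[, 1], z[, 2]))
  }, numeric(1))
  al <- (1 - conf_level) / 2
  tibble::tibble(
    shared_variance = cv, median_fold = fold_of(cv),
    conf_low = unname(quantile(boots, al)),
    conf_high = unname(quantile(boots, 1 - al)),
    negative_covariance = FALSE
  )
}

#' Wilcoxon rank-sum comparison of a donor-level quantity between regions
#'
#' Utility for between-region abundance contrasts (e.g. the D1/D2 MSN ratio
#' in caudate vs putamen). Exact for small samples without ties, normal
#' approximation with tie correction otherwise (the [stats::wilcox.test()]
#' default policy).
#'
#' @param df Tibble with columns `region` and `value`.
#' @param region_a,region_b The two regions to compare.
#' @return Tibble: region_a, region_b, n_a, n_b, statistic, p_value,
#'   median_a, median_b.
#' @export
region_wilcoxon <- function(df, region_a, region_b) {
  x <- df$value[df$region == region_a]
  y <- df$value[df$region == region_b]
  wt <- wilcox.test(x, y)
  tibble::tibble(region_a = region_a, region_b = region_b,
                 n_a = length(x), n_b = length(y),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 median_a = median(x), median_b = median(y))
}
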