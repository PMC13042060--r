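#' Train a cell-type-specific transcriptional aging clock
#'
#' Elastic-net regression of donor age on the standardized log2 expression
#' of the cell type's age-associated genes. Out-of-sample predictions come
#' from an outer K-fold cross-validation (every donor predicted by a model
#' that never saw it); the penalty is selected by an inner 5-fold CV on each
#' training set; feature standardization is estimated inside each training
#' fold only (no leakage). Repeating the outer CV over several fold
#' assignments yields a per-donor prediction SD. The reported coefficient
#' set comes from a final fit on all donors (used for gene-set overlap, not
#' for prediction).
#'
#' @param pb A `pseudobulk` object.
#' @param gene_ids Features: the cell type's age-associated genes (e.g.
#'   `q < 0.05` rows of [fit_age_sex_de()]).
#' @param donors Donor tibble (donor_id, age, ...).
#' @param n_folds Outer folds (default 10).
#' @param alpha Elastic-net mixing (default 0.5; 0 is ridge, 1 lasso).
#' @param n_repeats Outer-CV repeats for the prediction SD (default 20).
#' @param seed RNG seed.
#' @param lambda Optional fixed lambda (skips the inner CV).
#' @return A `clock_fit` list: `model` (cell type, region, selected genes
#'   and coefficients, alpha, lambda, CV descriptor, MAE, MAD) and
#'   `predictions` tibble (donor_id, chronological_age, predicted_age,
#'   prediction_sd).
#' @export
train_clock <- function(pb, gene_ids, donors, n_folds = 10, alpha = 0.5,
                        n_repeats = 20, seed = 1L, lambda = NULL) {
  gene_ids <- intersect(gene_ids, colnames(pb$log2cpm))
  if (length(gene_ids) < 10) abort("need >= 10 age-associated genes.")
  dn <- donors[match(pb$donors, donors$donor_id), ]
  if (nrow(dn) < 40) abort("need >= 40 donors.")
  X <- pb$log2cpm[, gene_ids, drop = FALSE]
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d constant features.", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  y <- dn$age
  n <- length(y)
  seeds <- derive_seeds(seed, n_repeats)
  pred_mat <- matrix(NA_real_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    pred_mat[, r] <- with_seed(seeds[r], {
      fold <- sample(rep_len(seq_len(n_folds), n))
      pr <- rep(NA_real_, n)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (is.null(lambda)) {
          cvf <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                                   alpha = alpha, nfolds = 5,
                                   standardize = TRUE)
          lam <- cvf$lambda.min
          fitf <- cvf$glmnet.fit
        } else {
          lam <- lambda
          fitf <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                                 alpha = alpha, standardize = TRUE)
        }
        pr[!tr] <- as.numeric(predict(fitf, X[!tr, , drop = FALSE],
                                      s = lam))
      }
      pr
    })
  }
  predicted <- rowMeans(pred_mat)
  pred_sd <- if (n_repeats > 1) apply(pred_mat, 1, sd) else rep(NA_real_, n)

  final <- with_seed(seeds[1], {
    if (is.null(lambda)) {
      cvf <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5,
                               standardize = TRUE)
      list(fit = cvf$glmnet.fit, lambda = cvf$lambda.min)
    } else {
      list(fit = glmnet::glmnet(X, y, alpha = alpha, standardize = TRUE),
           lambda = lambda)
    }
  })
  cf <- as.matrix(coef(final$fit, s = final$lambda))
  sel <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  preds <- tibble::tibble(
    donor_id = dn$donor_id, cell_type = pb$cell_type, region = pb$region,
    chronological_age = y, predicted_age = predicted,
    prediction_sd = pred_sd, raw_residual = predicted - y
  )
  model <- list(
    cell_type = pb$cell_type, region = pb$region,
    genes = sel, coefficients = setNames(cf[sel, 1], sel),
    intercept = cf["(Intercept)", 1], alpha = alpha,
    lambda = final$lambda,
    cv_scheme = sprintf("outer %d-fold x %d repeats, inner 5-fold",
                        n_folds, n_repeats),
    mae = mean(abs(predicted - y)),
    mad_residual = mad(predicted - y)
  )
  structure(list(model = model, predictions = preds), class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("<clock_fit> %s / %s: %d donors, %d genes | MAE %.2f y\n",
              x$model$cell_type, x$model$region, nrow(x$predictions),
              length(x$model$genes), x$model$mae))
  invisible(x)
}

#' Tidy an aging-clock fit
#' @param x A `clock_fit`.
#' @param ... Unused.
#' @return Tibble of nonzero gene coefficients.
#' @export
tidy.clock_fit <- function(x, ...) {
  tibble::tibble(cell_type = x$model$cell_type, region = x$model$region,
                 gene_id = x$model$genes,
                 coefficient = unname(x$model$coefficients))
}

#' One-row summary of an aging-clock fit
#' @param x A `clock_fit`.
#' @param ... Unused.
#' @return Tibble with MAE, MAD, gene count, lambda, alpha, CV scheme.
#' @export
glance.clock_fit <- function(x, ...) {
  tibble::tibble(cell_type = x$model$cell_type, region = x$model$region,
                 n_donors = nrow(x$predictions),
                 n_genes = length(x$model$genes), mae = x$model$mae,
                 mad_residual = x$model$mad_residual,
                 lambda = x$model$lambda, alpha = x$model$alpha,
                 cv_scheme = x$model$cv_scheme)
}

#' Bias-correct clock residuals against chronological age
#'
#' Clock predictions regress toward the cohort mean, so raw residuals are
#' age-correlated. A penalized cubic-spline (Gaussian additive model) fit
#' of predicted on chronological age, smoothness chosen by generalized
#' cross-validation, defines the expected prediction at each age; the
#' corrected residual is the prediction minus this curve, and is
#' uncorrelated with chronological age by construction.
#'
#' @param predictions Tibble with `chronological_age` and `predicted_age`
#'   (as from [train_clock()]).
#' @return List: `predictions` (input plus `bias_fitted` and
#'   `corrected_residual`), `gam` (the mgcv fit), `age_cor` (check:
#'   Pearson correlation of corrected residuals with age).
#' @export
fit_bias_curve <- function(predictions) {
  d <- predictions
  n_distinct <- length(unique(d$chronological_age))
  if (n_distinct < 4) abort("need >= 4 distinct ages.")
  if (nrow(d) < 20 ||
      diff(range(d$chronological_age)) < 30) {
    warn("fewer than 20 predictions or an age span under 30 years; the bias curve may be unstable.")
  }
  kk <- min(10, n_distinct - 1)
  g <- mgcv::gam(predicted_age ~ s(chronological_age, k = kk, bs = "cr"),
                 data = d, method = "GCV.Cp")
  d$bias_fitted <- as.numeric(fitted(g))
  d$corrected_residual <- d$predicted_age - d$bias_fitted
  list(predictions = d, gam = g,
       age_cor = suppressWarnings(
         cor(d$corrected_residual, d$chronological_age)))
}

#' Cross-cell-type correlation of corrected age residuals
#'
#' Whether a donor's clocks "run fast or slow together": pairwise
#' correlation (Spearman by default, Pearson alongside) of GAM-corrected
#' residuals across cell types, on donors shared by each pair.
#'
#' @param predictions Combined tibble of bias-corrected predictions for
#'   several cell types (columns donor_id, cell_type,
#'   corrected_residual).
#' @param min_donors Minimum shared donors per pair (default 20).
#' @return Tibble: cell_type_a, cell_type_b, n_shared, rho_spearman,
#'   rho_pearson.
#' @export
residual_correlation <- function(predictions, min_donors = 20) {
  wide <- tidyr::pivot_wider(predictions, id_cols = "donor_id",
                             names_from = "cell_type",
                             values_from = "corrected_residual")
  cts <- setdiff(names(wide), "donor_id")
  pairs <- utils::combn(cts, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    ok <- complete.cases(x, y)
    if (sum(ok) < min_donors) {
      return(tibble::tibble(cell_type_a = pr[1], cell_type_b = pr[2],
                            n_shared = sum(ok), rho_spearman = NA_real_,
                            rho_pearson = NA_real_))
    }
    tibble::tibble(cell_type_a = pr[1], cell_type_b = pr[2],
                   n_shared = sum(ok),
                   rho_spearman = cor(x[ok], y[ok], method = "spearman"),
                   rho_pearson = cor(x[ok], y[ok]))
  })
}

#' Jaccard overlap of clock gene sets
#'
#' Pairwise `|A intersect B| / |A union B|` of the nonzero-coefficient gene
#' sets of several clock models.
#'
#' @param gene_sets Named list of character vectors (one per model), or a
#'   list of `clock_fit` objects.
#' @return Tibble: model_a, model_b, jaccard.
#' @export
gene_set_jaccard <- function(gene_sets) {
  if (length(gene_sets) && inherits(gene_sets[[1]], "clock_fit")) {
    nm <- vapply(gene_sets, function(m)
      paste(m$model$cell_type, m$model$region, sep = "."), "")
    gene_sets <- setNames(lapply(gene_sets, function(m) m$model$genes), nm)
  }
  nms <- names(gene_sets) %||% as.character(seq_along(gene_sets))
  pairs <- utils::combn(seq_along(gene_sets), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- gene_sets[[pr[1]]]; b <- gene_sets[[pr[2]]]
    u <- union(a, b)
    if (!length(u)) abort("empty union of gene sets.")
    tibble::tibble(model_a = nms[pr[1]], model_b = nms[pr[2]],
                   jaccard = length(intersect(a, b)) / length(u))
  })
}
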