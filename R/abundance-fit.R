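# Beta-binomial abundance regression.
#
# Parameterization: logit link on the mean fraction mu, overdispersion
# rho in [0, 1) so that Var(k) = n mu (1-mu) (1 + (n-1) rho); equivalently
# shape parameters a = mu (1-rho)/rho, b = (1-mu)(1-rho)/rho. rho is
# optimized on the logit scale from a binomial-GLM warm start.

bb_loglik_obs <- function(k, n, mu, rho) {
  rho <- max(min(rho, 1 - 1e-10), 1e-10)
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

bb_design <- function(obs, covariates = NULL) {
  regions <- sort(unique(obs$region))
  sexes <- unique(obs$sex)
  has_sex <- length(sexes) > 1
  X <- sapply(regions, function(r) as.numeric(obs$region == r))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(regions))
  colnames(X) <- paste0("region", regions)
  X <- cbind(X, age_decade = age_decades(obs$age))
  if (has_sex) X <- cbind(X, sexM = as.numeric(obs$sex == "M"))
  for (cv in covariates) X <- cbind(X, setNames(list(obs[[cv]]), cv)[[1]])
  if (!is.null(covariates)) {
    colnames(X)[(ncol(X) - length(covariates) + 1):ncol(X)] <- covariates
  }
  list(X = X, regions = regions, has_sex = has_sex, covariates = covariates)
}

bb_nll_factory <- function(k, n, X, fix_rho = NULL) {
  function(par) {
    if (is.null(fix_rho)) {
      beta <- par[-length(par)]
      rho <- plogis(par[length(par)])
    } else {
      beta <- par
      rho <- fix_rho
    }
    mu <- plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(bb_loglik_obs(k, n, mu, rho))
  }
}

bb_optimize <- function(k, n, X, fix_rho = NULL) {
  gfit <- suppressWarnings(
    stats::glm.fit(X, k / n, weights = n, family = binomial())
  )
  start <- gfit$coefficients
  start[is.na(start)] <- 0
  if (is.null(fix_rho)) start <- c(start, qlogis(0.02))
  nll <- bb_nll_factory(k, n, X, fix_rho)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt2 <- optim(opt$par, nll, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  opt$nll_fn <- nll
  opt
}

# Per-observation score matrix (numeric central differences).
bb_scores <- function(k, n, X, par) {
  p <- length(par)
  obs_ll <- function(q) {
    beta <- q[-p]
    rho <- plogis(q[p])
    mu <- pmin(pmax(plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
    bb_loglik_obs(k, n, mu, rho)
  }
  S <- matrix(0, length(k), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * (abs(par[j]) + 1e-3)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    S[, j] <- (obs_ll(up) - obs_ll(dn)) / (2 * h)
  }
  S
}

#' Fit a beta-binomial regression of cell-type abundance
#'
#' Maximum-likelihood beta-binomial with a logit link on the mean fraction,
#' one intercept per brain region, age in decades centered at 60, and (when
#' both sexes are present) a male-vs-female term. Sampling variability in
#' nuclei counts is handled by the binomial denominator itself. Because
#' donors are typically sampled in several regions and carry shared latent
#' propensities, default confidence intervals and p-values use a
#' cluster-robust (sandwich) variance clustered on donor with a G/(G-1)
#' correction; model-based Wald SEs and likelihood-ratio p-values for the
#' age and sex terms are reported alongside.
#'
#' @param obs Tibble of abundance observations: columns `k` (target-type
#'   nuclei), `n` (denominator nuclei), `age`, `region`, and optionally
#'   `sex`, `donor_id` plus extra covariate columns.
#' @param covariates Optional character vector of extra covariate columns.
#' @param fix_rho Optionally fix the overdispersion (e.g. a value near 0
#'   reproduces binomial logistic regression exactly).
#' @param se `"cluster"` (sandwich clustered on donor; the default when any
#'   donor contributes more than one observation) or `"model"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `bb_fit` object; see [tidy.bb_fit()] and [glance.bb_fit()].
#' @export
fit_beta_binomial <- function(obs, covariates = NULL, fix_rho = NULL,
                              se = NULL, conf_level = 0.95) {
  if (any(obs$k > obs$n)) abort("found k > n.")
  if (any(obs$n <= 0)) abort("found non-positive denominators.")
  if (nrow(obs) < 10) warn("fewer than 10 observations; estimates unstable.")
  if (!"sex" %in% names(obs)) obs$sex <- "unknown"
  if (!"donor_id" %in% names(obs)) obs$donor_id <- as.character(seq_len(nrow(obs)))
  des <- bb_design(obs, covariates)
  X <- des$X
  opt <- bb_optimize(obs$k, obs$n, X, fix_rho)
  if (opt$convergence != 0) {
    warn(sprintf("optim did not report convergence (code %d).",
                 opt$convergence))
  }
  p_beta <- ncol(X)
  par <- opt$par
  rho <- if (is.null(fix_rho)) plogis(par[p_beta + 1]) else fix_rho
  full_par <- if (is.null(fix_rho)) par else c(par, qlogis(max(rho, 1e-10)))

  H <- optimHess(par, opt$nll_fn)
  vcov_model <- tryCatch(solve(H), error = function(e) {
    warn("information matrix singular; SEs from pseudoinverse.")
    MASS::ginv(H)
  })

  clustered <- anyDuplicated(obs$donor_id) > 0
  se_type <- se %||% if (clustered) "cluster" else "model"
  if (se_type == "cluster") {
    S <- bb_scores(obs$k, obs$n, X, full_par)
    if (!is.null(fix_rho)) S <- S[, seq_len(p_beta), drop = FALSE]
    G <- rowsum(S, obs$donor_id)
    meat <- crossprod(G)
    g <- nrow(G)
    vcov_used <- vcov_model %*% meat %*% vcov_model * g / (g - 1)
  } else {
    vcov_used <- vcov_model
  }

  est <- unname(par[seq_len(p_beta)])
  rho <- unname(rho)
  se_used <- sqrt(pmax(diag(vcov_used)[seq_len(p_beta)], 0))
  se_model <- sqrt(pmax(diag(vcov_model)[seq_len(p_beta)], 0))
  z <- est / se_used
  zq <- qnorm(1 - (1 - conf_level) / 2)

  # Likelihood-ratio p-values for age (and sex) by refitting without the term
  lrt_p <- setNames(rep(NA_real_, p_beta), colnames(X))
  for (term in intersect(c("age_decade", "sexM"), colnames(X))) {
    X0 <- X[, setdiff(colnames(X), term), drop = FALSE]
    opt0 <- bb_optimize(obs$k, obs$n, X0, fix_rho)
    lrt_p[term] <- pchisq(2 * (opt0$value - opt$value), df = 1,
                          lower.tail = FALSE)
  }

  coefs <- tibble::tibble(
    term = colnames(X), estimate = est,
    std_error = se_used, std_error_model = se_model,
    statistic = z, p_value = 2 * pnorm(-abs(z)),
    p_lrt = unname(lrt_p),
    conf_low = est - zq * se_used, conf_high = est + zq * se_used
  )
  structure(
    list(coefficients = coefs, rho = rho, logLik = -opt$value,
         converged = opt$convergence == 0, n_obs = nrow(obs),
         n_donors = length(unique(obs$donor_id)), se_type = se_type,
         design = des, vcov = vcov_used, fix_rho = fix_rho,
         conf_level = conf_level),
    class = "bb_fit"
  )
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf(
    "<bb_fit> %d obs, %d donors | logLik %.2f | rho %.4g | SE: %s\n",
    x$n_obs, x$n_donors, x$logLik, x$rho, x$se_type))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a beta-binomial abundance fit
#' @param x A `bb_fit`.
#' @param ... Unused.
#' @return Tibble of coefficients with SEs, CIs and p-values.
#' @export
tidy.bb_fit <- function(x, ...) x$coefficients

#' One-row summary of a beta-binomial abundance fit
#' @param x A `bb_fit`.
#' @param ... Unused.
#' @return Tibble with logLik, overdispersion, sizes and convergence flag.
#' @export
glance.bb_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, rho = x$rho, n_obs = x$n_obs,
                 n_donors = x$n_donors, converged = x$converged,
                 se_type = x$se_type)
}

bb_linear_predictor <- function(fit, obs) {
  des <- fit$design
  miss <- setdiff(unique(obs$region), des$regions)
  if (length(miss)) {
    abort(sprintf("region(s) not in fit: %s", paste(miss, collapse = ", ")))
  }
  if (!"sex" %in% names(obs)) obs$sex <- "unknown"
  X <- sapply(des$regions, function(r) as.numeric(obs$region == r))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(des$regions))
  X <- cbind(X, age_decades(obs$age))
  if (des$has_sex) X <- cbind(X, as.numeric(obs$sex == "M"))
  for (cv in des$covariates) X <- cbind(X, obs[[cv]])
  drop(X %*% fit$coefficients$estimate)
}

#' Age-expected abundance residuals
#'
#' The residual of a sample is its observed fraction minus the fraction the
#' fitted model expects at that sample's age, sex and region — the
#' "fraction residual" used to ask whether a donor's abundance deviation
#' reappears across brain regions.
#'
#' @param obs Abundance observations (as for [fit_beta_binomial()]).
#' @param fit A `bb_fit` for the same cell type.
#' @return `obs` with columns `expected` and `residual` added.
#' @export
age_residuals <- function(obs, fit) {
  eta <- bb_linear_predictor(fit, obs)
  obs |>
    dplyr::mutate(expected = plogis(eta),
                  residual = .data$k / .data$n - .data$expected)
}
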