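#' @importFrom rlang %||% abort warn .data
#' @importFrom stats plogis qlogis rnorm rbinom runif rmultinom rnbinom rlnorm
#'   optim optimHess glm binomial coef pchisq pnorm qnorm quantile median mad
#'   cor cor.test p.adjust lm.wfit pt rpois sd var cov complete.cases
#'   setNames kmeans predict fitted residuals pbinom binom.test wilcox.test
#'   rbeta na.omit
#' @importFrom utils head combn
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

logit <- function(p) qlogis(p)
expit <- function(x) plogis(x)

#' Age in centered decades
#'
#' Ages are expressed as decades since age 60 throughout the package, so that
#' slope coefficients read as "per decade of age" and intercepts refer to a
#' 60-year-old donor.
#'
#' @param age Numeric vector of ages in years.
#' @param center Center in years (default 60).
#' @return Numeric vector, `(age - center) / 10`.
#' @export
age_decades <- function(age, center = 60) (age - center) / 10

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1].", name))
  }
}
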