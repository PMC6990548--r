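#' Classify anaemia from altitude-adjusted haemoglobin
#'
#' WHO rule for children aged 6-59 months: anaemic if and only if the
#' altitude-adjusted haemoglobin concentration is strictly below 11 g/dL.
#'
#' @param hb_adjusted_gdl positive haemoglobin value(s), g/dL.
#' @return integer 0/1 vector (`NA` preserved).
#' @export
#' @examples
#' classify_anaemia(c(10.9, 11, 7.2)) # 1 0 1
classify_anaemia <- function(hb_adjusted_gdl) {
  if (any(hb_adjusted_gdl <= 0, na.rm = TRUE))
    stop("haemoglobin must be positive")
  as.integer(hb_adjusted_gdl < 11)
}

# logit-scale Wald interval on a weighted proportion, with effective sample
# size n_eff = (sum w)^2 / sum w^2; boundary proportions fall back to an
# exact one-sided bound at the effective n.
.prev_ci <- function(p, n_eff, level = 0.95) {
  alpha <- 1 - level
  if (n_eff <= 0 || is.na(p)) return(c(NA_real_, NA_real_))
  if (p <= 0) return(c(0, 1 - (alpha / 2)^(1 / n_eff)))
  if (p >= 1) return(c((alpha / 2)^(1 / n_eff), 1))
  se <- sqrt(1 / (n_eff * p * (1 - p)))
  z <- qnorm(1 - alpha / 2)
  plogis(qlogis(p) + c(-z, z) * se)
}

#' Weighted anaemia prevalence with 95% confidence intervals
#'
#' Survey-weighted prevalence `100 * sum(w * y) / sum(w)` overall and within
#' groups, with a logit-scale Wald interval using the effective sample size
#' `(sum w)^2 / sum(w^2)`. With unit (or any constant) weights this reduces
#' exactly to the unweighted proportion, and the estimate and interval are
#' invariant to rescaling all weights.
#'
#' @param children child table with `anaemic` and `survey_weight` filled.
#' @param by optional character vector of grouping columns; the overall row is
#'   always included.
#' @param level confidence level.
#' @return `data.frame` with columns `group`, `level`, `n_weighted`,
#'   `prevalence` (percent), `ci_lo`, `ci_hi`.
#' @export
weighted_prevalence <- function(children, by = NULL, level = 0.95) {
  y <- children$anaemic
  w <- children$survey_weight
  if (anyNA(y) || anyNA(w)) stop("anaemic and survey_weight must be complete")
  if (any(w <= 0)) stop("weights must be positive")
  one <- function(idx, group, lev) {
    yy <- y[idx]; ww <- w[idx]
    p <- sum(ww * yy) / sum(ww)
    n_eff <- sum(ww)^2 / sum(ww^2)
    ci <- .prev_ci(p, n_eff, level)
    data.frame(group = group, level = lev, n_weighted = sum(ww),
               prevalence = 100 * p, ci_lo = 100 * ci[1], ci_hi = 100 * ci[2],
               stringsAsFactors = FALSE)
  }
  out <- one(seq_along(y), "overall", "")
  for (g in by) {
    for (lev in unique(children[[g]]))
      out <- rbind(out, one(which(children[[g]] == lev), g, as.character(lev)))
  }
  rownames(out) <- NULL
  out
}

#' Univariate logistic screening of candidate covariates
#'
#' Fits a non-spatial univariate maximum-likelihood logistic regression of the
#' outcome on each covariate alone, and tests the association with a
#' likelihood-ratio test against the intercept-only model (a single test also
#' for multi-level factors). Covariates with `p < alpha` (default 10% level)
#' are flagged for inclusion in the multivariable model. Complete separation
#' is flagged; the covariate is kept with a warning.
#'
#' @param children child table with `anaemic` filled.
#' @param covariates character vector of covariate names to screen.
#' @param alpha inclusion level (default 0.10).
#' @return `data.frame` with `covariate`, `p_value`, `include`, `separation`.
#' @export
univariate_screen <- function(children, covariates, alpha = 0.10) {
  y <- children$anaemic
  if (length(unique(y[!is.na(y)])) < 2)
    stop("need both outcome classes present")
  rows <- lapply(covariates, function(v) {
    x <- children[[v]]
    if (is.null(x)) stop(sprintf("covariate '%s' not present", v))
    if (v %in% names(.covariate_levels))
      x <- factor(x, levels = .covariate_levels[[v]])
    ok <- !is.na(x) & !is.na(y)
    fit <- suppressWarnings(glm(y[ok] ~ x[ok], family = binomial()))
    sep <- any(fitted(fit) > 1 - 1e-8 | fitted(fit) < 1e-8) &&
      any(abs(coef(fit)[-1]) > 10)
    if (sep)
      warning(sprintf("possible complete separation for '%s'; kept with flag", v))
    lr <- fit$null.deviance - fit$deviance
    df <- fit$df.null - fit$df.residual
    p <- pchisq(lr, df = df, lower.tail = FALSE)
    data.frame(covariate = v, p_value = p,
               include = sep | p < alpha, separation = sep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factors of continuous covariates
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of each
#' continuous covariate on the others; values at or above 4 are flagged as
#' collinear. A single covariate has VIF 1 by convention.
#'
#' @param children child table.
#' @param continuous character vector of continuous covariate names.
#' @param threshold flag level (default 4).
#' @return `data.frame` with `covariate`, `vif`, `collinear`.
#' @export
vif_table <- function(children, continuous, threshold = 4) {
  X <- children[, continuous, drop = FALSE]
  if (any(vapply(X, function(x) var(x, na.rm = TRUE) == 0, logical(1))))
    stop("constant covariate: VIF undefined")
  vifs <- vapply(continuous, function(v) {
    if (length(continuous) == 1L) return(1)
    f <- lm(stats::reformulate(setdiff(continuous, v), response = v),
            data = X)
    r2 <- summary(f)$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
  data.frame(covariate = continuous, vif = unname(vifs),
             collinear = unname(vifs) >= threshold, stringsAsFactors = FALSE)
}
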