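#' Fit the Bayesian geoadditive logit by Polya-Gamma Gibbs sampling
#'
#' Draws from the joint posterior of all fixed effects, spline coefficients,
#' structured and unstructured district effects and precision parameters.
#' Each Gibbs sweep (i) draws the full latent Gaussian block from its
#' conditionally Gaussian law given the Polya-Gamma augmentation variables,
#' (ii) refreshes the augmentation variables given the linear predictor,
#' (iii) draws each precision from its conjugate
#' `Gamma(a + rank/2, b + quadratic_form/2)` full conditional, and (iv)
#' imposes the sum-to-zero identifiability constraints (each smooth centred
#' over the observed covariate values; structured effects per connected
#' component; unstructured effects overall) exactly, by conditioning the
#' Gaussian draw on the constraints. Every stored draw therefore satisfies the
#' constraints to machine precision. Chains are reproducible under the
#' configured seed.
#'
#' @param design a [build_design()] result, or a child table (in which case
#'   `spec` and `graph` are used to build the design).
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_config()].
#' @param spec,graph used only when `design` is a child table.
#' @return object of class `"geoadd_fit"` with elements `draws` (pooled
#'   post-burn-in, thinned draws of the latent block; named columns),
#'   `tau2` (precision draws), `deviance` (per-draw Bernoulli deviance
#'   `-2 sum(y log pi + (1-y) log(1-pi))`), and the design.
#' @export
fit_geoadd <- function(design, priors = prior_config(), mcmc = mcmc_config(),
                       spec = NULL, graph = NULL) {
  if (!inherits(design, "geoadd_design")) {
    if (is.null(spec)) stop("supply a geoadd_design or a child table + spec")
    design <- build_design(design, spec, graph)
  }
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))

  pd <- ncol(design$X)
  ridge <- as.integer(seq_len(pd) <= design$n_fixed)
  blocks <- lapply(design$smooths, function(s)
    list(start = s$start, K = s$K, rank = s$rank,
         a = priors$hyper_a, b = priors$hyper_b, w = s$w))
  if (design$spatial) {
    nd <- length(design$graph$nodes)
    comp <- design$icar$components
    comp_ind <- t(vapply(seq_len(max(comp)),
                         function(k) as.numeric(comp == k), numeric(nd)))
    Q <- design$icar$Q
    rank_Q <- design$icar$rank
  } else {
    nd <- 0L
    comp_ind <- matrix(0, 0, 0)
    Q <- matrix(0, 0, 0)
    rank_Q <- 0L
  }

  draws <- NULL; tau2 <- NULL; dev <- NULL
  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + chain - 1L)
    res <- gibbs_logistic_pg(design$X, design$y, design$district0, nd, Q,
                             rank_Q, unname(blocks),
                             1 / priors$beta_variance, ridge, design$spatial,
                             priors$hyper_a, priors$hyper_b,
                             priors$hyper_a, priors$hyper_b, comp_ind,
                             mcmc$n_iter, mcmc$burn_in, mcmc$thin)
    draws <- rbind(draws, res$draws)
    tau2 <- rbind(tau2, res$tau2)
    dev <- c(dev, res$deviance)
  }
  cn <- colnames(design$X)
  if (design$spatial)
    cn <- c(cn, paste0("f_str_", design$graph$nodes),
            paste0("f_unstr_", design$graph$nodes))
  colnames(draws) <- cn
  tn <- c(if (length(design$smooths)) paste0("tau2_", names(design$smooths)),
          if (design$spatial) c("tau2_str", "tau2_unstr"))
  if (length(tn)) colnames(tau2) <- tn

  structure(list(draws = draws, tau2 = tau2, deviance = dev,
                 design = design, priors = priors, mcmc = mcmc),
            class = "geoadd_fit")
}

#' @export
print.geoadd_fit <- function(x, ...) {
  d <- x$design
  cat(sprintf("Bayesian geoadditive logit fit (%s): n = %d, %d kept draws\n",
              d$spec$model, d$n, nrow(x$draws)))
  cat(sprintf("  %d fixed-effect columns", d$n_fixed))
  if (length(d$smooths))
    cat(sprintf(", smooth term(s): %s",
                paste(names(d$smooths), collapse = ", ")))
  if (d$spatial)
    cat(sprintf(", spatial effects over %d districts", length(d$graph$nodes)))
  cat("\n")
  invisible(x)
}

# Design pieces for new data, using the stored column metadata, knots and
# factor coding of the fit.
.prediction_design <- function(fit, children) {
  d <- fit$design
  meta <- d$meta[-1, , drop = FALSE] # drop intercept row
  cols <- matrix(0, nrow(children), nrow(meta) + 1L,
                 dimnames = list(NULL, c("intercept", meta$column)))
  cols[, 1] <- 1
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    if (!v %in% names(children))
      stop(sprintf("covariate '%s' not present in the new data", v))
    cols[, i + 1L] <- if (nzchar(meta$level[i]))
      as.numeric(children[[v]] == meta$level[i]) else
        as.numeric(children[[v]])
  }
  for (s in d$smooths) {
    B <- bspline_design(children[[s$covariate]], s$basis_spec)
    colnames(B) <- paste0("f_", s$covariate, "_", seq_len(s$basis_spec$M))
    cols <- cbind(cols, B)
  }
  district0 <- integer(0)
  if (d$spatial) {
    bad <- setdiff(unique(children$district_id), d$graph$nodes)
    if (length(bad))
      stop("district(s) not in the fitted adjacency graph: ",
           paste(bad, collapse = ", "))
    district0 <- match(children$district_id, d$graph$nodes) - 1L
  }
  list(X = cols, district0 = district0)
}

#' Per-draw linear predictor and probabilities
#'
#' Evaluates `eta = x'beta + f(age) + f_str + f_unstr` and
#' `pi = plogis(eta)` for every stored posterior draw, either on the training
#' data or on new children compatible with the fitted specification.
#'
#' @param fit a [fit_geoadd()] result.
#' @param children optional new child table; defaults to the training data
#'   design.
#' @return list with matrices `eta` and `pi`, both `n x n_draws`.
#' @export
linear_predictor <- function(fit, children = NULL) {
  stopifnot(inherits(fit, "geoadd_fit"))
  d <- fit$design
  if (is.null(children)) {
    X <- d$X
    district0 <- d$district0
  } else {
    pr <- .prediction_design(fit, children)
    X <- pr$X
    district0 <- pr$district0
  }
  pd <- ncol(d$X)
  eta <- X %*% t(fit$draws[, seq_len(pd), drop = FALSE])
  if (d$spatial) {
    nd <- length(d$graph$nodes)
    eta <- eta + t(fit$draws[, pd + 1L + district0, drop = FALSE]) +
      t(fit$draws[, pd + nd + 1L + district0, drop = FALSE])
  }
  list(eta = eta, pi = plogis(eta))
}

#' Posterior deviance draws and plug-in deviance
#'
#' Returns the per-draw Bernoulli deviance
#' `D(theta) = -2 sum_k [y log pi + (1 - y) log(1 - pi)]` stored during
#' sampling, together with the plug-in deviance `D(theta_bar)` evaluated at
#' the posterior mean of all latent quantities (posterior mean on the linear
#' predictor scale) — the two ingredients of the DIC.
#'
#' @param fit a [fit_geoadd()] result.
#' @return list with `D` (vector of per-draw deviances) and `D_at_mean`.
#' @export
deviance_draws <- function(fit) {
  stopifnot(inherits(fit, "geoadd_fit"))
  d <- fit$design
  theta_bar <- colMeans(fit$draws)
  pd <- ncol(d$X)
  eta_bar <- as.numeric(d$X %*% theta_bar[seq_len(pd)])
  if (d$spatial) {
    nd <- length(d$graph$nodes)
    eta_bar <- eta_bar + theta_bar[pd + 1L + d$district0] +
      theta_bar[pd + nd + 1L + d$district0]
  }
  # -2 log-likelihood, numerically stable
  lse <- pmax(eta_bar, 0) + log1p(exp(-abs(eta_bar)))
  D_at_mean <- -2 * sum(d$y * eta_bar - lse)
  list(D = fit$deviance, D_at_mean = D_at_mean)
}
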