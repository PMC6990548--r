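#' Deviance Information Criterion
#'
#' Computes `Dbar` (posterior mean deviance), the plug-in deviance
#' `D(theta_bar)` at the posterior mean of the latent quantities, the
#' effective number of parameters `pD = Dbar - D(theta_bar)` and
#' `DIC = Dbar + pD = 2 Dbar - D(theta_bar)`. The identities hold exactly by
#' construction. A negative `pD` (possible for strongly non-log-concave
#' posteriors) triggers a warning, not an error.
#'
#' @param fit a [fit_geoadd()] result.
#' @return list of class `"geoadd_dic"` with `DIC`, `pD`, `Dbar`, `D_at_mean`.
#' @export
dic <- function(fit) {
  dv <- deviance_draws(fit)
  Dbar <- mean(dv$D)
  pD <- Dbar - dv$D_at_mean
  if (!is.finite(pD)) stop("non-finite effective number of parameters")
  if (pD < 0) warning("negative pD: posterior mean fits worse than average draw")
  structure(list(DIC = Dbar + pD, pD = pD, Dbar = Dbar,
                 D_at_mean = dv$D_at_mean),
            class = "geoadd_dic")
}

#' @export
print.geoadd_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n", x$DIC, x$Dbar, x$pD))
  invisible(x)
}

#' Compare fitted models by DIC
#'
#' Ranks a set of fits of the same data by ascending DIC (smallest = best
#' fit). Fits trained on different data are refused, based on the stored
#' row count and design checksums.
#'
#' @param fits named list of [fit_geoadd()] results.
#' @return `data.frame` with one row per model: `model`, `DIC`, `pD`, `Dbar`,
#'   `D_at_mean` and `rank`, ordered by DIC.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits to compare")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$design$spec$model, character(1))
  ref <- fits[[1]]$design$checksum[c("n", "sy")]
  for (f in fits[-1]) {
    if (!identical(unname(f$design$checksum[c("n", "sy")]), unname(ref)))
      stop("fits were not trained on the same data")
  }
  rows <- lapply(names(fits), function(nm) {
    d <- dic(fits[[nm]])
    data.frame(model = nm, DIC = d$DIC, pD = d$pD, Dbar = d$Dbar,
               D_at_mean = d$D_at_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$DIC), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Hyper-prior sensitivity analysis
#'
#' Refits the model under a grid of Gamma(a, b) hyper-parameter settings for
#' the precision priors and summarises how the reported quantities move: the
#' adjusted odds ratios of all fixed effects and the posterior mean
#' precisions, with the maximum relative change of each quantity across the
#' grid (relative to the first setting).
#'
#' @param design a [build_design()] result.
#' @param hyper_grid list of `c(a, b)` pairs; the default grid
#'   `{(1, 0.001), (1, 0.01), (0.5, 0.0005)}` brackets the standard choice.
#' @param mcmc an [mcmc_config()].
#' @param beta_variance fixed-effect prior variance (held fixed).
#' @return list with `aor` (AOR per fixed effect x setting), `precisions`
#'   (posterior mean precisions per setting), and `max_rel_change` (named
#'   vector, the largest relative AOR change per covariate effect).
#' @export
sensitivity_analysis <- function(design,
                                 hyper_grid = list(c(1, 0.001), c(1, 0.01),
                                                   c(0.5, 0.0005)),
                                 mcmc = mcmc_config(),
                                 beta_variance = 1000) {
  if (!length(hyper_grid)) stop("hyper_grid must be non-empty")
  labels <- vapply(hyper_grid, function(g)
    sprintf("a=%g,b=%g", g[1], g[2]), character(1))
  aors <- NULL
  precs <- list()
  for (i in seq_along(hyper_grid)) {
    g <- hyper_grid[[i]]
    f <- fit_geoadd(design,
                    priors = prior_config(beta_variance, g[1], g[2]),
                    mcmc = mcmc)
    at <- aor_table(f)
    if (is.null(aors))
      aors <- data.frame(effect = at$column, stringsAsFactors = FALSE)
    aors[[labels[i]]] <- at$AOR
    precs[[labels[i]]] <- if (ncol(f$tau2)) colMeans(f$tau2) else numeric(0)
  }
  rel <- apply(as.matrix(aors[, -1, drop = FALSE]), 1, function(r)
    max(abs(r / r[1] - 1)))
  list(aor = aors,
       precisions = do.call(rbind, precs),
       max_rel_change = stats::setNames(rel, aors$effect))
}
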