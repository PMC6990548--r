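#' Model specification for the geoadditive logit
#'
#' Three nested model classes are supported, mirroring the usual model-building
#' sequence for spatial child-health analyses:
#' \describe{
#'   \item{m1}{GLM: linear fixed effects of all covariates, including the
#'     child's age in months.}
#'   \item{m2}{GAM: as m1 but the age effect is a P-spline smooth.}
#'   \item{m3}{Geoadditive: m2 plus the district spatial effect, split into a
#'     structured (ICAR) and an unstructured (iid) component.}
#' }
#' Categorical covariates are dummy-coded against fixed reference levels
#' (gender: male; malaria RDT: negative; residence: urban; mother's education:
#' none; head gender: male; toilet: no facilities). Continuous covariates
#' enter linearly and unstandardised, so reported odds ratios are per unit
#' (altitude per 100 m).
#'
#' @param model `"m1"`, `"m2"` or `"m3"`.
#' @param fixed_terms character vector of fixed-effect covariates; defaults to
#'   the standard set (age is added for m1).
#' @param smooth_degree,smooth_n_inner,smooth_order P-spline settings for the
#'   age smooth (cubic, 17 interior intervals so 20 basis functions,
#'   second-order random walk by default). Ignored for m1.
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(model = c("m3", "m1", "m2"),
                       fixed_terms = NULL,
                       smooth_degree = 3L, smooth_n_inner = 17L,
                       smooth_order = 2L) {
  model <- match.arg(model)
  base_terms <- c("gender", "malaria_rdt", "household_size", "residence",
                  "mother_education", "head_gender", "toilet", "wealth_index",
                  "cluster_altitude_100m", "evi", "lst")
  if (is.null(fixed_terms)) {
    fixed_terms <- if (model == "m1") c(base_terms, "age_months") else base_terms
  }
  smooth_terms <- if (model == "m1") list() else
    list(age_months = list(degree = as.integer(smooth_degree),
                           n_inner = as.integer(smooth_n_inner),
                           order = as.integer(smooth_order)))
  overlap <- intersect(fixed_terms, names(smooth_terms))
  if (length(overlap))
    stop("covariate(s) in both fixed and smooth terms: ",
         paste(overlap, collapse = ", "))
  structure(list(model = model, fixed_terms = fixed_terms,
                 smooth_terms = smooth_terms, spatial = model == "m3"),
            class = "model_spec")
}

#' Prior configuration
#'
#' Vague zero-mean Gaussian priors with variance 1000 (precision 0.001) on all
#' fixed effects including the intercept, and Gamma(a, b) hyperpriors — the
#' log-gamma convention on the log-precision scale — with a = 1, b = 0.001 on
#' every precision parameter (smooth, structured spatial, unstructured
#' spatial).
#'
#' @param beta_variance prior variance of the fixed effects.
#' @param hyper_a,hyper_b Gamma hyper-parameters of the precision priors.
#' @return object of class `"prior_config"`.
#' @export
prior_config <- function(beta_variance = 1000, hyper_a = 1, hyper_b = 0.001) {
  if (beta_variance <= 0 || hyper_a <= 0 || hyper_b <= 0)
    stop("all prior constants must be positive")
  structure(list(beta_variance = beta_variance, hyper_a = hyper_a,
                 hyper_b = hyper_b),
            class = "prior_config")
}

#' MCMC configuration
#'
#' @param n_iter total Gibbs sweeps per chain.
#' @param burn_in sweeps discarded (`0 <= burn_in < n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; chains `2..n_chains` use `seed + chain - 1`.
#' @param n_chains number of independent chains (draws are pooled).
#' @return object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 4000L, burn_in = 1000L, thin = 2L,
                        seed = 1L, n_chains = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin); n_chains <- as.integer(n_chains)
  if (burn_in < 0L || n_iter <= burn_in)
    stop("need n_iter > burn_in >= 0")
  if (thin < 1L) stop("thin must be >= 1")
  if (n_chains < 1L) stop("n_chains must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), n_chains = n_chains),
            class = "mcmc_config")
}
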