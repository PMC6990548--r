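#' Adjusted posterior odds ratios of the fixed effects
#'
#' One row per non-intercept fixed-effect column: the adjusted odds ratio
#' (posterior mean of `exp(beta)`), the 95% equal-tailed credible interval of
#' `exp(beta)` (2.5 and 97.5 percentiles of the draws), and a significance
#' flag (interval excludes 1, i.e. significant at the 5% level). Categorical
#' effects carry their level and reference level.
#'
#' @param fit a [fit_geoadd()] result.
#' @param point `"mean"` (posterior mean of `exp(beta)`, the default) or
#'   `"exp_mean"` (`exp` of the posterior mean).
#' @param level credible level.
#' @return `data.frame` with columns `column`, `variable`, `level`,
#'   `reference`, `AOR`, `ci_lo`, `ci_hi`, `significant`.
#' @export
aor_table <- function(fit, point = c("mean", "exp_mean"), level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  point <- match.arg(point)
  meta <- fit$design$meta[-1, , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    b <- fit$draws[, meta$column[i]]
    or <- exp(b)
    ci <- quantile(or, probs, names = FALSE, type = 7)
    aor <- if (point == "mean") mean(or) else exp(mean(b))
    cbind(meta[i, , drop = FALSE],
          data.frame(AOR = aor, ci_lo = ci[1], ci_hi = ci[2],
                     significant = ci[1] > 1 || ci[2] < 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior variance components (precisions)
#'
#' Posterior mean and 95% equal-tailed credible interval of every precision
#' parameter: one row per smooth term (`tau2_<covariate>`) and, for the
#' geoadditive model, the structured (`tau2_str`) and unstructured
#' (`tau2_unstr`) spatial precisions. Since the precision is the inverse
#' variance, the spatial component with the *lower* precision has the larger
#' variance and is the dominant source of spatial variation; the returned
#' table carries a `"dominance"` attribute naming it.
#'
#' @param fit a [fit_geoadd()] result.
#' @param level credible level.
#' @return `data.frame` with `effect`, `mean`, `ci_lo`, `ci_hi`; attribute
#'   `"dominance"` is `"structured"`, `"unstructured"` or `NA` (non-spatial
#'   fits). Empty for a pure GLM fit.
#' @export
variance_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (!ncol(fit$tau2)) {
    out <- data.frame(effect = character(0), mean = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0))
    attr(out, "dominance") <- NA_character_
    return(out)
  }
  out <- do.call(rbind, lapply(colnames(fit$tau2), function(nm) {
    x <- fit$tau2[, nm]
    ci <- quantile(x, probs, names = FALSE)
    data.frame(effect = nm, mean = mean(x), ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  dom <- NA_character_
  if (all(c("tau2_str", "tau2_unstr") %in% out$effect)) {
    ms <- out$mean[out$effect == "tau2_str"]
    mu <- out$mean[out$effect == "tau2_unstr"]
    dom <- if (mu < ms) "unstructured" else "structured"
  }
  attr(out, "dominance") <- dom
  out
}

#' Posterior summary of a smooth effect
#'
#' Evaluates the centred smooth `f(z) = sum_m alpha_m B_m(z)` on a grid for
#' every posterior draw and returns the pointwise posterior mean and 95%
#' equal-tailed band. The stored draws already satisfy the sum-to-zero
#' constraint over the observed covariate values, so the mean curve is centred
#' with respect to the data's empirical distribution.
#'
#' @param fit a [fit_geoadd()] result of a model with a smooth term.
#' @param covariate smooth covariate name (default the first smooth).
#' @param grid evaluation grid; defaults to 200 points over the knot span
#'   (the integer grid for age in months).
#' @param level credible level.
#' @return `data.frame` with `grid`, `mean`, `ci_lo`, `ci_hi`.
#' @export
smooth_summary <- function(fit, covariate = NULL, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  if (!length(fit$design$smooths)) stop("fit has no smooth terms")
  if (is.null(covariate)) covariate <- names(fit$design$smooths)[1]
  s <- fit$design$smooths[[covariate]]
  if (is.null(s)) stop(sprintf("no smooth term for '%s'", covariate))
  k <- s$basis_spec$knots
  if (is.null(grid)) {
    grid <- if (covariate == "age_months") seq(ceiling(k[1]), floor(k[length(k)]))
            else seq(k[1], k[length(k)], length.out = 200)
  }
  B <- bspline_design(grid, s$basis_spec)
  idx <- s$start + seq_len(s$basis_spec$M) # start is 0-based
  fdraws <- B %*% t(fit$draws[, idx, drop = FALSE]) # grid x draws
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(fdraws, 1, quantile, probs = probs, names = FALSE)
  data.frame(grid = grid, mean = rowMeans(fdraws),
             ci_lo = qs[1, ], ci_hi = qs[2, ])
}

#' Per-district spatial effect summaries
#'
#' Posterior mean, 95% equal-tailed credible interval and significance class
#' of the structured and unstructured spatial effect of every district. A
#' district is `significantly_positive` / `significantly_negative` when its
#' credible interval excludes 0 (5% level) on the corresponding side, `null`
#' otherwise.
#'
#' @param fit a geoadditive (`m3`) [fit_geoadd()] result.
#' @param level credible level.
#' @return list of class `"district_summary"` with elements `summary` (one
#'   row per district x component: `district`, `component`, `mean`, `ci_lo`,
#'   `ci_hi`, `class`), `counts` (class counts per component) and `range`
#'   (min/max posterior mean per component).
#' @export
district_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  if (!fit$design$spatial) stop("district summaries need a spatial (m3) fit")
  nodes <- fit$design$graph$nodes
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  one <- function(prefix, component) {
    cols <- paste0(prefix, nodes)
    d <- fit$draws[, cols, drop = FALSE]
    m <- colMeans(d)
    qs <- apply(d, 2, quantile, probs = probs, names = FALSE)
    cls <- ifelse(qs[1, ] > 0, "significantly_positive",
                  ifelse(qs[2, ] < 0, "significantly_negative", "null"))
    data.frame(district = nodes, component = component, mean = unname(m),
               ci_lo = unname(qs[1, ]), ci_hi = unname(qs[2, ]),
               class = unname(cls), stringsAsFactors = FALSE)
  }
  summary <- rbind(one("f_str_", "structured"),
                   one("f_unstr_", "unstructured"))
  counts <- as.data.frame(table(component = summary$component,
                                class = summary$class),
                          stringsAsFactors = FALSE)
  range <- do.call(rbind, lapply(split(summary, summary$component), function(s)
    data.frame(component = s$component[1], min_mean = min(s$mean),
               max_mean = max(s$mean), stringsAsFactors = FALSE)))
  rownames(range) <- NULL
  structure(list(summary = summary, counts = counts, range = range),
            class = "district_summary")
}

#' @export
print.district_summary <- function(x, ...) {
  n <- length(unique(x$summary$district))
  cat(sprintf("Spatial effect summary over %d districts\n", n))
  for (comp in unique(x$summary$component)) {
    s <- x$summary[x$summary$component == comp, ]
    cat(sprintf("  %s: mean range [%.4f, %.4f]; %d +, %d -, %d null\n",
                comp, min(s$mean), max(s$mean),
                sum(s$class == "significantly_positive"),
                sum(s$class == "significantly_negative"),
                sum(s$class == "null")))
  }
  invisible(x)
}

#' Export district effect summaries for mapping
#'
#' Writes the per-district summaries as CSV (always) and, when a GeoJSON file
#' of district polygons is supplied, as a GeoJSON FeatureCollection whose
#' features carry `mean`, `ci_lo`, `ci_hi` and `class` properties per
#' component. Polygons whose id has no summary are flagged `no_data`.
#'
#' @param summaries a [district_summary()] result.
#' @param csv_path output CSV path.
#' @param polygons_path optional input GeoJSON of district polygons with `id`
#'   properties.
#' @param geojson_path output GeoJSON path (required when `polygons_path` is
#'   given).
#' @return invisibly, the paths written.
#' @export
export_district_summary <- function(summaries, csv_path,
                                    polygons_path = NULL,
                                    geojson_path = NULL) {
  stopifnot(inherits(summaries, "district_summary"))
  utils::write.csv(summaries$summary, csv_path, row.names = FALSE,
                   quote = FALSE)
  written <- csv_path
  if (!is.null(polygons_path)) {
    if (is.null(geojson_path))
      stop("geojson_path is required when polygons are supplied")
    gj <- jsonlite::read_json(polygons_path)
    s <- summaries$summary
    for (i in seq_along(gj$features)) {
      f <- gj$features[[i]]
      id <- f$properties$id
      if (is.null(id)) id <- f$id
      id <- as.character(id)
      props <- f$properties
      if (is.null(props)) props <- list()
      props$id <- id
      hit <- FALSE
      for (comp in unique(s$component)) {
        row <- s[s$district == id & s$component == comp, ]
        if (nrow(row) == 1) {
          hit <- TRUE
          pre <- if (comp == "structured") "str" else "unstr"
          props[[paste0(pre, "_mean")]] <- row$mean
          props[[paste0(pre, "_lo")]] <- row$ci_lo
          props[[paste0(pre, "_hi")]] <- row$ci_hi
          props[[paste0(pre, "_class")]] <- row$class
        }
      }
      props$no_data <- !hit
      gj$features[[i]]$properties <- props
    }
    jsonlite::write_json(gj, geojson_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, geojson_path)
  }
  invisible(written)
}
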