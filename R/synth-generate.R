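#' Generate a district adjacency layout
#'
#' Builds the contiguity graph for a synthetic study region: either a rook
#' grid (districts are cells of an `r x c` lattice, neighbours share an edge)
#' or a ring. Both layouts are connected.
#'
#' @param n_districts number of districts (>= 2).
#' @param layout `"grid"` or `"ring"`.
#' @param dims optional `c(rows, cols)` for the grid; by default the most
#'   square factorisation of `n_districts` is used. A size with no
#'   factorisation other than `1 x n` (a prime) is rejected.
#' @return an [adjacency_graph()] with nodes `d01, d02, ...` in row-major
#'   order for grids and around the circle for rings.
#' @export
generate_adjacency <- function(n_districts, layout = c("grid", "ring"),
                               dims = NULL) {
  layout <- match.arg(layout)
  n <- as.integer(n_districts)
  if (n < 2L) stop("need at least 2 districts")
  ids <- sprintf(paste0("d%0", max(2L, nchar(n)), "d"), seq_len(n))
  nb <- stats::setNames(rep(list(character(0)), n), ids)
  if (layout == "ring") {
    for (i in seq_len(n)) {
      prev <- if (i == 1L) n else i - 1L
      nxt <- if (i == n) 1L else i + 1L
      nb[[i]] <- unique(ids[c(prev, nxt)])
    }
  } else {
    if (is.null(dims)) {
      r <- max(which(seq_len(floor(sqrt(n))) |>
                       vapply(function(k) n %% k == 0L, logical(1))))
      if (r == 1L)
        stop(sprintf("%d districts cannot be arranged into a grid (prime size); supply dims or choose another size", n))
      dims <- c(r, n %/% r)
    }
    if (prod(dims) != n) stop("dims must multiply to n_districts")
    r <- dims[1]; cc <- dims[2]
    idx <- function(i, j) (i - 1L) * cc + j
    for (i in seq_len(r)) {
      for (j in seq_len(cc)) {
        k <- idx(i, j)
        adj <- integer(0)
        if (i > 1L) adj <- c(adj, idx(i - 1L, j))
        if (i < r) adj <- c(adj, idx(i + 1L, j))
        if (j > 1L) adj <- c(adj, idx(i, j - 1L))
        if (j < cc) adj <- c(adj, idx(i, j + 1L))
        nb[[k]] <- ids[adj]
      }
    }
  }
  adjacency_graph(nb, ids)
}

#' Draw true district spatial effects
#'
#' Samples the structured effect from the intrinsic CAR distribution with
#' precision `tau2_str * Q`, restricted to the sum-to-zero subspace: the
#' (improper) ICAR density is only defined up to per-component constants, so
#' the draw is taken in the span of the positive eigenvalues of `Q`
#' (`f_str = V diag(1/sqrt(tau2_str * lambda)) z`), which makes each connected
#' component of the draw sum to zero exactly. The unstructured effect is iid
#' Gaussian with variance `1/tau2_unstr`, then centred. In the infinite
#' precision limit both effects vanish.
#'
#' @param graph an [adjacency_graph()].
#' @param tau2_str,tau2_unstr positive precisions (may be `Inf`).
#' @param seed integer seed.
#' @return list of class `"district_effects"` with named vectors `f_str` and
#'   `f_unstr` over the graph's nodes.
#' @export
generate_spatial_effects <- function(graph, tau2_str, tau2_unstr, seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (tau2_str <= 0 || tau2_unstr <= 0) stop("precisions must be positive")
  set.seed(as.integer(seed))
  Q <- suppressMessages(icar_structure(graph))$Q
  n <- length(graph$nodes)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(e$values, 1)
  z <- rnorm(sum(pos))
  f_str <- as.numeric(e$vectors[, pos, drop = FALSE] %*%
                        (z / sqrt(tau2_str * e$values[pos])))
  f_unstr <- rnorm(n, 0, sqrt(1 / tau2_unstr))
  f_unstr <- f_unstr - mean(f_unstr)
  structure(list(f_str = stats::setNames(f_str, graph$nodes),
                 f_unstr = stats::setNames(f_unstr, graph$nodes)),
            class = "district_effects")
}

#' Construct district effects directly
#'
#' Wraps user-specified structured and unstructured district effect vectors
#' (e.g. a designed pattern of +1 / -1 districts for a signal-recovery study)
#' in the container [simulate_outcomes()] expects.
#'
#' @param f_str,f_unstr numeric vectors named by district id.
#' @return list of class `"district_effects"`.
#' @export
district_effects <- function(f_str, f_unstr) {
  if (is.null(names(f_str)) || is.null(names(f_unstr)) ||
      !identical(names(f_str), names(f_unstr)))
    stop("f_str and f_unstr must share district-id names")
  structure(list(f_str = f_str, f_unstr = f_unstr),
            class = "district_effects")
}

#' Generate the covariate frame of a synthetic survey
#'
#' Draws the nested child population of a [synth_design()]: clusters nested in
#' districts, households in clusters, children aged 6-59 months in households.
#' Covariates are drawn at their natural level of the hierarchy (residence,
#' altitude, EVI and LST per cluster; household size, wealth, mother's
#' education, head gender and toilet type per household; gender, age and
#' malaria status per child). Survey weights are the inverse of a synthetic
#' cluster selection probability, constant within cluster. The outcome column
#' `anaemic` is left `NA`; see [simulate_outcomes()].
#'
#' @param design a [synth_design()].
#' @param graph an [adjacency_graph()] with at least `design$n_districts`
#'   nodes; the first `n_districts` nodes are used.
#' @return a child table `data.frame` (one row per child).
#' @export
generate_population <- function(design, graph) {
  stopifnot(inherits(design, "synth_design"),
            inherits(graph, "adjacency_graph"))
  if (length(graph$nodes) < design$n_districts)
    stop("graph has fewer nodes than design$n_districts")
  set.seed(design$seed)
  g <- design$covariate_generators
  districts <- graph$nodes[seq_len(design$n_districts)]

  n_clus <- design$n_districts * design$clusters_per_district
  clus <- data.frame(
    district_id = rep(districts, each = design$clusters_per_district),
    cluster_no = rep(seq_len(design$clusters_per_district),
                     times = design$n_districts),
    stringsAsFactors = FALSE
  )
  clus$cluster_id <- paste0(clus$district_id, "_c", clus$cluster_no)
  clus$residence <- sample(names(g$residence), n_clus, TRUE, prob = g$residence)
  clus$cluster_altitude_100m <- rnorm(n_clus, g$cluster_altitude_100m["mean"],
                                      g$cluster_altitude_100m["sd"])
  clus$evi <- rnorm(n_clus, g$evi["mean"], g$evi["sd"])
  clus$lst <- rnorm(n_clus, g$lst["mean"], g$lst["sd"])
  # inverse of a synthetic first-stage selection probability
  clus$survey_weight <- 1 / runif(n_clus, 0.5, 1.5)

  n_hh <- n_clus * design$households_per_cluster
  hh <- clus[rep(seq_len(n_clus), each = design$households_per_cluster), ]
  hh$household_id <- paste0(hh$cluster_id, "_h",
                            rep(seq_len(design$households_per_cluster), n_clus))
  hh$household_size <- pmax(1L, as.integer(round(
    rnorm(n_hh, g$household_size["mean"], g$household_size["sd"]))))
  hh$wealth_index <- rnorm(n_hh, g$wealth_index["mean"], g$wealth_index["sd"])
  hh$mother_education <- sample(names(g$mother_education), n_hh, TRUE,
                                prob = g$mother_education)
  hh$head_gender <- sample(names(g$head_gender), n_hh, TRUE,
                           prob = g$head_gender)
  hh$toilet <- sample(names(g$toilet), n_hh, TRUE, prob = g$toilet)

  n_child <- 1L + rpois(n_hh, design$children_per_household - 1)
  ch <- hh[rep(seq_len(n_hh), times = n_child), ]
  n <- nrow(ch)
  ch$child_id <- sprintf("ch%06d", seq_len(n))
  ch$age_months <- sample(design$age_range[1]:design$age_range[2], n, TRUE)
  ch$gender <- sample(names(g$gender), n, TRUE, prob = g$gender)
  ch$malaria_rdt <- sample(names(g$malaria_rdt), n, TRUE, prob = g$malaria_rdt)
  ch$hb_adjusted_gdl <- NA_real_
  ch$anaemic <- NA_integer_
  rownames(ch) <- NULL
  ch[, .child_table_columns]
}

#' Simulate anaemia outcomes under the geoadditive model
#'
#' Runs the model generatively: for each child,
#' `eta = x'beta + f_age(age) + f_str(district) + f_unstr(district)` and
#' `anaemic ~ Bernoulli(plogis(eta))`. Every non-intercept name in
#' `params$beta` must correspond to a design column of the covariate frame
#' (`variable_level` for categorical effects, the column name for continuous
#' ones); a missing covariate is rejected by name. The realised linear
#' predictor is attached as attribute `"linpred"` for testing.
#'
#' @param children covariate frame from [generate_population()].
#' @param params a [true_params()].
#' @param effects district effects from [generate_spatial_effects()].
#' @param seed integer seed for the Bernoulli draws (and haemoglobin, if
#'   requested).
#' @param hb if `TRUE` also fill `hb_adjusted_gdl` with synthetic
#'   haemoglobin values consistent with the outcome under the 11 g/dL rule
#'   (below 11 for anaemic children, at or above 11 otherwise). These exist
#'   only to exercise the classification rule; the generative truth is the
#'   Bernoulli outcome.
#' @return `children` with `anaemic` filled (and optionally
#'   `hb_adjusted_gdl`), linear predictor in `attr(, "linpred")`.
#' @export
simulate_outcomes <- function(children, params, effects, seed = 1L,
                              hb = FALSE) {
  stopifnot(inherits(params, "true_params"),
            inherits(effects, "district_effects"))
  fd <- .fixed_design(children,
                      setdiff(names(.covariate_levels), character(0)) |>
                        c(setdiff(.continuous_covariates, "age_months")))
  beta <- params$beta
  cov_beta <- beta[setdiff(names(beta), "intercept")]
  missing_cols <- setdiff(names(cov_beta), colnames(fd$X))
  if (length(missing_cols))
    stop("covariate(s) named in beta not present in the data: ",
         paste(missing_cols, collapse = ", "))
  bad_d <- setdiff(unique(children$district_id), names(effects$f_str))
  if (length(bad_d))
    stop("district(s) without spatial effects: ", paste(bad_d, collapse = ", "))
  set.seed(as.integer(seed))
  eta <- as.numeric(beta["intercept"] +
                      fd$X[, names(cov_beta), drop = FALSE] %*% cov_beta) +
    params$age_curve(children$age_months) +
    effects$f_str[children$district_id] +
    effects$f_unstr[children$district_id]
  eta <- unname(eta)
  children$anaemic <- rbinom(nrow(children), 1L, plogis(eta))
  if (hb) {
    gap <- abs(rnorm(nrow(children), 1.2, 0.9))
    children$hb_adjusted_gdl <- pmax(
      ifelse(children$anaemic == 1L, 11 - gap - 1e-6, 11 + gap), 2)
  }
  attr(children, "linpred") <- eta
  children
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper tying the generator together: adjacency layout, true
#' spatial effects, nested covariate frame and simulated outcomes, all
#' deterministic functions of `design$seed`.
#'
#' @param design a [synth_design()].
#' @param params a [true_params()]; defaults to the package's standard truth.
#' @param graph optional [adjacency_graph()]; generated from the design if
#'   omitted.
#' @param hb passed to [simulate_outcomes()].
#' @return list of class `"synth_survey"` with elements `children`, `graph`,
#'   `effects`, `params`, `design`.
#' @export
#' @examples
#' sv <- simulate_survey(synth_design(n_districts = 6, seed = 7))
#' nrow(sv$children)
simulate_survey <- function(design, params = true_params(), graph = NULL,
                            hb = FALSE) {
  stopifnot(inherits(design, "synth_design"))
  if (is.null(graph)) graph <- generate_adjacency(design$n_districts,
                                                  design$layout)
  effects <- generate_spatial_effects(graph, params$tau2_str,
                                      params$tau2_unstr,
                                      seed = design$seed + 1L)
  children <- generate_population(design, graph)
  children <- simulate_outcomes(children, params, effects,
                                seed = design$seed + 2L, hb = hb)
  structure(list(children = children, graph = graph, effects = effects,
                 params = params, design = design),
            class = "synth_survey")
}
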