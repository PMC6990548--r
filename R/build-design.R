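# Dummy-coded fixed-effect matrix with reference levels, plus column metadata.
# drop_empty: drop indicator columns for levels absent from the data (with a
# warning), as required when the matrix feeds a model fit.
.fixed_design <- function(children, terms, drop_empty = FALSE) {
  cols <- list()
  meta <- list()
  for (v in terms) {
    if (!v %in% names(children))
      stop(sprintf("covariate '%s' not present in the data", v))
    if (v %in% names(.covariate_levels)) {
      levs <- .covariate_levels[[v]]
      x <- children[[v]]
      bad <- which(!is.na(x) & !x %in% levs)
      if (length(bad))
        stop(sprintf("unknown %s label '%s' in row %d", v, x[bad[1]], bad[1]))
      for (lev in levs[-1]) {
        if (drop_empty && !any(x == lev, na.rm = TRUE)) {
          warning(sprintf("level '%s' of '%s' absent from data: column dropped",
                          lev, v))
          next
        }
        nm <- paste(v, lev, sep = "_")
        cols[[nm]] <- as.numeric(x == lev)
        meta[[nm]] <- data.frame(column = nm, variable = v, level = lev,
                                 reference = levs[1],
                                 stringsAsFactors = FALSE)
      }
    } else {
      cols[[v]] <- as.numeric(children[[v]])
      meta[[v]] <- data.frame(column = v, variable = v, level = "",
                              reference = "", stringsAsFactors = FALSE)
    }
  }
  if (length(cols)) {
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
  } else {
    X <- matrix(numeric(0), nrow(children), 0)
  }
  list(X = X, meta = do.call(rbind, meta))
}

#' Assemble the model matrices of the geoadditive predictor
#'
#' Builds everything [fit_geoadd()] needs from a child table and a
#' [model_spec()]: the dense design (leading intercept column, dummy-coded
#' fixed effects against the stated reference levels, one B-spline basis per
#' smooth term), the random-walk penalty for each smooth, and — for the
#' geoadditive model — the district incidence mapping and ICAR structure from
#' the adjacency graph. Rows with missing values in the outcome or any model
#' covariate are dropped with a message. Children in districts absent from the
#' graph are rejected by district name.
#'
#' @param children child table with the outcome `anaemic` filled.
#' @param spec a [model_spec()].
#' @param graph an [adjacency_graph()]; required iff `spec$spatial`.
#' @return object of class `"geoadd_design"`.
#' @export
build_design <- function(children, spec, graph = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$spatial && is.null(graph))
    stop("the geoadditive model (m3) requires an adjacency graph")
  used <- c("anaemic", spec$fixed_terms, names(spec$smooth_terms),
            if (spec$spatial) "district_id")
  used <- intersect(used, names(children))
  miss <- setdiff(c(spec$fixed_terms, names(spec$smooth_terms)),
                  names(children))
  if (length(miss))
    stop("covariate(s) not present in the data: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(children[, used, drop = FALSE])
  if (!all(keep)) {
    message(sprintf("dropping %d row(s) with missing values", sum(!keep)))
    children <- children[keep, , drop = FALSE]
  }
  y <- children$anaemic
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome 'anaemic' must be 0/1 with no missing values")

  fd <- .fixed_design(children, spec$fixed_terms, drop_empty = TRUE)
  X <- cbind(intercept = rep(1, nrow(children)), fd$X)
  meta <- rbind(data.frame(column = "intercept", variable = "intercept",
                           level = "", reference = "",
                           stringsAsFactors = FALSE),
                fd$meta)
  n_fixed <- ncol(X)

  smooths <- list()
  for (v in names(spec$smooth_terms)) {
    st <- spec$smooth_terms[[v]]
    bspec <- make_basis_spec(children[[v]], degree = st$degree,
                             n_inner = st$n_inner)
    B <- bspline_design(children[[v]], bspec)
    pen <- rw_penalty(bspec$M, st$order)
    colnames(B) <- paste0("f_", v, "_", seq_len(bspec$M))
    smooths[[v]] <- list(covariate = v, start = ncol(X), # 0-based offset
                         basis_spec = bspec, K = pen$K, rank = pen$rank,
                         order = st$order, w = colMeans(B))
    X <- cbind(X, B)
  }

  district0 <- integer(0)
  icar <- NULL
  if (spec$spatial) {
    stopifnot(inherits(graph, "adjacency_graph"))
    bad <- setdiff(unique(children$district_id), graph$nodes)
    if (length(bad))
      stop("district(s) in the data but not in the adjacency graph: ",
           paste(bad, collapse = ", "))
    icar <- suppressMessages(icar_structure(graph))
    district0 <- match(children$district_id, graph$nodes) - 1L
  }

  structure(
    list(X = X, y = as.numeric(y), meta = meta, n_fixed = n_fixed,
         smooths = smooths, spatial = spec$spatial, district0 = district0,
         icar = icar, graph = graph, spec = spec, n = nrow(children),
         weights = children$survey_weight,
         checksum = c(n = nrow(children), sy = sum(y),
                      sx = round(sum(abs(X)), 6))),
    class = "geoadd_design"
  )
}
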