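#' District adjacency graph
#'
#' Constructs the neighbourhood structure used by the structured (ICAR)
#' spatial effect: two districts are neighbours if they share a common
#' boundary. The graph must be symmetric with no self-neighbours; isolated
#' districts (no neighbours) are allowed but flagged with a warning, since
#' their structured effect is undefined and pinned to zero during fitting.
#'
#' @param neighbours named list: one entry per district, a character vector of
#'   neighbouring district ids (possibly empty).
#' @param nodes optional character vector fixing node order; defaults to
#'   `names(neighbours)`.
#' @return object of class `"adjacency_graph"`: list with `nodes`,
#'   `neighbours` (named list) and `degrees`.
#' @export
adjacency_graph <- function(neighbours, nodes = names(neighbours)) {
  if (is.null(nodes) || anyDuplicated(nodes))
    stop("nodes must be uniquely named")
  nodes <- as.character(nodes)
  neighbours <- lapply(neighbours, as.character)
  names(neighbours) <- nodes
  for (v in nodes) {
    nb <- neighbours[[v]]
    if (v %in% nb) stop(sprintf("district '%s' lists itself as a neighbour", v))
    if (!all(nb %in% nodes))
      stop(sprintf("district '%s' has unknown neighbours: %s", v,
                   paste(setdiff(nb, nodes), collapse = ", ")))
    for (w in nb)
      if (!(v %in% neighbours[[w]]))
        stop(sprintf("asymmetric adjacency: '%s' lists '%s' but not vice versa",
                     v, w))
  }
  deg <- vapply(neighbours, length, integer(1))
  if (any(deg == 0L))
    warning(sprintf("isolated district(s) with no neighbours: %s",
                    paste(nodes[deg == 0L], collapse = ", ")))
  structure(list(nodes = nodes, neighbours = neighbours, degrees = deg),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("District adjacency graph: %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), sum(x$degrees) / 2,
              max(graph_components(x))))
  invisible(x)
}

#' Connected components of an adjacency graph
#'
#' @param graph an `"adjacency_graph"`.
#' @return integer vector of component labels (1-based), named by node.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  nodes <- graph$nodes
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (v in nodes) {
    if (!is.na(comp[[v]])) next
    cur <- cur + 1L
    queue <- v
    comp[[v]] <- cur
    while (length(queue)) {
      w <- queue[[1]]
      queue <- queue[-1]
      for (u in graph$neighbours[[w]]) {
        if (is.na(comp[[u]])) {
          comp[[u]] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

#' Read a GAL spatial-weights file
#'
#' Reads the plain-text GAL exchange format: a header line giving the number
#' of areas (either a single count or the 4-token `0 n shapefile id` variant),
#' then for each area a line `id degree` followed by a line listing its
#' neighbours. The declared degree must match the neighbour list and the graph
#' must be symmetric; violations are rejected naming the offending node(s).
#'
#' @param path file path.
#' @return an [adjacency_graph()].
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*!", lines)]
  if (!length(lines)) stop("empty GAL file")
  head_tok <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- if (length(head_tok) >= 2) as.integer(head_tok[[2]]) else as.integer(head_tok[[1]])
  if (is.na(n) || n < 1) stop("malformed GAL header")
  neighbours <- list()
  i <- 2L
  for (k in seq_len(n)) {
    while (i <= length(lines) && !nzchar(trimws(lines[[i]]))) i <- i + 1L
    if (i > length(lines)) stop("GAL file truncated: fewer areas than declared")
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) != 2) stop(sprintf("malformed GAL node header line: '%s'", lines[[i]]))
    id <- tok[[1]]
    deg <- as.integer(tok[[2]])
    i <- i + 1L
    if (deg > 0L) {
      if (i > length(lines)) stop(sprintf("GAL file truncated at node '%s'", id))
      nb <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
      nb <- nb[nzchar(nb)]
      i <- i + 1L
    } else {
      # degree 0: neighbour line may be empty or absent
      if (i <= length(lines) && !nzchar(trimws(lines[[i]]))) i <- i + 1L
      nb <- character(0)
    }
    if (length(nb) != deg)
      stop(sprintf("node '%s' declares degree %d but lists %d neighbours",
                   id, deg, length(nb)))
    neighbours[[id]] <- nb
  }
  adjacency_graph(neighbours)
}

#' Write a GAL spatial-weights file
#'
#' Inverse of [read_gal()]; `read_gal(write_gal(g, path))` recovers `g`.
#'
#' @param graph an `"adjacency_graph"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(graph$nodes)), con)
  for (v in graph$nodes) {
    nb <- graph$neighbours[[v]]
    writeLines(paste(v, length(nb)), con)
    writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}

# TRUE if segments p1-p2 and q1-q2 overlap collinearly over positive length.
.segments_share_edge <- function(p1, p2, q1, q2, tol = 1e-9) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < tol) return(FALSE)
  u <- d / len
  # both q endpoints must lie on the infinite line through p1-p2
  for (q in list(q1, q2)) {
    off <- q - p1
    perp <- abs(off[1] * u[2] - off[2] * u[1])
    if (perp > tol * max(1, len)) return(FALSE)
  }
  # overlap of the projections must have positive length
  t1 <- sum((q1 - p1) * u)
  t2 <- sum((q2 - p1) * u)
  lo <- max(0, min(t1, t2))
  hi <- min(len, max(t1, t2))
  (hi - lo) > tol * max(1, len)
}

# All boundary edges of a GeoJSON Polygon / MultiPolygon coordinates array,
# as a list of 2x2 matrices (rows = endpoints).
.polygon_edges <- function(coords, multi) {
  rings <- list()
  if (multi) {
    for (poly in coords) rings <- c(rings, poly)
  } else {
    rings <- coords
  }
  edges <- list()
  for (ring in rings) {
    pts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    n <- nrow(pts)
    for (i in seq_len(n - 1))
      edges[[length(edges) + 1L]] <- pts[c(i, i + 1L), , drop = FALSE]
  }
  edges
}

#' Derive district adjacency from GeoJSON polygons
#'
#' Reads a GeoJSON FeatureCollection of district polygons (each feature
#' carrying an `id` property, or a top-level feature `id`) and derives rook
#' contiguity: two districts are neighbours if and only if their boundaries
#' share a collinear segment of positive length. Polygons touching only at a
#' corner point are not neighbours.
#'
#' @param path path to a GeoJSON file of Polygon / MultiPolygon features.
#' @return an [adjacency_graph()] over the feature ids.
#' @export
adjacency_from_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  ids <- character(0)
  edge_sets <- list()
  for (f in gj$features) {
    id <- f$properties$id
    if (is.null(id)) id <- f$id
    if (is.null(id)) stop("feature without an 'id' property")
    id <- as.character(id)
    if (id %in% ids) stop(sprintf("duplicate district id '%s'", id))
    typ <- f$geometry$type
    if (!typ %in% c("Polygon", "MultiPolygon"))
      stop(sprintf("feature '%s' is not a polygon", id))
    ids <- c(ids, id)
    edge_sets[[id]] <- .polygon_edges(f$geometry$coordinates,
                                      typ == "MultiPolygon")
  }
  neighbours <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        found <- FALSE
        for (ea in edge_sets[[ids[a]]]) {
          for (eb in edge_sets[[ids[b]]]) {
            if (.segments_share_edge(ea[1, ], ea[2, ], eb[1, ], eb[2, ])) {
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (found) {
          neighbours[[ids[a]]] <- c(neighbours[[ids[a]]], ids[b])
          neighbours[[ids[b]]] <- c(neighbours[[ids[b]]], ids[a])
        }
      }
    }
  }
  suppressWarnings(adjacency_graph(neighbours, ids))
}

#' ICAR precision structure of an adjacency graph
#'
#' Builds the joint precision structure `Q` of the intrinsic conditional
#' autoregressive (ICAR) prior implied by the conditional specification in
#' which each district's structured effect, given all others, is Gaussian with
#' mean the average of its neighbours' effects and precision
#' `n_h * tau2_str` (where `n_h` is the number of neighbours):
#' `Q[h, h] = n_h`, `Q[h, i] = -1` if `h ~ i`, 0 otherwise. `Q` is symmetric
#' positive semi-definite with zero row sums and rank
#' `n - (number of connected components)`; its null space is spanned by the
#' per-component constant vectors, which is why a per-component sum-to-zero
#' constraint is imposed at fitting time. Isolated districts contribute a zero
#' row (their structured effect is pinned to 0) and are reported.
#'
#' @param graph an [adjacency_graph()].
#' @return object of class `"icar_structure"`: list with `Q` (dense matrix with
#'   dimnames), `components` (integer labels per node), `rank`, `nodes`, and
#'   `isolated` (character vector of degree-0 nodes).
#' @export
icar_structure <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  Q <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    nb <- graph$neighbours[[nodes[i]]]
    Q[i, i] <- length(nb)
    Q[i, match(nb, nodes)] <- -1
  }
  comp <- graph_components(graph)
  isolated <- nodes[graph$degrees == 0L]
  if (length(isolated))
    message(sprintf("isolated district(s) %s: structured effect pinned to 0",
                    paste(isolated, collapse = ", ")))
  structure(
    list(Q = Q, components = comp, rank = n - max(comp), nodes = nodes,
         isolated = isolated),
    class = "icar_structure"
  )
}
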