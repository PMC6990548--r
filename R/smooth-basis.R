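#' Equally spaced B-spline basis specification
#'
#' Defines a polynomial B-spline basis of degree `l` on `n_inner` equal-width
#' interior intervals spanning the observed range of a covariate. The basis
#' has `M = n_inner + degree` functions; a random-walk prior on the basis
#' coefficients (see [rw_penalty()]) turns it into a Bayesian P-spline.
#'
#' @param z numeric covariate values (used only for their range).
#' @param degree spline degree `l >= 1`; degree 3 (cubic) is the default used
#'   throughout.
#' @param n_inner number of interior intervals `n_r >= 1`; the default 17
#'   gives the package's standard 20 cubic basis functions, with the
#'   random-walk penalty controlling effective smoothness.
#' @return an object of class `"spline_basis_spec"`: a list with elements
#'   `degree`, `n_inner`, `knots` (the `n_inner + 1` equally spaced knots,
#'   spanning `range(z)` exactly) and `M` (number of basis functions).
#' @seealso [bspline_design()], [rw_penalty()]
#' @export
#' @examples
#' spec <- make_basis_spec(6:59, degree = 3, n_inner = 17)
#' spec$M # 20
make_basis_spec <- function(z, degree = 3L, n_inner = 17L) {
  z <- as.numeric(z)
  z <- z[is.finite(z)]
  if (length(unique(z)) < 2L)
    stop("covariate is constant: cannot build a spline basis")
  degree <- as.integer(degree)
  n_inner <- as.integer(n_inner)
  if (degree < 1L) stop("spline degree must be >= 1")
  if (n_inner < 1L) stop("n_inner must be >= 1")
  knots <- seq(min(z), max(z), length.out = n_inner + 1L)
  structure(
    list(degree = degree, n_inner = n_inner, knots = knots,
         M = n_inner + degree),
    class = "spline_basis_spec"
  )
}

#' Evaluate the B-spline design matrix
#'
#' Evaluates all basis functions of a [make_basis_spec()] specification at the
#' given covariate values. Boundary knots are clamped (repeated to full
#' multiplicity), so the basis forms a partition of unity on the whole closed
#' knot span: every row of the returned matrix is non-negative, sums to 1, and
#' has at most `degree + 1` non-zero entries. Values outside the knot span are
#' rejected; the basis does not extrapolate.
#'
#' @param z numeric values at which to evaluate, all within the knot span.
#' @param spec a `"spline_basis_spec"`.
#' @return numeric matrix with `length(z)` rows and `spec$M` columns.
#' @export
bspline_design <- function(z, spec) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  z <- as.numeric(z)
  k <- spec$knots
  if (any(z < k[1] - 1e-10 | z > k[length(k)] + 1e-10))
    stop(sprintf("values outside the knot span [%g, %g]: no extrapolation",
                 k[1], k[length(k)]))
  z <- pmin(pmax(z, k[1]), k[length(k)])
  allknots <- c(rep(k[1], spec$degree), k, rep(k[length(k)], spec$degree))
  B <- splines::splineDesign(allknots, z, ord = spec$degree + 1L,
                             outer.ok = FALSE)
  stopifnot(ncol(B) == spec$M)
  B
}

#' Random-walk penalty matrix for P-spline coefficients
#'
#' Builds the improper Gaussian prior precision structure implied by a
#' first- or second-order random walk on the spline coefficients
#' `alpha_m = alpha_{m-1} + u_m` (order 1) or
#' `alpha_m = 2 alpha_{m-1} - alpha_{m-2} + u_m` (order 2) with iid Gaussian
#' increments: `K = D'D` where `D` is the order-`d` difference operator. The
#' prior on the coefficient block is then proportional to
#' `exp(-tau2/2 * alpha' K alpha)` with rank `M - d`. `K` annihilates
#' polynomial sequences in the coefficient index up to degree `d - 1`
#' (constants for RW1; constants and linear trends for RW2), which is what
#' makes the penalty shrink towards those polynomials rather than to zero.
#'
#' @param M number of basis coefficients.
#' @param order random-walk order, 1 or 2 (default 2, the package standard).
#' @return object of class `"penalty_matrix"`: list with `K` (M x M symmetric
#'   positive semi-definite), `order`, and `rank` (`M - order`).
#' @export
rw_penalty <- function(M, order = 2L) {
  M <- as.integer(M)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("random-walk order must be 1 or 2")
  if (M <= order) stop("need more coefficients than the random-walk order")
  D <- diff(diag(M), differences = order)
  structure(
    list(K = crossprod(D), order = order, rank = M - order),
    class = "penalty_matrix"
  )
}
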