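#' Truncated power spline specification
#'
#' Describes a q-degree truncated power basis with knots `kappa_1 < ... <
#' kappa_K` on the scale of a single index `u = beta' x`. The basis is
#' `(1, u, ..., u^q, (u - kappa_1)_+^q, ..., (u - kappa_K)_+^q)`, of
#' dimension `q + K + 1`.
#'
#' @param degree spline degree `q >= 1`; the linear part must be separable
#'   so that linearity of a coefficient function is a testable sub-model.
#' @param knots numeric vector of strictly increasing interior knots
#'   (possibly empty, in which case the basis is purely polynomial).
#' @return An object of class `spline_spec` with elements `degree`, `knots`
#'   and `basis_dim = degree + length(knots) + 1`.
#' @export
spline_spec <- function(degree, knots = numeric(0)) {
  degree <- as.integer(degree)
  knots <- as.numeric(knots)
  if (degree < 1L) stop("spline degree must be >= 1")
  if (length(knots) > 1L && any(diff(knots) <= 0))
    stop("knots must be strictly increasing")
  structure(
    list(degree = degree, knots = knots,
         basis_dim = degree + length(knots) + 1L),
    class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("Truncated power spline basis: degree %d, %d knot(s), dim %d\n",
              x$degree, length(x$knots), x$basis_dim))
  if (length(x$knots)) cat("  knots:", paste(signif(x$knots, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the truncated power basis
#'
#' @param u numeric vector of index values.
#' @param spec a [spline_spec()].
#' @return A `length(u) x basis_dim` matrix; row `i` is
#'   `(1, u_i, ..., u_i^q, (u_i - kappa_1)_+^q, ...)`. Truncated terms are
#'   exactly zero for `u <= kappa_k`.
#' @export
basis_vector <- function(u, spec) {
  q <- spec$degree
  poly <- outer(u, 0:q, `^`)
  if (length(spec$knots) == 0L) return(poly)
  trunc <- sapply(spec$knots, function(kap) pmax(u - kap, 0)^q)
  cbind(poly, matrix(trunc, nrow = length(u)))
}

#' Derivative of the truncated power basis
#'
#' Elementwise derivative of [basis_vector()] in `u`. At a knot the value 0
#' is used (right-continuity of the truncated terms; see the package
#' vignette for the convention).
#'
#' @inheritParams basis_vector
#' @return A `length(u) x basis_dim` matrix of derivatives
#'   `(0, 1, 2u, ..., q u^{q-1}, q (u - kappa_k)_+^{q-1} ...)`.
#' @export
basis_derivative <- function(u, spec) {
  q <- spec$degree
  dpoly <- cbind(matrix(0, length(u), 1),
                 outer(u, seq_len(q) - 1, `^`) *
                   rep(seq_len(q), each = length(u)))
  if (length(spec$knots) == 0L) return(dpoly)
  dtrunc <- sapply(spec$knots, function(kap) {
    w <- u - kap
    ifelse(w > 0, q * w^(q - 1), 0)
  })
  cbind(dpoly, matrix(dtrunc, nrow = length(u)))
}

#' Place interior knots over the range of an index
#'
#' Knots are evenly spaced strictly inside the observed range of the index
#' values: `kappa_k = min + k (max - min) / (K + 1)`.
#'
#' @param index_values observed index values `beta' x`.
#' @param K number of interior knots (`K >= 0`).
#' @return Numeric vector of `K` knots (empty when `K = 0`).
#' @export
place_knots <- function(index_values, K) {
  if (length(index_values) == 0L) stop("no index values supplied")
  K <- as.integer(K)
  if (K < 0L) stop("K must be >= 0")
  if (K == 0L) return(numeric(0))
  rng <- range(index_values)
  if (diff(rng) <= 0) stop("degenerate index range: all values identical")
  rng[1] + seq_len(K) * diff(rng) / (K + 1)
}
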