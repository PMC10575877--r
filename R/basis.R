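#' Specify a temperature-response basis
#'
#' The four candidate forms of the nonlinear temperature response: raw
#' polynomial, cubic B-spline, and natural cubic splines with 3 or 5 knots.
#' Knots may be given explicitly (degrees C, strictly increasing) or placed
#' by the quantile rule of [place_knots()] when the basis is evaluated on
#' data.  The intercept column is never included: the model's common
#' intercept absorbs it.
#'
#' Column counts: polynomial of degree `d` has `d` columns; a natural cubic
#' spline with `k` knots has `k - 1`; the cubic B-spline has
#' `length(interior knots) + degree` columns (the full partition-of-unity
#' basis minus the intercept-carrying column).
#'
#' @param kind `"polynomial"`, `"bspline"`, `"ncs3"`, or `"ncs5"`.
#' @param degree polynomial/B-spline degree (defaults: 3, the conventional
#'   cubic choice for both).
#' @param knots numeric vector of explicit knots, or `NULL` for quantile
#'   placement.  For `"ncs3"`/`"ncs5"` these are all knots (3 or 5, boundary
#'   included); for `"bspline"` they are interior knots (default: quartiles
#'   of the data).
#' @return An object of class `"basis_spec"`.
#' @examples
#' basis_spec("ncs3", knots = c(-7, 10, 27))
#' @export
basis_spec <- function(kind = c("polynomial", "bspline", "ncs3", "ncs5"),
                       degree = 3L, knots = NULL) {
  kind <- match.arg(kind)
  if (!is_count(degree, 1L)) stopf("`degree` must be a positive integer")
  if (!is.null(knots)) {
    knots <- as.numeric(knots)
    if (is.unsorted(knots, strictly = TRUE)) stopf("`knots` must be strictly increasing")
    k_need <- switch(kind, ncs3 = 3L, ncs5 = 5L, NA_integer_)
    if (!is.na(k_need) && length(knots) != k_need)
      stopf("%s requires exactly %d knots, got %d", kind, k_need, length(knots))
  }
  structure(list(kind = kind, degree = as.integer(degree), knots = knots),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("basis spec: %s (degree %d)%s\n", x$kind, x$degree,
              if (is.null(x$knots)) ", quantile knot placement"
              else paste0(", knots ", paste(format(x$knots), collapse = ", "))))
  invisible(x)
}

#' Place spline knots at empirical quantiles
#'
#' Knots sit at equally spaced empirical quantiles with the 5th and 95th
#' percentiles as boundary knots: `k = 3` uses the 5th, 50th and 95th;
#' `k = 5` uses the 5th, 27.5th, 50th, 72.5th and 95th.  Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param temperatures numeric vector of observed temperatures.
#' @param k number of knots (3 or 5).
#' @return Sorted numeric vector of `k` knots.
#' @export
place_knots <- function(temperatures, k) {
  if (!k %in% c(3L, 5L)) stopf("`k` must be 3 or 5")
  x <- temperatures[is.finite(temperatures)]
  if (length(unique(x)) < k)
    stopf("need at least %d distinct temperatures to place %d knots", k, k)
  probs <- seq(0.05, 0.95, length.out = k)
  kn <- stats::quantile(x, probs, type = 7, names = FALSE)
  if (is.unsorted(kn, strictly = TRUE))
    stopf("degenerate temperature distribution: quantile knots are not distinct")
  kn
}

#' Evaluate a temperature basis on a grid
#'
#' Deterministically evaluates the basis described by `spec` at the given
#' temperatures, resolving quantile-rule knots against the supplied data
#' when necessary.  Evaluation is pointwise: the row for a given temperature
#' does not depend on the rest of the grid (once knots are resolved), so
#' evaluating on a superset grid reproduces the original rows.
#'
#' @param temperatures numeric vector (finite).
#' @param spec a [basis_spec()].
#' @param keep_intercept logical; for `"bspline"` only, return the full
#'   partition-of-unity basis including the intercept-carrying column
#'   (used for diagnostics; model fitting always drops it).
#' @return Numeric matrix, one row per temperature, with the resolved spec
#'   attached as attribute `"resolved"` (a `basis_spec` with explicit knots
#'   and boundary).  Pass that resolved spec back in to evaluate the same
#'   basis on new grids.
#' @export
make_basis <- function(temperatures, spec, keep_intercept = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- as.numeric(temperatures)
  if (!all(is.finite(x))) stopf("temperatures must be finite")
  res <- resolve_basis(x, spec)
  B <- eval_basis(x, res, keep_intercept = keep_intercept)
  attr(B, "resolved") <- res
  B
}

# fill in data-dependent pieces (knots, boundary) once, so later evaluations
# on arbitrary grids reproduce the same basis functions
resolve_basis <- function(x, spec) {
  if (!is.null(spec$resolved)) return(spec)
  out <- spec
  rng <- range(x)
  if (spec$kind %in% c("ncs3", "ncs5")) {
    k <- if (spec$kind == "ncs3") 3L else 5L
    if (is.null(spec$knots)) {
      out$knots <- place_knots(x, k)
    } else if (spec$knots[1] < rng[1] || spec$knots[k] > rng[2]) {
      stopf("explicit knots [%g, %g] fall outside the data range [%g, %g]",
            spec$knots[1], spec$knots[k], rng[1], rng[2])
    }
  } else if (spec$kind == "bspline") {
    if (is.null(spec$knots)) {
      out$knots <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    } else if (any(spec$knots <= rng[1]) || any(spec$knots >= rng[2])) {
      stopf("interior B-spline knots must lie strictly inside the data range")
    }
    out$boundary <- rng
  }
  out$resolved <- TRUE
  out
}

eval_basis <- function(x, res, keep_intercept = FALSE) {
  switch(res$kind,
    polynomial = {
      B <- outer(x, seq_len(res$degree), `^`)
      colnames(B) <- paste0("temp^", seq_len(res$degree))
      B
    },
    bspline = {
      B <- splines::bs(x, knots = res$knots, degree = res$degree,
                       intercept = TRUE, Boundary.knots = res$boundary)
      B <- unclass(B)[, , drop = FALSE]
      colnames(B) <- paste0("bs", seq_len(ncol(B)))
      if (keep_intercept) B else B[, -1L, drop = FALSE]
    },
    ncs3 = ncs_basis(x, res$knots),
    ncs5 = ncs_basis(x, res$knots),
    stopf("unknown basis kind '%s'", res$kind))
}

# Natural cubic spline, truncated-power construction (k knots -> k-1
# columns): N_1 = x, N_{j+1} = d_j(x) - d_{k-1}(x) for j = 1..k-2, with
# d_j(x) = ((x - xi_j)_+^3 - (x - xi_k)_+^3) / (xi_k - xi_j).
# Second derivative is zero outside the boundary knots (linear tails).
ncs_basis <- function(x, knots) {
  k <- length(knots)
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(j) (pp3(x - knots[j]) - pp3(x - knots[k])) / (knots[k] - knots[j])
  B <- matrix(x, length(x), 1L)
  if (k >= 3L) {
    dk1 <- d(k - 1L)
    for (j in seq_len(k - 2L)) B <- cbind(B, d(j) - dk1)
  }
  colnames(B) <- c("temp", if (k >= 3L) paste0("ncs", seq_len(k - 2L)))
  B
}

#' Default basis candidates for DIC selection
#'
#' The four response forms compared by [select_basis()]: cubic polynomial,
#' cubic B-spline, and natural cubic splines with 3 and 5 quantile knots.
#'
#' @param polynomial_degree degree of the polynomial candidate.
#' @return Named list of [basis_spec()] objects.
#' @export
default_basis_candidates <- function(polynomial_degree = 3L) {
  list(polynomial = basis_spec("polynomial", degree = polynomial_degree),
       bspline = basis_spec("bspline"),
       ncs3 = basis_spec("ncs3"),
       ncs5 = basis_spec("ncs5"))
}
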