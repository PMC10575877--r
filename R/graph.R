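#' County adjacency graph
#'
#' A symmetric, self-loop-free neighbourhood structure over county ids; the
#' backbone of the intrinsic conditional autoregressive (ICAR) prior in the
#' spatiotemporal model.
#'
#' @param county_ids character vector of unique county identifiers.
#' @param edges two-column matrix or data.frame of county-id pairs (order
#'   within a pair is irrelevant; duplicates and reversed duplicates are
#'   collapsed).
#' @return An object of class `"county_graph"` with elements `county_ids` and
#'   `edges` (a two-column character matrix with `from < to` by index).
#' @examples
#' g <- county_graph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
#' icar_precision(g)
#' @export
county_graph <- function(county_ids, edges = NULL) {
  county_ids <- as.character(county_ids)
  if (anyDuplicated(county_ids)) stopf("`county_ids` must be unique")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), 0L, 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    i <- match(em[, 1L], county_ids); j <- match(em[, 2L], county_ids)
    if (anyNA(i) || anyNA(j))
      stopf("edge endpoint(s) not in `county_ids`: %s",
            paste(unique(c(em[, 1L][is.na(i)], em[, 2L][is.na(j)])), collapse = ", "))
    if (any(i == j)) stopf("self-loops are not allowed")
    lo <- pmin(i, j); hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    em <- cbind(county_ids[lo[keep]], county_ids[hi[keep]])
  }
  structure(list(county_ids = county_ids, edges = em), class = "county_graph")
}

#' @export
print.county_graph <- function(x, ...) {
  cat(sprintf("county graph: %d counties, %d edges, %d connected component(s)\n",
              length(x$county_ids), nrow(x$edges), graph_n_components(x)))
  invisible(x)
}

# igraph view of the adjacency, used for connectivity queries
graph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$county_ids, stringsAsFactors = FALSE))
}

graph_n_components <- function(graph) {
  if (length(graph$county_ids) == 0L) return(0L)
  igraph::components(graph_igraph(graph))$no
}

#' Read a county adjacency edge list
#'
#' Parses a two-column, whitespace- or comma-delimited edge-list text file.
#' Pair order is irrelevant.
#'
#' @param path path to the edge-list file.
#' @param county_ids optional full set of county ids (so that isolated
#'   counties without any edge are still vertices of the graph).
#' @return A [county_graph()].
#' @export
read_adjacency <- function(path, county_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) && is.null(county_ids))
    stopf("empty adjacency file and no `county_ids` given: %s", path)
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stopf("malformed edge on line(s): %s", paste(which(bad), collapse = ", "))
  em <- do.call(rbind, parts)
  ids <- county_ids %||% sort(unique(c(em)))
  county_graph(ids, em)
}

#' ICAR precision structure of a county graph
#'
#' Builds the intrinsic conditional autoregressive structure matrix
#' `Q = D - W` (vertex degree on the diagonal, -1 for each neighbour pair).
#' `Q` is symmetric positive semidefinite with row sums exactly zero; its
#' null space is spanned by the indicator of each connected component, so on
#' a connected graph the rank is `n - 1`.
#'
#' @param graph a [county_graph()].
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`), with county ids
#'   as dimnames.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "county_graph"))
  n <- length(graph$county_ids)
  if (n == 0L) stopf("empty graph")
  i <- match(graph$edges[, 1L], graph$county_ids)
  j <- match(graph$edges[, 2L], graph$county_ids)
  deg <- tabulate(c(i, j), nbins = n)
  Q <- Matrix::sparseMatrix(i = c(seq_len(n), i, j), j = c(seq_len(n), j, i),
                            x = c(deg, rep(-1, 2L * length(i))), dims = c(n, n),
                            dimnames = list(graph$county_ids, graph$county_ids))
  Matrix::forceSymmetric(Q)
}

#' First-order random-walk precision structure
#'
#' Structure matrix of the RW1 prior penalizing first differences of an
#' ordered effect: `u' Q u = sum (u_t - u_{t-1})^2`, with the additional
#' wrap-around difference `(u_n - u_1)` when `cyclic = TRUE` (used for the
#' month-of-year effect, where December is adjacent to January).
#'
#' @param n number of ordered levels (at least 2).
#' @param cyclic logical; close the walk into a cycle.
#' @return A sparse symmetric matrix with zero row sums; rank `n - 1`.
#' @examples
#' rw1_precision(3)
#' rw1_precision(12, cyclic = TRUE)
#' @export
rw1_precision <- function(n, cyclic = FALSE) {
  if (!is_count(n, min = 2L)) stopf("`n` must be an integer >= 2")
  n <- as.integer(n)
  D <- Matrix::bandSparse(n - 1L, n, k = 0:1,
                          diagonals = list(rep(-1, n - 1L), rep(1, n - 1L)))
  if (cyclic) {
    wrap <- Matrix::sparseMatrix(i = c(1L, 1L), j = c(1L, n), x = c(1, -1),
                                 dims = c(1L, n))
    D <- rbind(D, wrap)
  }
  Matrix::forceSymmetric(Matrix::crossprod(D))
}

# Spectral reparameterization of a (possibly improper) Gaussian structure
# matrix: returns eigenvectors V and eigenvalues lambda restricted to the
# positive part of the spectrum.  Coefficients expressed as u = V %*% w with
# prior w ~ N(0, (tau * diag(lambda))^-1) then satisfy the per-component
# sum-to-zero constraints exactly (for ICAR/RW1 the dropped null space is the
# component-wise constants).
structure_eigen <- function(Q, tol = 1e-9) {
  eg <- eigen(as.matrix(Q), symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 1)
  list(V = eg$vectors[, keep, drop = FALSE], lambda = eg$values[keep],
       rank = sum(keep), nullity = nrow(Q) - sum(keep))
}
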