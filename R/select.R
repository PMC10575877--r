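#' Choose the temperature-response basis by DIC
#'
#' Fits the model once per candidate basis and picks the candidate with the
#' minimal DIC.  Ties (equal DIC to within numerical tolerance) are broken
#' by fewer basis columns, then by declaration order.  A hard failure in any
#' candidate aborts selection, naming the failing spec.
#'
#' @param linked a [link_exposures()] result.
#' @param candidates named list of [basis_spec()] objects (at least 2);
#'   default the four standard candidates of [default_basis_candidates()].
#' @param spec an [st_spec()] whose temperature term is replaced by each
#'   candidate in turn.
#' @param outcome outcome score name.
#' @param seed RNG seed shared by all candidate fits.
#' @return list with `winner` (candidate name), `spec` (the winning
#'   [basis_spec()]), `fit` (the winning [st_fit()]), `fits` (all fits) and
#'   `dic_table` (data.frame: candidate, columns, dbar, p_d, dic).
#' @export
select_basis <- function(linked, candidates = default_basis_candidates(),
                         spec = st_spec(), outcome = "global", seed = NULL) {
  if (length(candidates) < 2L) stopf("need at least 2 candidate bases")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  fits <- vector("list", length(candidates))
  names(fits) <- names(candidates)
  for (nm in names(candidates)) {
    stopifnot(inherits(candidates[[nm]], "basis_spec"))
    sp <- spec_with(spec, temperature_term = temp_basis(candidates[[nm]]))
    fits[[nm]] <- tryCatch(
      st_fit(linked, sp, outcome = outcome, seed = seed),
      error = function(e) stopf("candidate '%s' (%s) failed to fit: %s",
                                nm, candidates[[nm]]$kind, conditionMessage(e)))
  }
  dic <- vapply(fits, function(f) f$dic$dic, numeric(1))
  ncols <- vapply(fits, function(f) length(f$design$temp_cols), numeric(1))
  tab <- data.frame(candidate = names(candidates),
                    columns = as.integer(ncols),
                    dbar = vapply(fits, function(f) f$dic$dbar, numeric(1)),
                    p_d = vapply(fits, function(f) f$dic$p_d, numeric(1)),
                    dic = dic, row.names = NULL, stringsAsFactors = FALSE)
  tol <- 1e-8 * max(1, abs(min(dic)))
  tied <- which(dic - min(dic) <= tol)
  win <- tied[order(ncols[tied], tied)][1L]
  list(winner = names(candidates)[win], spec = candidates[[win]],
       fit = fits[[win]], fits = fits, dic_table = tab)
}
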