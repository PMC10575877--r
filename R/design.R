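#' Assemble the model design from a linked dataset
#'
#' Turns a linked dataset and an [st_spec()] into the internal design bundle
#' used by the inference engines: the response vector, the fixed-effect
#' columns (intercept, centered study-month index "time", optional
#' precipitation and PM2.5, and the temperature columns of the chosen term),
#' and one design/prior block per active random effect.
#'
#' Conventions: "time" is the consecutive study-month index centered at
#' mid-study (decorrelating intercepts from slopes); month blocks use month
#' of year 1--12 with a cyclic RW1 structure (December adjacent to January);
#' the county-by-month interaction cell for county `i` (in graph order) and
#' month `m` has flat index `(i - 1) * 12 + m` (row-major, county-major);
#' the global walk `nu` runs over the full consecutive study-month index.
#' Temperature, precipitation and PM2.5 columns are centered at their sample
#' means (centers recorded for prediction; contrasts are unaffected).
#'
#' ICAR and RW1 blocks are reparameterized onto the positive eigenspace of
#' their structure matrix, which enforces the per-component sum-to-zero
#' constraints exactly; iid interaction blocks stay in indicator coordinates
#' and carry an explicit sum-to-zero constraint applied by conditioning.
#'
#' @param linked a [link_exposures()] result.
#' @param spec an [st_spec()].
#' @param outcome `"global"` or one of the five domain scores
#'   (`"general"`, `"reaction"`, `"attention"`, `"memory"`, `"language"`).
#' @return The design bundle (list), deterministic given its inputs.
#' @export
build_design <- function(linked, spec, outcome = "global") {
  stopifnot(inherits(linked, "tc_linked"), inherits(spec, "st_spec"))
  rec <- linked$records
  if (!nrow(rec)) stopf("linked dataset has no records")
  y <- outcome_vector(rec, outcome)
  n <- length(y)
  Tn <- linked$n_months
  time_c <- rec$time_index - (Tn + 1) / 2
  moy <- as.integer(rec$month)
  graph <- linked$graph
  cidx <- match(rec$county_id, graph$county_ids)
  if (anyNA(cidx)) stopf("record county not in graph: %s",
                         rec$county_id[which(is.na(cidx))[1L]])
  flags <- spec$effects

  centers <- numeric(0)
  center <- function(x, name) {
    mu <- mean(x)
    centers[[name]] <<- mu
    x - mu
  }

  X <- cbind(`(Intercept)` = rep(1, n), time = time_c)
  if (flags$precipitation) {
    if (anyNA(rec$precipitation_mm)) stopf("missing precipitation values")
    X <- cbind(X, precipitation = center(rec$precipitation_mm, "precipitation"))
  }
  if (flags$pm25) {
    if (anyNA(rec$pm25_ugm3)) stopf("missing PM2.5 values")
    X <- cbind(X, pm25 = center(rec$pm25_ugm3, "pm25"))
  }

  tt <- spec$temperature_term
  resolved_basis <- NULL
  if (tt$kind == "linear") {
    TT <- cbind(temperature = rec$temperature_c)
  } else if (tt$kind == "basis") {
    B <- make_basis(rec$temperature_c, tt$basis)
    resolved_basis <- attr(B, "resolved")
    TT <- B
  } else {
    cols <- lag_columns(linked, tt)
    TT <- as.matrix(rec[cols])
    colnames(TT) <- paste0("temp_", tt$direction, 0:tt$l_max)
    cc <- stats::cor(TT)
    hi <- which(abs(cc) > 0.99 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hi))
      warnf("offset temperatures are nearly collinear (|r| > 0.99 between %s and %s)",
            colnames(TT)[hi[1, 1]], colnames(TT)[hi[1, 2]])
  }
  for (j in seq_len(ncol(TT))) TT[, j] <- center(TT[, j], colnames(TT)[j])
  temp_cols <- ncol(X) + seq_len(ncol(TT))
  X <- cbind(X, TT)
  p_fix <- ncol(X)

  ind <- function(idx, m, w = NULL)
    Matrix::sparseMatrix(i = seq_len(n), j = idx, x = w %||% rep(1, n), dims = c(n, m))

  blocks <- list()
  add_eigen_block <- function(name, Q, idx, w = NULL, labels) {
    se <- structure_eigen(Q)
    A <- ind(idx, nrow(Q), w) %*% se$V
    blocks[[name]] <<- list(name = name, A = methods::as(A, "CsparseMatrix"),
                            lambda = se$lambda, V = se$V, labels = labels,
                            constraint = NULL, structure = attr(Q, "structure"))
  }

  nC <- length(graph$county_ids)
  Qc <- icar_precision(graph); attr(Qc, "structure") <- "icar"
  if (flags$county_bym_intercept) {
    add_eigen_block("county_intercept_structured", Qc, cidx, labels = graph$county_ids)
    blocks$county_intercept_iid <- list(
      name = "county_intercept_iid", A = ind(cidx, nC), lambda = rep(1, nC),
      V = NULL, labels = graph$county_ids, constraint = NULL, structure = "iid")
  }
  if (flags$county_slope) {
    add_eigen_block("county_slope_structured", Qc, cidx, w = time_c,
                    labels = graph$county_ids)
    blocks$county_slope_iid <- list(
      name = "county_slope_iid", A = ind(cidx, nC, time_c), lambda = rep(1, nC),
      V = NULL, labels = graph$county_ids, constraint = NULL, structure = "iid")
  }
  Qm <- rw1_precision(12L, cyclic = TRUE); attr(Qm, "structure") <- "rw1_cyclic"
  if (flags$month_rw_intercept)
    add_eigen_block("month_intercept", Qm, moy, labels = month.abb)
  if (flags$month_slope)
    add_eigen_block("month_slope", Qm, moy, w = time_c, labels = month.abb)
  if (flags$interaction || flags$interaction_slope) {
    cell_code <- (cidx - 1L) * 12L + moy     # row-major (county-major) pair index
    cells <- sort(unique(cell_code))
    m <- length(cells)
    lab <- sprintf("%s:%s", graph$county_ids[(cells - 1L) %/% 12L + 1L],
                   month.abb[(cells - 1L) %% 12L + 1L])
    ci <- match(cell_code, cells)
    if (flags$interaction)
      blocks$interaction_intercept <- list(
        name = "interaction_intercept", A = ind(ci, m), lambda = rep(1, m),
        V = NULL, labels = lab, cells = cells, constraint = rep(1, m),
        structure = "iid_sum_zero")
    if (flags$interaction_slope)
      blocks$interaction_slope <- list(
        name = "interaction_slope", A = ind(ci, m, time_c), lambda = rep(1, m),
        V = NULL, labels = lab, cells = cells, constraint = rep(1, m),
        structure = "iid_sum_zero")
  }
  if (flags$global_time_rw) {
    Qt <- rw1_precision(Tn, cyclic = FALSE); attr(Qt, "structure") <- "rw1"
    add_eigen_block("nu_time", Qt, rec$time_index,
                    labels = sprintf("%d-%02d", linked$time_index$year,
                                     linked$time_index$month))
  }

  # assemble sparse design and column bookkeeping
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  parts <- c(list(Xs), lapply(blocks, `[[`, "A"))
  M <- do.call(cbind, parts)
  offs <- p_fix
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]]$A)
    blocks[[nm]]$cols <- offs + seq_len(k)
    offs <- offs + k
  }
  col_names <- c(colnames(X), unlist(lapply(blocks, function(b)
    paste(b$name, seq_along(b$cols), sep = ".")), use.names = FALSE))

  list(y = y, M = M, p_fix = p_fix, fixed_names = colnames(X),
       col_names = col_names, blocks = blocks, temp_cols = temp_cols,
       temp_names = colnames(TT), centers = centers,
       resolved_basis = resolved_basis, temperature_term = tt,
       outcome = outcome, n = n, n_months = Tn, time_center = (Tn + 1) / 2)
}

# names of the lagged/lead temperature columns a displacement term needs
lag_columns <- function(linked, tt) {
  side <- if (tt$direction == "lag") "lag" else "lead"
  have <- if (side == "lag") linked$lag_window else linked$lead_window
  if (have < tt$l_max)
    stopf("linked data has %s window %d but the temperature term needs %d; relink with link_exposures()",
          side, have, tt$l_max)
  c("temperature_c", paste0("temperature_", side, seq_len(tt$l_max)))
}
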