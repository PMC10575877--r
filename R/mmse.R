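#' MMSE scoring configuration
#'
#' The cognitive screen used here has 24 items scored by correctness and a
#' global score on 0--30, split over five sub-domains (general ability,
#' reaction, attention and calculation, memory, language comprehension and
#' self-coordination).  The per-item point values and the item-to-domain
#' partition of the instrument are not published with the survey extract this
#' package emulates, so the shipped default is a declared stand-in: six
#' 2-point items carried by the attention-and-calculation domain and 1-point
#' items elsewhere, summing to 30.
#'
#' @param weights integer vector of 24 positive item weights summing to 30.
#' @param domains character vector of length 24 assigning each item to one of
#'   `"general"`, `"reaction"`, `"attention"`, `"memory"`, `"language"`.
#' @return An object of class `"mmse_config"`.
#' @examples
#' cfg <- mmse_config()
#' sum(cfg$weights)  # 30
#' @export
mmse_config <- function(weights = NULL, domains = NULL) {
  if (is.null(weights))
    weights <- c(rep(1L, 11L), rep(2L, 6L), rep(1L, 7L))
  if (is.null(domains))
    domains <- c(rep("general", 8L), rep("reaction", 3L),
                 rep("attention", 6L), rep("memory", 3L), rep("language", 4L))
  weights <- as.integer(weights)
  if (length(weights) != 24L) stopf("`weights` must have length 24, got %d", length(weights))
  if (any(weights < 1L)) stopf("item weights must be positive integers")
  if (sum(weights) != 30L) stopf("item weights must sum to 30, got %d", sum(weights))
  if (length(domains) != 24L) stopf("`domains` must have length 24, got %d", length(domains))
  bad <- setdiff(unique(domains), mmse_domains())
  if (length(bad)) stopf("unknown domain(s): %s", paste(bad, collapse = ", "))
  structure(list(weights = weights, domains = domains), class = "mmse_config")
}

#' @export
print.mmse_config <- function(x, ...) {
  cat("MMSE scoring configuration: 24 items, global score 0-30\n")
  tab <- tapply(x$weights, factor(x$domains, mmse_domains()), sum)
  cat("domain maxima:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

mmse_domains <- function() c("general", "reaction", "attention", "memory", "language")

# names of the score columns on record tables
score_cols <- function() c(global = "global_score",
                           general = "score_general", reaction = "score_reaction",
                           attention = "score_attention", memory = "score_memory",
                           language = "score_language")

#' Score a 24-item MMSE response vector
#'
#' Items are scored by correctness: each response is 0 (incorrect) or 1
#' (correct) and contributes its configured weight to its domain.  The global
#' score is the sum of the five domain scores and lies in 0--30.
#'
#' @param item_responses integer vector of 24 values in `{0, 1}`.
#' @param config an [mmse_config()].
#' @return A list with `domain_scores` (named integer vector of length 5,
#'   ordered general, reaction, attention, memory, language) and
#'   `global_score` (integer).
#' @examples
#' score_mmse(rep(1, 24))$global_score  # 30
#' @export
score_mmse <- function(item_responses, config = mmse_config()) {
  stopifnot(inherits(config, "mmse_config"))
  if (length(item_responses) != 24L)
    stopf("`item_responses` must have length 24, got %d", length(item_responses))
  if (anyNA(item_responses) || !all(item_responses %in% c(0, 1)))
    stopf("item responses must be 0 (incorrect) or 1 (correct)")
  pts <- config$weights * as.integer(item_responses)
  dom <- factor(config$domains, levels = mmse_domains())
  domain_scores <- as.integer(tapply(pts, dom, sum, default = 0L))
  names(domain_scores) <- mmse_domains()
  list(domain_scores = domain_scores, global_score = sum(domain_scores))
}

#' Filter subject records and log exclusions
#'
#' Applies the record-validity rules used for the survey extract: records
#' with missing location, missing sociodemographic covariates, or fewer than
#' five sub-domain scores are removed, and duplicated subject ids keep only
#' the first occurrence in input order.  Filtering never errors on bad rows;
#' every removal is logged with a reason.  The operation is idempotent.
#'
#' @param records data.frame with columns `subject_id`, `county_id`, the five
#'   `score_*` columns (see [score_mmse()]) and covariates `gender`, `age`,
#'   `residence`, `education`, `income`, `ethnicity`.  Missing values may be
#'   `NA` or empty strings.
#' @return A list with `kept` (the surviving rows, input order preserved) and
#'   `exclusions` (data.frame of `subject_id`, `reason`).
#' @export
filter_records <- function(records) {
  need_cols(records, c("subject_id", "county_id"), "`records`")
  n <- nrow(records)
  blank <- function(x) is.na(x) | (is.character(x) & !is.na(x) & trimws(x) == "")
  covs <- c("gender", "age", "residence", "education", "income", "ethnicity")
  doms <- unname(score_cols()[mmse_domains()])
  reason <- rep(NA_character_, n)

  miss_loc <- blank(records$county_id)
  reason[miss_loc] <- "missing location"

  present_cov <- intersect(covs, names(records))
  cov_bad <- if (length(present_cov) < length(covs)) rep(TRUE, n) else
    Reduce(`|`, lapply(records[present_cov], blank))
  reason[is.na(reason) & cov_bad] <- "missing covariates"

  present_dom <- intersect(doms, names(records))
  dom_bad <- if (length(present_dom) < length(doms)) rep(TRUE, n) else
    Reduce(`|`, lapply(records[present_dom], blank))
  reason[is.na(reason) & dom_bad] <- "incomplete domains"

  dup <- duplicated(records$subject_id) & !blank(records$subject_id)
  reason[is.na(reason) & dup] <- "duplicate id"

  keep <- is.na(reason)
  exclusions <- data.frame(subject_id = as.character(records$subject_id[!keep]),
                           reason = reason[!keep], stringsAsFactors = FALSE)
  list(kept = records[keep, , drop = FALSE], exclusions = exclusions)
}
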