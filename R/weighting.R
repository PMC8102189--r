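# inverse-probability-of-treatment weights, trimming of extreme propensity
# scores, and weight truncation

#' Compute raw inverse-probability-of-treatment weights
#'
#' Exposed patients receive `1/PS`, controls `1/(1-PS)`, so that each group is
#' reweighted to the covariate distribution of the full cohort (the ATE
#' pseudo-population). Trimming and truncation are applied separately by
#' [trim_extreme_ps()] and [truncate_weights()].
#'
#' @param ps numeric propensity scores, strictly inside (0, 1).
#' @param exposed logical exposure flags, parallel to `ps`.
#' @param patient_id patient identifiers; defaults to `names(ps)`.
#' @return A `weighted_cohort` data frame with columns `patient_id`, `exposed`,
#'   `ps`, `raw_weight`, `trimmed` (all `FALSE`), `weight` (`= raw_weight`).
#' @export
compute_weights <- function(ps, exposed, patient_id = names(ps)) {
  if (is.null(patient_id)) patient_id <- as.character(seq_along(ps))
  stopifnot(length(ps) == length(exposed), length(ps) == length(patient_id))
  if (any(is.na(ps)) || any(ps <= 0) || any(ps >= 1))
    stop("propensity scores must lie strictly inside (0, 1)")
  raw <- ifelse(exposed, 1 / ps, 1 / (1 - ps))
  wc <- data.frame(patient_id = as.character(patient_id),
                   exposed = as.logical(exposed),
                   ps = as.numeric(ps),
                   raw_weight = raw,
                   trimmed = FALSE,
                   weight = raw,
                   stringsAsFactors = FALSE)
  class(wc) <- c("weighted_cohort", "data.frame")
  wc
}

#' Trim the most extreme propensity scores
#'
#' Flags the `floor(fraction/2 * n)` patients with the lowest propensity scores
#' and the same number with the highest (symmetric tails, 2.5% per tail at the
#' default 5%). Trimmed patients stay in the table but carry zero weight in all
#' downstream weighted estimates; unweighted analyses still see them. Ties at
#' the boundary are broken by patient id, so repeated runs flag the same
#' patients.
#'
#' @param wc a `weighted_cohort` from [compute_weights()].
#' @param fraction total proportion of the cohort to trim (default 0.05).
#' @return The `weighted_cohort` with updated `trimmed` flags and zeroed
#'   weights for trimmed patients.
#' @export
trim_extreme_ps <- function(wc, fraction = 0.05) {
  stopifnot(inherits(wc, "weighted_cohort"), fraction >= 0, fraction < 1)
  n <- nrow(wc)
  k <- floor(fraction / 2 * n)
  wc$trimmed <- FALSE
  if (k > 0) {
    ord <- order(wc$ps, wc$patient_id)
    wc$trimmed[ord[seq_len(k)]] <- TRUE
    wc$trimmed[ord[seq(n - k + 1, n)]] <- TRUE
  }
  # trimming resets untrimmed weights from raw; truncation is applied after
  wc$weight <- ifelse(wc$trimmed, 0, wc$raw_weight)
  wc
}

#' Truncate extreme weights
#'
#' Caps every untrimmed patient's weight at `cap` (default 10), the standard
#' guard against residual extreme weights after trimming. The weight ordering
#' is preserved up to ties at the cap, and the operation is idempotent.
#'
#' @param wc a `weighted_cohort`.
#' @param cap positive weight ceiling.
#' @return The `weighted_cohort` with `weight = min(weight, cap)` for untrimmed
#'   patients.
#' @export
truncate_weights <- function(wc, cap = 10) {
  stopifnot(inherits(wc, "weighted_cohort"), is.numeric(cap), cap > 0)
  wc$weight <- ifelse(wc$trimmed, 0, pmin(wc$weight, cap))
  wc
}

#' Write a weights table as TSV
#'
#' @param wc a `weighted_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(wc, path) {
  utils::write.table(as.data.frame(wc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
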