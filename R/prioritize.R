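# Semi-quantification and risk-based priority scoring.
#
# Response factors (area per uM) are fitted per calibration chemical by
# regression through the origin, then transferred to unknown features via a
# log-linear model on predicted ionization efficiency (log IE). The priority
# score is a predicted hazard quotient: predicted concentration divided by
# predicted LC50, both in mM. It compares features to one another; it is not
# an absolute risk estimate.

# ng/mL -> uM using the formula's monoisotopic mass as molar mass
# (ng/mL = ug/L; ug/L divided by g/mol gives umol/L).
ng_ml_to_um <- function(conc_ng_ml, molar_mass) conc_ng_ml / molar_mass

#' Fit a response factor from a calibration curve
#'
#' Converts concentrations (ng/mL) to uM via the chemical's molar mass and
#' fits `area = rf * conc_uM` by least squares through the origin. Curves
#' detected at fewer than `min_levels` levels are rejected (`NULL` with a
#' message attribute via warning), as are non-positive fitted slopes.
#'
#' @param curve data.frame with columns `conc_ng_ml` and `area`; rows with
#'   zero/NA area count as not detected.
#' @param molar_mass Molar mass, g/mol (the formula's monoisotopic mass is
#'   used throughout the package).
#' @param min_levels Minimum detected calibration levels. Default 5.
#' @return A `response_factor`: list with `rf` (area per uM) and
#'   `n_levels_used`; or `NULL` (with a warning) when rejected.
#' @export
fit_response_factor <- function(curve, molar_mass, min_levels = 5) {
  stopifnot(all(c("conc_ng_ml", "area") %in% names(curve)),
            molar_mass > 0)
  det <- !is.na(curve$area) & curve$area > 0
  curve <- curve[det, , drop = FALSE]
  if (any(curve$conc_ng_ml <= 0)) stop("calibration concentrations must be > 0")
  if (anyDuplicated(curve$conc_ng_ml)) stop("calibration levels must be distinct")
  if (nrow(curve) < min_levels) {
    warning("calibration curve rejected: detected at ", nrow(curve),
            " level(s), need >= ", min_levels)
    return(NULL)
  }
  x <- ng_ml_to_um(curve$conc_ng_ml, molar_mass)
  rf <- sum(curve$area * x) / sum(x^2)
  if (rf <= 0) {
    warning("calibration curve rejected: non-positive response factor")
    return(NULL)
  }
  structure(list(rf = rf, n_levels_used = nrow(curve)),
            class = "response_factor")
}

#' Fit the ionization-efficiency transfer model
#'
#' Ordinary least squares of `log10(rf)` on predicted log ionization
#' efficiency over the calibration chemicals, mapping predictor-scale log IE
#' to instrument-specific response factors.
#'
#' @param calibrant_rfs data.frame with columns `log_ie` (predicted) and
#'   `rf` (fitted response factor, area per uM, > 0).
#' @return An `ie_transfer`: list with `slope`, `intercept`, `r_squared`,
#'   `n_calibrants`.
#' @export
fit_ie_transfer <- function(calibrant_rfs) {
  stopifnot(all(c("log_ie", "rf") %in% names(calibrant_rfs)))
  ok <- stats::complete.cases(calibrant_rfs[, c("log_ie", "rf")]) &
    calibrant_rfs$rf > 0
  d <- calibrant_rfs[ok, , drop = FALSE]
  if (nrow(d) < 2 || length(unique(d$log_ie)) < 2)
    stop("IE transfer needs >= 2 calibrants with distinct log IE")
  fit <- stats::lm(log10(rf) ~ log_ie, data = d)
  y <- log10(d$rf)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[["log_ie"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_calibrants = nrow(d)),
            class = "ie_transfer")
}

#' Predict a concentration from peak area and predicted log IE
#'
#' The instrument-specific response factor is
#' `rf = 10^(slope * log_ie + intercept)`; the concentration is
#' `area / rf` in uM, returned in mM.
#'
#' @param area Integrated peak area.
#' @param log_ie Predicted log ionization efficiency of the feature.
#' @param transfer An [fit_ie_transfer()] model.
#' @return Predicted concentration, mM.
#' @export
predict_concentration <- function(area, log_ie, transfer) {
  stopifnot(inherits(transfer, "ie_transfer"))
  rf <- 10^(transfer$slope * log_ie + transfer$intercept)
  (area / rf) / 1000
}

#' Priority score (predicted hazard quotient)
#'
#' @param concentration_mM Predicted concentration, mM.
#' @param lc50_mM Predicted LC50, mM (> 0).
#' @return Dimensionless score, concentration / LC50.
#' @export
#' @examples
#' priority_score(0.3875, 0.25)  # 1.55
priority_score <- function(concentration_mM, lc50_mM) {
  if (any(!is.finite(lc50_mM)) || any(lc50_mM <= 0))
    stop("lc50_mM must be positive and finite")
  concentration_mM / lc50_mM
}

#' Rank features by priority score
#'
#' Descending priority score; ties broken by lower LC50 (more toxic first),
#' then feature id. Records without a score (e.g. negative-mode features for
#' which no concentration was calculated) are ranked after scored records,
#' among themselves by ascending LC50 then id, so toxicity-only records
#' remain rankable.
#'
#' @param records data.frame with `feature_id`, `priority_score` (may be
#'   NA), `lc50_mM`.
#' @return `records` reordered with a `rank` column (1 = highest priority).
#' @export
rank_features <- function(records) {
  stopifnot(all(c("feature_id", "priority_score", "lc50_mM") %in%
                  names(records)))
  scored <- !is.na(records$priority_score)
  key_score <- ifelse(scored, records$priority_score, -Inf)
  key_lc50 <- ifelse(is.na(records$lc50_mM), Inf, records$lc50_mM)
  ord <- order(-key_score, key_lc50, records$feature_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Toxicity-predictor constructors
#'
#' A toxicity predictor is a function `(structure_id) -> LC50 (mM)`.
#' `lc50_lookup()` builds one from a named table (for known/spiked
#' chemicals); `lc50_constant()` is a trivial baseline returning one value
#' for every structure. Trained structure-based toxicity models are outside
#' the package's scope and plug in through the same contract.
#'
#' @param table Named numeric vector: structure id -> LC50 (mM).
#' @param default Value returned for structures absent from `table`
#'   (default `NA`).
#' @return A predictor function.
#' @export
lc50_lookup <- function(table, default = NA_real_) {
  force(table); force(default)
  function(structure_id) {
    out <- unname(table[structure_id])
    out[is.na(out)] <- default
    out
  }
}

#' @rdname lc50_lookup
#' @param value Constant LC50, mM.
#' @export
lc50_constant <- function(value) {
  force(value)
  function(structure_id) rep(value, length(structure_id))
}

#' Build ranked priority records for annotated features
#'
#' Convenience wrapper: predicts a concentration for each feature that has
#' an area and a log-IE prediction, predicts LC50 from the annotated
#' structure, computes priority scores and ranks. Features without an area
#' or log IE (e.g. negative-mode features) get `NA` concentration and score
#' but are still ranked by toxicity.
#'
#' @param features data.frame with `feature_id`, `area`, `log_ie` (NA
#'   allowed), and `structure_id`.
#' @param transfer An [fit_ie_transfer()] model.
#' @param lc50_predictor A predictor from [lc50_lookup()] /
#'   [lc50_constant()].
#' @return Ranked data.frame with `predicted_conc_mM`, `lc50_mM`,
#'   `priority_score`, `rank`.
#' @export
prioritize_features <- function(features, transfer, lc50_predictor) {
  stopifnot(all(c("feature_id", "area", "log_ie", "structure_id") %in%
                  names(features)))
  conc <- ifelse(is.na(features$area) | is.na(features$log_ie), NA_real_,
                 predict_concentration(features$area, features$log_ie,
                                       transfer))
  lc50 <- lc50_predictor(features$structure_id)
  out <- features
  out$predicted_conc_mM <- conc
  out$lc50_mM <- lc50
  out$priority_score <- ifelse(is.na(conc) | is.na(lc50), NA_real_,
                               conc / lc50)
  rank_features(out)
}
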