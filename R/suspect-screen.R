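# Suspect screening: adduct expansion of a suspect list, exact-mass matching
# within a mDa tolerance, retention-time-index (RTI) regression on calibrants,
# and a predicted-retention-time plausibility filter.
#
# Suspect lists are data.frames in NORMAN Suspect List Exchange export style:
# columns name, formula and/or exact_mass, rti (optional), exposure_score
# (optional), source.

.check_suspects <- function(suspects) {
  if (!"name" %in% names(suspects))
    stop("suspect list missing 'name' column")
  if (!any(c("formula", "exact_mass") %in% names(suspects)))
    stop("suspect list needs a 'formula' or 'exact_mass' column")
  invisible(suspects)
}

.suspect_masses <- function(suspects) {
  m <- if ("exact_mass" %in% names(suspects)) as.numeric(suspects$exact_mass)
       else rep(NA_real_, nrow(suspects))
  if ("formula" %in% names(suspects)) {
    fill <- is.na(m) & !is.na(suspects$formula) & nzchar(suspects$formula)
    m[fill] <- vapply(suspects$formula[fill],
                      function(f) monoisotopic_mass(parse_formula(f)),
                      numeric(1))
  }
  m
}

#' Expand a suspect list into adduct candidates
#'
#' Positive mode expands to \[M+H\]+; negative mode to \[M-H\]- and
#' \[M+Cl\]-. Suspects with neither formula nor exact mass are skipped with
#' a warning.
#'
#' @param suspects Suspect list data.frame.
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame of candidate ions: suspect columns plus `adduct`,
#'   `neutral_mass` and `theoretical_mz`.
#' @export
expand_adducts <- function(suspects, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  .check_suspects(suspects)
  if (nrow(suspects) == 0) {
    out <- suspects
    out$adduct <- character(0); out$neutral_mass <- numeric(0)
    out$theoretical_mz <- numeric(0)
    return(out)
  }
  mass <- .suspect_masses(suspects)
  if (anyNA(mass)) {
    warning(sum(is.na(mass)), " suspect(s) without formula or exact mass skipped")
    suspects <- suspects[!is.na(mass), , drop = FALSE]
    mass <- mass[!is.na(mass)]
  }
  adds <- adducts()
  adds <- adds$name[adds$polarity == polarity]
  out <- do.call(rbind, lapply(adds, function(a) {
    x <- suspects
    x$adduct <- a
    x$neutral_mass <- mass
    x$theoretical_mz <- adduct_mz(mass, a)
    x
  }))
  rownames(out) <- NULL
  out
}

#' Match features against suspect candidates by exact mass
#'
#' A feature matches a candidate iff the absolute m/z difference is at most
#' `tol_mda` (inclusive). All matches are kept: a feature matched by several
#' suspects carries every candidate.
#'
#' @param features Feature table (same polarity as `candidates`).
#' @param candidates Output of [expand_adducts()].
#' @param tol_mda Mass tolerance, mDa. Default 2.
#' @return data.frame of matches: `feature_id`, `observed_mz`, `rt`,
#'   suspect `name`, `adduct`, `theoretical_mz`, `error_mda`, `error_ppm`,
#'   plus `rti`, `exposure_score`, `source` when present in the list.
#' @export
match_mz <- function(features, candidates, tol_mda = 2) {
  .check_features(features)
  carry <- intersect(c("rti", "exposure_score", "source", "formula"),
                     names(candidates))
  empty <- data.frame(feature_id = character(0), observed_mz = numeric(0),
                      rt = numeric(0), name = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      error_mda = numeric(0), error_ppm = numeric(0),
                      stringsAsFactors = FALSE)
  for (cc in carry) empty[[cc]] <- vector(class(candidates[[cc]]), 0)
  if (nrow(features) == 0 || nrow(candidates) == 0) return(empty)
  # inclusive boundary; the epsilon absorbs floating-point representation of
  # decimal m/z values at exactly the tolerance
  tol <- tol_mda / 1000 + 1e-12
  rows <- list()
  for (i in seq_len(nrow(features))) {
    hit <- which(abs(features$mz[i] - candidates$theoretical_mz) <= tol)
    if (length(hit) == 0) next
    err <- mass_error(features$mz[i], candidates$theoretical_mz[hit])
    r <- data.frame(feature_id = features$feature_id[i],
                    observed_mz = features$mz[i], rt = features$rt[i],
                    name = candidates$name[hit],
                    adduct = candidates$adduct[hit],
                    theoretical_mz = candidates$theoretical_mz[hit],
                    error_mda = err$error_mda, error_ppm = err$error_ppm,
                    stringsAsFactors = FALSE)
    for (cc in carry) r[[cc]] <- candidates[[cc]][hit]
    rows[[length(rows) + 1]] <- r
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the retention-time-index regression
#'
#' Ordinary least squares of calibrant RTI on measured retention time:
#' `rti = slope * rt + intercept`.
#'
#' @param calibrants data.frame with columns `rt` (seconds) and `rti`.
#' @return An `rti_model`: list with `slope` (RTI per second), `intercept`
#'   (RTI), `r_squared`, `n_calibrants`.
#' @export
fit_rti_model <- function(calibrants) {
  stopifnot(all(c("rt", "rti") %in% names(calibrants)))
  ok <- stats::complete.cases(calibrants[, c("rt", "rti")])
  calibrants <- calibrants[ok, , drop = FALSE]
  if (nrow(calibrants) < 2 || length(unique(calibrants$rt)) < 2)
    stop("RTI regression needs >= 2 calibrants with distinct retention times")
  fit <- stats::lm(rti ~ rt, data = calibrants)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((calibrants$rti - mean(calibrants$rti))^2)
  structure(list(slope = unname(stats::coef(fit)[["rt"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_calibrants = nrow(calibrants)),
            class = "rti_model")
}

#' @export
print.rti_model <- function(x, ...) {
  cat(sprintf("<rti_model> rti = %.4f * rt + %.2f  (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_calibrants))
  invisible(x)
}

#' Predicted-retention-time filter for suspect matches
#'
#' Inverts the RTI regression to predict each suspect's retention time,
#' `predicted_rt = (rti - intercept) / slope`, and flags matches whose
#' observed retention time deviates by at most `window_seconds` (inclusive).
#' Matches whose suspect lacks an RTI pass with `predicted_rt` unset and a
#' warning.
#'
#' @param matches Output of [match_mz()] (suspect `rti` column used).
#' @param model An [fit_rti_model()] fit.
#' @param window_seconds Maximum absolute deviation, seconds. Default 120.
#' @return `matches` with `predicted_rt`, `rt_deviation` and
#'   `passed_rt_filter` columns added.
#' @export
rt_filter <- function(matches, model, window_seconds = 120) {
  if (model$slope == 0) stop("RTI model slope is zero; cannot invert")
  rti <- if ("rti" %in% names(matches)) as.numeric(matches$rti)
         else rep(NA_real_, nrow(matches))
  matches$predicted_rt <- (rti - model$intercept) / model$slope
  matches$rt_deviation <- matches$rt - matches$predicted_rt
  matches$passed_rt_filter <- abs(matches$rt_deviation) <= window_seconds
  no_rti <- is.na(rti)
  if (any(no_rti)) {
    warning(sum(no_rti), " match(es) without suspect RTI pass the RT filter by default")
    matches$passed_rt_filter[no_rti] <- TRUE
  }
  matches
}

#' Screen features against suspect lists
#'
#' Full suspect-screening chain per list: adduct expansion, exact-mass
#' matching, RTI regression on the calibrants, and the predicted-retention-
#' time filter. Features of both polarities may be supplied; each polarity is
#' expanded and matched separately.
#'
#' @param features Feature table.
#' @param suspect_lists Named list of suspect-list data.frames.
#' @param calibrants data.frame with `rt` and `rti` for [fit_rti_model()].
#' @param config A [pipeline_config()].
#' @return List with `model` (the fitted `rti_model`) and, per suspect list,
#'   `matches` (flagged match table) and `summary` (n features matched,
#'   multi-matched, and passing the RT filter).
#' @export
screen_suspects <- function(features, suspect_lists, calibrants,
                            config = pipeline_config()) {
  model <- fit_rti_model(calibrants)
  res <- lapply(suspect_lists, function(sl) {
    parts <- lapply(c("positive", "negative"), function(pol) {
      fs <- features[features$polarity == pol, , drop = FALSE]
      if (nrow(fs) == 0) return(NULL)
      match_mz(fs, expand_adducts(sl, pol), config$mz_tol_mda)
    })
    m <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    if (is.null(m) || nrow(m) == 0) {
      return(list(matches = m,
                  summary = c(n_matched = 0, n_multi = 0, n_rt_pass = 0)))
    }
    m <- rt_filter(m, model, config$rt_filter_window)
    per_feat <- table(m$feature_id)
    list(matches = m,
         summary = c(n_matched = length(per_feat),
                     n_multi = sum(per_feat > 1),
                     n_rt_pass = length(unique(m$feature_id[m$passed_rt_filter]))))
  })
  c(list(model = model), res)
}
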