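# Quality-control filter cascade for aligned LC-HRMS feature tables:
# intensity threshold -> replicate RSD -> blank ratio -> peak quality ->
# componentization -> MS2 assembly. Stage order is part of the contract;
# every stage returns a subset of its input and a trace entry.
#
# Feature tables are plain data.frames: feature_id, mz, rt (seconds),
# polarity, then one intensity column per replicate. 0 or NA means "not
# detected" in that replicate.

#' Experiment design
#'
#' Describes which replicate columns of a feature table belong to which
#' sample and which are method blanks.
#'
#' @param samples Named list: sample id -> character vector of replicate ids
#'   (column names of the feature table).
#' @param blanks Character vector of blank replicate ids.
#' @return An `experiment_design` object (data.frame with columns
#'   `replicate_id`, `sample_id`, `is_blank`).
#' @export
#' @examples
#' experiment_design(list(S1 = c("S1_r1", "S1_r2", "S1_r3")),
#'                   blanks = c("B_r1", "B_r2", "B_r3"))
experiment_design <- function(samples, blanks = character(0)) {
  stopifnot(is.list(samples), length(samples) >= 1)
  reps <- unlist(samples, use.names = FALSE)
  ids <- c(reps, blanks)
  if (anyDuplicated(ids))
    stop("replicate ids must be unique across samples and blanks")
  d <- data.frame(
    replicate_id = ids,
    sample_id = c(rep(names(samples), lengths(samples)),
                  rep("blank", length(blanks))),
    is_blank = c(rep(FALSE, length(reps)), rep(TRUE, length(blanks))),
    stringsAsFactors = FALSE
  )
  class(d) <- c("experiment_design", "data.frame")
  d
}

.design_samples <- function(design) unique(design$sample_id[!design$is_blank])

.check_features <- function(features, design = NULL) {
  need <- c("feature_id", "mz", "rt", "polarity")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(features$polarity), c("positive", "negative"))
  if (length(bad))
    stop("unknown polarity value(s): ", paste(bad, collapse = ", "))
  if (!is.null(design)) {
    miss <- setdiff(design$replicate_id, names(features))
    if (length(miss))
      stop("feature table lacks replicate column(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(features)
}

# intensity matrix (features x replicates), NA -> 0
.intensity_matrix <- function(features, replicate_ids) {
  m <- as.matrix(features[, replicate_ids, drop = FALSE])
  m[is.na(m)] <- 0
  storage.mode(m) <- "double"
  m
}

#' Intensity threshold filter
#'
#' A feature survives iff its maximum replicate intensity reaches the
#' threshold for its polarity (inclusive at the boundary).
#'
#' @param features Feature table.
#' @param design An [experiment_design()].
#' @param thresholds Named numeric, per polarity. Defaults
#'   `c(positive = 1e5, negative = 5e4)`.
#' @return Surviving subset of `features`.
#' @export
filter_intensity <- function(features, design,
                             thresholds = c(positive = 1e5, negative = 5e4)) {
  .check_features(features, design)
  if (nrow(features) == 0) return(features)
  m <- .intensity_matrix(features, design$replicate_id)
  thr <- thresholds[features$polarity]
  if (anyNA(thr)) stop("no threshold for polarity: ",
                       paste(setdiff(features$polarity, names(thresholds)),
                             collapse = ", "))
  keep <- apply(m, 1, max) >= thr
  features[keep, , drop = FALSE]
}

# sample-wise RSD on raw intensities; sd uses the n-1 denominator
.sample_rsd_pass <- function(vals, max_rsd_pct) {
  if (any(vals <= 0)) return(FALSE)          # must be present in every replicate
  mu <- mean(vals)
  100 * stats::sd(vals) / mu <= max_rsd_pct
}

#' Replicate-reproducibility (RSD) filter
#'
#' A feature survives iff there is at least one sample in which it is present
#' in every replicate and the sample-wise relative standard deviation
#' (100 * sd / mean, sample sd) is at most `max_rsd_pct`.
#'
#' @inheritParams filter_intensity
#' @param max_rsd_pct Maximum RSD, percent. Default 50.
#' @return Surviving subset of `features`.
#' @export
filter_replicate_rsd <- function(features, design, max_rsd_pct = 50) {
  .check_features(features, design)
  samples <- .design_samples(design)
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  if (any(lengths(rep_of) < 2))
    stop("RSD is undefined with fewer than 2 replicates per sample")
  if (nrow(features) == 0) return(features)
  m <- .intensity_matrix(features, design$replicate_id)
  keep <- vapply(seq_len(nrow(features)), function(i) {
    any(vapply(samples, function(s)
      .sample_rsd_pass(m[i, rep_of[[s]]], max_rsd_pct), logical(1)))
  }, logical(1))
  features[keep, , drop = FALSE]
}

#' Blank-ratio filter
#'
#' A feature survives iff the mean intensity over its best sample's
#' replicates strictly exceeds `factor` times the mean intensity over the
#' method-blank replicates (absent intensities count as zero). With no
#' blanks in the design all features survive, with a warning.
#'
#' @inheritParams filter_intensity
#' @param factor Blank ratio factor (> 0). Default 3.
#' @return Surviving subset of `features`.
#' @export
filter_blank_ratio <- function(features, design, factor = 3) {
  .check_features(features, design)
  stopifnot(factor > 0)
  blank_reps <- design$replicate_id[design$is_blank]
  if (length(blank_reps) == 0) {
    warning("no blanks in design; blank-ratio filter passes all features")
    return(features)
  }
  if (nrow(features) == 0) return(features)
  m <- .intensity_matrix(features, design$replicate_id)
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  keep <- vapply(seq_len(nrow(features)), function(i) {
    best <- max(vapply(rep_of, function(r) mean(m[i, r]), numeric(1)))
    best > factor * mean(m[i, blank_reps])
  }, logical(1))
  features[keep, , drop = FALSE]
}

#' Default peak-quality heuristic
#'
#' Labels an extracted-ion chromatogram (EIC) "high" quality iff it has at
#' least 5 points above half its maximum and a single local maximum.
#' Replaces neural-network EIC classifiers behind the same pluggable
#' contract (`function(feature, eic) -> "high"|"low"`).
#'
#' @param feature One-row feature table (unused by the default heuristic;
#'   part of the classifier contract).
#' @param eic Two-column matrix or data.frame: time, intensity. `NULL` is
#'   handled upstream.
#' @return `"high"` or `"low"`.
#' @export
default_peak_classifier <- function(feature, eic) {
  y <- as.numeric(eic[[2]])
  if (length(y) == 0 || max(y) <= 0) return("low")
  if (sum(y > max(y) / 2) < 5) return("low")
  # count strict interior local maxima (plateaus at the max count once)
  n_max <- 0L
  for (i in seq_along(y)) {
    left <- if (i == 1) -Inf else y[i - 1]
    right <- if (i == length(y)) -Inf else y[i + 1]
    if (y[i] > left && y[i] >= right) n_max <- n_max + 1L
  }
  if (n_max == 1L) "high" else "low"
}

#' Classify MS1 peak quality
#'
#' @param feature One-row feature table.
#' @param eic EIC trace (time, intensity) or `NULL`.
#' @param classifier Classifier conforming to the contract; default
#'   [default_peak_classifier()].
#' @return `"high"` or `"low"`; features without EIC data pass as `"high"`
#'   with a warning.
#' @export
classify_peak_quality <- function(feature, eic = NULL,
                                  classifier = default_peak_classifier) {
  if (is.null(eic)) {
    warning("feature ", feature$feature_id[1],
            ": no EIC data; passing peak-quality filter")
    return("high")
  }
  out <- tryCatch(classifier(feature, eic), error = function(e)
    stop("peak-quality classifier failed for feature ",
         feature$feature_id[1], ": ", conditionMessage(e)))
  if (!out %in% c("high", "low"))
    stop("classifier must return 'high' or 'low', got '", out, "'")
  out
}

#' Known co-elution mass deltas
#'
#' m/z differences used by [componentize()] to recognise non-protonated
#' adducts and isotopes of the same compound: 13C isotope spacing, sodium
#' and potassium exchange against a proton, and ammonium attachment.
#'
#' @return Named numeric vector of deltas, Da.
#' @export
adduct_deltas <- function() {
  c("13C" = 1.003355, "Na-H" = 21.981944,
    "K-H" = 37.955882, "NH3" = 17.026549)
}

#' Componentize co-eluting adducts and isotopes
#'
#' Groups co-eluting features (absolute retention-time difference at most
#' `rt_tol`) whose m/z difference matches a known adduct/isotope delta within
#' `delta_tol_mda`; only the lowest-mass member of each group — the one
#' consistent with \[M+H\]+ / \[M-H\]- — is kept. Features are expected to
#' share one polarity. Singletons are kept.
#'
#' @param features Feature table (one polarity).
#' @param rt_tol Co-elution tolerance, seconds. Default 5.
#' @param deltas Named delta table, Da. Default [adduct_deltas()].
#' @param delta_tol_mda Delta match tolerance, mDa. Default 2.
#' @return Surviving subset of `features`.
#' @export
componentize <- function(features, rt_tol = 5, deltas = adduct_deltas(),
                         delta_tol_mda = 2) {
  .check_features(features)
  n <- nrow(features)
  if (n <= 1) return(features)
  if (length(unique(features$polarity)) > 1)
    stop("componentize() expects features of a single polarity")
  drop <- rep(FALSE, n)
  ord <- order(features$mz)
  tol <- delta_tol_mda / 1000
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      i <- ord[a]; j <- ord[b]                 # mz[i] <= mz[j]
      if (abs(features$rt[i] - features$rt[j]) > rt_tol) next
      d <- features$mz[j] - features$mz[i]
      if (any(abs(d - deltas) <= tol)) drop[j] <- TRUE
    }
  }
  features[!drop, , drop = FALSE]
}

#' MS2 spectrum constructor
#'
#' @param precursor_mz Precursor m/z, Da.
#' @param rt Retention time, seconds.
#' @param collision_energy Collision energy, volts (NA if merged/unknown).
#' @param peaks Two-column matrix (mz, intensity); sorted ascending by mz on
#'   construction; intensities must be positive.
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(precursor_mz, rt, collision_energy = NA_real_,
                         peaks) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(peaks[, "intensity"] <= 0)) stop("peak intensities must be > 0")
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  structure(list(precursor_mz = precursor_mz, rt = rt,
                 collision_energy = collision_energy, peaks = peaks),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f, rt %.1f s, CE %s, %d peaks\n",
              x$precursor_mz, x$rt,
              ifelse(is.na(x$collision_energy), "merged",
                     format(x$collision_energy)), nrow(x$peaks)))
  invisible(x)
}

#' Assemble a merged MS2 spectrum for a feature
#'
#' Collects spectra whose precursor m/z lies within half of
#' `precursor_window` of the feature m/z and whose retention time lies within
#' half of `rt_window` of the feature retention time (both windows are full
#' widths). Each spectrum is normalized to base peak 100; fragments are
#' clustered across spectra within `frag_tol_mda`, relative intensities are
#' averaged over all collected spectra (a fragment absent from a spectrum
#' contributes zero), and fragments with mean relative intensity strictly
#' above `min_rel_intensity` are retained.
#'
#' @param feature One-row feature table.
#' @param spectra List of [ms2_spectrum()] objects.
#' @param precursor_window Full-width precursor m/z window, Da. Default 0.4.
#' @param rt_window Full-width retention-time window, seconds. Default 5.
#' @param min_rel_intensity Relative-intensity floor, percent of base peak.
#'   Default 5.
#' @param frag_tol_mda Fragment clustering tolerance, mDa. Default 5.
#' @return A merged `ms2_spectrum` (collision_energy `NA`), or `NULL` when no
#'   spectrum matches or no fragment survives.
#' @export
assemble_ms2 <- function(feature, spectra, precursor_window = 0.4,
                         rt_window = 5, min_rel_intensity = 5,
                         frag_tol_mda = 5) {
  sel <- Filter(function(s)
    abs(s$precursor_mz - feature$mz) <= precursor_window / 2 &&
      abs(s$rt - feature$rt) <= rt_window / 2, spectra)
  if (length(sel) == 0) return(NULL)
  # normalize each spectrum to base peak 100
  rel <- lapply(sel, function(s) {
    p <- s$peaks
    p[, "intensity"] <- 100 * p[, "intensity"] / max(p[, "intensity"])
    p
  })
  all_pk <- do.call(rbind, rel)
  ord <- order(all_pk[, "mz"])
  all_pk <- all_pk[ord, , drop = FALSE]
  src <- rep(seq_along(rel), vapply(rel, nrow, integer(1)))[ord]
  # single-linkage clustering along mz with gap > tolerance starting new bins
  tol <- frag_tol_mda / 1000
  cl <- cumsum(c(1, diff(all_pk[, "mz"]) > tol))
  mzs <- tapply(all_pk[, "mz"], cl, mean)
  # average across all collected spectra; within one spectrum duplicate hits
  # in a cluster sum first
  avg <- vapply(split(seq_along(cl), cl), function(idx) {
    per_spec <- tapply(all_pk[idx, "intensity"], src[idx], sum)
    sum(per_spec) / length(rel)
  }, numeric(1))
  keep <- avg > min_rel_intensity
  if (!any(keep)) return(NULL)
  ms2_spectrum(feature$mz, feature$rt, NA_real_,
               cbind(mz = as.numeric(mzs[keep]),
                     intensity = as.numeric(avg[keep])))
}

.trace_row <- function(stage, n_in, n_out) {
  data.frame(stage = stage, features_in = n_in, features_out = n_out,
             stringsAsFactors = FALSE)
}

#' Run the full filter cascade
#'
#' Applies, in order: intensity threshold, replicate RSD, blank ratio, peak
#' quality, componentization (per polarity), and MS2 assembly. Returns the
#' surviving features, their merged spectra, and a `filter_trace` recording
#' in/out counts per stage plus percentages relative to the input.
#'
#' @param features Feature table.
#' @param design An [experiment_design()].
#' @param spectra Optional list of [ms2_spectrum()] objects for MS2 assembly.
#' @param eics Optional named list (feature id -> EIC trace) for peak
#'   quality; features without an entry pass with a warning.
#' @param config A [pipeline_config()].
#' @return List with elements `features`, `spectra` (named by feature id),
#'   and `trace` (a `filter_trace` data.frame).
#' @export
run_cascade <- function(features, design, spectra = NULL, eics = NULL,
                        config = pipeline_config()) {
  .check_features(features, design)
  n0 <- nrow(features)
  trace <- list()

  f <- filter_intensity(features, design, config$intensity_thresholds)
  trace[[1]] <- .trace_row("intensity", n0, nrow(f))

  n_in <- nrow(f)
  f <- filter_replicate_rsd(f, design, config$max_rsd_pct)
  trace[[2]] <- .trace_row("replicate_rsd", n_in, nrow(f))

  n_in <- nrow(f)
  f <- filter_blank_ratio(f, design, config$blank_factor)
  trace[[3]] <- .trace_row("blank_ratio", n_in, nrow(f))

  n_in <- nrow(f)
  if (n_in > 0) {
    labels <- vapply(seq_len(n_in), function(i) {
      eic <- if (!is.null(eics)) eics[[f$feature_id[i]]] else NULL
      if (is.null(eic) && is.null(eics)) "high"  # no EIC data supplied at all
      else classify_peak_quality(f[i, , drop = FALSE], eic,
                                 config$peak_classifier)
    }, character(1))
    f <- f[labels == "high", , drop = FALSE]
  }
  trace[[4]] <- .trace_row("peak_quality", n_in, nrow(f))

  n_in <- nrow(f)
  if (n_in > 0) {
    parts <- split(f, f$polarity)
    f <- do.call(rbind, lapply(parts, componentize,
                               rt_tol = config$componentize_rt_tol,
                               delta_tol_mda = config$mz_tol_mda))
    f <- f[order(match(f$feature_id, features$feature_id)), , drop = FALSE]
    rownames(f) <- NULL
  }
  trace[[5]] <- .trace_row("componentize", n_in, nrow(f))

  n_in <- nrow(f)
  merged <- list()
  if (!is.null(spectra) && n_in > 0) {
    for (i in seq_len(n_in)) {
      m <- assemble_ms2(f[i, , drop = FALSE], spectra,
                        config$precursor_window, config$rt_window,
                        config$min_rel_intensity, config$frag_tol_mda)
      if (!is.null(m)) merged[[f$feature_id[i]]] <- m
    }
  }
  trace[[6]] <- .trace_row("ms2_assembly", n_in, length(merged))

  trace <- do.call(rbind, trace)
  trace$pct_of_input <- if (n0 > 0) round(100 * trace$features_out / n0, 1) else 0
  class(trace) <- c("filter_trace", "data.frame")
  list(features = f, spectra = merged, trace = trace)
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Filter cascade trace:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %6d -> %6d  (%.1f%% of input)\n",
                x$stage[i], x$features_in[i], x$features_out[i],
                x$pct_of_input[i]))
  invisible(x)
}
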