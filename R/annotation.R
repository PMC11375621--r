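# Consensus structural annotation: spectral-library cosine matching,
# cross-engine agreement via fingerprint Tanimoto similarity, and
# confidence-level assignment on the Schymanski scale (2b = online library
# match, 3 = confident in-silico structure, 4 = unequivocal formula,
# 5 = unknown; level 1 requires a local reference standard and is never
# emitted here).

#' Cosine similarity between two fragment spectra
#'
#' Fragments are paired greedily within `frag_tol_mda` (best intensity
#' product first, each peak used at most once). The score is
#' `sum(Ia * Ib) / sqrt(sum(Ia^2) * sum(Ib^2))` over matched pairs, with all
#' peaks — matched or not — contributing to the norms, so the measure is
#' symmetric and bounded in \[0, 1\].
#'
#' @param a,b [ms2_spectrum()] objects (non-empty).
#' @param frag_tol_mda Fragment match tolerance, mDa. Default 5.
#' @return Cosine score in \[0, 1\].
#' @export
#' @examples
#' s <- ms2_spectrum(200, 60, 30, cbind(c(81.07, 105.07), c(100, 40)))
#' cosine_score(s, s)  # 1
cosine_score <- function(a, b, frag_tol_mda = 5) {
  pa <- a$peaks; pb <- b$peaks
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("cosine_score() requires non-empty spectra")
  tol <- frag_tol_mda / 1000
  cand <- which(abs(outer(pa[, "mz"], pb[, "mz"], "-")) <= tol, arr.ind = TRUE)
  dot <- 0
  if (nrow(cand) > 0) {
    prod <- pa[cand[, 1], "intensity"] * pb[cand[, 2], "intensity"]
    ord <- order(prod, decreasing = TRUE)
    used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      dot <- dot + prod[k]
    }
  }
  unname(dot / sqrt(sum(pa[, "intensity"]^2) * sum(pb[, "intensity"]^2)))
}

#' Match a spectrum against a spectral library
#'
#' @param spectrum Query [ms2_spectrum()].
#' @param library List of library entries, each a list with `structure_id`
#'   and `spectrum` (an `ms2_spectrum`; peaks are normalized to base peak 100
#'   on load by the readers).
#' @param min_cosine Minimum cosine score, strict. Default 0.5.
#' @param frag_tol_mda Fragment tolerance for the cosine, mDa. Default 5.
#' @return data.frame of candidates with `structure_id`, `cosine` and
#'   `matched_peaks`, sorted by descending cosine, ties broken by
#'   matched-peak count then structure id. Empty when nothing scores above
#'   `min_cosine`.
#' @export
library_match <- function(spectrum, library, min_cosine = 0.5,
                          frag_tol_mda = 5) {
  rows <- lapply(library, function(entry) {
    sc <- cosine_score(spectrum, entry$spectrum, frag_tol_mda)
    data.frame(structure_id = entry$structure_id, cosine = sc,
               matched_peaks = .n_matched_peaks(spectrum, entry$spectrum,
                                                frag_tol_mda),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(structure_id = character(0),
                                      cosine = numeric(0),
                                      matched_peaks = integer(0))
  out <- out[out$cosine > min_cosine, , drop = FALSE]
  out <- out[order(-out$cosine, -out$matched_peaks, out$structure_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# number of greedily matched fragment pairs (same pairing rule as the cosine)
.n_matched_peaks <- function(a, b, frag_tol_mda = 5) {
  pa <- a$peaks; pb <- b$peaks
  tol <- frag_tol_mda / 1000
  cand <- which(abs(outer(pa[, "mz"], pb[, "mz"], "-")) <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  prod <- pa[cand[, 1], "intensity"] * pb[cand[, 2], "intensity"]
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  n <- 0L
  for (k in order(prod, decreasing = TRUE)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    n <- n + 1L
  }
  n
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` on equal-length bit vectors; defined as 1 when both
#' vectors are all-zero.
#'
#' @param fp_a,fp_b Fingerprints: logical/0-1 integer vectors, or bitstrings
#'   like `"1100"`.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto("1100", "1010")  # 1/3
tanimoto <- function(fp_a, fp_b) {
  a <- .as_bits(fp_a); b <- .as_bits(fp_b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

.as_bits <- function(fp) {
  if (is.character(fp) && length(fp) == 1) {
    bits <- strsplit(fp, "")[[1]]
    if (!all(bits %in% c("0", "1")))
      stop("fingerprint bitstring may contain only 0 and 1")
    return(bits == "1")
  }
  as.logical(fp)
}

#' Consensus structural annotation of one feature
#'
#' Combines candidate annotations from a spectral library and from forward /
#' inverse in-silico engines into one structure with a confidence level.
#' Rule order:
#' \enumerate{
#'   \item a library candidate with cosine above `min_cosine` and more than
#'     `min_matched_peaks` matched fragments: its structure at Level 2b;
#'   \item else, if the top forward and top inverse in-silico candidates each
#'     match more than `min_matched_peaks` fragments and their fingerprints
#'     agree (Tanimoto above `min_tanimoto`): the higher-scoring-within-its-
#'     engine (forward-first) structure at Level 3;
#'   \item else, an unequivocal formula candidate: Level 4;
#'   \item else Level 5 (unknown).
#' }
#' Engine-native scores are compared only within a source; cross-engine
#' agreement is established through the fingerprint gate, not by comparing
#' scores.
#'
#' @param feature_id Feature identifier.
#' @param candidates data.frame with columns `source` (one of `"library"`,
#'   `"silico_forward"`, `"silico_inverse"`, `"formula_only"`),
#'   `structure_id`, `score` (engine-native; for library candidates the
#'   cosine), `matched_peaks`, and optionally `fingerprint` (bitstring).
#' @param config A [pipeline_config()] supplying `min_cosine`,
#'   `min_matched_peaks` and `min_tanimoto`.
#' @return A `consensus_annotation`: list with `feature_id`, `structure_id`
#'   (or `NA`), `level` (`"2b"`, `"3"`, `"4"` or `"5"`), and `evidence`
#'   (character trace of the clauses evaluated).
#' @export
consensus_annotate <- function(feature_id, candidates,
                               config = pipeline_config()) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(.consensus(feature_id, NA_character_, "5",
                      "no candidates: Level 5 (unknown)"))
  }
  stopifnot(all(c("source", "structure_id") %in% names(candidates)))
  evidence <- character(0)
  top <- function(src) {
    x <- candidates[candidates$source == src, , drop = FALSE]
    if (nrow(x) == 0) return(NULL)
    x[order(-x$score, x$structure_id), , drop = FALSE][1, , drop = FALSE]
  }

  # (a) spectral-library clause
  lib <- candidates[candidates$source == "library", , drop = FALSE]
  if (nrow(lib) > 0) {
    lib <- lib[lib$score > config$min_cosine &
                 lib$matched_peaks > config$min_matched_peaks, , drop = FALSE]
    if (nrow(lib) > 0) {
      best <- lib[order(-lib$score, -lib$matched_peaks, lib$structure_id), ,
                  drop = FALSE][1, ]
      evidence <- c(evidence, sprintf(
        "library match %s (cosine %.3f, %d matched peaks): Level 2b",
        best$structure_id, best$score, best$matched_peaks))
      return(.consensus(feature_id, best$structure_id, "2b", evidence))
    }
    evidence <- c(evidence, "library candidates present but below cosine/peak gates")
  }

  # (b) in-silico agreement clause
  fwd <- top("silico_forward"); inv <- top("silico_inverse")
  if (!is.null(fwd) && !is.null(inv)) {
    peaks_ok <- fwd$matched_peaks > config$min_matched_peaks &&
      inv$matched_peaks > config$min_matched_peaks
    tan <- if (!is.null(fwd$fingerprint) && !is.null(inv$fingerprint) &&
               !is.na(fwd$fingerprint) && !is.na(inv$fingerprint))
      tanimoto(fwd$fingerprint, inv$fingerprint) else NA_real_
    if (peaks_ok && !is.na(tan) && tan > config$min_tanimoto) {
      evidence <- c(evidence, sprintf(
        "forward/inverse in-silico agreement (Tanimoto %.3f): Level 3", tan))
      return(.consensus(feature_id, fwd$structure_id, "3", evidence))
    }
    evidence <- c(evidence, sprintf(
      "in-silico candidates disagree or under-supported (Tanimoto %s)",
      ifelse(is.na(tan), "unavailable", sprintf("%.3f", tan))))
  }

  # (c) unequivocal formula
  frm <- candidates[candidates$source == "formula_only", , drop = FALSE]
  if (nrow(frm) == 1) {
    evidence <- c(evidence, sprintf("unequivocal formula %s: Level 4",
                                    frm$structure_id))
    return(.consensus(feature_id, frm$structure_id, "4", evidence))
  }
  if (nrow(frm) > 1)
    evidence <- c(evidence, "multiple formula candidates: not unequivocal")

  evidence <- c(evidence, "no clause satisfied: Level 5 (unknown)")
  .consensus(feature_id, NA_character_, "5", evidence)
}

.consensus <- function(feature_id, structure_id, level, evidence) {
  structure(list(feature_id = feature_id, structure_id = structure_id,
                 level = level, evidence = evidence),
            class = "consensus_annotation")
}

#' @export
print.consensus_annotation <- function(x, ...) {
  cat(sprintf("<consensus_annotation> %s: %s (Level %s)\n", x$feature_id,
              ifelse(is.na(x$structure_id), "unannotated", x$structure_id),
              x$level))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Annotate a set of features
#'
#' Applies [consensus_annotate()] per feature and returns a tidy table.
#'
#' @param candidate_sets Named list (feature id -> candidate data.frame).
#' @param config A [pipeline_config()].
#' @return data.frame with `feature_id`, `structure_id`, `level`, `evidence`
#'   (clauses collapsed with `"; "`).
#' @export
annotate_features <- function(candidate_sets, config = pipeline_config()) {
  rows <- lapply(names(candidate_sets), function(fid) {
    a <- consensus_annotate(fid, candidate_sets[[fid]], config)
    data.frame(feature_id = a$feature_id, structure_id = a$structure_id,
               level = a$level, evidence = paste(a$evidence, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature_id = character(0),
                                      structure_id = character(0),
                                      level = character(0),
                                      evidence = character(0))
  out
}
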