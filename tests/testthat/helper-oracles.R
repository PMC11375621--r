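# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive each predicate with plain loops,
# separately from the implementation under test.

make_design <- function(n_samples = 2, n_replicates = 3, n_blanks = 2) {
  experiment_design(
    samples = stats::setNames(lapply(seq_len(n_samples), function(s)
      paste0("S", s, "_r", seq_len(n_replicates))),
      paste0("S", seq_len(n_samples))),
    blanks = if (n_blanks > 0) paste0("B_r", seq_len(n_blanks))
             else character(0))
}

# one-row-per-feature table; `intensities` is a list of named vectors
make_features <- function(mz, rt, polarity, intensities, design) {
  reps <- design$replicate_id
  rows <- lapply(seq_along(mz), function(i) {
    v <- stats::setNames(rep(0, length(reps)), reps)
    v[names(intensities[[i]])] <- intensities[[i]]
    as.data.frame(c(list(feature_id = sprintf("F%03d", i), mz = mz[i],
                         rt = rt[i], polarity = polarity[i]), as.list(v)))
  })
  do.call(rbind, rows)
}

# brute-force filter predicates, straight from the definitions
oracle_pass_intensity <- function(vals, threshold) max(vals, na.rm = TRUE) >= threshold

oracle_pass_rsd <- function(by_sample, max_rsd) {
  any(vapply(by_sample, function(v) {
    if (any(is.na(v)) || any(v <= 0)) return(FALSE)
    100 * stats::sd(v) / mean(v) <= max_rsd
  }, logical(1)))
}

oracle_pass_blank <- function(by_sample, blanks, factor) {
  best <- max(vapply(by_sample, mean, numeric(1)))
  best > factor * mean(blanks)
}

# all-pairs suspect matching
oracle_match <- function(feature_mz, candidate_mz, tol_mda) {
  hits <- list()
  for (i in seq_along(feature_mz)) for (j in seq_along(candidate_mz))
    if (abs(feature_mz[i] - candidate_mz[j]) <= tol_mda / 1000)
      hits[[length(hits) + 1]] <- c(i, j)
  if (length(hits) == 0) matrix(integer(0), ncol = 2)
  else do.call(rbind, hits)
}

# exact set-algebra Tanimoto
oracle_tanimoto <- function(a, b) {
  on_a <- which(a == 1); on_b <- which(b == 1)
  u <- union(on_a, on_b)
  if (length(u) == 0) return(1)
  length(intersect(on_a, on_b)) / length(u)
}

# cosine for spectra whose peaks pair one-to-one by proximity (peaks
# separated by more than the tolerance, so the optimal assignment is the
# unique feasible one)
oracle_cosine_separated <- function(pa, pb, tol) {
  dot <- 0
  for (i in seq_len(nrow(pa))) {
    j <- which(abs(pb[, 1] - pa[i, 1]) <= tol)
    if (length(j) == 1) dot <- dot + pa[i, 2] * pb[j, 2]
  }
  unname(dot / sqrt(sum(pa[, 2]^2) * sum(pb[, 2]^2)))
}

# spectra with prescribed peak sets, mutually separated by > 0.05 Da;
# `offset` interleaves the m/z grids of two spectra so that cross-spectrum
# pairings within tolerance are unique by construction
random_separated_peaks <- function(n, offset = 0) {
  mz <- sort(sample(seq(50, 500, by = 0.5), n)) + offset
  cbind(mz = mz, intensity = stats::runif(n, 1, 100))
}

noise_free_config <- function(...) {
  defaults <- list(intensity_sigma = 0, sample_sigma = 0,
                   calib_noise_sigma = 0, rti_jitter_sd = 0,
                   mz_error_sd_mda = 0, log_ie_noise_sd = 0)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
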