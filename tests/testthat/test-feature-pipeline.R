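# Filter cascade: per-stage predicates against hand computations and a
# brute-force oracle; stage order, subset monotonicity, determinism.

design2 <- make_design(n_samples = 2, n_replicates = 3, n_blanks = 2)

test_that("intensity threshold is inclusive and polarity-specific", {
  f <- make_features(
    mz = c(200, 201, 202, 203), rt = c(100, 100, 100, 100),
    polarity = c("positive", "positive", "negative", "negative"),
    intensities = list(c(S1_r1 = 100000), c(S1_r1 = 99999),
                       c(S1_r1 = 60000), c(S1_r1 = 49999)),
    design = design2)
  out <- filter_intensity(f, design2)
  expect_identical(out$feature_id, c("F001", "F003"))
  expect_error(filter_intensity(transform(f, polarity = "both"), design2),
               "polarity")
})

test_that("replicate RSD uses the sample sd and any-sample survival", {
  v1 <- c(S1_r1 = 100000, S1_r2 = 150000, S1_r3 = 200000)   # RSD 33.3%
  v2 <- c(S1_r1 = 100000, S1_r2 = 300000, S1_r3 = 800000)   # RSD 90.1%
  expect_equal(100 * sd(v1) / mean(v1), 33.3, tolerance = 0.05)
  expect_equal(100 * sd(v2) / mean(v2), 90.1, tolerance = 0.05)
  v3 <- c(S1_r1 = 5e5, S1_r2 = 5e5, S1_r3 = 5e5)            # RSD 0
  v4 <- c(S1_r1 = 9e5, S1_r2 = 9e5,                          # missing in r3
          S2_r1 = 2e5, S2_r2 = 2.1e5, S2_r3 = 1.9e5)         # but S2 clean
  f <- make_features(rep(200, 4), rep(100, 4), rep("positive", 4),
                     list(v1, v2, v3, v4), design2)
  out <- filter_replicate_rsd(f, design2)
  expect_identical(out$feature_id, c("F001", "F003", "F004"))
  bad_design <- experiment_design(list(S1 = "S1_r1"))
  expect_error(filter_replicate_rsd(f[0, names(f) %in% c(
    "feature_id", "mz", "rt", "polarity", "S1_r1")], bad_design),
    "2 replicates")
})

test_that("blank ratio is strict and zero-blank features survive", {
  mk <- function(sample_mean, blank_mean)
    c(S1_r1 = sample_mean, S1_r2 = sample_mean, S1_r3 = sample_mean,
      B_r1 = blank_mean, B_r2 = blank_mean)
  f <- make_features(rep(200, 3), rep(100, 3), rep("positive", 3),
                     list(mk(301000, 100000), mk(300000, 100000),
                          mk(1, 0)), design2)
  out <- filter_blank_ratio(f, design2)
  expect_identical(out$feature_id, c("F001", "F003"))
  d0 <- make_design(n_blanks = 0)
  f0 <- make_features(200, 100, "positive",
                      list(c(S1_r1 = 3e5, S1_r2 = 3e5, S1_r3 = 3e5)), d0)
  expect_warning(out0 <- filter_blank_ratio(f0, d0), "no blanks")
  expect_equal(nrow(out0), 1)
})

test_that("peak-quality heuristic separates Gaussian peaks from spikes", {
  tt <- seq(-10, 10, length.out = 20)
  gaussian <- data.frame(t = tt, i = exp(-tt^2 / 18) * 1e5)
  spike <- data.frame(t = c(0, 1), i = c(1e5, 1))
  flat0 <- data.frame(t = tt, i = rep(0, 20))
  bimodal <- data.frame(t = tt, i = 1e5 * (exp(-(tt - 5)^2) + exp(-(tt + 5)^2)))
  f <- data.frame(feature_id = "F1", mz = 200, rt = 0, polarity = "positive")
  expect_identical(classify_peak_quality(f, gaussian), "high")
  expect_identical(classify_peak_quality(f, spike), "low")
  expect_identical(classify_peak_quality(f, flat0), "low")
  expect_identical(classify_peak_quality(f, bimodal), "low")
  expect_warning(lbl <- classify_peak_quality(f, NULL), "no EIC")
  expect_identical(lbl, "high")
  expect_error(classify_peak_quality(f, gaussian,
                                     classifier = function(...) stop("boom")),
               "F1")
})

test_that("componentization drops co-eluting adducts/isotopes, keeps others", {
  base <- c(S1_r1 = 5e5, S1_r2 = 5e5, S1_r3 = 5e5)
  f <- make_features(
    mz = c(300.1000, 300.1000 + 21.981944,   # sodiated pair, co-eluting
           400.2000, 400.2000 + 1.003355,    # isotope pair, co-eluting
           500.3000, 500.3000 + 21.981944),  # delta matches but far in rt
    rt = c(100, 101, 200, 200.5, 300, 350),
    polarity = rep("positive", 6),
    intensities = rep(list(base), 6), design = design2)
  out <- componentize(f)
  expect_identical(out$feature_id, c("F001", "F003", "F005", "F006"))
  # isolated feature is kept
  expect_equal(nrow(componentize(f[5, , drop = FALSE])), 1)
})

test_that("MS2 assembly windows, normalization and pruning behave", {
  feat <- data.frame(feature_id = "F1", mz = 300, rt = 500,
                     polarity = "positive")
  sp <- function(dmz, drt, peaks, ce = 30)
    ms2_spectrum(300 + dmz, 500 + drt, ce, peaks)
  # one spectrum: relative 100/50/4 -> sub-5% fragment pruned
  m <- assemble_ms2(feat, list(sp(0, 0, cbind(c(100, 150, 200),
                                              c(1000, 500, 40)))))
  expect_equal(nrow(m$peaks), 2)
  expect_equal(m$peaks[, "intensity"], c(100, 50), ignore_attr = TRUE)
  # precursor offset beyond the half-window excludes the spectrum
  expect_null(assemble_ms2(feat, list(sp(0.21, 0, cbind(100, 10)))))
  expect_null(assemble_ms2(feat, list(sp(0, 2.6, cbind(100, 10)))))
  # fragment at relative 8 in one energy and 1 in the other: mean 4.5 -> pruned
  m <- assemble_ms2(feat, list(
    sp(0, 0, cbind(c(100, 120), c(1000, 80)), ce = 30),
    sp(0, 0, cbind(c(100, 120), c(1000, 10)), ce = 70)))
  expect_equal(nrow(m$peaks), 1)
  expect_equal(m$peaks[1, "mz"], 100, ignore_attr = TRUE)
})

test_that("cascade matches a brute-force oracle and is monotone/ordered", {
  set.seed(11)
  b <- simulate_experiment(synthetic_config(n_spiked_chemicals = 20,
                                            n_noise_features = 16,
                                            n_background_features = 10),
                           seed = 101)
  res <- run_cascade(b$features, b$design, spectra = b$spectra,
                     eics = b$eics)
  # oracle: apply each predicate independently with plain loops
  design <- b$design
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  blanks <- design$replicate_id[design$is_blank]
  surv <- b$features$feature_id
  tabm <- as.matrix(b$features[, design$replicate_id])
  rownames(tabm) <- b$features$feature_id
  thr <- c(positive = 1e5, negative = 5e4)[b$features$polarity]
  names(thr) <- b$features$feature_id
  surv <- surv[vapply(surv, function(id)
    oracle_pass_intensity(tabm[id, ], thr[[id]]), logical(1))]
  surv <- surv[vapply(surv, function(id)
    oracle_pass_rsd(lapply(rep_of, function(r) tabm[id, r]), 50),
    logical(1))]
  surv <- surv[vapply(surv, function(id)
    oracle_pass_blank(lapply(rep_of, function(r) tabm[id, r]),
                      tabm[id, blanks], 3), logical(1))]
  surv <- surv[vapply(surv, function(id)
    default_peak_classifier(NULL, b$eics[[id]]) == "high", logical(1))]
  # componentization oracle: drop any feature that co-elutes above a lighter
  # one at a known delta
  deltas <- adduct_deltas()
  keep <- surv
  for (id in surv) {
    i <- match(id, b$features$feature_id)
    for (id2 in surv) {
      j <- match(id2, b$features$feature_id)
      if (b$features$polarity[i] != b$features$polarity[j]) next
      d <- b$features$mz[i] - b$features$mz[j]
      if (d > 0 && abs(b$features$rt[i] - b$features$rt[j]) <= 5 &&
          any(abs(d - deltas) <= 0.002))
        keep <- setdiff(keep, id)
    }
  }
  expect_setequal(res$features$feature_id, keep)

  # monotone subset per stage, in the documented order
  expect_identical(res$trace$stage,
                   c("intensity", "replicate_rsd", "blank_ratio",
                     "peak_quality", "componentize", "ms2_assembly"))
  expect_true(all(res$trace$features_out <= res$trace$features_in))
  expect_true(all(diff(res$trace$features_in) <= 0))

  # determinism
  res2 <- run_cascade(b$features, b$design, spectra = b$spectra,
                      eics = b$eics)
  expect_identical(res, res2)
})

test_that("empty and all-pass inputs traverse the cascade unchanged", {
  b <- simulate_experiment(noise_free_config(n_spiked_chemicals = 6,
                                             n_noise_features = 0,
                                             n_background_features = 0,
                                             n_adduct_satellites = 0),
                           seed = 5)
  res <- run_cascade(b$features, b$design, eics = b$eics)
  expect_identical(res$features$feature_id, b$features$feature_id)

  empty <- b$features[0, , drop = FALSE]
  res0 <- run_cascade(empty, b$design)
  expect_equal(nrow(res0$features), 0)
  expect_true(all(res0$trace$features_in == 0) &&
                all(res0$trace$features_out == 0))
})

test_that("synthetic filter fates are realised stage by stage", {
  b <- simulate_experiment(noise_free_config(), seed = 31)
  res <- run_cascade(b$features, b$design, spectra = b$spectra,
                     eics = b$eics)
  fate <- b$truth$fate[match(b$features$feature_id, b$truth$feature_id)]
  expect_setequal(res$features$feature_id,
                  b$truth$feature_id[b$truth$fate == "pass"])
  # per-stage counts equal the constructed fates
  n <- table(fate)
  tr <- res$trace
  expect_equal(tr$features_in[1] - tr$features_out[1],
               unname(n["fail_intensity"]))
  expect_equal(tr$features_in[2] - tr$features_out[2], unname(n["fail_rsd"]))
  expect_equal(tr$features_in[3] - tr$features_out[3],
               unname(n["fail_blank"]))
  expect_equal(tr$features_in[4] - tr$features_out[4],
               unname(n["fail_quality"]))
  expect_equal(tr$features_in[5] - tr$features_out[5],
               unname(n["drop_adduct"]))
})
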