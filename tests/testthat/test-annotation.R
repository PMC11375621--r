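# Spectral cosine, Tanimoto, library matching and the consensus rules.

test_that("cosine score: identity, disjoint sets, hand computation", {
  a <- ms2_spectrum(300, 100, 30, cbind(c(100, 200), c(100, 50)))
  b <- ms2_spectrum(300, 100, 30, cbind(c(100, 300), c(50, 100)))
  d <- ms2_spectrum(300, 100, 30, cbind(c(150, 250), c(80, 20)))
  expect_equal(cosine_score(a, a), 1)
  expect_equal(cosine_score(a, d), 0)
  # single shared fragment: 100*50 / sqrt((100^2+50^2) * (50^2+100^2)) = 0.4
  expect_equal(cosine_score(a, b), 0.4, tolerance = 1e-12)
  expect_equal(cosine_score(a, b), cosine_score(b, a))
  expect_error(cosine_score(a, ms2_spectrum(300, 100, 30,
                                            matrix(numeric(0), ncol = 2))),
               "non-empty")
})

test_that("cosine equals the assignment oracle on separated-peak spectra", {
  set.seed(21)
  for (k in 1:30) {
    pa <- random_separated_peaks(sample(2:6, 1))
    pb <- random_separated_peaks(sample(2:6, 1), offset = 0.25)
    # overlap some peaks exactly (within tolerance, unique pairing)
    n_shared <- sample(0:2, 1)
    if (n_shared > 0 && nrow(pb) >= n_shared)
      pb[seq_len(n_shared), 1] <- pa[seq_len(n_shared), 1] + 0.002
    pb <- pb[order(pb[, 1]), , drop = FALSE]
    sa <- ms2_spectrum(600, 100, 30, pa)
    sb <- ms2_spectrum(600, 100, 30, pb)
    got <- cosine_score(sa, sb)
    want <- oracle_cosine_separated(sa$peaks, sb$peaks, 5e-3)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)
    expect_equal(got, cosine_score(sb, sa), tolerance = 1e-12)
  }
})

test_that("library matching gates at the cosine threshold and ranks ties", {
  q <- ms2_spectrum(300, 100, 30, cbind(c(100, 150, 200), c(100, 60, 30)))
  lib <- list(
    list(structure_id = "self", spectrum = q),
    list(structure_id = "far",
         spectrum = ms2_spectrum(300, 100, 30, cbind(c(111, 222), c(50, 50)))),
    list(structure_id = "near",
         spectrum = ms2_spectrum(300, 100, 30,
                                 cbind(c(100, 150, 240), c(100, 60, 30)))))
  out <- library_match(q, lib)
  expect_identical(out$structure_id[1], "self")
  expect_equal(out$cosine[1], 1)
  expect_false("far" %in% out$structure_id)
  expect_true(all(diff(out$cosine) <= 0))
  none <- library_match(q, lib[2])
  expect_equal(nrow(none), 0)
})

test_that("tanimoto matches the set-algebra oracle", {
  expect_equal(tanimoto("1100", "1010"), 1 / 3)
  expect_equal(tanimoto("1111", "1111"), 1)
  expect_equal(tanimoto("1100", "0011"), 0)
  expect_equal(tanimoto("0000", "0000"), 1)
  expect_error(tanimoto("110", "1100"), "length mismatch")
  set.seed(8)
  for (k in 1:40) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("consensus clauses fire in order with correct levels", {
  cfg <- pipeline_config()
  lib_cand <- data.frame(source = "library", structure_id = "X",
                         score = 0.89, matched_peaks = 5L,
                         fingerprint = NA_character_)
  silico <- data.frame(source = c("silico_forward", "silico_inverse"),
                       structure_id = c("Y", "Y2"), score = c(0.9, 0.8),
                       matched_peaks = 4L,
                       fingerprint = c("11110000", "11100000"))  # tanimoto 0.75
  silico_agree <- transform(silico, fingerprint = c("11110000", "11110001"))
  # 4/5 shared of 5 union = 0.8 -> not > 0.8; make it 1.0
  silico_agree$fingerprint <- c("11110000", "11110000")
  frm <- data.frame(source = "formula_only", structure_id = "C6H6O",
                    score = 1, matched_peaks = 0L,
                    fingerprint = NA_character_)

  a <- consensus_annotate("F1", rbind(lib_cand, silico_agree, frm), cfg)
  expect_identical(a$level, "2b"); expect_identical(a$structure_id, "X")

  a <- consensus_annotate("F2", rbind(silico_agree, frm), cfg)
  expect_identical(a$level, "3"); expect_identical(a$structure_id, "Y")

  # fingerprint disagreement (or Tanimoto exactly at the gate) drops to formula
  a <- consensus_annotate("F3", rbind(silico, frm), cfg)
  expect_identical(a$level, "4"); expect_identical(a$structure_id, "C6H6O")

  a <- consensus_annotate("F4", frm, cfg)
  expect_identical(a$level, "4")

  a <- consensus_annotate("F5", NULL, cfg)
  expect_identical(a$level, "5"); expect_true(is.na(a$structure_id))

  # matched-peak gate is strict: exactly 2 matched peaks is not enough
  weak_lib <- transform(lib_cand, matched_peaks = 2L)
  a <- consensus_annotate("F6", weak_lib, cfg)
  expect_identical(a$level, "5")

  # level 1 is never emitted
  for (cand in list(rbind(lib_cand, silico_agree, frm), lib_cand, frm))
    expect_true(consensus_annotate("F", cand, cfg)$level %in%
                  c("2b", "3", "4", "5"))
})

test_that("adding a passing library candidate never lowers confidence", {
  cfg <- pipeline_config()
  lib_cand <- data.frame(source = "library", structure_id = "L",
                         score = 0.9, matched_peaks = 6L,
                         fingerprint = NA_character_)
  rank_of <- c("5" = 0, "4" = 1, "3" = 2, "2b" = 3)
  base_sets <- list(
    NULL,
    data.frame(source = "formula_only", structure_id = "CH4O", score = 1,
               matched_peaks = 0L, fingerprint = NA_character_),
    data.frame(source = c("silico_forward", "silico_inverse"),
               structure_id = "Z", score = c(1, 1), matched_peaks = 5L,
               fingerprint = "1111"))
  for (cand in base_sets) {
    before <- consensus_annotate("F", cand, cfg)$level
    after <- consensus_annotate("F", rbind(cand, lib_cand), cfg)$level
    expect_gte(rank_of[[after]], rank_of[[before]])
  }
})

test_that("synthetic candidate sets annotate to their constructed levels", {
  b <- simulate_experiment(noise_free_config(), seed = 23)
  ann <- annotate_features(b$candidates)
  intended <- b$truth$intended_level[match(ann$feature_id,
                                           b$truth$feature_id)]
  expect_identical(ann$level, intended)
  # structures correct wherever a structure is claimed at 2b/3
  claimed <- ann$level %in% c("2b", "3")
  expect_identical(ann$structure_id[claimed],
                   b$truth$true_structure[match(ann$feature_id,
                                                b$truth$feature_id)][claimed])
})
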