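# Seeded synthetic-experiment generator.
#
# Produces a complete, truth-labeled screening experiment — feature tables
# with replicate/blank structure, MS2 spectra at three collision energies, a
# spectral library, a suspect list with retention-time indices, calibration
# curves, and per-feature annotation candidate sets — so that every pipeline
# stage can be exercised end to end with known ground truth and no
# instrument data. One root seed is split into independent per-component
# streams, so adding a component never perturbs the draws of another.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic experiment configuration
#'
#' Defaults emulate the study design the package targets: 13 textile-extract
#' samples in triplicate plus triplicate method blanks, 38 spiked QC
#' chemicals, and a ten-level calibration series from 1 to 1000 ng/mL.
#' Electrospray response is log-linear in predicted ionization efficiency;
#' retention time derives from a latent hydrophobicity scale; the RTI slope
#' (0.4666 RTI/s) reproduces the conventional correspondence of a 120 s
#' retention-time window to about 56 RTI units.
#'
#' @param n_samples,n_replicates,n_blanks Experiment layout.
#' @param n_spiked_chemicals Number of spiked (truth-known) chemicals.
#' @param n_noise_features Features constructed to fail specific filters,
#'   split according to `fail_fractions` (intensity, rsd, blank, quality).
#' @param n_background_features Unknown features that pass every filter.
#' @param n_adduct_satellites Sodiated satellites of spiked features,
#'   removed at componentization.
#' @param calib_levels Calibration concentrations, ng/mL.
#' @param intensity_sigma Log-normal replicate noise (sd on the log scale).
#' @param sample_sigma Log-normal between-sample intensity variation.
#' @param blank_carryover Blank intensity as a fraction of the feature's
#'   area, for features designed to fail the blank-ratio filter.
#' @param detect_prob Per-sample presence probability of a spiked chemical.
#' @param log_ie_mean,log_ie_sd Predicted log-ionization-efficiency
#'   distribution.
#' @param ie_slope,ie_intercept Generative response model:
#'   `rf = 10^(ie_slope * log_ie + ie_intercept)` (area per uM).
#' @param log_ie_noise_sd Error added to the *predicted* log IE handed to
#'   the quantification step (0 = oracle predictor).
#' @param lc50_meanlog,lc50_sdlog Log-normal LC50 distribution, mM.
#' @param conc_range True extract concentration range, mM (log-uniform).
#' @param rti_slope,rti_intercept,rti_jitter_sd RTI mapping
#'   `rti = slope * rt + intercept + N(0, jitter)`.
#' @param mz_error_sd_mda Gaussian m/z measurement error, mDa.
#' @param frac_suspects Fraction of spiked chemicals present on the suspect
#'   list.
#' @param n_decoy_suspects Suspect-list entries matching no feature.
#' @param level_fractions Intended consensus outcomes for spiked chemicals
#'   (named: `"2b"`, `"3"`, `"4"`, `"5"`).
#' @param fail_fractions Split of `n_noise_features` over intended filter
#'   fates (named: intensity, rsd, blank, quality).
#' @param n_fragments Fragments per chemical's MS2 fingerprint.
#' @param frac_positive Fraction of chemicals ionizing in positive mode.
#' @param calib_dropout_n Chemicals whose calibration curve is truncated to
#'   4 detected levels (exercises the minimum-level rejection).
#' @param calib_noise_sigma Log-normal noise on calibration areas.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 13, n_replicates = 3, n_blanks = 3,
                             n_spiked_chemicals = 38,
                             n_noise_features = 20,
                             n_background_features = 15,
                             n_adduct_satellites = 5,
                             calib_levels = 10^seq(0, 3, length.out = 10),
                             intensity_sigma = 0.2,
                             sample_sigma = 0.1,
                             blank_carryover = 0.5,
                             detect_prob = 0.6,
                             log_ie_mean = 3, log_ie_sd = 1,
                             ie_slope = 0.9, ie_intercept = 2,
                             log_ie_noise_sd = 0,
                             lc50_meanlog = log(0.3), lc50_sdlog = 1,
                             conc_range = c(0.001, 1),
                             rti_slope = 0.4666, rti_intercept = 0,
                             rti_jitter_sd = 20,
                             mz_error_sd_mda = 0.3,
                             frac_suspects = 0.6,
                             n_decoy_suspects = 10,
                             level_fractions = c("2b" = 0.4, "3" = 0.4,
                                                 "4" = 0.1, "5" = 0.1),
                             fail_fractions = c(intensity = 0.25, rsd = 0.25,
                                                blank = 0.25, quality = 0.25),
                             n_fragments = 6,
                             frac_positive = 0.75,
                             calib_dropout_n = 3,
                             calib_noise_sigma = 0.02) {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 1, n_replicates >= 2, n_blanks >= 0,
            all(cfg$calib_levels > 0),
            all(fail_fractions >= 0), all(fail_fractions <= 1),
            abs(sum(level_fractions) - 1) < 1e-9,
            frac_suspects >= 0, frac_suspects <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# ---- internal generators ----------------------------------------------------

# random supported-element formula with neutral mass in [110, 1400] Da
.random_formula <- function() {
  repeat {
    nC <- sample(6:30, 1)
    counts <- c(C = nC, H = nC + sample(0:nC, 1))
    if (stats::runif(1) < 0.6) counts["O"] <- sample(1:5, 1)
    if (stats::runif(1) < 0.4) counts["N"] <- sample(1:3, 1)
    if (stats::runif(1) < 0.15) counts["S"] <- 1
    if (stats::runif(1) < 0.1) counts["Cl"] <- sample(1:2, 1)
    f <- structure(as.integer(counts), names = names(counts),
                   class = "molformula")
    m <- monoisotopic_mass(f)
    if (m >= 110 && m <= 1400) return(f)
  }
}

# deterministic per-chemical fragment profile: m/z below the precursor,
# mutually separated by > 0.1 Da, relative intensities including one sub-5%
# peak to exercise pruning
.fragment_profile <- function(precursor_mz, n_fragments, frag_seed) {
  with_seed(frag_seed, {
    lo <- 50
    hi <- max(precursor_mz - 20, lo + 10)
    repeat {
      mzs <- sort(stats::runif(n_fragments, lo, hi))
      if (all(diff(mzs) > 0.1)) break
    }
    rel <- c(100, stats::runif(n_fragments - 2, 10, 90), 3)
    # per-fragment smooth energy response: linear trend in collision energy
    trend <- stats::runif(n_fragments, -0.006, 0.006)
    list(mz = mzs, rel = rel, trend = trend)
  })
}

#' Simulate MS2 spectra for one chemical
#'
#' Generates one spectrum per collision energy from the chemical's fragment
#' profile. Fragment m/z values sit below the precursor; intensities vary
#' smoothly (linearly) with collision energy; a sub-5% fragment is always
#' included so that relative-intensity pruning is exercised.
#'
#' @param chemical One row of a bundle's `chemicals` table (uses `mz_true`,
#'   `rt`, `fragment_seed`, `n_fragments`).
#' @param energies Collision energies, volts.
#' @param seed Optional seed overriding the chemical's `fragment_seed`.
#' @return List of [ms2_spectrum()] objects, one per energy.
#' @export
simulate_spectra <- function(chemical, energies = c(30, 70, 120),
                             seed = NULL) {
  fs <- if (!is.null(seed)) seed else chemical$fragment_seed
  prof <- .fragment_profile(chemical$mz_true, chemical$n_fragments, fs)
  lapply(energies, function(ce) {
    inten <- prof$rel * pmax(0.05, 1 + prof$trend * (ce - 70))
    ms2_spectrum(chemical$mz_true, chemical$rt, ce,
                 cbind(mz = prof$mz, intensity = inten))
  })
}

# reference library entry: collision-energy-averaged relative profile,
# computed with the same merging rule as assemble_ms2()
.library_spectrum <- function(chemical, energies = c(30, 70, 120),
                              min_rel_intensity = 5) {
  sp <- simulate_spectra(chemical, energies)
  fake_feat <- data.frame(feature_id = chemical$chemical_id,
                          mz = chemical$mz_true, rt = chemical$rt,
                          polarity = chemical$polarity)
  assemble_ms2(fake_feat, sp, precursor_window = 0.4, rt_window = 5,
               min_rel_intensity = min_rel_intensity)
}

.random_fingerprint <- function(n_bits = 256, n_on = 64) {
  bits <- rep(0L, n_bits)
  bits[sample.int(n_bits, n_on)] <- 1L
  paste(bits, collapse = "")
}

.counts_from_fractions <- function(n, fractions) {
  k <- floor(n * fractions)
  rem <- n - sum(k)
  if (rem > 0) {
    frac_part <- n * fractions - k
    add <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  k
}

# ---- main generator ---------------------------------------------------------

#' Simulate a complete truth-labeled screening experiment
#'
#' @param config A [synthetic_config()].
#' @param seed Integer root seed; identical config + seed give identical
#'   bundles.
#' @return A `truth_bundle` list: `design`, `chemicals` (with true
#'   concentration, LC50, log IE, RTI, fingerprint, intended annotation
#'   level and suspect membership), `features` (feature table), `truth`
#'   (per-feature labels: chemical, intended filter fate, true concentration
#'   and structure), `spectra`, `eics`, `library`, `suspects`, `calibration`
#'   (curves and true response factors) and `candidates` (per-feature
#'   annotation candidate sets).
#' @export
simulate_experiment <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n_susp <- round(config$frac_suspects * config$n_spiked_chemicals)
  if (n_susp > config$n_spiked_chemicals)
    stop("more suspect-list chemicals requested than spiked chemicals")

  design <- experiment_design(
    samples = stats::setNames(lapply(seq_len(config$n_samples), function(s)
      paste0("S", s, "_r", seq_len(config$n_replicates))),
      paste0("S", seq_len(config$n_samples))),
    blanks = if (config$n_blanks > 0) paste0("B_r", seq_len(config$n_blanks))
             else character(0))

  chemicals <- with_seed(seed + 11L, .gen_chemicals(config, seed))
  features <- with_seed(seed + 22L, .gen_features(config, chemicals, design))
  truth <- features$truth
  tab <- features$table
  eics <- with_seed(seed + 33L, .gen_eics(tab, truth))

  spectra <- list()
  for (i in which(truth$fate == "pass" & !is.na(truth$chemical_id))) {
    chem <- chemicals[chemicals$chemical_id == truth$chemical_id[i], ]
    sp <- simulate_spectra(chem)
    # spectra are acquired at the measured feature coordinates
    sp <- lapply(sp, function(s) {
      s$precursor_mz <- tab$mz[i]; s$rt <- tab$rt[i]; s
    })
    spectra <- c(spectra, sp)
  }

  lib <- lapply(which(chemicals$intended_level == "2b"), function(k) {
    list(structure_id = chemicals$chemical_id[k],
         spectrum = .library_spectrum(chemicals[k, ]))
  })

  suspects <- with_seed(seed + 44L, .gen_suspects(config, chemicals))
  calibration <- simulate_calibration(config, seed + 55L,
                                      chemicals = chemicals)
  candidates <- with_seed(seed + 66L,
                          .gen_candidates(config, chemicals, tab, truth, lib))

  structure(list(config = config, seed = seed, design = design,
                 chemicals = chemicals, features = tab, truth = truth,
                 spectra = spectra, eics = eics, library = lib,
                 suspects = suspects, calibration = calibration,
                 candidates = candidates),
            class = "truth_bundle")
}

.gen_chemicals <- function(config, seed) {
  n <- config$n_spiked_chemicals
  forms <- replicate(n, .random_formula(), simplify = FALSE)
  mass <- vapply(forms, monoisotopic_mass, numeric(1))
  n_pos <- round(config$frac_positive * n)
  polarity <- c(rep("positive", n_pos), rep("negative", n - n_pos))
  adduct <- ifelse(polarity == "positive", "[M+H]+", "[M-H]-")
  mz_true <- vapply(seq_len(n), function(i) adduct_mz(mass[i], adduct[i]),
                    numeric(1))
  # latent hydrophobicity -> retention time (seconds)
  hydro <- stats::rnorm(n)
  rt <- pmin(pmax(700 + 280 * hydro, 60), 1380)
  log_ie <- stats::rnorm(n, config$log_ie_mean, config$log_ie_sd)
  rf_true <- 10^(config$ie_slope * log_ie + config$ie_intercept)
  conc_mM <- exp(stats::runif(n, log(config$conc_range[1]),
                              log(config$conc_range[2])))
  lc50 <- stats::rlnorm(n, config$lc50_meanlog, config$lc50_sdlog)
  # ensure spiked features clear the intensity threshold: scale the true
  # concentration up where the generative area would sit below 2x threshold
  thr <- ifelse(polarity == "positive", 1e5, 5e4)
  area <- rf_true * conc_mM * 1000            # uM = mM * 1000
  low <- area < 2 * thr
  conc_mM[low] <- conc_mM[low] * (2 * thr[low] / area[low])
  area <- rf_true * conc_mM * 1000

  n_levels <- .counts_from_fractions(n, config$level_fractions)
  intended <- rep(names(config$level_fractions), n_levels)[sample.int(n)]
  fp <- replicate(n, .random_fingerprint())

  data.frame(chemical_id = sprintf("chem_%02d", seq_len(n)),
             formula = vapply(forms, format_formula, character(1)),
             exact_mass = mass, polarity = polarity, adduct = adduct,
             mz_true = mz_true, rt = rt,
             rti_true = config$rti_slope * rt + config$rti_intercept,
             log_ie = log_ie, rf_true = rf_true, conc_mM = conc_mM,
             area_true = area, lc50_mM = lc50,
             fingerprint = fp, intended_level = intended,
             fragment_seed = seed + 1000L + seq_len(n),
             n_fragments = config$n_fragments,
             stringsAsFactors = FALSE)
}

.gen_features <- function(config, chemicals, design) {
  samples <- .design_samples(design)
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  blank_reps <- design$replicate_id[design$is_blank]
  all_reps <- design$replicate_id
  rows <- list(); truth <- list()
  fid <- 0L
  add_feature <- function(mz, rt, polarity, intens, chemical_id, fate,
                          conc = NA_real_, structure = NA_character_,
                          level = NA_character_) {
    fid <<- fid + 1L
    id <- sprintf("F%04d", fid)
    r <- c(list(feature_id = id, mz = mz, rt = rt, polarity = polarity),
           as.list(intens[all_reps]))
    rows[[fid]] <<- as.data.frame(r, stringsAsFactors = FALSE)
    truth[[fid]] <<- data.frame(feature_id = id, chemical_id = chemical_id,
                                fate = fate, true_conc_mM = conc,
                                true_structure = structure,
                                intended_level = level,
                                stringsAsFactors = FALSE)
    id
  }
  zero <- stats::setNames(rep(0, length(all_reps)), all_reps)
  fill_samples <- function(area, det_samples, blank_frac = 0) {
    v <- zero
    for (s in det_samples) {
      s_eff <- exp(stats::rnorm(1, 0, config$sample_sigma))
      v[rep_of[[s]]] <- area * s_eff *
        exp(stats::rnorm(length(rep_of[[s]]), 0, config$intensity_sigma))
    }
    if (blank_frac > 0 && length(blank_reps) > 0)
      v[blank_reps] <- area * blank_frac
    v
  }
  mz_jitter <- function(mz) mz + stats::rnorm(1, 0, config$mz_error_sd_mda / 1000)

  # spiked chemicals: all pass the cascade by construction
  for (i in seq_len(nrow(chemicals))) {
    ch <- chemicals[i, ]
    n_det <- max(1, stats::rbinom(1, length(samples), config$detect_prob))
    det <- sample(samples, n_det)
    add_feature(mz_jitter(ch$mz_true), ch$rt, ch$polarity,
                fill_samples(ch$area_true, det),
                ch$chemical_id, "pass", ch$conc_mM, ch$chemical_id,
                ch$intended_level)
  }

  # sodiated satellites of the first positive-mode spiked features
  pos_idx <- which(chemicals$polarity == "positive")
  n_sat <- min(config$n_adduct_satellites, length(pos_idx))
  for (i in pos_idx[seq_len(n_sat)]) {
    ch <- chemicals[i, ]
    add_feature(ch$mz_true + 21.981944, ch$rt + stats::runif(1, -1, 1),
                "positive",
                fill_samples(max(0.4 * ch$area_true, 4e5), samples[1:2]),
                ch$chemical_id, "drop_adduct")
  }

  # noise features designed to fail one stage each
  k <- .counts_from_fractions(config$n_noise_features, config$fail_fractions)
  rand_mz <- function() stats::runif(1, 150, 900)
  rand_rt <- function() stats::runif(1, 60, 1380)
  for (j in seq_len(k[["intensity"]])) {
    thr <- 1e5
    add_feature(rand_mz(), rand_rt(), "positive",
                fill_samples(0.3 * thr, sample(samples, 2)),
                NA_character_, "fail_intensity")
  }
  for (j in seq_len(k[["rsd"]])) {
    v <- zero
    s <- sample(samples, 1)
    v[rep_of[[s]]] <- 3e5 * c(0.2, 1, 5)[seq_along(rep_of[[s]]) %% 3 + 1]
    add_feature(rand_mz(), rand_rt(), "positive", v, NA_character_,
                "fail_rsd")
  }
  for (j in seq_len(k[["blank"]])) {
    add_feature(rand_mz(), rand_rt(), "positive",
                fill_samples(5e5, sample(samples, 2),
                             blank_frac = config$blank_carryover),
                NA_character_, "fail_blank")
  }
  for (j in seq_len(k[["quality"]])) {
    add_feature(rand_mz(), rand_rt(), "positive",
                fill_samples(5e5, sample(samples, 2)),
                NA_character_, "fail_quality")
  }

  # background unknowns: pass everything, annotate as unknown
  for (j in seq_len(config$n_background_features)) {
    add_feature(rand_mz(), rand_rt(), "positive",
                fill_samples(6e5, sample(samples, max(1, stats::rbinom(
                  1, length(samples), config$detect_prob)))),
                NA_character_, "pass", level = "5")
  }

  tab <- do.call(rbind, rows)
  tru <- do.call(rbind, truth)
  # avoid accidental componentization: nudge co-eluting pairs whose m/z
  # difference falls near a known delta
  deltas <- adduct_deltas()
  repeat {
    moved <- FALSE
    for (a in seq_len(nrow(tab) - 1)) for (b in seq(a + 1, nrow(tab))) {
      if (tru$fate[b] == "drop_adduct" || tru$fate[a] == "drop_adduct") next
      if (tab$polarity[a] != tab$polarity[b]) next
      if (abs(tab$rt[a] - tab$rt[b]) > 6) next
      d <- abs(tab$mz[a] - tab$mz[b])
      if (any(abs(d - deltas) <= 0.003)) {
        tab$rt[b] <- tab$rt[b] + 20
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(table = tab, truth = tru)
}

.gen_eics <- function(tab, truth) {
  eics <- list()
  tt <- seq(-10, 10, length.out = 20)
  for (i in seq_len(nrow(tab))) {
    eics[[tab$feature_id[i]]] <- if (truth$fate[i] == "fail_quality") {
      data.frame(time = tab$rt[i] + c(0, 1), intensity = c(1e5, 9e4))
    } else {
      data.frame(time = tab$rt[i] + tt,
                 intensity = 1e5 * exp(-tt^2 / (2 * 3^2)) + 100)
    }
  }
  eics
}

.gen_suspects <- function(config, chemicals) {
  n_susp <- round(config$frac_suspects * nrow(chemicals))
  idx <- sort(sample.int(nrow(chemicals), n_susp))
  on_list <- chemicals[idx, ]
  susp <- data.frame(
    name = on_list$chemical_id,
    formula = on_list$formula,
    exact_mass = on_list$exact_mass,
    rti = on_list$rti_true + stats::rnorm(nrow(on_list), 0,
                                          config$rti_jitter_sd),
    exposure_score = sample.int(25, nrow(on_list), replace = TRUE),
    source = "SYN-LIST",
    stringsAsFactors = FALSE)
  # decoys far (>= 10 mDa in all adduct channels) from every spiked mass
  if (config$n_decoy_suspects > 0) {
    dec_mass <- numeric(0)
    while (length(dec_mass) < config$n_decoy_suspects) {
      m <- stats::runif(1, 120, 1300)
      if (min(abs(outer(m, chemicals$exact_mass, "-"))) > 0.05 &&
          min(abs(outer(m + 35.976678, chemicals$exact_mass, "-"))) > 0.05)
        dec_mass <- c(dec_mass, m)
    }
    susp <- rbind(susp, data.frame(
      name = sprintf("decoy_%02d", seq_along(dec_mass)),
      formula = NA_character_, exact_mass = dec_mass,
      rti = stats::runif(length(dec_mass), 0, 700),
      exposure_score = sample.int(25, length(dec_mass), replace = TRUE),
      source = "SYN-LIST", stringsAsFactors = FALSE))
  }
  attr(susp, "truth_members") <- chemicals$chemical_id[idx]
  susp
}

#' Simulate calibration curves with known response factors
#'
#' Per-chemical curves over `config$calib_levels`, with areas
#' `rf * conc_uM * exp(noise)`. A configurable number of chemicals have
#' their lowest levels undetected, leaving only 4 levels, to exercise the
#' minimum-level rejection rule downstream.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param chemicals Optional chemicals table (from a bundle); generated
#'   fresh when `NULL`.
#' @return List with `curves` (named list of data.frames `conc_ng_ml`,
#'   `area`), `chemicals` and `true_rf` (named vector, area per uM).
#' @export
simulate_calibration <- function(config = synthetic_config(), seed = 1,
                                 chemicals = NULL) {
  if (is.null(chemicals))
    chemicals <- with_seed(seed + 11L, .gen_chemicals(config, seed))
  with_seed(seed + 7L, {
    dropout <- utils::head(chemicals$chemical_id, config$calib_dropout_n)
    curves <- lapply(seq_len(nrow(chemicals)), function(i) {
      ch <- chemicals[i, ]
      conc_um <- ng_ml_to_um(config$calib_levels, ch$exact_mass)
      area <- ch$rf_true * conc_um *
        exp(stats::rnorm(length(conc_um), 0, config$calib_noise_sigma))
      if (ch$chemical_id %in% dropout)
        area[seq_len(length(area) - 4)] <- NA
      data.frame(conc_ng_ml = config$calib_levels, area = area)
    })
    names(curves) <- chemicals$chemical_id
    list(curves = curves, chemicals = chemicals,
         true_rf = stats::setNames(chemicals$rf_true,
                                   chemicals$chemical_id))
  })
}

.gen_candidates <- function(config, chemicals, tab, truth, lib) {
  cand <- list()
  decoy_fp <- function() .random_fingerprint()
  for (i in seq_len(nrow(tab))) {
    fid <- tab$feature_id[i]
    chem_id <- truth$chemical_id[i]
    if (truth$fate[i] != "pass" || is.na(chem_id)) {
      if (truth$fate[i] == "pass") cand[[fid]] <- .empty_candidates()
      next
    }
    ch <- chemicals[chemicals$chemical_id == chem_id, ]
    lvl <- ch$intended_level
    rows <- .empty_candidates()
    if (lvl == "2b") {
      # the engine's library score is the cosine; identical profiles -> 1
      rows <- rbind(rows, data.frame(
        source = "library", structure_id = chem_id, score = 1,
        matched_peaks = config$n_fragments - 1L,  # sub-5% peak pruned
        fingerprint = ch$fingerprint, stringsAsFactors = FALSE))
    }
    if (lvl %in% c("2b", "3")) {
      rows <- rbind(rows, data.frame(
        source = c("silico_forward", "silico_inverse"),
        structure_id = chem_id, score = c(0.9, 0.85),
        matched_peaks = config$n_fragments - 1L,
        fingerprint = ch$fingerprint, stringsAsFactors = FALSE))
      # trailing decoys, lower scores, dissimilar fingerprints
      rows <- rbind(rows, data.frame(
        source = c("silico_forward", "silico_inverse"),
        structure_id = paste0(chem_id, "_decoy"), score = c(0.4, 0.3),
        matched_peaks = 2L,
        fingerprint = c(decoy_fp(), decoy_fp()), stringsAsFactors = FALSE))
    }
    if (lvl == "4") {
      rows <- rbind(rows, data.frame(
        source = "formula_only", structure_id = ch$formula, score = 1,
        matched_peaks = 0L, fingerprint = NA_character_,
        stringsAsFactors = FALSE))
    }
    cand[[fid]] <- rows
  }
  cand
}

.empty_candidates <- function() {
  data.frame(source = character(0), structure_id = character(0),
             score = numeric(0), matched_peaks = integer(0),
             fingerprint = character(0), stringsAsFactors = FALSE)
}

#' Best-sample mean areas for quantification
#'
#' The integrated area handed to quantification is the mean intensity over
#' the replicates of the feature's highest-mean sample — the same statistic
#' the blank-ratio filter uses.
#'
#' @param features Feature table.
#' @param design An [experiment_design()].
#' @return Named numeric vector (feature id -> area).
#' @export
feature_areas <- function(features, design) {
  .check_features(features, design)
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  m <- .intensity_matrix(features, design$replicate_id)
  out <- vapply(seq_len(nrow(features)), function(i)
    max(vapply(rep_of, function(r) mean(m[i, r]), numeric(1))), numeric(1))
  stats::setNames(out, features$feature_id)
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf(paste0("<truth_bundle> seed %d: %d features (%d spiked",
                     " chemicals), %d samples x %d replicates + %d blanks\n"),
              x$seed, nrow(x$features), nrow(x$chemicals),
              x$config$n_samples, x$config$n_replicates, x$config$n_blanks))
  invisible(x)
}
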