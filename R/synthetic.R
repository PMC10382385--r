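# Synthetic datasets with known ground truth. The generator emulates an
# ESI+ LC-MS/MS run over a small metabolome: per compound a handful of
# adduct features with ppm-perturbed m/z, an M+1 isotopologue, correlated
# per-sample intensities, optional MS2 spectra, plus decoy database entries
# competing within a few ppm and a random biochemical network over the true
# compounds.

#' First-order M+1/M+0 abundance ratio of a formula
#'
#' Closed form `sum over elements of n_e * a1_e / a0_e`, where `a0` is the
#' principal isotope abundance and `a1` the abundance of the isotope one
#' nominal mass unit heavier (zero when the element has none, e.g. Cl).
#' This is exactly the ratio of the aggregated M+1 and M+0 isotopologue
#' bins.
#'
#' @param x Formula string or named element-count vector.
#' @return M+1/M+0 abundance ratio.
#' @export
m1_ratio_closed_form <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  total <- 0
  for (el in names(counts)) {
    iso <- ELEMENT_ISOTOPES[[el]]
    p <- which.max(iso$abundance)
    plus1 <- which(abs(iso$mass - iso$mass[p] - 1) < 0.3)
    if (length(plus1)) {
      total <- total +
        counts[[el]] * iso$abundance[plus1[1]] / iso$abundance[p]
    }
  }
  total
}

#' Simulate a toy annotation problem with known ground truth
#'
#' @param n_compounds Number of true compounds (default 15).
#' @param n_samples Number of samples for the intensity matrix (default 10).
#' @param adducts Adduct rule table for feature generation (default: the
#'   positive-mode shipped rules). The first rule is always emitted per
#'   compound; the rest appear with probability `adduct_prob`.
#' @param adduct_prob Probability that each secondary adduct is observed.
#' @param frac_with_ms2 Fraction of true compounds with library + measured
#'   MS2 spectra.
#' @param noise List with `sigma_ppm` (mass accuracy, ppm), `sigma_rt`
#'   (RT jitter, seconds) and `sigma_log_intensity` (log-intensity noise).
#' @param decoys_per_compound Decoy database entries per true compound.
#' @param decoy_ppm_max Decoy masses sit within `[1, decoy_ppm_max]` ppm of
#'   the true mass (either side); ignored when `decoy_same_formula`.
#' @param decoy_same_formula When `TRUE`, decoys are exact isobars: same
#'   formula and mass as the truth, distinguishable only by their (distinct)
#'   library MS2 spectra, which are then always generated for truths and
#'   decoys alike.
#' @param bio_graph_density Probability of a biochemical edge between any
#'   two true compounds.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return List with `db` ([ipa_db()]), `features` ([ipa_features()],
#'   unclustered), `spectra` (measured MS2 list), `ground_truth` (data
#'   frame `feature_id, compound_id, adduct, role, iso_k`).
#' @export
simulate_dataset <- function(n_compounds = 15L, n_samples = 10L,
                             adducts = default_adducts("positive"),
                             adduct_prob = 0.4,
                             frac_with_ms2 = 0.3,
                             noise = list(sigma_ppm = 3, sigma_rt = 5,
                                          sigma_log_intensity = 0.2),
                             decoys_per_compound = 2L,
                             decoy_ppm_max = 10,
                             decoy_same_formula = FALSE,
                             bio_graph_density = 0.3,
                             seed = 1L) {
  stopifnot(n_compounds >= 1, n_samples >= 1, decoys_per_compound >= 0)
  noise <- utils::modifyList(
    list(sigma_ppm = 3, sigma_rt = 5, sigma_log_intensity = 0.2), noise)
  set.seed(seed)

  # --- true compounds: valence-plausible CHNO formulas, masses separated
  # by > 50 ppm; RT apexes on a jittered grid over a 60-540 s gradient so
  # that compounds stay chromatographically resolved at any density
  formulas <- character(n_compounds)
  masses <- numeric(n_compounds)
  spacing <- 480 / n_compounds
  rts <- sample(60 + spacing * (seq_len(n_compounds) - 0.5) +
                  stats::runif(n_compounds, -0.2, 0.2) * spacing)
  for (i in seq_len(n_compounds)) {
    repeat {
      nc <- sample(5:20, 1)
      nn <- sample(0:3, 1)
      no <- sample(1:8, 1)
      hmax <- 2 * nc + 2 + nn
      nh <- sample(seq(ceiling(hmax / 2), hmax), 1)
      f <- paste0("C", nc, "H", nh,
                  if (nn > 0) paste0("N", nn) else "",
                  "O", no)
      m <- monoisotopic_mass(f)
      if (i == 1L || all(abs(m - masses[seq_len(i - 1)]) / m * 1e6 > 50)) {
        break
      }
    }
    formulas[i] <- f
    masses[i] <- m
  }
  truth_ids <- sprintf("C%03d", seq_len(n_compounds))

  # --- database: truths + decoys (stated mass a few ppm off the truth,
  # carbon count shifted so the isotope fingerprint can disagree)
  compounds <- data.frame(
    compound_id = truth_ids,
    name = paste("compound", seq_len(n_compounds)),
    formula = formulas,
    monoisotopic_mass = masses,
    rt_min = rts - 30, rt_max = rts + 30,
    prior_weight = 1,
    stringsAsFactors = FALSE)
  decoy_parent <- character(0)
  if (decoys_per_compound > 0L) {
    drows <- list()
    for (i in seq_len(n_compounds)) {
      counts <- parse_formula(formulas[i])
      for (k in seq_len(decoys_per_compound)) {
        if (decoy_same_formula) {
          dform <- formulas[i]
          dmass <- masses[i]
        } else {
          shift <- sample(c(-1L, 1L), 1)
          dc <- counts
          dc[["C"]] <- max(1L, dc[["C"]] + shift)
          dc[["H"]] <- max(1L, dc[["H"]] + 2L * shift)
          dform <- paste0(names(dc), ifelse(dc > 1L, dc, ""),
                          collapse = "")
          u <- sample(c(-1, 1), 1) * stats::runif(1, 1, decoy_ppm_max)
          dmass <- masses[i] * (1 + u / 1e6)
        }
        drows[[length(drows) + 1L]] <- data.frame(
          compound_id = sprintf("D%03d_%d", i, k),
          name = sprintf("decoy %d of compound %d", k, i),
          formula = dform, monoisotopic_mass = dmass,
          rt_min = rts[i] - 30, rt_max = rts[i] + 30, prior_weight = 1,
          stringsAsFactors = FALSE)
        decoy_parent <- c(decoy_parent, truth_ids[i])
      }
    }
    compounds <- rbind(compounds, do.call(rbind, drows))
  }

  # --- biochemical network over the true compounds
  connections <- NULL
  if (n_compounds >= 2L && bio_graph_density > 0) {
    pr <- utils::combn(truth_ids, 2)
    on <- stats::runif(ncol(pr)) < bio_graph_density
    if (any(on)) {
      connections <- data.frame(compound_id_a = pr[1, on],
                                compound_id_b = pr[2, on],
                                stringsAsFactors = FALSE)
    }
  }

  # --- MS2: which compounds carry spectra
  has_ms2 <- stats::runif(n_compounds) < frac_with_ms2
  main_adduct <- adducts$name[1]
  random_spectrum <- function(precursor, name) {
    npk <- 8L
    mz <- sort(stats::runif(npk, 50, max(60, precursor - 1)))
    intensity <- 100 * (stats::rexp(npk) + 0.05)
    ms2_spectrum(mz, intensity, precursor_mz = precursor, name = name)
  }
  library_spectra <- list()
  lib_of_truth <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    if (has_ms2[i] || decoy_same_formula) {
      theo <- adduct_mz(masses[i], adducts[1, ])
      sp <- random_spectrum(theo, paste0(truth_ids[i], "|", main_adduct))
      library_spectra[[sp$name]] <- list(sp)
      lib_of_truth[[i]] <- sp
    }
  }
  for (ii in seq_along(decoy_parent)) {
    # decoys get their own distinct library spectra under the same regime
    i <- match(decoy_parent[ii], truth_ids)
    if (has_ms2[i] || decoy_same_formula) {
      id <- compounds$compound_id[n_compounds + ii]
      theo <- adduct_mz(compounds$monoisotopic_mass[n_compounds + ii],
                        adducts[1, ])
      sp <- random_spectrum(theo, paste0(id, "|", main_adduct))
      library_spectra[[sp$name]] <- list(sp)
    }
  }

  # --- features
  feat <- list()
  ints <- list()
  truth_rows <- list()
  measured <- list()
  fcount <- 0L
  for (i in seq_len(n_compounds)) {
    use <- c(TRUE, stats::runif(nrow(adducts) - 1L) < adduct_prob)
    profile <- 1e6 * exp(stats::rnorm(1, 0, 1)) *
      exp(stats::rnorm(n_samples, 0, 0.8))
    rt_comp <- rts[i] + stats::rnorm(1) * noise$sigma_rt
    for (ai in which(use)) {
      rule <- adducts[ai, ]
      theo <- adduct_mz(masses[i], rule)
      mz_obs <- theo * (1 + stats::rnorm(1) * noise$sigma_ppm / 1e6)
      eff <- if (ai == 1L) 1 else stats::runif(1, 0.1, 0.6)
      si <- profile * eff *
        exp(stats::rnorm(n_samples, 0, noise$sigma_log_intensity))
      fcount <- fcount + 1L
      fid <- sprintf("F%03d", fcount)
      feat[[fcount]] <- data.frame(
        feature_id = fid, mz = mz_obs,
        rt = max(0, rt_comp + stats::rnorm(1) * 0.1 * noise$sigma_rt),
        intensity = mean(si), stringsAsFactors = FALSE)
      ints[[fcount]] <- si
      truth_rows[[fcount]] <- data.frame(
        feature_id = fid, compound_id = truth_ids[i],
        adduct = rule$name, role = "main", iso_k = 0L,
        stringsAsFactors = FALSE)
      if (ai == 1L) {
        # M+1 isotopologue of the primary adduct feature
        ion_counts <- apply_adduct_counts(parse_formula(formulas[i]), rule)
        r1 <- m1_ratio_closed_form(ion_counts) *
          exp(stats::rnorm(1, 0, noise$sigma_log_intensity / 2))
        mz1 <- (theo + ISO_SPACING / abs(rule$charge)) *
          (1 + stats::rnorm(1) * noise$sigma_ppm / 1e6)
        fcount <- fcount + 1L
        fid1 <- sprintf("F%03d", fcount)
        feat[[fcount]] <- data.frame(
          feature_id = fid1, mz = mz1,
          rt = feat[[fcount - 1L]]$rt, intensity = mean(si * r1),
          stringsAsFactors = FALSE)
        ints[[fcount]] <- si * r1
        truth_rows[[fcount]] <- data.frame(
          feature_id = fid1, compound_id = truth_ids[i],
          adduct = rule$name, role = "isotopologue", iso_k = 1L,
          stringsAsFactors = FALSE)
        # measured MS2 attaches to the primary adduct feature
        if (!is.null(lib_of_truth[[i]]) && (has_ms2[i] || decoy_same_formula)) {
          lib <- lib_of_truth[[i]]
          measured[[length(measured) + 1L]] <- ms2_spectrum(
            lib$mz * (1 + stats::rnorm(length(lib$mz)) *
                        noise$sigma_ppm / 1e6),
            lib$intensity *
              exp(stats::rnorm(length(lib$mz), 0,
                               noise$sigma_log_intensity)),
            precursor_mz = mz_obs, rt = feat[[fcount - 1L]]$rt,
            name = paste0("ms2_", truth_ids[i]))
        }
      }
    }
  }
  table <- do.call(rbind, feat)
  intensities <- do.call(rbind, ints)
  colnames(intensities) <- paste0("sample_", seq_len(n_samples))
  list(
    db = ipa_db(compounds, spectra = library_spectra,
                connections = connections),
    features = ipa_features(table, intensities = intensities),
    spectra = measured,
    ground_truth = do.call(rbind, truth_rows)
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `features.csv`, `db_compounds.csv`, `db_spectra.msp`,
#' `db_connections.csv` (when present), `spectra.mgf` and
#' `ground_truth.csv` into a directory, in the formats the pipeline reads.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(sim$features, file.path(dir, "features.csv"))
  utils::write.csv(sim$db$compounds, file.path(dir, "db_compounds.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(sim$db$spectra)) {
    write_msp(unlist(sim$db$spectra, recursive = FALSE),
              file.path(dir, "db_spectra.msp"))
  }
  if (!is.null(sim$db$connections)) {
    utils::write.csv(sim$db$connections,
                     file.path(dir, "db_connections.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (length(sim$spectra)) {
    write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  }
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Top-1 annotation accuracy against ground truth
#'
#' For each annotatable unit the top candidate set is taken as all
#' candidates within numerical tolerance of the maximum probability; the
#' unit scores `1/|top set|` when the true compound is among them (so an
#' exact tie between the truth and one rival scores 0.5, not 1).
#'
#' @param annot `ipa_annotations` table.
#' @param ground_truth Ground-truth data frame from [simulate_dataset()].
#' @param prob `"posterior"` or `"prior"`.
#' @return Mean per-unit accuracy in `[0, 1]`.
#' @export
top1_accuracy <- function(annot, ground_truth,
                          prob = c("posterior", "prior")) {
  prob <- match.arg(prob)
  p <- annot[[prob]]
  units <- unique(annot$feature_id)
  acc <- numeric(0)
  for (fid in units) {
    rows <- which(annot$feature_id == fid)
    truth <- ground_truth$compound_id[ground_truth$feature_id == fid]
    if (!length(truth)) next
    top <- rows[p[rows] >= max(p[rows]) - 1e-12]
    acc <- c(acc, (truth[1] %in% annot$compound_id[top]) / length(top))
  }
  mean(acc)
}
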