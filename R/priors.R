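# Prior probabilities: combine prior belief, m/z accuracy, RT, isotope
# fingerprint and MS2 similarity into one normalized distribution per
# annotatable unit (step 1 of the method).

#' Signed ppm error
#'
#' @param observed,theoretical m/z values (theoretical > 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
compute_ppm <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Gaussian m/z accuracy score
#'
#' @param ppm_err Signed ppm error.
#' @param sigma_ppm Mass-accuracy standard deviation in ppm (> 0).
#' @return `exp(-ppm_err^2 / (2 sigma_ppm^2))`, in `(0, 1]`.
#' @export
mz_score <- function(ppm_err, sigma_ppm = 3) {
  stopifnot(sigma_ppm > 0)
  exp(-ppm_err^2 / (2 * sigma_ppm^2))
}

#' Retention-time score against a database RT range
#'
#' 1 when the database has no RT range for the compound (evidence absent) or
#' the feature elutes inside the range; outside, a Gaussian falloff in the
#' distance to the nearest bound.
#'
#' @param feature_rt Observed RT in seconds.
#' @param rt_min,rt_max Range bounds in seconds (`NA` = no range).
#' @param sigma_rt Falloff standard deviation in seconds (default 10).
#' @return Score in `(0, 1]`.
#' @export
rt_score <- function(feature_rt, rt_min = NA_real_, rt_max = NA_real_,
                     sigma_rt = 10) {
  if (is.na(rt_min) || is.na(rt_max)) return(1)
  d <- max(0, rt_min - feature_rt, feature_rt - rt_max)
  exp(-d^2 / (2 * sigma_rt^2))
}

#' Engine parameters
#'
#' One place for every tunable of the scoring and sampling machinery, with
#' the package defaults. Values can be overridden individually.
#'
#' @param ppm_window Candidate retrieval window, ppm.
#' @param sigma_ppm m/z score standard deviation, ppm.
#' @param sigma_rt RT score standard deviation, seconds.
#' @param sigma_iso_mz Isotope-score m/z standard deviation, ppm.
#' @param sigma_iso_ratio Isotope-score log-ratio standard deviation.
#' @param ms2_tol Fragment match tolerance, Da.
#' @param dummy_score MS2 score for candidates without library spectra.
#' @param sqrt_intensity Square-root intensity transform in the cosine.
#' @param use_ms2 Include the MS2 factor (set `FALSE` to ignore MS2).
#' @param unknown_frac The "unknown" pseudo-candidate weight as a fraction
#'   of the best candidate weight.
#' @param adducts Adduct rule table.
#' @param polarity Acquisition polarity.
#' @param delta_bio,delta_add Gibbs pseudo-counts for biochemical and
#'   adduct connections.
#' @param n_iter,burn_in Gibbs sweeps and discarded initial sweeps.
#' @return Named list of parameters.
#' @export
ipa_params <- function(ppm_window = 10, sigma_ppm = 3, sigma_rt = 10,
                       sigma_iso_mz = 5, sigma_iso_ratio = 0.4,
                       ms2_tol = 0.05, dummy_score = 0.5,
                       sqrt_intensity = TRUE, use_ms2 = TRUE,
                       unknown_frac = 0.05,
                       adducts = default_adducts(),
                       polarity = "positive",
                       delta_bio = 1, delta_add = 1,
                       n_iter = 5000L, burn_in = 1000L) {
  as.list(environment())
}

#' Compute prior annotation probabilities
#'
#' For every annotatable unit — features tagged `main` or `unrelated`;
#' isotopologues are folded into their main's fingerprint and not annotated
#' separately — candidates are retrieved by accurate mass and each receives
#' the unnormalized weight
#' `prior_weight * mz_score * rt_score * iso_score * ms2_score`.
#' An "unknown" pseudo-candidate with weight
#' `unknown_frac * max(candidate weights)` guards against forcing full
#' confidence onto a wrong candidate; the weights are then normalized to a
#' probability distribution per unit. A unit with no candidates gets
#' `{UNKNOWN: 1}`.
#'
#' @param features Prepared [ipa_features()] (clustered, isotope-mapped,
#'   MS2 attached as applicable).
#' @param db An [ipa_db()] object.
#' @param params An [ipa_params()] list.
#' @return Data frame of class `ipa_annotations`, one row per
#'   (unit, candidate) including the unknown rows, with columns
#'   `feature_id, cluster_id, compound_id, name, adduct, theoretical_mz,
#'   ppm, mz_score, rt_score, iso_score, ms2_score, prior, posterior`
#'   (`posterior` is `NA` until [gibbs_posterior()]).
#' @export
compute_priors <- function(features, db, params = ipa_params()) {
  stopifnot(inherits(features, "ipa_features"), inherits(db, "ipa_db"))
  tb <- features$table
  units <- which(tb$iso_role != "isotopologue")
  cmp <- db$compounds
  rows <- vector("list", length(units))
  for (ui in seq_along(units)) {
    i <- units[ui]
    fid <- tb$feature_id[i]
    cand <- retrieve_candidates(tb$mz[i], params$polarity, db,
                                ppm_window = params$ppm_window,
                                adducts = params$adducts)
    n <- nrow(cand)
    if (n > 0L) {
      fp <- NULL
      if (!is.na(tb$iso_group_id[i])) {
        fp <- features$fingerprints[[as.character(tb$iso_group_id[i])]]
      }
      measured_ms2 <- if (params$use_ms2) features$ms2[[fid]] else NULL
      sc_mz <- mz_score(cand$ppm, params$sigma_ppm)
      sc_rt <- numeric(n)
      sc_iso <- numeric(n)
      sc_ms2 <- numeric(n)
      for (k in seq_len(n)) {
        ci <- match(cand$compound_id[k], cmp$compound_id)
        sc_rt[k] <- rt_score(tb$rt[i], cmp$rt_min[ci], cmp$rt_max[ci],
                             params$sigma_rt)
        rule <- params$adducts[params$adducts$name == cand$adduct[k], ]
        sc_iso[k] <- if (!is.null(fp) && nrow(fp) > 1L) {
          pat <- theoretical_pattern(cmp$formula[ci], adduct = rule)
          isotope_score(fp, pat, sigma_mz = params$sigma_iso_mz,
                        sigma_ratio = params$sigma_iso_ratio)
        } else 1
        sc_ms2[k] <- ms2_score(
          measured_ms2 %||% list(),
          db_library_spectra(db, cand$compound_id[k], cand$adduct[k]),
          mz_tol = params$ms2_tol, dummy_score = params$dummy_score,
          sqrt_intensity = params$sqrt_intensity)
      }
      w <- cand$prior_weight * sc_mz * sc_rt * sc_iso * sc_ms2
      w[!is.finite(w)] <- 0
      w_unknown <- params$unknown_frac * max(w)
      # every candidate ruled out (all factors underflow) -> unknown
      if (max(w) == 0 && w_unknown == 0) w_unknown <- 1
      cand_rows <- data.frame(
        feature_id = fid, cluster_id = tb$cluster_id[i],
        compound_id = cand$compound_id, name = cand$name,
        adduct = cand$adduct, theoretical_mz = cand$theoretical_mz,
        ppm = cand$ppm, mz_score = sc_mz, rt_score = sc_rt,
        iso_score = sc_iso, ms2_score = sc_ms2,
        prior = c(w), stringsAsFactors = FALSE)
    } else {
      w <- numeric(0)
      w_unknown <- 1
      cand_rows <- NULL
    }
    unk <- data.frame(
      feature_id = fid, cluster_id = tb$cluster_id[i],
      compound_id = "UNKNOWN", name = "unknown",
      adduct = NA_character_, theoretical_mz = NA_real_, ppm = NA_real_,
      mz_score = NA_real_, rt_score = NA_real_, iso_score = NA_real_,
      ms2_score = NA_real_, prior = w_unknown, stringsAsFactors = FALSE)
    block <- rbind(cand_rows, unk)
    block$prior <- block$prior / sum(block$prior)
    rows[[ui]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$posterior <- NA_real_
  structure(out, class = c("ipa_annotations", "data.frame"))
}
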