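# Feature container and data-preparation steps: correlation/RT clustering,
# isotopologue mapping into fingerprints, MS2-to-feature assignment.

#' Build a feature set
#'
#' @param table Data frame with columns `feature_id, mz, rt, intensity` and
#'   optionally `cluster_id`. RT in seconds, m/z in Da per unit charge.
#' @param intensities Optional numeric matrix of per-sample intensities,
#'   one row per feature (rownames ignored; row order matches `table`).
#'   `NA` means the feature was not observed in that sample.
#' @param ms2 Optional named list mapping `feature_id` to a list of measured
#'   spectra.
#' @return Object of class `ipa_features`.
#' @export
ipa_features <- function(table, intensities = NULL, ms2 = list()) {
  req <- c("feature_id", "mz", "rt", "intensity")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  table$feature_id <- as.character(table$feature_id)
  if (anyDuplicated(table$feature_id)) {
    stop("duplicated feature_id", call. = FALSE)
  }
  if (any(table$mz <= 0)) stop("mz must be > 0", call. = FALSE)
  if (any(table$rt < 0)) stop("rt must be >= 0", call. = FALSE)
  if (is.null(table$cluster_id)) table$cluster_id <- NA_integer_
  table$iso_role <- "unrelated"
  table$iso_group_id <- NA_integer_
  table$iso_k <- NA_integer_
  table$charge_guess <- 1L
  if (!is.null(intensities)) {
    intensities <- as.matrix(intensities)
    stopifnot(nrow(intensities) == nrow(table))
    rownames(intensities) <- table$feature_id
  }
  structure(list(table = table, intensities = intensities, ms2 = ms2,
                 fingerprints = list()),
            class = "ipa_features")
}

#' @export
print.ipa_features <- function(x, ...) {
  tb <- x$table
  cat(sprintf(
    "<ipa_features> %d features, %d clusters, %d fingerprints, %d with MS2\n",
    nrow(tb), length(unique(tb$cluster_id[!is.na(tb$cluster_id)])),
    length(x$fingerprints), length(x$ms2)))
  invisible(x)
}

#' Cluster co-eluting, correlated features
#'
#' Single-linkage grouping: two features are linked iff their retention
#' times differ by at most `rt_window` seconds and their Pearson correlation
#' over samples where both are observed is at least `min_corr` (requiring at
#' least `min_samples` shared observations; pairs with fewer are simply not
#' linked). Features in one cluster are the candidates for having been
#' generated by the same metabolite (adducts, in-source fragments,
#' isotopologues). Cluster ids are dense integers ordered by the cluster's
#' minimum RT.
#'
#' @param features An [ipa_features()] object with per-sample intensities.
#' @param rt_window Maximum RT difference in seconds (default 5).
#' @param min_corr Minimum Pearson correlation (default 0.8).
#' @param min_samples Minimum shared observations for a correlation to count
#'   (default 3).
#' @return The feature set with `cluster_id` assigned.
#' @export
cluster_features <- function(features, rt_window = 5, min_corr = 0.8,
                             min_samples = 3L) {
  stopifnot(inherits(features, "ipa_features"), rt_window > 0,
            min_corr >= -1, min_corr <= 1)
  tb <- features$table
  n <- nrow(tb)
  ints <- features$intensities
  if (is.null(ints)) {
    ints <- matrix(tb$intensity, ncol = 1)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (abs(tb$rt[i] - tb$rt[j]) > rt_window) next
        both <- !is.na(ints[i, ]) & !is.na(ints[j, ])
        if (sum(both) < min_samples) next
        r <- suppressWarnings(stats::cor(ints[i, both], ints[j, both]))
        if (!is.na(r) && r >= min_corr) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  min_rt <- tapply(tb$rt, root, min)
  ord <- rank(min_rt, ties.method = "first")
  tb$cluster_id <- as.integer(ord[as.character(root)])
  features$table <- tb
  features
}

#' Construct an isotope fingerprint
#'
#' @param iso_group_id Integer group id.
#' @param main_feature_id Feature id of the main (monoisotopic) peak.
#' @param mz,ratio Peak m/z values and intensity ratios relative to the main
#'   peak (main first, ratio 1, m/z strictly increasing).
#' @param charge Inferred charge state.
#' @return Data frame of class `isotope_fingerprint`.
#' @export
isotope_fingerprint <- function(iso_group_id, main_feature_id, mz, ratio,
                                charge = 1L) {
  stopifnot(length(mz) == length(ratio), all(ratio > 0), ratio[1] == 1,
            !is.unsorted(mz, strictly = TRUE))
  structure(data.frame(mz = mz, ratio = ratio),
            class = c("isotope_fingerprint", "data.frame"),
            iso_group_id = iso_group_id,
            main_feature_id = main_feature_id,
            charge = as.integer(charge))
}

# mean observed intensity of a feature row (sample mean when available)
feature_abundance <- function(features, idx) {
  ints <- features$intensities
  if (!is.null(ints)) {
    m <- rowMeans(ints[idx, , drop = FALSE], na.rm = TRUE)
    ifelse(is.nan(m), features$table$intensity[idx], m)
  } else {
    features$table$intensity[idx]
  }
}

#' Map isotopologue series into isotope fingerprints
#'
#' Within each cluster, putative main peaks are considered from the most
#' intense feature downward. For each main and each charge z up to
#' `max_charge`, features sitting at `mz_main + k * 1.003355 / z` (within
#' `ppm_tol`) with intensity ratio at most `ratio_max` are tagged as the
#' k-th isotopologue; the charge giving the longest series (ties: smallest
#' mean ppm deviation) wins. A feature claimed by two mains goes to the one
#' with the smaller ppm deviation (a message is logged). Every feature that
#' is not an isotopologue becomes a main with a fingerprint (length 1 when
#' no isotopologues were found); measured ratios come from mean sample
#' intensities.
#'
#' @param features Clustered [ipa_features()].
#' @param ppm_tol Isotopologue m/z tolerance in ppm (default 10).
#' @param ratio_max Maximum isotopologue/main intensity ratio (default 1).
#' @param max_charge Maximum charge state searched (default 3).
#' @param max_k Longest isotopologue tail searched (default 5).
#' @return Feature set with `iso_role`, `iso_group_id`, `iso_k`,
#'   `charge_guess` filled and `fingerprints` populated.
#' @export
map_isotope_patterns <- function(features, ppm_tol = 10, ratio_max = 1.0,
                                 max_charge = 3L, max_k = 5L) {
  stopifnot(inherits(features, "ipa_features"))
  tb <- features$table
  if (all(is.na(tb$cluster_id))) {
    stop("features must be clustered first (see cluster_features)",
         call. = FALSE)
  }
  abund <- feature_abundance(features, seq_len(nrow(tb)))
  claimed_ppm <- rep(NA_real_, nrow(tb)) # ppm dev of current iso assignment
  group_id <- 0L
  fingerprints <- list()
  tb$iso_role <- "unrelated"

  for (cl in sort(unique(tb$cluster_id))) {
    members <- which(tb$cluster_id == cl)
    for (i in members[order(abund[members], decreasing = TRUE)]) {
      if (tb$iso_role[i] == "isotopologue") next
      # best charge: longest consecutive series, then smallest mean |ppm|
      best <- NULL
      for (z in seq_len(max_charge)) {
        hits <- integer(0)
        devs <- numeric(0)
        ks <- integer(0)
        for (k in seq_len(max_k)) {
          expected <- tb$mz[i] + k * ISO_SPACING / z
          cand <- setdiff(members, c(i, hits))
          if (!length(cand)) break
          ppm <- compute_ppm(tb$mz[cand], expected)
          ok <- abs(ppm) <= ppm_tol &
            abund[cand] / abund[i] <= ratio_max &
            tb$mz[cand] > tb$mz[i]
          if (!any(ok)) break
          pick <- cand[ok][which.min(abs(ppm[ok]))]
          hits <- c(hits, pick)
          devs <- c(devs, abs(ppm[ok][which.min(abs(ppm[ok]))]))
          ks <- c(ks, k)
        }
        if (length(hits) &&
            (is.null(best) || length(hits) > length(best$hits) ||
             (length(hits) == length(best$hits) &&
              mean(devs) < mean(best$devs)))) {
          best <- list(z = z, hits = hits, devs = devs, ks = ks)
        }
      }
      group_id <- group_id + 1L
      tb$iso_role[i] <- "main"
      tb$iso_group_id[i] <- group_id
      tb$iso_k[i] <- 0L
      taken <- logical(0)
      if (!is.null(best)) {
        taken <- rep(FALSE, length(best$hits))
        for (h in seq_along(best$hits)) {
          j <- best$hits[h]
          if (tb$iso_role[j] == "isotopologue" &&
              !is.na(claimed_ppm[j]) && claimed_ppm[j] <= best$devs[h]) {
            next # previous main explains this peak better
          }
          if (tb$iso_role[j] == "isotopologue") {
            message(sprintf(
              "feature %s matched two mains; reassigned to %s (%.2f ppm)",
              tb$feature_id[j], tb$feature_id[i], best$devs[h]))
            old <- tb$iso_group_id[j]
            if (!is.na(old) && as.character(old) %in% names(fingerprints)) {
              fingerprints[[as.character(old)]] <- NULL
            }
          }
          tb$iso_role[j] <- "isotopologue"
          tb$iso_group_id[j] <- group_id
          tb$iso_k[j] <- best$ks[h]
          tb$charge_guess[j] <- best$z
          claimed_ppm[j] <- best$devs[h]
          taken[h] <- TRUE
        }
        tb$charge_guess[i] <- best$z
      }
      idx <- c(i, if (!is.null(best)) best$hits[taken])
      fingerprints[[as.character(group_id)]] <- isotope_fingerprint(
        group_id, tb$feature_id[i],
        mz = tb$mz[idx], ratio = abund[idx] / abund[i],
        charge = if (is.null(best)) 1L else best$z)
    }
  }
  features$table <- tb
  features$fingerprints <- fingerprints
  features
}

#' Assign measured MS2 spectra to MS1 features
#'
#' Each spectrum attaches to the feature minimizing the absolute precursor
#' ppm error, subject to the error being within `mz_tol` and (when the
#' spectrum carries an RT) the RT difference within `rt_tol`; ties are
#' broken by the smaller RT difference. Spectra matching no feature are
#' collected in the `unassigned` attribute, not raised as errors.
#'
#' @param features An [ipa_features()] object.
#' @param spectra List of measured spectra with `precursor_mz` set.
#' @param mz_tol Precursor tolerance in ppm (default 10).
#' @param rt_tol RT tolerance in seconds (default 10).
#' @return Feature set with `ms2` populated; unassigned spectra in
#'   `attr(, "unassigned")`.
#' @export
assign_ms2 <- function(features, spectra, mz_tol = 10, rt_tol = 10) {
  stopifnot(inherits(features, "ipa_features"))
  tb <- features$table
  unassigned <- list()
  for (s in spectra) {
    if (is.na(s$precursor_mz)) {
      unassigned[[length(unassigned) + 1L]] <- s
      next
    }
    ppm <- abs(compute_ppm(s$precursor_mz, tb$mz))
    ok <- ppm <= mz_tol
    if (!is.na(s$rt)) ok <- ok & abs(tb$rt - s$rt) <= rt_tol
    if (!any(ok)) {
      unassigned[[length(unassigned) + 1L]] <- s
      next
    }
    idx <- which(ok)
    drt <- if (is.na(s$rt)) rep(0, length(idx)) else abs(tb$rt[idx] - s$rt)
    best <- idx[order(ppm[idx], drt)][1]
    fid <- tb$feature_id[best]
    features$ms2[[fid]] <- c(features$ms2[[fid]], list(s))
  }
  attr(features, "unassigned") <- unassigned
  features
}
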