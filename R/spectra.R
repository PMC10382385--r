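#' Construct an MS2 spectrum
#'
#' @param mz Numeric vector of fragment m/z values (Da).
#' @param intensity Numeric vector of intensities (arbitrary units, >= 0).
#' @param precursor_mz Optional precursor m/z.
#' @param rt Optional retention time in seconds.
#' @param name Optional identifier (library spectra use
#'   `"compound_id|adduct"`).
#' @return Object of class `ms2_spectrum`: peaks sorted by m/z, zero-intensity
#'   peaks dropped.
#' @export
ms2_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                         rt = NA_real_, name = NA_character_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  keep <- intensity > 0
  mz <- mz[keep]
  intensity <- intensity[keep]
  if (length(mz) == 0L) stop("spectrum has no non-zero peaks", call. = FALSE)
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o],
                 precursor_mz = precursor_mz, rt = rt, name = name),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %d peaks, precursor %.4f, rt %.1f%s\n",
              length(x$mz), x$precursor_mz, x$rt,
              if (is.na(x$name)) "" else paste0(", name ", x$name)))
  invisible(x)
}

#' Cosine similarity of two fragmentation spectra
#'
#' Peaks are matched greedily one-to-one: all pairs within `mz_tol` are
#' ranked by the product of their (transformed) intensities and accepted in
#' that order, each peak used at most once. With the default square-root
#' intensity transform the score is
#' `(sum over matches of sqrt(Ia*Ib))^2 / (sum(Ia) * sum(Ib))`,
#' the squared cosine of the aligned root-intensity vectors; it is 1 for a
#' spectrum against itself and 0 when no peaks match.
#'
#' @param a,b Spectra created with [ms2_spectrum()].
#' @param mz_tol Fragment match tolerance in Da (default 0.05).
#' @param sqrt_intensity Apply the square-root transform (default `TRUE`);
#'   set `FALSE` for a raw-intensity cosine.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b, mz_tol = 0.05, sqrt_intensity = TRUE) {
  wa <- if (sqrt_intensity) sqrt(a$intensity) else a$intensity
  wb <- if (sqrt_intensity) sqrt(b$intensity) else b$intensity
  # candidate pairs within tolerance
  dm <- abs(outer(a$mz, b$mz, "-"))
  idx <- which(dm <= mz_tol, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  prod <- wa[idx[, 1]] * wb[idx[, 2]]
  o <- order(prod, decreasing = TRUE)
  used_a <- logical(length(wa))
  used_b <- logical(length(wb))
  dot <- 0
  for (k in o) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      dot <- dot + prod[k]
    }
  }
  min(1, dot^2 / (sum(wa^2) * sum(wb^2)))
}

#' MS2 evidence score for one candidate annotation
#'
#' If the feature carries no measured MS2 spectra the evidence is absent and
#' every candidate scores a neutral 1. Otherwise a candidate with library
#' spectra scores the maximum cosine similarity over all (measured, library)
#' pairs, and a candidate without library spectra receives the user-defined
#' `dummy_score` so that it remains comparable.
#'
#' @param measured List of measured spectra attached to the feature (possibly
#'   empty).
#' @param library_spectra List of library spectra for the candidate (possibly
#'   empty).
#' @param mz_tol Fragment match tolerance in Da.
#' @param dummy_score Score in `[0, 1]` for library-less candidates.
#' @param sqrt_intensity Passed to [cosine_similarity()].
#' @return Score in `[0, 1]`.
#' @export
ms2_score <- function(measured, library_spectra, mz_tol = 0.05,
                      dummy_score = 0.5, sqrt_intensity = TRUE) {
  stopifnot(dummy_score >= 0, dummy_score <= 1)
  if (length(measured) == 0L) return(1)
  if (length(library_spectra) == 0L) return(dummy_score)
  best <- 0
  for (m in measured) {
    for (l in library_spectra) {
      s <- cosine_similarity(m, l, mz_tol = mz_tol,
                             sqrt_intensity = sqrt_intensity)
      if (s > best) best <- s
    }
  }
  best
}
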