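# Theoretical isotope patterns (aggregated convolution) and the
# isotope-fingerprint score.

# merge peaks of a (mass, abundance) table that fall within bin_width of the
# running abundance-weighted mean mass; input must be sorted by mass
bin_peaks <- function(mass, abundance, bin_width) {
  o <- order(mass)
  mass <- mass[o]
  abundance <- abundance[o]
  gm <- numeric(0)
  ga <- numeric(0)
  for (i in seq_along(mass)) {
    k <- length(gm)
    if (k > 0L && mass[i] - gm[k] <= bin_width) {
      tot <- ga[k] + abundance[i]
      gm[k] <- (gm[k] * ga[k] + mass[i] * abundance[i]) / tot
      ga[k] <- tot
    } else {
      gm <- c(gm, mass[i])
      ga <- c(ga, abundance[i])
    }
  }
  list(mass = gm, abundance = ga)
}

# convolve two aggregated distributions, then bin and prune numeric dust
convolve_dist <- function(a, b, bin_width, prune = 1e-12) {
  mass <- as.vector(outer(a$mass, b$mass, "+"))
  ab <- as.vector(outer(a$abundance, b$abundance, "*"))
  keep <- ab > prune
  bin_peaks(mass[keep], ab[keep], bin_width)
}

# distribution of `n` atoms of one element, by repeated squaring
element_dist <- function(element, n, bin_width) {
  iso <- ELEMENT_ISOTOPES[[element]]
  base <- list(mass = iso$mass, abundance = iso$abundance)
  out <- list(mass = 0, abundance = 1)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- convolve_dist(out, base, bin_width)
    base <- convolve_dist(base, base, bin_width)
    n <- n %/% 2L
  }
  out
}

#' Theoretical isotope pattern of a formula (optionally as an adduct ion)
#'
#' Computes the aggregated (unit-resolution) isotopologue distribution of a
#' molecular formula by convolving each element's isotope distribution,
#' merging peaks that fall within `bin_width` of each other by
#' abundance-weighted mean mass. When an adduct rule is supplied the pattern
#' is computed for the full ion formula (multiplicity copies of the molecule
#' plus/minus the adduct atoms) and m/z values account for the electron mass
#' and charge.
#'
#' @param formula Formula string of the neutral molecule.
#' @param adduct Optional one-row adduct rule (see [adduct_rule()]); when
#'   `NULL` the pattern is that of the bare species at charge `charge`.
#' @param charge Ion charge used when `adduct` is `NULL` (signed; 0 gives the
#'   neutral mass scale).
#' @param min_abundance Peaks below this relative abundance (most abundant
#'   peak = 1) are dropped.
#' @param bin_width Peak-merge width in Da (default 0.05, i.e. aggregated
#'   isotopologues, no fine structure).
#' @return Object of class `isotope_pattern`: data frame with columns `mz`
#'   (ascending) and `abundance` (max = 1), plus `charge` and `formula`
#'   attributes.
#' @examples
#' theoretical_pattern("C6H12O6",
#'                     adduct = adduct_rule("[M+H]+", 1, formula_add = "H"))
#' @export
theoretical_pattern <- function(formula, adduct = NULL, charge = 1L,
                                min_abundance = 1e-4, bin_width = 0.05) {
  stopifnot(min_abundance > 0, min_abundance <= 1)
  counts <- parse_formula(formula)
  z <- charge
  if (!is.null(adduct)) {
    counts <- apply_adduct_counts(counts, adduct)
    z <- adduct$charge
  }
  dist <- list(mass = 0, abundance = 1)
  for (el in names(counts)) {
    dist <- convolve_dist(dist, element_dist(el, counts[[el]], bin_width),
                          bin_width)
  }
  mass <- dist$mass - z * ELECTRON_MASS
  mz <- if (z == 0) mass else mass / abs(z)
  ab <- dist$abundance / max(dist$abundance)
  keep <- ab >= min_abundance
  o <- order(mz[keep])
  structure(
    data.frame(mz = mz[keep][o], abundance = ab[keep][o]),
    class = c("isotope_pattern", "data.frame"),
    charge = z, formula = formula
  )
}

#' Score a measured isotope fingerprint against a theoretical pattern
#'
#' Each measured peak is matched to the nearest theoretical peak. Matched
#' peaks contribute a Gaussian factor in the m/z deviation (ppm) and a
#' Gaussian factor in the log intensity-ratio deviation; a measured peak with
#' no theoretical partner within `3 * sigma_mz` contributes a factor of 0.
#' The score is the geometric mean of the per-peak factors. A single-peak
#' fingerprint carries no isotope evidence and scores a neutral 1.
#'
#' Ratios are taken relative to the main (most intense) peak on both sides,
#' so the main peak contributes only its m/z accuracy. The log-ratio metric
#' is symmetric: a two-fold excess penalizes exactly like a two-fold deficit.
#'
#' @param measured Data frame (or [isotope_fingerprint()]) with columns `mz`
#'   and `ratio` (main peak first, ratio 1).
#' @param theoretical An [theoretical_pattern()] result.
#' @param sigma_mz m/z standard deviation in ppm (default 5).
#' @param sigma_ratio Log-ratio standard deviation (default 0.4).
#' @return Score in `[0, 1]`.
#' @export
isotope_score <- function(measured, theoretical, sigma_mz = 5,
                          sigma_ratio = 0.4) {
  stopifnot(nrow(measured) >= 1, nrow(theoretical) >= 1)
  if (nrow(measured) == 1L) return(1)
  r_meas <- measured$ratio / max(measured$ratio)
  r_theo <- theoretical$abundance / max(theoretical$abundance)
  log_fac <- 0
  for (i in seq_len(nrow(measured))) {
    j <- which.min(abs(theoretical$mz - measured$mz[i]))
    ppm_err <- compute_ppm(measured$mz[i], theoretical$mz[j])
    if (abs(ppm_err) > 3 * sigma_mz) return(0)
    dlr <- log(r_meas[i]) - log(r_theo[j])
    log_fac <- log_fac - ppm_err^2 / (2 * sigma_mz^2) -
      dlr^2 / (2 * sigma_ratio^2)
  }
  exp(log_fac / nrow(measured))
}
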