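#' Build an annotation database object
#'
#' The annotation database holds one row per compound plus two optional
#' sidecars: a library of MS2 spectra keyed by `compound_id|adduct_name`,
#' and a biochemical-connection edge list.
#'
#' @param compounds Data frame with columns `compound_id, name, formula,
#'   monoisotopic_mass` and optionally `rt_min, rt_max, prior_weight`.
#'   A missing `monoisotopic_mass` is computed from the formula. RT is in
#'   seconds. `prior_weight` defaults to 1.
#' @param spectra Named list; names are `"<compound_id>|<adduct_name>"` keys
#'   and each element is a list of spectra (see [ms2_spectrum()]).
#' @param connections Data frame with columns `compound_id_a, compound_id_b`,
#'   or `NULL`.
#' @return Object of class `ipa_db`.
#' @export
ipa_db <- function(compounds, spectra = list(), connections = NULL) {
  req <- c("compound_id", "name", "formula")
  miss <- setdiff(req, names(compounds))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  compounds$compound_id <- as.character(compounds$compound_id)
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicated compound_id in database", call. = FALSE)
  }
  if (is.null(compounds$monoisotopic_mass)) {
    compounds$monoisotopic_mass <- NA_real_
  }
  need <- is.na(compounds$monoisotopic_mass)
  if (any(need)) {
    compounds$monoisotopic_mass[need] <-
      vapply(compounds$formula[need], monoisotopic_mass, numeric(1))
  }
  if (any(compounds$monoisotopic_mass <= 0)) {
    stop("monoisotopic_mass must be > 0", call. = FALSE)
  }
  if (is.null(compounds$rt_min)) compounds$rt_min <- NA_real_
  if (is.null(compounds$rt_max)) compounds$rt_max <- NA_real_
  bad_rt <- !is.na(compounds$rt_min) & !is.na(compounds$rt_max) &
    compounds$rt_min >= compounds$rt_max
  if (any(bad_rt)) {
    stop("rt_min must be < rt_max (compound ",
         compounds$compound_id[bad_rt][1], ")", call. = FALSE)
  }
  if (is.null(compounds$prior_weight)) compounds$prior_weight <- 1
  compounds$prior_weight[is.na(compounds$prior_weight)] <- 1
  if (any(compounds$prior_weight <= 0)) {
    stop("prior_weight must be > 0", call. = FALSE)
  }
  # validate formulas eagerly so errors surface at load time
  invisible(lapply(compounds$formula, parse_formula))
  if (!is.null(connections)) {
    cn <- c("compound_id_a", "compound_id_b")
    if (!all(cn %in% names(connections))) {
      stop("connections need columns compound_id_a, compound_id_b",
           call. = FALSE)
    }
    connections$compound_id_a <- as.character(connections$compound_id_a)
    connections$compound_id_b <- as.character(connections$compound_id_b)
  }
  structure(list(compounds = compounds, spectra = spectra,
                 connections = connections),
            class = "ipa_db")
}

#' @export
print.ipa_db <- function(x, ...) {
  cat(sprintf(
    "<ipa_db> %d compounds, %d library spectrum keys, %s connections\n",
    nrow(x$compounds), length(x$spectra),
    if (is.null(x$connections)) "no" else nrow(x$connections)))
  invisible(x)
}

#' Read an annotation database from CSV (+ optional sidecars)
#'
#' @param compounds_csv CSV with header
#'   `compound_id,name,formula,monoisotopic_mass,rt_min,rt_max,prior_weight`
#'   (the mass/RT/weight columns may be omitted or empty).
#' @param spectra_msp Optional MSP file of library spectra; each entry's
#'   `Name` field must be `compound_id|adduct_name`.
#' @param connections_csv Optional CSV with header
#'   `compound_id_a,compound_id_b`.
#' @param rt_unit `"seconds"` (default) or `"minutes"`; RT ranges are
#'   converted to seconds on read.
#' @return An [ipa_db()] object.
#' @export
read_database <- function(compounds_csv, spectra_msp = NULL,
                          connections_csv = NULL,
                          rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  compounds <- utils::read.csv(compounds_csv, stringsAsFactors = FALSE)
  if (rt_unit == "minutes") {
    for (col in c("rt_min", "rt_max")) {
      if (!is.null(compounds[[col]])) {
        compounds[[col]] <- compounds[[col]] * 60
      }
    }
  }
  spectra <- list()
  if (!is.null(spectra_msp)) {
    sp <- read_msp(spectra_msp)
    for (s in sp) {
      key <- s$name
      spectra[[key]] <- c(spectra[[key]], list(s))
    }
  }
  connections <- if (!is.null(connections_csv)) {
    utils::read.csv(connections_csv, stringsAsFactors = FALSE)
  }
  ipa_db(compounds, spectra, connections)
}

# library spectra for one (compound, adduct); falls back to spectra filed
# under the bare compound_id (adduct-agnostic entries)
db_library_spectra <- function(db, compound_id, adduct_name) {
  key <- paste0(compound_id, "|", adduct_name)
  out <- db$spectra[[key]]
  if (is.null(out)) out <- db$spectra[[compound_id]]
  if (is.null(out)) list() else out
}

#' Retrieve annotation candidates by accurate mass
#'
#' Scans all (compound, adduct) pairs of the requested polarity and returns
#' those whose theoretical m/z lies within `ppm_window` of the observed
#' feature m/z, ordered by |ppm error| (ties broken by compound_id, then
#' adduct name).
#'
#' @param feature_mz Observed m/z (Da per unit charge).
#' @param polarity `"positive"` or `"negative"`.
#' @param db An [ipa_db()] object.
#' @param ppm_window Match window in ppm (> 0).
#' @param adducts Adduct rule table; defaults to [default_adducts()].
#' @return Data frame with one row per candidate: `compound_id, name,
#'   adduct, theoretical_mz, ppm, prior_weight`.
#' @export
retrieve_candidates <- function(feature_mz, polarity, db, ppm_window = 10,
                                adducts = default_adducts()) {
  stopifnot(ppm_window > 0, feature_mz > 0)
  polarity <- match.arg(polarity, c("positive", "negative"))
  rules <- adducts[adducts$polarity == polarity, , drop = FALSE]
  cmp <- db$compounds
  if (nrow(cmp) == 0L || nrow(rules) == 0L) {
    return(empty_candidates())
  }
  grid <- expand.grid(ci = seq_len(nrow(cmp)), ri = seq_len(nrow(rules)))
  theo <- (rules$multiplicity[grid$ri] * cmp$monoisotopic_mass[grid$ci] +
             rules$mass_shift[grid$ri]) / abs(rules$charge[grid$ri])
  ppm <- compute_ppm(feature_mz, theo)
  keep <- theo > 0 & abs(ppm) <= ppm_window
  if (!any(keep)) return(empty_candidates())
  out <- data.frame(
    compound_id = cmp$compound_id[grid$ci[keep]],
    name = cmp$name[grid$ci[keep]],
    adduct = rules$name[grid$ri[keep]],
    theoretical_mz = theo[keep],
    ppm = ppm[keep],
    prior_weight = cmp$prior_weight[grid$ci[keep]],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$ppm), out$compound_id, out$adduct), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(compound_id = character(0), name = character(0),
             adduct = character(0), theoretical_mz = numeric(0),
             ppm = numeric(0), prior_weight = numeric(0),
             stringsAsFactors = FALSE)
}
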