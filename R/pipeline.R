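# End-to-end pipeline driver: the engine behind the command-line interface.

PIPELINE_KEYS <- c("features", "db_compounds", "db_spectra",
                   "db_connections", "spectra", "out", "seed", "mode",
                   "rt_unit", "bio_mode", "params", "prep")

#' Run the full annotation pipeline
#'
#' Stages: read inputs, cluster features, map isotope fingerprints, assign
#' MS2 spectra, compute priors, build the connection graph, run the Gibbs
#' sampler, write the annotation CSV. Every stage logs its counts. With
#' `mode: "priors"` the network step is skipped and priors are reported.
#'
#' @param config Path to a YAML file or a named list with keys:
#'   `features` (feature CSV, required), `db_compounds` (compound CSV,
#'   required), `db_spectra` (MSP, optional), `db_connections` (CSV,
#'   optional), `spectra` (measured MGF/MSP, optional), `out` (output CSV,
#'   optional), `seed` (integer, default 1), `mode` (`"full"` or
#'   `"priors"`), `rt_unit` (`"seconds"`/`"minutes"`), `bio_mode`
#'   (`"db_edges"`/`"mass_diff"`; defaults to `db_edges` when a connection
#'   sidecar is given, else `mass_diff`), `params` (overrides for
#'   [ipa_params()]), `prep` (overrides for the preparation stages:
#'   `rt_window`, `min_corr`, `min_samples`, `iso_ppm_tol`,
#'   `iso_ratio_max`, `max_charge`, `ms2_ppm`, `ms2_rt`).
#' @return The annotation table, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("features", "db_compounds")) {
    if (is.null(config[[req]])) {
      stop("config is missing required key: ", req, call. = FALSE)
    }
  }
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "full"
  if (!mode %in% c("full", "priors")) {
    stop("mode must be 'full' or 'priors'", call. = FALSE)
  }
  rt_unit <- config$rt_unit %||% "seconds"
  params <- do.call(ipa_params, config$params %||% list())
  prep <- utils::modifyList(
    list(rt_window = 5, min_corr = 0.8, min_samples = 3L,
         iso_ppm_tol = 10, iso_ratio_max = 1.0, max_charge = 3L,
         ms2_ppm = 10, ms2_rt = 10),
    config$prep %||% list())

  db <- read_database(config$db_compounds, spectra_msp = config$db_spectra,
                      connections_csv = config$db_connections,
                      rt_unit = rt_unit)
  message(sprintf("db: %d compounds, %d library spectrum keys",
                  nrow(db$compounds), length(db$spectra)))
  features <- read_feature_table(config$features, rt_unit = rt_unit)
  message(sprintf("features: %d read", nrow(features$table)))

  if (all(is.na(features$table$cluster_id))) {
    features <- cluster_features(features, rt_window = prep$rt_window,
                                 min_corr = prep$min_corr,
                                 min_samples = prep$min_samples)
  }
  message(sprintf("clusters: %d",
                  length(unique(features$table$cluster_id))))
  features <- map_isotope_patterns(features, ppm_tol = prep$iso_ppm_tol,
                                   ratio_max = prep$iso_ratio_max,
                                   max_charge = prep$max_charge)
  n_iso <- sum(features$table$iso_role == "isotopologue")
  message(sprintf("isotope mapping: %d isotopologues folded, %d units",
                  n_iso, nrow(features$table) - n_iso))
  if (!is.null(config$spectra)) {
    sp <- read_spectra(config$spectra)
    features <- assign_ms2(features, sp, mz_tol = prep$ms2_ppm,
                           rt_tol = prep$ms2_rt)
    message(sprintf("ms2: %d spectra read, %d unassigned", length(sp),
                    length(attr(features, "unassigned"))))
  }

  annot <- compute_priors(features, db, params)
  message(sprintf("priors: %d candidate rows over %d units",
                  sum(annot$compound_id != "UNKNOWN"),
                  length(unique(annot$feature_id))))
  if (mode == "full") {
    bio_mode <- config$bio_mode %||%
      (if (is.null(db$connections)) "mass_diff" else "db_edges")
    graph <- build_connections(annot, db, bio_mode = bio_mode)
    message(sprintf("connections: %d bio, %d adduct edges (%s mode)",
                    nrow(graph$bio), nrow(graph$add), bio_mode))
    annot <- gibbs_posterior(annot, graph,
                             delta_bio = params$delta_bio,
                             delta_add = params$delta_add,
                             n_iter = params$n_iter,
                             burn_in = params$burn_in, seed = seed)
  }
  if (!is.null(config$out)) {
    write_annotations(annot, config$out, seed = seed)
    message("written: ", config$out)
  }
  invisible(annot)
}
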