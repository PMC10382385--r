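# Posterior probabilities: connection graphs over candidates and the Gibbs
# sampler (step 2 of the method).

#' Shipped table of common biochemical mass differences
#'
#' About thirty single-step transformations (methylation, hydroxylation,
#' glycosylation, phosphorylation, common conjugations, ...) used by the
#' `mass_diff` connection mode: two compounds whose neutral masses differ by
#' one of these values, within tolerance, are treated as biochemically
#' connected. Masses are computed from the embedded isotope table, so they
#' are exact monoisotopic differences. The selection of entries is a package
#' default; supply your own table for other chemistries.
#'
#' @return Data frame with columns `name`, `formula`, `mass`.
#' @export
default_transformations <- function() {
  def <- c(
    "(de)hydrogenation" = "H2",
    "methylation" = "CH2",
    "ethylation" = "C2H4",
    "acetylene unit" = "C2H2",
    "propylation" = "C3H6",
    "hydroxylation" = "O",
    "(de)hydration" = "H2O",
    "formylation" = "CO",
    "carboxylation" = "CO2",
    "hydroxymethylation" = "CH2O",
    "acetylation" = "C2H2O",
    "malonylation" = "C3H2O3",
    "pyruvate unit" = "C3H4O2",
    "amination" = "NH",
    "ammonia addition" = "NH3",
    "glycine conjugation" = "C2H3NO",
    "alanine conjugation" = "C3H5NO",
    "serine unit" = "C3H5NO2",
    "glutamyl transfer" = "C5H7NO3",
    "taurine conjugation" = "C2H5NO2S",
    "cysteine conjugation" = "C3H5NOS",
    "glutathione conjugation" = "C10H15N3O6S",
    "sulfation" = "SO3",
    "thiol exchange" = "S",
    "phosphorylation" = "HPO3",
    "pyrophosphate unit" = "H2P2O6",
    "glycosylation (hexose)" = "C6H10O5",
    "glucuronidation" = "C6H8O6",
    "pentose unit" = "C5H8O4",
    "deoxyhexose unit" = "C6H10O4",
    "prenylation" = "C5H8",
    "adenylation" = "C10H12N5O6P"
  )
  data.frame(name = names(def), formula = unname(def),
             mass = vapply(unname(def), monoisotopic_mass, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the candidate connection graph
#'
#' Two kinds of edges between candidate rows of *different* annotatable
#' units: biochemical edges (the two compounds are curated neighbours in
#' `db_edges` mode, or their neutral-mass difference matches a
#' transformation mass within `ppm_tol` in `mass_diff` mode) and
#' adduct/in-source-fragment edges (same compound annotating two features of
#' the same cluster under different adduct rules). Unknown pseudo-candidates
#' get no edges.
#'
#' @param annot An `ipa_annotations` table from [compute_priors()].
#' @param db The [ipa_db()] used to compute the priors.
#' @param bio_mode `"db_edges"` (curated edge list) or `"mass_diff"`.
#' @param transformations Transformation table for `mass_diff` mode.
#' @param ppm_tol Mass-difference tolerance in ppm (default 10), applied to
#'   the heavier neutral mass.
#' @param include One or both of `"bio"`, `"add"` — which edge families to
#'   build.
#' @return Object of class `connection_graph`: list of two 2-column integer
#'   matrices (`bio`, `add`) of annotation row indices.
#' @export
build_connections <- function(annot, db,
                              bio_mode = c("db_edges", "mass_diff"),
                              transformations = default_transformations(),
                              ppm_tol = 10,
                              include = c("bio", "add")) {
  bio_mode <- match.arg(bio_mode)
  cmp <- db$compounds
  is_cand <- annot$compound_id != "UNKNOWN"
  idx <- which(is_cand)
  unit <- match(annot$feature_id, unique(annot$feature_id))
  bio <- matrix(integer(0), ncol = 2)
  add <- matrix(integer(0), ncol = 2)
  if (length(idx) >= 2L) {
    ci <- match(annot$compound_id[idx], cmp$compound_id)
    mass <- cmp$monoisotopic_mass[ci]
    pairs <- utils::combn(seq_along(idx), 2)
    u <- idx[pairs[1, ]]
    v <- idx[pairs[2, ]]
    diff_unit <- unit[u] != unit[v]
    if ("add" %in% include) {
      same_cluster <- !is.na(annot$cluster_id[u]) &
        annot$cluster_id[u] == annot$cluster_id[v]
      is_add <- diff_unit & same_cluster &
        annot$compound_id[u] == annot$compound_id[v] &
        annot$adduct[u] != annot$adduct[v]
      add <- cbind(u[is_add], v[is_add])
    }
    if ("bio" %in% include) {
      if (bio_mode == "db_edges") {
        if (is.null(db$connections)) {
          stop(paste("database has no connection sidecar;",
                     "use bio_mode = \"mass_diff\""), call. = FALSE)
        }
        key <- function(a, b) paste(pmin(a, b), pmax(a, b))
        edge_keys <- key(db$connections$compound_id_a,
                         db$connections$compound_id_b)
        is_bio <- diff_unit &
          annot$compound_id[u] != annot$compound_id[v] &
          key(annot$compound_id[u], annot$compound_id[v]) %in% edge_keys
      } else {
        mu <- mass[pairs[1, ]]
        mv <- mass[pairs[2, ]]
        dm <- abs(mu - mv)
        tol <- pmax(mu, mv) * ppm_tol / 1e6
        is_bio <- diff_unit & annot$compound_id[u] != annot$compound_id[v] &
          vapply(seq_along(dm), function(k) {
            any(abs(dm[k] - transformations$mass) <= tol[k])
          }, logical(1))
      }
      bio <- cbind(u[is_bio], v[is_bio])
    }
  }
  structure(list(bio = bio, add = add, n_rows = nrow(annot)),
            class = "connection_graph")
}

#' @export
print.connection_graph <- function(x, ...) {
  cat(sprintf("<connection_graph> %d bio edges, %d adduct edges\n",
              nrow(x$bio), nrow(x$add)))
  invisible(x)
}

#' Posterior probabilities by Gibbs sampling over the connection graph
#'
#' Systematic-scan Gibbs sampler. The full conditional for a unit f given
#' the current assignment of every other unit is
#' `P(a | rest) proportional to prior(a) * (n_bio(a) + delta_bio) *
#' (n_add(a) + delta_add)`,
#' where `n_bio(a)`/`n_add(a)` count the currently assigned candidates in
#' other units connected to `a`. Posteriors are visit frequencies after
#' burn-in. Unknown pseudo-candidates participate with no edges (the
#' no-network null). Deterministic given `seed`.
#'
#' @param annot `ipa_annotations` table with priors.
#' @param graph A [build_connections()] result.
#' @param delta_bio,delta_add Positive pseudo-counts.
#' @param n_iter Total sweeps (> burn_in).
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param scan `"systematic"` (default, unit index ascending) or `"random"`.
#' @return The annotation table with the `posterior` column filled;
#'   attributes `n_cond_evals` (total conditional evaluations, a complexity
#'   diagnostic) and `geweke_maxdiff` (largest per-candidate visit-frequency
#'   difference between the two post-burn-in chain halves, a crude
#'   convergence diagnostic, also logged).
#' @export
gibbs_posterior <- function(annot, graph, delta_bio = 1, delta_add = 1,
                            n_iter = 5000L, burn_in = 1000L, seed = NULL,
                            scan = c("systematic", "random")) {
  scan <- match.arg(scan)
  stopifnot(n_iter > burn_in, burn_in >= 0, delta_bio > 0, delta_add > 0,
            graph$n_rows == nrow(annot))
  if (!is.null(seed)) set.seed(seed)
  unit_of <- match(annot$feature_id, unique(annot$feature_id)) - 1L
  res <- gibbs_sample_cpp(unit_of, annot$prior,
                          graph$bio - 1L, graph$add - 1L,
                          max(unit_of) + 1L, as.integer(n_iter),
                          as.integer(burn_in),
                          delta_bio, delta_add, scan == "random")
  annot$posterior <- res$posterior
  gew <- max(abs(res$visits_first_half - res$visits_second_half))
  message(sprintf(
    "gibbs: %d units, %d sweeps (%d burn-in), half-chain max |diff| = %.4f",
    max(unit_of) + 1L, n_iter, burn_in, gew))
  attr(annot, "n_cond_evals") <- res$n_cond_evals
  attr(annot, "geweke_maxdiff") <- gew
  annot
}
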