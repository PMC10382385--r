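#' Construct an adduct / in-source-fragment rule
#'
#' An adduct rule describes how a neutral molecule M of a compound turns into
#' an observed ion, `[nM+X]z`: a multiplicity n, a set of atoms gained and/or
#' lost, and a charge. The m/z shift is derived from the atom deltas and the
#' electron mass, so e.g. `[M+H]+` shifts by the proton mass 1.00727646 Da.
#'
#' @param name Rule name, e.g. `"[M+H]+"`.
#' @param charge Signed ion charge (non-zero integer).
#' @param multiplicity n in `[nM+X]`; positive integer, default 1.
#' @param formula_add Formula string of atoms gained (may be `""`).
#' @param formula_remove Formula string of atoms lost (may be `""`).
#' @param in_source Logical; `TRUE` marks an in-source fragment rule.
#' @return One-row data frame with columns `name, polarity, charge,
#'   multiplicity, formula_add, formula_remove, mass_shift, in_source`.
#' @examples
#' adduct_rule("[M+H]+", charge = 1, formula_add = "H")
#' @export
adduct_rule <- function(name, charge, multiplicity = 1L,
                        formula_add = "", formula_remove = "",
                        in_source = FALSE) {
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (charge == 0L) stop("charge must be non-zero", call. = FALSE)
  if (multiplicity < 1L) stop("multiplicity must be >= 1", call. = FALSE)
  m_add <- if (nzchar(formula_add)) monoisotopic_mass(formula_add) else 0
  m_rem <- if (nzchar(formula_remove)) monoisotopic_mass(formula_remove) else 0
  data.frame(
    name = name,
    polarity = if (charge > 0L) "positive" else "negative",
    charge = charge,
    multiplicity = multiplicity,
    formula_add = formula_add,
    formula_remove = formula_remove,
    mass_shift = m_add - m_rem - charge * ELECTRON_MASS,
    in_source = in_source,
    stringsAsFactors = FALSE
  )
}

#' Default adduct rule set
#'
#' The shipped defaults cover the ions most commonly seen in ESI
#' metabolomics: `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+NH4]+`, `[2M+H]+`,
#' the water-loss in-source fragment `[M-H2O+H]+`, `[M-H]-` and `[M+Cl]-`.
#' This set is a package default, not a property of any particular compound
#' database; supply your own rules built with [adduct_rule()] when your
#' instrument or chemistry differs.
#'
#' @param polarity `"both"` (default), `"positive"` or `"negative"`.
#' @return Data frame of adduct rules.
#' @export
default_adducts <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  rules <- rbind(
    adduct_rule("[M+H]+",      1L, formula_add = "H"),
    adduct_rule("[M+Na]+",     1L, formula_add = "Na"),
    adduct_rule("[M+K]+",      1L, formula_add = "K"),
    adduct_rule("[M+NH4]+",    1L, formula_add = "NH4"),
    adduct_rule("[2M+H]+",     1L, multiplicity = 2L, formula_add = "H"),
    adduct_rule("[M-H2O+H]+",  1L, formula_add = "H", formula_remove = "H2O",
                in_source = TRUE),
    adduct_rule("[M-H]-",     -1L, formula_remove = "H"),
    adduct_rule("[M+Cl]-",    -1L, formula_add = "Cl")
  )
  if (polarity == "both") rules else rules[rules$polarity == polarity, ]
}

#' Theoretical m/z of an adduct ion
#'
#' `(multiplicity * M + mass_shift) / |charge|` for a neutral monoisotopic
#' mass M and an adduct rule.
#'
#' @param monoisotopic_mass Neutral monoisotopic mass in Da.
#' @param rule One-row adduct rule data frame (see [adduct_rule()]).
#' @return m/z in Da per unit charge.
#' @examples
#' adduct_mz(180.06339, adduct_rule("[M+H]+", 1, formula_add = "H"))
#' @export
adduct_mz <- function(monoisotopic_mass, rule) {
  mz <- (rule$multiplicity * monoisotopic_mass + rule$mass_shift) /
    abs(rule$charge)
  if (any(mz <= 0)) {
    stop(sprintf("adduct '%s' yields non-positive m/z for mass %.5f",
                 rule$name[mz <= 0][1], monoisotopic_mass), call. = FALSE)
  }
  mz
}

# net element-count change of a rule applied to `multiplicity` copies of
# `counts`; errors if the rule removes atoms the molecule does not have
apply_adduct_counts <- function(counts, rule) {
  out <- counts
  if (rule$multiplicity > 1L) {
    out <- stats::setNames(as.integer(out) * rule$multiplicity, names(out))
  }
  if (nzchar(rule$formula_add)) {
    out <- add_counts(out, parse_formula(rule$formula_add))
  }
  if (nzchar(rule$formula_remove)) {
    rem <- parse_formula(rule$formula_remove)
    rem <- stats::setNames(-as.integer(rem), names(rem))
    out <- add_counts(out, rem)
  }
  if (any(out < 0L)) {
    stop(sprintf("adduct '%s' removes atoms not present in the formula",
                 rule$name), call. = FALSE)
  }
  out
}
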