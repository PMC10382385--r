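#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula (e.g. `"C6H12O6"`) into a named
#' vector of element counts. Only elements present in the embedded isotope
#' table are accepted (C, H, N, O, P, S, Na, K, Cl, Br, F, Si).
#'
#' @param formula Single formula string, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts (elements with count 0 are
#'   dropped).
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  # verify the tokens tile the whole string; report the first leftover piece
  rest <- formula
  for (tk in toks) {
    if (startsWith(rest, tk)) {
      rest <- substring(rest, nchar(tk) + 1L)
    } else {
      break
    }
  }
  if (nzchar(rest)) {
    stop(sprintf("malformed formula '%s': cannot parse near '%s'",
                 formula, substr(rest, 1L, 8L)), call. = FALSE)
  }
  counts <- integer(0)
  for (tk in toks) {
    elem <- sub("[0-9]*$", "", tk)
    nstr <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (!elem %in% SUPPORTED_ELEMENTS) {
      stop(sprintf("unknown element '%s' in formula '%s'", elem, formula),
           call. = FALSE)
    }
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  counts[counts > 0L]
}

#' Monoisotopic mass of a formula
#'
#' Sums the principal-isotope (most abundant) masses for each element.
#'
#' @param x Formula string or a named element-count vector as returned by
#'   [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6") # 180.0634
#' @export
monoisotopic_mass <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  if (length(counts) == 0L) return(0)
  m <- vapply(names(counts), function(el) {
    iso <- ELEMENT_ISOTOPES[[el]]
    iso$mass[which.max(iso$abundance)]
  }, numeric(1))
  sum(m * as.numeric(counts))
}

# arithmetic on element-count vectors; result may contain negative counts
# (used for adduct deltas), caller validates where that matters
add_counts <- function(a, b, mult_a = 1L) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + mult_a * as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out[out != 0L]
}
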