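# Small fixtures built in code.

# three-compound toy database (glucose, fructose is an isobar of glucose,
# caffeine) with RT ranges
toy_db <- function(connections = NULL, spectra = list()) {
  ipa_db(data.frame(
    compound_id = c("CPD1", "CPD2", "CPD3"),
    name = c("glucose", "fructose", "caffeine"),
    formula = c("C6H12O6", "C6H12O6", "C8H10N4O2"),
    monoisotopic_mass = NA_real_,
    rt_min = c(100, 200, 300), rt_max = c(140, 240, 340),
    prior_weight = 1,
    stringsAsFactors = FALSE
  ), spectra = spectra, connections = connections)
}

# minimal feature set: one row per (mz, rt) with flat intensities
toy_features <- function(mz, rt, intensity = rep(1e6, length(mz)),
                         intensities = NULL) {
  ipa_features(data.frame(
    feature_id = sprintf("F%02d", seq_along(mz)),
    mz = mz, rt = rt, intensity = intensity,
    stringsAsFactors = FALSE
  ), intensities = intensities)
}

PROTON <- 1.00727646
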