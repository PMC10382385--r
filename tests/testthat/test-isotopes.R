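test_that("single-carbon pattern reads back the embedded isotope table", {
  p <- theoretical_pattern("C1", charge = 0)
  expect_equal(p$mz, c(12.0, 13.00335), tolerance = 1e-5)
  expect_equal(p$abundance, c(1, 0.0107 / 0.9893), tolerance = 1e-6)
})

test_that("patterns agree with exhaustive isotopologue enumeration", {
  set.seed(42)
  elements <- c("C", "H", "N", "O", "S", "Cl")
  for (rep in 1:50) {
    n_el <- sample(2:4, 1)
    els <- sample(elements, n_el)
    counts <- stats::setNames(sample(1:8, n_el, replace = TRUE), els)
    counts <- counts[cumsum(counts) <= 20] # at most 20 atoms
    if (!length(counts)) next
    formula <- paste0(names(counts), counts, collapse = "")
    pat <- theoretical_pattern(formula, charge = 0, min_abundance = 1e-6)
    oracle <- enumerate_isotopologues(counts)
    oracle$rel <- oracle$abundance / max(oracle$abundance)
    keep <- oracle$rel >= 1e-6
    for (i in which(keep)) {
      j <- which.min(abs(pat$mz - oracle$mass[i]))
      expect_lt(abs(pat$mz[j] - oracle$mass[i]), 0.01)
      expect_lt(abs(pat$abundance[j] - oracle$rel[i]), 1e-6)
    }
  }
})

test_that("glucose M+1/M+0 matches the first-order closed form", {
  pat <- theoretical_pattern("C6H12O6", charge = 0)
  ratio <- pat$abundance[2] / pat$abundance[1]
  closed <- m1_ratio_closed_form("C6H12O6")
  expect_equal(ratio, closed, tolerance = 1e-6)
  # hand value: 6*0.0107/0.9893 + 12*0.000115/0.999885 + 6*0.00038/0.99757
  expect_equal(closed, 0.06856, tolerance = 1e-4)
})

test_that("truncation and probability conservation behave", {
  p1 <- theoretical_pattern("C20H30N5O10", min_abundance = 1)
  expect_equal(nrow(p1), 1)
  # unscaled abundances conserve probability as the threshold vanishes
  p <- theoretical_pattern("C10H14N2O4", charge = 0, min_abundance = 1e-10)
  oracle <- enumerate_isotopologues(c(C = 10, H = 14, N = 2, O = 4))
  scale <- max(oracle$abundance)
  expect_lte(sum(p$abundance) * scale, 1 + 1e-9)
  expect_equal(sum(p$abundance) * scale, 1, tolerance = 1e-6)
})

test_that("adduct ions shift the pattern by the adduct arithmetic", {
  mh <- adduct_rule("[M+H]+", 1, formula_add = "H")
  p <- theoretical_pattern("C6H12O6", adduct = mh)
  expect_equal(p$mz[1], monoisotopic_mass("C6H12O6") + 1.00727646,
               tolerance = 1e-6)
  # removing atoms the molecule lacks is an error
  frag <- adduct_rule("[M-H2O+H]+", 1, formula_add = "H",
                      formula_remove = "H2O")
  expect_error(theoretical_pattern("C6H12", adduct = frag),
               "removes atoms")
})

test_that("isotope score is exact on closed-form cases", {
  pat <- theoretical_pattern("C6H12O6",
                             adduct = adduct_rule("[M+H]+", 1,
                                                  formula_add = "H"))
  # identical fingerprint -> 1
  fp <- data.frame(mz = pat$mz[1:2], ratio = pat$abundance[1:2])
  expect_equal(isotope_score(fp, pat), 1, tolerance = 1e-12)
  # doubled ratio, zero ppm, sigma_ratio = ln 2 -> geometric mean of
  # exp(0) (main) and exp(-1/2)
  fp2 <- data.frame(mz = pat$mz[1:2],
                    ratio = c(1, 2 * pat$abundance[2]))
  expect_equal(isotope_score(fp2, pat, sigma_ratio = log(2)),
               exp(-0.5 / 2), tolerance = 1e-10)
  # three-peak fingerprint equals the hand-computed per-peak product
  fp3 <- data.frame(
    mz = pat$mz[1:3] * (1 + c(0, 2, -1) * 1e-6),
    ratio = pat$abundance[1:3] * c(1, 1.2, 0.7))
  sigma_mz <- 5
  sigma_ratio <- 0.4
  by_hand <- exp(mean(
    -c(0, 2, -1)^2 / (2 * sigma_mz^2) -
      c(0, log(1.2), log(0.7))^2 / (2 * sigma_ratio^2)))
  expect_equal(isotope_score(fp3, pat, sigma_mz, sigma_ratio), by_hand,
               tolerance = 1e-6)
  # single-peak fingerprint carries no evidence
  expect_equal(isotope_score(fp[1, , drop = FALSE], pat), 1)
  # peak far outside 3 sigma -> 0
  fp_far <- data.frame(mz = c(pat$mz[1], pat$mz[2] + 0.5),
                       ratio = pat$abundance[1:2])
  expect_equal(isotope_score(fp_far, pat), 0)
})

test_that("isotope score decreases in ppm error and log-ratio error", {
  pat <- theoretical_pattern("C10H14N2O4", charge = 0)
  base <- data.frame(mz = pat$mz[1:2], ratio = pat$abundance[1:2])
  scores_ppm <- vapply(c(0, 1, 2, 4, 8), function(e) {
    fp <- base
    fp$mz <- fp$mz * (1 + e * 1e-6)
    isotope_score(fp, pat)
  }, numeric(1))
  expect_true(all(diff(scores_ppm) < 0))
  scores_ratio <- vapply(c(1, 1.3, 1.8, 2.5), function(m) {
    fp <- base
    fp$ratio[2] <- fp$ratio[2] * m
    isotope_score(fp, pat)
  }, numeric(1))
  expect_true(all(diff(scores_ratio) < 0))
})

test_that("the generating formula outscores carbon-count decoys", {
  set.seed(99)
  for (rep in 1:10) {
    nc <- sample(6:15, 1)
    nh <- sample(nc:(2 * nc), 1)
    no <- sample(1:6, 1)
    f_true <- paste0("C", nc, "H", nh, "O", no)
    pat_true <- theoretical_pattern(f_true, charge = 0)
    fp <- data.frame(mz = pat_true$mz[1:2], ratio = pat_true$abundance[1:2])
    s_true <- isotope_score(fp, pat_true)
    for (d in c(-2L, -1L, 1L, 2L)) {
      f_decoy <- paste0("C", nc + d, "H", nh, "O", no)
      s_decoy <- isotope_score(fp, theoretical_pattern(f_decoy, charge = 0))
      expect_gte(s_true, s_decoy)
    }
  }
})
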