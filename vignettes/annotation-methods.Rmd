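---
title: "Probabilistic annotation of LC-MS/MS features: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic annotation of LC-MS/MS features: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The annotation problem

An untargeted LC-MS/MS experiment yields thousands of MS1 features — peaks
characterized by m/z, retention time and intensity across samples. Deciding
which metabolite generated each feature (its *annotation*) is ambiguous:
many compounds share a nominal mass, one compound produces several features
(adducts such as [M+H]+ and [M+Na]+, in-source fragments, isotopologues),
and reference databases are incomplete. `metannot` treats annotation as
Bayesian inference: each annotatable unit receives a probability
distribution over candidate (compound, adduct) pairs, first from the
feature's own evidence (the prior), then refined by the evidence of its
neighbours in a connection network (the posterior).

## Step 0: data preparation

Three preparation steps turn a raw feature table into the engine's input.

*Clustering.* Features generated by one metabolite co-elute and co-vary
across samples. `cluster_features()` links two features when their RT
difference is at most `rt_window` (default 5 s) and their Pearson
correlation over samples observed in both is at least `min_corr` (default
0.8, requiring `min_samples = 3` shared observations; missing intensities
are treated as unobserved, not zero). Single-linkage components become
clusters. Single linkage is deliberate: adduct intensities are proportional
to each other, so any member chains the rest, and the RT window caps
chaining across the gradient.

*Isotope fingerprints.* Within a cluster, `map_isotope_patterns()` searches
each putative main peak (most intense first) for features at
`mz + k * 1.003355 / z` (the 13C-12C spacing; the charge z up to
`max_charge = 3` is chosen by the longest consistent series, ties by ppm),
with intensity ratio at most `ratio_max = 1`. Matched features are folded
into an isotope fingerprint — an ordered list of (m/z, ratio-to-main) — and
are no longer annotated separately. This both adds evidence (the
fingerprint) and shrinks the problem handed to the sampler, whose per-sweep
cost is the total candidate count. Choosing the most intense series member
as the main peak assumes the monoisotopic peak dominates, which holds for
small CHNO molecules but not for heavily brominated/chlorinated or very
large species — a documented limitation.

*MS2 assignment.* Measured fragmentation spectra attach to the feature with
the smallest precursor ppm error within `ms2_ppm = 10` ppm (and `ms2_rt =
10` s when the spectrum carries an RT); unassignable spectra are reported,
never fatal.

## Step 1: prior probabilities

For each unit, candidates are every (compound, adduct) pair of matching
polarity whose theoretical m/z lies within `ppm_window = 10` ppm. Each
candidate's unnormalized weight is the product of five factors:

* **prior belief** — the database `prior_weight` (default 1), a per-compound
  plausibility the user can curate between experiments;
* **m/z accuracy** — `exp(-ppm^2 / (2 sigma_ppm^2))`, `sigma_ppm = 3` ppm,
  matching Orbitrap-class calibration;
* **retention time** — 1 inside the database RT range (or when none is
  recorded: absent evidence is neutral), Gaussian falloff with
  `sigma_rt = 10` s outside;
* **isotope fingerprint** — the geometric mean over fingerprint peaks of
  Gaussian factors in the ppm deviation (`sigma_iso_mz = 5` ppm) and in the
  log intensity-ratio deviation (`sigma_iso_ratio = 0.4`); a peak with no
  theoretical partner within 3 sigma zeroes the score, and a single-peak
  fingerprint is neutral. The log-ratio metric makes a two-fold excess and
  a two-fold deficit cost the same. The functional form (Gaussian on both
  axes, combined by geometric mean) is this package's construction; the
  two difference axes — m/z and intensity ratio — are the standard ones.
  Ratios, not absolute intensities, are compared, because absolute response
  depends on ionization efficiency, which the theory does not predict;
* **MS2 similarity** — the maximum cosine over all (measured, library)
  spectrum pairs. Intensities are square-root transformed before the cosine
  (the usual damping of base-peak dominance; raw cosine is available via
  `sqrt_intensity = FALSE`), and matching is greedy, intensity-ordered and
  one-to-one with `ms2_tol = 0.05` Da — deterministic and O(n log n) rather
  than an optimal assignment. Candidates without library spectra receive
  the user-defined `dummy_score = 0.5`, the uninformative midpoint, so that
  library coverage does not by itself decide the ranking; features without
  measured spectra score a neutral 1 everywhere.

Theoretical isotope patterns are aggregated (unit-resolution) isotopologue
distributions: per-element distributions from the embedded isotope table
are convolved by repeated squaring, peaks merged within `bin_width = 0.05`
Da by abundance-weighted mean mass, and the ion's m/z values account for
the adduct atoms, the electron mass and the charge. Fine isotopic structure
is out of scope — at the resolution of the instruments this targets, the
aggregated pattern is what is measured. Convolution dust below 1e-12 is
pruned for numerical hygiene; truncation to `min_abundance` happens only
after scaling, so probability is conserved as the threshold vanishes
(verified against exhaustive enumeration to 1e-6).

A per-unit **unknown** pseudo-candidate with weight `unknown_frac = 0.05`
times the best candidate weight guards against certainty by elimination: a
unit whose only candidates are wrong would otherwise be forced to 100%
confidence in one of them. The weights are then normalized to a
distribution. With no candidates at all, the unknown takes probability 1.

## Step 2: posterior probabilities by Gibbs sampling

Two edge families connect candidates of *different* units:

* **biochemical** — the two compounds are curated neighbours
  (`db_edges` mode) or their neutral masses differ by one of ~30 shipped
  single-step transformation masses (methylation, hydroxylation,
  glycosylation, phosphorylation, common conjugations, ...) within 10 ppm
  (`mass_diff` mode). The shipped table is a package default and is
  replaceable.
* **adduct/in-source** — the same compound annotating two features of one
  cluster under different adduct rules.

The sampler resamples one unit at a time (systematic scan, unit index
ascending, for reproducibility; a random scan is available) from

```
P(a | rest)  ∝  prior(a) · (n_bio(a) + delta_bio) · (n_add(a) + delta_add)
```

where `n_bio`/`n_add` count currently assigned candidates in other units
connected to `a`, and `delta_bio = delta_add = 1` are pseudo-counts that
keep unconnected candidates alive. Posteriors are visit frequencies over
`n_iter = 5000` sweeps after `burn_in = 1000`; a crude convergence check
(the largest visit-frequency difference between the two post-burn-in chain
halves) is logged on every run. Unknown pseudo-candidates carry no edges,
acting as the no-network null. All randomness flows through R's RNG, so a
seed makes runs bit-identical; the Rcpp inner loop draws from the same
stream.

One subtlety is worth recording. For two units the pseudo-count conditional
is the exact full conditional of the product-form joint
`P(x1, x2) ∝ p1 p2 (delta + [edge])`, but for more units no product-form
joint has these conditionals; the scan chain is still an ergodic Markov
chain with a well-defined stationary law. The correctness tests therefore
enumerate that stationary distribution exactly — building the full scan
kernel over the joint state space and marginalizing its fixed point — and
require the sampler's visit frequencies to match it in total variation,
rather than assuming a factorized target.

## The synthetic-data generator

`simulate_dataset()` emulates an ESI positive-mode run over a small
metabolome and is the package's test bed. Per true compound (default 15,
the scale of a spiked standard mix): a valence-plausible CHNO formula; an
RT apex on a jittered grid over a 60-540 s gradient (so compounds stay
resolved at any density); a primary adduct feature plus each further
adduct with probability 0.4; m/z perturbed by `sigma_ppm = 3` ppm; an M+1
isotopologue at the exact first-order abundance ratio perturbed on the log
scale; per-sample intensities that are exact scalar multiples within a
compound (biological variation times adduct efficiency) with
`sigma_log_intensity = 0.2` multiplicative noise; and, for 30% of
compounds, a random 8-peak library spectrum whose jittered copy is the
measured MS2. Decoy database entries (2 per compound) sit 1-10 ppm from
the true mass with a carbon count shifted by one, so m/z and isotope
evidence degrade but do not vanish; `decoy_same_formula = TRUE` instead
creates exact isobars distinguishable only by MS2. Biochemical edges
connect true compounds with density 0.3, and decoys never get edges —
which is exactly the asymmetry the posterior step exploits.

What the generator does *not* emulate: chromatographic peak-shape overlap,
correlated (matrix) noise across compounds, in-source fragmentation beyond
the water-loss rule, charge states above 1 for generated features, missing
values, and library spectra of wrong-but-related compounds. Passing tests
therefore demonstrate the statistical machinery under its own model
assumptions, not performance on real chromatograms.

Accuracy is scored as top-1 with tie splitting (`top1_accuracy()`): a unit
where the truth ties k-1 rivals at the maximum scores 1/k. Without this, a
deterministic tie-break on compound id would silently award exact isobars
to whichever sorts first.

## Numerical and design choices

* Element isotope masses and abundances are embedded (single authority,
  versioned in-repo); the proton mass constant is 1.00727646 Da and adduct
  shifts are derived from atom deltas and the electron mass.
* Candidate retrieval orders by |ppm|, breaking ties by compound id then
  adduct name, so output is permutation-invariant.
* A candidate whose every factor underflows to zero yields the unknown with
  probability 1 rather than NaN.
* Degenerate inputs: empty databases and unassignable spectra are reported,
  not errors; constant intensity vectors have undefined correlation and are
  simply not linked; a feature claimed by two isotopologue series goes to
  the smaller ppm deviation, logged.
* Problem sizes used by the test suite and the acceptance script — 50
  sampler instances of at most 4 units by 3 candidates at 50,000 sweeps
  against exact enumeration, 50 random formulas of at most 20 atoms against
  exhaustive isotopologue expansion, 20 replicate simulations for the MS2
  and network comparisons, and around 1,000 units for normalization checks
  — were chosen so the full battery exercises every code path at
  desk-machine scale.

## Known limitations

* `db_edges` bio mode needs a curated edge list; `mass_diff` mode will
  happily connect coincidental mass differences at loose tolerances.
* The greedy cosine can differ from the optimal assignment on pathological
  peak layouts (many near-duplicate m/z values within tolerance).
* RT evidence is a range plus Gaussian tails, not a retention model; units
  are seconds throughout (readers convert minutes on request).
* The sampler's pseudo-count conditionals are the method's definition, not
  a factorized posterior; interpret posteriors as network-smoothed
  confidence scores calibrated by the tests above.
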