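# Physical constants and the embedded element isotope table.
# Isotopic masses and abundances from the CODATA/NIST atomic weights
# compilation (2021 values, truncated to the precision useful at
# Orbitrap-class resolution). The table is versioned here, in-repo.

PROTON_MASS <- 1.00727646
ELECTRON_MASS <- 0.000548579909
ISO_SPACING <- 1.003355 # 13C - 12C mass difference, Da

# per element: isotope masses (Da) and natural abundances (sum to 1),
# ordered by increasing mass; the principal isotope is the most abundant.
ELEMENT_ISOTOPES <- list(
  C  = list(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.00782503207, 2.01410177812),
            abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.00307400443, 15.00010889888),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376199842, abundance = 1),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.9897692820, abundance = 1),
  K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Cl = list(mass = c(34.968852682, 36.965902602),
            abundance = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  F  = list(mass = 18.99840316273, abundance = 1),
  Si = list(mass = c(27.97692653465, 28.97649466490, 29.973770136),
            abundance = c(0.92223, 0.04685, 0.03092))
)

SUPPORTED_ELEMENTS <- names(ELEMENT_ISOTOPES)
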