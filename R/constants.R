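# Physical constants and residue tables used throughout.
# All masses are monoisotopic, in Da. Pinned in one place so that the
# 4-decimal-place marker m/z values are reproducible bit-for-bit.

PROTON_MASS   <- 1.00727646688
NEUTRON_SPACING <- 1.0033548378  # average isotopologue spacing (13C - 12C)

# Isotope tables: per element, a matrix with columns mass (Da) and
# abundance (fraction). First row is the lightest (monoisotopic) isotope.
# Values: IUPAC/NIST standard atomic compositions.
.ISOTOPES <- list(
  C = cbind(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  H = cbind(mass = c(1.0078250319, 2.0141017780),
            abundance = c(0.999885, 0.000115)),
  N = cbind(mass = c(14.0030740052, 15.0001088984),
            abundance = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.9949146221, 16.9991315, 17.9991604),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S = cbind(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = cbind(mass = 30.97376151, abundance = 1.0)
)

.ELEMENTS <- names(.ISOTOPES)

# Monoisotopic mass of one atom of each element.
.ELEMENT_MONO <- vapply(.ISOTOPES, function(m) m[1, "mass"], numeric(1))

WATER_MASS <- 2 * .ELEMENT_MONO[["H"]] + .ELEMENT_MONO[["O"]]  # 18.0105646

# Residue (amino-acid minus water) elemental formulas for the 20 standard
# one-letter codes. I and L are distinct letters with identical formulas.
.RESIDUE_FORMULA <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0, P = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0, P = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0, P = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0, P = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0, P = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0, P = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1, P = 0),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0, P = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0, P = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0, P = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0, P = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0, P = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0, P = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0, P = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1, P = 0),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0, P = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0, P = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0, P = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0, P = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0, P = 0)
)

.formulaMass <- function(counts) {
  sum(counts[.ELEMENTS] * .ELEMENT_MONO)
}

# Residue monoisotopic masses derived from the formulas above, so mass and
# composition can never disagree.
.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, .formulaMass, numeric(1))
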