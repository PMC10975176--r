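# Monoisotopic atomic masses (CODATA/IUPAC values, Da). CHNOS only: short
# venom peptides and the modifications handled here contain nothing else.
.ATOMIC <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.ELECTRON <- 0.00054857991
.PROTON   <- 1.00727646688

.MASS_H2O <- 2 * .ATOMIC[["H"]] + .ATOMIC[["O"]]          # 18.010565
.MASS_NH3 <- 3 * .ATOMIC[["H"]] + .ATOMIC[["N"]]          # 17.026549
.MASS_CO  <- .ATOMIC[["C"]] + .ATOMIC[["O"]]              # 27.994915
.MASS_CO2 <- .ATOMIC[["C"]] + 2 * .ATOMIC[["O"]]          # 43.989829
.MASS_NH2 <- .MASS_NH3 - .ATOMIC[["H"]]                   # 16.018724, y -> z. offset
.MASS_C2H5 <- 2 * .ATOMIC[["C"]] + 5 * .ATOMIC[["H"]]     # 29.039125, Ile w-loss
.MASS_C3H7 <- 3 * .ATOMIC[["C"]] + 7 * .ATOMIC[["H"]]     # 43.054775, Leu w-loss

# Residue (chain) elemental compositions of the 20 standard amino acids.
# 'J' is the Ile/Leu ambiguity symbol (identical composition C6H11NO).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  J = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",
  Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",
  H = "C6H7N3O",  F = "C9H9NO",   R = "C6H12N4O", W = "C11H10N2O",
  Y = "C9H9NO2"
)

# Immonium ion m/z = residue - CO + proton (singly charged cation).
.IMMONIUM_OFFSET <- -(.MASS_CO) + .PROTON

# I/L immonium diagnostics used by the MS3 resolver and simulator.
.IMM_IL  <- 113.08406398 - .MASS_CO + .PROTON             # 86.0964
.IMM_69  <- .IMM_IL - .MASS_NH3                           # 69.0699
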