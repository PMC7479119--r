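# Amino-acid alphabets and per-residue property scales used by the featurizer.
# All scales are indexed by the 20 standard one-letter codes; 'X' (unknown)
# carries NA and is excluded from window averages.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order. The
#' package additionally accepts `"X"` for unknown or non-standard residues.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Kyte-Doolittle hydropathy index
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Chou-Fasman secondary-structure propensities (helix, sheet, turn)
CHOU_FASMAN_HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)
CHOU_FASMAN_SHEET <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
  G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
  M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
  S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47
)
CHOU_FASMAN_TURN <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60,
  G = 1.56, H = 0.95, I = 0.47, K = 1.01, L = 0.59,
  M = 0.60, N = 1.56, P = 1.52, Q = 0.98, R = 0.95,
  S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14
)

# Isoelectric point of the free amino acid
AA_PI <- c(
  A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48,
  G = 5.97, H = 7.59, I = 6.02, K = 9.74, L = 5.98,
  M = 5.74, N = 5.41, P = 6.30, Q = 5.65, R = 10.76,
  S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66
)

# Vihinen normalized B-factor flexibility scale
AA_FLEXIBILITY <- c(
  A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915,
  G = 1.031, H = 0.950, I = 0.927, K = 1.102, L = 0.935,
  M = 0.952, N = 1.048, P = 1.049, Q = 1.037, R = 1.008,
  S = 1.046, T = 0.997, V = 0.931, W = 0.904, Y = 0.929
)

# Side-chain charge at pH 7 (His given a partial positive charge)
AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0,
  G = 0, H = 0.1, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1,
  S = 0, T = 0, V = 0, W = 0, Y = 0
)

# Residue classes used by windowed class-fraction features and by the
# hydrophobic-cluster mask. The disorder/order promoting sets follow the
# standard propensity ordering (Gly/Pro/polar promote disorder; bulky
# hydrophobics promote order).
HYDROPHOBIC_SET <- c("V", "I", "L", "F", "M", "Y", "W")
AROMATIC_SET <- c("F", "W", "Y", "H")
DISORDER_PROMOTING_SET <- c("G", "P", "S", "Q", "E", "K")
ORDER_PROMOTING_SET <- c("W", "I", "F", "Y", "L", "V")

# Bundled short-linear-motif patterns (ELM-style regular expressions),
# version 1. Deliberately small; the motif channel only needs to flag
# plausible interaction motifs, not be exhaustive.
SLIM_MOTIFS_V1 <- c(
  slim_sh3        = "P..P",
  slim_sh2_ptyr   = "Y..[ILVM]",
  slim_14_3_3     = "R..[ST].P",
  slim_cyclin_rxl = "[RK].L.{0,1}[FYLIVMP]",
  slim_pdz_cterm  = "[ST].[VIL]$",
  slim_kim_dock   = "[KR]{2}.{2,4}[LIV].[LIV]",
  slim_nls_mono   = "K[KR].[KR]",
  slim_deg_dbox   = "R..L..[LIVM]"
)

# splits a sequence string into a character vector of single letters
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}
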