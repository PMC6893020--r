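# Residue-level physical constants used throughout the package.
# Monoisotopic and average residue (i.e. amino acid minus water) masses in Da,
# cross-checked against standard atomic-composition tables.

#' @keywords internal
AA_MONO <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)

#' @keywords internal
AA_AVG <- c(
  G = 57.05140, A = 71.07802, S = 87.07742, P = 97.11537,
  V = 99.13125, T = 101.10404, C = 103.14281, L = 113.15787,
  I = 113.15787, N = 114.10280, D = 115.08757, Q = 128.12942,
  K = 128.17252, E = 129.11418, M = 131.19604, H = 137.13952,
  F = 147.17420, R = 156.18592, Y = 163.17360, W = 186.21031
)

# Total nitrogen atoms per residue: one backbone amide N each, plus
# side-chain N for K (1), R (3), H (2), N (1), Q (1), W (1).
#' @keywords internal
AA_NITROGEN <- c(
  G = 1L, A = 1L, S = 1L, P = 1L, V = 1L, T = 1L, C = 1L, L = 1L,
  I = 1L, N = 2L, D = 1L, Q = 2L, K = 2L, E = 1L, M = 1L, H = 3L,
  F = 1L, R = 4L, Y = 1L, W = 2L
)

#' @keywords internal
WATER_MONO <- 18.0105646837

#' @keywords internal
WATER_AVG <- 18.0152864349

# Proton mass for the [M+H]+ adduct (singly protonated MALDI ions).
#' @keywords internal
PROTON <- 1.007276467

# Mass difference between 15N and 14N in Da; a uniformly enriched peptide
# shifts by enrichment * n_nitrogen * this value.
#' @keywords internal
N15_SHIFT <- 0.9970349

#' @keywords internal
CANONICAL_AA <- names(AA_MONO)
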