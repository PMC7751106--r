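#' @keywords internal
"_PACKAGE"

## Canonical amino-acid order used throughout the package: alphabetical by
## one-letter code. All readers permute external column orders into this one.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Column order of PSI-BLAST ASCII PSSM exports.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Raw physico-chemical scales behind the pseudo-composition correlation
## factors, in the convention of the original pseudo-composition literature:
## Tanford transfer free-energy hydrophobicity, Hopp-Woods hydrophilicity,
## and side-chain masses. Config-replaceable via aa_scales(raw = ...).
RAW_SCALES <- list(
  hydrophobicity = c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                     G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                     M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                     S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26),
  hydrophilicity = c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                     G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                     M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                     S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  mass           = c(A = 15, C = 47, D = 59, E = 73, F = 91,
                     G = 1, H = 82, I = 57, K = 73, L = 57,
                     M = 75, N = 58, P = 42, Q = 72, R = 101,
                     S = 31, T = 45, V = 43, W = 130, Y = 107)
)

## Swiss-Prot-style background amino-acid frequencies (percent), used by the
## synthetic generator as the non-membrane residue composition.
BACKGROUND_FREQ <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86,
                     G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
                     M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
                     S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)

## BLOSUM62 log-odds (half-bit) scores restricted to the 20 standard residues,
## alphabetical order; seeds the synthetic profile rows.
BLOSUM62_20 <- matrix(c(
   4, 0,-2,-1,-2, 0,-2,-1,-1,-1,-1,-2,-1,-1,-1, 1, 0, 0,-3,-2,
   0, 9,-3,-4,-2,-3,-3,-1,-3,-1,-1,-3,-3,-3,-3,-1,-1,-1,-2,-2,
  -2,-3, 6, 2,-3,-1,-1,-3,-1,-4,-3, 1,-1, 0,-2, 0,-1,-3,-4,-3,
  -1,-4, 2, 5,-3,-2, 0,-3, 1,-3,-2, 0,-1, 2, 0, 0,-1,-2,-3,-2,
  -2,-2,-3,-3, 6,-3,-1, 0,-3, 0, 0,-3,-4,-3,-3,-2,-2,-1, 1, 3,
   0,-3,-1,-2,-3, 6,-2,-4,-2,-4,-3, 0,-2,-2,-2, 0,-2,-3,-2,-3,
  -2,-3,-1, 0,-1,-2, 8,-3,-1,-3,-2, 1,-2, 0, 0,-1,-2,-3,-2, 2,
  -1,-1,-3,-3, 0,-4,-3, 4,-3, 2, 1,-3,-3,-3,-3,-2,-1, 3,-3,-1,
  -1,-3,-1, 1,-3,-2,-1,-3, 5,-2,-1, 0,-1, 1, 2, 0,-1,-2,-3,-2,
  -1,-1,-4,-3, 0,-4,-3, 2,-2, 4, 2,-3,-3,-2,-2,-2,-1, 1,-2,-1,
  -1,-1,-3,-2, 0,-3,-2, 1,-1, 2, 5,-2,-2, 0,-1,-1,-1, 1,-1,-1,
  -2,-3, 1, 0,-3, 0, 1,-3, 0,-3,-2, 6,-2, 0, 0, 1, 0,-3,-4,-2,
  -1,-3,-1,-1,-4,-2,-2,-3,-1,-3,-2,-2, 7,-1,-2,-1,-1,-2,-4,-3,
  -1,-3, 0, 2,-3,-2, 0,-3, 1,-2, 0, 0,-1, 5, 1, 0,-1,-2,-2,-1,
  -1,-3,-2, 0,-3,-2, 0,-3, 2,-2,-1, 0,-2, 1, 5,-1,-1,-3,-3,-2,
   1,-1, 0, 0,-2, 0,-1,-2, 0,-2,-1, 1,-1, 0,-1, 4, 1,-2,-3,-2,
   0,-1,-1,-1,-2,-2,-2,-1,-1,-1,-1, 0,-1,-1,-1, 1, 5, 0,-2,-2,
   0,-1,-3,-2,-1,-3,-3, 3,-2, 1, 1,-3,-2,-2,-3,-2, 0, 4,-3,-1,
  -3,-2,-4,-3, 1,-2,-2,-3,-3,-2,-1,-4,-4,-2,-3,-3,-2,-3,11, 2,
  -2,-2,-3,-2, 3,-3, 2,-1,-2,-1,-1,-2,-3,-1,-2,-2,-2,-1, 2, 7),
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, AA_ALPHABET))

## Ambiguity-code mapping used by the "map" alphabet policy.
AMBIGUITY_MAP <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")
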