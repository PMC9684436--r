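# Amino-acid constant tables shared across modules.

#' @name aa-tables
#' @title Amino-acid constant tables
#' @description
#' Internal lookup tables: the 20-letter alphabet (plus the ambiguity code
#' `X`), average residue masses, one-/three-letter code conversion, residue
#' hydropathy scales and coarse per-residue effective radii.
#' @keywords internal
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA_ALPHABET <- c(.AA20, "X")

# Average (isotope-abundance weighted) residue masses in Da, i.e. the mass of
# the amino acid minus one water; the free chain adds one water (18.0153 Da).
.AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326,
  X = 110.0000)

.WATER_AVG_MASS <- 18.0153

.AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # common non-standard residues mapped to their parent code
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", MLY = "K", M3L = "K")

.AA_123 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK")

# Kyte-Doolittle hydropathy (positive = hydrophobic), plus two alternatives.
.HYDROPATHY_SCALES <- list(
  kd = c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9,
         M =  1.9, F =  2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V =  4.2, X =  0.0),
  hw = c(A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0, Q =  0.2,
         E =  3.0, G =  0.0, H = -0.5, I = -1.8, L = -1.8, K =  3.0,
         M = -1.3, F = -2.5, P =  0.0, S =  0.3, T = -0.4, W = -3.4,
         Y = -2.3, V = -1.5, X =  0.0),
  eisenberg = c(A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
                Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
                L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
                S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08,
                X =  0.00))

# Mean residue volumes (Zamyatnin), converted to an effective single-sphere
# radius per residue: r = (3V / 4 pi)^(1/3).  Used by the CA-coarse SASA.
.AA_VOLUME <- c(
  A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G =  60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S =  89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0, X = 141.0)

.AA_RADIUS <- (.AA_VOLUME * 3 / (4 * pi))^(1 / 3)

aa_split <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

check_alphabet <- function(sequence, what = "sequence") {
  chars <- aa_split(sequence)
  bad <- setdiff(unique(chars), .AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains letters outside the amino-acid alphabet: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(chars)
}

aa_three_to_one <- function(resid3) {
  out <- unname(.AA_321[toupper(resid3)])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(res1) {
  out <- unname(.AA_123[res1])
  out[is.na(out)] <- "UNK"
  out
}

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero to `digits` decimals (report convention; R's
# round() uses banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
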