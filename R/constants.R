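# Published constant tables used across the package. All values are the
# standard literature values (standard genetic code table 1; Kyte & Doolittle
# 1982 hydropathy; Expasy average residue masses; Bjellqvist pKa set;
# Guruprasad et al. 1990 dipeptide instability weights).

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

DNA_BASES <- c("A", "C", "G", "T")

#' The standard genetic code as a tidy table
#'
#' One row per codon of the standard genetic code (NCBI translation table 1),
#' with the encoded amino acid (`*` for stop) and the synonymous-family
#' degeneracy of that amino acid.
#'
#' @param render `"dna"` for T-containing codons, `"rna"` to render with U
#'   (the convention used in codon-usage reports).
#' @return A tibble with columns `codon`, `aa`, `degeneracy`.
#' @export
#' @examples
#' genetic_code_table()
genetic_code_table <- function(render = c("dna", "rna")) {
  render <- match.arg(render)
  gc <- Biostrings::GENETIC_CODE
  tbl <- tibble::tibble(codon = names(gc), aa = unname(gc))
  deg <- table(tbl$aa[tbl$aa != "*"])
  tbl$degeneracy <- ifelse(tbl$aa == "*", NA_integer_,
                           as.integer(deg[tbl$aa]))
  if (render == "rna") tbl$codon <- chartr("T", "U", tbl$codon)
  tbl
}

# internal fast lookups ------------------------------------------------------

.codon_env <- new.env(parent = emptyenv())

codon_map <- function() {
  if (is.null(.codon_env$map)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$map <- gc
    .codon_env$stops <- names(gc)[gc == "*"]
    .codon_env$sense <- names(gc)[gc != "*"]
    deg <- table(gc[gc != "*"])
    .codon_env$degeneracy <- stats::setNames(as.integer(deg), names(deg))
  }
  .codon_env$map
}

stop_codons <- function() {
  codon_map()
  .codon_env$stops
}

sense_codons <- function() {
  codon_map()
  .codon_env$sense
}

aa_degeneracy <- function() {
  codon_map()
  .codon_env$degeneracy
}

#' Kyte-Doolittle hydropathy values
#'
#' Per-residue hydropathy indices of Kyte & Doolittle (1982). Positive values
#' are hydrophobic; isoleucine (4.5) and arginine (-4.5) are the extremes.
#'
#' @return Named numeric vector over the 20 standard amino-acid letters.
#' @export
kd_hydropathy <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

# Average masses of the free amino acids (Da); a chain of length L weighs
# sum(masses) - (L - 1) * water.
AA_AVG_MASS <- c(
  A =  89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G =  75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)
WATER_MASS <- 18.0153

# Bjellqvist pKa set (as used by Expasy/Biopython), including the
# first/last-residue adjustments of the terminal pKa values.
PKA_SETS <- list(
  bjellqvist = list(
    pos = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    neg = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    nterm_adjust = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                     V = 7.44, E = 7.7),
    cterm_adjust = c(D = 4.55, E = 4.75)
  ),
  # EMBOSS iep default pKa values (no terminal-residue adjustments)
  emboss = list(
    pos = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    neg = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    nterm_adjust = c(), cterm_adjust = c()
  )
)

# Guruprasad et al. (1990) dipeptide instability weight values (DIWV).
# 20x20 matrix; rows = first residue, cols = second residue of the dipeptide.
diwv_matrix <- function() {
  if (!is.null(.codon_env$diwv)) return(.codon_env$diwv)
  m <- matrix(1.0, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  set <- function(first, ...) {
    v <- c(...)
    m[first, names(v)] <<- v
  }
  set("A", C = 44.94, D = -7.49, H = -7.49, P = 20.26)
  set("C", D = 20.26, H = 33.60, M = 33.60, L = 20.26, Q = -6.54,
      P = 20.26, T = 33.60, W = 24.68, V = -6.54)
  set("D", F = -6.54, K = -7.49, S = 20.26, R = -6.54, T = -14.03)
  set("E", C = 44.94, E = 33.60, D = 20.26, I = 20.26, H = -6.54,
      Q = 20.26, P = 20.26, S = 20.26, W = -14.03)
  set("F", D = 13.34, K = -14.03, P = 20.26, Y = 33.601)
  set("G", A = -7.49, E = -6.54, G = 13.34, I = -7.49, K = -7.49,
      N = -7.49, T = -7.49, W = 13.34, Y = -7.49)
  set("H", G = -9.37, F = -9.37, I = 44.94, K = 24.68, N = 24.68,
      P = -1.88, T = -6.54, W = -1.88, Y = 44.94)
  set("I", E = 44.94, H = 13.34, K = -7.49, L = 20.26, P = -1.88,
      V = -7.49)
  set("K", G = -7.49, I = -7.49, M = 33.60, L = -7.49, Q = 24.64,
      P = -6.54, R = 33.60, V = -7.49)
  set("L", K = -7.49, Q = 33.60, P = 20.26, R = 20.26, W = 24.68)
  set("M", A = 13.34, H = 58.28, M = -1.88, Q = -6.54, P = 44.94,
      S = 44.94, R = -6.54, T = -1.88, Y = 24.68)
  set("N", C = -1.88, G = -14.03, F = -14.03, I = 44.94, K = 24.68,
      Q = -6.54, P = -1.88, T = -7.49, W = -9.37)
  set("P", A = 20.26, C = -6.54, E = 18.38, D = -6.54, F = 20.26,
      M = -6.54, Q = 20.26, P = 20.26, S = 20.26, R = -6.54,
      W = -1.88, V = 20.26)
  set("Q", C = -6.54, E = 20.26, D = 20.26, F = -6.54, Q = 20.26,
      P = 20.26, S = 44.94, V = -6.54, Y = -6.54)
  set("R", G = -7.49, H = 20.26, N = 13.34, Q = 20.26, P = 20.26,
      S = 44.94, R = 58.28, W = 58.28, Y = -6.54)
  set("S", C = 33.60, E = 20.26, Q = 20.26, P = 44.94, S = 20.26,
      R = 20.26)
  set("T", E = 20.26, G = -7.49, F = 13.34, N = -14.03, Q = -6.54,
      W = -14.03)
  set("V", D = -14.03, G = -7.49, K = -1.88, P = 20.26, T = -7.49,
      Y = -6.54)
  set("W", A = -14.03, G = -9.37, H = 24.68, M = 24.68, L = 13.34,
      N = 13.34, T = -14.03, V = -7.49)
  set("Y", A = 24.68, E = -6.54, D = 24.68, G = -7.49, H = 13.34,
      M = 44.94, P = 13.34, R = -15.91, T = -7.49, W = -9.37,
      Y = 13.34)
  .codon_env$diwv <- m
  m
}
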