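# Physio-chemical protein profiling: the classic Expasy-style parameter
# bundle (molecular weight, pI, instability and aliphatic indices, GRAVY,
# extinction coefficient) plus composition and residue-set fractions.

check_protein <- function(s, id = "<seq>") {
  if (nchar(s) == 0) rlang::abort(paste0("empty protein: ", id))
  bad <- gsub(paste0("[", paste(AA_LETTERS, collapse = ""), "]"), "", s)
  if (nchar(bad) > 0) {
    rlang::abort(paste0("protein '", id, "' has non-standard letters: ",
                        paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  }
  invisible(s)
}

aa_counts_one <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = AA_LETTERS))
}

#' Amino-acid composition
#'
#' @param x A protein sequence tibble.
#' @return A long tibble with columns `id`, `species`, `aa`, `count`,
#'   `percent` (mole percent); counts sum to the protein length.
#' @export
aa_composition <- function(x) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    check_protein(x$seq[i], x$id[i])
    tab <- aa_counts_one(x$seq[i])
    tibble::tibble(id = x$id[i], species = x$species[i],
                   aa = AA_LETTERS, count = as.integer(tab),
                   percent = 100 * as.integer(tab) / nchar(x$seq[i]))
  })
}

#' Molecular weight (average masses)
#'
#' Sum of average free amino-acid masses minus one water per peptide bond
#' (equivalently: average residue masses plus one water), in Daltons.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector of masses in Da. Divide by 1000 and round to 2
#'   decimals for the conventional kDa report.
#' @export
molecular_weight <- function(seq) {
  vapply(seq, function(s) {
    check_protein(s)
    sum(AA_AVG_MASS[strsplit(s, "")[[1]]]) - (nchar(s) - 1) * WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

protein_charge <- function(counts, nterm, cterm, pH, pka) {
  pos <- pka$pos
  neg <- pka$neg
  if (nterm %in% names(pka$nterm_adjust)) {
    pos[["Nterm"]] <- pka$nterm_adjust[[nterm]]
  }
  if (cterm %in% names(pka$cterm_adjust)) {
    neg[["Cterm"]] <- pka$cterm_adjust[[cterm]]
  }
  n_of <- function(a) if (a %in% c("Nterm", "Cterm")) 1 else counts[[a]]
  positive <- sum(vapply(names(pos), function(a) {
    n_of(a) / (10^(pH - pos[[a]]) + 1)
  }, numeric(1)))
  negative <- sum(vapply(names(neg), function(a) {
    n_of(a) / (10^(neg[[a]] - pH) + 1)
  }, numeric(1)))
  positive - negative
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge over the termini and the
#' ionizable side chains (D, E, C, Y, H, K, R) crosses zero, found by
#' bisection to 1e-3 pH units.
#'
#' @param seq Character vector of protein sequences.
#' @param pka_set `"bjellqvist"` (Expasy-style, default) or `"emboss"`.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(seq, pka_set = c("bjellqvist", "emboss")) {
  pka_set <- match.arg(pka_set)
  pka <- PKA_SETS[[pka_set]]
  vapply(seq, function(s) {
    check_protein(s)
    counts <- as.list(aa_counts_one(s))
    nterm <- substr(s, 1, 1)
    cterm <- substr(s, nchar(s), nchar(s))
    lo <- 0; hi <- 14
    # net charge is monotone decreasing in pH, so plain bisection converges
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      q <- protein_charge(counts, nterm, cterm, mid, pka)
      if (q > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-4) break
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic: II = (10 / L) * sum of the
#' published weight of each consecutive dipeptide. Proteins with II below 40
#' are conventionally called stable.
#'
#' @param seq Character vector of protein sequences (length >= 2 each).
#' @return Numeric vector.
#' @export
instability_index <- function(seq) {
  w <- diwv_matrix()
  vapply(seq, function(s) {
    check_protein(s)
    if (nchar(s) < 2) rlang::abort("instability index needs length >= 2")
    ch <- strsplit(s, "")[[1]]
    first <- ch[-length(ch)]
    second <- ch[-1]
    10 / nchar(s) * sum(w[cbind(first, second)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Aliphatic index
#'
#' AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu), with X the mole percents;
#' the relative volume occupied by aliphatic side chains.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector.
#' @export
aliphatic_index <- function(seq) {
  vapply(seq, function(s) {
    check_protein(s)
    x <- 100 * aa_counts_one(s) / nchar(s)
    x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values
#' indicate a net hydrophobic protein.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector.
#' @export
gravy <- function(seq) {
  kd <- kd_hydropathy()
  vapply(seq, function(s) {
    check_protein(s)
    mean(kd[strsplit(s, "")[[1]]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sulfur atom count
#'
#' Number of sulfur atoms = #Cys + #Met (one sulfur each).
#'
#' @param seq Character vector of protein sequences.
#' @return Integer vector.
#' @export
sulfur_count <- function(seq) {
  vapply(seq, function(s) {
    check_protein(s)
    tab <- aa_counts_one(s)
    as.integer(tab[["C"]] + tab[["M"]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Extinction coefficient at 280 nm
#'
#' Expasy convention: 5500 per Trp + 1490 per Tyr, plus 125 per cystine
#' (floor(#Cys / 2) pairs) in the oxidized form.
#'
#' @param seq Character vector of protein sequences.
#' @return A tibble with columns `reduced` and `cystines` (M^-1 cm^-1).
#' @export
extinction_coefficient <- function(seq) {
  purrr::map_dfr(seq, function(s) {
    check_protein(s)
    tab <- aa_counts_one(s)
    red <- 5500 * tab[["W"]] + 1490 * tab[["Y"]]
    tibble::tibble(reduced = red,
                   cystines = red + 125 * (tab[["C"]] %/% 2))
  })
}

#' Default residue sets for charge/hydropathy fractions
#'
#' @return Named list with elements `negative`, `positive`, `hydrophobic`,
#'   `hydrophilic`.
#' @export
default_residue_sets <- function() {
  list(
    negative = c("D", "E"),
    positive = c("K", "R", "H"),
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W"),
    hydrophilic = c("D", "E", "G", "H", "K", "N", "Q", "R", "S", "T", "Y")
  )
}

#' Charged and hydropathic residue fractions
#'
#' Fraction of residues falling in each configured residue set. Defaults:
#' negative = D,E; positive = K,R,H; hydrophobic = A,C,F,I,L,M,V,W;
#' hydrophilic = D,E,G,H,K,N,Q,R,S,T,Y. The hydrophobic/hydrophilic split is
#' tool-specific (published grids often use undocumented partitions), so the
#' sets are exposed; override `residue_sets` to match a given tool.
#'
#' @param x A protein sequence tibble.
#' @param residue_sets Named list of character vectors (see
#'   `default_residue_sets()`); the negative and positive sets must not
#'   overlap.
#' @return A tibble `id`, `species`, then one fraction column per set.
#' @export
charge_and_hydropathy_fractions <- function(x,
                                            residue_sets = default_residue_sets()) {
  if (length(intersect(residue_sets$negative, residue_sets$positive)) > 0) {
    rlang::abort("negative and positive residue sets overlap")
  }
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    check_protein(x$seq[i], x$id[i])
    ch <- strsplit(x$seq[i], "")[[1]]
    fr <- lapply(residue_sets, function(set) mean(ch %in% set))
    dplyr::bind_cols(tibble::tibble(id = x$id[i], species = x$species[i]),
                     tibble::as_tibble(fr))
  })
}

#' Physio-chemical profile grid
#'
#' One row per protein with the full parameter bundle: molecular weight
#' (kDa, 2 decimals), isoelectric point, aliphatic index, sulfur atoms,
#' hydrophobic/hydrophilic and charged fractions, instability index, GRAVY,
#' extinction coefficients, and a stability label (stable iff II < 40).
#'
#' @param x A protein sequence tibble.
#' @param pka_set pKa set for the pI (see [isoelectric_point()]).
#' @param residue_sets Residue partition for the fraction columns.
#' @return A tibble of class `physchem_tbl`.
#' @export
#' @examples
#' seq_tbl("p", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", kind = "protein") |>
#'   physchem_profile()
physchem_profile <- function(x, pka_set = "bjellqvist",
                             residue_sets = default_residue_sets()) {
  fr <- charge_and_hydropathy_fractions(x, residue_sets)
  ext <- extinction_coefficient(x$seq)
  ii <- instability_index(x$seq)
  out <- tibble::tibble(
    id = x$id, species = x$species,
    length = nchar(x$seq),
    mw_kda = round(molecular_weight(x$seq) / 1000, 2),
    pi = isoelectric_point(x$seq, pka_set),
    aliphatic_index = aliphatic_index(x$seq),
    sulfur = sulfur_count(x$seq),
    hydrophobic = fr$hydrophobic,
    hydrophilic = fr$hydrophilic,
    negative = fr$negative,
    positive = fr$positive,
    instability_index = ii,
    gravy = gravy(x$seq),
    ext_reduced = ext$reduced,
    ext_cystines = ext$cystines,
    stability = ifelse(ii < 40, "stable", "unstable")
  )
  class(out) <- c("physchem_tbl", class(out))
  out
}
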