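#' Nucleotide and positional GC composition
#'
#' Per-sequence base percentages overall and at each codon position, plus
#' GC, GC1, GC2, GC3. Values are kept at full precision; use
#' [report_composition()] for the conventional 1-decimal report grid.
#'
#' @param x A DNA sequence tibble of in-frame CDS.
#' @return A tibble, one row per sequence, with columns `id`, `species`,
#'   `a`, `c`, `g`, `t` (overall percentages), `c1`, `g1`, `c2`, `g2`,
#'   `c3`, `g3` (positional percentages), and `gc`, `gc1`, `gc2`, `gc3`.
#' @export
#' @examples
#' seq_tbl("toy", "GGGCCC", kind = "dna") |> composition()
composition <- function(x) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    n <- nchar(s)
    if (n == 0) rlang::abort(paste0("empty sequence: ", x$id[i]))
    if (n %% 3 != 0) {
      rlang::abort(paste0("CDS '", x$id[i], "' length ", n,
                          " not divisible by 3"))
    }
    ch <- strsplit(s, "")[[1]]
    pos <- rep_len(1:3, n)
    pct <- function(v) 100 * vapply(DNA_BASES, function(b) mean(v == b),
                                    numeric(1))
    all_p <- pct(ch)
    p1 <- pct(ch[pos == 1]); p2 <- pct(ch[pos == 2]); p3 <- pct(ch[pos == 3])
    tibble::tibble(
      id = x$id[i], species = x$species[i],
      a = all_p[["A"]], c = all_p[["C"]], g = all_p[["G"]], t = all_p[["T"]],
      c1 = p1[["C"]], g1 = p1[["G"]], c2 = p2[["C"]], g2 = p2[["G"]],
      c3 = p3[["C"]], g3 = p3[["G"]],
      gc = all_p[["C"]] + all_p[["G"]],
      gc1 = p1[["C"]] + p1[["G"]],
      gc2 = p2[["C"]] + p2[["G"]],
      gc3 = p3[["C"]] + p3[["G"]]
    )
  })
}

#' Round a composition table to the conventional report precision
#'
#' @param comp Output of [composition()].
#' @param digits Decimal places (default 1).
#' @return The same tibble with numeric columns rounded.
#' @export
report_composition <- function(comp, digits = 1) {
  dplyr::mutate(comp, dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, digits)))
}

#' Codon usage counts
#'
#' Counts every codon of each in-frame CDS exactly once. Codons containing
#' ambiguity characters are excluded (and counted in the `n_ambiguous`
#' attribute); stop codons are tallied separately from the sense total.
#'
#' @param x A DNA sequence tibble of in-frame CDS.
#' @param render Codon rendering in the output: `"rna"` (default; CUG, AGC,
#'   ... as in codon-usage reports) or `"dna"`.
#' @return A long tibble with columns `id`, `species`, `codon`, `aa`,
#'   `count`, covering all 64 codons for every sequence.
#' @export
codon_usage <- function(x, render = c("rna", "dna")) {
  render <- match.arg(render)
  map <- codon_map()
  all_codons <- names(map)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    if (nchar(s) == 0 || nchar(s) %% 3 != 0) {
      rlang::abort(paste0("CDS '", x$id[i], "' length ", nchar(s),
                          " not divisible by 3"))
    }
    codons <- split_codons(s)
    keep <- codons %in% all_codons
    counts <- table(factor(codons[keep], levels = all_codons))
    out <- tibble::tibble(
      id = x$id[i], species = x$species[i],
      codon = all_codons, aa = unname(map[all_codons]),
      count = as.integer(counts)
    )
    attr(out, "n_ambiguous") <- sum(!keep)
    out
  }) -> tbl
  if (render == "rna") tbl$codon <- chartr("T", "U", tbl$codon)
  tbl
}

#' Relative synonymous codon usage
#'
#' For codon j of amino acid i with degeneracy n_i and counts x_ij,
#' RSCU_ij = n_i * x_ij / sum_j x_ij. Codons of an amino acid that does not
#' occur at all in the sequence get RSCU 0 by convention (the ratio is 0/0
#' there). Stop codons get `NA`.
#'
#' @param usage Output of [codon_usage()] (any codon rendering).
#' @return `usage` with columns `degeneracy`, `aa_total` and `rscu` added.
#' @export
#' @examples
#' seq_tbl("x", "ATGATGCTGCTGCTGCTGCTACTA", kind = "dna") |>
#'   codon_usage() |>
#'   rscu()
rscu <- function(usage) {
  deg <- aa_degeneracy()
  usage |>
    dplyr::group_by(.data$id, .data$aa) |>
    dplyr::mutate(aa_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      degeneracy = ifelse(.data$aa == "*", NA_integer_,
                          as.integer(deg[.data$aa])),
      rscu = dplyr::case_when(
        aa == "*" ~ NA_real_,
        aa_total == 0 ~ 0,
        TRUE ~ degeneracy * count / aa_total
      )
    )
}

#' Preferred and unused codon summary
#'
#' Summarizes an RSCU table per sequence: the number of preferred sense
#' codons (RSCU strictly > 1), the number of unused sense codons
#' (count 0), the preferred set itself, and the third-base tally of the
#' preferred codons.
#'
#' @param rscu_tbl Output of [rscu()].
#' @return A tibble with one row per sequence: `id`, `species`,
#'   `n_preferred`, `n_unused`, `preferred` (list-column of codons),
#'   `third_a`, `third_c`, `third_g`, `third_u`.
#' @export
codon_bias_summary <- function(rscu_tbl) {
  rscu_tbl |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::group_by(.data$id, .data$species) |>
    dplyr::summarise(
      n_preferred = sum(.data$rscu > 1),
      n_unused = sum(.data$count == 0),
      preferred = list(.data$codon[.data$rscu > 1]),
      third_a = sum(substr(.data$codon[.data$rscu > 1], 3, 3) == "A"),
      third_c = sum(substr(.data$codon[.data$rscu > 1], 3, 3) == "C"),
      third_g = sum(substr(.data$codon[.data$rscu > 1], 3, 3) == "G"),
      third_u = sum(substr(.data$codon[.data$rscu > 1], 3, 3) %in%
                      c("U", "T")),
      .groups = "drop"
    )
}

#' Codon-usage report grid
#'
#' Wide per-species grid of codon usage counts (integer) and RSCU (1
#' decimal), in the layout of the classic highly-preferred-codon tables.
#'
#' @param rscu_tbl Output of [rscu()].
#' @param codons Optional codon subset (in the table's rendering) to report.
#' @return A tibble with `codon`, `aa`, then `<species>_cu` and
#'   `<species>_rscu` column pairs.
#' @export
report_codon_usage <- function(rscu_tbl, codons = NULL) {
  tbl <- dplyr::filter(rscu_tbl, .data$aa != "*")
  if (!is.null(codons)) tbl <- dplyr::filter(tbl, .data$codon %in% codons)
  tbl |>
    dplyr::transmute(.data$species, .data$codon, .data$aa,
                     cu = .data$count, rscu = round(.data$rscu, 1)) |>
    tidyr::pivot_wider(names_from = "species",
                       values_from = c("cu", "rscu"),
                       names_glue = "{species}_{.value}")
}
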