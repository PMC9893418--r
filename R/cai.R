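#' Read a reference codon usage table
#'
#' Reads either the Kazusa "codon usage database" text layout (fields of the
#' form `UUU 17.6( 714298)` flowing across lines) or a two-column TSV with
#' header `codon<TAB>frequency` (an optional `count` column is used when
#' present). Frequencies may be per-thousand or fractions; CAI only uses
#' within-family ratios, so the scale is immaterial.
#'
#' @param path Path to the table.
#' @return A tibble with columns `codon` (DNA rendering), `aa`, `frequency`,
#'   and `count` (`NA` if the source has none), all 61 sense codons and the
#'   3 stops present.
#' @export
read_codon_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  txt <- paste(lines, collapse = "\n")
  is_tsv <- grepl("^\\s*codon[\t,]", tolower(lines[1] %||% ""))
  map <- codon_map()
  if (is_tsv) {
    df <- utils::read.delim(textConnection(txt), stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    codon <- chartr("U", "T", toupper(df$codon))
    freq <- as.numeric(df$frequency)
    count <- if ("count" %in% names(df)) as.numeric(df$count) else
      rep(NA_real_, length(codon))
  } else {
    # Kazusa layout: "UUU 17.6( 714298)UUC 20.3( 824692)..."
    m <- gregexpr("([AUCGT]{3})\\s+([0-9.]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
                  txt, perl = TRUE)
    hits <- regmatches(txt, m)[[1]]
    if (length(hits) == 0) {
      rlang::abort(paste0("unrecognized codon table format: ", path))
    }
    codon <- chartr("U", "T",
                    toupper(sub("^([AUCGTaucgt]{3}).*$", "\\1", hits)))
    freq <- as.numeric(sub("^[AUCGTaucgt]{3}\\s+([0-9.]+).*$", "\\1", hits))
    count <- as.numeric(sub("^.*\\(\\s*([0-9]+)\\s*\\)$", "\\1", hits))
  }
  if (anyDuplicated(codon)) rlang::abort("duplicate codons in table")
  missing <- setdiff(names(map), codon)
  if (length(setdiff(sense_codons(), codon)) > 0) {
    rlang::abort(paste0("codon table missing sense codons: ",
                        paste(setdiff(sense_codons(), codon), collapse = ", ")))
  }
  out <- tibble::tibble(codon = codon, aa = unname(map[codon]),
                        frequency = freq, count = count)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      codon = missing, aa = unname(map[missing]),
      frequency = 0, count = if (all(is.na(count))) NA_real_ else 0))
  }
  if (any(out$frequency < 0, na.rm = TRUE)) {
    rlang::abort("negative frequencies in codon table")
  }
  out
}

#' Relative adaptiveness weights from a reference table
#'
#' w_ij = f_ij / max_j f_ij within each synonymous family. Zero-frequency
#' reference codons are floored before the ratio: at 0.5 occurrences when
#' the table carries counts, otherwise at half the smallest positive
#' frequency; a warning reports which codons were floored.
#'
#' @param ref Output of [read_codon_table()] (or a compatible tibble).
#' @return `ref` restricted to sense codons with a `w` column added.
#' @export
relative_adaptiveness <- function(ref) {
  ref <- dplyr::filter(ref, .data$aa != "*")
  has_counts <- !all(is.na(ref$count))
  val <- if (has_counts) ref$count else ref$frequency
  zero <- which(val == 0)
  if (length(zero)) {
    floor_val <- if (has_counts) 0.5 else min(val[val > 0]) / 2
    val[zero] <- floor_val
    rlang::warn(paste0("zero-frequency reference codons floored: ",
                       paste(ref$codon[zero], collapse = ", ")))
  }
  ref$w <- stats::ave(val, ref$aa, FUN = function(v) v / max(v))
  ref
}

#' Codon adaptation index
#'
#' Sharp & Li CAI: the geometric mean of the relative adaptiveness w of each
#' sense codon of the CDS, excluding Met, Trp and stop codons (whose w is 1
#' by construction and carries no information).
#'
#' @param x A DNA sequence tibble of in-frame CDS.
#' @param ref Reference codon table (see [read_codon_table()]), or a table
#'   already carrying a `w` column.
#' @return A tibble with columns `id`, `species`, `cai`, `n_codons_scored`.
#' @export
cai <- function(x, ref) {
  if (!"w" %in% names(ref)) {
    ref <- suppressWarnings(relative_adaptiveness(ref))
  }
  w <- stats::setNames(ref$w, ref$codon)
  map <- codon_map()
  excluded <- c(stop_codons(), names(map)[map %in% c("M", "W")])
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    codons <- split_codons(x$seq[i])
    codons <- codons[codons %in% names(map) & !(codons %in% excluded)]
    if (length(codons) == 0) {
      rlang::abort(paste0("no scorable codons in ", x$id[i]))
    }
    lw <- log(w[codons])
    tibble::tibble(id = x$id[i], species = x$species[i],
                   cai = exp(mean(lw)),
                   n_codons_scored = length(codons))
  })
}

fit_markov <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch <- ch[ch %in% DNA_BASES]
  init <- table(factor(ch, levels = DNA_BASES))
  init <- as.numeric(init) / sum(init)
  from <- ch[-length(ch)]
  to <- ch[-1]
  trans <- table(factor(from, levels = DNA_BASES),
                 factor(to, levels = DNA_BASES))
  trans <- trans + 0.5  # pseudocount keeps the chain irreducible
  trans <- sweep(as.matrix(trans), 1, rowSums(trans), "/")
  list(init = stats::setNames(init, DNA_BASES), trans = trans)
}

markov_sequence <- function(model, n) {
  out <- character(n)
  out[1] <- sample(DNA_BASES, 1, prob = model$init)
  for (k in 2:n) {
    out[k] <- sample(DNA_BASES, 1, prob = model$trans[out[k - 1], ])
  }
  paste(out, collapse = "")
}

#' Expected CAI under a Markov composition model
#'
#' Monte-Carlo baseline for CAI significance: a first-order Markov
#' nucleotide chain is fitted to each query CDS (its dinucleotide
#' composition), `n_reps` random sequences of the same length are generated,
#' and the CAI distribution of those sequences is summarized. A CAI above
#' the upper 95% quantile of this distribution indicates codon usage more
#' adapted to the reference than composition alone explains.
#'
#' @param x A DNA sequence tibble of in-frame CDS (the queries).
#' @param ref Reference codon table.
#' @param n_reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the same seed.
#' @return A tibble with one row per query: `id`, `species`, `ecai_mean`,
#'   `ecai_sd`, `ecai_q95`, `n_reps`, `seed`.
#' @export
expected_cai <- function(x, ref, n_reps = 500, seed = 1) {
  if (n_reps < 1) rlang::abort("n_reps must be >= 1")
  if (!"w" %in% names(ref)) {
    ref <- suppressWarnings(relative_adaptiveness(ref))
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    model <- fit_markov(s)
    sims <- vapply(seq_len(n_reps), function(r) {
      rs <- markov_sequence(model, nchar(s))
      cai(seq_tbl("sim", rs, kind = "dna"), ref)$cai
    }, numeric(1))
    tibble::tibble(id = x$id[i], species = x$species[i],
                   ecai_mean = mean(sims),
                   ecai_sd = if (n_reps > 1) stats::sd(sims) else NA_real_,
                   ecai_q95 = stats::quantile(sims, 0.95, names = FALSE),
                   n_reps = n_reps, seed = seed)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
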