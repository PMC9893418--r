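#' Build a sequence table
#'
#' The package's central container is an ordinary tibble with one row per
#' sequence and columns `id`, `species`, `seq`, carrying a `kind` attribute
#' (`"dna"` or `"protein"`). All analysis functions accept and return such
#' tibbles so calls chain with the pipe.
#'
#' @param id Character vector of unique record identifiers.
#' @param seq Character vector of sequences (same length as `id`).
#' @param species Optional species labels; defaults to `id`.
#' @param kind `"dna"` or `"protein"`.
#' @return A `seq_tbl` tibble.
#' @export
#' @examples
#' seq_tbl(c("s1", "s2"), c("ATGAAA", "ATGCCC"), kind = "dna")
seq_tbl <- function(id, seq, species = id, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) {
    rlang::abort("sequence ids must be unique")
  }
  seq <- toupper(seq)
  if (kind == "dna") seq <- chartr("U", "T", seq)
  out <- tibble::tibble(id = as.character(id),
                        species = as.character(species),
                        seq = seq)
  class(out) <- c("seq_tbl", class(out))
  attr(out, "kind") <- kind
  out
}

seq_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) {
    # infer: protein letters beyond ACGTN imply protein
    k <- if (all(grepl("^[ACGTUN-]*$", x$seq))) "dna" else "protein"
  }
  k
}

#' Read sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file into a sequence tibble. The record id is the
#' header token before the first whitespace; the remainder of the header, if
#' any, is used as the species label (overridable with a sample sheet, see
#' [apply_sample_sheet()]). `U` is normalized to `T` internally for
#' nucleotide input.
#'
#' @param path Path to a FASTA file.
#' @param kind `"dna"` or `"protein"`.
#' @return A `seq_tbl` tibble, record order preserved.
#' @export
read_fasta <- function(path, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path))
  }
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) {
                   rlang::abort(paste0("malformed FASTA in ", path, ": ",
                                       conditionMessage(e)))
                 })
  if (length(ss) == 0) {
    rlang::abort(paste0("empty FASTA file: ", path))
  }
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), ids)
  seq_tbl(id = ids, seq = unname(as.character(ss)), species = unname(rest),
          kind = kind)
}

#' Write sequences to a FASTA file
#'
#' @param x A sequence tibble.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes one line per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (!is.null(x$species) && !identical(x$species[i], x$id[i])) {
      paste0(">", x$id[i], " ", x$species[i])
    } else {
      paste0(">", x$id[i])
    }
    writeLines(header, con)
    s <- x$seq[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Override species labels from a sample sheet
#'
#' @param x A sequence tibble.
#' @param sheet Path to a TSV with columns `id` and `species`, or a data
#'   frame with those columns.
#' @return `x` with species labels replaced where the sheet provides them.
#' @export
apply_sample_sheet <- function(x, sheet) {
  if (is.character(sheet)) {
    sheet <- utils::read.delim(sheet, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "species") %in% names(sheet)))
  idx <- match(x$id, sheet$id)
  hit <- !is.na(idx)
  x$species[hit] <- sheet$species[idx[hit]]
  x
}

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, by = 3), pmin(seq(3, n + 2, by = 3), n))
}

#' Validate coding sequences
#'
#' Report-only check of reading frame, internal stop codons, and alphabet.
#' Never mutates or rejects its input.
#'
#' @param x A DNA sequence tibble.
#' @param strict If `TRUE`, IUPAC ambiguity codes (N, R, Y, ...) are reported
#'   as alphabet violations; if `FALSE` only characters outside the IUPAC
#'   nucleotide alphabet are.
#' @return A tibble with one row per sequence: `id`, `frame_ok`,
#'   `n_codons`, `internal_stop_codon` (1-based codon index of the first
#'   internal stop, `NA` if none), `has_terminal_stop`, `alphabet_ok`,
#'   `bad_chars`, and overall `valid`.
#' @export
validate_cds <- function(x, strict = TRUE) {
  allowed <- if (strict) "^[ACGT]*$" else "^[ACGTRYSWKMBDHVN]*$"
  stops <- stop_codons()
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    n <- nchar(s)
    frame_ok <- n > 0 && n %% 3 == 0
    alphabet_ok <- grepl(allowed, s)
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    codons <- if (frame_ok) split_codons(s) else character()
    is_stop <- codons %in% stops
    internal <- which(is_stop[-length(is_stop)])
    tibble::tibble(
      id = x$id[i],
      frame_ok = frame_ok,
      n_codons = if (frame_ok) length(codons) else NA_integer_,
      internal_stop_codon = if (length(internal)) internal[1] else NA_integer_,
      has_terminal_stop = frame_ok && length(is_stop) > 0 &&
        is_stop[length(is_stop)],
      alphabet_ok = alphabet_ok,
      bad_chars = paste(bad, collapse = ""),
      valid = frame_ok && alphabet_ok && length(internal) == 0
    )
  })
}

translate_one <- function(s, drop_terminal_stop = TRUE, id = "<seq>") {
  n <- nchar(s)
  if (n == 0 || n %% 3 != 0) {
    rlang::abort(paste0("CDS '", id, "' length ", n,
                        " is not a positive multiple of 3"))
  }
  codons <- split_codons(s)
  map <- codon_map()
  aas <- unname(map[codons])
  if (anyNA(aas)) {
    bad <- which(is.na(aas))[1]
    rlang::abort(paste0("CDS '", id, "' has untranslatable codon '",
                        codons[bad], "' at codon ", bad))
  }
  stops <- which(aas == "*")
  internal <- stops[stops < length(aas)]
  if (length(internal)) {
    rlang::abort(paste0("CDS '", id, "' has internal stop codon '",
                        codons[internal[1]], "' at codon ", internal[1]))
  }
  if (length(stops) && drop_terminal_stop) aas <- aas[-length(aas)]
  paste(aas, collapse = "")
}

#' Translate coding sequences
#'
#' Translates each CDS with the standard genetic code. Errors name the
#' offending codon index (1-based) for internal stops and frame violations.
#'
#' @param x A DNA sequence tibble of in-frame CDS.
#' @param drop_terminal_stop Drop the trailing stop codon from the protein.
#' @return A protein sequence tibble with the same ids and species.
#' @export
#' @examples
#' seq_tbl("x", "ATGTGA", kind = "dna") |> translate_cds()
translate_cds <- function(x, drop_terminal_stop = TRUE) {
  prot <- vapply(seq_len(nrow(x)), function(i) {
    translate_one(x$seq[i], drop_terminal_stop, x$id[i])
  }, character(1))
  seq_tbl(x$id, prot, species = x$species, kind = "protein")
}
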