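# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is downloaded.

# alignment with prescribed column state counts, e.g. list(c(2,2,2,1,1))
# builds one 8-row column with three doubletons and two singletons
aln_from_counts <- function(count_list) {
  n <- sum(count_list[[1]])
  cols <- lapply(count_list, function(cnt) {
    stopifnot(sum(cnt) == n)
    rep(LETTERS[seq_along(cnt)], cnt)
  })
  m <- do.call(cbind, cols)
  seq_tbl(paste0("s", seq_len(n)), apply(m, 1, paste, collapse = ""),
          kind = "protein")
}

random_protein <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                   "Q","R","S","T","V","W","Y"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

sense_codons_for_test <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
}

random_cds <- function(len_codons, seed) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, len_codons, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(x, ...) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(x, path, ...)
  path
}

# uniform reference table: every codon equally frequent
uniform_ref <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc),
                 frequency = 1, count = NA_real_)
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "orthofam")
}

# Deposited avUCP family: present only after scripts/fetch_avucp.R has been
# run with network access. Tests that need it fail with a clear message
# when it is absent.
load_avucp <- function() {
  path <- extdata_path("avucp_cds.fasta")
  if (!nzchar(path) || !file.exists(path)) {
    stop("deposited avUCP CDS not available offline; ",
         "run scripts/fetch_avucp.R with network access to obtain them",
         call. = FALSE)
  }
  cds <- read_fasta(path, kind = "dna")
  sheet <- extdata_path("avucp_samples.tsv")
  if (nzchar(sheet) && file.exists(sheet)) {
    cds <- apply_sample_sheet(cds, sheet)
  }
  cds
}
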