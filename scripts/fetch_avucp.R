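#!/usr/bin/env Rscript
# Fetch the eight avian UCP coding sequences from NCBI (network required).
#
# Downloads the annotated CDS of the eight avUCP transcripts and writes
# them, with species labels, to inst/extdata/avucp_cds.fasta plus a sample
# sheet. Run once from the repository root; all analyses and the real-data
# acceptance checks read the resulting file. No test requires this script:
# offline runs use the synthetic ortholog-family generator instead.

accessions <- c(
  chicken = "NM_204107.2",
  mallard = "XM_005025525.4",
  manakin = "XM_032677900.1",
  pigeon  = "XM_021285112.1",
  sparrow = "XM_039697035.1",
  swallow = "XM_040089804.1",
  turkey  = "NM_001303164.1",
  wagtail = "XM_038133918.1"
)

out_fasta <- file.path("inst", "extdata", "avucp_cds.fasta")
out_sheet <- file.path("inst", "extdata", "avucp_samples.tsv")
dir.create(dirname(out_fasta), showWarnings = FALSE, recursive = TRUE)

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
records <- character(0)
for (sp in names(accessions)) {
  acc <- accessions[[sp]]
  url <- paste0(base, "?db=nuccore&id=", acc,
                "&rettype=fasta_cds_na&retmode=text")
  message("fetching ", acc, " (", sp, ")")
  txt <- readLines(url, warn = FALSE)
  txt <- txt[nzchar(txt)]
  txt[1] <- paste0(">", acc, " ", sp)
  records <- c(records, txt)
  Sys.sleep(0.4)  # NCBI rate courtesy
}
writeLines(records, out_fasta)
writeLines(c("id\tspecies",
             paste(unname(accessions), names(accessions), sep = "\t")),
           out_sheet)
message("wrote ", out_fasta)
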