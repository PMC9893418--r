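test_that("composition computes overall and positional GC", {
  gcc <- composition(seq_tbl("x", "GGGCCC"))
  expect_equal(gcc$gc, 100)
  expect_equal(gcc$gc3, 100)

  # ATG | CAT tallied by hand over 2 codons
  h <- composition(seq_tbl("x", "ATGCAT"))
  expect_equal(h$c1, 50)   # pos-1 bases A, C
  expect_equal(h$g1, 0)
  expect_equal(h$c2, 0)    # pos-2 bases T, A
  expect_equal(h$g2, 0)
  expect_equal(h$c3, 0)    # pos-3 bases G, T
  expect_equal(h$g3, 50)
  expect_equal(h$gc, 100 * 2 / 6)
  expect_error(composition(seq_tbl("x", "")), "empty")
})

test_that("composition is invariant under codon shuffling", {
  codons <- strsplit(random_cds(60, 9), "(?<=...)", perl = TRUE)[[1]]
  set.seed(1)
  shuffled <- paste(sample(codons), collapse = "")
  a <- composition(seq_tbl("a", paste(codons, collapse = "")))
  b <- composition(seq_tbl("a", shuffled))
  expect_equal(dplyr::select(a, -id, -species),
               dplyr::select(b, -id, -species))
})

test_that("codon usage counts every codon once and separates stops", {
  u <- codon_usage(seq_tbl("x", "ATGATG"))
  expect_equal(u$count[u$codon == "AUG"], 2L)
  expect_equal(sum(u$count), 2L)

  fam <- simulate_family(sim_config(n_taxa = 4, length_codons = 50, seed = 5))
  u <- codon_usage(fam$cds)
  totals <- u |>
    dplyr::group_by(id) |>
    dplyr::summarise(sense = sum(count[aa != "*"]),
                     stops = sum(count[aa == "*"]))
  expect_equal(totals$sense + totals$stops,
               rep(nchar(fam$cds$seq[1]) / 3, 4))
  expect_equal(totals$stops, rep(1L, 4))
})

test_that("RSCU matches the defining formula on hand-worked cases", {
  # Leu codons CTG x4 and CTA x2: n = 6, family total 6
  cds <- paste0(strrep("CTG", 4), strrep("CTA", 2))
  r <- rscu(codon_usage(seq_tbl("x", cds)))
  expect_equal(r$rscu[r$codon == "CUG"], 4)
  expect_equal(r$rscu[r$codon == "CUA"], 2)
  expect_equal(r$rscu[r$codon == "CUC"], 0)

  # equal use of all synonymous codons -> all RSCU exactly 1
  all_sense <- paste(sense_codons_for_test(), collapse = "")
  r1 <- rscu(codon_usage(seq_tbl("x", all_sense)))
  expect_true(all(r1$rscu[r1$aa != "*"] == 1))
  s <- codon_bias_summary(r1)
  expect_equal(s$n_preferred, 0L)
  expect_equal(s$n_unused, 0L)
})

test_that("RSCU family sums equal degeneracy and Met/Trp sit at 1 on fuzzed CDS", {
  for (seed in 1:5) {
    cds <- seq_tbl("f", random_cds(120, seed))
    r <- rscu(codon_usage(cds))
    fam_sums <- r |>
      dplyr::filter(aa != "*", aa_total > 0) |>
      dplyr::group_by(aa) |>
      dplyr::summarise(s = sum(rscu), deg = degeneracy[1])
    expect_equal(fam_sums$s, as.numeric(fam_sums$deg), tolerance = 1e-9)
    met <- r$rscu[r$aa == "M" & r$aa_total > 0]
    trp <- r$rscu[r$aa == "W" & r$aa_total > 0]
    expect_true(all(c(met, trp) == 1))
    # absent amino acids report 0 for all their codons
    absent <- r |> dplyr::filter(aa != "*", aa_total == 0)
    expect_true(all(absent$rscu == 0))
  }
})

test_that("RSCU agrees with an independent implementation", {
  skip_if_not_installed("seqinr")
  s <- random_cds(200, 42)
  ours <- rscu(codon_usage(seq_tbl("x", s), render = "dna"))
  theirs <- seqinr::uco(strsplit(tolower(s), "")[[1]], index = "rscu")
  names(theirs) <- toupper(names(theirs))
  cmp <- ours[ours$aa != "*" & ours$aa_total > 0, ]
  expect_equal(cmp$rscu, unname(theirs[cmp$codon]), tolerance = 1e-9)
})

test_that("codon bias summary counts preferred and unused codons", {
  # 4 Leu-CTG, 2 Leu-CTA, 1 Met: CUG preferred; most codons unused
  r <- rscu(codon_usage(seq_tbl("x", paste0(strrep("CTG", 4),
                                            strrep("CTA", 2), "ATG"))))
  s <- codon_bias_summary(r)
  expect_equal(s$n_preferred, 2L)  # CUG (4.0) and CUA (2.0)
  expect_equal(s$n_unused, 61L - 3L)
  expect_setequal(s$preferred[[1]], c("CUG", "CUA"))
  expect_equal(s$third_g, 1L)
  expect_equal(s$third_a, 1L)
})

test_that("reference codon tables parse identically from both dialects", {
  kaz <- read_codon_table(extdata_path("synthetic_codon_table_kazusa.txt"))
  tsv <- read_codon_table(extdata_path("synthetic_codon_table.tsv"))
  expect_equal(nrow(kaz), 64)
  expect_equal(dplyr::arrange(kaz, codon), dplyr::arrange(tsv, codon))
  expect_error(read_codon_table(write_tmp_fasta(seq_tbl("x", "ATG"))),
               "unrecognized|missing")
})

test_that("CAI is 1 for maximally adapted sequences and uniform references", {
  ref <- read_codon_table(extdata_path("synthetic_codon_table.tsv"))
  w <- relative_adaptiveness(ref)
  best <- w |>
    dplyr::filter(!aa %in% c("M", "W")) |>
    dplyr::group_by(aa) |>
    dplyr::slice_max(w, n = 1, with_ties = FALSE)
  cds_best <- paste(chartr("U", "T", best$codon), collapse = "")
  expect_equal(cai(seq_tbl("best", cds_best), ref)$cai, 1)

  any_cds <- seq_tbl("any", random_cds(100, 7))
  expect_equal(cai(any_cds, uniform_ref())$cai, 1)
})

test_that("CAI is invariant to codon order and floors zero-frequency codons", {
  ref <- read_codon_table(extdata_path("synthetic_codon_table.tsv"))
  codons <- strsplit(random_cds(90, 11), "(?<=...)", perl = TRUE)[[1]]
  set.seed(2)
  a <- cai(seq_tbl("a", paste(codons, collapse = "")), ref)$cai
  b <- cai(seq_tbl("a", paste(sample(codons), collapse = "")), ref)$cai
  expect_equal(a, b)

  ref0 <- ref
  ref0$frequency[ref0$codon == "GCT"] <- 0
  ref0$count[ref0$codon == "GCT"] <- 0
  expect_warning(w0 <- relative_adaptiveness(ref0), "floored")
  expect_gt(w0$w[w0$codon == "GCT"], 0)
})

test_that("expected CAI is seed-reproducible and exact under a uniform reference", {
  x <- seq_tbl("q", random_cds(60, 13))
  ref <- read_codon_table(extdata_path("synthetic_codon_table.tsv"))
  a <- expected_cai(x, ref, n_reps = 5, seed = 99)
  b <- expected_cai(x, ref, n_reps = 5, seed = 99)
  expect_equal(a, b)
  expect_true(a$ecai_mean >= 0 && a$ecai_mean <= 1)

  u <- expected_cai(x, uniform_ref(), n_reps = 3, seed = 1)
  expect_equal(u$ecai_mean, 1)
  expect_equal(u$ecai_sd, 0)

  one <- expected_cai(x, ref, n_reps = 1, seed = 4)
  expect_true(one$ecai_mean >= 0 && one$ecai_mean <= 1)
  expect_error(expected_cai(x, ref, n_reps = 0, seed = 1), "n_reps")
})

test_that("Monte-Carlo expected CAI is stable across seeds", {
  x <- seq_tbl("q", random_cds(100, 21))
  ref <- read_codon_table(extdata_path("synthetic_codon_table.tsv"))
  m <- vapply(c(1, 2), function(s) {
    expected_cai(x, ref, n_reps = 150, seed = s)$ecai_mean
  }, numeric(1))
  expect_lt(abs(diff(m)), 0.03)
})
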