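# Frozen reference values below were computed with an independent
# implementation of the same published tables (Biopython 1.88 ProtParam) on
# the exact peptides shown.

test_that("amino-acid composition counts are exact and conserve length", {
  comp <- aa_composition(seq_tbl("x", "AAL", kind = "protein"))
  expect_equal(comp$count[comp$aa == "A"], 2L)
  expect_equal(comp$count[comp$aa == "L"], 1L)
  expect_equal(sum(comp$count), 3L)
  for (seed in 1:3) {
    p <- random_protein(1, 57, seed)
    cc <- aa_composition(seq_tbl("x", p, kind = "protein"))
    expect_equal(sum(cc$count), 57L)
    expect_equal(sum(cc$percent), 100)
  }
})

test_that("molecular weight uses average masses plus one water", {
  expect_equal(molecular_weight("G"), 75.0666, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.1179, tolerance = 1e-4)
  expect_equal(molecular_weight("ACDEFGHIKLMNPQRSTVWY"), 2395.7134,
               tolerance = 1e-4)
  expect_equal(molecular_weight("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
               3935.5547, tolerance = 1e-4)
})

test_that("isoelectric point zeroes the Henderson-Hasselbalch net charge", {
  expect_gt(isoelectric_point("KKKKKKKKKK"), 10)
  expect_equal(isoelectric_point("KKKKKKKKKK"), 10.9544, tolerance = 2e-3)
  expect_equal(isoelectric_point("ACDEFGHIKLMNPQRSTVWY"), 6.7846,
               tolerance = 2e-3)
  expect_equal(isoelectric_point("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
               9.9880, tolerance = 2e-3)
  # poly-D: acidic-only chain, pI well below the D side-chain pKa
  expect_lt(isoelectric_point("DDDDDDDD"), 4.05)

  # defining property: net charge at the returned pI is ~0 (where the
  # charge curve crosses; poly-D pI is clamped by the pKa floor)
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  pI <- isoelectric_point(s)
  counts <- as.list(table(factor(strsplit(s, "")[[1]],
                                 levels = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                   "")[[1]])))
  q <- orthofam:::protein_charge(counts, substr(s, 1, 1),
                                 substr(s, nchar(s), nchar(s)), pI,
                                 orthofam:::PKA_SETS$bjellqvist)
  expect_lt(abs(q), 1e-3)
})

test_that("instability index reproduces the dipeptide-weight statistic", {
  expect_equal(instability_index("GG"), 66.7, tolerance = 1e-6)
  expect_equal(instability_index("ACDEFGHIKLMNPQRSTVWY"), 84.74,
               tolerance = 1e-4)
  # dipeptides are ordered: the reverse peptide scores differently
  expect_equal(instability_index("YWVTSRQPNMLKIHGFEDCA"), 26.84,
               tolerance = 1e-4)
  expect_equal(instability_index("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
               53.5485, tolerance = 1e-4)
  expect_error(instability_index("A"), "length")
})

test_that("aliphatic index, GRAVY and sulfur count follow their formulas", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("V"), 290)    # 2.9 * 100
  expect_equal(aliphatic_index("IL"), 390)   # 3.9 * (50 + 50)
  expect_equal(gravy("IIII"), 4.5)
  expect_equal(gravy("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"), -0.40303,
               tolerance = 1e-5)
  p <- random_protein(1, 40, 8)
  rev_p <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(gravy(p), gravy(rev_p))
  expect_equal(aliphatic_index(p), aliphatic_index(rev_p))
  expect_equal(sulfur_count("CMC"), 3L)
  expect_equal(sulfur_count("AAAA"), 0L)
})

test_that("extinction coefficients follow the 280 nm convention", {
  ec0 <- extinction_coefficient("AAAA")
  expect_equal(ec0$reduced, 0)
  expect_equal(ec0$cystines, 0)
  expect_equal(extinction_coefficient("WY")$reduced, 6990)
  ec <- extinction_coefficient("WYCCC")
  expect_equal(ec$cystines - ec$reduced, 125)  # one cystine pair from 3 Cys
  for (seed in 1:3) {
    e <- extinction_coefficient(random_protein(1, 50, seed))
    expect_gte(e$cystines, e$reduced)
  }
})

test_that("residue-set fractions partition correctly and reject overlap", {
  f <- charge_and_hydropathy_fractions(seq_tbl("d", "DDDD",
                                               kind = "protein"))
  expect_equal(f$negative, 1)
  expect_equal(f$positive, 0)
  bad <- default_residue_sets()
  bad$positive <- c(bad$positive, "D")
  expect_error(
    charge_and_hydropathy_fractions(seq_tbl("d", "DD", kind = "protein"),
                                    bad),
    "overlap")
  for (seed in 1:3) {
    fr <- charge_and_hydropathy_fractions(
      seq_tbl("x", random_protein(1, 60, seed), kind = "protein"))
    vals <- unlist(fr[, c("negative", "positive", "hydrophobic",
                          "hydrophilic")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("physchem grid bundles the indices with a stability label", {
  prot <- seq_tbl(c("stable", "unstable"),
                  c("YWVTSRQPNMLKIHGFEDCA", "ACDEFGHIKLMNPQRSTVWY"),
                  kind = "protein")
  g <- physchem_profile(prot)
  expect_equal(g$stability, c("stable", "unstable"))
  expect_equal(g$sulfur, c(2L, 2L))
  expect_equal(g$mw_kda, c(2.40, 2.40))
  expect_equal(g$instability_index, c(26.84, 84.74), tolerance = 1e-4)
  td <- tidy(g)
  expect_true(all(c("parameter", "value") %in% names(td)))
  expect_equal(glance(g)$n_proteins, 2L)
})
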