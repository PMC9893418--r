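# End-to-end pipeline: reads a CDS family, runs every analysis stage in
# dependency order, and writes TSV/JSON reports plus a manifest embedding
# the package version, configuration hash and seeds.

#' Default pipeline parameters
#'
#' @return Named list of the per-stage parameters with their defaults:
#'   entropy log base, zero-run threshold, KD window/threshold/min_len/
#'   min_gap, pKa set, bootstrap replicates, seed.
#' @export
pipeline_defaults <- function() {
  list(
    entropy_log_base = exp(1),
    zero_run_min_len = 10,
    kd_window = 19,
    kd_threshold = 1.6,
    tm_min_len = 15,
    tm_min_gap = 5,
    n_term = "extracellular",
    pka_set = "bjellqvist",
    bootstrap_reps = 100,
    ecai_reps = 500,
    seed = 1
  )
}

#' Run the full characterization pipeline
#'
#' Stages, in dependency order: read/validate/translate; nucleotide and
#' positional GC composition; codon usage, RSCU and bias summary (plus CAI
#' and expected CAI when a reference codon table is given); site
#' classification and entropy profiling of the CDS and protein alignments;
#' the physio-chemical grid; the NJ tree on Jukes-Cantor protein distances
#' with bootstrap supports; and per-protein membrane topology.
#'
#' @param input Path to a CDS FASTA file or a DNA `seq_tbl`.
#' @param out_dir Output directory for the report bundle (`NULL` to skip
#'   writing and just return the results).
#' @param sample_sheet Optional TSV path or data frame (`id`, `species`).
#' @param ref_codon_table Optional reference codon table path or tibble for
#'   CAI.
#' @param params Parameter list; defaults from [pipeline_defaults()],
#'   entries you supply override them.
#' @return A list of class `orthofam_run` with one element per stage plus a
#'   `manifest`.
#' @export
run_pipeline <- function(input, out_dir = NULL, sample_sheet = NULL,
                         ref_codon_table = NULL, params = list()) {
  p <- utils::modifyList(pipeline_defaults(), params)
  cds <- if (is.character(input)) read_fasta(input, "dna") else input
  if (!is.null(sample_sheet)) cds <- apply_sample_sheet(cds, sample_sheet)

  val <- validate_cds(cds)
  if (!all(val$valid)) {
    rlang::abort(paste0("invalid CDS: ",
                        paste(val$id[!val$valid], collapse = ", ")))
  }
  prot <- translate_cds(cds)

  comp <- composition(cds)
  usage <- rscu(codon_usage(cds))
  bias <- codon_bias_summary(usage)
  cai_tbl <- NULL
  ecai_tbl <- NULL
  if (!is.null(ref_codon_table)) {
    ref <- if (is.character(ref_codon_table)) {
      read_codon_table(ref_codon_table)
    } else {
      ref_codon_table
    }
    cai_tbl <- cai(cds, ref)
    ecai_tbl <- expected_cai(cds, ref, n_reps = p$ecai_reps, seed = p$seed)
  }

  sites_nt <- classify_sites(cds)
  sites_aa <- classify_sites(prot)
  ent <- column_entropy(prot, log_base = p$entropy_log_base)
  ent_sum <- entropy_summary(ent, zero_run_min_len = p$zero_run_min_len)
  logo <- logo_matrix(prot)
  phys <- physchem_profile(prot, pka_set = p$pka_set)

  boot <- bootstrap_support(prot, n_reps = p$bootstrap_reps, seed = p$seed)
  topo <- lapply(stats::setNames(prot$seq, prot$id), function(s) {
    membrane_topology(s, window = p$kd_window, threshold = p$kd_threshold,
                      min_len = p$tm_min_len, min_gap = p$tm_min_gap,
                      n_term = p$n_term)
  })

  res <- list(
    cds = cds, protein = prot, validation = val,
    composition = comp, codon_usage = usage, codon_bias = bias,
    cai = cai_tbl, expected_cai = ecai_tbl,
    sites_nt = sites_nt, sites_aa = sites_aa,
    site_counts_nt = site_counts(sites_nt),
    site_counts_aa = site_counts(sites_aa),
    entropy = ent, entropy_summary = ent_sum, logo = logo,
    physchem = phys, tree = boot, topology = topo,
    params = p
  )
  res$manifest <- list(
    package = "orthofam",
    version = as.character(utils::packageVersion("orthofam")),
    n_sequences = nrow(cds),
    params = p[setdiff(names(p), "entropy_log_base")],
    entropy_log_base = if (isTRUE(all.equal(p$entropy_log_base, exp(1))))
      "e" else p$entropy_log_base,
    config_hash = config_hash(p),
    seed = p$seed
  )
  class(res) <- "orthofam_run"
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

config_hash <- function(p) {
  s <- paste(names(p), vapply(p, function(v) paste(format(v), collapse = ","),
                              character(1)),
             sep = "=", collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% 2147483629
  }
  sprintf("%08x", h)
}

write_tsv_report <- function(df, path, manifest) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# orthofam %s config=%s seed=%s",
                     manifest$version, manifest$config_hash, manifest$seed),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the pipeline report bundle
#'
#' Emits per-stage TSVs (composition grid, codon usage/RSCU grid, bias
#' summary, site classes and counts, entropy profile and zero runs, logo
#' matrix, phys-chem grid, per-protein topology), the NJ tree as Newick,
#' and a combined `summary.json`. Every file embeds the package version,
#' config hash and seed.
#'
#' @param res An `orthofam_run` result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- res$manifest
  w <- function(df, name) {
    write_tsv_report(df, file.path(out_dir, name), man)
  }
  w(report_composition(res$composition), "composition.tsv")
  w(report_codon_usage(res$codon_usage), "codon_usage.tsv")
  w(dplyr::select(res$codon_bias, -"preferred"), "codon_bias.tsv")
  if (!is.null(res$cai)) w(res$cai, "cai.tsv")
  if (!is.null(res$expected_cai)) w(res$expected_cai, "expected_cai.tsv")
  w(as.data.frame(res$sites_nt), "sites_cds.tsv")
  w(as.data.frame(res$sites_aa), "sites_protein.tsv")
  w(res$entropy, "entropy.tsv")
  w(res$entropy_summary$zero_runs, "entropy_zero_runs.tsv")
  w(res$logo, "logo_matrix.tsv")
  w(as.data.frame(res$physchem), "physchem.tsv")
  topo_tbl <- purrr::imap_dfr(res$topology, function(t, id) {
    dplyr::mutate(tibble::as_tibble(t), id = id, .before = 1)
  })
  w(topo_tbl, "topology.tsv")
  write_newick(res$tree, file.path(out_dir, "nj_tree.nwk"))
  summary <- list(
    manifest = man,
    site_counts_cds = as.list(res$site_counts_nt),
    site_counts_protein = as.list(res$site_counts_aa),
    entropy = list(mean = res$entropy_summary$mean,
                   n_zero = res$entropy_summary$n_zero,
                   max = res$entropy_summary$max,
                   argmax = res$entropy_summary$argmax),
    codon_bias = as.list(dplyr::select(res$codon_bias, -"preferred")),
    tm_counts = vapply(res$topology, function(t)
      sum(t$label == "transmembrane"), numeric(1))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.orthofam_run <- function(x, ...) {
  cat(sprintf("orthofam run: %d sequences, %d nt each\n",
              nrow(x$cds), nchar(x$cds$seq[1])))
  print(x$site_counts_nt)
  invisible(x)
}
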