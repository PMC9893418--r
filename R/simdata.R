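# Synthetic ortholog-family generator. Supplies every analysis stage with
# inputs of known truth (tree, per-site substitution counts, realized GC3)
# so the whole pipeline is testable without any downloads. Substitution is
# simulated at the nucleotide level with stop-codon rejection and a
# tunable nonsynonymous acceptance probability; this reproduces the
# statistical structure the pipeline consumes (conserved / parsimony-
# informative / singleton mixtures, GC3 bias, tree signal) without claiming
# to be a phylogenetically rigorous codon model.

#' Simulation configuration
#'
#' Defaults emulate an avUCP-like single-copy ortholog family: 8 taxa,
#' 307 sense codons plus a terminal stop (924 nt leaves), strong GC3 bias
#' (0.88), moderate divergence, transition:transversion ratio 2, and
#' purifying selection accepting half of the nonsynonymous proposals.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param length_codons Number of sense codons per sequence.
#' @param gc3_target Probability that a root codon has G or C at its third
#'   position, in `[0, 1]`.
#' @param branch_scale Mean of the i.i.d. exponential branch lengths
#'   (expected nucleotide substitution attempts per site), > 0.
#' @param kappa Transition/transversion proposal weight (>= 0).
#' @param omega_like Acceptance probability for nonsynonymous proposals in
#'   `[0, 1]` (synonymous proposals are always accepted; proposals creating
#'   a stop codon are always rejected).
#' @param include_stop Append a fixed terminal `TAA` to every leaf.
#' @param min_branch Floor applied to sampled branch lengths (default 0,
#'   i.e. pure exponential). Parameter-recovery experiments set this to the
#'   resolvable-branch limit of the chosen sequence length, because with
#'   unconstrained exponential lengths near-polytomies occur with
#'   appreciable probability and no method can recover them.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 8, length_codons = 307, gc3_target = 0.88,
                       branch_scale = 0.03, kappa = 2, omega_like = 0.5,
                       include_stop = TRUE, min_branch = 0, seed) {
  if (missing(seed)) rlang::abort("seed is mandatory")
  stopifnot(n_taxa >= 3, length_codons >= 1,
            gc3_target >= 0, gc3_target <= 1,
            branch_scale >= 0, kappa >= 0,
            omega_like >= 0, omega_like <= 1, min_branch >= 0)
  structure(list(n_taxa = n_taxa, length_codons = length_codons,
                 gc3_target = gc3_target, branch_scale = branch_scale,
                 kappa = kappa, omega_like = omega_like,
                 include_stop = include_stop, min_branch = min_branch,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a random tree
#'
#' Yule (pure-birth) topology with i.i.d. exponential branch lengths of
#' mean `branch_scale`.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param branch_scale Mean branch length.
#' @param seed Integer seed.
#' @return A rooted binary `ape::phylo` with tip labels `t1..tn`.
#' @export
sample_tree <- function(n_taxa, branch_scale, seed) {
  if (n_taxa < 3) rlang::abort("n_taxa must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_scale)
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

sample_root_codons <- function(length_codons, gc3_target) {
  sc <- sense_codons()
  third <- substr(sc, 3, 3)
  is_gc <- third %in% c("G", "C")
  w <- ifelse(is_gc, gc3_target / sum(is_gc), (1 - gc3_target) / sum(!is_gc))
  sample(sc, length_codons, replace = TRUE, prob = w)
}

# evolve a nucleotide vector along one branch; returns list(seq, counts)
evolve_branch <- function(nt, len, kappa, omega_like, map) {
  n_sites <- length(nt)
  counts <- integer(n_sites)
  n_events <- stats::rpois(1, len * n_sites)
  if (n_events == 0) return(list(nt = nt, counts = counts))
  sites <- sample.int(n_sites, n_events, replace = TRUE)
  for (site in sites) {
    cur <- nt[site]
    others <- setdiff(DNA_BASES, cur)
    w <- ifelse(others == transition_of[[cur]], kappa, 1)
    prop <- sample(others, 1, prob = w)
    codon_idx <- (site - 1) %/% 3
    cstart <- codon_idx * 3 + 1
    old_codon <- paste(nt[cstart:(cstart + 2)], collapse = "")
    new_nt <- nt
    new_nt[site] <- prop
    new_codon <- paste(new_nt[cstart:(cstart + 2)], collapse = "")
    if (map[[new_codon]] == "*") next
    if (map[[new_codon]] != map[[old_codon]] &&
        stats::runif(1) > omega_like) next
    nt <- new_nt
    counts[site] <- counts[site] + 1L
  }
  list(nt = nt, counts = counts)
}

#' Simulate an ortholog CDS family with known truth
#'
#' Draws a root CDS codon-by-codon with the configured third-position GC
#' probability, evolves it along a sampled Yule tree by per-site nucleotide
#' substitution (kappa-weighted proposals; stop-creating proposals
#' rejected; nonsynonymous proposals accepted with probability
#' `omega_like`), and returns the leaf CDS set together with the generating
#' truth.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `cds` (a DNA `seq_tbl`, all leaves equal
#'   length, frame-valid and stop-free internally), `truth` (list: `tree`,
#'   `site_substitutions` integer vector over nucleotide sites,
#'   `realized_gc3` of the root, `root_seq`) and `config`.
#' @export
#' @examples
#' fam <- simulate_family(sim_config(n_taxa = 4, length_codons = 50,
#'                                   seed = 7))
#' fam$cds
simulate_family <- function(cfg) {
  if (!inherits(cfg, "sim_config")) rlang::abort("cfg must be a sim_config")
  set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_taxa, birth = 1, death = 0)
  tree$edge.length <- pmax(
    stats::rexp(nrow(tree$edge), rate = 1 / max(cfg$branch_scale, 1e-12)),
    cfg$min_branch)
  if (cfg$branch_scale == 0) tree$edge.length[] <- 0
  tree$tip.label <- paste0("t", seq_len(cfg$n_taxa))
  map <- codon_map()

  root_codons <- sample_root_codons(cfg$length_codons, cfg$gc3_target)
  root_nt <- strsplit(paste(root_codons, collapse = ""), "")[[1]]
  realized_gc3 <- mean(substr(root_codons, 3, 3) %in% c("G", "C"))

  n_sites <- length(root_nt)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  counts <- integer(n_sites)
  root_node <- ntip + 1
  seqs[[root_node]] <- root_nt
  # cladewise edge order guarantees a parent is evolved before its children
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    res <- evolve_branch(seqs[[parent]], tree$edge.length[e],
                         cfg$kappa, cfg$omega_like, map)
    seqs[[child]] <- res$nt
    counts <- counts + res$counts
  }
  leaf_seq <- vapply(seq_len(ntip), function(i) {
    s <- paste(seqs[[i]], collapse = "")
    if (cfg$include_stop) paste0(s, "TAA") else s
  }, character(1))
  cds <- seq_tbl(tree$tip.label, leaf_seq, kind = "dna")
  list(cds = cds,
       truth = list(tree = tree, site_substitutions = counts,
                    realized_gc3 = realized_gc3,
                    root_seq = paste(root_nt, collapse = "")),
       config = cfg)
}

#' Write a deterministic fixture battery
#'
#' Generates the toy alignments used in examples plus one avUCP-like
#' 8 x 924 nt family with its truth files, and a JSON manifest with MD5
#' checksums. The same seed always reproduces byte-identical files.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest as a list, invisibly; files are written under
#'   `out_dir`.
#' @export
make_fixture_suite <- function(out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed)
  fam <- simulate_family(cfg)
  paths <- list(
    family = file.path(out_dir, "family_cds.fasta"),
    tree = file.path(out_dir, "family_true_tree.nwk"),
    truth = file.path(out_dir, "family_site_substitutions.tsv"),
    toy = file.path(out_dir, "toy_alignment.fasta")
  )
  write_fasta(fam$cds, paths$family)
  ape::write.tree(fam$truth$tree, file = paths$tree)
  utils::write.table(
    data.frame(site = seq_along(fam$truth$site_substitutions),
               substitutions = fam$truth$site_substitutions),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  toy <- seq_tbl(paste0("s", 1:4), c("AAAA", "AAAB", "AABB", "AABB"),
                 kind = "protein")
  write_fasta(toy, paths$toy)
  manifest <- list(
    seed = seed,
    config = unclass(cfg),
    realized_gc3 = fam$truth$realized_gc3,
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
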