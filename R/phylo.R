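# Distance-based phylogenetics: p-distances, Jukes-Cantor protein
# correction, a deterministic Saitou-Nei neighbor-joining implementation,
# and column-resampling bootstrap supports. Trees are `ape::phylo` objects.

#' Pairwise mismatch proportion
#'
#' @param a,b Protein (or nucleotide) sequences of equal length.
#' @return Mismatch fraction over the compared columns.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) rlang::abort("sequences have unequal lengths")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

#' Jukes-Cantor protein distance
#'
#' d = -(19/20) ln(1 - 20 p / 19), the 20-state Jukes-Cantor multiple-hit
#' correction of an observed mismatch proportion p. Saturated inputs
#' (p >= 19/20) cannot be corrected; they are returned as the sentinel
#' `max_distance` with a warning rather than NaN.
#'
#' @param p Observed mismatch proportion(s) in `[0, 1]`.
#' @param max_distance Sentinel used for saturated distances.
#' @return Corrected distance(s); `d >= p` always.
#' @export
#' @examples
#' jc_protein_distance(0.05)
jc_protein_distance <- function(p, max_distance = 10) {
  if (any(p < 0 | p > 1)) rlang::abort("p must be in [0, 1]")
  sat <- p >= 19 / 20
  if (any(sat)) {
    rlang::warn(paste0(sum(sat), " saturated distance(s) (p >= 19/20) set",
                       " to sentinel ", max_distance))
  }
  d <- ifelse(sat, max_distance, -(19 / 20) * log(1 - 20 * p / 19))
  d
}

#' Pairwise distance matrix for a protein family
#'
#' @param x An aligned protein sequence tibble.
#' @param model `"jc"` (Jukes-Cantor corrected, default) or `"p"` (raw
#'   mismatch proportion).
#' @return A symmetric matrix with zero diagonal, labelled by `id`.
#' @export
protein_distances <- function(x, model = c("jc", "p")) {
  model <- match.arg(model)
  m <- align_matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(m[i, ] != m[j, ])
      d[i, j] <- d[j, i] <- if (model == "jc") jc_protein_distance(p) else p
    }
  }
  d
}

# Saitou-Nei neighbor joining with deterministic tie-breaking (the
# lexicographically smallest label pair among Q-minima) and non-negative
# branch lengths (a negative estimate is clamped to zero and the deficit
# moved to its sibling edge, preserving the path length between the pair).
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) rlang::abort("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) rlang::abort("neighbor joining needs at least 3 taxa")
  # active nodes as newick fragments
  frag <- labels
  repeat {
    n <- nrow(d)
    if (n == 3) break
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(frag[cand[, 1]], frag[cand[, 2]]),
                 pmax(frag[cand[, 1]], frag[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    # clamp negative estimates, moving the deficit to the sibling edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vj <- max(vj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, u = du), u = c(du, 0))
    frag <- c(frag[-c(i, j)], new_frag)
  }
  # final three nodes join at an internal node with closed-form lengths
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[1], v[1], frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree
#'
#' Builds the unrooted Saitou-Nei neighbor-joining tree from a symmetric
#' distance matrix. Ties in the Q criterion are broken by the
#' lexicographically smallest label pair so output is deterministic;
#' negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling edge.
#'
#' @param d Symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) nj_tree(as.matrix(d))

# canonical split strings of the internal edges of an unrooted tree
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1 || length(side) >= n - 1) next
    other <- setdiff(tips, side)
    canon <- if (length(side) < length(other) ||
                 (length(side) == length(other) &&
                  side[1] < other[1])) side else other
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree on
#' Jukes-Cantor protein distances for each replicate, and reports for every
#' internal bipartition of the full-data tree the percentage of replicates
#' containing it. Supports are attached as `node.label` on the returned
#' tree (root/trivial nodes get `NA`).
#'
#' @param x An aligned protein sequence tibble.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param model Distance model passed to [protein_distances()].
#' @return A list of class `boot_tree`: `tree` (the full-data `phylo` with
#'   `node.label` supports) and `supports` (tibble `split`, `support`).
#' @export
bootstrap_support <- function(x, n_reps = 100, seed = 1, model = "jc") {
  if (n_reps < 1) rlang::abort("n_reps must be >= 1")
  m <- align_matrix(x)
  ref <- neighbor_joining(protein_distances(x, model))
  ref_splits <- tree_splits(ref)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    xb <- x
    xb$seq <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    db <- protein_distances(xb, model)
    if (all(db == 0)) next  # degenerate replicate: identical sequences
    bs <- tree_splits(neighbor_joining(db))
    hits[ref_splits %in% bs] <- hits[ref_splits %in% bs] + 1
  }
  support <- 100 * hits / n_reps
  # attach supports to internal nodes
  ntip <- length(ref$tip.label)
  node_lab <- rep("", ref$Nnode)  # empty for root/trivial nodes
  for (node in (ntip + 1):(ntip + ref$Nnode)) {
    tips_below <- ref$tip.label[unlist(phy_descendants(ref, node))]
    all_tips <- sort(ref$tip.label)
    side <- sort(tips_below)
    other <- setdiff(all_tips, side)
    if (length(side) <= 1 || length(other) <= 1) next
    canon <- if (length(side) < length(other) ||
                 (length(side) == length(other) &&
                  side[1] < other[1])) side else other
    key <- paste(canon, collapse = "|")
    if (key %in% names(support)) {
      node_lab[node - ntip] <- format(round(support[[key]], 1))
    }
  }
  ref$node.label <- node_lab
  out <- list(tree = ref,
              supports = tibble::tibble(split = names(support),
                                        support = unname(support)),
              n_reps = n_reps, seed = seed)
  class(out) <- "boot_tree"
  out
}

phy_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phy_descendants, tree = tree))
}

#' @export
print.boot_tree <- function(x, ...) {
  cat(sprintf("Neighbor-joining tree with %d tips, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$n_reps))
  print(x$supports)
  invisible(x)
}

#' @export
tidy.boot_tree <- function(x, ...) x$supports

#' @export
glance.boot_tree <- function(x, ...) {
  tibble::tibble(n_tips = length(x$tree$tip.label), n_reps = x$n_reps,
                 min_support = min(x$supports$support),
                 mean_support = mean(x$supports$support))
}

#' Are two taxa sisters (a cherry) in a tree?
#'
#' @param tree An `ape::phylo`.
#' @param a,b Tip labels.
#' @return `TRUE` if `a` and `b` form a two-tip clade in the unrooted tree.
#' @export
is_sister_pair <- function(tree, a, b) {
  paste(sort(c(a, b)), collapse = "|") %in% tree_splits(tree)
}

#' Write a tree to Newick
#'
#' Branch lengths and any bootstrap supports (as internal node labels) are
#' preserved; the file round-trips through [read_newick()].
#'
#' @param tree An `ape::phylo` or a [bootstrap_support()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "boot_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix as square PHYLIP-like TSV
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(d, path) {
  df <- data.frame(taxon = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
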