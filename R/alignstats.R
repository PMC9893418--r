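# Alignment-level statistics: site classification, per-column Shannon
# entropy, entropy summaries, and logo matrices. Alignments are sequence
# tibbles whose rows all have the same length; no aligner is built in.

align_matrix <- function(x, strict = FALSE) {
  lens <- nchar(x$seq)
  if (nrow(x) < 2) rlang::abort("an alignment needs at least 2 sequences")
  if (length(unique(lens)) != 1) {
    rlang::abort(paste0(
      "sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
      "); supply a pre-computed alignment or equal-length ungapped sequences"))
  }
  m <- do.call(rbind, strsplit(x$seq, ""))
  rownames(m) <- x$id
  m
}

ambiguous_states <- function(kind) {
  if (kind == "dna") c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                       "-", ".") else c("X", "B", "Z", "J", "-", ".")
}

#' Classify alignment columns
#'
#' Labels every column of an equal-length alignment as `conserved` (a single
#' state), `parsimony_informative` (at least two states, each present in at
#' least two sequences) or `singleton` (variable but not
#' parsimony-informative). Gap/ambiguity characters are treated as an
#' additional state by default; with `strict = TRUE` columns containing any
#' such character are excluded from classification and reported.
#'
#' @param x An aligned sequence tibble.
#' @param strict Exclude columns containing gap/ambiguity characters.
#' @return A tibble with columns `position` (1-based), `n_states`, `class`.
#'   The counts are available through [site_counts()] or `glance()`.
#' @export
#' @examples
#' aln <- seq_tbl(paste0("s", 1:4), c("AAA", "AAA", "AAB", "ABB"),
#'                kind = "protein")
#' classify_sites(aln)
classify_sites <- function(x, strict = FALSE) {
  m <- align_matrix(x)
  amb <- ambiguous_states(seq_kind(x))
  excluded <- logical(ncol(m))
  cls <- character(ncol(m))
  nst <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (strict && any(col %in% amb)) {
      excluded[j] <- TRUE
      cls[j] <- NA_character_
      nst[j] <- NA_integer_
      next
    }
    tab <- table(col)
    nst[j] <- length(tab)
    cls[j] <- if (length(tab) == 1) {
      "conserved"
    } else if (sum(tab >= 2) >= 2) {
      "parsimony_informative"
    } else {
      "singleton"
    }
  }
  out <- tibble::tibble(position = seq_len(ncol(m)),
                        n_states = nst, class = cls)
  class(out) <- c("site_class", class(out))
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Aggregate site-classification counts
#'
#' @param sites Output of [classify_sites()].
#' @return One-row tibble with `n_sites`, `conserved`, `variable`,
#'   `parsimony_informative`, `singleton`, `excluded`. By construction
#'   `conserved + variable == n_sites - excluded` and
#'   `parsimony_informative + singleton == variable`.
#' @export
site_counts <- function(sites) {
  cls <- sites$class[!is.na(sites$class)]
  tibble::tibble(
    n_sites = nrow(sites),
    conserved = sum(cls == "conserved"),
    variable = sum(cls != "conserved"),
    parsimony_informative = sum(cls == "parsimony_informative"),
    singleton = sum(cls == "singleton"),
    excluded = attr(sites, "n_excluded") %||% 0L
  )
}

#' @export
glance.site_class <- function(x, ...) site_counts(x)

#' Per-column Shannon entropy
#'
#' H = -sum(p * log(p)) over the state frequencies of each column, in nats
#' by default (`log_base = exp(1)`); use `log_base = 2` for bits. A
#' monomorphic column has entropy 0; with n rows the maximum is
#' log(min(alphabet size, n)).
#'
#' @param x An aligned sequence tibble.
#' @param log_base Base of the logarithm (default natural).
#' @param strict Exclude columns containing gap/ambiguity characters
#'   (entropy `NA` there).
#' @return A tibble with columns `position` and `entropy`, of class
#'   `entropy_profile`.
#' @export
column_entropy <- function(x, log_base = exp(1), strict = FALSE) {
  m <- align_matrix(x)
  amb <- ambiguous_states(seq_kind(x))
  H <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (strict && any(col %in% amb)) return(NA_real_)
    p <- as.numeric(table(col)) / length(col)
    -sum(p * log(p)) / log(log_base)
  }, numeric(1))
  out <- tibble::tibble(position = seq_len(ncol(m)), entropy = H)
  class(out) <- c("entropy_profile", class(out))
  attr(out, "log_base") <- log_base
  attr(out, "n_rows") <- nrow(m)
  out
}

zero_runs <- function(is_zero) {
  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

#' Summarize an entropy profile
#'
#' Reports the mean entropy, the number of exactly-zero columns, the maximum
#' and its position(s), the top positions ranked by entropy (ties broken by
#' position), and all maximal zero-entropy runs strictly longer than
#' `zero_run_min_len` columns (1-based inclusive spans).
#'
#' @param profile Output of [column_entropy()].
#' @param zero_run_min_len Minimum length (strict) for a zero run to be
#'   reported; default 10.
#' @param n_top Number of top-entropy positions to report.
#' @return A list of class `entropy_summary` with elements `mean`, `n_zero`,
#'   `max`, `argmax`, `top` (tibble `position`, `entropy`) and `zero_runs`
#'   (tibble `start`, `end`, `length`).
#' @export
entropy_summary <- function(profile, zero_run_min_len = 10, n_top = 7) {
  H <- profile$entropy
  ok <- !is.na(H)
  runs <- zero_runs(ok & H == 0)
  runs <- runs[runs$length > zero_run_min_len, , drop = FALSE]
  ord <- order(-H[ok], profile$position[ok])
  top <- tibble::tibble(position = profile$position[ok][ord],
                        entropy = H[ok][ord])[seq_len(min(n_top, sum(ok))), ]
  out <- list(
    mean = mean(H[ok]),
    n_zero = sum(H[ok] == 0),
    max = max(H[ok]),
    argmax = profile$position[ok][H[ok] == max(H[ok])],
    top = top,
    zero_runs = runs,
    zero_run_min_len = zero_run_min_len
  )
  class(out) <- "entropy_summary"
  out
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("Entropy summary: mean %.3f, %d zero columns, max %.3f at %s\n",
              x$mean, x$n_zero, x$max, paste(x$argmax, collapse = ",")))
  cat(sprintf("%d zero-entropy runs longer than %d columns\n",
              nrow(x$zero_runs), x$zero_run_min_len))
  invisible(x)
}

#' @export
glance.entropy_summary <- function(x, ...) {
  tibble::tibble(mean_entropy = x$mean, n_zero = x$n_zero,
                 max_entropy = x$max, argmax = x$argmax[1],
                 n_zero_runs = nrow(x$zero_runs))
}

#' @export
tidy.entropy_summary <- function(x, ...) x$zero_runs

#' Sequence-logo matrix
#'
#' Per-column information content (bits) and per-letter heights for a
#' protein alignment: information = log2(20) - H_col (in bits, no
#' small-sample correction), letter height = letter frequency x column
#' information, so the heights of a column sum to its information.
#'
#' @param x An aligned protein sequence tibble.
#' @return A long tibble with columns `position`, `letter`, `frequency`,
#'   `information` (per column, bits) and `height`.
#' @export
logo_matrix <- function(x) {
  m <- align_matrix(x)
  n <- nrow(m)
  alpha_bits <- log2(20)
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    p <- as.numeric(tab) / n
    H <- -sum(p * log2(p))
    info <- max(alpha_bits - H, 0)
    tibble::tibble(position = j, letter = names(tab), frequency = p,
                   information = info, height = p * info)
  })
}
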