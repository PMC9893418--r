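# Kyte-Doolittle hydropathy profiling and alternating membrane-topology
# assembly for polytopic inner-membrane carriers (the 6-transmembrane
# mitochondrial carrier fold being the motivating case).

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted mean of per-residue Kyte-Doolittle values. Positions
#' are 1-based window centers, so the profile has `L - window + 1` rows.
#'
#' @param seq A single protein sequence (string).
#' @param window Odd window size `<=` the sequence length (default 19, the
#'   classic choice for transmembrane-helix detection).
#' @return A tibble of class `kd_profile` with columns `position`,
#'   `hydropathy`, carrying the window size as attribute.
#' @export
#' @examples
#' kd_profile(strrep("I", 30), window = 19)
kd_profile <- function(seq, window = 19) {
  check_protein(seq)
  L <- nchar(seq)
  if (window %% 2 == 0) rlang::abort("window must be odd")
  if (window > L) rlang::abort("window larger than the sequence")
  v <- kd_hydropathy()[strsplit(seq, "")[[1]]]
  prof <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  keep <- !is.na(prof)
  out <- tibble::tibble(position = which(keep), hydropathy = prof[keep])
  class(out) <- c("kd_profile", class(out))
  attr(out, "window") <- window
  attr(out, "length") <- L
  out
}

#' Call transmembrane segments on a hydropathy profile
#'
#' Maximal runs of profile values strictly above `threshold`; runs separated
#' by fewer than `min_gap` positions are merged, then runs shorter than
#' `min_len` are dropped. Deterministic.
#'
#' @param profile Output of [kd_profile()].
#' @param threshold Hydropathy cutoff (default 1.6, the Kyte-Doolittle
#'   recommendation for membrane-spanning segments).
#' @param min_len Minimum segment length in positions (default 15).
#' @param min_gap Runs closer than this many positions are merged
#'   (default 5).
#' @return A tibble with columns `start`, `end`, `label` (all
#'   `"transmembrane"`), 1-based inclusive profile positions.
#' @export
call_tm_segments <- function(profile, threshold = 1.6, min_len = 15,
                             min_gap = 5) {
  above <- profile$hydropathy > threshold
  if (!any(above)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          label = character()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = profile$position[starts[r$values]],
                    end = profile$position[ends[r$values]])
  # merge segments separated by a short gap
  if (nrow(seg) > 1) {
    merged <- seg[1, ]
    for (k in 2:nrow(seg)) {
      if (seg$start[k] - merged$end[nrow(merged)] - 1 < min_gap) {
        merged$end[nrow(merged)] <- seg$end[k]
      } else {
        merged <- rbind(merged, seg[k, ])
      }
    }
    seg <- merged
  }
  seg <- seg[seg$end - seg$start + 1 >= min_len, , drop = FALSE]
  tibble::tibble(start = seg$start, end = seg$end,
                 label = rep("transmembrane", nrow(seg)))
}

#' Assemble an alternating membrane topology
#'
#' Tiles residues 1..L with the called transmembrane segments and labels the
#' gaps between them alternately, starting from the N-terminal side
#' (extracellular by default, as for the mitochondrial carrier topology with
#' both termini outside). With 6 TM segments and an extracellular N-terminus
#' this yields 4 extracellular and 3 cytoplasmic regions.
#'
#' @param segments Tibble of non-overlapping, sorted TM segments
#'   (`start`, `end`).
#' @param length Protein length L.
#' @param n_term Label of the N-terminal segment: `"extracellular"`
#'   (default) or `"cytoplasmic"`.
#' @return A tibble of class `topology_model` with columns `start`, `end`,
#'   `label`, tiling 1..L exactly once.
#' @export
assemble_topology <- function(segments, length,
                              n_term = c("extracellular", "cytoplasmic")) {
  n_term <- match.arg(n_term)
  other <- setdiff(c("extracellular", "cytoplasmic"), n_term)
  if (nrow(segments) > 1) {
    if (any(diff(segments$start) <= 0) ||
        any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      rlang::abort("segments must be sorted and non-overlapping")
    }
  }
  if (nrow(segments) > 0 &&
      (segments$start[1] < 1 || segments$end[nrow(segments)] > length)) {
    rlang::abort("segments fall outside 1..length")
  }
  rows <- list()
  cursor <- 1
  side <- n_term
  for (k in seq_len(nrow(segments))) {
    if (segments$start[k] > cursor) {
      rows <- c(rows, list(tibble::tibble(start = cursor,
                                          end = segments$start[k] - 1,
                                          label = side)))
    }
    rows <- c(rows, list(tibble::tibble(start = segments$start[k],
                                        end = segments$end[k],
                                        label = "transmembrane")))
    cursor <- segments$end[k] + 1
    side <- if (side == n_term) other else n_term
  }
  if (cursor <= length) {
    rows <- c(rows, list(tibble::tibble(start = cursor, end = length,
                                        label = side)))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("topology_model", class(out))
  attr(out, "protein_length") <- length
  out
}

#' One-call membrane topology for a protein
#'
#' Runs [kd_profile()], [call_tm_segments()] and [assemble_topology()] with
#' shared defaults.
#'
#' @param seq A single protein sequence.
#' @inheritParams kd_profile
#' @inheritParams call_tm_segments
#' @inheritParams assemble_topology
#' @return A `topology_model` tibble; the TM segment count is
#'   `sum(label == "transmembrane")`.
#' @export
membrane_topology <- function(seq, window = 19, threshold = 1.6,
                              min_len = 15, min_gap = 5,
                              n_term = "extracellular") {
  prof <- kd_profile(seq, window)
  seg <- call_tm_segments(prof, threshold, min_len, min_gap)
  assemble_topology(seg, nchar(seq), n_term)
}

#' @export
glance.topology_model <- function(x, ...) {
  tibble::tibble(
    n_transmembrane = sum(x$label == "transmembrane"),
    n_extracellular = sum(x$label == "extracellular"),
    n_cytoplasmic = sum(x$label == "cytoplasmic"),
    protein_length = attr(x, "protein_length")
  )
}

#' @export
tidy.topology_model <- function(x, ...) {
  tibble::as_tibble(x)
}
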