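test_that("KD profiles are windowed means with 1-based center positions", {
  p <- kd_profile(strrep("I", 30), window = 19)
  expect_equal(nrow(p), 30 - 19 + 1)
  expect_true(all(abs(p$hydropathy - 4.5) < 1e-12))
  expect_equal(p$position, 10:21)

  raw <- kd_profile("MKTAYI", window = 1)
  kd <- kd_hydropathy()
  expect_equal(raw$hydropathy,
               unname(kd[strsplit("MKTAYI", "")[[1]]]))

  # hand-computed centers of a 21-mer, window 5
  s <- "IIIIIDDDDDIIIIIDDDDDI"
  p5 <- kd_profile(s, window = 5)
  v <- kd[strsplit(s, "")[[1]]]
  expect_equal(p5$hydropathy[1], mean(v[1:5]))
  expect_equal(p5$hydropathy[9], mean(v[9:13]))

  expect_error(kd_profile("IIII", window = 2), "odd")
  expect_error(kd_profile("III", window = 19), "larger")
})

test_that("TM segment calling finds separated plateaus and respects filters", {
  # 6 hydrophobic plateaus separated by hydrophilic linkers
  block <- function(n, ch) strrep(ch, n)
  s <- paste0(block(12, "D"),
              paste(rep(paste0(block(21, "I"), block(18, "D")), 6),
                    collapse = ""),
              block(5, "D"))
  prof <- kd_profile(s, window = 9)
  seg <- call_tm_segments(prof, threshold = 1.6, min_len = 10, min_gap = 3)
  expect_equal(nrow(seg), 6)

  low <- kd_profile(strrep("D", 50), window = 9)
  expect_equal(nrow(call_tm_segments(low)), 0)

  # min_len filter drops short spikes
  spike <- tibble::tibble(position = 1:30,
                          hydropathy = c(rep(0, 10), rep(3, 4), rep(0, 16)))
  expect_equal(nrow(call_tm_segments(spike, min_len = 5)), 0)
  expect_equal(nrow(call_tm_segments(spike, min_len = 3)), 1)

  # nearby runs merge across a sub-min_gap dip
  dip <- tibble::tibble(position = 1:40,
                        hydropathy = c(rep(3, 15), rep(0, 2), rep(3, 15),
                                       rep(0, 8)))
  m <- call_tm_segments(dip, min_len = 15, min_gap = 5)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 32))
})

test_that("raising the threshold never increases TM coverage, nor the count on plateau profiles", {
  # coverage (residues inside called segments) is monotone for any profile
  set.seed(3)
  prof <- tibble::tibble(position = 1:200,
                         hydropathy = stats::filter(rnorm(220, 0.5, 2),
                                                    rep(1 / 21, 21),
                                                    sides = 2)[11:210])
  coverage <- vapply(seq(0, 3, by = 0.5), function(th) {
    seg <- call_tm_segments(prof, threshold = th, min_len = 1, min_gap = 1)
    sum(seg$end - seg$start + 1)
  }, numeric(1))
  expect_true(all(diff(coverage) <= 0))

  # on well-separated flat plateaus the segment count itself is monotone
  plateau <- tibble::tibble(
    position = 1:120,
    hydropathy = rep(c(0, 1.0, 0, 2.0, 0, 3.0), each = 20))
  counts <- vapply(c(0.5, 1.5, 2.5, 3.5), function(th) {
    nrow(call_tm_segments(plateau, threshold = th, min_len = 5,
                          min_gap = 3))
  }, numeric(1))
  expect_equal(counts, c(3, 2, 1, 0))
})

test_that("topology assembly alternates sides and tiles the protein exactly", {
  seg6 <- tibble::tibble(start = c(10, 40, 70, 100, 130, 160),
                         end = c(25, 55, 85, 115, 145, 175))
  topo <- assemble_topology(seg6, 190)
  expect_equal(topo$label,
               c("extracellular", "transmembrane", "cytoplasmic",
                 "transmembrane", "extracellular", "transmembrane",
                 "cytoplasmic", "transmembrane", "extracellular",
                 "transmembrane", "cytoplasmic", "transmembrane",
                 "extracellular"))
  g <- glance(topo)
  expect_equal(g$n_transmembrane, 6L)
  expect_equal(g$n_extracellular, 4L)
  expect_equal(g$n_cytoplasmic, 3L)

  none <- assemble_topology(tibble::tibble(start = integer(),
                                           end = integer()), 50)
  expect_equal(none$label, "extracellular")
  expect_equal(c(none$start, none$end), c(1, 50))

  one <- assemble_topology(tibble::tibble(start = 10, end = 30), 50)
  expect_equal(one$label, c("extracellular", "transmembrane", "cytoplasmic"))

  expect_error(assemble_topology(tibble::tibble(start = c(1, 5),
                                                end = c(10, 20)), 30),
               "overlapping")
})

test_that("topology tiles 1..L once for fuzzed segment sets", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- sample(100:300, 1)
    k <- sample(0:6, 1)
    if (k > 0) {
      bounds <- sort(sample(seq_len(L), 2 * k))
      seg <- tibble::tibble(start = bounds[seq(1, 2 * k, 2)],
                            end = bounds[seq(2, 2 * k, 2)])
      seg <- seg[seg$end >= seg$start, ]
      if (nrow(seg) > 1 &&
          any(seg$start[-1] <= seg$end[-nrow(seg)])) next
    } else {
      seg <- tibble::tibble(start = integer(), end = integer())
    }
    topo <- assemble_topology(seg, L)
    covered <- unlist(Map(seq, topo$start, topo$end))
    expect_equal(covered, seq_len(L))
  }
})

test_that("membrane_topology chains profile, caller and assembly", {
  s <- paste0(strrep("D", 20), strrep("I", 25), strrep("D", 20),
              strrep("L", 25), strrep("D", 20))
  topo <- membrane_topology(s)
  expect_equal(sum(topo$label == "transmembrane"), 2)
  expect_equal(attr(topo, "protein_length"), nchar(s))
  expect_equal(tidy(topo)$end[nrow(topo)], nchar(s))
})
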