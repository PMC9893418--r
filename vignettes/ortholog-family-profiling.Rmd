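---
title: "Profiling ortholog coding-sequence families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ortholog coding-sequence families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofam)
library(dplyr)
```

orthofam characterizes small families of equal-length orthologous coding
sequences — the motivating case being the single avian uncoupling-protein
gene (avUCP), a 6-transmembrane mitochondrial inner-membrane carrier whose
CDS is 924 nt (307 residues) in each of eight bird species. This vignette
is the package's own account of the statistics it computes, the tunable
parameters and their defaults, the synthetic data generator used for
validation, and the numerical and design choices made where the
methodology was genuinely open.

## Codon-level statistics

**Positional composition.** For an in-frame CDS, `composition()` reports
base percentages overall and at codon positions 1–3, and GCk = Ck + Gk.
Values are held at full precision; `report_composition()` rounds to the
1-decimal convention of published GC grids. Third-position GC (GC3) is the
least constrained by selection on the protein and therefore the most
revealing of mutational/compositional bias.

**RSCU.** For codon $j$ of amino acid $i$ with degeneracy $n_i$ and count
$x_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{n_i\, x_{ij}}{\sum_j x_{ij}}.$$

RSCU > 1 marks a preferred codon, 0 an unused one. When an amino acid does
not occur at all the ratio is 0/0; we define all its codons' RSCU as 0,
matching the convention of published grids that print `0 0.0` for the
codons of absent amino acids. Met and Trp always carry RSCU 1 when
present. `codon_bias_summary()` counts strictly-greater-than-1 codons as
preferred and zero-count sense codons as unused.

**CAI.** `cai()` implements the Sharp–Li geometric mean of relative
adaptiveness $w_{ij} = f_{ij} / \max_j f_{ij}$ over the CDS's sense
codons, excluding Met, Trp and stops (their $w$ is constant 1).
Reference tables are read from either the Kazusa codon-usage text layout
or a plain TSV (`read_codon_table()`). Zero-frequency reference codons
would give $w = 0$ and a degenerate geometric mean; they are floored at
0.5 occurrences when the table carries counts, otherwise at half the
smallest positive frequency, with a warning. The package bundles only a
*synthetic* example reference table (`inst/extdata/synthetic_codon_table*`);
CAI values against real organisms require the corresponding real usage
table, which also makes published CAI values reproducible only up to the
(usually unstated) version of the reference table used.

**Expected CAI.** As a significance baseline, `expected_cai()` fits a
first-order Markov chain to the query's dinucleotide composition (with a
0.5 pseudocount on transitions to keep the chain irreducible), generates
`n_reps` random sequences of the same length (default 500 replications),
and summarizes the CAI distribution by mean, s.d. and upper 95% quantile.
The generator, seed handling and quantile choice are this package's
design; only the Markov-model-with-replications idea is inherited from
the CAIcal tradition. Results are reproducible under a fixed seed.

## Alignment statistics

Inputs must be pre-aligned or equal-length ungapped sequences (the avUCP
family is ungapped); unequal lengths are a hard error instructing the user
to supply an alignment — no aligner is built in.

**Site classification.** A column is *conserved* when it holds a single
state, *parsimony-informative* when at least two states each occur in at
least two sequences, else *singleton*. Two identities hold by
construction and are property-tested on fuzzed alignments:
conserved + variable = columns, and PI + singleton = variable. Gap and
ambiguity characters count as an extra state by default; `strict = TRUE`
excludes such columns and reports how many were dropped.

**Column entropy.** $H = -\sum_s p_s \log p_s$ over the observed state
frequencies. The default base is natural (nats): over 8 sequences the
extreme columns with state counts (2,2,2,1,1) and (4,1,1,1,1) give 1.56
and 1.39 nats, the values such profiles conventionally print; in bits
they would be 2.25 and 2.00. The base is configurable (`log_base = 2`
for bits). `entropy_summary()` reports the mean, the exactly-zero column
count, the ranked top positions (ties broken by position), and maximal
zero-entropy runs *strictly* longer than `zero_run_min_len` (default 10)
as 1-based inclusive spans — all positions throughout the package are
1-based inclusive.

**Logo matrix.** Column information is $\log_2 20 - H_{\mathrm{bits}}$
with no small-sample correction (deliberately: families of ~8 sequences
would otherwise be dominated by the correction term, and published logos
for such families do not apply it); letter height is frequency times
column information, so heights stack to the column information.

## Physio-chemical profiling

`physchem_profile()` bundles, per protein: molecular weight from average
(not monoisotopic) masses reported in kDa at 2 decimals; isoelectric
point; aliphatic index $X_A + 2.9 X_V + 3.9 (X_I + X_L)$ over mole
percents; sulfur atoms (#Cys + #Met); instability index; GRAVY (mean
Kyte–Doolittle hydropathy); extinction coefficients at 280 nm
(5500·Trp + 1490·Tyr, plus 125 per cystine pair, pairs counted as
floor(#Cys/2)); residue-set fractions; and a stability label (stable iff
II < 40).

The **instability index** is the Guruprasad dipeptide statistic
$\mathrm{II} = (10/L) \sum \mathrm{DIWV}(x_i, x_{i+1})$ with the published
400-entry weight table embedded in the package; it is the one per-residue
statistic that is *not* invariant under sequence reversal, which the test
suite asserts on a crafted example.

The **isoelectric point** bisects the Henderson–Hasselbalch net-charge
curve (termini plus D, E, C, Y, H, K, R) to 10⁻³ pH units. The default
pKa set is the Bjellqvist/Expasy-style set including first/last-residue
adjustments of the terminal pKa values; an EMBOSS-style set is
selectable. Published pI values from proprietary tools are reproducible
only to about ±0.2 because their pKa sets are unstated.

The hydrophobic/hydrophilic residue split is tool-specific and often
undocumented in published grids (some grids print fractions that do not
even sum to 1); the sets are therefore exposed as configuration
(`default_residue_sets()`), and the defaults
({A,C,F,I,L,M,V,W} / {D,E,G,H,K,N,Q,R,S,T,Y}) are offered as descriptive
output, not as a reproduction of any specific tool.

## Distance phylogeny

Protein distances use the 20-state Jukes–Cantor correction
$d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ of the mismatch proportion
$p$. Saturated pairs ($p \ge 19/20$) cannot be corrected and are recorded
as a large sentinel (default 10) with a warning, never as silent `NaN`.

`neighbor_joining()` is a deterministic Saitou–Nei implementation: ties
in the Q criterion are broken by the lexicographically smallest label
pair, and negative branch-length estimates are clamped to zero with the
deficit moved to the sibling edge, preserving the path length between the
joined pair. On additive matrices it provably recovers the generating
tree; the tests verify this on random trees up to 10 taxa via a
path-length oracle and against an independent NJ implementation.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports the percentage of replicates
containing each internal bipartition of the full-data tree, attached as
node labels and round-tripped through Newick.

## Membrane topology

`kd_profile()` computes the sliding unweighted mean of Kyte–Doolittle
hydropathy (window 19 by default, the classic choice for membrane-helix
detection). `call_tm_segments()` takes maximal runs above a threshold
(default 1.6), merges runs separated by fewer than `min_gap` = 5
positions, and drops runs shorter than `min_len` = 15. All parameters
are configurable and logged in the pipeline output; published segment
boundaries from homology-based predictors will not be matched exactly —
only the segment *count* is a stable target. `assemble_topology()` tiles
1..L, labelling inter-segment gaps alternately from the N-terminus
(extracellular by default, the documented orientation of the
mitochondrial carrier fold with both termini outside; configurable for
other proteins). With 6 TM segments this yields the canonical
4-extracellular / 3-cytoplasmic alternation.

One caution on invariants: the *count* of called segments is not globally
monotone in the threshold (raising it can split a run crossing a shallow
dip into two runs). What is monotone — and what the tests assert on
arbitrary profiles — is the above-threshold coverage; the count itself is
additionally checked on well-separated plateau profiles, the regime the
intuition describes.

## The synthetic ortholog-family generator

`simulate_family()` supplies every stage with inputs of known truth. A
root CDS is drawn codon-by-codon from the 61 sense codons with
third-position G+C probability `gc3_target`; it evolves along a Yule
topology with i.i.d. exponential branch lengths (mean `branch_scale`) by
per-site nucleotide events: proposal weights favour transitions by
`kappa`, proposals creating stop codons are rejected, and nonsynonymous
proposals are accepted with probability `omega_like`. Leaves are
equal-length, frame-valid and internally stop-free, with an optional
fixed terminal stop.

The defaults emulate the avUCP study conditions: 8 taxa, 307 sense
codons (+ stop = 924 nt), `gc3_target` 0.88 (the published GC3 range is
roughly 80–95%), `branch_scale` 0.03, `kappa` 2, `omega_like` 0.5. Under
these defaults a typical family shows on the order of 650–700 conserved
of 924 nucleotide sites — the same conservation regime as the real
family. What the generator does *not* emulate: indels (the real family is
ungapped), rate heterogeneity across sites, a rigorous codon-model rate
matrix (GY94-style), lineage-specific composition, and real codon-usage
preferences. Passing tests on simulated data therefore demonstrate the
*correctness of the statistics and their invariants*, not distributional
realism of any particular organism.

**Identifiability and the recovery experiment.** Exponential branch
lengths place positive density at zero, so a family of trees contains
near-polytomies: at protein length 1000 an internal branch below ~0.005
expected substitutions/site is within one standard error of the distance
noise and *no* method can recover it reliably. In a pilot across branch
scales 0.02–0.15 and 5–8 taxa, unconditioned recovery plateaued at
roughly 80–90% for exactly this reason, with every failure traceable to
an internal branch under 0.0074. The parameter-recovery experiment
therefore conditions on identifiable trees via `min_branch = 0.01`
(a floor on sampled branch lengths; the default 0 keeps the pure
exponential model), at `branch_scale` 0.05, neutral acceptance
(`omega_like = 1`), 8 taxa and 1000 codons, where recovery measured
97.5% over a 40-seed pilot. The frozen test asserts ≥ 90% over 20 seeds.

## Problem sizes and reproducibility

The test suite runs entirely on generated data: fuzzed families of 3–10
taxa and 40–150 codons for unit properties, 20 seeds × 1000 codons for
the recovery experiment, and 100-replicate bootstraps on 4–8 taxa —
about 15 s in total. The acceptance script
(`scripts/acceptance.R --seed N --out f.json`) regenerates the
study-condition family from its seed, runs every stage (500 expected-CAI
replications, 100 bootstrap replicates, the 20-seed recovery experiment)
and writes the headline numbers as JSON in about 15 s. Every stochastic
step is driven by the supplied seed; rerunning with the same seed
reproduces the output byte for byte.

Checks that require the *deposited* eight-species avUCP sequences (the
published composition/RSCU/entropy/physio-chemical grids and the
chicken–turkey sister relationship) live in the acceptance test file and
need `scripts/fetch_avucp.R` to have been run once with network access;
without the data they fail with a clear message rather than silently
skipping.

## Known limitations

- CAI against real organisms needs a real reference table; only a
  synthetic example table ships with the package.
- The hydropathy segment caller is threshold-based; it matches the
  count-level behaviour of SVM/homology predictors on strongly
  hydrophobic carriers but not their boundaries.
- The simulator's substitution process is adequate for producing
  conserved/PI/singleton structure and tree signal, but is not a
  likelihood-grade codon model and should not be used for inference
  benchmarking beyond topology recovery.
- `p_distance` compares all columns including gaps as states; families
  with many gaps should be pre-filtered.
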