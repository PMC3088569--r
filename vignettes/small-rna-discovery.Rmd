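---
title: "Annotating small RNA libraries and discovering novel miRNA hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating small RNA libraries and discovering novel miRNA hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

srnapipe analyses deep-sequencing libraries of small RNAs read at a fixed
length (36 nt) on early Illumina chemistry: because inserts are 16-30 nt,
every legitimate read runs through the insert into the 3' sequencing
adaptor, and the adaptor content of a read is itself the primary evidence
that the read is a genuine library insert. This vignette explains the model
behind each stage, the tunable parameters, what the synthetic data generator
does and does not emulate, and the numerical choices that make runs
bit-reproducible.

## The pipeline at a glance

```{r}
library(srnapipe)
cfg <- run_config()
ds  <- generate_dataset(generator_config(n_reads = 100000, rng_seed = 1))
run <- run_small_rna_pipeline(ds$reads, ds$genome, ds$tracks, cfg,
                              mirna_meta = ds$mirna_meta)
run$report
```

Stages, in order: read collapsing into unique tags, adaptor screening,
dual-end exact alignment, precedence annotation, CPM expression, candidate
selection and hairpin discovery. Each stage is also exported on its own and
operates on tibbles, so intermediate results can be inspected or replaced.

## Unique tags and adaptor classes

All downstream accounting is per *unique tag* — a distinct 36-nt read
sequence with its read count. Collapsing applies no quality or adaptor
filter; qualities are read and discarded. Ranking is by decreasing count
with lexicographic tie-break: the tie-break is not part of any biological
claim, it simply makes tag identifiers (`<prefix>_<rank>`) stable across
runs and machines.

Adaptor screening is exact-match: `overlap_3p` is the longest prefix of the
3' adaptor (`TCGTATGCCGTCTTCTGCTTGT`) that matches a suffix of the tag, and
`overlap_5p` the longest suffix of the 5' adaptor
(`GTTCAGAGTTCTACAGTCCGACGATC`) matching the tag's prefix, each requiring at
least `min_adaptor_overlap` (default 6) nt. We chose exact matching over an
alignment-based screen because no mismatch model is defensible at 6-20 nt
overlaps without a quality model, and 6 nt keeps the chance of a spurious
call at a read end near 4^-6. The three classes follow directly: neither
end found means the read is interior sequence of a longer transcript
(`no_adaptor` contamination), an empty insert means a cloning artefact
(`adaptor_only`), anything else with at least one adaptor end is
`legitimate`.

Insert size classes are `<=15`, `16-19`, `20-25`, `26-29`, `>=30` nt. A
16-nt insert is assigned to `16_19`, keeping the bins disjoint; the lowest
bin is everything 15 nt and shorter.

## Exact dual-end alignment

Tags are aligned by two 22-nt end queries: the 5'-most 22 nt (14 bases
stripped from the 3' end — for short inserts this strips the adaptor and is
the pass that should match) and the 3'-most 22 nt (14 stripped from the 5'
end). Queries are taken from the raw 36-nt tag, not the trimmed insert.
Matching is perfect-match only, against a k-mer index holding both strands;
queries or genomic windows containing N cannot match by construction.

All tags are aligned, not only legitimate ones — the matched and unmatched
read totals must partition the full library, which forces this choice.
Multi-locus tags are retained and categorised rather than discarded, with
the listed loci capped (`multi_locus_report_cap`, default 10) and the true
locus count kept.

When both passes of one tag match, they usually represent the same physical
placement 14 nt apart. Hits are therefore normalised to the implied 36-nt
tag footprint before combination, and the duplicate (the `end5` copy) is
flagged redundant; tag-level uniqueness is computed over distinct
footprints. Without this normalisation every fully genomic tag would count
as two "loci".

## Annotation precedence

Each genome-matched tag receives exactly one category by fixed precedence:
repeats > infrastructure ncRNAs > known miRNAs/stars/precursors > RefSeq >
ESTs, falling through to `unique_no_annotation` / `multi_no_annotation`.
One category per tag is what makes the summary table a partition (its rows
sum to the matched totals), and repeats are screened first so that
repeat-derived fragments can never inflate miRNA counts. Overlap of >= 1 nt
suffices and is strand-agnostic by default, since repeat and EST tracks are
frequently unstranded; `strand_aware_tracks` switches individual tracks to
stranded matching. Multi-locus tags take the best-precedence category over
all their reported loci.

## Expression

Per-miRNA counts are the summed read counts of all tags annotated to the
feature, and CPM is count / total sequence reads x 10^6 — the denominator
is the library total, not the mapped total. Per-feature CPM is reported to
2 decimals, family aggregates (sums over member CPM) to the nearest
integer; all reported rounding is half-up, and percentages are printed to 1
decimal of total reads.

## Hairpin discovery

Candidates are unique-locus tags annotated RefSeq, EST or nothing. No
count floor is applied: single-count tags are retained, because genuinely
expressed miRNAs sit in that abundance range too. For each candidate the
mature insert's genomic span is flanked by `flank_default` (150 nt, the
midpoint of the admissible 100-200 range) and the window is scanned:
every subwindow of 60-150 nt containing the full mature sequence is scored
by minimum free energy, then — in order of increasing energy, shorter
length, 5'-most position — folded and evaluated until a candidate passes
all seven criteria:

* `length_ok`: final precursor 60-80 nt;
* `mfe_ok`: MFE <= -30 kcal/mol;
* `unbranched_ok`: exactly one terminal loop (no multiloop, single stem);
* `arm_ok`: the mature lies entirely on one arm, not touching the loop;
* `pairing_ok`: >= 16 mature nucleotides paired to the opposite arm
  (`mature_pair_mode = "total"` counts all paired mature positions;
  `"contiguous"` counts the unbroken run from the mature 5' end — "total"
  is the default because natural precursors commonly interrupt the mature
  duplex with single-nucleotide bulges);
* `loop_ok`: no interior loop side longer than 10 nt;
* `bulge_ok`: no interior loop with side asymmetry above 4 nt.

The loop/bulge thresholds quantify the qualitative requirement that a
precursor must not contain large internal loops or asymmetric bulges; 10
and 4 nt are our interpretations, exposed as `max_internal_loop` and
`max_bulge_asymmetry`. Subwindows whose energy misses the cutoff or whose
length is outside 60-80 nt are skipped without folding — they cannot pass —
which is what keeps the scan fast on unstructured windows.

Putative matures are finally compared against known miRNAs two ways:
full-length Levenshtein distance (threshold `homology_max_edit`, default 2)
and exact identity of the seed (nucleotides 2-8).

## The energy model

Folding is a Zuker-style dynamic programme over nested structures with
Watson-Crick and G·U pairs and a minimum hairpin loop of 3 nt. The model is
a compact nearest-neighbour parameterisation, tabulated in one place
(`energy_params()`) and shared verbatim by the C++ engine and the R-side
loop-decomposition evaluator `structure_energy()`:

* a 6x6 stacking table (kcal/mol at 37 °C) over pair types CG, GC, GU, UG,
  AU, UA;
* hairpin, bulge and internal-loop penalties tabulated by size with
  logarithmic extrapolation `E(n) = E(n0) + 1.079 ln(n/n0)` beyond the
  table;
* an internal-loop asymmetry penalty of 0.5 kcal/mol per unpaired-side
  difference, capped at 3.0;
* an affine multiloop cost (3.4 closing + 0.4 per branch);
* no dangling ends, coaxial stacking or terminal-pair corrections.

Interior loops are capped at 30 unpaired nucleotides in total, the standard
search restriction. Energies are integers in 10 cal units internally, so
the DP, the evaluator and serialised candidates agree exactly; tests verify
the engine against exhaustive enumeration of all nested structures for
sequences up to 14 nt and verify that every reported energy is recomputable
from the reported pairs. Because the parameterisation is deliberately
lean, absolute energies differ somewhat from full Turner-model
implementations; the -30 kcal/mol acceptance cutoff applies to *this*
model. Stable hairpins of the kind accepted here (26-30 bp stems) sit near
-50 kcal/mol, far from the cutoff, so the simplification does not decide
verdicts at the margin.

The engine fills one set of tables per window and reads off the MFE of
every subwindow from the exterior table, so a full scan costs one O(n³)
fill rather than one per subwindow. Among co-optimal structures a fixed
traceback preference (pair as early and as left as possible) selects one
deterministically.

## The synthetic data generator

`generate_dataset()` builds the complete study universe in memory: a
uniform-random genome (default 100 kb over 3 chromosomes — large enough
that 22-mers are unique with high probability, small enough for exhaustive
oracles), annotation tracks, a read multiset and a truth table. Feature
sequences are *sampled from the genome* rather than spliced in, so planted
inserts match their loci exactly by construction; the two exceptions are
duplicated repeats (copied to a second locus to exercise multi-mapping) and
novel hairpins (constructed, verified against `evaluate_precursor()` at
generation time, then spliced in). Adaptor-class fractions default to
0.821 / 0.069 / 0.110 (legitimate / no-adaptor / adaptor-only) and known
miRNAs carry ~60% of legitimate reads, the composition of a developing-brain
library; abundances follow a log-normal law (meanlog 2, sdlog 2), a heavy
tail spanning the single-digit to ~10^5 count range such libraries show.

Planted hairpins are complementary stems of 28-30 bp with 4-10 nt terminal
loops and up to two small symmetric internal loops, constrained to 70-78 nt
— the size range of validated novel precursors. Two deliberate touches make
the planted truth exact rather than approximate. First, every stem carries
one G·U wobble inside the mature span: a perfectly complementary stem would
place an exact reverse complement of the mature query on the star arm and
destroy unique mapping, an artifact real (imperfect) precursor stems do not
have. Second, the spliced hairpin is flanked by 6-nt single-stranded poly-A
spacers, emulating the unstructured basal segments that real Microprocessor
substrates require; without them, random flanking sequence occasionally
offers the scan a slightly lower-energy extension of the stem and the
recovered boundaries wobble by a few nucleotides.

The generator audits itself: reads duplicated across features, or planted
22-nt queries occurring at unplanned genomic loci, are flagged in the truth
table (`collision`) instead of being silently kept.

What the generator does *not* emulate: sequencing error and quality
structure (the pipeline ignores qualities by design), genuine repeat
families and their divergence, transcriptome-scale EST redundancy, isomiR
5'/3' heterogeneity, and chromosome-scale genome composition. Passing
tests on synthetic data therefore demonstrate the correctness of the
accounting, alignment, annotation and discovery logic under the stated
read-composition model — not robustness to base-calling error or to the
ambiguity structure of a real mammalian genome.

## Reproducibility and problem sizes

Every randomised step runs under an explicit seed (`rng_seed` in both
configs); identical seeds give byte-identical datasets and reports. The
test suite exercises the alignment oracle on genomes up to 8 kb, the
folding oracle on sequences up to 14 nt, boundary recovery on 20 planted
windows, and one full 100,000-read end-to-end run — sizes chosen so the
whole suite completes in a few minutes on one CPU while still covering
every code path at meaningful scale.

## Known limitations

* The adaptor screen is exact-match; heavily error-laden adaptor remnants
  classify as `no_adaptor`, as they did under the modelled protocol's
  ranking (which applied no error correction either).
* The folding model is intentionally lean (no dangles, no special
  tetraloops); energies are comparable within this package, not across
  tools.
* Candidate discovery scans one flank width (default 150 nt) rather than
  all of 100-200; the flank is configurable and the window always covers
  every admissible 60-150 nt precursor around the mature.
* CPM is the only normalisation offered; differential expression is out of
  scope.
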