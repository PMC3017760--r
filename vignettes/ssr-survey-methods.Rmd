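---
title: "Methods: genome-wide SSR cataloguing and read-based heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide SSR cataloguing and read-based heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

## The problem

Simple sequence repeats (SSRs) — tandem arrays of a short motif repeated
perfectly — are among the fastest-evolving features of a genome.  Their
length changes by replication slippage (usually one repeat unit at a time,
the stepwise mutation model), while base substitutions and non-unit indels
("non-repeat unit polymorphisms", NRUPs) interrupt arrays and break long
repeats into shorter ones.  The balance between these two processes shapes
the genome-wide spectrum of repeat abundance.

When a genome is sequenced from a *single heterozygous diploid individual*,
the shotgun reads themselves carry both alleles at every locus.  `ssrscape`
implements the full survey that this design permits: catalogue every perfect
repeat in the assembly, then re-align the reads and genotype each locus for
repeat-length heterozygosity, multistep (two or more unit) differences, and
NRUPs, and finally test the motif, position and recombination biases of the
resulting calls.

## The catalogue

`find_ssrs()` scans each sequence with a greedy algorithm:

* at every position all motif sizes 1–100 are tried, and the maximal
  perfect run for each period is measured; only **full** motif copies
  count, so the array length is always `motif_size * repeat_number`;
* the candidate with the largest array wins; ties go to the smaller motif
  size, which both reproduces smallest-motif reduction (`GAGAGAGA` is four
  copies of `GA`, never one copy of `GAGAGAGA`) and guarantees a primitive
  motif;
* scanning resumes after each recorded locus, so loci never overlap;
* no mismatches are tolerated, `N` terminates any run, and soft-masked
  (lowercase) bases are uppercased before scanning.

The default minimum of 3 repeats follows standard practice for perfect-SSR
surveys.  It is a parameter because the greedy preference for the largest
array is most visible below that threshold: `AAAGAGAAAGAG` is a single
2-copy `AAAGAG` locus at `min_repeats = 2`, but two `AAA` homopolymers at
the default 3.  Both behaviours are frozen in tests.

Motifs are counted as they occur on the given strand (`GA` and `AG` are
distinct), which is what makes the starting-nucleotide preference test
possible; `motif_class_members()` supplies the conventional grouping
(rotations plus rotations of the reverse complement, e.g.
`CA = AC = GT = TG`) when orientation-blind summaries are wanted.

The scanner core is compiled (Rcpp) and is validated against an independent
brute-force enumerator over all (start, motif size) pairs on a thousand
random strings per test run.

## Genotyping from reads

The caller consumes standard SAM alignments of shotgun reads against the
assembly — any aligner can produce them, and the bundled simulator emits
truth alignments directly.  Per locus, in order:

1. **Anchoring.** Only primary, mapped reads that span the locus plus a
   5 bp flank on both sides, align with at least 90% identity overall, and
   match the flanks base-for-base are used.  The anchored segment between
   the flanks is recounted for perfect motif copies, which makes the allele
   call independent of where the aligner chose to place indels inside the
   repeat.
2. **Allele decomposition.** A segment that is an exact tiling of the motif
   gives `delta_units` directly.  Otherwise the segment is decomposed
   against the reference array by a unit-cost global alignment (match +1,
   mismatch −1, gap −1 per base; compiled Needleman–Wunsch): indels whose
   length is a multiple of the motif size are unit-length variation and go
   into `delta_units`; everything else is an NRUP.  Indel NRUPs are
   left-shifted across identical bases before their position is reported,
   so homopolymer indels always report the array start while dimer
   single-base indels stay at their (unique) junction.
3. **Filters.** The published, deliberately conservative cascade: every
   locus position must have coverage within [4, 16] inclusive (the cap
   removes collapsed paralogs, the floor guarantees both alleles had a
   chance to be sampled); every allele and every NRUP needs at least two
   supporting reads (singleton variant reads are tallied as read errors);
   loci with more than two supported repeat alleles, or more than two
   supported base states at one site, are discarded as paralogous.
4. **Classification.** One surviving allele → homozygous; two →
   heterozygous, *multistep* when the alleles differ by two or more full
   units.  NRUPs are classified *end* when they fall in the first or last
   full repeat unit, *middle* otherwise — the random expectation for that
   split is `2/n` of interruptions at a locus of `n` repeats, which is what
   `end_middle_expected()` computes and `end_middle_test()` tests.

`summarize_heterozygosity()` bins the calls by motif size × repeat number
and by motif class, reporting percent heterozygosity among genotyped loci,
the multistep share of heterozygotes, NRUP calls per assayed nucleotide,
and the multiallelic discard frequency.

## Statistical layer

* **Starting-nucleotide preference** (`starting_preference_test()`): within
  a motif class each member should be equally frequent under no preference;
  a chi-square goodness-of-fit test on the class total is used.  Expected
  values are displayed rounded half-up; the tests always run on unrounded
  expectations.
* **End/middle interruption bias** (`end_middle_test()`): 1-df chi-square
  against the `2/n` expectation, with an automatic exact-binomial fallback
  when any expected cell is below 5 (the published tables never name the
  test; chi-square reproduces their printed expectations and their
  underflowed p-values, and the exact fallback keeps small bins honest).
* **Composition expectation** (`composition_expectation_test()`): the A/T
  versus G/C homopolymer split against the genomic base composition, exact
  binomial for small totals and chi-square at genome scale.
* **Heterozygosity curves** (`fit_het_curve()`): ordinary least squares,
  with the exponential model fitted on `log(y)` over positive bins —
  small motifs typically fit the exponential, motif sizes 4–5 a line.
  `select_het_model()` picks the better r².
* **Recombination** (`density_recombination_correlation()`): per
  genetic-map interval, SSR density (loci/Mb, motif size ≥ 2 by default)
  and recombination rate (cM/Mb, i.e. `cm / span`), then a linear
  regression with 95% confidence and prediction bands.  Density is treated
  as the response and cM/Mb as the predictor; r², the slope test and the
  null calibration are unaffected by that choice of axis.
* **Scaffold flags** (`scaffold_abundance_flags()`): two-sided exact
  binomial test of each scaffold's locus count against the genome-wide
  rate, Bonferroni-corrected across scaffolds (multiply `n_tests` out when
  flagging several motif-size classes side by side).

## The simulator

`sim_config()` fixes the study conditions; the defaults emulate the
sequencing design the method was built for: a 1 Mb diploid from one
heterozygous genotype over 4 scaffolds, 8.7× single-end coverage, read
length 774 ± 80 nt (minimum 100), substitution error rate 10⁻³, and a
genomic A+T fraction of 0.59.

* **Planted loci.** The default spec plants 2,450 loci — homopolymers
  dominating, then dimers and trimers — at repeat numbers 5–12, where
  slippage rates change fastest.  Planted loci sit in spacers of at least
  30 nt.
* **Repeat-free background.** Background sequence is drawn iid at the
  target composition and then *swapped* clean: bases inside any
  non-planted qualifying repeat (on either strand) are exchanged with
  random distant background bases until the catalogue of the scaffold —
  and of its reverse complement — equals the planted truth exactly.
  Because swaps are permutations, the realised base composition is
  untouched.  This is what makes truth-joined testing exact; the cost is a
  background *less* repetitive than real sequence, so absolute locus
  densities in the simulation are not calibrated to any real genome — only
  the per-locus genotyping behaviour is.
* **Heterozygosity model.** The per-locus probability of a length variant
  rises logistically with repeat number
  (`plogis(-4.8 + 0.3 * repeat_number)`, capped at 0.95) and is scaled per
  motif class with multipliers ordered AC > AG > AT > CG and G/C
  homopolymers (×2) above A/T (×1) — the ordering reported for this kind
  of survey; the magnitudes put per-bin rates in the 3–40% range where the
  read-depth design actually has power.  Variants are single-unit with
  probability `1 − q` and multistep otherwise, with
  `q = plogis(-2.5 + 0.08 * repeat_number + 0.25 * (motif_size − 1))`
  (multistep share rising with repeat number and motif size); multistep
  magnitudes are `2 + Geom(0.5)` units and variant alleles always keep at
  least two full perfect units.
* **NRUPs.** Loci without a length variant receive a point interruption
  with probability 0.05, placed in a terminal repeat unit with probability
  0.7 (the end bias the position tables show).  Restricting NRUPs to
  length-homozygous loci keeps truth offsets in reference coordinates; the
  excluded double events would occur at rate ~p·q ≈ 0.3% per locus.
* **Reads and truth SAM.** Reads are sampled uniformly from both
  haplotypes; haplotype-2 reads acquire I/D CIGAR operations at variant
  loci through an explicit haplotype-to-reference block map, so the SAM is
  exact by construction.  Read errors are substitutions only, which keeps
  the singleton-read error tally interpretable.
* **Paralogy emulation.** Optionally, extra reads from a diverged ghost
  copy of selected loci are emitted *aligned onto the source locus* — the
  situation the coverage cap and two-allele filters exist to catch.  A
  paired clean/paralog run raises the multiallelic discard frequency, and
  that directional check is a test.
* **Genetic map.** `generate_map()` tiles the scaffolds into 61 intervals
  and assigns cM either independently of planted SSR density (gamma draws,
  the null for calibration) or linearly coupled to it (positive control).

## What the tests show — and what they cannot

Every stage is validated end to end on the synthetic diploid: the
catalogue equals the planted truth; error-free reads genotype back to the
planted genotypes exactly; at the default 8.7× with sequencing errors, the
estimated per-bin heterozygosity rates, the multistep fraction and the NRUP
end fraction sit inside their 95% binomial confidence intervals around the
truth, with no spurious heterozygote calls; and the recombination slope's
95% CI covers zero in at least 90 of 100 replicates under the independent
map.

Two-layer sampling matters when reading those checks.  An estimate from the
1 Mb run carries both read-sampling noise *and* the binomial noise of the
truth draw itself, so end-to-end estimates are compared against the
*realised* truth rates; the generator's parameters (e.g. the 0.7 end bias)
are verified separately against truth tallies at n = 1000 where the draw
noise is small.  Likewise, a two-read consensus minimum at 8.7× censors
detection when a haplotype happens to be sampled fewer than twice, so
recovery is assessed on loci with at least two anchored reads per
haplotype — computed from the simulator truth, not from the caller output.
This is a property of the published filter settings, not an implementation
artefact: unconditional heterozygosity estimates from ~8× data are biased
low by design.

The simulator does not model base-quality variation, indel sequencing
errors (simulated read errors are substitutions only), chimeric reads,
assembly errors, or a realistically repetitive background.  Passing tests
therefore demonstrate the correctness of the detection, filtering and
estimation machinery under the stated read model — not that any particular
real genome's error modes are handled.

Running the cataloguer on a real assembly (`catalog_genome()` accepts any
FASTA) is the external validation path: on the genome this survey design
was developed for, the published totals are ~7.2 million perfect SSRs
covering ~21% of the assembly, 93% of them homopolymers.  That comparison
requires downloading the assembly and traces and is not part of the test
suite.

## Numerical choices and degenerate inputs

* Expected counts are displayed rounded half-up (`round_half_up()`),
  matching how such tables are conventionally printed; tests always use
  unrounded expectations.
* Chi-square p-values are reported as 0 when they underflow double
  precision, as the published tables print them.
* `end_middle_test()` at `repeat_number = 2` has a zero middle
  expectation; the binomial fallback handles it.
* Zero totals (empty classes, empty bins) are signalled as errors rather
  than returning NaN; bins without heterozygotes report `NA` multistep
  fractions.
* The greedy tie-break (largest array, then smallest motif) is the only
  point where the scan is not a pure set operation; two consequences are
  documented in tests: reverse-complement invariance of class counts is
  exact for isolated arrays but not across overlapping candidates, and a
  locus recorded immediately after another may be left-extendable in the
  full-string sense.
* Pipeline runs are deterministic: every stage derives its RNG stream from
  the configuration seed, and rerunning a configuration reproduces every
  output byte for byte.

## Problem sizes

The shipped tests exercise the full pipeline at 1 Mb × 8.7× (≈11,000
reads, 2,450 loci; about a minute), the oracle sweep on 1,000 random
strings up to 300 nt, and 100 map replicates for the null calibration —
sizes chosen so the whole suite completes in a few minutes while leaving
every statistical check enough resolution to be meaningful.
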