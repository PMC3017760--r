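# ssrscape

Genome-wide cataloguing of simple sequence repeats (SSRs) and read-based
measurement of their heterozygosity.

## What it does, and for whom

SSRs — perfect tandem arrays of 1–100 nt motifs — mutate by replication
slippage (gain/loss of repeat units, usually one at a time under the
stepwise mutation model) and are simultaneously eroded by base
substitutions and non-unit indels that interrupt them (non-repeat unit
polymorphisms, NRUPs).  When a genome is sequenced from a single
heterozygous diploid individual, the shotgun reads carry both alleles of
every locus, so the genome project's own raw data doubles as a genome-wide,
marker-selection-free survey of SSR variation.

`ssrscape` is for genomicists running that survey.  It provides:

* **`find_ssrs()` / `catalog_genome()`** — a greedy maximal-array scanner
  for perfect repeats (no mismatches, smallest-motif reduction, `N` breaks
  runs), producing a BED-style locus table and abundance summaries.
* **`call_variants()`** — per-locus genotyping from SAM alignments under
  the conservative filter cascade used for single-individual data: every
  locus position within a coverage window of [4, 16]; reads anchored with
  exact 5 bp flanks; alleles and NRUPs requiring ≥ 2 supporting reads;
  loci with more than two alleles discarded as paralogs.  Repeat units are
  recounted inside the anchored segment, so calls do not depend on aligner
  gap placement; non-unit differences are resolved by unit-cost global
  alignment with left-aligned indels.
* **`starting_preference_test()`, `end_middle_test()`,
  `composition_expectation_test()`, `fit_het_curve()`,
  `density_recombination_correlation()`, `scaffold_abundance_flags()`** —
  the statistical layer: motif-class bias tests, the 2/n end-vs-middle
  interruption expectation, heterozygosity-vs-repeat-number curve fits,
  and recombination/density regressions over a genetic map.
* **`sim_config()` → `generate_reference()` → `diploidize()` →
  `simulate_reads()` → `generate_map()`** — a diploid genome simulator
  with planted SSR loci, repeat-number-dependent slippage, multistep
  variants, end-biased NRUPs, shotgun reads (default 8.7×, 774 nt) and
  exact truth alignments in SAM, so the whole pipeline is testable with no
  external data.
* **`run_pipeline()`** — catalogue → genotype → statistics end to end from
  a YAML or list config, writing report tables (a thin CLI wrapper ships
  in `inst/scripts/ssrscape.R`).

## The statistics at the core

For a locus of `n` repeat units, an interruption landing uniformly falls in
a terminal unit with probability `2/n`:

    E[end] = total * 2/n,   E[middle] = total * (n - 2)/n

and the observed split is tested with a 1-df chi-square (exact binomial when
expected cells are small).  Within a motif class (all rotations of a motif
and of its reverse complement, e.g. CA = AC = GT = TG), starting-nucleotide
preference is a chi-square goodness-of-fit test against a uniform split of
the class total.  Heterozygosity percentages are computed among genotyped
loci per motif-size × repeat-number bin; the multistep fraction is the share
of heterozygotes whose alleles differ by ≥ 2 full units.  SSR density
(loci/Mb) is regressed on recombination rate (cM/Mb) across genetic-map
intervals with 95% confidence and prediction bands.

## Worked example

```r
library(ssrscape)

find_ssrs("TTGAGAGAGAGAGACC")
#>   start end motif motif_size repeat_number array_length
#> 1     2  14    GA          2             6           12
```

One locus: a `GA` dimer starting at 0-based position 2, six full copies, 12
nt.  The trailing partial copy is not counted, and the motif is reported as
it occurs (`GA`, not `AG`).

```r
r <- starting_preference_test(c(TA = 48814, AT = 35558))
#> class AT: expected 42186 per member, chi-square = 2082.7 (df 1), p = 0

round_half_up(end_middle_expected(5, 2549 + 1168))
#>    end middle
#>   1487   2230
```

Given 84,372 TA/AT dimer loci, 42,186 would start with each base under no
preference; the observed split rejects that at a p-value below double
precision.  Of 3,717 interruptions at 5-unit homopolymers, 1,487 are
expected in a terminal unit by chance.

A small synthetic end-to-end run:

```r
cfg <- list(mode = "synthetic", out_dir = "readme_run",
            sim = list(seed = 7, genome_length = 2e5, n_scaffolds = 2,
                       coverage = 10,
                       planted = data.frame(motif = c("A","C","AC","AG"),
                                            repeat_number = c(8L,10L,10L,12L),
                                            count = c(120L,100L,100L,80L))),
            map_mode = "coupled")
res <- run_pipeline(cfg, quiet = TRUE)
res$het$by_class_total[c("class","n_assayed","n_het","pct_het","pct_multistep_of_het")]
#>   class n_assayed n_het pct_het pct_multistep_of_het
#> 1     A       118    12    10.2                 33.3
#> 2    AC        98    20    20.4                 35.0
#> 3    AG        79    18    22.8                 22.2
#> 4     C        97    26    26.8                 19.2
```

Per motif class: loci passing the coverage window, heterozygous calls,
percent heterozygosity among genotyped loci, and the multistep share of the
heterozygotes.  G/C homopolymers (class `C`) are more heterozygous than A/T
(class `A`), as planted.  With the map coupled to dimer density:

```r
res$stats$recombination$fit[c("slope","r2","p","n")]
#> recombination: slope 185.338, r2 = 0.95, p = 6.5e-40 (n = 60 intervals)
```

All tables are also written to `out_dir` as TSV/JSON.

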