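---
title: "Modelling CRISPR manipulation of a satellite DNA array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CRISPR manipulation of a satellite DNA array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satdrive)
library(dplyr)
```

## The system

Pericentromeric satellite DNA consists of megabase-scale blocks of short
tandem repeats. The *Responder* (*Rsp*) satellite on chromosome 2R of
*Drosophila melanogaster* is a higher-order repeat: an imperfect dimer of
"left" and "right" ~120-bp monomers, repeated in tandem, interrupted by
islands of transposable elements (TEs), flanked proximally by the simple
satellite AAGAG and distally by a TE cluster. *Rsp* copy number matters
phenotypically because it is the target of *Segregation Distorter* (*SD*),
a selfish haplotype that disables sperm carrying a repeat-rich homolog in
*SD*/+ males. Engineering the array up or down with CRISPR, and reading the
consequences out through genome assembly, recombination mapping and drive
assays, requires a chain of small computational procedures. This package
implements that chain as composable, tibble-first functions, with a seeded
synthetic-data layer so that every step can be tested against known truth.

## The array model

A `sat_array` is an ordered tibble of non-overlapping units on one contig,
each unit carrying a class (`repeat-left`, `repeat-right`,
`repeat-variant`, `repeat-truncated`, `te-island`, `flank-proximal`,
`flank-distal`, `other`), a family label, and optional identity/bitscore
metadata. Coordinates are 0-based half-open throughout; BED is read
natively and RepeatMasker `.out` tables (1-based inclusive) are converted
on input. Overlapping units are rejected rather than merged: the editing
simulator and the copy counter both assume a linear unit order, and an
overlap indicates an upstream annotation problem the user should see.

Repeat units found by aligning left/right consensus sequences are
classified by three thresholds applied in a fixed order:

1. alignment length < 90 bp → `repeat-truncated` (truncation is a
   structural property, so it takes precedence: a 60-bp perfect match is
   truncated, not variant);
2. otherwise percent identity < 90 or bitscore ratio < 0.7 →
   `repeat-variant`;
3. otherwise `repeat-left` / `repeat-right` by which consensus produced
   the hit.

The bitscore threshold is interpreted as a *ratio* of the hit bitscore to
the bitscore of a perfect self-alignment of the consensus (a raw bitscore
of 0.7 would be meaningless); the self-alignment score defaults to 2
bits/bp, the usual blastn approximation, and both the ratio and the
reference score are configurable. `count_copies()` totals only the four
repeat classes — TE islands and flanks never count toward copy number — and
`percent_change()` turns two totals into the signed deletion/expansion
percentage. For wet-lab screening, `relative_abundance()` implements
ΔΔCt with an assumed amplification efficiency of 2.0 per cycle,
normalising the satellite signal to a single-copy reference
(*tRNA-Lys-CTT* in the motivating experiments) and a parent-strain
control.

## Guide target sites

`find_target_sites()` scans both strands for protospacer matches with a
configurable mismatch budget, requiring an exact IUPAC-pattern PAM match
(default NGG) immediately 3′ of the protospacer. Mismatches are counted
only in the protospacer; `N` in the subject sequence never matches
anything, including pattern `N`. Cut positions use standard SpCas9
geometry — a blunt cut 3 bp 5′ of the PAM, between protospacer positions
17 and 18 — because the editing simulator needs a concrete cut coordinate.
Sites on opposite strands are reported independently; deduplication is the
caller's choice. The default mismatch budget is 0 (on-target counting);
the original experiment's off-target survey used an external genome-wide
tool, which is out of scope here, but the same scan can be run on any
supplied sequence.

`cluster_sites()` groups cut positions by single-linkage with a gap
threshold. The spatial clustering of sites is not incidental: under
multi-cut repair it predicts which deletion classes are reachable.
`site_survival()` counts how many of a parent allele's sites remain in an
edited sequence — the readout used to judge whether an editing round
exhausted its target sites and whether a second round with a fresh guide
is worthwhile.

## The editing simulator

`simulate_editing()` is a hypothesis-exploration tool for the
cleavage-load idea — that many simultaneous cuts overwhelm repair and
produce a small set of discrete outcome classes — not an estimator of
per-site cleavage efficiencies, which are unknown. Each replicate cleaves
every site independently with the model's cleavage probability. Fewer
than two cuts leaves the array unchanged. Otherwise repair follows one of
three explicit rules: `adjacent-join` (each segment between consecutive
cuts is lost independently with probability 1/2 before religation; the
default, because it generates discrete classes when sites are clustered),
`outermost-join` (everything between the first and last cut is lost), or
`random-pair-join` (one uniformly chosen cut pair). With a configurable
probability a repair event instead resolves by recombination with a
homolog, splicing the homolog's segment between its outermost cuts into
the gap — a single-crossover model of the expansion pathway; double
crossovers are not modelled. An optional logistic lethality term discards
outcomes with many cuts, mimicking the sparse recovery of progeny from
high-site-count guides; it is off by default.

Two deliberate simplifications: repair is sequence-precise (no indels at
junctions — note that religating two cuts made through *identical* repeat
copies can therefore reconstitute one target site at the junction), and a
unit partially overlapping a deleted interval is destroyed rather than
retained as a fragment. Both keep the outcome space enumerable, which is
what makes the simulator testable: for ten or fewer sites the exact
outcome distribution can be computed by enumerating all cleaved subsets,
and the test suite holds simulation frequencies to within three standard
errors of that enumeration at 10,000 replicates.

## Breakpoint inference from allele-depth ratios

Variant records (read from a single-sample VCF via `vcfR`, or from TSV)
are filtered to `QUAL > 30` and total depth inside the inclusive 25–75%
quantile band of the input's own depth distribution; the quantile
definition (linear interpolation, type 7) is configurable because it
changes which records pass. Each site's alternate allele-depth ratio
`alt/(ref+alt)` is classified as `alternate` (≥ 0.9), `reference`
(≤ 0.1), `heterozygous` ([0.3, 0.7]) or `uncertain` (the open gaps);
multiallelic records contribute only their first alternate allele, with a
count of affected records attached to the table.

Windows of 50 kb tile the contig. Each window reports the per-state
counts and the alternate frequency among classified sites. For breakpoint
calling, windows are labelled on their **mean allele dose** (reference 0,
heterozygous 0.5, alternate 1, averaged over classified sites): dose
≥ 0.9 is alternate-like, ≤ 0.1 reference-like, within [0.3, 0.7]
heterozygous-like, anything else ambiguous. The dose resolves an
ambiguity in frequency-based labelling — a purely heterozygous window
contains almost no alternate-classified sites, so its site-count
alternate frequency is near zero and would masquerade as reference-like;
the dose maps the per-site bands onto windows one-to-one. A depth-summed
window frequency is available behind `freq_method = "depth"` for users
who prefer aggregating read counts over site votes.

A breakpoint is emitted between the last window of one homogeneous run of
at least `min_run` windows (default 2) and the first window of the next
differing run, skipping ambiguous and empty windows; when the per-site
table is supplied the interval is narrowed to the gap between the
outermost classified sites of the two flanking windows. The run-based
localisation rule and the `min_run` default are this package's own
choices — windowed state summaries admit several reasonable calling rules,
and this one is simple, conservative and testable: on synthetic
recombinants with tracts at least 10 windows long, ≤ 5% per-site state
noise and ≥ 20 classified sites per window, the suite requires every true
breakpoint to be recovered within ±1 window with no spurious calls across
20 seeds.

## Drive statistics

Drive strength *k* is the proportion of offspring of an *SD*/+
heterozygous father that inherit *SD*: 0.5 is Mendelian, 1.0 perfect
drive. Because *SD*-bearing genotypes can also differ in viability, the
raw proportion is corrected using the reciprocal cross (heterozygous
mother), where transmission is Mendelian and any departure from 1:1
estimates relative viability `v = n_SD/n_+`. The correction rescales the
male cross's SD count by `1/v`:

$$k_{\mathrm{corr}} = \frac{n_{SD}/v}{\,n_{SD}/v + n_{+}\,}.$$

The reciprocal-cross adjustment is stated in the motivating work without
an explicit formula; rescaling the SD count by `1/v` is the natural
reading (the alternative, rescaling `n_+` by `v`, is algebraically the
same here). Exact Clopper–Pearson intervals are reported on the raw
proportion — corrected counts are not integer-valued, so the interval
describes sampling error before correction. `drive_test()` compares two
crosses with Fisher's exact test, two-sided by the probability-mass rule
(summing hypergeometric probabilities no larger than the observed
table's, with the conventional `1 + 1e-7` rounding guard); the
two-sidedness convention is stated because the doubling alternative gives
different p-values. `estimate_drive()` pools replicate rows per line and
sex before estimating — corrections are applied to pooled counts.

## The synthetic-data layer

Three generators make the pipeline testable end-to-end with no external
data; each is a pure function of its spec and an explicit integer seed
(`withr::with_seed`, no global RNG state leakage).

`gen_array()` emits a locus as AAGAG flank → mutated left/right dimers
with optional TE islands → TE-block distal flank. Its defaults are chosen
to resemble the parent array of the motivating experiments: 878 dimers
(1,756 monomers of 120 bp), two interior TE islands, per-base mutation
rate 0.02 and truncation probability 0.02 — enough divergence to populate
the variant and truncated classes without dominating them. Consensus
monomers are generated from the seed (no published consensus is
embedded). The generator labels every unit with the same
length/identity/bitscore rules the classifier applies (scoring matches at
+2 and mismatches at −3), and emits the corresponding alignment-hit
table, so classifier and generator can be cross-validated exactly. It can
plant a guide's protospacer+PAM at chosen dimers and records where, so
the site scanner's recall is testable exactly.

`gen_variant_table()` lays genotype tracts along a contig, places sites
by a Poisson process, draws depths from a negative binomial (mean 50,
size 5 by default — overdispersed on purpose, so the quantile depth
filter has real work to do) and allele depths binomially from the
tract state (error rate 0.02 at homozygous sites). Truth breakpoints are
the interior tract boundaries. `gen_cross_counts()` draws male-cross SD
counts as binomial with success probability `kv/(kv + (1-k))` and
reciprocal-cross counts with probability `v/(1+v)`.

What the generators do *not* emulate: read-level error profiles and
mapping artefacts (no FASTQ simulation), realistic TE sequence content,
linked-variant haplotype structure, or biased site spacing. Passing tests
therefore demonstrate correctness of the procedures under the stated
generative model, not robustness to every pathology of real long-read
callsets.

## Numerical and interface choices

- Coordinates: 0-based half-open internally everywhere; VCF positions
  (1-based) are converted at the boundary; BED written natively.
- Quantiles: type 7, band-inclusive; both configurable.
- State thresholds are parameters with the published defaults
  (0.1/0.3/0.7/0.9); `classify_state` is total on [0, 1].
- Ties in `outcome_classes()` modes: all bins at the maximum count are
  flagged modal.
- Degenerate inputs: empty variant tables filter to empty with a warning;
  a parent with no target sites gives an `NA` survival fraction; zero
  totals and non-positive thresholds error early with plain messages.
- Problem sizes in the test suite (arrays of tens of dimers, contigs of
  2–3 Mb, 10,000 simulator replicates, 1,000 simulated crosses of 200
  offspring) were chosen as the smallest sizes at which the statistical
  assertions have power; the generators scale to full-size arrays.

## Worked example

```{r example, eval = FALSE}
# a parent-scale array and a guide planted in 40 dimers
g <- guide_spec("g1", "ACGTTGACCTAGGACTTGCA")
sim <- gen_array(array_spec(n_dimers = 878, seed = 42),
                 plant_guide = g, plant_at = seq(200, 590, by = 10))
sites <- find_target_sites(sim$sequence, g)
cluster_sites(sites, gap_threshold = 5000)

out <- simulate_editing(sim$array, sites,
                        edit_model(0.8, "adjacent-join"),
                        replicates = 200, seed = 1)
outcome_classes(out, bin_width = 50)
percent_change(sim$truth$total_repeats, median(out$copy_total))

# drive assay on synthetic crosses
crosses <- gen_cross_counts(true_k = 0.8, viability = 0.9,
                            n_offspring = 200, n_crosses = 20, seed = 7)
fit <- estimate_drive(crosses)
tidy(fit)
glance(fit)
```

## Known limitations

- The simulator's repair rules are caricatures; they bound the space of
  outcomes rather than predict junction sequences.
- Breakpoint calling reports window-scale intervals; it does not attempt
  base-pair resolution and will merge tract switches shorter than
  `min_run` windows.
- The viability correction assumes the reciprocal cross measures
  viability alone (no maternal drive) and that viability is
  genotype-specific but environment-independent across the paired
  crosses.
- Guide search is exact-count based; it does not score partial activity
  of mismatched sites (no CFD/MIT-style models).
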