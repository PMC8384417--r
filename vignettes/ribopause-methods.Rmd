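---
title: "Codon-level pause scores from 3'-anchored ribosome profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level pause scores from 3'-anchored ribosome profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

# The measurement model

Bacterial ribosome-profiling libraries produced with MNase footprinting have
ragged 5' ends but comparatively well-defined 3' ends, so this package
anchors the ribosome's position at the **3' terminal nucleotide** of each
footprint. Two reads sharing a 3' end are treated as the same ribosome
position regardless of length; truncating 5' ends never changes a density
track, and the test suite asserts exactly that.

The position of the A-site codon is the 3' end shifted upstream by the
**A-site offset** (`asite_offset`, nt). The offset depends on the nuclease
and library geometry and is not knowable from the statistic itself, so it is
an explicit parameter everywhere and is stamped into every result object.
The default of 15 nt is the canonical bacterial footprint geometry
(~15 nt from the first base of the A-site codon to the protected 3'
boundary); users with different chemistry should recalibrate it per sample
(e.g. from the offset of the start-codon peak) and override the default.

## The pause score

For every instance of a codon, the score is the A-site-shifted density at
the codon's **first nucleotide** divided by the mean per-nucleotide density
of its ORF, and the per-codon statistic is the unweighted mean over all
instances transcriptome-wide. Three filters shape the instance set:

* **Edge trim** (`trim`, default 7 codons): the first and last seven codons
  of every ORF are ignored, removing initiation/termination peaks.
* **Coverage filter** (`min_reads_per_codon`, default 0.1, strict `>`): a
  gene enters the statistic only when its average footprint coverage
  exceeds 0.1 reads per codon over the whole ORF.
* **Sense codons only**: stop codons are retained in the ORF model but never
  scored; the table always has at most 61 rows.

One deliberate coupling: the gene-mean denominator is computed over the same
trimmed interior as the instance set. With a mismatched denominator a
strictly uniform track would not score exactly 1; with the coupled one it
does, and that exactness is used as a unit test. Because the score is a
ratio within each gene it is invariant to rescaling the track, so pause
scores are computed from raw counts and rpm normalization is irrelevant to
them.

Genes flagged as overlapping another ORF are included by default (their
density mixes signal from both frames, but excluding them discards real
instances); `exclude_overlaps = TRUE` reverses the choice. Per-codon means
are unweighted across instances, not averaged per gene first; the amino-acid
panel reports both the instance-weighted mean and the mean of codon means,
since the two differ whenever a family's codons have unequal usage.

## Metagene profiles and peaks

`codon_metagene()` averages gene-mean-normalized density at offsets
`-W..+W` nt around every instance of the query codons (same filters as the
pause score; default `W = 50`). Offsets are along the coding direction
relative to the codon's first nucleotide: negative offsets are 5'
(upstream). Instances closer than `W` to an ORF edge contribute masked
partial windows with per-offset denominators — dropping them would bias the
profile against short genes.

Interpretation of the characteristic peaks:

* an arrested library shows a single peak at offset 0 (the aligned codon in
  the A site);
* **run-on blurring** (ribosomes continuing to translate in the lysate)
  moves ribosomes forward, so the aligned codon transits into the P and E
  sites and extra density appears at offsets **+3 and +6**;
* **collisions** (a trailing ribosome stacked behind a paused one) deposit
  footprint density ~25 nt upstream, at offsets near **-25**.

`find_peaks()` reports local maxima above `min_height` (default 1.5,
normalized density, not background-subtracted), greedily by height with
`min_separation` (default 3 nt, one codon) spacing.

## Expression, occupancy, attenuation, gene sets

`quantify()` computes per-gene RPKM
(`counts * 1e9 / (total_mapped * length_nt)`) for RNA-seq and Ribo-seq
tracks and the ribosome occupancy `RO = ribo_rpkm / rna_rpkm`, flagged
undefined when the RNA term is zero. The rpm/RPKM denominator is the number
of reads retained after the length filter and bounds check — the package's
own bookkeeping, recorded on every track, so results are reproducible from
the pipeline alone.

`attenuation_ratio()` measures transcriptional attenuation as the
length-adjusted RNA-seq density of a leader region divided by that of a
downstream region (same strand, disjoint). Ribosome stalling in a leader
peptide suppresses terminator formation, so deficiency strains show a
smaller fold-decrease than controls. The ratio is unit-invariant; a zero
downstream density yields `Inf` with an explicit flag. Region choice is the
user's: for a *leuL*-type operon the natural regions are the leader ORF and
the first downstream gene; for an *ilvL*-type operon the leader ORF and the
5' half of the downstream gene.

`compare_gene_sets()` takes externally defined gene lists (the package does
not re-derive differential-expression calls; shrinkage estimators are out of
scope) and reports per set the log2 RPKM ratios between two conditions,
their median, a one-sample t test against 0, and a Mann-Whitney test against
all quantified genes outside the set. Genes with zero counts in either
condition are excluded by default and counted in the output; a pseudocount
option (`pseudocount = 0.5` added to raw counts) is available instead. Note
that at fixed sequencing depth RPKM ratios are compositional: scaling one
set up deflates every other gene's share, so a true k-fold change appears as
`log2(k)` minus the log total-mass ratio. The test suite checks the detected
median against that closed form rather than against `log2(k)`.

# The synthetic-data generator

`simulate_transcriptome()` / `simulate_footprints()` / `simulate_rnaseq()`
generate data with exactly the statistical structure the analysis assumes,
so parameter recovery is a meaningful end-to-end test. All stages are
deterministic given `seed`.

**Transcriptome.** `n_genes` ORFs (default 200) with lengths uniform on
150–450 codons (a typical bacterial ORF-length range at a scale that keeps
simulations fast), random strands, interior codons drawn i.i.d. from
`codon_usage` (default uniform over the 61 sense codons, so every codon
collects comparable instance counts), fixed ATG start and a random stop,
separated by 100 nt random intergenic gaps (enough that shifted reads and
collision footprints stay on-reference). Per-gene abundance is log-normal
with `sdlog = 1`, a realistic ~1 order-of-magnitude interquartile spread for
bacterial mRNA that also exercises the coverage filter.

**Footprints.** A read picks a gene proportionally to abundance times total
dwell, then a position within the gene proportionally to per-nucleotide
dwell weight. Unenriched positions have weight 1; an enriched codon carries
its factor on its **first nucleotide only**, mirroring the quantity the
pause score measures (a `whole_codon` mode exists for robustness checks).
The observed 3' end is the position plus `asite_offset`; the read length is
drawn independently (uniform 10–40 nt by default, 24–40 nt in the
high-Mg2+-arrest presets), so position recovery is length-independent by
construction. Optional mechanisms:

* `runon_blur = p`: each ribosome advances a geometric number of codons
  (continuation probability `p` per codon) after lysis — the generative
  counterpart of the A-site peak blurring into P/E-site offsets. The
  geometric form is an artifact choice validated only qualitatively (the
  real post-lysis kinetics are not quantified); it is not used in the
  calibrated presets.
* `collision_prob`: a footprint sampled at an enriched position seeds, with
  this probability, a stacked footprint exactly 25 nt upstream with ±2 nt
  jitter.

**Calibration of presets.** For a gene with `L` interior nucleotides and `k`
interior instances of a codon whose first-nt dwell is multiplied by `f`, the
expected recovered score is not `f` but

```
E[score] = f * L / (L + k * (f - 1))
```

because the enriched instances also inflate the gene-mean denominator. With
several families enriched at once (the depletion presets raise all four Pro
codons, CGG, and CUA simultaneously) the denominators couple, so
`calibrate_dwell()` solves the factors jointly by fixed-point iteration on
the realized transcriptome until the expected instance-weighted mean of each
family equals its target. The preset targets are the published strain-level
scores (Pro 1.4/3.5 control/depletion, 1.2/2.5 in the knockout pair;
CGG 3.0 and CUA 1.4 in deficiency), kept in one versioned table. The presets
simulate arrested libraries (no blur, no collisions): the published scores
were measured as A-site first-nt densities, and the calibration targets that
same statistic.

**RNA-seq and attenuation.** RNA-seq read 3' ends are uniform within each
ORF, proportional to abundance. Attenuation presets build a two-segment
operon — leader geometries of 29 codons (*leuL*-like) or 33 codons
(*ilvL*-like) followed by a ~520–550 codon gene — with downstream abundance
equal to leader abundance times a read-through probability set to the
inverse of the published fold-decrease (1/29 and 1/4 for the leu geometry,
1/45 and 1/9 for ilv). The measured fold-decrease then recovers the
published value up to multinomial sampling error.

**What the generator does not emulate.** No ligation/nuclease sequence
bias, no base-calling error, no rRNA contamination, no multi-mapping, no
codon-usage realism, no correlated dwell along a message, and run-on
kinetics are a stylized geometric model. Passing recovery tests therefore
demonstrates that the *pipeline arithmetic* is correct and unbiased under
the stated generative assumptions — not that any particular biological
library satisfies those assumptions.

# Numerical and format choices

* Coordinates are 0-based half-open internally; WIG output is 1-based
  (bedGraph 0-based), converted only at the writers.
* U is normalized to T at load time; all internal sequence is DNA alphabet.
* The WIG writer emits one variableStep block per (reference, strand) with a
  `strand=` attribute on the block line — a small dialect extension, since
  standard WIG carries no strand — and formats values so that
  write→read→write is byte-stable.
* The TSV alignment dialect (`ref, strand, five_prime, length`, 0-based
  biological 5' coordinate) lets the simulator and tests avoid any BAM
  dependency; SAM/BAM remain the standard ingestion path, with the 3' end
  taken from the aligned reference span (soft-clips do not shift it).
* Degenerate inputs: an empty read file, a fully filtered read set, a zero
  gene mean, a zero-length trimmed interior, and a zero downstream density
  each have a defined outcome (error, skip, score 0, error, `Inf` flag
  respectively) and are covered by tests.
* Ties in peak finding are resolved toward the lower offset (plateau edges
  count as maxima); peak selection is greedy by height.

# Problem sizes

The recovery runs used by the acceptance script and the heavier tests
simulate 200 genes and 1e6 reads per scenario — enough that every codon
collects ~1000 scored instances and the per-codon standard error is ~0.02,
while a full scenario (simulate + pipeline) completes in well under a
minute. Unit tests use 1–60 genes and 1e2–3e5 reads. Recovery assertions use
a tolerance of ±10% of the target or three standard errors of the instance
mean, whichever is larger; the uniform-dwell null (all 61 codon means at
1.0) is asserted before any enriched scenario is trusted.

# Known limitations

* Single-exon (bacterial) gene models only; no splicing, no multi-exon
  arithmetic.
* One global A-site offset per run; length-dependent offsets (common in
  eukaryotic data) are not modeled.
* P/E-site occupancy is read qualitatively from metagene peaks; the package
  does not produce per-codon P- or E-site score tables.
* Attenuation regions must be supplied (or taken from the simulated operon);
  the package does not discover terminators.
* Gene-set comparisons report raw p-values with set sizes; multiple-testing
  correction across many sets is left to the caller (`p.adjust`).
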