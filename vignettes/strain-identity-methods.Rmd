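---
title: "Calling identical, related, and different bacterial strains from ANI null distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling identical, related, and different bacterial strains from ANI null distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainani)
library(tibble)
```

## The problem

Average nucleotide identity (ANI) separates bacterial species cleanly (the
conventional species boundary sits near 95%), but at the *strain* level the
question is harder: when two genome assemblies — say, one from a urine
isolate and one from a vaginal swab of the same person — show an ANI of
99.98%, is that *the same strain*, or merely a close relative? Assemblies of
the very same isolate, resequenced, do not reach ANI 100: sequencing error,
coverage fluctuations, and assembler consensus artifacts leave a small,
sample-specific deficit. A fixed ANI cutoff cannot separate that technical
noise from real biological divergence.

`strainani` implements a resampling answer. For each species, it builds an
empirical *null distribution* of ANI values between assemblies that are
known to be the same strain — replicate assemblies rebuilt from independent
subsamples of one isolate's reads — and then projects observed
assembly-pair ANI values onto that null as a one-sided empirical P-value:

$$P = \frac{\#\{\text{null ANI} \le \text{observed ANI}\}}{n}.$$

A small $P$ means the observed ANI is a left-tail outlier relative to
same-strain noise (the pair is *different*); a $P$ near 1 means the pair is
indistinguishable from resequencing noise (*identical*); the middle ground
is *related*. The operational thresholds are $P < 0.05$ for different and
$P \ge 0.95$ for identical, with ties resolved exactly at those bounds
(0.95 is identical, 0.05 is related).

## The null-simulation design

For each strain with a deep read set:

1. **Subsample** 150,000 whole read pairs, uniformly without replacement,
   50 times, each replicate with its own seed derived deterministically
   from one master seed (`make_replicates()`). Mates are never separated
   and input order is preserved.
2. **Assemble** each replicate (here: the assembly emulator, below; a
   real-assembler backend can be plugged in as a function
   `function(reads, genome, seed, label)` via
   `pipeline_config(assembly_backend = )`).
3. **Pair disjointly**: replicates are consumed in consecutive pairs
   (1,2), (3,4), ..., giving 25 ANI comparisons in which no assembly is
   reused — avoiding pseudo-replication in the null.
4. **Pool per species** across strains, keeping strain labels.
5. **Bootstrap** the pool with replacement into a sample of 10,000 values,
   the empirical distribution observed ANI values are projected onto.
6. **ANOVA** of ANI by strain is reported (never used as a gate): a
   significant result is evidence that strain-level diversity is
   represented inside the pool; a non-significant one triggers a logged
   caution.
7. A **Gaussian KDE** (Silverman bandwidth) is fitted for plotting. The
   P-value deliberately comes from the plain ECDF of the bootstrap sample,
   not from integrating the KDE: the procedure names an empirical
   probability, and the ECDF is its simplest consistent estimator; the
   difference from a plotting-position formula is $O(1/n)$ at $n = 10^4$.

All of this is `run_null_construction()`; `run_classification()` adds the
projection and the three-way call. Each species is treated independently.

Every numeric default lives in one place:

```{r config}
pipeline_config()
```

## What the synthetic-data generator emulates

The package ships a simulator so the whole pipeline runs, and is tested,
without any sequence download.

* `generate_ancestor()` draws an i.i.d. genome at a chosen GC fraction
  (default 0.37, typical of the urogenital lactobacilli this kind of study
  targets).
* `derive_strain()` applies per-base substitutions and short indels
  (lengths $1 + \mathrm{Geom}$, mean 3 — the paper-level analyses are
  insensitive to the indel-length law, since ANI and SNP counting are
  substitution-driven) and returns a replayable mutation log. The log is
  the ground truth for the ANI estimator's accuracy checks: on a no-indel
  strain pair, true identity is exactly $1 - d$ where $d$ is the realised
  substitution density.
* `simulate_reads()` produces 2×150 bp pairs with uniform fragment starts,
  Gaussian insert sizes, and uniform per-base substitution errors.
  Quality-score realism, GC-coverage bias, and read trimming are out of
  scope.
* `emulate_assembly()` stands in for a real assembler at desk scale.

### The assembly emulator and its parameters

The emulator reproduces the one statistical structure the method depends
on: replicate assemblies of the same genome have ANI slightly below 100
with replicate-to-replicate spread. Per window of `window` bp (default
1000), depth is drawn $\mathrm{Poisson}(\texttt{mean\_depth})$; windows
below `min_contig_depth` become coverage gaps that break the genome into
contigs (contigs under 1000 bp are then dropped, the conventional
post-assembly trim). Within kept windows, each base is flipped to a wrong
consensus base with the exact binomial probability that a strict majority
of $d$ reads carry the same wrong base,

$$p_{\mathrm{err}}(d) = 3\,P\!\left(\mathrm{Binom}(d, e/3) > d/2\right),$$

where $e$ is `base_error_rate`. This probability decays rapidly with depth
— compare any $d$ with $d+2$; between *consecutive* depths it alternates
slightly, because the strict-majority threshold only moves at odd depths
(`consensus_error_prob(2, e)` $< $ `consensus_error_prob(3, e)`). The
defaults (`mean_depth = 5`, `base_error_rate = 0.05`,
`min_contig_depth = 2`, `window = 1000`) were chosen once to place
same-strain ANI around 99.90 with a spread of roughly ±0.015 on a 100-kb
genome and a handful of contigs — the qualitative regime real draft
assemblies occupy. `mean_depth` is an *effective consensus depth*, not raw
coverage: consensus evidence in a real assembler is far from independent
across reads, so the effective depth that governs consensus errors is much
smaller than the nominal coverage of the subsampled read set. With
`base_error_rate = 0`, contigs are exact subsequences of the genome and
self-ANI is exactly 100.

Because the emulator is driven by the genome and the replicate's seed, the
subsampled reads define the replicate (its seed, its bookkeeping, and the
input an external assembler would consume) but their bases are not
re-consumed by the emulator itself.

What passing tests on this generator do **not** show: fidelity to any real
instrument's error profile, repeat-induced misassembly, GC bias, or
contamination. They show that the statistical machinery — subsampling,
disjoint pairing, pooling, bootstrap, ECDF projection, classification — is
correct and calibrated given a same-strain noise process of realistic
location and spread.

## The built-in ANI estimator

`fragment_ani()` is a fragment-mapping estimator in the FastANI mould,
implemented in C++: the query is cut into non-overlapping 3000-bp
fragments (terminal remainders discarded); each fragment is anchored to
the reference by shared 16-mers on both strands (forward strand wins
ties); the best-supported diagonal is extended *ungapped* and scored as
percent identity over the part of the fragment that projects into a
single reference contig, requiring at least 300 bp of overlap and 80%
identity for the fragment to count as mapped. ANI is the mean identity
over mapped fragments, and is reported as missing (`NA`, never 0) when
fewer than `min_mapped = 10` fragments map — a guard against meaningless
means on tiny overlaps. Because the estimator is directional,
`symmetric_ani()` reports the arithmetic mean of the two directions, which
is the pipeline's per-pair summary.

Numerical behaviour worth knowing:

* On substitution-only pairs the ungapped score equals the Hamming
  identity, so the estimator tracks the mutation-log oracle to well under
  0.1 percentage points.
* Identity is computed over the *clipped overlap*, so re-cutting the
  reference into contigs (no sequence change) moves ANI by less than 0.05
  points.
* Two unrelated random 200-kb genomes share a handful of 16-mers by
  chance, but a stray anchor extends to ~25% identity — far below the 80%
  seed — so no fragment maps and ANI is undefined rather than misleading.
* Indel-containing pairs are scored ungapped past the indel; the built-in
  estimator is a consistent statistic for the null-vs-observed comparison,
  not a reimplementation of any external mapper. For real-data work an
  external tool's 5-column table drops in via `parse_ani_table()`.

## Statistical choices and degenerate inputs

* **ECDF convention** `#\{x \le obs\}/n`: observed at or above the null
  maximum gives exactly 1; below the minimum gives exactly 0.
* **Bootstrap size ambiguity**: "bootstrap 10,000 times" is read as one
  bootstrap sample of 10,000 values (not 10,000 resamples of size $n$);
  it is a single config value (`bootstrap_B`).
* **Calibration is a large-pool property.** $P$-values computed against an
  *estimated* null inherit its estimation error: conditional on a pool of
  $n$ values, the $P$-values of fresh same-strain pairs deviate from
  uniform by about $\sup|\hat F_n - F| \approx 0.87/\sqrt{n}$. With the
  design-scale pools (hundreds of pooled comparisons per species) the
  deviation is inside what a KS test at $\alpha = 0.01$ tolerates and the
  type-I rate at the 0.05 threshold is nominal; with very small pools
  (tens of values) the same procedure is visibly miscalibrated — not an
  implementation artifact but a property of ECDF P-values, and the reason
  the published design uses 25 comparisons per strain pooled over several
  strains. The test suite checks calibration at a 240-value pool; the
  acceptance script reports both a 20-value desk pool and a 240-value pool
  side by side.
* **KDE**: Gaussian, Silverman's rule (`bw.nrd0`), evaluated exactly on a
  2048-point grid spanning six bandwidths beyond the data range so the
  density integrates to 1 within $10^{-6}$. Degenerate (all-equal) samples
  need an explicit bandwidth. The KDE never feeds the P-value.
* **ANOVA degeneracies** are errors with named conditions: fewer than two
  strains, fewer than two values in a strain, or zero total variance.
* **Sequence hygiene**: IUPAC ambiguity codes are mapped to `N` (counted,
  messaged); `N` never matches in ANI, never counts as a comparable column
  in SNP statistics, and never matches a CRISPR spacer.

## SNP counting and CRISPR arrays

`count_snps()` consumes whole-genome multiple alignments (aligned FASTA,
or XMFA concatenated per genome in block order). A column is considered
iff every row has an unambiguous base; a considered column is a SNP iff at
least two bases occur. The denominator of `snp_percent` is the considered
columns — the only convention under which "substitution" is well defined
for every row — and is recorded in the output, since published percent
differences rarely state theirs.

`arrays_equivalent()` treats two genomes' CRISPR spacer arrays as the same
when some concatenation order of one genome's arrays (each readable on
either strand) equals some order of the other's, spacer by spacer. This
makes the verdict invariant under strand flips and under arrays split
across contigs — both routine in draft assemblies. Matching is exact;
shared/unique spacer counts over strand-canonicalized multisets are
reported whatever the verdict, so partially overlapping arrays are
described without forcing a call. The order/strand search is exhaustive up
to 6 arrays per genome and falls back to the multiset comparison (with a
warning) beyond that. Two genomes with no spacers at all are reported as
the distinct "no CRISPR system" case.

## A worked miniature

```{r mini, fig.width = 6, fig.height = 3.5, eval = FALSE}
anc <- generate_ancestor(50000, seed = 1, label = "anc")
s1 <- derive_strain(anc, 0.0025, 0, seed = 2, label = "s1")$genome
s2 <- derive_strain(anc, 0.0025, 0, seed = 3, label = "s2")$genome

cfg <- pipeline_config(n_pairs = 2000, n_replicates = 10,
                       bootstrap_B = 2000, master_seed = 9)
strains <- tibble(
  strain = c("s1", "s2"), species = "sp",
  genome = list(s1, s2),
  reads = list(simulate_reads(s1, 2500, error_rate = 0.002, seed = 4),
               simulate_reads(s2, 2500, error_rate = 0.002, seed = 5))
)
nulls <- run_null_construction(strains, cfg)

obs <- tibble(
  genome_a = c("s1_asmA", "s1_asmA"), genome_b = c("s1_asmB", "far"),
  species = "sp",
  assembly_a = list(emulate_assembly(s1, seed = 11),
                    emulate_assembly(s1, seed = 11)),
  assembly_b = list(emulate_assembly(s1, seed = 12),
                    emulate_assembly(derive_strain(s1, 0.02, 0, seed = 6)$genome,
                                     seed = 13))
)
report <- run_classification(nulls, obs, cfg)
tidy(report)
autoplot(report)
```

The first pair (two emulated assemblies of the same strain) lands inside
the null and is called identical or related; the second (2% divergence)
sits far left of it with $P = 0$ and is called different.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely from synthetic data at
desk scale, chosen to exercise every code path with tight statistics:
100-kb genomes with 10 replicates of 20,000 read pairs for the
null-construction fixture, 200-kb genomes for estimator accuracy, 50-kb
genomes with a 240-value pool for the calibration property, and 200
classification pairs for power. Scaling `pipeline_config()` back up to the
published defaults changes only run time, not any code path.

## Known limitations

* The emulator does not model repeats, misassembly, contamination, or
  coverage bias; its parameters are statistical, not instrumental.
* The built-in ANI estimator is ungapped after anchoring; heavily
  indel-diverged pairs are better served by an external mapper whose
  table feeds `parse_ani_table()`.
* No multiple-testing correction across pairs (the upstream procedure
  applies none).
* Whole-genome alignment and CRISPR array *detection* are external; this
  package consumes their exports.
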