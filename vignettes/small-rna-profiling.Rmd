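---
title: "Profiling small RNAs in fly neurodegeneration models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNAs in fly neurodegeneration models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirarms)
```

## Scope

`mirarms` re-implements, as a tested and reusable pipeline, the analysis
chain of a small RNA sequencing study in *Drosophila* neurodegeneration
models: adapter trimming and length filtering; 0/1-mismatch matching of
short reads to reference sequence sets; a hierarchical, mutually exclusive
annotation cascade; assignment of miRNA stem-loop reads to 5p and 3p mature
arms by an optimal split-position search; negative binomial exact-test
differential expression with an augmented reference control set; head
versus whole-body enrichment classification; and edit-tolerant detection of
small CAG-repeat RNAs (sCAG) against polyglutamine transgenes. A seeded
synthetic data generator provides inputs that carry the statistical
structure the analysis assumes, so every stage can be exercised end to end
without any external download.

## Preprocessing

Raw reads are clipped at the first occurrence of the 3' library adapter
(`CTGTAGGCACCATCAAT` by default). When a read's insert plus adapter exceeds
the sequencer read length, the read ends in a truncated adapter; we
therefore also clip a terminal adapter *prefix* of at least `min_overlap`
(default 5) nucleotides when it is a suffix of the read, taking the longest
such overlap. Two consequences are worth knowing:

* partial clipping is deliberately not idempotent for inserts whose 3' end
  happens to coincide with an adapter prefix — re-trimming such an insert
  clips again. At `min_overlap = 5` this affects about one read in a
  thousand of random sequence;
* reads in which no adapter is found are kept by default (the
  `discard_untrimmed` flag discards them instead); both behaviours are
  defensible and the choice is exposed rather than hidden.

Only reads of **more than 18 nt** enter the annotation cascade; the cutoff
is strictly exclusive (a 19-mer passes, an 18-mer does not). The sCAG scan
deliberately consumes trimmed reads *upstream* of this filter, with its own
15 nt floor, because repeat-derived RNAs down to 15 nt are informative.

Matching allows 0 or 1 mismatch on either strand. Internally the search is
delegated to `Biostrings::matchPattern` with `fixed = TRUE`, so an `N` in a
read never counts as a match; minus-strand hits are placements of the
reverse complement reported in forward coordinates. The test suite holds
the matcher to a brute-force Hamming scan over every offset and both
strands. All internal coordinates are 0-based half-open; every report
converts to 1-based inclusive.

## The annotation cascade

Reads are first gated against the genome. Genome-matched reads are then
re-matched tier by tier — miRNA stem-loops, other non-coding RNAs
(tRNA/rRNA/misc sub-labels), transposons, introns, mRNAs — and assigned to
the **first** tier with a hit; reads exhausting all five sequence tiers
fall into the intergenic category. Reads failing the genome gate are
reported as a separate `unmatched` count outside the six categories, so
category counts always sum to the number of genome-matched reads. Within a
tier, a multi-hit read is attributed to the reference with the fewest
mismatches, ties broken by lexicographic reference id then smallest offset:
the rule is arbitrary, but a deterministic rule is mandatory for
reproducibility.

## Arm assignment by optimal split

For each stem-loop we collect the alignment interval of every retained
read (one per read id, best placement) and search every integer split
position within 20 nt of the sequence middle (window clipped into
`[1, L-1]`). At a candidate split `s`, reads entirely upstream
(`end <= s`, half-open intervals, so "across the split" means
`start < s < end`) count as `U` and reads entirely downstream
(`start >= s`) as `D`; spanning reads are discarded. The retained split
maximizes `U + D` — equivalently, makes the kept total nearest the number
of mapped reads — with ties broken by distance to the middle and then the
smaller position. `U` becomes the 5p count and `D` the 3p count, with no
dependence on external arm annotations. For non-canonical precursors whose
reads tile the whole hairpin, the partition is arbitrary but the sum
`5p + 3p + discarded` still equals the mapped total, so precursor-level
expression is preserved; a property test asserts exactly this.

## Differential expression

Counts are normalized with median-of-ratios size factors (computed over
rows with all-positive entries). Dispersion is the quadratic
overdispersion `alpha` of the variance model `v = mu + alpha mu^2`:

* **gene-wise**: each condition group and the reference-control set is a
  replicate group. Within each group, the variance in excess of the
  shot-noise term `mu * mean(1/s_j)` is scaled by the *group's own*
  squared mean before pooling across groups with degree-of-freedom
  weights. Scaling per group matters: the dispersion is scale-free, and
  scaling a high-mean group's variance by a grand mean would inflate
  `alpha` for every gene with a genuine fold change;
* **trend**: `alpha(mu) = a0 + a1/mu` fitted across genes by non-negative
  least squares, falling back to the median gene-wise value if the fit
  degenerates;
* **sharing**: under the default `"maximum"` mode the final `alpha` is the
  pointwise maximum of gene-wise and fitted values — a conservative choice
  that accepts some loss of power to avoid understating variability for
  individual features.

The reference-control set enters *only* the dispersion estimation, never
the tested contrast: it sharpens the estimate of within-condition
variability (2 + 2 contrast samples alone leave 2 degrees of freedom) while
comparisons remain between samples of the same genotype.

The test itself is a two-sided conditional exact test: with group totals
`K_A`, `K_B`, the null models the pair as a product of two negative
binomials whose means are proportional to the group size-factor sums
(`q = (K_A+K_B)/(S_A+S_B)`, `mu_A = q S_A`) and whose variances are those
of sums of per-sample NB counts, `mu_A + alpha q^2 sum(s_j^2)`. The
p-value sums the probabilities of all splits of the total no more likely
than the observed one, normalized over all splits; `K_A + K_B = 0` gives
p = 1 by convention. In the Poisson limit with equal size factors this
reduces exactly to the binomial conditional test, which the suite checks to
1e-6. Benjamini–Hochberg adjustment is applied across all tested rows
(`stats::p.adjust`), and the significance threshold (default 0.01) applies
to adjusted values, with a flag for raw-p thresholding.

Two calibration regimes are locked in by tests: under a null NB simulation
(2 vs 2 with 8 reference controls, `alpha = 0.1`, 300 features, 200 runs)
the raw `p < 0.01` rate stays within `[0.002, 0.03]`; and ten 4-fold
effects planted at high counts under the generator's biological dispersion
(0.05) are recovered at `padj < 0.01` with no false positives in the
median run. With only two replicates per condition the exact test is
dispersion-limited — at `alpha = 0.1` a 4-fold change sits at the edge of
detectability no matter how deep the libraries are — which is precisely why
the study design leans on the augmented reference set and why the power
regime is stated at the generator's default dispersion.

Auxiliary report statistics: per-sample Pearson correlation against the
per-feature median of the control samples, computed on `log1p`-transformed
normalized counts (raw-scale correlation of overdispersed counts saturates
near `sqrt(1/(1+alpha))`, about 0.976 at `alpha = 0.05`, and the
above-0.99 replicate regime is a log-scale property); head/body enrichment
classification of significant features by which side of 1 their
whole-body/head ratio falls; directional concordance between ratio sets
from independent experiments (ratios exactly 1 reported separately); and
the comparative Ct fold change `2^-(dCt_B - dCt_A)` with two normalizer
genes for qPCR validation arithmetic.

## The sCAG scan

Reads at least 15 nt long are aligned to both strands of a declared
transgene with a semi-global dynamic program allowing substitutions and
single-nucleotide insertions in the read, but no deletions — matching the
edit classes reported for repeat-derived reads. The best placement per
read (fewest edits, then leftmost, then plus strand) is kept when within
`max_edits` (default 2, the largest edit count observed in published
per-read tables; configurable). A hit is "in repeat" when its *start*
falls inside the declared repeat region, because published per-read
coordinates vary by a nucleotide or two at the region edge, implying
start-based bookkeeping. Densities are reads per kilobase, rounded to the
nearest integer; the repeat-region length uses the `end - start`
convention in printed 1-based coordinates, which reproduces all published
density values simultaneously, while the transgene density uses the full
sequence length.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale:

* a genome (default 10 kb) with non-overlapping planted loci for all six
  categories, so every reference is a genome substring and the cascade's
  gate is consistent by construction;
* stem-loops of 70–100 nt with disjoint 5p/3p arm intervals hugging the
  hairpin ends; arm abundances drawn log-normal with `sdlog = 2`, giving
  expression spanning roughly four orders of magnitude, as in real miRNA
  libraries where a few species dominate;
* counts drawn NB with mean `depth_j * q_i * fold-change` and variance
  `mu + alpha mu^2` (default `alpha = 0.05`; `alpha = 0` gives the Poisson
  limit, verified by a moment test on 10,000 draws);
* reads of 36 nt: an arm-interval insert with optional one-nucleotide end
  wobble (exercising the split search's spanning-read rule), at most one
  substitution per read at the configured error rate, the 3' adapter, and
  random padding; counts per arm match the matrix exactly, so an
  error-free run round-trips to the planted matrix;
* transgenes with a CAG tract at declared coordinates. The flanks end in a
  short repeat-breaking T-run: with fully random flanks, the leftmost best
  alignment of a repeat read can creep a few bases past the declared
  boundary through coincidentally phase-extending flank bases, which would
  break start-based in-repeat bookkeeping — real constructs likewise have
  sharp repeat boundaries. Spiked repeat reads carry their requested edit
  counts exactly (substitutions at least 3 apart, so edits cannot collapse
  under an alternative frame of a period-3 repeat);
* truth labels travel in a sidecar table, never in the FASTQ.

What the generator does *not* emulate: position-specific sequencing error,
quality-value structure, ligation bias, PCR duplication, isomiR end
heterogeneity beyond the one-nucleotide wobble, and genuine genomic repeat
structure. Passing tests therefore demonstrate the correctness of the
analysis logic under the declared statistical model, not robustness to
every artefact of real libraries.

## Numerical choices and degenerate inputs

* All tie-breaks (split position, representative reference, best
  placement) are deterministic and documented above.
* Size factors require at least one all-positive row; the error message
  says so rather than returning NaN.
* Features with zero counts everywhere are dropped before testing and
  recorded in the `"filtered"` attribute of the DE table.
* `K_A + K_B = 0` gives p = 1; empty profiles split at the midpoint with
  zero counts; an empty reference set yields an index with no hits.
* Fold changes with a zero baseline are reported as `Inf` (a real
  sentinel), and tables round to 2 decimals while full precision is kept
  internally.
* Every stochastic function takes a seed and restores the RNG state
  (`withr::local_seed`), so pipeline runs are byte-identical under a fixed
  seed.

## Problem sizes

The bundled simulations are sized for a desk run: pipeline tests use 4
stem-loops and a few thousand reads per run; the calibration suite uses
300 features over 12 samples and 200 replicate runs; the replicate-QC
simulation uses 100 stem-loops (200 arms), 12 replicates and 2e6 expected
reads per library; the matcher and split oracles use hundreds to a
thousand random cases. These sizes are the package's own choices for a
reproducible demonstration of the statistical properties; all of them
scale up through the same interfaces.
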