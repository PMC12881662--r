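---
title: "Methods: uracil enrichment scoring and mutation-spectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uracil enrichment scoring and mutation-spectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uraseq)
```

## The measurement model

U-DNA-seq quantifies genomic uracil as a per-bin (100 bp by default)
coverage ratio of a uracil-sensor pulldown against its input library. The
ratio is only a relative signal: its scale depends on pulldown efficiency
and library depth. An orthogonal biochemical measurement (dot blot)
provides one number per sample — the global uracil content, in uracils per
million base pairs. `rescale_to_ptrack()` joins the two by a single
multiplicative scalar chosen so that the length-weighted mean of the
rescaled track equals the measured content:

$$p_i = r_i \cdot C, \qquad C = \frac{\text{content} \cdot \sum_j l_j}{\sum_j r_j l_j}.$$

The resulting *p-track* is a quasi-absolute per-bin uracil probability
(U/Mb). Two assumptions are inherited from the design of the assay: the
global content measurement is taken as correct, and excluded (blacklisted
or hard-masked) regions are assumed to carry the genome-mean uracil
frequency. The second assumption lets us normalize over retained bins only
and simply not emit values for the excluded regions; the conservation
identity $\sum_i p_i l_i = \text{content} \cdot \sum_i l_i$ over retained
bins then holds exactly and is asserted in the test suite. An alternative
reading — normalizing over the whole genome including the excluded mass —
would change the scalar by the excluded fraction; we chose retained-bin
normalization because it is the only choice under which the stated
mean-frequency assumption is self-consistent.

Bins overlapping any exclusion interval are dropped entirely rather than
trimmed; at 100-bp bins the bias from partial overlaps is negligible
compared with replicate noise, and the rule is trivially idempotent.

## U-scores and differential uracilation

A gene's **U-score** is the coverage-weighted mean of the p-track over the
gene's longest-isoform body (introns included) plus a 1,000-bp upstream
core promoter on the strand-aware 5' side, after blacklist subtraction.
Averaging uses covered-base semantics: bases with no track coverage are
excluded from the mean rather than counted as zero, matching the behavior
of the standard average-over-bed utilities; `covered_bp` is reported so
downstream users can filter poorly covered genes.

For comparisons across samples whose global content is unknown or
irrelevant, the **relative U-score** divides the gene mean of the cleaned
ratio track by that replicate's genome-wide length-weighted mean, making
each replicate unit-free with mean 1. This is the minimal normalization
consistent with computing relative scores "per replicate, separately"; it
deliberately uses the cleaned-track mean (not a gene-restricted mean) as
the denominator.

Differential uracilation between two treatments uses, per gene,

* fold change $\mathrm{FC} = \sum_r U_{A,r} / \sum_r U_{B,r}$ (the ratio
  of group sums, equal to the ratio of means for balanced designs);
* a two-sided Welch (unequal-variance) $t$ test across replicates;
* the significance rule $p < 0.05$ **and** $|\log_2 \mathrm{FC}| >
  \log_2 1.5 = 0.58496$;
* the ranking score $\log_2(\mathrm{FC}) \cdot (-\log_{10} p)$.

Raw p-values drive the significance flag: with tens of thousands of genes
and two replicates per group, FDR control removes everything, so the raw-p
volcano convention is retained and a Benjamini–Hochberg column is emitted
for reference only. With two replicates per group the Welch test has at
most two degrees of freedom — the flag is a screening device, not a
calibrated error rate, and the combined score is the more robust ranking.

One subtlety matters for validation: if one genome segment's uracilation
rate is multiplied by $k$ in group A only, genes inside that segment
recover $\mathrm{FC} = k$ on *absolute* U-scores, but not on relative
ones — the boost also raises the genome-wide mean, so relative scores
attenuate the fold change by exactly that factor. The parameter-recovery
tests therefore use absolute p-track scores.

Gene-class enrichment among the top-*n* (default 2,000) scorers compares
observed class counts with expectations proportional to class size among
all scored genes; ties at the boundary are broken by gene identifier so
the selection is reproducible. Score histograms use half-open bins with an
explicit overflow bucket, so counts always conserve the number of scored
genes. Interaction-network summaries report the average node degree
$2E/N$ and the mean local clustering coefficient over **all** nodes
(degree < 2 nodes contribute 0), matching the conventions of the STRING
statistics they mirror.

## Variant statistics

Variant records pass through, in order: multi-allelic splitting, FILTER
label exclusion (defaults: `weak_evidence`, `normal_artifact`, `slippage`,
`germline`, `base_qual` — a record dies if it carries *any* of them),
pyrimidine-strand classification into the six SBS classes with tri- and
pentanucleotide contexts, and a hard error if the stated reference allele
disagrees with the genome (the cheapest possible guard against 0/1-based
coordinate drift). Allele frequency is taken from INFO/AF, then FORMAT/AF
of the first sample, then FORMAT/AD as alt/(ref+alt); records without any
source keep `NA` and are excluded from weighted statistics, counted.

Weighted occurrences sum allele frequencies per class; fractions divide by
the total and always sum to 1 over assigned records. AF weighting
emphasizes clonal events over single-read subclonal calls; the unweighted
mode (`weighted = FALSE`) is the plain count reduction.

Intermutational distances are gaps between consecutive same-type events
per chromosome. Cluster detection is a deterministic maximal-run scan:
runs of consecutive variants with all successive gaps ≤ `max_imd` and at
least `min_size` members. The threshold is a tool parameter with default
100 bp — kataegis-like clusters show gaps of a few to several tens of
nucleotides, and no printed constant exists to anchor it, so it is exposed
prominently rather than buried.

Doublet (DBS) calls merge two SBS at adjacent positions greedily left to
right (an explicit 2-bp MNP is accepted directly) and collapse into the 78
strand-agnostic categories. For reverse-complement-palindromic reference
doublets (AT, CG, GC, TA) the alternate pair is represented by the
lexicographically smaller of alt / revcomp(alt); this choice is arbitrary
but deterministic, and category membership is identical to the standard
table.

Replication-timing strata follow the E/L convention (higher = earlier):
early > 2.5, late < −2.5, and **boundary values belong to "middle"**
(the inclusive reading of "between 2.5 and −2.5"). Variants outside track
coverage go to an explicit `unassigned` bucket so the partition always
sums to the input size.

## Spectra and refitting

The 96-channel matrix stratifies pyrimidine-strand substitutions by one
flanking base on each side, the 1,536-channel matrix by two; collapsing
the latter over the outer positions reproduces the former exactly
(asserted as a marginalization identity). Channel order is the de-facto
COSMIC canonical order, and every emitted table carries explicit channel
names so downstream code never relies on positions.

Refitting a measured spectrum against fixed reference components uses
non-negative least squares on probability-normalized vectors
(`pracma::lsqnonneg`, a deterministic active-set solver):
$w = \arg\min_{w \ge 0} \|m - Cw\|_2$. Contributions are $w/\sum w$; the
reconstituted spectrum is the renormalized mixture and its cosine
similarity to the measurement is reported. With fixed, known components
this constrained least squares is the standard deterministic equivalent of
extractor tools run in refit mode. Duplicate (collinear) components make
the weights non-unique; the active-set order resolves ties
deterministically and a warning is emitted. Reference spectra are
user-supplied: published deaminase spectra are figure-digitized in the
literature and not reproducible, so the package ships only clearly labeled
synthetic stand-ins (`synthetic_components()`).

## Hairpin (stem-loop) context

APOBEC3A/B prefer cytosines presented in short hairpin loops, so the ±15-nt
context of each substitution (31-nt window) is searched exhaustively for
stem-loops: a loop of 3–6 nt flanked by exact reverse-complement stem arms
of at least 4 nt. Stems are reported at maximal extension per (loop
position, loop length) — sub-stems are not double counted. Pairing is
Watson–Crick by default with G:T wobble behind a flag (conservative
default; the wobble alphabet roughly doubles call counts on random
sequence). Hairpins anywhere in the window are reported; only
`classify_loop_position()` asks whether the variant base itself lies in a
loop, and overlapping hairpins are not deduplicated — a center is
loop-located if *any* predicted loop contains it. Both choices are
exposed: stricter variants can filter on the per-hairpin table. The
implementation is validated for exact agreement against an $O(n^3)$
brute-force enumerator on 1,000+ random windows, including wobble mode.

## Segment statistics

Per-label signal distributions report the base-weighted mean signal and
the SD **across per-interval means** (not across bases) — the two-stage
procedure used for segmentation heatmap error bars: intervals of a label
are first averaged individually, then summarized. The same two-stage rule
applies to replication-timing summaries. AT content excludes N bases from
numerator and denominator. Jaccard indices merge book-ended and
overlapping intervals before intersecting, following the standard genome
arithmetic semantics; feature-overlap fractions are covered-base fractions
and therefore invariant to splitting feature intervals. Heatmap-style
row rescaling offers min–max and z-score variants behind a flag
(default none; min–max is what segmentation heatmaps conventionally show).

## The synthetic-data generator

The generator exists to give every stage a ground truth. It emulates the
*statistical structure* of the study data, not the data themselves:

* i.i.d. genomes at a stated GC fraction (default 0.41, human-like), with
  optional hard-masked N runs;
* non-overlapping gene bodies with GENCODE-style biotype labels at
  configurable weights; 1,000-bp promoters;
* exponential-length labeled segmentations;
* per-bin uracil rates = segment-label mean × lognormal replicate noise
  (unit mean; default CV 0.1–0.2, chosen as a realistic replicate
  concordance for enrichment sequencing), with the per-replicate global
  content defined as the length-weighted mean rate — so rescaling the
  emitted ratio track with that content recovers the per-bin rates
  exactly;
* RT tracks = label mean + Gaussian noise;
* variant sets drawn channel-first from a mixture of 96-channel component
  spectra, placed on genome positions whose trinucleotide context matches
  the sampled channel; allele frequencies Beta(2, 8) (low-frequency
  somatic-like, mean 0.2, so AF weighting is exercised with non-degenerate
  weights); clusters are runs of 2–6 C→T events with successive gaps
  uniform in [2, `cluster_imd`], reproducing the short-IMD mode without
  claiming any particular cluster-generating process.

Truth tables round-trip exactly: channel counts equal the 96-matrix built
from the emitted VCF + FASTA, cluster members are recovered at recall 1
when `cluster_imd ≤ max_imd`, and every generator is byte-deterministic
given its seed.

What passing these tests does **not** show: real enrichment tracks have
spatially correlated noise, GC- and mappability-coupled coverage bias, and
segment boundaries that are themselves estimated; real somatic calls carry
caller-specific artifacts, strand bias and purity effects. The generator
validates the arithmetic and the contracts, not robustness to those
phenomena.

## Numerical and scale choices

Coordinates are 0-based half-open everywhere internally; VCF positions are
converted on read, and a reference-allele check enforces the convention.
Bin widths are read from files, not assumed; mixed widths are handled by
length weighting. Test and acceptance problem sizes — 1–2 Mb genomes,
10⁴ variants, 10³ hairpin oracle windows, 20-gene fold-change recovery
fixtures — were chosen so each statistical check has comfortable power
(e.g. the mixture-recovery band is the analytic 3σ multinomial error
inflated by the Beta-AF second moment) while the whole suite stays fast
enough to run routinely. Degenerate inputs are handled by stated
conventions rather than silence: zero-variance Welch inputs (p = 1 on
equal means), all-zero ratio tracks (error), empty interval sets in
Jaccard (0 with a warning), zero-coverage genes (`NA`, counted),
unassigned variants (explicit buckets).

## Known limitations

* The differential caller assumes replicate U-scores are comparable after
  the chosen normalization; batch effects between replicates are not
  modeled.
* NNLS refitting inherits the usual collinearity caveat: similar
  components trade weight with little change in fit quality; inspect the
  cosine and residual, not just contributions.
* Hairpin prediction is purely combinatorial (no thermodynamics): a 4-nt
  A:T-only stem counts as much as a G:C stem.
* The cluster scan uses a single IMD threshold rather than a background
  rate model; for genome-scale kataegis calling a rate-aware method is
  more appropriate.
* `segment_at_content()` and `signal_distribution()` iterate per interval
  and are sized for segment counts in the hundreds to low thousands, not
  for base-resolution segmentations of full mammalian genomes.
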