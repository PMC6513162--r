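---
title: "De novo GBS variant calling: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo GBS variant calling: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsnp)
```

Genotyping-by-sequencing (GBS) reduces a genome to restriction fragments and
sequences them as stacked reads across a population. Without a reference
genome, variant discovery must first reconstruct the loci themselves:
`gbsnp` clusters reads into a *mock reference* of consensus GBS fragments,
maps all reads back onto it, and calls bi-allelic SNPs and indels from
per-individual pileups, with dedicated screens for the two failure modes
that dominate de novo GBS calling — sequencing/PCR error and collapsed
homologous loci. A built-in read simulator with complete truth records
makes every stage of the pipeline measurable.

This vignette documents the models, the tunable parameters, and the design
decisions taken where the design was genuinely open. The README shows a
worked end-to-end example; here we focus on *why* the pieces look the way
they do.

## The simulator: what it emulates

`simulate_gbs()` draws a fragment space, induces variants, assigns
population genotypes, and emits error-laden reads:

* **Fragments.** `n_fragments` sequences with i.i.d. uniform bases, lengths
  uniform on `fragment_length_range` (default 240–400 bp). Random fragments
  of this length are pairwise dissimilar with overwhelming probability,
  which matches the intent of a "unique fragment" genomic space and gives
  the clustering stage a clean identifiability baseline.
* **Variants.** At most one variant per fragment: SNPs plus bi-allelic
  indels (insertion or deletion with equal probability, lengths uniform on
  1–`max_indel_len`, default 10 bp so an indel always fits inside one
  read). Alleles are stored left-anchored and left-normalized against the
  fragment, the same normal form the caller uses, so truth matching is a
  coordinate comparison rather than a re-alignment problem. Offsets are
  restricted to `[margin, read_length - margin]` (default margin 10 bp):
  an uncovered variant would make false-negative rates uninterpretable.
* **Genotypes.** Per variant a minor-allele frequency is drawn uniformly
  from `maf_range` (default 0.1–0.5) and individuals are drawn under
  Hardy–Weinberg proportions; variants that end up with zero alt carriers
  are redrawn so every truth record is discoverable in principle.
* **Reads.** Per (individual, fragment) the depth is uniform on
  `depth_range` (default 20–30x). Each read copies the first `read_length`
  bases of one haplotype (heterozygotes pick either with probability 0.5);
  paired mode adds a reverse-complement tail read. Each base is substituted
  independently with probability `error_rate` (default 1.1%) by a uniformly
  chosen different base. Qualities are constant: the pipeline does not use
  base qualities, and modelling quality profiles would add parameters
  without exercising any code path.

What the simulator deliberately does **not** model: barcode/adapter
sequence and demultiplexing, PCR duplicates, sequencing indel errors,
quality-score degradation along the read, restriction-site biases, and
genuinely homologous loci (paralog fixtures are built explicitly in the
test suite instead). Passing the end-to-end benchmark therefore shows that
the pipeline's logic is sound under idealized GBS noise; it does not certify
performance on real libraries, where error is structured and loci really do
collapse.

All randomness flows through R's RNG from one integer seed; each stage
derives a fixed sub-seed, so a configuration reproduces its output
byte-for-byte regardless of which stages are re-run.

## Mock-reference construction

Reads from the selected individuals are dereplicated exactly, then
clustered greedily in decreasing (length, count, lexicographic) order: a
sequence joins the first centroid with identity at least
`identity_threshold`, else founds a new cluster. Identity is global:
`1 - edit_distance / max(length_a, length_b)`. Key choices:

* **Identity threshold 0.93.** With 150 bp reads and ≤1.1% error, true
  same-locus reads differ by a handful of edits (identity ≥ 0.97 in the
  bulk), while distinct random loci sit near identity 0.5; 0.93 leaves a
  wide corridor on both sides and tolerates one ≤10 bp indel
  (1 − 2·10/150 ≈ 0.87 is the worst same-locus case, which deliberately
  *splits* large-indel haplotypes — see limitations).
* **Abundance floor (`min_count = 2`).** Unique sequences seen once are
  mostly error reads (expected ~80% of reads carry ≥1 error at 1.1% over
  150 bp, and almost every errored read is unique). They may still *join*
  clusters but cannot found one, which suppresses error-only centroids
  without discarding their depth contribution.
* **Exactness of the candidate search.** The greedy rule is implemented
  with a shared-k-mer prefilter whose k is chosen by the pigeonhole bound
  `k ≤ min_len / (max_edits + 1)`, so any sequence within the identity
  threshold of a centroid is guaranteed to share a k-mer with it; the
  prefilter changes nothing about the result, only the cost. Below the
  bound's useful range the code falls back to scanning all centroids.
* **Consensus.** Members are aligned to the centroid (banded, affine gaps)
  and each centroid column takes the count-weighted majority base, ties to
  the centroid. Insertions relative to the centroid are dropped, so the
  consensus length equals the centroid length. One base per column is
  emitted (no IUPAC ambiguity codes): downstream calling works from
  pileups, so a polymorphic column loses nothing by having a single
  representative in the reference.
* **Data usage.** The default builds the mock reference from the single
  most read-abundant individual. Pooling more individuals mixes more
  haplotypes (and more error) into the clustering problem and measurably
  increases both error rates in the benchmark, consistent with
  single-genotype assembly being the recommended practice.

## Read mapping

`align_reads()` is a k-mer seed-and-extend mapper specialized for
GBS-on-mock-reference geometry (reads are full-length near-prefixes of
their centroid):

* Seeds of length `k = 20` sampled every 7 bp vote for (centroid,
  diagonal) candidates on both strands.
* A candidate whose best diagonal explains the read with ≤ 4 mismatches
  (Hamming) is accepted as an all-M alignment without running the DP; a
  gapped alignment cannot beat the all-M score at that distance except in
  degenerate end-tie representations. Everything else goes through a
  banded affine DP (match +1, mismatch −1, gap open −2, gap extend −1,
  band half-width 12 > the 10 bp maximum simulated indel), global in the
  read with free reference ends and a trailing soft clip allowed once the
  centroid is exhausted (deletion haplotypes overrun a prefix-length
  centroid by up to the deletion length).
* A read maps if its edit distance (mismatches + gap bases) is at most
  `max_mismatch_frac` (default 0.1) of the read length. At 1.1% error the
  expected edit load is ~1.7, so the budget of 15 accommodates error plus
  one full-size indel.
* **Unique-mapping policy.** Ties on one centroid break by lower edit
  distance, then more seed hits; a best alignment tied across *different*
  centroids marks the read unmapped. Multi-mapping reads are exactly the
  reads that would contaminate the homolog Z-score's interpretation, so
  they are excluded rather than assigned.

Pileups count M-column bases per individual; I/D segments are recorded as
left-normalized indel alleles anchored on the preceding base (the VCF
normal form), so the caller and the truth matcher share one coordinate
convention. Coordinates are 0-based internally and 1-based only in
VCF/SAM output.

## Variant calling

Calling combines within-individual depth rules with across-population
filters. Per individual at a site with primary/secondary allele depths
`p ≥ s`:

| rule | default | rationale |
|---|---|---|
| genotype only if depth ≥ `min_depth_call` | 6 | below ~6 reads hom/het separation is noise |
| het if `s ≥ min_minor_depth_het` and `s/(p+s) ≥ min_minor_frac_het` | 3 reads, 0.20 | at 20–30x a true het has s ≈ 10–15; 3 errors of one base at one site are rare (~10⁻⁴ per site per individual) but 3 reads *and* 20% together are rarer still |
| hom if `s/(p+s) ≤ max_minor_frac_hom` | 0.10 | tolerates ~1–2 error reads at 20–30x |
| otherwise | missing | evidence between the bands is ambiguous; forcing a genotype would trade silent errors for honest missingness |

A site becomes a variant only if the population-wide top-two alleles are
the centroid allele plus one alternative, no third allele exceeds the
noise floor `max(2 reads, 5% of pooled depth)` (multi-allelic sites are
dropped — the pipeline is explicitly bi-allelic), the call rate reaches
`min_call_rate` (0.75), and at least `min_alt_carriers` (1) called
individuals carry the alternative. These thresholds are deliberately
conservative at 20–30x and fully configurable; none is canonical.

The genotype matrix, the variant description table and the VCF carry the
same content; VCF emission is a pure format conversion (`GT:AD:DP`, INFO
`NS/AF/ZSCORE`, contig headers from the mock reference).

## Homolog screening

When two homologous loci collapse onto one centroid, every individual
receives reads from both copies. At a site where one locus is fixed and
the other segregates, apparent heterozygotes show a systematic
allele-depth imbalance (≈3:1 instead of 1:1 at a diploid het). The screen
pools reference and total depths over heterozygous individuals and
standardizes against binomial(n, 0.5):

$$ z = \frac{x - n/2}{\sqrt{n/4}} $$

Variants with $|z| > 5$ (strict) are culled. At pooled depths in the
hundreds this matches the exact binomial two-sided test at the equivalent
tail probability for every count except, at some `n`, the single boundary
count where the normal approximation rounds the threshold differently —
the test suite pins down exactly that statement. Pooling is the default
because it weights individuals by their information content; averaging
per-individual ratios ("mean" mode, `method = "mean"`) is provided behind
the same interface since the field uses both. Variants with no
heterozygotes carry no evidence either way and are never culled.

The screen's null false-positive rate at |z| > 5 is ~6×10⁻⁷, so on a
homolog-free simulation essentially nothing is culled; the test suite
verifies both the null calibration and the detection of a constructed 1:1
collapsed two-locus fixture.

## Ploidy inference

Higher ploidies change the allele-balance distribution at heterozygous
sites: diploids cluster at 1/2, triploids at {1/3, 2/3}, tetraploids at
{1/4, 1/2, 3/4}. `infer_ploidy()` fits fixed-mean Gaussian mixtures with
free weights and component variances tied as `m(1−m)/d_eff` through one
free effective depth — the Gaussian approximation of binomial allele
sampling, whose noise is wider at balanced ratios than at skewed ones.
Ignoring that heteroscedasticity (a single shared variance) demonstrably
confuses triploid and tetraploid fits at GBS-typical depths.

Because the candidate models are nested (the tetraploid mixture can set
its side weights to zero), the maximized likelihood alone always prefers
the richest model; `best_model` is therefore chosen by BIC, and the full
log-likelihood table is reported so users can apply their own criterion.
Fewer than 30 usable ratios yields an explicit "insufficient data" report
rather than a guess. Candidate set 2n/3n/4n by default; the mean vectors
are trivially extensible.

## Evaluation

Centroids are anchored to their source fragments by the same aligner
(identity ≥ 0.9 over the centroid, unique best hit). Calls are projected
through that alignment into fragment coordinates and matched one-to-one
against truth records: position exact for SNPs, ±2 bp for indels (both
sides left-normalized; the slack absorbs consensus-versus-fragment
coordinate jitter around repeats). The allele pair is compared *unordered*:
when the mock-reference individual carries the alternative allele, the
centroid itself contains it and every call at that site has REF/ALT
swapped relative to the truth table — orientation is a property of the
arbitrary reference choice, not of the discovery. A pair that differs in
content never validates. Genotype concordance (a separate diagnostic)
harmonizes orientation the same way before comparing.

The three reported rates are: Type I = % of calls not validated, Type II =
% of simulated variants not detected, and overall accuracy =
100·validated/(simulated + non-validated). Accuracy punishes false
positives and false negatives in one number and is the headline metric of
the benchmark.

## Benchmark problem sizes

The package's standing benchmark (test suite and `scripts/acceptance.R`)
runs the full pipeline on 4,000 fragments with 1,000 SNPs + 400 indels, 25
individuals, 150 bp single-end reads at 20–30x and 1.1% error (~2.5
million reads), with the mock reference from the single most read-abundant
individual — the same population design as the full-scale experiment at
1/25 of the fragment space, chosen so a complete run takes a few minutes
on one CPU. Variant-induction conformance is additionally checked at the
full 100,000-fragment scale, where it is cheap. Under these conditions the
pipeline reaches ~89% overall accuracy (seed-dependent within a few
points), with Type I below 1% and genotype concordance ≈ 100% at validated
sites.

The remaining Type II error has two understood structural sources, both
measured on the zero-error control rather than assumed: fragments whose
selected individual contributes no error-free read pair lose their
centroid (abundance floor), and large (≥ ~6 bp) indels whose
mock-reference individual is heterozygous split into two centroids whose
reads then separate perfectly — each centroid looks monomorphic and the
variant is silently absorbed into the reference. Both are properties of
single-individual mock references generally, not of this implementation;
neither affects Type I.

## Numerical and degenerate-input choices

* Edit distances and DP scores are integer arithmetic throughout; there
  are no floating-point tolerances in the combinatorial core.
* Clustering ties (equal length, count) break lexicographically; candidate
  evaluation order is the founding order — both fixed so runs are
  reproducible to the byte.
* Consensus ties resolve to the centroid base; all-zero columns keep the
  centroid base.
* `greedy_cluster(min_count = 1)` partitions its input exactly; with a
  floor > 1, unassigned singletons are returned explicitly (`cluster =
  NA`) so read counts always reconcile.
* Empty inputs propagate as empty, well-typed tables (empty truth table,
  empty call set, header-only VCF) rather than errors; genuinely invalid
  configuration fails fast with the violated constraint named.
* EM runs to a 10⁻⁸ log-likelihood tolerance with the effective depth
  clamped to [1, 10⁴]; the fixed means make the likelihood well-behaved
  and initialization-insensitive.

## Known limitations

* Paired-end reads are simulated and alignable, but the pipeline does not
  stitch mates into longer pseudo-fragments; R2 reads simply map
  independently.
* The caller is strictly bi-allelic and emits no genotype likelihoods.
* The homolog screen tests allele-depth balance only; collapsed loci that
  are balanced everywhere (two fixed, identical-frequency copies) are
  invisible to it, as they are to any depth-ratio method.
* Real-data effects outside the simulator's scope (structured error,
  PCR duplicates, true paralogy, quality variation) are exactly the
  conditions under which the published-scale numbers should be expected to
  degrade; the benchmark here bounds algorithmic, not biological, error.
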