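---
title: "The kmertyper genotyping model"
author: "kmertyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kmertyper genotyping model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmertyper)
```

`kmertyper` genotypes known biallelic SNPs and short indels without
aligning reads. This vignette explains the statistical model, the data
structures behind it, the tunable parameters and their defaults, the
numerical choices, and what the bundled simulator does and does not
emulate.

## Graph representation

A reference genome plus a set of non-overlapping biallelic variants
defines an acyclic sequence graph: reference segments chained per contig,
interrupted at each variant by a reference-allele node and an
alternative-allele node that share predecessors and successors
(`buildVariantGraph()`). Deletion alleles are empty nodes, so paths
through them skip the deleted bases; insertions are nodes on the
alternative path only. Every source-to-sink path spells a haplotype, and
with v variants on a contig there are 2^v such paths. Alleles are
left-trimmed of their shared VCF prefix, so coordinates are 0-based
first-affected-base positions and at most one allele of a pair may be
empty. Variants whose reference intervals overlap cannot be represented
in this node topology; the builder keeps the first by position and skips
the rest with a warning. Multi-allelic records are likewise skipped at
VCF parsing time — the model is strictly biallelic.

## Choosing k-mers for alleles

A window of length k can cover an allele at offsets -(k-1) .. 0 relative
to the allele start (the junction for empty alleles). At each offset,
`enumerateAlleleWindows()` spells one k-mer per combination of ref/alt
choices at the neighbouring variants whose nodes intersect the window.
Each candidate k-mer is scored by its *expected population frequency*:
the expected number of copies in a random panel individual's diploid
genome, computed over all graph windows with each occurrence weighted by
the mean number of panel haplotypes consistent with its local allele
combination (`buildFrequencyModel()`). A k-mer occurring once on the
reference far from any variant therefore scores 2.0 — one copy per
chromosome. We define frequency in diploid-copy units because the Poisson
rates downstream are per genome copy; haplotype-count or individual-count
definitions would only rescale the ordering.

`selectVariantKmers()` keeps, per variant, the offset minimising the
maximum frequency over the union of its ref- and alt-allele k-mer sets —
ambiguous k-mers are avoided when any unique alternative exists. Ties go
to the most window-centred offset (nearest -⌊(k-1)/2⌋, most robust to
read-end errors), then to the lower offset, making selection
deterministic. A window set with more than 2^8 spellings (or more than 8
intersecting variants) is flagged degenerate and excluded; if every
offset is degenerate the smallest set is used and the variant marked
low-confidence. The default k = 31 (odd, so no k-mer is its own reverse
complement, and 2 bits/base fit one 64-bit word in the counting core) is
configurable down to 3.

Because reads have unknown strand, every k-mer — in the index and in the
reads — is canonicalized to the lexicographic minimum of itself and its
reverse complement, which coincides with the numeric minimum of the 2-bit
encodings.

## The count model

For each variant, allele and genotype class, the index stores the
histogram over panel individuals of d, the total number of occurrences of
the allele's selected k-mers in that individual's diploid genome
(`buildCountModel()`). d counts own-site copies *and* duplicate copies
elsewhere in the graph, computed from the same occurrence catalogue as
the frequency model; on non-overlapping variants this equals brute-force
counting on written-out haplotype sequences, which is how the test suite
validates it. Histograms are clamped at dMax = 15 with an overflow bin —
beyond ~15 copies the corresponding Poisson components are practically
indistinguishable and storage stays bounded. A genotype class with no
panel individual receives one pseudo-individual at the idealized d
(estimated off-site copies plus 0/1/2 own copies), so every mixture is
well defined even for rare genotypes.

The likelihood of an observed allele count K is the equally-weighted (per
individual) mixture

P(K | G) = Σ_d (c[d] / Σc) · Pois(K; λ₀(d + ε))

with `alleleLikelihood()`. λ₀, the expected read k-mer count per genome
copy, is (C/2)·(L−k+1)/L for coverage C and read length L
(`estimateLambda0()`): half the coverage is haploid depth, and only
(L−k+1) of the L read positions covering a base start a full window. The
error term ε (default 0.01) keeps the likelihood of error-derived counts
non-zero without drowning signal; a rate of exactly zero is treated as a
point mass at zero. The two allele counts of a variant are modelled as
conditionally independent given the genotype, so P(**K**|G) is their
product; when an allele has several selected k-mers, both K and d are
sums over the set, preserving the mean relationship. Evidence is
accumulated in log space with max-subtraction before normalization,
because Poisson tails underflow doubles at deep coverage.

## The helper prior

Nearby variants are correlated through linkage. Rather than full
haplotype inference, each variant depends on exactly *one* other variant:
among the 100 nearest variants on each side by sorted rank (clipped at
contig ends, so 200 in the interior), `selectHelper()` picks the one
maximising Σ_G log π(G, G), the log-probability that the pair agrees in
all three genotypes, with π the panel's smoothed 3×3 joint genotype
table. Smoothing adds s = 1/n to each of the nine cells — the metric
takes logs, so zero cells must be regularized, and 1/n vanishes as the
panel grows. The same smoothed π is used as the genotyping prior, and the
helper relation is directed (no symmetry or chaining is enforced), which
keeps genotyping a single table lookup per variant regardless of panel
size.

`posteriorWithHelper()` combines the variant's own likelihoods L_i with
the helper's L_h by marginalising the nine genotype combinations:
posterior(G_i) ∝ L_i(G_i) Σ_{G_h} P(G_h) P(G_i|G_h) L_h(G_h). The
stated relation is a proportionality — the normalizing constant over G_i
is applied explicitly. If the unnormalized posterior vanishes entirely
(possible only with degenerate zero-rate mixtures), the call falls back
to the smoothed population prior with a warning. In `likelihoods-only`
mode — the output meant for external imputation tools — the helper term
is skipped and the posterior is the normalized product of the k-mer
likelihood with the population genotype prior; helper-less variants (a
single-variant contig) degrade to the same formula. VCF output always
stores GL as log10 of the normalized *pre-prior* likelihoods, GT/GQ from
the active mode's posterior; GQ is −10·log10(1 − max posterior), rounded
and capped at 99, and exact ties call 0/0 before 0/1 before 1/1.

A `naive = TRUE` ablation replaces every d by the idealized own-site
copies (0/1/2 by genotype), i.e. the model a unique-k-mer genotyper would
use. It exists so the benefit of population-modelled duplicate counts is
testable: on fixtures with a planted segmental duplication, the full
model's accuracy on non-unique-k-mer variants exceeds the ablation's
while unique-k-mer accuracy is unchanged — the test suite and
`scripts/acceptance.R` both measure exactly this.

## Counting

`countReads()` scans each read once with a rolling 2-bit encoder (C++),
skips windows containing non-ACGT bases, and increments every allele node
an indexed canonical k-mer maps to — a k-mer selected for several alleles
increments all of them; ambiguity is resolved by the count model, not at
count time. Counting is exact, order-independent and additive over any
partition of the read set, so chunked or two-stage workflows (the `count`
CLI subcommand writes a node-count TSV) give byte-identical results.
Base qualities are ignored.

## The simulator

`simulateDataset()` generates a uniform random reference (optionally with
segmental duplications copied to a target position at a configurable
sequence identity, which plants shared k-mers), variant sites placed
uniformly without overlap (10% short indels of 1-5 bp by default), and a
phased panel built by mosaic block-copying from a small founder set: each
haplotype copies a random founder in blocks of `ldBlockLength`
consecutive variants (default 50), so genotype correlation decays with
rank distance — the structure the helper prior exploits. The genotyped
sample's two haplotypes are drawn by the same mosaic process (in-panel
linkage, novel combination), and single-end reads are drawn uniformly
from both haplotype strings with random strand and per-base substitution
/ insertion / deletion errors of 0.001 each by default, matching common
short-read simulation settings. The defaults — 100 kb, 500 variants, 50
individuals, 4 founders, 15x 150 bp reads — are the package's study
conditions; all outputs are deterministic given the seed.

The simulator is deliberately not a population-genetics simulator: there
is no coalescent, no recombination map, no mutation-rate heterogeneity,
no quality-score model, no paired-end structure, and the reference has
none of the large-scale repeat architecture of real genomes beyond the
planted duplications. Passing tests therefore demonstrate the
correctness of the estimator under its own model assumptions and its
robustness to the modelled error processes — not calibrated performance
on real human data.

## Numerical and design choices

* Internal coordinates are 0-based half-open; VCF I/O converts to/from
  1-based and re-anchors empty alleles on the preceding base.
* Heterozygous genotypes are unordered (1|0 ≡ 0|1); missing panel
  genotypes (./.) are counted and treated as hom-ref — a documented bias
  that keeps the panel matrices complete.
* The allele-frequency input filter (keep AF > threshold, e.g. 0.1%) is
  off by default and only applied when requested (`minAF`,
  `--min-af`): synthetic panels contain no sub-threshold ultra-rare
  variants, so the filter exists for real-world catalogues.
* The occurrence catalogue behind the frequency model deduplicates
  alternative-path windows by anchoring each at its leftmost alternative
  allele, and extends window offsets to len(alt)−1 so windows starting
  inside multi-base insertions are counted; without this the
  written-out-haplotype oracle would not be matched exactly.
* The index archive is a single serialized file with an explicit format
  version; loading a stale version fails loudly.
* Test and acceptance problem sizes (100 kb / 500 variants / n = 50 for
  end-to-end checks; ≤ 200 bp / ≤ 10 variants / n ≤ 5 for exact oracle
  comparisons; 20 replicates of 15 kb / 80 variants for the prior-mode
  comparison) were chosen to exercise every code path at desk scale with
  tight runtimes.

## Known limitations

Strictly biallelic, non-overlapping variants; k ≤ 31; single-sample
genotyping of known sites only (no discovery, no phasing, no structural
variants); paired-end information is unused; the frequency model uses
phased haplotypes when available and falls back to a deterministic
heterozygote split otherwise, which can slightly mis-weight multi-variant
windows in unphased panels.
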