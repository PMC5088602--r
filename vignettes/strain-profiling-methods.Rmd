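---
title: "Strain-level metagenomic profiling with metastrain: models and methods"
author: "metastrain maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level metagenomic profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun metagenomes mix reads from hundreds of bacterial populations.
Reference-based strain profiling asks four nested questions about each
sample: which species are present and how abundant are they; which genes of
each species' pan-genome does the resident population carry, and in how many
copies per cell; at which core-genome sites does the population differ from
a reference genome; and, across hosts, do two samples carry the *same
strain* — evidence of transmission. `metastrain` implements this pipeline
end to end, together with a mock-community simulator that provides complete
ground truth, so every stage is validated against data whose answer is
known by construction.

## Species delineation

Genomes are grouped into species operationally: for each universal marker
gene family, pairwise percent identities $P_{ab}$ are computed from the
best local alignment, masked whenever the alignment covers less than 70% of
either sequence, and converted to distances

$$D_{ab} = \frac{100 - P_{ab}}{100}.$$

Distances are averaged across the (by default 30) marker families and the
averaged matrix is clustered by average linkage (UPGMA), cutting at a
distance of 0.035 — i.e. 96.5% marker identity, the operational species
boundary calibrated against the average-nucleotide-identity (ANI $\ge$ 95%)
gold standard. The implementation delegates the agglomeration to
`stats::hclust(method = "average")`; the test suite verifies it against an
exhaustive brute-force agglomerator on small instances. Masked pairs are
treated as distance 1.0 (never mergeable), a deliberately conservative
convention; species labels are derived from the lexicographically smallest
member genome so that the assignment is invariant to input order. All
argmax and modal ties anywhere in the package break lexicographically, for
determinism.

Each species is represented by the member genome with the highest mean
marker identity to the rest of its cluster, and by a pan-genome: all member
genes greedily clustered at 99% identity (genes sorted by decreasing
length, each joining the first centroid at $\ge$ 99% identity and $\ge$ 70%
mutual coverage). Coarser aggregations (75–95%) are produced by re-running
the same greedy procedure on the centroids.

## Read mapping

All profilers share one self-contained seed-and-extend mapper: targets are
indexed by exact 15-mers, candidate (target, diagonal) pairs are collected
from seed hits (every second read position by default), and candidates are
scored by banded dynamic programming (match +1, mismatch −2, gap −3, band
half-width 8). Candidates supported by fewer than a quarter of the best
candidate's seed count are not extended. Two modes mirror the two mapping
stages: *local* (gene and marker databases; unaligned read ends are free)
and *global* (representative genomes; the entire read must align). Each
read is reported once, for its best hit; co-optimal hits are flagged as
ties with mapping quality 3, unique best hits get mapping quality 60, so
the default `mapq >= 20` filter is exactly "discard non-unique hits". The
standard alignment filters are percent identity $\ge$ 94, aligned read
fraction $\ge$ 0.70, mapping quality $\ge$ 20 and mean read quality $\ge$
20; "sequence quality" is read as the mean base quality of the read, since
a separate, stricter per-base threshold (30) governs SNP pileups.

Because candidate discovery is seed-based, sensitivity degrades for reads
below roughly 85% identity to every target; within this package's scope
(species-level cutoffs of 94.5–98% and a 75% lenient screen applied to
communities whose members have database relatives) this is immaterial, but
the mapper is not a general-purpose divergent-homology search tool.

## Species abundance

Reads are recruited to a database of 15 universal single-copy gene (USCG)
families, one sequence per (species, family). An alignment counts only if
it covers $\ge$ 70% of the read and meets the family-specific identity
cutoff (tuned cutoffs range 94.5–98%; simulator-built databases default to
95%). Reads unique to one species count fully; reads tying across species
are split fractionally in proportion to each species' uniquely-mapped read
counts — a deterministic, expectation-equivalent alternative to random
assignment. Species coverage is pooled aligned bases divided by summed
marker length (a per-family median is available as an option), so partial
alignments contribute proportionally; relative abundance normalises
coverages to sum to one. Since reads overhanging marker ends are dropped by
the coverage filter, the estimator carries a small negative bias
(about $50/L$ per marker of length $L$, i.e. ~5% at 1 kb) — coverage is
slightly underestimated while relative abundances are unaffected.

Database coverage — how much of a community the reference explains — is
the ratio of summed database-species coverage to an estimate of total
cellular genome coverage, times 100. The denominator offers two documented
strategies: re-screening marker alignments at a lenient 75% identity and
taking the median per-family fold, or dividing total read bases by a known
average genome size. Both are stated simplifications of genome-size-aware
estimators and are flagged as such in the output.

## Gene content

For species above a coverage threshold (default 1×), reads are mapped
locally against the pooled pan-genome centroids and filtered at
94/0.70/20/20. Cluster coverage is aligned bases over centroid length;
copy number divides by the species normaliser — the median coverage of the
USCG families, computed from the same pan-genome mapping so that
normaliser and gene coverages share alignment biases; a family with no
mapped reads contributes 0, so low-depth species are flagged rather than
silently normalised. A gene is called present when its copy number is at
least 0.35 ("less than 0.35" is absent; the boundary itself is present).
Cross-sample merging yields genes × samples matrices and Jaccard distances
on presence sets.

## Core-genome SNPs

Reads are mapped globally against the representative genome; bases with
quality below 30 are discarded and substitution counts accumulated per
reference position (`N` bases and indels are ignored — the variation model
is substitution-only). Depth is therefore *effective*, post-quality-filter
depth. The core genome is identified from data, not annotation: a site is
core when its depth strictly exceeds 10 in at least 95% of samples.
Cross-sample merging defines cohort-wide major/minor alleles from pooled
counts and emits minor-allele frequency and depth matrices, with zero-depth
cells encoded as missing (`NA`), distinct from frequency zero. Consensus
SNP calls (highest-count allele differing from the reference, at any
nonzero depth) are conservative on ties: no call.

## Strain tracking

An allele is present in a sample when supported by at least 3 reads and at
least 10% of the site's reads. Restricting to biallelic sites (exactly two
present alleles cohort-wide), a *marker allele* of a unit — an individual,
or a mother–infant pair during discovery — is an allele present in at least
one of the unit's samples and in no sample outside the unit. Sharing from
donor to recipient is the percentage of the donor's marker alleles detected
in the recipient; donors with fewer than 10 markers are excluded rather
than scored, and sharing strictly above 5% is classified as transmission.
The sharing denominator is all of the donor's markers (not just
recipient-covered sites); the >10× coverage gate on both samples makes
uncovered marker sites rare, and a restricted-denominator option is
available. Biallelism is evaluated on post-threshold present alleles, which
makes it robust to singleton sequencing errors.

## The simulator: what it emulates, and what it does not

The generator builds, per species, an ancestral genome of marker genes
(30 families, 15 flagged as the abundance panel, single copy), a pool of
pan-genome genes (30% accessory by default) and random spacers. Species
marker sets diverge from shared family ancestors at 10% pairwise
divergence, strains within a species at 2% pairwise (per-lineage rates are
half the pairwise targets), so the within/between bands bracket the 96.5%
species boundary with a wide margin, as in real marker-gene distributions.
The representative genome is the ancestral genome itself — the single
"database strain" — so community strains sit at ~1% true divergence from
the reference, the regime in which consensus SNP calling is meant to
operate. Community strains retain each accessory gene with probability
0.5; their true gene sets and substitution sets are emitted as ground
truth. Reads are fixed-length (100 bp), single-end, uniformly placed,
strand-symmetric, with independent substitution errors (default 1%);
correct bases draw qualities uniformly from 30–40 and errored bases from
2–35, so both the mean-quality filter (20) and the per-base filter (30)
have bite. Read counts per genome are Poisson with mean
coverage × length / read length, with coverage allocated as total coverage
× relative abundance.

Defaults chosen where no external condition fixes a value: marker genes
1000 bp (the scale of real single-copy marker genes; also keeps the
read-overhang bias of coverage estimation near 5%), pan genes 400 bp,
spacers 60 bp, 16 pool genes per species in abundance experiments and 40
in gene-content experiments, clustering-marker length 400 bp in the
200-genome clustering experiment (alignment-fragment scale, which keeps
the 597,000 pairwise alignments affordable on one CPU).

What the simulator does *not* model: indels, GC bias, duplicate reads,
quality-by-cycle structure, chimeras, within-sample strain mixtures, and
genuinely novel community members absent from the database. Passing the
validation experiments therefore demonstrates the correctness of the
pipeline's logic and its behaviour under substitution noise and known gene
turnover — not robustness to every artifact of real Illumina libraries;
the filters' default values come from the tool lineage this package
follows, where they were tuned on real data.

## Validation experiments and problem sizes

Four experiments, reproducible via `scripts/acceptance.R` and the test
suite, each on a single CPU within minutes:

1. **Abundance recovery** — 20 communities × 20 species, exponentially
   decreasing abundances ($a_i \propto 2^{-i}$: 50%, 25%, 12.5%, ...),
   100× total coverage, 1% error; pooled squared Pearson correlation
   between true and estimated relative abundance.
2. **Gene presence** — 12 species placed at coverage tiers 0.5–30×, strains
   carrying known gene subsets; balanced accuracy
   (sensitivity + specificity)/2 of presence calls at copy-number cutoff
   0.35 for species above 3× estimated coverage, plus a cutoff sweep
   (0.05–0.95) to confirm 0.35 sits on the optimum plateau.
3. **Clustering** — 200 genomes in 25 species; pairwise F1 of the
   cutoff-0.035 assignment against the generating partition.
4. **Transmission controls** — 30 units × 2 independent samplings at 20×
   of two shared species; replicate-pair sensitivity and unrelated-pair
   specificity of the 5% sharing rule.

## Numerical and degenerate-input conventions

Tie-breaks are lexicographic throughout (cluster seeds, representatives,
modal names) or conservative (consensus ties: no call). Zero denominators
are explicit: zero total coverage gives an undefined database coverage
(`NA`), a zero USCG normaliser flags the species rather than producing
infinities, zero evaluable pairs give an undefined transmission rate, and
an empty filtered read set yields an empty, flagged profile, never an
error. Coordinates are 0-based half-open internally and 1-based in
exported site tables and VCF. All randomness flows from user-supplied
integer seeds through R's RNG, so outputs are bit-reproducible across
platforms.

## Known limitations

Single-end reads only; substitution-only variation (no indel calling);
seed-limited mapper sensitivity below ~85% identity; the database-coverage
denominator is a simplified estimator, not a genome-size-aware census; and
transmission is binary — quantitative strain mixtures are out of scope.
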