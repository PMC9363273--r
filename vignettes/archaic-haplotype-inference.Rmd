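---
title: "Testing a candidate haplotype for archaic introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing a candidate haplotype for archaic introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

Some haplotypes segregating in present-day non-African populations entered
the modern human gene pool through admixture with Neandertals roughly
2,000 generations ago. A candidate region — here, the pharmacogenetically
important CYP2C8/CYP2C9 locus on chromosome 10, where the star alleles
CYP2C8\*3 and CYP2C9\*2 co-segregate on a ~300 kb haplotype — can be
tested for archaic origin with three mutually reinforcing lines of
evidence:

1. **An unusually long LD block.** Alleles introduced together on one
   archaic chromosome remain in strong linkage disequilibrium until
   recombination separates them. The block is delineated as every site
   whose $r^2$ with the index variant reaches a cutoff (default 0.8), and
   its span is the min–max envelope of the linked sites.
2. **Archaic allele matching.** If the haplotype is archaic, the
   high-coverage archaic genomes should carry its defining alleles,
   typically homozygously, while an African outgroup population should
   lack them.
3. **Phylogenetic placement.** On a tree of haplotype sequences spanning
   the region, a truly introgressed modern haplotype coalesces with the
   archaic sequences rather than with other modern haplotypes.

The alternative explanation — incomplete lineage sorting (ILS), i.e. an
ancestral polymorphism that persisted through the modern–archaic split —
is addressed by an explicit haplotype-length survival test.

```{r, eval = FALSE}
library(archhap)
sim <- simulate_dataset(sim_config(seed = 1))
index <- which(sim$truth$site_class == "archaic_derived" &
                 colMeans(sim$matrix$geno) > 0)[30]
report <- run_full_analysis(data = sim, index = index,
                            bootstrap_B = 200, seed = 1)
report
```

## Linkage disequilibrium on phased haplotypes

$r^2$ is computed from phased haplotype counts, never from genotype
correlation: with $p_A$, $p_B$ the alt-allele frequencies and $p_{AB}$
the two-locus haplotype frequency, $D = p_{AB} - p_A p_B$ and

$$r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}.$$

Haplotypes missing at either site are excluded pairwise (not listwise).
A site that is monomorphic after exclusion has no defined LD; the package
raises a distinct `archhap_undefined_ld` condition rather than reporting
$r^2 = 0$, because "no information" and "no association" lead to
different decisions during block building (undefined sites are skipped,
zero-LD sites are genuine non-members).

Block membership uses $r^2 \ge$ cutoff. The printed convention in the
source literature is a strict inequality at 0.8; at that cutoff the two
are indistinguishable on real data because exact ties occur with
probability zero, and the cutoff is an exposed parameter in any case.
Block *length* is defined as `span_end - span_start` — the distance
between the outermost linked positions, which is the convention that
reproduces a published span of 313,414 bp for the CYP2C block
(96,851,277 − 96,537,863). LD is computed on all samples pooled;
per-population LD is available by subsetting the matrix.

## The ILS haplotype-length test

Under ILS, a haplotype shared by moderns and archaics has survived
recombination along both lineages since their split. With a local
recombination rate $r$ (cM/Mb, converted as 1 cM/Mb = $10^{-8}$ per bp
per generation; no map function is applied at these scales) and a total
branch length of $G$ generations, the unbroken tract around a focal
variant extends an exponential distance with mean $L_e = 1/(10^{-8} r G)$
bp on each side. The two-sided tract length is therefore gamma with shape
2 and mean $2 L_e$, and the probability of observing a tract of length at
least $\ell$ is the closed-form survival

$$p = \left(1 + \tfrac{\ell}{L_e}\right) e^{-\ell/L_e}.$$

Defaults are $T_{split} = 550{,}000$ years, 29 years/generation, and
`branch_factor = 2` (the haplotype must escape recombination on both the
modern and the archaic branch). These are conventions of the
haplotype-survival literature, not measurements made by this package, and
none of them is printed alongside the published p-value for the CYP2C
block — so the package deliberately does not present any parameter
combination as "the published one". Every report carries the full
parameter set next to the p-value, and `ils_sensitivity()` sweeps the
split time so the reader can see how the conclusion depends on it
(p decreases monotonically with split time). The local rate comes from
linear interpolation of the cumulative genetic map at the block
endpoints; extrapolation beyond the map support is refused rather than
guessed.

A zero-length block (an index variant with no linked partner) has
survival probability 1 by construction and is reported as
"ILS not rejected".

## Archaic matching and the haplotype phylogeny

Archaic genotype calls are matched to the modern site list on exact
(chrom, pos, ref, alt); allele-swapped records are excluded with a
warning rather than flipped, since all supported inputs are on the same
reference strand. Missing archaic calls stay missing and are handled by
pairwise deletion downstream. Carrier verdicts distinguish homozygous
carriers, heterozygous carriers, partial carriers (derived at some
defining sites only, the Denisovan pattern at this locus) and
non-carriers.

Sites for the phylogeny are those that segregate among the modern
haplotypes and are homozygous-alternate in a chosen reference archaic
("variant" being relative to the human reference assembly, matching the
C>T / T>C notation used for the defining alleles). Requiring modern
segregation is a deliberate resolution of an ambiguity in the source
description; the selected-site count is always reported. Heterozygous
calls in *other* archaics are resolved to one allele by a seeded uniform
draw — the draw is recorded, and an all-homozygous input is bit-identical
across seeds.

Each haplotype sequence conceptually spans the whole candidate region;
the selected SNVs are merely its variable columns. The alignment
therefore records the count of implied invariant columns, and distances
are per bp of the region — the same "mutations per site" scale a
published tree figure uses. This matters numerically: on ascertained SNP
columns alone, modern–archaic mismatch fractions approach the divergence
ceiling of any finite-state substitution model, whereas per-region
distances are of order $10^{-4}$–$10^{-3}$, far from saturation.

Distances use the Tamura–Nei (1993) model with base frequencies pooled
from the whole alignment (per-pair frequencies are a documented
alternative; pooled is the default because an 11-taxon SNP alignment
gives unstable per-pair estimates). Saturation (a non-positive logarithm
argument) is an error, not a silent fallback to a simpler model — these
alignments are closely related and saturation indicates a data problem.
The tree is neighbor joining, which is exact on additive matrices;
negative NJ branch lengths are clamped to zero with the clamped deficit
logged. Balanced-minimum-evolution NNI refinement (the default of the
distance program used in the source study) is not implemented: for
alignments of this size NJ and BME almost always agree, and NJ is fully
specifiable and testable against its additivity guarantee. This is a
known limitation.

Bootstrap supports resample the variable columns with replacement (B
replicates, same length), rebuild the tree, and count the replicates
containing each bipartition of the full-data tree. Replicate $r$ uses
the deterministic seed `master + r`, so runs are reproducible and
insensitive to taxon order. A replicate whose resample is all-constant
or saturated contributes a star (no bipartitions) and is counted in
`n_degenerate`. The tree is rooted on the ancestral sequence by placing
the root at the midpoint of the ancestral branch, preserving supports on
the induced bipartitions.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces every input the pipeline reads (phased
VCF, panel, archaic genotype table, ancestral track, genetic map) from a
stem-branch model with a planted introgression history:

* **Deep divergence**: derived mutations are placed independently on the
  archaic and modern stem branches, Poisson with mean
  $\mu \, G_{split} \, L$ per branch (defaults $\mu = 1.25\times10^{-8}$,
  $G_{split} = 19{,}000$ generations ≈ 550 kyr at 29 years/generation,
  $L = 300$ kb — so ~71 diagnostic sites per branch among 400 candidate
  SNVs).
* **Background variation**: the remaining sites segregate with a
  U-shaped (Beta(0.5, 0.5), truncated) frequency spectrum shared by both
  modern populations; the archaic pool's allele at a shared polymorphism
  and the ancestral allele are both frequency-weighted, reflecting that
  derived alleles skew rare.
* **Recombination erosion**: one introgressed tract per dataset, centred
  on `tract_center`, with two independent exponential half-lengths of
  mean $1/(10^{-8} r \, G_{admix})$ (defaults $r = 0.27$ cM/Mb,
  $G_{admix} = 2{,}000$ — mean half-length ≈ 185 kb, so the default
  tract usually fills most of the 300 kb region, emulating a
  strong-signal candidate). Every carrier haplotype (each recipient
  haplotype independently with probability `admix_fraction = 0.1`)
  carries this same tract. Modelling the tract at the dataset level
  rather than eroding it independently per carrier keeps the
  block-detection and ILS tests a closed loop with the gamma survival
  model, and mirrors the empirical situation where carriers of a young
  introgressed haplotype share essentially one segment; per-carrier
  erosion would make the $r^2$ envelope systematically shorter than the
  median tract and is not what the LD span estimates.
* **Archaic individuals** are diploids drawn from the archaic pool with
  a small per-site flip probability (`archaic_het = 0.02`) supplying
  heterozygous calls and within-pool diversity.

Deliberate simplifications: no coalescent demography, no recurrent
mutation (infinite sites at the chosen positions, keeping truth labels
unambiguous), no selection, a uniform recombination map, one admixture
pulse, and site-independent background alleles (no background LD beyond
the planted tract). Passing the recovery tests therefore demonstrates
that the chain of estimators is internally consistent under its own
model assumptions — it does not validate the method against demographic
histories the generator cannot produce, nor against genotyping error,
phasing switch errors, or reference bias in archaic genotypes.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally (VCF
  convention); BED output converts to 0-based half-open.
* Multi-allelic and indel records are dropped on ingest, never split,
  with counts reported; the analysis concerns biallelic SNVs.
* $r^2$ is clamped into [0, 1] against rounding and computed with a
  symmetric grouping so `r_squared(a, b)` is bit-identical to
  `r_squared(b, a)`.
* The genetic-map reader refuses single-row maps (no interval rate is
  definable) and non-monotone inputs, naming the offending line.
* Frequencies of 0 in a population are legitimate results (the
  absent-in-outgroup signature), not errors; only an empty group errs.
* p-values are printed to two significant figures; JSON output keeps
  full precision.
* Problem sizes in the validation suite (400 sites × 400 haplotypes,
  B = 200 bootstrap replicates, $10^5$ Monte-Carlo draws) were chosen so
  the whole chain, including the end-to-end recovery study, re-runs in
  well under a minute while leaving the statistical checks sharp
  (binomial/Monte-Carlo error well below the tested margins).

## Reproducing the published CYP2C analysis

The package ships no cohort data. Given a phased 1000 Genomes phase 3
slice of chr10:96,537,863–96,851,277, the sample panel, genotype calls
for the four high-coverage archaic genomes, the Ensembl ancestral track
and a deCODE-style genetic map, `run_full_analysis()` with
`index = "rs1799853"`, the three defining variants, Vindija as reference
archaic and YRI as outgroup population reproduces the published
frequency table, the $r^2$ values, the 313,414 bp block, the 0.27 cM/Mb
rate, the 278 selected sites and the carrier-with-Neandertals topology;
the acceptance test encodes exactly this run and activates when the
files are placed under `real_data/`.
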