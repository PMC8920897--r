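---
title: "Gamete binning for tetraploid haplotype phasing: models and methods"
author: "polygamete"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamete binning for tetraploid haplotype phasing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygamete)
```

## The problem

A contig-level assembly of an autotetraploid genome collapses wherever two
or more of the four haplotypes are (nearly) identical — typically inside
identical-by-descent (IBD) blocks left by recent inbreeding. Gamete
binning resolves the four haplotypes genetically: a tetraploid plant sheds
*diploid* pollen, each nucleus carrying two of the four somatic
haplotypes, paired at random across gametes. Sequencing several hundred
pollen nuclei at very low coverage (~0.18x) turns each ~50-kb region of
the assembly into a genetic marker: a pollen genome has reads on a marker
exactly when one of its two haplotypes carries the region. Across the
panel this yields a presence/absence pattern (PAP) per marker, and
markers on the same haplotype share nearly identical PAPs, while
homologous haplotypes (which can never co-occur more often than random
pairing allows) are anticorrelated. Correlation clustering of PAPs
therefore groups contigs into one cluster per haplotype per chromosome;
long reads are then routed to per-haplotype read sets via their best
marker overlap and reassembled independently.

`polygamete` implements this method end to end — depth-based copy
classing, PAP genotyping, correlation clustering, collapsed-contig
multi-assignment, read binning, and trio-style evaluation — together with
a fully labeled simulator so every stage is testable without external
data.

## Depth typing

Somatic sequencing depth identifies how many haplotypes a window
collapses. With a per-haplotype genome-wide depth $H$ (x coverage), the
upper bound of copy class $i$ is

$$b_i = \mathrm{round}\left(H \times (i + \tfrac12)\right), \qquad
  i = 1, \ldots, 4,$$

with round-half-up; class 1 starts at 0 and depths above $b_4$ are
classed `REP` (repetitive). At $H = 113$ the bounds are 170, 283, 396 and
509. Windows (10 kb by default) are classified individually and maximal
same-class runs are merged, then cut into chunks of the 50-kb target
marker size. The chunking rule is a design choice the depth-typing
contract leaves open: a trailing remainder shorter than half a marker is
folded into the previous chunk, otherwise it stands alone. This bounds
marker length to [25 kb, 75 kb) inside long runs, keeping the expected
per-gamete read count of each marker (~60 reads at 0.18x and 150-bp
reads) comparable across markers; runs shorter than 50 kb become a single
marker of the run length. Terminal windows shorter than 10 kb keep their
own depth and follow the same classification rule.

## PAP genotyping

For gamete $g$ with $N$ total aligned reads, the raw count $r$ at a
marker of length $W$ is normalized to
$n_r = r \times (10^4 / W) \times (10^6 / N)$. The gamete's scale factor
$m_r$ is the mean $n_r$ over its *informative* markers — those with more
than $7 \times N/10^6$ reads — so $n_r / m_r \approx$ the number of
copies the gamete carries. The coverage genotype is
$\mathrm{round}(n_r/m_r)$, clipped into the class domain: $\{0,1\}$
(haplotig), $\{0,1,2\}$ (diplotig), $\{1,2\}$ (triplotig), $\{2\}$
(tetraplotig). Rounding is half-up and clipping happens after rounding;
the domains force this clip because a noisy haplotig marker can round to
2. Gametes with fewer than 50 informative markers (configurable) are
dropped panel-wide; cells with no alignment record count as $r = 0$.

PAP correlation is the plain Pearson correlation over the gamete panel,
evaluated by its explicit sum formula. Zero-variance PAPs — notably every
tetraplotig marker, whose domain is the single value 2 — have no defined
correlation and are excluded from every threshold test rather than being
assigned 0.

## Linkage clustering

Haplotigs of at least 100 kb are graph vertices. Two vertices are joined
when the *highest* correlation among the (up to four) pairs of their end
markers exceeds $\theta_{link} = 0.55$; connected components are the
initial groups. A component containing an end-marker pair below
$\theta_{hom} = -0.25$ mixes homologous haplotypes (e.g. through a
chimeric contig); such components are split by removing their
minimum-weight edge until no conflict remains. Group identifiers derive
from each group's alphabetically first contig, which — together with
position-ordered marker subsampling — makes the whole procedure invariant
to input order. Haplotigs below 100 kb are then rescued into the group
holding the marker most correlated with any of their markers (ties to the
lowest group id, flagged). Homologous groups are detected by the lowest
pairwise marker correlation between two groups falling below
$\theta_{hom}$; chromosomes are the transitive closure of this relation,
four groups each when data are complete. The homology test uses all
markers of a group up to a configurable cap (50 by default, subsampled
evenly along the group) — the contract's wording leaves open whether all
markers or only end markers are meant, and using all markers with a cap
is the more sensitive choice at no practical cost.

### Collapsed contigs and the AND rule

A diplotig's PAP $Z$ is approximately $X + Y$ for the PAPs $X, Y$ of its
two constituent haplotypes, so the bitwise AND of the binarized patterns
satisfies $Z \& X \approx X$. Each group is scored by
$\max_X \mathrm{cor}(\mathrm{bin}(Z) \& \mathrm{bin}(X), \mathrm{bin}(X))$
over its representative markers, and a class-$k$ contig joins the $k$
top-scoring groups. Two numerical points matter here:

* The AND score of a true group is exactly 1 up to floating-point
  jitter; scores are rounded to 9 decimals before ranking so that true
  ties are treated as ties.
* For every triplotig (and any diplotig whose region is carried by all
  gametes), the binarized $Z$ is saturated at 1 — a diploid gamete always
  carries at least one of three haplotypes — and the AND score
  degenerates to 1 for *every* group. Tied AND scores are therefore
  re-ranked by the plain correlation $\mathrm{cor}(Z, X)$, which for a
  triplotig is positive for the three true groups ($1/3$ in expectation
  under random pairing) and negative for the fourth homolog. Remaining
  ties break to the lowest group id and are flagged.

Contigs consisting solely of tetraplotig markers carry no linkage
information and stay unassigned, mirroring the method's stated
limitation; a class-4 contig with at least one groupable non-class-4
marker is assigned to all four groups of that marker's chromosome.

## Read binning

A long read's overlap with each marker is accumulated over its alignment
records (gapped records contribute in proportion to their aligned bp —
the contract does not fix whether the 500-bp floor applies per record or
per marker, and accumulation matches the intent of total aligned length
per marker). Markers with under 500 bp of the read are discarded; the
largest overlap wins, exact ties going to the marker earlier in
(contig, start) order, flagged. Haplotig markers route the read to their
group; multi-assigned markers choose uniformly at random among their
groups. The random choice is derived from a polynomial hash of the read
id XOR the run seed, so each read's assignment is reproducible in
isolation and independent of input order, and disabling randomization
diverts those reads to an `AMBIGUOUS` bucket instead.

## Phasing evaluation

Because every haplotype descends from exactly one parent, phasing quality
is measured trio-style. In sequence mode, canonical (strand-collapsed)
$k$-mers ($k = 21$) unique to one parent are intersected with each
haplotype assembly; when parents are given as reads, their $k$-mers are
first filtered to a multiplicity window (defaults 6–12 and 5–11 for the
two parents, reflecting slightly different parental sequencing depths) to
remove error and repeat $k$-mers, while truth-assembly input skips the
filter. Per unit, the correctly phased count is
$\max(\mathrm{count}_A, \mathrm{count}_B)$, and overall precision is the
ratio of summed correct counts to summed investigated counts; units with
no diagnostic $k$-mers are excluded and reported. Counts mode applies the
same arithmetic to truth-labeled markers per linkage group, which lets
the full-scale counts-only simulation report precision without
sequences; both modes agree within 1% on the same simulation (tested).

## The simulator

The generator emulates the statistical structure the method relies on,
with defaults fixed at the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `nChromosomes` x `chromLengthBp` | 12 x 1 Mb | desk-scale genome |
| `somaticDepthPerHaplotype` (H) | 113x | somatic depth per haplotype |
| `nGametes` | 717 | pollen genomes |
| `gameteCoverage` | 0.18x | per carried copy, per gamete |
| `snpRateDivergent` | 1/60 per bp | divergence outside IBD |
| `ibdFraction` | 0.5 | genome fraction inside IBD blocks |
| `ibdBlockMeanBp` | 100 kb | block size scaled to the 1-Mb chromosome |
| `ibdMultiplicityWeights` | 0.8 / 0.2 / 0 | blocks shared by 2 / 3 / 4 haplotypes |
| `crossoversPerBivalentMean` | 0.3 | see below |
| `windowBp`, `markerBp` | 10 kb, 50 kb | depth windows, coverage markers |
| `readLengthBp` | 150 | gamete short reads |

IBD blocks are placed with exponential lengths and gaps (uniformly along
the chromosome; a flag biases them toward the middle to mimic
pericentromeric enrichment), snapped to the 10-kb window grid so somatic
depth windows are copy-number pure. Four-way sharing is off by default:
it is rare in a two-parent pedigree, and a block shared by all four
haplotypes is exactly the case the method cannot link to a chromosome.
The contig tiling is literal: one collapsed contig per maximal IBD block,
one haplotig per maximal non-IBD segment of each haplotype, so with
`ibdFraction = 0` the assembly is exactly `4 * nChromosomes` haplotigs.

Meiosis uses pure bivalent pairing — the three pairings of four
haplotypes into two bivalents are equiprobable, matching random pairing —
with one recombinant chromatid per bivalent carrying
Poisson-distributed crossovers at uniform positions, and optional double
reduction (both chromatids from one bivalent; default off, as it is a
rare outcome). Somatic window depth is Normal($Hk$, $\sqrt{Hk}$)
truncated at 0 for $k$ collapsed haplotypes — Poisson-like noise that
reproduces well-separated depth peaks. Gamete read counts are
Poisson with mean $cov/RL \times W \times c$, where $c$ is the
(fractional) number of the gamete's chromatids carrying a contig
haplotype over the marker.

### The crossover default

The crossover rate per bivalent is not something the phasing method
prescribes; it is a property of the organism, roughly one obligate
chiasma per chromosome regardless of physical size. Carrying "1 per
bivalent" onto a 1-Mb desk-scale chromosome, however, would make
neighboring 50-kb markers ~5 cM apart — two orders of magnitude more
recombinant per marker gap than real data, i.e. outside the regime
("recombination is rare between closely linked markers") the method is
built for. PAP correlation between same-haplotype markers at distance
$d$ decays as $\exp(-2\lambda d/L)$ for $\lambda$ crossovers per
chromatid on a chromosome of length $L$, so the default
$\lambda = 0.3$ keeps markers across a typical IBD gap (~100–200 kb)
correlated well above $\theta_{link}$ while leaving thousands of
crossovers visible in a default panel. The parameter remains exposed for
studying the breakdown regime.

### What the simulator does not model

Read-level errors and mapping artifacts (counts are exact Poisson draws),
organellar contamination, chimeric input contigs, unequal chromosome
lengths, segregation distortion, assembly-induced contig fragmentation
beyond the IBD tiling, and Hi-C structure. Passing tests therefore
demonstrate the correctness and statistical behavior of the method's
logic under its own model assumptions — not robustness to every artifact
of real pollen sequencing data, where marker filtering and gamete QC
carry more weight.

## Problem sizes and numerical choices

The test suite exercises the full study-condition scale (12 x 1 Mb,
700 gametes) for the panel-level checks and smaller genomes (1–3
chromosomes of 0.3–0.5 Mb, 100–400 gametes) for unit and property tests;
`scripts/acceptance.R` re-runs the full scale over ten seeded replicates
plus a 100,000-read binning experiment. These sizes keep a complete run
in minutes on one core while leaving every statistical margin (depth
misclassification below 1%, correlation sampling noise ~0.03) far from
the decision thresholds. All randomness flows from a single master seed
through fixed per-stage derivations, so every artifact is bit-reproducible.

Other numerical conventions: all rounding is half-up (169.5 to 170);
genomic coordinates are 0-based half-open in every TSV and 1-based closed
inside `GRanges`; undefined correlations propagate as `NA` and never pass
a threshold; every argmax/top-k tie has a deterministic, flagged
resolution.

## Known limitations

* Groups are unordered within chromosomes and contigs unordered within
  groups; scaffolding is out of scope.
* Tetraplotig-only contigs are unassignable by design.
* The homolog test assumes enough gametes that the $-1/3$ expected
  anticorrelation of homologs separates from sampling noise; below ~100
  gametes chromosome detection degrades before group detection does.
* Counts-mode evaluation relies on simulator truth labels and is only
  available for simulated data; real data use the k-mer path.
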