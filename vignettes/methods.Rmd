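---
title: "Permutation tests for genomic and spatial concentration of functional gene groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation tests for genomic and spatial concentration of functional gene groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcoloc)
```

## The question and the model

Genes that act together -- the two partners of a protein--protein
interaction (PPI), the subunits of a complex, the members of a pathway --
are not placed at random in eukaryotic genomes. `funcoloc` quantifies that
non-randomness at three complementary levels:

1. **Inter-chromosomal dispersal.** For a group $i$, count the number of
   distinct chromosomes carrying at least one member. The test statistic is
   the mean of this count over all groups of one type; concentration means
   the observed mean is *smaller* than under the null. A finer view is the
   histogram $f_c$ = number of groups occupying exactly $c$ chromosomes,
   and its cumulative "at most $c$ chromosomes" curve.
2. **Intra-chromosomal distance.** For each group, $d_i$ is the mean
   base-pair distance between member pairs on the same chromosome
   (midpoint to midpoint). The statistic is the unweighted mean of $d_i$
   over groups.
3. **Spatial (3D) proximity.** From a binned contact map (e.g. 1 Mb Hi-C
   bins), the distance between two segments is $1 - r$, where $r$ is the
   Pearson correlation of the segments' contact profiles over the columns
   where both are defined, excluding the two segments' own columns. Values
   lie in $[0, 2]$; small values mean the segments see the rest of the
   genome alike, i.e. are close in the nucleus. Group statistics are the
   mean over all member pairs, the mean over inter-chromosomal pairs only,
   and the pooled individual inter-chromosomal pair distances.

## The permutation null

All significance is empirical. A null genome is produced by randomly
reassigning gene identifiers to the **fixed set of loci occupied in the
real genome**, so the locus multiset and the per-chromosome gene counts are
invariants, and group composition never changes. Two schemes:

* `global` -- labels are shuffled genome-wide. Used for chromosome-level
  dispersal and for the all-pairs spatial test.
* `within_chromosome` -- labels are shuffled independently inside each
  chromosome, so every gene keeps its chromosome. Used whenever
  chromosome-level concentration must be controlled for: the linear
  distance tests and the inter-chromosomal spatial tests. Under this
  scheme each group's number of intra- and inter-chromosomal pairs is
  itself invariant, which is exactly the control needed to separate 3D
  signal from 1D signal.

With $n$ permutation replicates and $k$ replicates at least as extreme as
the observed statistic $v_0$ (ties counting as extreme), the p-value is
$(k+1)/(n+1)$, with floor $1/(n+1)$. The +1 correction counts the observed
genome among the permutations and makes the test valid at every $n$; for
discrete statistics ties make it conservative. Extremeness direction is
explicit per statistic: `le` for means of distances and chromosome counts,
`ge` for enrichment counts.

Replicate $r$ of a test seeds its own RNG stream derived deterministically
from the base seed and $r$, so results are bit-reproducible and
independent of evaluation order.

## The distribution tail test

Moment statistics can miss signal that lives only in the closest pairs.
The tail test bins the real values into $k$ equal-occupancy bins (default
$k = 20$, i.e. 5% of values per bin) using the values' own empirical
quantiles, then bins every replicate set *by the same thresholds*. For each
prefix $j$, the cumulative real count $F_j = f_1 + \dots + f_j$ is compared
to the replicate $F_j$ distribution by empirical p-value ($p_j$, direction
`ge`), and the minimal $j$ with $j \cdot p_j \le \alpha$ is reported with
its Bonferroni-by-$j$ corrected p-value. The full vector $p_j$ is retained
so significance over ranges of bins can be reported. An optional
lexicographic refinement declares a replicate extreme when its whole prefix
vector $(F_1, \dots, F_k)$ is lexicographically $\ge$ the real one, which
resolves heavy ties on the first bins.

Numerical conventions, chosen once:

* Thresholds are inverse-ECDF quantiles (R `type = 1`): $t_j$ is the
  $\lceil jn/k \rceil$-th order statistic, so the real cumulative curve is
  the straight line $F_j = \lceil jn/k \rceil$ by construction. $t_0$ is
  the domain minimum (0 for distances); bins are $(t_{j-1}, t_j]$ with the
  first bin closed on the left.
* Exactly tied thresholds are merged into fewer, wider bins with a
  warning, rather than failing. Ties are structural for segment-level
  spatial distances -- many gene pairs share one segment pair and inherit
  the identical distance -- so a hard error would make the individual-pair
  test unusable exactly where it is most interesting. Merging preserves
  equal occupancy as closely as ties permit.
* Replicate values above $t_k$ fall into an overflow bin counted in no
  prefix. This can only deflate replicate prefix counts, which is the
  conservative direction for an enrichment test.
* For chromosome counts the bins are the integers $1..C$ ($t_j = j$), so
  $F_c$ is directly the "groups on at most $c$ chromosomes" curve.
* The minimal-$j$ search uses the corrected value ($j \cdot p_j \le
  \alpha$). Note that $j^* p_{j^*}$ need not exceed $p_1$: a large,
  non-significant first bin does not bound the corrected value of a later
  significant prefix.

## Preprocessing

* **Unique positions.** Gene identifiers appearing at more than one
  position are dropped entirely on load.
* **Tandem duplicates.** Adjacent genes of one gene family (family
  assignments are consumed as input, e.g. from sequence clustering) would
  fake linear clustering by ancestry alone. Maximal runs of consecutive
  same-family genes are merged into one gene spanning the run, and member
  identifiers alias to the merged gene for group lookups. The operation is
  idempotent.
* **Distance anchor.** Distances are midpoint to midpoint. Midpoints stay
  well defined for merged interval genes; gap-to-gap or start-to-start
  anchors do not.
* **Gene-to-segment assignment.** A gene belongs to the contact-map
  segment containing its midpoint (half-open intervals), hence exactly one
  segment even when it spans a boundary.
* **Missing contact entries** are excluded pairwise, never imputed as
  zero; a correlation is only reported when at least `min_overlap`
  (default 10) shared columns remain and both profiles vary on them.
* Groups are restricted to the layout after alias resolution; groups
  reduced below 2 members are dropped. Groups with no eligible pair under
  a metric/filter are omitted from that statistic rather than scored with
  a sentinel value, so omission cannot masquerade as signal. For spatial
  statistics the omission set can differ between real and permuted
  genomes; for the linear intra-chromosomal statistic under the
  within-chromosome scheme it cannot.

## The synthetic-data module

Every input has a generator with known ground truth:

* `generate_genome()` draws exponential gene lengths (default mean 10 kb,
  floor 200 bp) and intergenic gaps (default mean 40 kb) per chromosome;
  chromosome lengths emerge from the draws, mimicking variable gene
  density. Defaults give two chromosomes of 100 genes, about 5 Mb each.
* `generate_groups()` samples group sizes as $2 + \mathrm{Poisson}(2)$ and
  members under four modes: `null` (uniform without replacement);
  `chrom_concentrated` (each member drawn from the group's anchor
  chromosome with probability $\rho$); `linear_clustered` (members within
  a window of 5% of the chromosome length around an anchor gene with
  probability $\rho$, so pairwise distances within the window are bounded
  by it; the draw falls back to uniform when the window is exhausted);
  and `spatial_colocalized` (size-2 groups placed into a planted
  inter-chromosomal segment pair with probability $\rho$). The planted
  strength parameters are mixture probabilities rather than base-pair
  effect sizes, so power is interpretable across configurations.
* `generate_contact_map()` builds intra-chromosomal entries decaying as
  $(1+d)^{-\alpha}$ in segment separation $d$ (default $\alpha = 1$), a
  weak constant inter-chromosomal background (default 0.05), symmetric
  half-normal noise (default scale 0.1), and planted inter-chromosomal
  segment pairs whose profiles are blended with weight $\sigma$: at
  $\sigma = 1$ and zero noise a planted pair has distance exactly 0, the
  map minimum. The default segment size for synthetic data is 100 kb so
  that a 5 Mb chromosome spans ~50 segments.

What the generators do *not* emulate: real karyotypes, compartment/TAD
structure, read-level Hi-C noise, normalization artifacts, or biased gene
identifier mapping. Passing tests on synthetic data therefore demonstrate
the statistical machinery -- calibration, power against the planted effect
types, exactness of the permutation procedure -- not biological claims
about any real genome.

## Problem sizes used in the test suite

The suite verifies the implementation at sizes a desk machine handles
comfortably: exact-enumeration checks on a 7-gene, 3-chromosome genome
(5040 global permutations); calibration on 500 null genomes of 2 x 100
genes with 50 groups and 499 permutations each; power on 200 genomes per
planted scenario with 199 permutations each. Calibration uses the exact
binomial 99% band around the nominal level. For continuous statistics the
attained level is exact by construction; the two integer-valued statistics
(mean chromosome count, single-chromosome enrichment) are conservative
under heavy ties, which is visible as rejection fractions in the lower
half of the band.

## Known limitations

* Spatial distances depend on the whole contact map through profile
  correlations; removing or adding segments changes all distances
  slightly.
* The within-chromosome scheme conditions on the real chromosome
  assignment; it cannot detect concentration that manifests only as
  chromosome choice (that is the global scheme's job).
* Empirical p-values are floored at $1/(n+1)$; claims below that
  resolution require more permutations.
* The tail test's bins come from the real values; with fewer values than
  bins the test refuses to run rather than extrapolate.
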