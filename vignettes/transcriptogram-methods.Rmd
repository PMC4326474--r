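---
title: "Transcriptogram profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptogram profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xgram)
library(tibble)
```

## The problem

Genome-wide expression measurements are noisy, and single-gene tests often
miss coordinated shifts spread over a functional module. Transcriptogram
profiling attacks this by first building a *seriated gene list*: a
permutation of all genes with at least one protein-protein association, laid
out so that the probability of association decays with distance along the
list. Averaging expression over a sliding window of the list then pools
genes that tend to work together, damping uncorrelated noise while
preserving module-level signal. Everything downstream -- differential
expression, noise summaries, between-laboratory concordance -- operates on
these windowed profiles.

## Seriation cost and annealing

For an ordering, write the association matrix in list coordinates:
$A_{ij} = 1$ when the genes at positions $i$ and $j$ are associated. The
cost being minimized is

$$F \;=\; \sum_{i<j} A_{ij}\,|i-j|^{\alpha} \;+\; \beta \sum_{i,j}
\big(|A_{i,j}-A_{i+1,j}| + |A_{i,j}-A_{i,j+1}|\big),$$

with out-of-range comparisons omitted. The first term pulls associated
genes together, with $\alpha$ setting how steeply long-range placements are
punished ($\alpha = 1$ is the standard working point; around $\alpha = 10$
long-range associations are effectively forbidden and the occupation
fraction collapses at large distances). The second term is an adjacent-row /
adjacent-column smoothness penalty: it falls when genes sharing partners are
neighbors, sharpening block structure. The literature leaves the exact
algebraic weight of this second term open; we fix it as the L1 difference
between adjacent rows and columns and expose its weight $\beta$ (default 1)
so alternative published forms can be matched. By symmetry of $A$ the row
and column sums are equal, which is what the implementation exploits.

Minimization is Metropolis Monte Carlo over permutations: a uniformly
random pair of list positions is proposed for a swap; the move is accepted
when $\Delta F \le 0$ and with probability $e^{-\Delta F/T}$ otherwise. The
schedule is deliberately quench-like: $T_0$ is $10^{-4}$ of the initial
cost and $T$ halves every 100 Monte Carlo steps, one MCS being $N$
attempted swaps (a convention the source description leaves unstated; $N$
swaps per MCS is the standard choice). "The number of changes has
stabilized" is quantified as: fewer than 0.01% of proposals accepted over
50 consecutive MCS. The best-seen ordering is returned rather than the
final state, since a finite chain can end above its own minimum. A single
seeded generator drives the initial shuffle, the proposals and the
acceptance draws, so a seed fully determines the output.

$\Delta F$ is computed incrementally. A swap of positions $p, q$ only
perturbs the distance terms of edges incident to the two swapped nodes and
the smoothness terms of rows $\{p-1, p, q-1, q\}$; each row difference is a
symmetric-difference count between two neighbor-position sets, so the work
per proposal scales with the local degrees, not with $N^2$. The equality of
the incremental and fully recomputed $\Delta F$ on random instances is the
central correctness property of the engine and is tested to numerical
precision.

## Ordering diagnostics

Two quantities summarize how good an ordering is. The occupation fraction
$\gamma(d)$ is the fraction of a gene's association partners found at list
distance $d$, averaged over genes; it sums to one over $d$, and a seriation
is good exactly when its mass concentrates at small $d$. The window
modularity $M_i(r)$ is the ratio of associations entirely inside the window
of radius $r$ centred at $i$ to associations touching that window; peaks
mark functional clusters. Windows touched by no association are reported as
missing -- zero has the distinct meaning "every incident edge leaves the
window". Windows truncate at the list ends rather than wrapping: the
ordering has a biological start and end, and the coverage-weighted window
average renormalizes truncated windows naturally.

## The windowed profile and the signal model

A measured sample is modeled as three additive terms on the log2 scale:
a gene-and-condition signal $s$, a biological deviation (per gene and
biological replicate, shared by that replicate's technical replicates,
SD $\sigma_b$), and technical noise (independent per measurement, SD
$\sigma_\xi$). The transcriptogram of a sample assigns to position $i$ the
coverage-weighted average

$$T_i \;=\; \frac{\sum_{j \in \mathrm{win}(i)} \theta_j E_j}
{\sum_{j \in \mathrm{win}(i)} \theta_j},$$

where $\theta_j$ flags positions whose gene the platform actually measures.
At $r = 0$ the profile *is* the transcriptome. Smoothing happens per sample
and class averages are taken afterwards; the two orders commute under full
coverage, but with $\theta$ gaps the per-sample window mean is the faithful
reading. A window with no covered position is missing, and downstream
statistics skip missing positions and report the effective count. Genes
measured but absent from the ordering are never silently dropped; they are
returned as an "unmapped" attribute.

Relative profiles divide a biological replicate's technical-replicate mean
by the reference class's mean profile, position-wise. These are ratios of
log2-scale values -- not differences -- which mirrors how such profiles are
plotted in the field; the choice of position-wise (rather than scalar)
division is ours, as the verbal description admits both readings. Reference
positions at or below zero are flagged missing rather than divided through.

Gene sets are projected by smoothing their 0/1 membership indicator with
the same box-car at full coverage; profile peaks locate enrichment
intervals along the list.

## Variance components

With $n_a$ technical replicates inside $n_b$ biological replicates,
$\sigma^2_\xi$ is estimated per gene by pooling within-biological-replicate
variances, and $\sigma^2_b$ from the spread of biological-replicate means
with the technical contribution $\sigma^2_\xi/n_a$ subtracted (floored at
zero). Whether windowing helps depends on the mean off-diagonal covariance
$\bar\kappa$ of biological variation across gene pairs in a window: when
genes vary independently ($\bar\kappa = 0$) the windowed variance falls as
$(\sigma^2_\xi + \sigma^2_b)/w$ with $w = 2r+1$; when a whole window moves
together, the biological term does not shrink at all. $\bar\kappa$ is
computed per window from the identity that the variance of a window sum
equals the sum of all pairwise covariances, which reduces the computation
to two sliding sums.

## Statistics

Per-position comparisons use Welch's two-tailed $t$ with Satterthwaite
degrees of freedom, the replicate unit being the sample transcriptogram
(technical and biological replicates pooled as provided; collapsing to
biological means first is a caller decision -- feed `welch_compare`
bio-rep mean profiles to get it). When both groups have zero variance the
conventions are $P = 1$ for equal means and $P = 0$ otherwise. The
Bonferroni family defaults to the number of non-missing tested positions;
the fixed-family convention (all list positions, e.g. 9684 for the full
human ordering, giving a per-test threshold of order $10^{-6}$ at family
level 0.01) is available through `family_size`. Both BH and Storey
q-values are always computed; Storey's $\pi_0$ uses the standard
$\lambda$-grid 0.05..0.95 with a cubic smoother evaluated at the largest
$\lambda$, written in-package. For fewer than 100 P-values the smoother is
unreliable and $\pi_0$ is fixed at 1 (reducing to BH).

Contrast is the absolute deviation of the class mean profile from its
global average; noise is the per-position SD across replicate profiles.
The displayed aggregation formulas in the source material are garbled, so
the ratios are defined as position-averaged contrast (resp. signal) over
position-averaged noise $\Omega$, matching the verbal description ("the
average of the difference ... in units of transcriptogram standard
deviation"); a per-position-ratio variant sits behind `per_position =
TRUE`. On iid noise, $\Omega$ falls as $w^{-1/2}$; the contrast-to-noise
ratio must fall to zero as the window approaches the whole list, since all
profiles then approach the global average.

Concordance between two laboratories' fold-change vectors uses Lin's
coefficient with population ($1/n$) moments, the classical convention; a
sample-moment variant is available. Fold changes on the log2 scale are
differences of condition mean transcriptograms, so "relative expression
near 1" corresponds to a log fold change near 0.

## The synthetic generator, and what it does not emulate

The planted-partition generator draws within-cluster edges at `p_in` and
between-cluster edges at `p_out`; isolated nodes are re-wired to one
within-cluster partner because seriation requires degree at least one. The
expression generator implements the three-component model exactly, with a
within-cluster biological correlation knob realized as
$\sqrt{\rho}\,(\text{shared draw}) + \sqrt{1-\rho}\,(\text{own draw})$,
preserving the marginal SD. Default condition differences shift
$\lceil m/5 \rceil$ randomly chosen clusters by a configurable amount,
mimicking localized differential peaks. Default noise scales
($\sigma_b = 0.3$, $\sigma_\xi = 0.5$ log2 units, $n_b = 5$, $n_a = 4$) are
typical of replicated microarray designs.

The generator does *not* emulate probe effects, intensity-dependent
variance, saturation, batch structure, or count noise; passing tests
demonstrate correctness of the machinery and the qualitative window
properties (noise shrinkage, power gain, reproducibility gain), not
robustness to those artifacts on real platforms.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
planted networks of 300 nodes (10 clusters of 30) for ordering recovery,
2,000-position expression sets for the statistical properties, radii up to
80, and 100 random-ordering baselines. Full-scale orderings (~10,000 genes
from a curated association network at combined score at or above 800) use
exactly the same code path through the command line interface but take
hours of annealing; nothing in the package depends on them.

Notable numerical choices: distance powers $|i-j|^\alpha$ are precomputed
in a lookup table; the running cost is re-synchronized by a full
recomputation at every temperature halving to stop incremental drift;
box-car averages use cumulative sums (one pass per sample); window
modularity uses difference-array accumulation over edge intervals, with
the touch region handled as the union of the two endpoint neighborhoods
(two disjoint intervals when endpoints are more than $2r$ apart).

## Known limitations

One planted-partition regime worth knowing about: with `p_in = 0.5`,
`p_out = 0.005` on 10 clusters of 30, about 8.5% of edges are
between-cluster, so even a perfect contiguous ordering leaves short-range
occupation mass near 0.93 -- an intrinsic ceiling of the generator's
parameters, not an annealing failure (the annealer in fact beats the
contiguous arrangement slightly by placing connected clusters adjacently).
Storey's $\pi_0$ is unstable below ~100 P-values and degrades to BH there.
The per-gene Welch test treats technical replicates as independent
samples; with correlated replicates it is mildly anti-conservative, which
is the standard caveat for pooling replicate types.
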