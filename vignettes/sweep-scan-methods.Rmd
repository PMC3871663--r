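---
title: "Detecting domestication sweeps with simulation-null diversity-ratio scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication sweeps with simulation-null diversity-ratio scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepqtl)
```

## The problem

Crop domestication fixes beneficial alleles by strong artificial selection.
Around each fixed allele, hitchhiking erases neutral variation over a scale
set by recombination, leaving *low-diversity valleys* in the cultivated
genome.  The difficulty is that domestication also imposes a genome-wide
bottleneck, which depresses diversity everywhere.  A credible sweep scan
must therefore ask: *is the diversity in this window lower than the
bottleneck alone can explain?*

`sweepqtl` implements this programme for panels of near-homozygous (inbred)
accessions of a crop and its wild progenitor — the motivating system being
Asian rice, with a wild *O. rufipogon* sample and cultivated *indica* and
*japonica* (temperate/tropical) samples.  The package covers the whole
chain: simulating realistic test data, diversity estimation, bottleneck
inference, the simulation-null window scan, differentiation scans between
cultivated subgroups, co-localization with QTL intervals, and a screen for
functionally interpretable variants fixed in the cultivated group.

## The demographic model

The null model is a two-population split with bottleneck.  Looking backward
in time, cultivated lineages live in a population of constant diploid size
$N_1$ from the present back to the founding time $T_1$ generations ago,
then merge into the wild population of constant size $N_0$.  Partial
selfing at rate $s$ is absorbed by the standard equilibrium scaling with
inbreeding coefficient $F = s/(2-s)$: effective size $N/(1+F)$ and
effective recombination $r(1-F)$.  After this scaling, lineages are treated
as haploid — appropriate because the accessions are inbred to
near-homozygosity, so one haplotype is observed per accession.

Simulation uses an exact ancestral-recombination-graph (ARG) coalescent
with infinite-sites mutation on continuous coordinates (rounded to integer
bp at export; collisions re-drawn to the nearest free base).  A completed
sweep is modelled through its diversity footprint only (the *star
approximation*): at the fixation time, each cultivated lineage keeps an
interval around the sweep position `pos` extending `Exp(lambda)` bp
independently to each side, and everything inside the kept intervals
coalesces instantaneously into a single lineage.  Marginally, a site at
distance $d$ escapes the sweep with probability $1 - e^{-d/\lambda}$.  No
selection coefficient is modelled; $\lambda$ is the user-facing knob for
sweep width.

### Default parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N0` | 180,000 | wild diploid effective size; maximum-likelihood value reported for *O. rufipogon* |
| `N1` | 17,000 | cultivated size since founding; chosen so the expected genome-wide cultivated/wild diversity ratio $\approx e^{-T_1/(2 N_1^{(e)})}$ matches the observed ~60% |
| `T1` | 9,000 generations | founding of the cultivated lineage; rice is annual and domestication dates to roughly nine millennia ago |
| `mu` | 6.5e-9 /bp/gen | order-of-magnitude plant nuclear mutation rate |
| `rec` | 4e-8 /bp/gen | order-of-magnitude rice recombination rate |
| `s_wild`, `s_cult` | 0.95 | cultivated rice is a ~95% selfer; wild rice selfing spans 40–95% and we take the upper end, treating both taxa as predominant selfers |

All are explicit arguments of `demographic_model()`; none is inferred from
the package's own outputs.

## Diversity estimators

Per site, diversity is the mean pairwise difference among non-missing
calls, $\hat\pi_i = \binom{n_i}{2}^{-1} \sum_{\text{pairs}} d_{jk}$, and
windows aggregate $\pi = \sum_i \hat\pi_i / C$ over the callable-site count
$C$.  Watterson's estimator uses per-site called sample sizes:
$\hat\theta_W = \sum_{i \in \text{seg}} a_{n_i-1}^{-1} / C$ with
$a_k = \sum_{j=1}^k 1/j$, so missing data are handled exactly rather than
by dropping sites.  Windows are 500 kb sliding by 20 kb by default (the
scan is insensitive to window sizes in the 100–500 kb range on data of this
LD scale); terminal truncated windows are kept and flagged, and excluded
from top-K ranking by default.  When a chromosome is shorter than one
window, a single truncated whole-chromosome window is emitted.

The callable denominator is, by default, the overlap of the window with
gene regions — the panel's SNPs are restricted to genes to avoid paralogy
artifacts from repetitive DNA — with plain window width as the fallback
when no gene mask is supplied.  Because the sweep statistic is a *ratio* of
two groups' diversities over the same windows, the choice of denominator
cancels there.

Hudson's $F_{ST}$ is computed as a ratio of sums over sites,
$1 - \overline{H}_w / \overline{H}_b$, with the within term the average of
the two populations' mean pairwise differences.  Ratio-of-sums is used for
stability in windows with few SNPs.  Negative window values (a
finite-sample phenomenon when the groups are effectively panmictic) are
retained in tracks but never rank as peaks.  Note a finite-sample subtlety:
with *identical sample allele frequencies* in both groups the estimator is
slightly negative, not zero, because the within term carries the
$n/(n-1)$ pairwise correction; it is zero only in the infinite-sample
limit.

Per-gene synonymous diversity uses the first 1,000 synonymous sites of each
gene in transcript order from the translation start, normalising gene
length differences; genes with fewer are excluded.  "Synonymous sites" are
operationalised as fourfold-degenerate third codon positions of the
reference CDS.

## Bottleneck inference

The bottleneck is estimated by simulation-based composite likelihood from
per-gene summaries $(S_{\text{wild}}, S_{\text{cult}})$ — segregating-site
counts over the fixed-length synonymous loci.  $S$ on a fixed-length locus
has a clean discrete distribution and is insensitive to how missing calls
perturb per-site depths.

1. **Wild size.** For each $N_0$ on a grid, $R$ single-population loci are
   simulated at $\theta = 4 N_0 \mu$ per site; the empirical PMF of $S$
   (add-one smoothed over the observed support) scores the observed wild
   counts; the composite log-likelihood is summed over loci.
2. **Bottleneck surface.** With $N_0$ fixed at its MLE, each $(N_1, T_1)$
   cell simulates $R$ two-population loci and forms the empirical
   conditional $\hat P(S_{\text{cult}} \mid S_{\text{wild}})$, again with
   add-one smoothing; conditioning on the locus's own wild count absorbs
   locus-to-locus mutation-rate variation.  Observed wild counts never seen
   in a cell's simulations fall back to the nearest simulated stratum (the
   count of such fallbacks is recorded on the object).

Loci are treated as non-recombining internally and freely recombining
between one another — the standard composite-likelihood design for short
loci.  The argmax cell is the MLE; ties break toward the least extreme
bottleneck (largest $N_1$, then smallest $T_1$).  Default grids are
geometric: $N_1 \in N_0 \times \{0.02 \ldots 1\}$ and
$T_1 \in 4 N_0 \times \{0.005 \ldots 0.25\}$ generations, five points each.
`fit_bottleneck()` wraps both stages and returns a classed object with
`print`/`summary`/`coef`/`logLik`/`plot` methods.

A note on grid design: the cultivated site-count distribution is dominated
by the bottleneck *severity* $T_1/(2 N_1)$, so the surface has a ridge
along constant severity.  If both grids are geometric with the *same* step
ratio, every diagonal cell has identical severity and the surface is
degenerate along the diagonal — the argmax then wanders among
severity-equivalent cells.  The default grids therefore use different
step ratios ($\times 2.66$ per step for $N_1$, $\times 3.76$ for $T_1$),
giving every cell a distinct severity; with 200 loci at $R = 2{,}000$,
parameters generated at a grid point are then recovered within one cell.

## The sweep scan

Under the fitted (or known) null model, `build_null_distribution()`
simulates $R$ independent window-sized neutral loci and records the
cultivated/wild ratios of $\pi$ and of $\theta_W$.  Replicates with zero
wild diversity are re-drawn and counted.  The full-scale analysis uses
$R = 10^5$; the package default is $10^4$ and the validation suite uses
$5 \times 10^3$, which bounds scores at $\log_{10}(R+1) \approx 3.7$ —
ample for rank-based region calling.

An observed window with ratio $r$ gets the empirical p-value
$p = (\#\{r_{\text{sim}} \le r\} + 1)/(R + 1)$ and score
$\mathrm{logP} = -\log_{10} p$.  The pseudocount keeps $p > 0$ when the
observation undercuts every replicate; base 10 is a reporting convention.
The null is simulated without missing data while observed ratios use
callable sites — a documented approximation that is exact for the ratio's
null mean and conservative for its variance.

Candidate regions are windows ranking in the top $K = 15$ of **both**
measures (ties: lower observed ratio, then leftmost), merged when
overlapping or abutting, and labelled `S01`, `S02`, ... in genomic order.
Requiring both measures suppresses windows where a single segregating-site
outlier or a local $\pi$ fluctuation drives one measure only.  The
same machinery applies to wild–indica and wild–japonica pairs with
pair-specific fitted demographies.

Calibration: windows simulated under the null itself produce
$\Pr(\mathrm{logP} \ge 1) \approx 0.10$ and
$\Pr(\mathrm{logP} \ge 2) \approx 0.01$; the test suite verifies both on
1,000 independent (non-overlapping) windows against an $R = 5{,}000$ null.

## Differentiation scans

`fst_scan()` applies the windowed Hudson estimator to subspecies or
subgroup pairs (indica–japonica; temperate–tropical japonica) on the same
window grid as the sweep scan, and `top_fst_regions()` extracts merged peak
regions with deterministic tie-breaking (higher peak, then leftmost).  The
underlying study reports such peaks descriptively; the permutation
threshold offered by `fst_permutation_threshold()` is an addition of this
package and is flagged as such in its output.

## QTL co-localization and the fixed-variant screen

QTL records (id, trait, category, interval) are reduced to their interval
midpoints (floor of the mean); records spanning more than 5 Mb are
discarded as too imprecise.  A QTL maps to a candidate region iff its
midpoint lies within the region padded by 2 Mb on both sides.  Counts of
the four highlighted domestication categories — shattering, awn length,
seed dormancy, grain quality — are tabulated per region via configurable
keyword lists (trait ontologies are external to this package).

The screen walks every panel variant in genes (plus 200 bp upstream and
100 bp downstream of the TSS, strand-aware) inside each candidate region
and reports it iff (i) at least 6 wild and 12 cultivated accessions are
called (6 for indica-specific regions), (ii) *all* called cultivated
accessions carry one identical allele — the fixed-allele criterion is
allele identity, not difference from the reference, (iii) per-site Hudson
$F_{ST}$ against the wild sample is at least 0.7, and (iv) the effect is
`replacement`, `frameshift`, `upstream` or `downstream`.  SNPs in CDS are
classified by codon translation on the coding strand; indels by length
modulo 3; genes whose CDS length is not divisible by 3 are flagged and
excluded from codon effects.  The $F_{ST}$ gate alone provides the
divergence criterion; no requirement is placed on the wild majority
allele.

## The synthetic-data generator

`synthesize_genome()` emulates the study conditions end to end: a
multi-chromosome panel of 10 wild + 22 cultivated haploid accessions (12
indica, 6 temperate japonica, 4 tropical japonica) under the default model
above; a random reference genome whose genes have real codon structure
(start/stop, fourfold-rich codons so the 1,000-synonymous-site convention
is exercisable on 3.6 kb CDSs at ~1 gene/10 kb); per-call missingness with
per-site quality and depth annotations on which the SNP filters
(quality ≥ 100, 3 ≤ depth < 100) act; a QTL table with some intervals
purposely placed over planted sweeps; planted causal variants
(replacement, frameshift, upstream — fixed in the cultivated sample) and
negative controls (near-fixed, low-coverage, synonymous) at each sweep
center; and truth tables for all of it.

What it deliberately does **not** emulate: read-level errors and mapping
artifacts (missingness and depth are drawn from simple parametric models,
independent across calls); population structure *within* the cultivated
group (indica/japonica labels are assigned, not simulated — subgroup
F_ST scans on synthetic data are null by construction unless a
differentiated interval is planted); linkage across the 500 kb chunks from
which chromosomes are stitched (within-chunk linkage is exact; a sweep's
escape draws are independent across chunks, preserving per-site expected
diversity but decorrelating its spatial footprint at chunk boundaries);
and segmental duplication/TE landscapes.  Passing the end-to-end tests
therefore demonstrates the method's correctness under its own model
assumptions, not robustness to mapping artifacts in real short-read data.

## Numerical choices and degenerate inputs

* Empirical p-values use the $(+1)/(R+1)$ pseudocount; scores are bounded
  by $\log_{10}(R+1)$.
* Add-one smoothing guarantees finite composite log-likelihoods
  everywhere; unseen conditioning strata fall back to the nearest
  simulated stratum, with the fallback count reported.
* Heterozygous or half-called VCF genotypes become missing (inbred
  accessions; hets are treated as artifacts), multi-allelic sites are
  dropped with a logged count.
* QTL records with `start > end` are swapped with a warning; rows with
  non-numeric coordinates are rejected with line numbers.
* Windows with no callable sites, no called pair, or zero denominator
  diversity are `NA` and excluded from ranking; all-`NA` tracks yield
  empty (not error) region lists.
* Monomorphic-after-degradation sites are removed so every panel site
  segregates among non-missing calls.
* Sites are keyed by (chromosome, position, alternate allele); infinite-
  sites rounding collisions re-draw deterministically outward to the
  nearest free base.

## Validation problem sizes

The test suite and the acceptance script run the method at these sizes,
chosen to put Monte-Carlo error well inside the asserted tolerances while
keeping a full run in the minutes range on one core: estimator calibration
on 2,000 neutral loci of 10 kb at $\theta = 10$, $\rho = 20$ (recombination
does not move $E[\pi]$ or $E[S]/a_{n-1}$ but roughly halves their
Monte-Carlo spread, tightening the 2% check); the split-model $F_{ST}$
closed form $\tau/(1+\tau)$ on 2,000 loci at $\tau = 1$; null calibration
with $R = 5{,}000$ and 1,000 self-scored windows; sweep recall on a 30 Mb
genome with three planted sweeps of $\lambda = 200$ kb; and demographic
recovery from 200 loci at $R = 2{,}000$ per grid cell with the generating
cell in the middle of the default 5×5 grid.  An independent coalescent
simulator (msprime) serves as an external oracle for the engine's site
count and diversity means on a small single-population configuration.

## Known limitations

* **Sweeps much narrower than the window are only partially recallable.**
  Under the escape model, a *pair* of cultivated lineages is still jointly
  swept at distance $d$ with probability $e^{-2d/\lambda}$, so the
  both-swept fraction averaged over a 500 kb window centred on the sweep is
  $(\lambda/W)(1 - e^{-W/\lambda})$ with $W = 500$ kb — only ~0.37 at
  $\lambda = 200$ kb.  Escaped haplotypes carry ordinary bottleneck-depth
  diversity and refill the valley, leaving an expected window ratio of
  ~0.42 against a neutral baseline of ~0.64, inside the null
  distribution's left tail.  Detection of such narrow sweeps therefore
  depends on favourable escape-draw realizations (roughly 15% of
  realizations put the centre window past an $R = 5{,}000$ null's top-15
  threshold on a 30 Mb genome), whereas sweeps with $\lambda$ at or above
  the window size are recalled reliably.  Mb-scale valleys — the kind
  observed in a ~95% selfer, where effective recombination is twenty-fold
  reduced — correspond to $\lambda \gtrsim 1$ Mb in this
  parameterisation.  The fixation time barely matters here: escaped
  lineages coalesce over the whole bottleneck either way.
* The star approximation has no partial or ongoing sweeps, and a single
  sweep operator acts per simulated locus; two planted sweeps closer than
  ~10 $\lambda$ on one chunk resolve to the nearer one.
* The demographic model has no migration after the split, no recovery
  phase (an explicit design choice: the founding size persists to the
  present), and at most two populations; subgroup-specific demographies
  are fitted by re-running the two-population machinery per pair.
* Composite likelihood understates parameter uncertainty; the surface is
  for point estimation and grid-scale comparison, not confidence regions.
* `sample.int`-based subsampling in the LD decay estimator makes r²
  values reproducible only for a fixed seed and sample order.
* Sample sizes are capped at 128 haploid accessions by the simulator's
  bitmask representation.
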