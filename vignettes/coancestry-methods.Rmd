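---
title: "Methods: fine-scale population structure from coancestry matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale population structure from coancestry matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finestructr)
library(dplyr)
```

finestructr implements the downstream analyses that turn a
chromosome-painting coancestry ("chunkcount") matrix and individual
birthplace metadata into statements about fine-scale population
structure: who clusters with whom, how certain each individual's
east/west assignment is, how populations relate hierarchically, and
how strongly they are differentiated. The painting itself (Li–Stephens
haplotype copying) and the Bayesian clustering that produces the
population labels are upstream tools and are out of scope here; this
package starts from their outputs.

## The data model

The central object is the chunkcount matrix: a square, nonnegative
matrix whose entry $(i, j)$ counts the genome segments ("chunks")
recipient $i$ copied from donor $j$ under the haplotype-copying model.
Its diagonal is zero — an individual never copies from itself. Given a
labeling of individuals into $K$ populations, each individual has a
*copying vector* on the $K$-simplex: element $k$ is the share of its
copied genome attributable to donors of population $k$. A population's
copying vector is the unweighted mean over its members' vectors.

## Geographic cohort construction

Cohorts of this kind are built from individuals whose parents were
born near each other, so that each individual can be placed at a
single point predating modern internal migration. The package
provides:

* `great_circle_km()` — haversine distance on a sphere of radius
  6371 km (mean Earth radius; ellipsoidal corrections are well below
  the 10 km resolution at which such distances are reported).
* `parental_distance_filter()` — retains individuals whose parents
  were born within `max_km` (default 80 km) of each other. The
  boundary is inclusive: "within 80 km" reads most naturally as
  $\le 80$.
* `add_mean_parent_coords()` — an individual sits at the
  coordinate-wise mean of its parents' birthplaces.
* `grid_subsample()` — spatially uniform subsampling: a planar grid of
  `cell_km` (default 25 km) squares is laid over the cohort and at
  most `max_per_cell` individuals are kept per cell, drawn uniformly.
  The projection is a local equirectangular one ($x = R\lambda\cos
  \varphi_0$, $y = R\varphi$, with $\varphi_0$ the cohort's mean
  latitude) anchored at the bounding-box minimum. Over a
  country-sized extent at Nordic latitudes the cell-size distortion of
  this projection is under one percent, far below the sampling noise
  of the draw itself; the anchor and projection do affect individual
  cell membership, which is why retained *counts* (not identities) are
  the meaningful output of a subsampling run.

## PCA on the coancestry matrix

PCA is performed directly on the chunkcount matrix after the transform
used in the chromosome-painting literature: set each diagonal entry to
its column's sum, subtract each column's mean, and symmetrise by
multiplying with the transpose ($S = XX^\top$). The column means are
computed *after* the diagonal replacement, following the stated order
of operations. $S$ is positive semidefinite by construction; scores
are eigenvectors scaled by the square roots of their eigenvalues
(standard PCA scaling, so distances in score space are interpretable),
with each component's sign fixed by making its largest-magnitude
loading positive.

### The dispersion statistic

To compare how tightly geographic groups (e.g. provinces) cluster in
the PC1–PC2 plane, `dispersion_statistic()` computes the group's
empirical variance — the average squared Euclidean distance from the
group mean, with the $1/n$ (not $1/(n-1)$) normalisation implied by
"average squared distance" — and calibrates it against the same
statistic for random same-sized sets of individuals drawn from the
same score cloud (default 100{,}000 resamplings). Three choices here
were genuinely open and are fixed as follows:

* the null resamples **without replacement from all scored
  individuals**, including the group's own members, matching the idea
  of "a similar sized random sample from the same plot";
* the reported *ratio* is observed over the null mean, so it is
  invariant both to the variance normalisation and to the score
  scaling convention;
* the empirical $p$ is the fraction of null statistics $\le$ the
  observed one: small $p$ means the group is unusually tight.

## East/west assignment with uncertainty

Given eastern and western reference panels (sets of individuals fixed
to the two sides of the main genetic divide), each individual's
statistic is the natural-log ratio of its average copying from the two
panels,

$$x_i = \log\frac{\tfrac1{n_e}\sum_{e} c_{ie}}
                  {\tfrac1{n_w}\sum_{w} c_{iw}},$$

where the sums run over panel members and $c_{ij}$ are chunk counts. A
panel member's own zero diagonal simply contributes nothing to its
panel's average; the divisor remains the panel size. A two-component
Gaussian mixture is then fitted to all $x_i$ by EM in semi-supervised
form: panel members' responsibilities are fixed at their known
component, everyone else's are latent. Both means, both (unpooled)
variances and the mixture weight are updated from all
responsibilities. In one dimension with moment-based initialisation
from the labeled groups this is deterministic and needs no restarts;
the log-likelihood is nondecreasing by the usual EM argument, and the
test suite asserts it on every fit. Individuals with posterior
probability below the threshold (default 0.8) for *both* components
are labeled `uncertain`; a posterior exactly at the threshold assigns,
since "under 80% for both" defines the uncertain class.

Two small conventions: variances are not pooled (the more general
default; nothing suggests equal spread of the two ancestry clouds),
and panels enter the M-step with fixed responsibilities (the
semi-supervised likelihood, which is what lets the whole cohort —
panels included — receive probabilities).

## TVD and the TVD-tree

Total variation distance between two copying vectors $a, b$ is
$\mathrm{TVD}(a,b) = \tfrac12\sum_k |a_k - b_k|$: zero iff equal, one
iff disjointly supported, and — because population vectors are
*means* over members — unchanged when a population's members are
duplicated. That sample-size independence is the reason to prefer it
over model-probability-based merge criteria when population sizes are
very uneven.

`build_tvd_tree()` agglomerates $K$ populations in $K-1$ steps,
each time merging the pair with smallest TVD and replacing it by a
population whose profile is the unweighted mean over **all member
individuals'** copying vectors (equivalently the size-weighted mean of
the two profiles — forced by the definition of a population's vector
as the average over its individuals). Profiles are always expressed
against the original $K$ reference populations, whatever the current
number of merged groups; `reference_labeling` lets the reference set
differ from the populations being merged, which is how the robustness
of the topology to the choice of $K$ is tested. Ties in the minimal
TVD are broken by the lexicographically smallest label pair, so trees
are reproducible.

Newick export uses the cumulative-height convention: a node sits at
the TVD of its merge, a branch is the parent height minus the child
height. Merge heights need not be monotone (a later merge of tight
clusters can be lower than an earlier one); negative branch lengths
are clipped at zero with a warning, preserving the merge order. An
alternative convention (per-merge branch lengths) exists in the wild;
cumulative heights were chosen because they make root-to-tip depth
equal to the root merge's TVD.

## Hudson's F\_ST

Pairwise differentiation is estimated from per-SNP allele frequencies
$p_1, p_2$ with $n_1, n_2$ called alleles as the **ratio of averages**

$$\hat F = \frac{\sum_s N_s}{\sum_s D_s},\qquad
N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\quad D = p_1(1-p_2) + p_2(1-p_1).$$

Averaging per-SNP ratios instead is a known source of bias and is
explicitly guarded against by a constructed two-SNP counterexample in
the tests. Negative per-SNP numerators are expected and correct at low
differentiation. SNPs monomorphic for the same allele in both
populations ($D=0$) are excluded and counted; SNPs monomorphic in only
one population are retained. The standard error is a delete-one-block
jackknife over contiguous SNP blocks (default 100 SNPs), a documented
convention of this package: contiguous blocks absorb local linkage
disequilibrium, and the block size is configurable because the
original reports of such SEs do not state their procedure.

## The synthetic cohort generator

Real painted cohorts of this kind sit behind biobank access
controls, so the package ships a generator that reproduces the
*statistical shape* of the data with full ground truth:

* **Geography** — individuals are assigned to populations with known
  centres; parents are placed isotropically around the centre with
  `cluster_spread_km` defined as the standard deviation of the
  parent-to-centre great-circle distance (radial distances are
  Rayleigh). Kilometres convert to degrees on a spherical Earth with
  longitude scaled by $\cos$(centre latitude) — an approximation
  comfortably valid at the latitudes being emulated. Individuals sit
  at the mean of their parents' coordinates.
* **Chunkcounts** — a population-level propensity matrix $Q$ (row
  stochastic) gives the expected copying proportions; each recipient
  draws its own propensity from a Dirichlet with mean $Q[p,\cdot]$ and
  concentration $\alpha$, then allocates a fixed total $T$ of chunks
  multinomially across donor populations and uniformly among each
  population's members, excluding itself. This Dirichlet–multinomial
  construction was chosen because its population-mean copying vector
  *equals* the corresponding row of $Q$, so tree- and
  assignment-recovery tests have analytically known truth. Demand that
  would fall on a self-only population is reallocated proportionally
  to the remaining propensities, matching the zero diagonal of real
  painting output. Rows sum to exactly $T$ by construction.
* **Mixture values** — labeled/unlabeled draws from two Gaussians for
  exercising the EM fit.
* **Allele counts** — Balding–Nichols: ancestral frequencies uniform
  on $[0.05, 0.95]$, population frequencies
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, binomial sampling from
  diploid population sizes. The Hudson estimator is unbiased for $F$
  under this model, which the recovery tests exploit.

The generator emulates clustered geography, propensity-driven copying
and drift-driven allele frequencies; it does **not** emulate linkage
disequilibrium along the genome, admixture gradients within a
population, relatedness structure, or painting noise beyond the
multinomial level. Passing recovery tests therefore show the
estimators are implemented correctly under their own assumptions, not
that those assumptions hold in any particular real cohort.

Because no painted dataset reports a canonical chunk total per
individual, $T$ defaults to 1000 and is configurable; the recovery
tests state their own sizes.

## Problem sizes and numerical choices

The shipped checks run at sizes chosen to make sampling noise small
relative to the tolerances they assert: mixture recovery at
$n = 2000$ with 20 replicates; tree-topology recovery on 100 cohorts
of 60 individuals over four populations whose propensity rows are
0.1 apart within pairs and 0.6 apart between pairs; F\_ST recovery at
60{,}000 SNPs and 500 diploids per population (truth $F = 0.002$, the
magnitude typical of within-country divides); dispersion calibration
on a 1000-individual cohort with 200 random groups of 50 and 10{,}000
resamplings per group. EM stops when the log-likelihood gain drops
below $10^{-8}$ (at most 1000 iterations); component variances are
floored at $10^{-12}$ with a warning if a degenerate configuration
collapses one; eigenvalues of the PSD transform are clipped at zero
before taking square roots.

## A worked micro-example

```{r example}
cfg <- synthetic_config(
  n_individuals = 80,
  cluster_centers = data.frame(lat = c(61, 64), lon = c(23, 29),
                               population = c("W", "E")),
  cluster_spread_km = 15,
  propensity = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE),
  total_chunks = 1000, dirichlet_concentration = 50, seed = 42
)
cohort <- generate_cohort(cfg)
labels <- setNames(cohort$individuals$true_population,
                   cohort$individuals$id)

population_profiles(cohort$chunkcounts, labels)

tree <- build_tvd_tree(cohort$chunkcounts, labels)
to_newick(tree)

panel_e <- head(names(labels)[labels == "E"], 10)
panel_w <- head(names(labels)[labels == "W"], 10)
x <- log_copy_ratio(cohort$chunkcounts, panel_e, panel_w)
x$panel <- ifelse(x$id %in% panel_e, "E",
                  ifelse(x$id %in% panel_w, "W", NA))
fit <- fit_semisupervised_gmm(x$x, x$panel)
tidy(fit)
head(assign_populations(x, fit, threshold = 0.8))
```

## Known limitations

* The grid subsampler's cell membership depends on the documented
  anchor and projection; published retained counts from other
  implementations are not expected to be reproduced exactly even on
  identical input.
* The TVD-tree is a greedy agglomeration; it is a visualisation of
  pairwise distances, not an inferred phylogeny.
* The block-jackknife SE assumes SNPs are exchangeable between blocks
  at the block scale; with strong long-range LD, larger blocks are
  needed.
* The assignment model is strictly two-component; cohorts with more
  than two ancestry sources need a different model, not a larger
  threshold.
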