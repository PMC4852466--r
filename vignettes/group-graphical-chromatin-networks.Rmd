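---
title: "Group graphical models of the chromatin network from binned ChIP-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group graphical models of the chromatin network from binned ChIP-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromgm)
```

## The model

ChIP-seq experiments localize DNA-associated regulatory factors
(transcription factors and histone marks) along the genome.  When many such
experiments are viewed jointly, each fixed-width genomic bin becomes one
observation of a vector of read counts, and the *chromatin network* — which
factors co-localize with which — becomes a multivariate dependence problem.

`chromgm` works on raw binned read-start counts (default 1000-bp bins;
`bin_reads()`), deliberately without peak calling or normalizing transforms.
Transforms such as `sqrt` or `asinh` de-emphasize high counts, but in
ChIP-seq high counts are the signal and low counts the noise, so the raw
scale is the default (`standardize(transform = "raw")`; the transforms are
available).

Three nested network estimators are provided:

* **Correlation** — the sample correlation matrix $\hat\Sigma$ of the
  standardized columns.  It measures co-occurrence but conflates direct and
  indirect association: if A and B each track C, then A and B correlate.
* **Inverse correlation** — $\hat\Theta = \hat\Sigma^{-1}$.  In the Gaussian
  approximation a zero off-diagonal entry means conditional independence
  given all other data sets, so indirect associations are *explained away*.
  Genome-wide confounders (mappability, transcriptional activity, batch)
  that inflate all marginal correlations are absorbed by the conditioning.
* **Group graphical model (GroupGM)** — conditional dependence is unstable
  under near-collinearity: if A and A$'$ are close duplicates, $\hat\Theta$
  connects them tightly to each other and only weakly (and unstably) to the
  rest of the network.  Rather than deleting or merging duplicates, GroupGM
  scores edges between *groups*, with weight
  $G_{ij} = \sum_{k \in g_i} \sum_{l \in g_j} \hat\Theta_{kl}$.
  The estimation errors of the summed entries are strongly negatively
  correlated under collinearity, so the sum recovers the edge the
  individual entries lost (`test-acceptance.R`, criterion 2: duplicating a
  variable at correlation $\ge 0.999$ leaves the group edge within 5% while
  the single-variable edge moves by far more than 25%).

Groups come from complete-linkage hierarchical clustering of
$1 - \hat\Sigma$ (`build_groups()`).  All $p$ leaves and $p-1$ internal
nodes are candidates; a multi-member group is retained only when its minimum
pairwise correlation *strictly exceeds* $\rho = 0.8$ — looser clusters do
not cause the collinearity problem the groups exist to fix, and would only
blur edges.  Groups may overlap (a data set can sit in every cluster on its
root path); edges between overlapping groups are undefined and excluded.

When data-set pairs must be compared across methods (or against an
interaction database), `pair_edge_weights()` reduces group edges to pairs:
each unordered data-set pair gets the maximum ranking statistic over all
disjoint retained group pairs containing the two data sets, restricted to
*factor-pure* groups (all members sharing one ChIP target), so an edge can
be called true or false at the factor level.

### Edge sign and ranking statistic

The package keeps $\hat\Theta$ literal: a *positive association* between two
data sets appears as a *negative* off-diagonal entry (as in any precision
matrix).  `pair_edge_weights()` therefore exposes the ranking statistic
explicitly: `"signed"` ranks by the raw group weight, `"abs"` by magnitude.
For recovery studies on simulated data — where true dependencies carry
random signs — magnitude is the meaningful statistic and is what the
package's own evaluations use.  For co-localization ranking against
databases of physical interactions, negate the weights (or use `"abs"`).

## Genomic context of an edge

An edge is a genome-wide summary; the bins that drive it are often a small,
biologically specific subset (e.g. the bins where a mediating factor binds).
`edge_context()` scores every bin by the change in a chosen group-edge
weight when that bin is removed, using a rank-one Woodbury downdate of
$\hat\Theta$:

$$\bar\Theta = D\left(\Theta - \frac{vv^{\mathsf T}}{u^{\mathsf T}v - 1}\right)D,
\qquad v = \Theta u,\; D_{ii} = \sqrt{1 - u_i^2},$$

where $u$ is the bin's standardized count vector divided by $\sqrt n$.  Two
numerical choices make this identity *exact* rather than approximate:

* columns are standardized with the **population** variance (divide by $n$),
  so that $\Sigma - uu^{\mathsf T}$ is exactly the downdated second-moment
  matrix;
* means and standard deviations are held at their full-data values when a
  bin is removed (removing one of millions of bins does not move them), and
  the diagonal renormalization $D$ restores unit diagonal afterwards.

The same two conventions are imposed on the brute-force oracle in the tests,
which recomputes and inverts the downdated correlation per bin; agreement is
at the $10^{-15}$ level.  The computation is $O(p^2)$ per bin and never
holds more than two $n \times p$ matrices, so memory does not grow with the
number of bins beyond the score vector.  Bins with $|u_i| \ge 1$ (a single
bin carrying a column's whole variance, impossible at genome scale) are
rejected with `NA` influence.

`top_context_overlap()` reproduces the mediator analysis: the top-$k$
context bins of an edge are intersected with every experiment's top-$k$
count bins.  "Top" follows the edge's own sign — for a co-occurrence edge
(negative $\hat\Theta$ weight) the most edge-strengthening bins are the most
negative influences.  Count ties are broken by bin index, and constant count
columns are reported as degenerate.

## The simulator: a stated world

`generate_truth()` + `simulate_counts()` generate counts whose
conditional-dependence structure is known, so recovery can be scored
exactly.  Per bin $t$ and data set $j$:

$$c_j = v_j + \varepsilon_j, \qquad
v_j \sim \mathrm{Poisson}(\text{rate}_j),\;
\text{rate}_j = \max(0, s_j),\;
\varepsilon_j \sim \mathrm{NB}(r = 25, p = 0.9),$$

with $s \sim N(\mu, \Sigma)$ drawn jointly across data sets, a per-data-set
genome-wide batch-effect track added to the rates, and rates smoothed along
the genome with weights $(1/20,\, 9/10,\, 1/20)$ so neighboring bins are
dependent (positive lag-1 autocorrelation, asserted in the tests).

The dependence structure: data sets form complexes of size 1/2/3 with
probabilities 0.6/0.2/0.2; within-complex latent correlations are uniform in
$[0.8, 0.9]$; each cross-complex precision entry is nonzero with probability
0.1, magnitude uniform in $[0.1, 0.3]$, random sign.  Cross-complex pairs
joined by a nonzero generative precision entry are the true edges.

Parameter choices the underlying description leaves open, fixed here once:

* **Latent signal scale** (`signal_sd = 10` reads/bin).  Only the latent
  *correlations* are prescribed; the scale is not.  It matters greatly: with
  unit scale, the NB background (variance $\approx 3.1$) swamps the
  thresholded signal (variance $\approx 0.34$) and no method recovers
  anything.  Enriched 1000-bp bins in real data carry tens of reads, so the
  latent standard deviation is set to 10.  With $\mu = 0$ the marginals are
  zero-inflated and right-skewed (skewness $> 0$ for every data set,
  asserted), resembling real binned ChIP-seq counts.
* **NB parameterization**: number of successes $r = 25$, success
  probability $p = 0.9$, counting failures, mean $r(1-p)/p \approx 2.78$
  reads of unrelated background per bin.  The alternative reading (mean 225)
  would drown the Poisson signal and cannot be called "background".
* **Batch effects**: form unspecified; implemented as eight independent
  smoothed thresholded-Gaussian rate tracks of amplitude 0.5 reads/bin,
  assigned to data sets uniformly at random — a mild genome-wide additive
  confounder of the kind that makes most real data sets positively
  correlated.
* **Positive definiteness**: the precision assembled from within-complex
  blocks plus random couplings need not be positive-definite, and the
  description gives targets, not a construction.  The cross-complex part is
  shrunk geometrically until the minimum eigenvalue reaches $10^{-3}$ *and*
  the within-complex marginal correlations stay inside the target range
  $\pm 0.02$.  Shrinking (rather than diagonal loading) leaves the
  within-complex blocks untouched, and terminates at any dimension because
  the block-diagonal limit meets the targets exactly.
* **Smoothing boundary**: the first and last bin lack a neighbor; the
  missing neighbor contributes zero (so `[0, 10, 0]` smooths to
  `[0.5, 9.0, 0.5]`).  A renormalizing variant is available via
  `boundary = "renormalize"`.

### What a green recovery test does and does not establish

On this world (20 complexes, $n = 20{,}000$) inverse correlation beats
correlation decisively — the explaining-away phenomenon survives
thresholding, Poisson sampling, background noise, batch effects and
autocorrelation.  The observed *count* correlations within complexes land
around 0.6–0.7 (attenuated from the latent 0.8–0.9 by count noise), below
the $\rho = 0.8$ retention threshold, so no multi-member groups form and
GroupGM coincides with inverse correlation on simulated data.  The group
mechanism is therefore exercised where it actually operates — under
near-duplication, in the Gaussian redundancy test — not in the simulation.
The simulator emulates count marginals, positional dependence and batch
confounding; it does not emulate mappability structure, fragment-length
effects, or the same-factor replicate redundancy of real compendia.

## Evaluation

`label_edges()` applies the evaluation conventions for real data: edges
between data sets of the same factor are excluded (they would inflate every
method), edges touching a histone mark are excluded (absent from
protein–protein interaction databases), and scope restricts to within- or
cross-cell-type pairs.  Fold enrichment of the top-$N$ edges is

$$\mathrm{fold}(N) = \frac{\mathrm{TP} \cdot N_{\mathrm{total}}}
{(\mathrm{TP}+\mathrm{FP})(\mathrm{TP}+\mathrm{FN})},$$

i.e. observed hits over the hypergeometric expectation of a random edge set
of the same size.  The background is computed analytically (the tests verify
it against exhaustive subset enumeration for $N_\mathrm{total} \le 12$ and
against 1000 random permutations); a sampling mode would only add variance.
The summary statistic for comparing methods is the mean fold over all $N$ up
to the number of labeled edges.

`bootstrap_compare()` resamples *factors* with replacement, entering every
data set of a drawn factor with multiplicity.  Edges do not vary
independently — one bad data set moves every edge it touches — so
edge-level resampling would understate variability; factor-level resampling
is conservative.  Ties count against the challenger, also conservative (two
identical rankings give $P = 1$).  On simulated data the analogous unit is
the complex, which is what `label_simulated_edges()` wires up.

## Embedding

For a single global picture, edge weights are turned into distances via the
resistance distance.  Viewing $\hat\Theta$ as a signed graph Laplacian,
$\Gamma = \hat\Theta^{-1}$ and
$\Omega_{ij} = \Gamma_{ii} + \Gamma_{jj} - \Gamma_{ij} - \Gamma_{ji}$.
Entries of $\hat\Theta$ below 0.01 in magnitude are zeroed first (they are
mostly noise); because the inverse of the thresholded matrix is no longer
exactly correlation-shaped, $\Gamma$ is renormalized to unit diagonal, after
which the four-term form is the affine map $2(1 - \Gamma_{ij})$ of the
simplified $\Omega_{ij} = 1 - \Gamma_{ij}$ that the package uses.  The two
are rank-order identical (asserted on random models) and classical MDS is
invariant to the scale factor.  `embed_2d()` is classical
(double-centering + top-2 eigenvectors) rather than stress-minimizing MDS:
deterministic, exact on planar configurations (recovered to $10^{-8}$ in
the tests), with reflections fixed by a sign convention on the first node.

`export_viz_json()` writes the static data model of the interactive viewer:
nodes with coordinates and metadata, groups, and edges with
$|w| \ge 0.2$ — the magnitude below which edges stop being enriched for
known interactions.  When two connected groups have children that are
themselves connected above the threshold, the parental edge is redundant and
hidden.  `annotation_overlay()` sizes nodes by their correlation with a
per-bin annotation indicator (largest size normalized to 1).

## Numerical conventions and degenerate inputs

* Correlation uses population normalization throughout; the two-variable
  closed form $\Theta = \frac{1}{1-r^2}\binom{\ \ 1\ -r}{-r\ \ \ 1}$ and the
  partial-correlation renormalization
  $P = -D^{-1/2}\Theta D^{-1/2}$ are tested against regression-residual
  oracles.
* Ill-conditioned $\hat\Sigma$ (duplicate columns) is an explicit error;
  an optional ridge is available but never applied silently, because any
  ridge changes the group-edge sums.
* Zero-variance columns are dropped with a warning and an index map;
  all-constant input is an error.
* Binning: 0-based half-open coordinates, bin = `floor(pos / bin_size)`;
  reads on unknown contigs are counted and reported as skipped (a warning,
  not an error — compendia routinely contain alternate contigs), while
  positions beyond a declared contig end are an error.
* Retention of a group requires min-correlation strictly greater than
  $\rho$; linkage ties are resolved by `hclust`'s deterministic order.
* All simulation and bootstrap randomness flows from a single integer seed;
  identical seeds give bit-identical output.

## Known limitations

* The Gaussian approximation is used as in the source method; count
  likelihoods (e.g. multivariate negative binomial) are out of scope.
* `pair_edge_weights()` enumerates retained group pairs; at $p$ in the
  thousands a sparse implementation would be needed.
* The real-data evaluation requires the user to supply the interaction
  table (two columns of factor names); database retrieval and identifier
  mapping are out of scope.
* The embedding reduces a multi-scale group structure to data-set-level
  coordinates; group areas are exported but not laid out.
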