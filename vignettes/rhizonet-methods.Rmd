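---
title: "Methods behind rhizonet: diversity, ordination and co-occurrence networks for rhizosphere amplicon surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

## Scope and data model

rhizonet analyses genus-by-sample integer count tables from 16S rRNA
amplicon surveys of rhizosphere soils, together with a taxonomy map
(taxon → phylum/class/genus), an environment table of soil variables
(pH, SOC, AP, TP, NO3, NH4 and texture fractions) and, optionally, a
rooted phylogeny for UniFrac distances. All tables travel as TSV with
taxa as rows. The package's reference design is a seven-sample survey
with library depths between roughly 7,000 and 25,000 reads and a soil
pH gradient from about 3.8 to 7.8; all pipeline defaults are the
settings of that design so that a bare run reproduces the standard
procedure.

## Alpha diversity under rarefaction

Unequal library sizes bias every richness estimator, so all
within-sample indices are computed on subsamples drawn without
replacement at a common depth (by default the smallest library). For a
rarefied column the package reports observed richness, Good's coverage
$C = (1 - F_1/N) \times 100$, the bias-corrected Chao1 estimator
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (the classic $F_1^2/2F_2$ form is a
flag; the corrected form is defined even when no doubletons are seen),
and the Shannon index $H = -\sum_i p_i \ln p_i$ in natural-log units —
published values in the 5–7 range for communities of thousands of taxa
are only consistent with nats, and the log base is exposed as an
option. Indices are computed per rarefaction draw and then averaged
(100 draws by default); single-subsample behaviour, which some
published tables use, is `iterations = 1`. The rarefaction-curve
expectation has a closed hypergeometric form,
$E[S_d] = \sum_i 1 - \binom{N-n_i}{d}/\binom{N}{d}$, which the test
suite uses as an oracle against the Monte-Carlo estimate.

## Beta diversity and principal coordinates

Bray–Curtis dissimilarity is the count-based default; when a rooted
tree with branch lengths is supplied, weighted UniFrac is used instead:
each branch contributes its length times the absolute difference in the
proportion of reads descending from it. The normalized form divides by
$\sum_j (p_{Aj} + p_{Bj})\, d_j$ (root-to-tip depths $d_j$), the maximum
attainable value given the two samples' tip placements, so distances lie
in $[0,1]$; normalization is the default because it makes distances
comparable across sample pairs, and proportions are taken after
rarefaction when a normalization depth is in force.

Principal coordinates analysis double-centers $-\tfrac12 D^2$ (Gower)
and eigendecomposes the result. Coordinates are eigenvectors scaled by
the square root of their positive eigenvalues. Negative eigenvalues —
routine for non-Euclidean dissimilarities like Bray–Curtis — are
reported but excluded from the percent-variance denominator rather than
silently corrected; a Lingoes correction is available by flag. For
run-to-run reproducibility each axis's sign is fixed so that its first
non-negligible loading is positive.

## Composition summaries

Counts aggregate exactly (column sums conserved) to phylum, class or
genus, with unmapped taxa in an explicit `unclassified` bucket.
Dominance follows the conventional survey rules with strict
inequalities: dominant means above 5% relative abundance in *every*
sample, subdominant above 1% in *at least one*, rare otherwise; both
thresholds and the sample set the rule is applied over are parameters,
because group-wise dominance calls (e.g. within one vegetation type)
use a subset of samples. The heatmap input is the union of per-sample
top-15 genera, with ties at the boundary broken by total abundance and
then name so the selection is deterministic.

## Diversity–environment regression and redundancy analysis

The Shannon–pH association is an ordinary least-squares fit with a
two-sided t-test on the slope. On the packaged seven-sample summary
tables this fit gives $R^2 = 0.920$; recomputing from rounded published
inputs cannot reproduce a published $R^2$ beyond the rounding of those
inputs, which is why the package's regression check carries a ±0.01
band.

Redundancy analysis is implemented directly: the community matrix
(relative abundances of genera reaching 1% in at least one sample,
column-centered; Hellinger transform by flag) is regressed on the
standardized constraints, and the canonical axes are the principal axes
of the fitted values, with eigenvalues scaled by $n-1$ so their total
over all axes equals the total variance of the centered response.
Per-axis pseudo-canonical correlations are the correlations between
linear-combination and weighted-average site scores. Because a
"Pearson's test" for per-variable contributions is not a defined
procedure, each variable's marginal share is tested by free permutation
of community rows (999 permutations by default, seeded); both the share
and the permutation P are reported so the ordering of contributions can
be inspected. With seven samples the constraint set must stay below
seven variables; the pipeline default uses the six chemistry variables
and leaves texture out. The implementation is cross-checked in the test
suite against an independent constrained-ordination implementation and
against the identity that RDA under space-spanning constraints is PCA
of the response.

## Co-occurrence networks with exact small-sample significance

Genera with pooled relative abundance below 0.12% are removed (the
pooled reading of the filter; a per-sample reading is a flag), then all
pairwise Spearman correlations are computed on midranks of per-sample
*relative abundances*. Ranking raw counts instead would let the varying
library depth act as a factor common to every genus — two unrelated
genera both track total depth, inflating positive correlations and
breaking the exchangeability premise of the permutation test — so
depth normalization is the default and raw-count ranking is a flag for
pre-normalized input. The simulator demonstrates the artifact directly:
genera with fixed proportions sequenced at different depths correlate
perfectly on raw-count ranks and not at all on abundance ranks. With seven
samples the t and large-sample approximations for Spearman significance
are unreliable, so for $n \le 8$ the two-sided P is computed *exactly*:
all $n!$ orderings of one variable's observed (tied) ranks are
enumerated, and P is the proportion with $|\rho|$ at least the observed
value. The null distribution depends only on the two tie patterns, so
it is cached per pattern; at $n = 7$ the enumeration is 5,040 orderings
and a ~200-genus table completes in well under a second. The
t-approximation remains available by flag for comparison with tools
that use it.

Edges follow the strict published rules: positive when $\rho > 0.6$ and
$P < 0.01$, negative when $\rho < -0.6$ and $P < 0.05$; no
multiple-testing correction is applied, deliberately replicating the
published procedure verbatim. At $n = 7$ the exact test makes the
positive-edge rule sharper than it looks: for untied ranks the smallest
attainable $|\rho|$ with $P < 0.01$ is $13/14 \approx 0.929$, so the
$\rho > 0.6$ clause is not binding there. Tied rank patterns have
coarser nulls with their own, sometimes lower, critical values (down to
about 0.87 in practice), which is an intrinsic property of exact
conditional inference, not a defect.

Topology statistics are computed on each signed subgraph: average
shortest-path length over connected ordered pairs, diameter, degrees,
hubs (degree ≥ 8 by default), and modularity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$ under deterministic greedy modularity
maximization (Clauset–Newman–Moore). The community algorithm is seeded
and pluggable because published workflows differ (Gephi/Louvain among
them). Edge incidence is also broken down by unordered phylum pair,
with intra- and inter-phylum totals summing to 100%.

## The synthetic community generator

Every stage is testable without external data through a generative
model with the statistical structure the analyses assume. Samples sit
on an evenly spaced pH gradient (jitter available, default 0). Genus
$g$'s latent log-abundance in sample $s$ is

$$\eta_{gs} = b_g + \beta_g\,\mathrm{pH}_s + L_{B(g),s} + \varepsilon_{gs},$$

with baselines $b_g \sim N(0, \sigma_b^2)$ setting rank-abundance skew,
per-unit-pH slopes $\beta_g \sim N(0, \sigma_\beta^2)$, one latent
factor per planted block $B$ shared by its members, and residual noise.
Proportions are the per-sample softmax of $\eta$ and counts are
multinomial at a depth drawn uniformly from the depth range, so column
sums equal the drawn depths exactly; Dirichlet-multinomial
overdispersion is available through a concentration parameter. One
global seed feeds deterministic per-stage sub-streams, making outputs
bitwise reproducible. Defaults emulate the reference survey: 7 samples,
700 genera in 10 phyla, depths 7,310–24,687, pH 3.84–7.79,
$\sigma_b = 2$ (top-genus shares around 5–20%, matching the skew of
real genus tables), $\sigma_\beta = 0.3$ per pH unit, residual sd 0.5,
and two planted 8-genus blocks with latent sd 1.5.

The generator emulates gradient structure, compositional closure,
depth-varying multinomial noise and planted co-occurrence; it does not
emulate phylogenetic signal in responses, chimeras, OTU-clustering
error or spatial autocorrelation, so passing tests speak to the
statistical machinery, not to upstream sequence processing.

## Test problem sizes and numerical choices

The suite runs the null calibration at the reference design (7 samples,
200 genera, 500 simulated surveys) and the planted-block recovery at a
30-sample, 200-genus community with one 8-genus block (latent sd 2,
residual sd 0.3, depth 50,000, baseline sd 1 so block members reliably
clear the 0.12% filter). Exact-P comparisons enumerate up to $7! =
5040$ orderings. Tolerances: closed-form oracles at $10^{-10}$,
eigen-identities (PCoA distance recovery, RDA-vs-PCA) at $10^{-8}$,
exact-P agreement at tolerance zero. Tie-breaks everywhere are
deterministic (documented sign conventions for eigenvectors, abundance
then name for rank ties).

## Known limitations

Two limitations of the *replicated method* — not of the implementation
— deserve emphasis. First, correlation networks on relative abundances
are subject to compositional closure: a guild of taxa whose absolute
abundance swings strongly dilutes every other taxon coherently, so the
very signal that makes a planted block detectable also induces positive
correlations among unrelated taxa. In the generator this is visible
directly: with a strong 8-genus block (latent sd 2 in natural-log
units), latent-scale correlations among non-members are ~0 while their
count-scale Spearman correlations are large, and within-block recall is
high while edge precision over all predicted edges collapses. This is
the standard motivation for compositionality-aware association methods
(SparCC, SPIEC-EASI), which are deliberately out of scope here because
the package replicates the thresholded-Spearman procedure. Second, with
seven samples and no multiple-testing correction, a ~20,000-pair screen
at $P < 0.01$ retains a material number of chance edges; the exact test
controls the per-pair level precisely (the null calibration test
verifies this) but cannot control the family-wise error. Published
headline network figures (specific node, edge and hub counts,
modularity, path lengths) depend on the underlying unpublished genus
table and are treated as structural references, not as reproduction
targets.
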