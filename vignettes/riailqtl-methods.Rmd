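---
title: "Methods: QTL mapping, heritability, and hotspots for RIAIL panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping, heritability, and hotspots for RIAIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riailqtl)
```

## The study design this package models

riailqtl implements the quantitative-genetics workflow used to dissect
toxin-response variation in a panel of recombinant inbred advanced
intercross lines (RIAILs) derived from two *C. elegans* founders (an
N2-like parent A and a CB4856-like parent B). Populations of each strain
are grown in microtiter wells and measured with a large-particle sorter,
which records per-animal time of flight (TOF, a length proxy) and
extinction (EXT, an optical-density proxy). Wells are summarized into 24
growth-response traits; each toxin condition is mapped by marker
regression with a forward cofactor search; correlated traits are reduced
by principal components; heritability is decomposed into additive and
pairwise-interaction components; QTL across all conditions are pooled to
find hotspot regions; and candidate regions are validated with
near-isogenic lines (NILs) and chromosome substitution strains (CSSs)
whose phenotypes are sorted into explicit genetic-model categories.

Every stage is exercised end to end on synthetic data with known
architecture, so the pipeline's statistical behaviour (error control,
parameter recovery) is testable without any external data.

## The synthetic RIAIL generator

`simulate_riail_panel()` draws each strain's chromosome as a two-state
Markov chain along the marker grid. The first marker is parent A or B
with probability 1/2; the allele switches between adjacent markers with
the recombination fraction given by the Haldane map function
$r = \tfrac12(1 - e^{-2d})$ applied to the interval's *expanded* map
distance $d$ (in Morgans). Advanced-intercross panels accumulate
crossovers over the intercross generations, which expands the effective
genetic map; we do not simulate the pedigree, because every downstream
computation consumes only marginal genotype correlations. Instead the
map specification carries the already-expanded lengths. The default
`riail_map()` uses six chromosomes totalling 1,690 cM
(260/260/260/312/312/286), chosen so the genome divides evenly into 65
bins of 26 cM — the binning used for hotspot detection. The Haldane
function is a deliberate, documented choice; any map function consistent
with the expanded lengths would serve, since only interval switch
probabilities matter here.

Alleles are coded parent A = −1, parent B = +1. The symmetric coding
keeps every marker at unit variance and allele frequency 1/2, and makes
$g_i$, $g_j$, and the product $g_i g_j$ mutually orthogonal for unlinked
markers — so an effect of $\sqrt f$ on a unit-variance term plants a
variance fraction of exactly $f$. `simulate_phenotypes()` builds a
latent genetic value from planted additive markers, planted pairwise
product (epistasis) terms, optional per-assay batch shifts, and Gaussian
noise, then projects it through per-trait loadings onto the 24-trait
roster with independent trait noise, giving mutually correlated traits
the way sorter summary statistics are correlated. `simulate_raw_objects()`
goes one level deeper and emits per-animal TOF/EXT records whose strain
means carry the latent value, for exercising the well-summarization
pipeline.

What the generator does *not* emulate: residual heterozygosity,
segregation distortion, nonuniform recombination within an interval
(each interval is a single Bernoulli switch), contamination and bubble
artifacts, and non-Gaussian trait noise. Passing tests therefore
demonstrate the statistical machinery under clean Gaussian conditions,
not robustness to the full messiness of sorter data.

## Sorter-trait processing

`summarize_well()` computes the frozen 24-trait roster:
{mean, median, q10, q25, q75, q90} × {TOF, EXT, norm.EXT} plus var.TOF,
var.EXT, cv.TOF, cv.EXT, n, and norm.n, where norm.EXT = EXT/TOF per
animal and norm.n = n / animals sorted. Quantiles use the type-7
(linear interpolation) definition, configurable via `quantile_type`.
Objects with non-positive TOF are invalid; a single-object well has
variance 0 by convention; an empty well keeps n = 0 and marks the
distributional traits missing.

Processing order in `process_phenotypes()` is: well summarization →
per strain × assay averaging → assay regression → outlier removal →
control regression. Outliers-before-control is a deliberate ordering
choice (either could be defended; one is frozen and documented).
`regress_assay()` removes additive batch effects as residuals of
`phenotype ~ assay`; `remove_outliers()` drops values beyond
mean ± 2 SD — with mean and SD computed *once* on the input, not
iteratively — unless at least 5% of values fall outside the band, in
which case everything is retained (a tail that heavy is treated as real
strain variation); `regress_control()` returns residuals of
`toxin ~ control` per trait over matched strains, so the mapped
phenotype is the toxin-specific effect. Degenerate cases (single assay
level, zero-variance control) reduce to mean-centering and are flagged.

## Trait reduction

`pca_select()` standardizes each trait to mean 0, SD 1 (constant traits
are dropped with a warning) and eigendecomposes the resulting
correlation structure; the number of retained components is the
smallest $k$ whose cumulative variance fraction reaches 90% (the
`variance_threshold` default). Only strains with complete trait vectors
enter the decomposition. Eigenvector signs are arbitrary, so each
component is flipped to make its largest-magnitude loading positive —
a determinism requirement for reproducible downstream mapping.

`cluster_traits()` clusters traits on the distance 1 − |Pearson r|
(pairwise-complete) with complete linkage, cut into $k$ groups, where
$k$ is typically the retained-component count for the same condition.
The distance and linkage are frozen-but-configurable choices: absolute
correlation groups traits that carry the same signal regardless of
sign, and complete linkage keeps clusters tight. For each mapped
component, `representative_traits()` returns the trait most correlated
with the component plus that trait's whole cluster — the set of
directly measurable traits carried into validation assays.

## Linkage mapping

`lod_scan()` computes, for each marker, the LOD score
$$\mathrm{LOD} = -\,n \,\frac{\ln(1 - r^2)}{2 \ln 10},$$
with $r$ the Pearson correlation between marker genotype and trait over
the per-marker complete cases. This equals the likelihood-ratio
statistic $(n/2)\log_{10}(\mathrm{SST}/\mathrm{SSE})$ of the
single-marker regression, an identity the test suite asserts to 1e−9.
The phenotype is standardized first; correlations are scale-invariant,
so scaling cannot change a mapping, and a test asserts that too.
Monomorphic markers are assigned LOD 0; $r^2$ is capped at
$1 - 10^{-12}$ (flagged) to avoid infinite LOD on perfect correlation.

Significance uses a permutation genome-wide error rate (GWER):
`permutation_threshold()` permutes strain labels 1,000 times — one
shared permutation applied jointly to all trait columns, preserving the
correlation structure among phenotypes (an independent per-trait mode
exists for sensitivity checks) — and takes the 95th percentile of the
per-permutation maximum LOD. `forward_search()` then iterates: scan; if
the peak exceeds the threshold, accept it (leftmost marker on exact
ties) as a QTL and cofactor; residualize the phenotype on all accepted
cofactors; recompute the threshold on the residualized phenotype; stop
when nothing is significant or `max_qtl` (default 10, a safety cap) is
reached. Recomputing the threshold each iteration is the default
because the residualized phenotype is the quantity actually scanned; a
`recompute_threshold = FALSE` flag reuses the first threshold instead.
Each accepted QTL is annotated with its 1.5-LOD-drop confidence
interval — contiguous markers within 1.5 LOD of the peak, stopping at
the first marker below — and its explained variance, the squared
correlation between peak genotype and the input trait.

`pair_scan()` is the two-dimensional counterpart: markers are thinned
to a uniform cM grid (default 5 cM; 0 keeps full resolution), and for
each pair the full model {$g_i$, $g_j$, $g_i g_j$} and additive model
{$g_i$, $g_j$} are fit through a shared orthonormal basis, giving
$\mathrm{LOD}_{\mathrm{int}} = \mathrm{LOD}_{\mathrm{full}} -
\mathrm{LOD}_{\mathrm{add}} \ge 0$ by nesting. The interaction
threshold is the 95th percentile of the per-permutation maximum
interaction LOD over all pairs (1,000 joint permutations). Because the
genotypes are fixed under phenotype permutation, each pair's basis is
reused across permutations, which keeps the scan a few seconds at
panel scale. Near-collinear pairs (tightly linked markers) lose their
product column in the basis and contribute no interaction evidence.

## Heritability

Broad-sense heritability uses
$H^2 = (\sigma_R^2 - \sigma_P^2)/\sigma_R^2$ with $\sigma_R^2$ the
variance among panel phenotypes and $\sigma_P^2$ the variance among
parental phenotypes. The literal pooled-parental reading conflates the
between-parent genetic difference with measurement noise, so
`broad_sense_h2(pool_within = TRUE)` offers a within-parent pooled
alternative; the literal reading remains the default. Estimates are
clamped to [0, 1] with the raw value attached.

Narrow-sense and interaction components come from
`fit_variance_components()`: a restricted maximum likelihood (REML) fit
of $y = \mu + a + i + e$ with $\mathrm{cov}(a) = \sigma^2_A A$,
$\mathrm{cov}(i) = \sigma^2_I (A \circ A)$, and
$\mathrm{cov}(e) = \sigma^2_E I$, where $A$ is the additive kernel —
the Pearson correlation of marker vectors between strain pairs — and
$A \circ A$ its Hadamard square, the natural covariance of pairwise
marker-product effects (positive semidefinite by the Schur product
theorem whenever $A$ is). The restricted log-likelihood is optimized
directly over log-variances (Nelder-Mead; dense Cholesky algebra is
trivial at panel scale). The two-component fit is initialized at the
one-component optimum with a tiny interaction variance, so the nested
likelihood ordering holds by construction; a second equal-split start
guards against local optima. Kernels failing a PSD eigenvalue check get
1e−6 diagonal jitter with a warning. Both one- and two-component
results are available, since either can be quoted as "narrow-sense".
A strain with zero genotype variance (a pure parental genotype mixed
into a panel) has no defined marker correlation; its kernel entries
fall back to match-based similarity (2 × agreement − 1) and are
flagged.

## Hotspots

`estimate_genetic_map()` rebuilds the genetic map from the panel
itself: each interval's cM is 100 × the fraction of strains switching
parental origin between the adjacent markers. No map-function
correction is applied — advanced-intercross switch fractions already
reflect the accumulated (expanded) recombination the analysis bins.
`bin_genome()` lays half-open 26-cM bins per chromosome from 0
(terminal partial bins retained and flagged; bins never span
chromosomes), and `detect_hotspots()` assigns each QTL peak to its bin,
sets $\lambda$ = total QTL / total bins (kept exact, never rounded),
takes the Poisson 99th-percentile count $q$ (smallest integer with
CDF ≥ 0.99), and flags bins with count strictly greater than $q$ —
strict, because a hotspot must hold *more* QTL than the threshold
count. With 82 QTL and 65 bins, $\lambda = 1.2615$ and $q = 4$.
Peak-in-bin assignment is used for detection; CI-overlap
(`hotspot_membership()`) is a separate, deliberately distinct operation
used to list which QTL a validated region covers.

## Validation categorization

Strain comparisons use Tukey's honest significant difference on a
one-way ANOVA (`phenotype ~ strain`), p < 0.05, with replicate counts
chosen by `replicates_for_power()` (exact noncentral-t power, floor 2,
cap 100 reflecting assay throughput). Degenerate inputs resolve
explicitly: zero within-group variance yields p = 1 for equal means and
p = 0 otherwise.

`categorize_nil()` evaluates a fixed-order decision tree over the four
assay strains (both parents, both reciprocal introgression lines):
(1) parents not different → *no parental difference*; (2) both lines
recapitulate → *recapitulation*; (3) neither line differs from its
background parent → *no QTL effect*; (4) both lines transgressive →
*bidirectional transgressive*; (5) exactly one transgressive, the
other recapitulating or inert → *unidirectional transgressive*;
(6) otherwise *miscellaneous*. "Transgressive" requires significance
against both parents *and* a median outside the closed parental-median
interval; "expected direction" means the sign of (line − background
parent) matches the sign of (introgression parent − background parent).
One refinement proved necessary for coherence: a line that satisfies
the direction test but overshoots past the parental range is
*transgressive, not recapitulating* — otherwise a synergistic
transgression (overshoot toward the introgression parent) could never
reach the transgressive branches, and the bidirectional category would
be unreachable for synergistic effects. Transgressive lines carry a
synergistic/antagonistic tag (overshoot toward vs away from the
introgression direction); the tag never affects the category, since
the boundary between the two is ill-defined when the parental
difference is near zero.

`categorize_combined()` places a trait tested in both assays into seven
classes by comparing where the interaction shows up: interaction in the
CSS only → *interchromosomal external* (the partner locus sits on the
introgressed chromosome outside the NIL interval, so NIL loci share a
genotype); the same interaction (same directionality and same
transgressive line/side) in both → *interchromosomal internal*;
interaction in the NIL only → *intrachromosomal*; matching
recapitulation or no-effect → those classes; inconsistent parental
behaviour → *no parental difference*; anything else *miscellaneous*.
Requiring the *same side* for "same interaction" is a frozen choice:
opposite-side transgressions in the two assays are evidence of
different architectures and fall to miscellaneous.

## Numerical choices and problem sizes

Fixed numerical conventions: type-7 quantiles throughout; permutation
thresholds as type-7 empirical quantiles of 1,000 maxima; $r^2$ capped
at $1-10^{-12}$; LOD-drop intervals stop at the first sub-threshold
marker; ties at a scan peak break to the leftmost marker in map order;
diagonal jitter 1e−6 for non-PSD kernels; negative variance estimates
are impossible by the log-scale parameterization (they underflow to
~0). Reproducibility is strict: every stochastic function takes a seed,
and identical seed + specification gives bit-identical output.

The test suite and the acceptance script run at deliberately compact
sizes chosen to keep the statistical claims meaningful: panels of 296
strains (the study's panel size) with 24-120 markers, 1,000
permutations where error control is being measured, 100 simulation
replicates for recovery rates, 500 null traits for GWER calibration,
and 1,000 placements for the hotspot false-positive rate. These sizes
were chosen once, from what each check needs to resolve its target
quantity, and are stated here so the numbers in the README can be
reproduced exactly.

## Known limitations

Marker regression only — no interval mapping between markers, no
multi-trait joint mapping, and no model-averaged multiple-QTL search.
The simulator's traits are Gaussian with a single shared latent factor;
real sorter traits have heavier tails and richer correlation structure.
The NIL/CSS calculus takes strain roles as given and does not model
plate-within-assay replicate structure beyond the upstream assay
regression. Dominance is out of scope (the panels are inbred). The
deposited phenotypes of the original study are not bundled, so
study-specific mapping results (e.g. per-trait QTL tables) are
reproducible in form, not in value; the quantities the package does
reproduce exactly are the design bookkeeping, the hotspot statistic,
and the calibration/recovery behaviour of the methods themselves.
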