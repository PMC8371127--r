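---
title: "Models and methods behind phylosf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylosf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylosf packages the downstream machinery used to interrogate deep,
long-branch-prone nodes of phylogenomic trees: per-site rate
estimation, slow-fast site stripping with support curves, RELL/AU
topology tests, Dollo parsimony gene-content reconstruction, and
binary-profile comparative statistics. This vignette explains the
models, the defaults and the design decisions, and states what the
synthetic benchmarks do and do not demonstrate.

## The substitution model

All likelihood computations use the 20-state Poisson model: equal
amino-acid frequencies (1/20) and equal exchangeabilities, normalized
so branch lengths are expected substitutions per site. Its transition
probability has the closed form

$$P_{ij}(t) = e^{-\tfrac{20}{19}t}\,\delta_{ij} +
  \bigl(1 - e^{-\tfrac{20}{19}t}\bigr)\tfrac{1}{20},$$

which gives three practical advantages: the pruning recursion needs
only a per-node column sum rather than a 20×20 matrix product; pairwise
distances have the analytic inverse
$d = -\tfrac{19}{20}\log\!\left(1-\tfrac{20}{19}\hat p\right)$; and
every simulation result can be checked against closed forms (e.g. the
probability that two leaves separated by path length $t$ at rate $r$
show the same residue is $\tfrac{1}{20} +
\tfrac{19}{20}e^{-\frac{20}{19}rt}$).

Empirical studies of deep fungal relationships use richer models
(LG exchangeabilities with profile mixtures such as C20/C60, free-rate
models, PMSF approximations). Those are deliberately out of scope here:
the slow-fast procedure consumes only the *ranks* of site rates, and
rate ranks are robust to the exchangeability matrix. The tree-inference
stage is isolated behind `infer_tree()` precisely so an external
maximum-likelihood engine can be substituted when model adequacy
matters. This is the package's main simplification and should be kept
in mind when interpreting absolute likelihood values.

Gap (`-`), unknown (`X`) and query (`?`) characters are treated as one
missing state and marginalized in the likelihood — the simplest
treatment consistent with trimmed alignments whose provenance of gaps
is unknown. Fully-missing columns are accepted with a warning, since
trimmed real alignments occasionally retain them.

## Site rates and the slow-fast procedure

Among-site rate variation follows the discrete-gamma convention:
`K = 4` equiprobable categories (the field's default; medians are not
used, category means are) of a mean-one Gamma(α). The shape α is fitted
by bounded scalar optimization of the mixture log-likelihood over
α ∈ [0.02, 100] on a log scale, reproducible to 1e-4. Branch lengths
are taken from the input tree and not re-optimized: rates are meant to
be estimated on the tree the user already inferred. Degenerate
alignments push α to a bound and warn; for an all-invariant alignment
that bound is the *lower* one (spreading rate mass always rewards
constant columns — the per-site likelihood is convex and decreasing in
the rate), which is worth knowing when diagnosing pathological inputs.

The posterior-mean rate of site $i$ is
$\sum_k r_k P(x_i\mid r_k)/\sum_k P(x_i\mid r_k)$, computed in log
space so saturated sites never underflow. Identical columns get
identical rates, and the profile is equivariant under site and taxon
permutations — both properties are tested.

Slow-fast stripping removes the `ceiling(k · step · n)` highest-rate
sites at cumulative step `k`, with ties broken toward the lower site
index for determinism; subsets are produced while at least `step · n`
sites would remain, so `step = 0.05` always yields 19 reduced datasets.
Rates are computed **once** on the full alignment and reused for every
subset; whether to recompute rates per subset is genuinely open in the
procedure's folklore, but fixed rates match how the procedure is used
with a single best-fit model and keep subsets nested. The ceiling (not
floor) guarantees progress on tiny alignments.

Support curves re-infer trees per subset by neighbor joining on the
Poisson maximum-likelihood distances above (saturated pairs capped at
10 substitutions/site), with bootstrap replicates drawn by multinomial
site resampling; a pair of sequences with no jointly observed sites is
an error, never a silent guess. Support of a hypothesis is the
percentage of bootstrap trees whose unrooted split set contains the
hypothesis bipartition; hypotheses naming taxa absent from the trees
are errors rather than silently pruned, and a split and its
complementary labelling give identical support by construction
(splits are canonicalized to the side not containing the
alphabetically first taxon).

## Topology tests

`constrained_site_logliks()` evaluates fully resolved candidate
topologies: branch lengths are optimized coordinate-wise, each edge by
bounded scalar search on its closed-form conditional likelihood given
two-pass partials (downward subtree partials and upward
rest-of-the-tree partials), with partials refreshed once per sweep and
convergence declared when the total log-likelihood improves by less
than 1e-6. Constrained *searches* (resolving a constraint tree by ML)
are reduced to "evaluate the supplied resolved topologies" — a
deliberate deviation that keeps the test surface at per-site
likelihood vectors.

RELL bootstrap resamples site indices with replacement (equivalently:
multinomial weights), sums per-topology site log-likelihoods, and
records the per-replicate best topology; exact ties share credit
fractionally, so two identical vectors get proportions of exactly
one half. Proportions are invariant to adding any per-site constant
across topologies.

The AU test uses ten resampling scales r ∈ {0.5, …, 1.4} (10,000
replicates per scale by default; both configurable). For each topology
the selection frequencies BP_r are transformed to
$z_r = \Phi^{-1}(1-\mathrm{BP}_r)$ and fitted by weighted least squares
to $d\sqrt{r} + c/\sqrt{r}$, with the delta-method weights
$n\,\phi(z_r)^2/(\mathrm{BP}_r(1-\mathrm{BP}_r))$; the p-value is
$1-\Phi(d-c)$, clamped to [0, 1]. A topology whose BP is 0 (or 1) at
every scale is reported as p = 0 (or 1) with a `degenerate` flag rather
than fitted through infinities. Calibration is checked by a permutation
null — per-site differences of two equal-total vectors are shuffled —
where the rejection rate at α = 0.05 stays below 0.10.

## Dollo reconstruction

Under single-gain irreversible-loss evolution, the minimal-loss
ancestral reconstruction of a binary trait places the gain at the MRCA
of its possessors and marks present exactly the nodes on paths from
that MRCA to possessors; losses are the edges from a present node into
a wholly absent subtree. The root edge carries no loss events, gains
sit at nodes, and traits absent everywhere still count in percentage
denominators if present in the matrix — explicit bookkeeping that the
tests pin down. Equivalence with an exhaustive search over all
single-gain assignments is verified on a thousand random instances of
up to eight leaves. Per-node summaries default to percentages of
*traits* (individual proteins); a trait→family map switches the
denominator to families, counting a family as retained when any member
survives — matching how ancestral "repertoire percentage" figures are
usually quoted.

## Profile statistics

The species distance for clustering is `1 − φ` (the Pearson
correlation of binary vectors), range [0, 2], deliberately unclamped
because the downstream clustering is defined on interspecific Pearson
correlations; Jaccard and simple matching are available where a metric
with the triangle inequality is wanted. Constant all-0/all-1 profiles
have no defined correlation; their distance is declared 0 to an
identical profile and 1 otherwise, with a warning. PCoA is classical
scaling (double-centering of −D²/2); negative eigenvalues are dropped
and their absolute mass reported in an attribute rather than corrected
(no Cailliez/Lingoes), the simplest reproducible choice; axis signs are
fixed by making each axis's first nonzero loading positive. Ward
clustering uses Ward.D2 semantics (squared distances inside the
update) with items taken in ascending label order so ties resolve
deterministically.

## The synthetic-data generator

`simulate_tree()` draws a fixed-n Yule topology (birth rate 1) and
rescales it to an exact root-to-tip height of 1 expected
substitution/site — exact rather than expected height, so that a seed
pins the scale too. Long-branch lineages are emulated by multiplying
the named terminal branches only; covarion-like within-lineage rate
shifts are not modelled. `simulate_alignment()` draws per-site rates
from a mean-one Gamma(α = 0.5 by default — strong heterogeneity of the
kind deep phylogenomic datasets show) and evolves sites independently
under the Poisson model; `simulate_traits()` gains each trait once
(default at the root) and loses it with probability 0.1 per branch.
One seed determines everything; each generator derives a fixed-offset
sub-stream so stages are independently reproducible.

The bundled LBA benchmark (`lba_scenario()`) fixes a 12-taxon topology
with 0.01-substitution internal branches, 0.1 terminals and a 12-fold
elongation of two unrelated leaves, 2000 sites at α = 0.5. Under these
conditions distance-based reinference unites the two long branches with
full bootstrap support, and that support collapses once roughly half of
the fastest sites are removed — the qualitative pattern the slow-fast
procedure is designed to expose.

What passing these benchmarks shows: the bookkeeping, estimators and
tests behave correctly under a known generating process, including a
regime engineered to mislead tree inference. What it does not show:
performance under profile-mixture misspecification, heterotachy,
alignment error or biased taxon sampling — real-data phenomena outside
the generator's scope.

## Problem sizes and numerics

The shipped tests and the acceptance script use 6–12 taxa, 200–5000
sites, 10–100 bootstrap replicates and 1000 AU replicates per scale —
sizes chosen so a full run stays in the minutes range on one core
while keeping Monte-Carlo standard errors well inside the asserted
margins (closed-form checks use 3 standard errors). All mixture and
posterior computations are done in log space with per-site rescaling
during pruning; per-site likelihood consistency between the posterior
machinery and the direct mixture likelihood is asserted to 1e-9, and
rerooting invariance of the pruning engine to 1e-9. Sites are 0-based
nowhere: every report and TSV uses 1-based site indices.
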