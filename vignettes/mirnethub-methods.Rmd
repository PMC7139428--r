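---
title: "From small-RNA counts to validated targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From small-RNA counts to validated targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnethub)
```

mirnethub implements a complete analysis path for two-group cardiac
small-RNA experiments: differential expression of mature miRNAs,
integration of target predictions from heterogeneous databases,
construction of a signed miRNA–mRNA regulatory network whose hubs are
prioritized for wet-lab validation, and the statistics of that
validation by qRT-PCR. This vignette explains each model, its
assumptions and its tunable parameters, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where several defensible choices existed.

## Differential expression of miRNA counts

Read counts for mature miRNAs are modeled per miRNA $g$ and sample $j$
as negative binomial,

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi), \qquad
\mathrm{Var}(y_{gj}) = \mu_{gj} + \phi\,\mu_{gj}^2,$$

with a log-linear mean $\log \mu_{gj} = \beta_{0g} + \beta_{1g} x_j +
o_j$, where $x_j \in \{0, 1\}$ indicates the treated group and the
offset $o_j$ is the log *effective* library size: raw library size
times the sample's TMM normalization factor. TMM (trimmed mean of
M-values, `normalize_tmm()`) removes compositional bias between
libraries by trimming the most extreme 30% of per-miRNA log ratios and
5% of average log abundances against a reference sample and
precision-weighting the rest; factors are rescaled to geometric mean 1.

A single **common dispersion** $\phi$ is shared across miRNAs and
estimated by maximizing the Cox–Reid adjusted profile likelihood
$\sum_g \left[\ell_g(\phi) - \tfrac12 \log\det(X^\top W_g X)\right]$ on
a log-spaced grid ($10^{-4}$ to about $5$, 22 points) followed by a
golden-section refinement of the bracketing interval. The adjustment
compensates for the group means being estimated per miRNA; without it
the dispersion is biased low and the test becomes anticonservative.
Sharing one dispersion is deliberately simpler than per-miRNA
empirical-Bayes shrinkage: with a handful of samples per group the
common value is estimated precisely, the likelihood ratio test below
stays well calibrated (the test suite checks a null type-I fraction of
$0.05 \pm 0.02$ at raw $p < 0.05$), and the scientific output — which
miRNAs change and in which direction — does not hinge on per-miRNA
dispersion detail. Exact replication of any particular DE package is a
non-goal.

Each miRNA is then tested by a likelihood ratio test of $\beta_{1g}$
against $\chi^2_1$. Because the design is the saturated two-group one,
each IRLS step has a closed form (weighted group means of the working
response), which lets all miRNAs be updated simultaneously with matrix
arithmetic — this is why dispersion profiling and multi-seed
simulations run in seconds. Reported log2 fold changes are computed
from group-mean CPM with a pseudo-count of 0.5 per group mean, so they
are finite for miRNAs absent in one group; p-values are
Benjamini–Hochberg adjusted (`bh_adjust()`), and a miRNA is called up-
or downregulated when FDR < `alpha` (default 0.05).

The detectability filter (`filter_detectable()`) keeps miRNAs with a
total count of at least `min_total` (default 1) across all samples.
Published analyses rarely state their detectability criterion; the
default is the weakest meaningful one and is configurable.

## Target integration

Three interaction sources are integrated, mirroring the common trio of
a prediction score database, a regression-score database, and a
manually curated database of experimentally validated interactions:

* `predicted_scoreA`: prediction score in 0–100, kept when **score >
  80.0** (strict);
* `predicted_scoreB`: mirSVR-style regression score, kept when
  **score < −1.2** (strict; more negative means stronger predicted
  repression);
* `curated`: accepted unconditionally — curation is the evidence, and
  no score threshold applies.

Only miRNAs significant in the DE step enter integration. The three
filtered tables are combined as a **union** — a pair found by any one
source is kept — because requiring agreement between predictors with
very different recall would discard most curated interactions; the
union reading also matches how integrated target tools describe
themselves. Pairs are deduplicated with every contributing source
recorded. miRNA names are case-folded to one canonical form, always
preserving the -3p/-5p arm suffix (the two arms are distinct mature
sequences); gene symbols are treated as opaque, case-insensitive
identifiers stored upper-case — no ortholog mapping is attempted.
Cutoffs are configurable; both defaults are strict inequalities.

## Signed network and hubs

The integrated interactions form a directed bipartite graph. Each edge
carries weight **+1** if its miRNA is upregulated and **−1** if
downregulated. For a target gene $t$, the degree $\deg(t)$ counts
incident edges and the **node strength** $s(t)$ sums their weights, so
$|s(t)| \le \deg(t)$ and $s(t) \equiv \deg(t) \pmod 2$. A strength
near $-\deg$ means the regulating miRNAs coherently rise (miRNA up
represses its target), predicting target downregulation; mixed signs
give intermediate strengths.

Hubs default to the **maximal observed degree** policy: the hub set is
all targets whose degree equals the network's maximum number of
regulating DE miRNAs. The maximum is a property of the data, not a
constant; a fixed-threshold policy (`degree >= k`) is available for
reuse across networks. In the bundled worked example (five DE miRNAs,
five printed target genes, 15 interaction marks) the maximal degree is
3 and the strengths are $(+1, +1, +1, -1, -1)$.

Exports are SIF, GraphML (via igraph, with direction/strength
attributes) and a per-gene TSV. Layout and visualization are out of
scope.

## GO over-representation

`enrich_targets()` performs classic over-representation analysis: for
a target list of size $n$ drawn from an $N$-gene universe, a term
annotating $K$ universe genes and $k$ targets gets

$$\text{fold enrichment} = \frac{k/n}{K/N}, \qquad
p = P(X \ge k), \; X \sim \mathrm{Hypergeom}(N, K, n).$$

The universe defaults to all genes in the annotation; terms with
$k = 0$ are not reported, and the correction is applied across all
tested terms. Both Benjamini–Hochberg and Bonferroni corrections are
provided because published GO analyses use either (and sometimes name
both in one paper); the default is BH, and the choice must be made
explicitly when reproducing a specific published term list. GO DAG
propagation and term-hierarchy pruning are out of scope, so fold
enrichments are computed on the annotation exactly as supplied.
`top_terms()` ranks significant terms by fold enrichment, breaking
ties by smaller p-value and then term id so the ranking is
deterministic.

## Hub selection for validation

`select_candidates()` encodes the prioritization rule:

1. every hub with **negative node strength** is selected
   unconditionally (coherent miRNA upregulation predicts target
   repression — the most directly testable prediction);
2. positive-strength hubs are ranked by the **highest fold enrichment
   among significant terms that annotate them**, and the top
   `n_positive` (default 3) are added.

The published description of this step names the annotating processes
but no scoring formula; ranking by the best annotating term is the
most direct operationalization, and the tie-break chain (fold
enrichment ↓, term p ↑, gene symbol ↑) makes the selection
deterministic and order-invariant. Alternatives (sum over annotating
terms, counting memberships among the top $m$ terms) would also be
defensible; the single-best-term reading was chosen because it is the
only one that never depends on an arbitrary $m$.

## qRT-PCR validation

`ddcp()` implements relative quantification by $2^{-\Delta\Delta
C_p}$. Duplicate wells are averaged **on the Cp scale** (the
conventional reading of reactions "run in duplicate"; averaging on the
linear scale would weight the duplicates asymmetrically). Per sample,
$\Delta C_p = C_p(\text{target}) - C_p(\text{reference})$; the
calibrator is the **control-group mean** $\Delta C_p$, so control
expressions center on 1 and treated-group means read directly as fold
change versus control. Group differences use Student's unpaired
equal-variance t-test by default (Welch via `var_equal = FALSE`), with
means ± SEM reported. Degenerate inputs are handled explicitly: a
sample missing the reference gene is excluded with a warning; a group
with fewer than two samples yields no test; zero variance in both
groups with equal means yields $p = 1$ by convention, with a warning.
The whole chain is invariant to adding a constant to every Cp — the
shifts cancel in $\Delta\Delta C_p$ — and the test suite checks this
to $10^{-12}$.

`verify_amplicon()` checks primer pairs in silico: exact string match
of the forward primer and of the reverse complement of the reverse
primer on the spliced transcript, product size `end(reverse site) −
start(forward site) + 1` in 1-based inclusive coordinates, smallest
product with a warning when sites are multiple, and a no-amplicon
error when a primer is absent or the reverse site lies upstream.
Mismatch-tolerant matching and efficiency correction (Pfaffl) are
deliberately out of scope.

## The synthetic-data generator

Every pipeline input can be generated with planted ground truth
(`simulation_config()` + `simulate_counts()`,
`simulate_target_databases()`, `simulate_go_annotation()`,
`simulate_qpcr()`), so all downstream claims are testable without
downloads. Defaults encode the emulated study conditions: 6 samples
per group for sequencing and 7 per group for qPCR (validation cohorts
are often slightly larger than sequencing cohorts), 500 mature miRNAs
of which 20 carry $|\log_2 FC| = 2$ with alternating signs, NB
dispersion $\phi = 0.1$ (typical biological replication in rodent
tissue), per-miRNA baseline abundances spanning $2^1$–$2^8$ relative
units, library sizes of 0.8–1.2 million reads, and a 2000-gene target
universe.

Design choices worth knowing:

* Counts are generated per **mature** miRNA with `rno-miR-…-3p/5p`
  names, so name-normalization paths are exercised.
* The planted DE set is the first `n_de_mirnas` miRNAs —
  deterministic, so hub specifications can reference DE miRNAs by name
  before any sampling happens.
* Planted group-2 means are shifted by exactly $2^{\pm\text{lfc}}$
  without renormalizing proportions; with 4% of miRNAs differentially
  expressed in balanced directions the compositional distortion is
  negligible and TMM absorbs the rest.
* Each planted hub edge is emitted in exactly one source table
  (rotating over the three) with a passing score; decoys draw failing
  scores, including a few placed exactly at each cutoff to exercise
  strictness, and curated decoys use only non-DE miRNAs so the
  significance restriction removes them.
* Cp values include a per-sample loading offset that cancels exactly
  in the reference-gene normalization — reference normalization is
  therefore doing real work in the tests.
* Each generator draws from its own fixed offset of `rng_seed`, so
  outputs are bit-reproducible per seed.

What the generator does **not** emulate: FASTQ-level artifacts
(adapters, quality), miRNA families with correlated expression,
tagwise dispersion variation, annotation bias in GO term sizes, and
database disagreement structure beyond pass/fail scores. Passing the
planted-truth suites therefore demonstrates correctness of the
statistics and plumbing, not robustness to every failure mode of real
libraries.

## Numerical choices and problem sizes

* IRLS iterates to a $10^{-10}$ step tolerance (at most 100
  iterations) with the linear predictor clamped to $\pm 30$ to keep
  all-zero miRNAs finite; such miRNAs fall out as $p \approx 1$ and,
  if a fit is non-finite, are flagged and reported as $p = 1$,
  $\log FC = 0$.
* The dispersion grid spans $10^{-4}$ to $10^{0.7}$; data near the
  Poisson limit simply hit the lower bound.
* BH ties need no special casing — the step-up formula handles them.
* Simulation-based checks in the test suite use 500 miRNAs × 6
  samples/group over 20 seeds for effect recovery and 300 miRNAs over
  50 seeds for null calibration; the exhaustive hypergeometric oracle
  enumerates subsets for universes up to 20 genes. These sizes give
  Monte-Carlo error comfortably below the tested tolerances while the
  whole suite runs in well under a minute.

## Limitations

* The DE module is a two-group design only; no covariates or batch
  terms.
* Common dispersion understates miRNA-to-miRNA variance heterogeneity;
  strongly outlying miRNAs can be over- or under-called relative to a
  tagwise method.
* Integration treats the three sources as given tables; it does not
  snapshot or re-host any real database, so published target counts
  that depend on specific database versions are not reproduced.
* Enrichment ignores the GO hierarchy; parent terms will co-appear
  with their children.
* Amplicon verification is exact-match on supplied transcripts; it
  cannot detect off-target amplification elsewhere in the
  transcriptome.
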