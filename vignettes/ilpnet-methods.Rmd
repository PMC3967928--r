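---
title: "Methods: phenotype confidence calling, ILP network inference and its characterization"
author: "ilpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype confidence calling, ILP network inference and its characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilpnet)
```

# Scope

The *C. elegans* genome encodes 40 insulin-like peptides (ILPs) signalling
through a single receptor, DAF-2. ilpnet implements the computational core of
a systematic ILP study design: score deletion mutants across eight
developmental and physiological assays with multi-trial confidence calling;
infer a directed, signed ILP-to-ILP regulatory network from qPCR profiling of
every ILP transcript in every mutant; characterize that network with graph
theory and bipartite modularity; and classify genetic interactions among
double mutants from dauer-entry counts. Every stage is exercised end-to-end
on synthetic data with known ground truth, generated by the package itself.

# Per-trial phenotype statistics

**Survival assays** (lifespan, dauer exit, thermotolerance, reproductive
span) are compared between a mutant and its same-trial control with the
two-group log-rank test under right censoring (`logrankRightCensored()`,
built on `survival::survdiff`). Direction is +1 when the mutant dies later
than expected (fewer observed than expected deaths).

**Interval-scored assays** (pathogen killing scored every 8-9 h) only bound
each death inside an inspection interval $(L, R]$. Because the inspection
grid is shared within a trial, the package uses the grouped-time log-rank:
deaths are placed at the interval's right endpoint and the ordinary log-rank
is computed on the resulting discrete times (`logrankIntervalCensored()`).
The general NPMLE machinery for arbitrary interval censoring is unnecessary
on a fixed grid; the grouped-time statistic converges to the exact-time
log-rank as the grid refines, which the test suite verifies directly on
simulated data.

**Dauer-entry counts** use the exact hypergeometric test on the 2x2
dauer/non-dauer table, conditioning on both margins
(`hypergeomCountTest()`). The two-sided p sums the probabilities of all
tables no more likely than the observed one (the rule Fisher's exact test
uses; a doubling rule is available by option). Exact conditional tests are
discrete and therefore conservative: at 50 eggs per group and moderate
baseline rates their realized type-I error sits near 3-4% rather than 5%,
which is the attainable size of the test, not a calibration defect.

**Cross-trial combination.** Log-rank chi-squares are summed across trials
and referred to a chi-square distribution with one degree of freedom per
trial. Count assays are combined with a binomial GLM of dauer proportion on
genotype plus a trial blocking factor, with a likelihood-ratio test on the
genotype term — the nearest standard reading of combining exact count tests
"with a linear model", recorded here as a design choice.

**Confidence calling** (`classifyConfidence()`) applies three criteria:
combined p below 0.01; for two-lab designs, per-trial significance (p <
0.05) in the majority of trials in both labs; for one-lab designs, majority
significance and at least two significant trials. All three give a
high-confidence call, the combined criterion alone a low-confidence call,
and significant trials in opposite directions force a "variable" call
regardless. Majority means strictly more than half; a tie is resolved
conservatively as no majority.

# qPCR normalization and network inference

Copy numbers per reaction are normalized per sample by the geometric mean of
the two most stable reference genes, selected by the geNorm stability
criterion: candidate $j$'s stability $M_j$ is the mean standard deviation of
$\log_2(x_j/x_k)$ across samples over the other candidates $k$, with
iterative elimination of the least stable candidate until two remain
(`genormStability()`, `normalizeExpression()`). Normalized values are
scale-free, so uniform distortions of a sample (pipetting, input amount)
cannot create edges; the suite asserts this invariance.

Differential expression is tested on $\log_2$ normalized values —
multiplicative assay noise argues for the log scale. `differentialTable()`
fits one linear model per transcript across all genotypes, so the residual
variance is pooled over the whole design (df = N − G, with each mutant's
self-deletion cell excluded from pooling because its variance is noise at
the detection floor). Pooling across genotypes is the package's design
choice: every genotype shares the same assay noise, and the df ≈ 100
residual makes the family-wide q < 0.05 threshold attainable at the assay's
3-4 replicates, which two-group df = 2n−2 tests cannot reliably do. The
two-group pooled-variance t (`differentialTest()`, `pooling = "pairwise"`)
is retained for sensitivity analysis.

Multiple testing uses Storey q-values computed over the full mutant x
target family as one dataset (`storeyQvalues()`): $\hat\pi_0(\lambda)$ on
the grid 0.05-0.90 smoothed with a cubic spline, step-up q-values capped at
1 and monotone in p. With $\pi_0$ fixed at 1 the procedure reduces exactly
to Benjamini-Hochberg, which the suite checks against `p.adjust`.

**Edge calling** (`callEdges()`): a cell becomes an edge when q < 0.05 and
the cell is testable — the mutant's own transcript is excluded (its change
is deletion, not regulation) and transcripts below the detection floor
(default 10 copies/reaction, the assay's sensitivity) are excluded for all
mutants. With 35 mutants and 34 analyzable transcripts this yields the
1190-cell family; both this count and the further self-deletion-adjusted
count are reported (`expressionCensus()`). The sign states the direction of
regulation by the *normal* gene product: a target up in a null mutant means
the gene normally represses it (−1); down means activation (+1). For a
gain-of-function (overexpressing) allele the inference flips. When one gene
is represented by several alleles, only interactions significant with the
same inferred sign in all alleles are kept.

# Graph characterization

Topology metrics ignore edge signs. Isolated genes are dropped from the
analysis view. The characteristic path length is the mean shortest-path
length over *reachable ordered pairs* of the directed graph — the network is
not strongly connected, so unreachable pairs must be excluded to obtain a
finite mean — with an undirected-projection mode reported alongside as a
sensitivity analysis, since published values of this quantity do not always
state the convention. Clustering uses the Watts-Strogatz local coefficient
on the undirected projection (nodes of degree < 2 contribute 0), plus global
transitivity. Small-worldness follows Humphries:
$S = (C/\langle C_{rand}\rangle)/(L/\langle L_{rand}\rangle)$ against
uniform random simple directed graphs with identical node and edge counts;
both the clustering and transitivity variants are computed, with the
percentile of the observed $S$ within the null distribution. Rank robustness
re-ranks every node on a chosen centrality after adding or removing a
fraction (default 25%) of edges uniformly at random, reporting mean and SD
of rank over iterations; ties take average ranks. Betweenness, closeness,
clustering and shortest paths come from igraph and are verified in the test
suite against hand-written breadth-first-search and path-enumeration
oracles on small graphs.

# Bipartite modularity

For a binary incidence matrix $\tilde A$ ($p \times q$, $m$ interactions)
and a joint assignment of rows and columns to modules, the Barber
modularity is

$$Q = \frac{1}{m}\sum_{ij}\left(\tilde A_{ij} - \frac{k_i d_j}{m}\right)
\delta(g_i, h_j).$$

BRIM alternates optimal reassignment of rows given columns and vice versa;
each half-step can only increase $Q$, so the alternation reaches a fixed
point. The adaptive wrapper searches the module count per run — starting at
$c = 2$, doubling while the fixed-point $Q$ improves by more than $10^{-9}$,
then refining by ±1 — and, because alternating reassignment has degenerate
fixed points (e.g. everything in one module) that a single unlucky start can
hit even on noiseless block matrices, each module count is tried from three
random initializations. The headline value is the *mean* of $Q$ over 30
random restarts (the heuristic is stochastic; the mean is reproducible to
SD ≤ 0.02 across seed batches), with the best single-run partition returned
alongside. $c$ is capped at $\min(p, q)$: any module contributing to $Q$
needs at least one row and one column, and surplus single-type modules
contribute zero.

Significance uses two null families: a Bernoulli null with the same number
of interactions placed uniformly at random, and the stronger probabilistic
degree null filling cell $(i,j)$ with probability $(k_i/q + d_j/p)/2$,
preserving expected margins. The named-but-undefined degree null is pinned
to this standard formula and isolated behind one function for easy
replacement. Empirical p-values use the $(1 + \#\{Q_{null} \ge Q\})/(1+n)$
convention so they are never zero.

The two matrices the pipeline scores are the unsigned regulator x target
incidence of the called network and the binary ILP x process phenotype
matrix. For the phenotype matrix the three dauer-entry screens (plain,
*daf-2*- and *daf-28*-sensitized) are aggregated into one process by OR, and
high-confidence calls populate it by default; both choices are arguments,
since published analyses do not always state which variant was scored.

# Double-mutant interaction classification

If two mutations promote dauer independently, an animal escapes dauer only
by escaping both effects, giving the expectation
$P_{xy} = P_x + P_y - P_x P_y$ from the single-mutant rates (an
odds-multiplicative alternative sits behind the same interface). Expected
dauer/non-dauer counts at the double mutant's scored $n$ use
largest-remainder rounding so they sum to $n$ exactly. Each trial's observed
counts are tested against the expected counts with the exact conditional
test (a binomial reference-distribution variant is available), using
same-trial single-mutant rates.

The decision tree (`classifyInteraction()`): a strict majority of trials
significantly above expectation is *synergistic*. Otherwise, with no strain
differing from wild type the call is *no effect*. Opposing singles give
*suppression* when the double is pulled significantly below the promoting
single, the deliberately conservative *non-synergistic* when the double
differs from exactly one single yet not from expectation, and
*no interaction* otherwise. Concordant phenotype-bearing singles give
*non-additive* when the double falls below expectation and *additive* when
it stays within it. Strain-vs-strain differences count as significant when
at least half of the trials show p < 0.05; the deviation-direction tally
requires a strict majority, with exact ties resolved conservatively.

# The synthetic-data generators

Each generator draws from its own RNG substream derived from
(seed, generator name), so outputs are bit-reproducible and adding a
generator never shifts another's draws. The defaults encode the study
design being emulated:

* **Dauer trials**: 50 eggs per group per trial, binomial dauer counts,
  three trials.
* **Survival**: exponential event times (memoryless, one parameter — the
  proportional-hazards alternative the log-rank is powered against), mutant
  hazard scaled by the hazard ratio, uniform right-censoring calibrated to
  the requested censored fraction; interval trials bin latent times onto a
  shared grid.
* **qPCR**: 40 ILP genes plus two stable reference genes in wild type and
  35 null mutants, 4 replicates, log-normal multiplicative noise at CV 10%,
  six transcripts below the 10 copies/reaction detection floor, planted
  signed edges of |log2 fold change| = 1 following the null-allele
  convention (knocking out an activator lowers its target).
* **Double mutants**: class-specific generating probabilities. Promoting
  singles default to 0.65 (non-additive/additive) or 0.30 (synergistic),
  baseline 0.05, and the suppression scenario uses a raised 0.30 baseline so
  a suppressor single can fall below it — magnitudes typical of the
  sensitized backgrounds such screens run in, chosen once. Weaker singles
  make the additive-vs-non-additive distinction statistically undecidable at
  50 eggs x 3 trials.
* **Planted bipartite matrices**: even row/column module split, cells filled
  at `p_within` / `p_between`.

What the generators deliberately do **not** emulate: day-to-day and
lab-to-lab batch effects beyond the trial factor, overdispersion of dauer
counts (counts are exactly binomial), qPCR amplification-efficiency drift
and standard-curve error (generation starts at copy numbers), and any
correlation structure among planted edges (wiring is uniform given the
census). Passing tests therefore certify the statistical machinery under
the stated noise model, not robustness to those real-data pathologies; in
particular, wiring-dependent graph quantities (path length, clustering) of
a planted network reflect random topology, not the biological one.

# Problem sizes and numerical choices

The test suite and the acceptance script run the expression screen at its
natural size (35 mutants x 40 genes x 4 replicates), 200 replicate datasets
for false-discovery calibration, 1000 null simulations per per-trial test,
500 planted doubles for class recovery, and exhaustive partition search on
all ~5,000 binary matrices up to 3x4 for the BRIM oracle — sizes at which
every check completes in a few minutes on one core. Ties in BRIM
reassignment keep the current module, then the lowest index; fixed-point
detection uses a $10^{-12}$ tolerance on Q; q-values are capped at 1;
degenerate zero-variance differential cells report t = 0, p = 1 when means
agree and a limiting p = 0 with a warning otherwise.

# Known limitations

* The interval log-rank assumes a genuinely shared inspection grid; trials
  with per-animal grids are rejected rather than approximated.
* The q-value $\pi_0$ smoother needs a few hundred p-values to be stable;
  for small families `pi0_mode = "fixed_1"` (pure Benjamini-Hochberg) is the
  safer choice.
* Edge signs for gain-of-function alleles rely on the allele class being
  supplied; misclassified alleles silently flip signs.
* The interaction classifier inherits the discreteness of exact count
  tests: with weak single-mutant effects it resolves toward
  "no interaction", which is the intended conservative behaviour.
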