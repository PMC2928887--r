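---
title: "Genetic-similarity speciation dynamics: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-similarity speciation dynamics: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsim)
```

## The model

`radsim` simulates a sexual, haploid, hermaphroditic population of fixed
size $N$ (one individual per site; zero-sum dynamics) whose state is the
$N \times N$ matrix $Q$ of pairwise genetic similarities $q_{ij}$ — the
proportion of identical nucleotides between two effectively infinite
genomes. Mating is assortative: a pair can produce fertile offspring only
if its similarity clears a threshold $q_{\min}$ (optionally also
$q_{ij} \le q_{\max}$, blocking excessively similar pairs). The
*evolutionary graph* connects compatible pairs; a **species** is a
connected component — two individuals are conspecific whenever a chain of
compatible intermediates links them, even if they are themselves
incompatible.

Each elementary time step is a Moran-style cycle:

1. a uniformly chosen individual dies (independent of fitness);
2. a first parent is drawn — uniformly among individuals with at least one
   compatible partner in the neutral regime, or with probability
   proportional to $1/(1+k_i)$ (degree $k_i$) under negative
   frequency-dependent selection, so that carriers of rare alleles mate
   more often;
3. a mate is drawn uniformly from the first parent's compatible partners;
4. the offspring fills the vacant site.

One **generation** is $N$ elementary steps. Because genomes are
effectively infinite and recombination is free, the offspring's similarity
row never needs explicit sequences; it follows the overlap recursion

$$ q_{oj} \;=\; e^{-2\mu}\,\frac{q_{p_1 j} + q_{p_2 j}}{2}, $$

with $\mu$ the mutation rate per birth: inheritance averages the parental
rows (each site comes from either parent with probability $\tfrac12$) and
mutation rescales identity by $e^{-2\mu}$ (each mutation hits a fresh
site). This makes one birth $O(N)$ and is exact in the infinite-genome
limit; the test suite checks it against a brute-force simulator with
explicit genomes of $10^4$ sites, per-site inheritance and
infinite-alleles mutation, which reproduces offspring similarities within
the binomial sampling error $O(L^{-1/2})$.

### Speciation events and their classification

Two modes of speciation arise and are detected at distinct sub-steps:

* **Fission** (after the death): the death removes the sole genetic
  pathway holding a species together, and the component splits. The
  largest surviving fragment keeps the mother's label (ties broken by the
  smallest member index); every other fragment is a new species.
* **Mutation-induced** (after the birth): the newborn is incompatible with
  everyone, founding an instant singleton species.

A newborn that reconnects two existing species triggers a bookkeeping
*merge* (the smaller label is retired); merges are excluded from
speciation and extinction tallies. A death that removes the last member of
a species is an extinction. Species identity is genealogical: labels
persist through membership turnover and are never genetically
re-identified.

### Analytic feasibility quantities

Under the neutral, non-fragmenting dynamics the expected mean off-diagonal
similarity obeys the mean-field recursion
$\bar q \mapsto e^{-2\mu}\,[(N-2)\bar q + 1]/(N-1)$ (two of the newborn's
$N-1$ similarities point at its parents), whose fixed point is

$$ \hat q \;=\; \frac{e^{-2\mu}}{\,N-1-e^{-2\mu}(N-2)\,}
   \;\approx\; \frac{1}{1+2N\mu} \quad (\mu \ll 1). $$

Because parent choice is uniform when the graph is complete, the recursion
is exact for the expectation, and a $5000$-generation run at $N=50$,
$\mu=0.005$ time-averages to $\hat q$ well within Monte-Carlo error
(0.6699 observed vs 0.6700 predicted). Note the constant $2N\mu$: the
frequently quoted $1/(1+4N\mu)$ belongs to synchronous (Wright–Fisher
style) generations, where the pair-coalescence time is $N$ generations
rather than the Moran $N/2$; the asynchronous clock used here halves it.

Speciation requires the graph to shed edges at equilibrium, i.e.
$\hat q < q_{\min}$ (`speciation_feasible()`); fitting grids are
pre-filtered by this condition. Mutation-induced speciation additionally
needs a single birth to clear the threshold: from two identical parents
the offspring-to-parent similarity is $e^{-2\mu}$, so the one-step minimum
mutation rate is $\mu_{\min} = -\ln(q_{\min})/2$ (`min_mutation_rate()`).
Two caveats, both consequences of the recursion rather than additional
assumptions: (i) parents that are compatible but *not* identical
($q_{p_1p_2}$ just above $q_{\min}$) can produce a disconnected offspring
already for $\mu > \tfrac12\ln\!\big((1+q_{\min})/(2q_{\min})\big)$, a
weaker bound than $\mu_{\min}$; (ii) below that weaker bound, no birth can
ever disconnect from its parents, so every speciation event is a fission —
the mode-exclusivity tests use parameters in this strict region
($q_{\min}=0.95$, $\mu=0.01 < 0.013$).

## Parameters that matter

| parameter | meaning | default / typical | units |
|---|---|---|---|
| `N` | population size (sites) | 32–128 | individuals |
| `mu` | mutation rate per birth | $10^{-3}$–$10^{-2}$ | similarity decay per birth |
| `q_min` | fertility threshold | 0.90–0.95 | similarity |
| `q_max` | self-incompatibility ceiling | disabled | similarity |
| `regime` | parent-selection weights | `neutral` | — |
| `viability` | mate-choice function shape | `step` | — |
| `generations` | run length | study-dependent | $N$ steps each |

The `step` viability kind is the headline case (the simplest
Dobzhansky–Muller incompatibility); `range`, `linear` and `exponential`
kinds are provided as variants and enter mating as acceptance
probabilities on candidate mates. The threshold is inclusive
($q \ge q_{\min}$); boundary cases have measure zero under the recursion.
The Moore-8 lattice variant restricts *mating* to the 8-neighborhood
(torus optional); the offspring always takes the freed site, and the
first parent is still drawn population-wide by the regime weights.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen once, as the regimes in which each question is
well-posed:

* **Equilibrium**: $N=50$, $\mu=0.005$, $q_{\min}=0.05$ (non-binding, so
  the graph stays complete and the mean-field recursion is exact in
  expectation), 5000 generations, time-averaged after a 1000-generation
  burn-in; agreement asserted within 3 batch-mean standard errors.
* **Regime contrast**: $N=64$, $\mu=0.002$, $q_{\min}=0.90$, 2000
  generations, 20 replicate pairs. This is the weak-mutation, fission-only
  radiation regime near the feasibility boundary
  ($\hat q(64, 0.002)=0.80$, $\mu \ll \mu_{\min}(0.90)=0.053$): under
  frequency dependence a handful of fission events early on is followed by
  a long plateau with stable, even-sized species, while the neutral model
  keeps speciating (and losing species) at a steady pace. Deeper inside
  the fragmented regime (larger $\mu$ or higher $q_{\min}$) both regimes
  show sustained turnover and the trend contrast washes out, though the
  diversity and symmetry contrasts persist.
* **Rate trend tag**: windowed event rates (window = span/20) are fitted
  by least squares; the tag is *constant* when the fitted change across
  the span is below half the mean rate — a scale-free criterion that
  correctly tags both a front-loaded burst and an evenly spaced series.
  The transient (everything before the first speciation event) is
  excluded, configurable.
* **Population-size independence**: the long-term neutral speciation rate
  is compared on the *per-elementary-update* clock, $N\in\{32,64,128\}$ at
  $\mu=0.01$, $q_{\min}=0.95$, 2000 generations, 20 replicates. Per
  generation the rate scales essentially linearly with $N$ (a generation
  is $N$ updates); per update it is nearly invariant. A genuine
  finite-size correction of order $1/N$ remains (about 2% between $N=32$
  and $N=128$, with replicate spread of roughly 1%): adjacent sizes'
  95% replicate intervals overlap, but the extremes can separate — the
  invariance is asymptotic, and the strict all-pairs overlap check is
  expected to fail at this precision. We report the rates rather than
  widen the interval.
* **Self-recovery fit**: observed series generated at
  $(q_{\min}, \mu, N) = (0.92, 0.002, 64)$ over 500 generations, fitted on
  the centered $3\times3$ grid
  $\{0.90,0.92,0.94\}\times\{0.001,0.002,0.004\}$ (all feasible), 20
  replicates per triple.

## The quasi-likelihood fit

Observed data are an event series: speciation times with cumulative
species counts, plus the present time. Both observed and simulated series
are normalized so the first event maps to 0 and the present to 1. For
each admissible window of the simulated series the first $k$ events are
paired in order with the $k$ observed events and scored by

$$ E = \sum_{i=1}^{k} \left( |\Delta S_i| + |\Delta\tau_i| \right), $$

the summed absolute misfits of cumulative species count and normalized
event time. Pairing is order-based — cumulative counts force the order,
so no within-window permutation can help — and both terms enter
unweighted. Window semantics follow from the worked identity
$E(\text{obs}=(0,1), \text{sim}=(0,0.8)) = 0.2$: each window is
re-anchored at its first event but re-scaled to the *series* present, so
only the window start matters (`window = "sliding"`, the default); a
`"prefix"` variant instead varies the truncation time treated as the
present. Window counts are rebased to a one-species baseline. Replicates
with fewer events than the data score as missing rather than being
penalized; the missing fraction is reported per triple. Confidence bands
pool, from every triple within 2 units of the minimum, each replicate's
*best-matching window* — the same alignment the misfit scores — so the
pooled curves are commensurable with the data; coverage is assessed at
the band's sampled time points against the observed step curve.

Under independent exponential errors $E$ is the model's negative
log-likelihood up to the error scale (fixed to 1 — only rankings and the
2-unit rule are consumed downstream), so the grid surface of mean $E$ is
a quasi-likelihood surface: the best triple minimizes mean $E$, and
percentile confidence bands pool species-through-time curves from fresh
replicates at every triple within 2 units of the minimum (pointwise
2.5%/97.5%). Replicate $r$ of every triple uses seed $\texttt{seed}+r$ —
common random numbers across triples, which smooths the surface without
biasing the ranking. In self-recovery experiments the generating triple
or a neighbor is recovered in the large majority of trials and the band
covers the observed curve at well over 90% of event points; note the
surface is fairly flat along directions that trade $\mu$ against
$q_{\min}$, because time normalization deliberately discards the absolute
rate and compares only the *shape* of the radiation.

## What the synthetic fixtures do and do not emulate

`fixture_event_series()` supplies observed series with known truth:
`constant_rate` (equal normalized gaps), `burst_plateau` (≥70% of events
in the first 30% of normalized time) and `self_recovery` (a full
simulator run at stated parameters). The analytic kinds emulate only the
two radiation *shapes* the model distinguishes; they carry no abundance
information, no measurement error in event times, and no phylogenetic
uncertainty — all present in real molecular-phylogeny-derived series. A
passing recovery experiment therefore demonstrates internal consistency
of the fitting machinery, not that real radiations identify these
parameters.

## Numerical choices and degenerate inputs

* The compiled engine and the pure-R reference engine consume the R
  random stream in an identical draw order (inverse-CDF categorical
  draws), so trajectories are bitwise identical for a seed; this is
  tested, and makes the fast path fully auditable against the slow one.
* Components are maintained incrementally: a death can only split the
  dead individual's species, and the split check exits early once all of
  the dead node's former neighbors reconnect; a birth can only join or
  merge. Incremental labels are tested against recomputation from scratch
  (union–find, itself tested against an independent DFS).
* Selfing is disabled; the dead individual is excluded from parenthood.
  Singleton species are therefore sterile and go extinct on their
  member's death. If *no* individual has a compatible partner the run
  halts with a "population sterile" signal and returns partial results.
* `mu = 0` keeps $Q \equiv 1$: no speciation ever, and
  `equilibrium_similarity()` returns 1. `min_mutation_rate()` rejects
  $q_{\min} \in \{0, 1\}$.
* Ties in fragment size (mother-label assignment) go to the fragment with
  the smallest member index; label merges keep the larger component's
  label (ties to the smaller label).
* Asynchronous updating only; a synchronous variant is out of scope.
* The self-incompatibility variant (`q_max < 1`) blocks *all* pairs in
  the identical founding population: every founder is its own species and
  the run halts sterile at the first step. The variant is meaningful only
  as a continuation of diversified dynamics; both engines handle the
  degenerate start gracefully (initial species are the components of the
  initial graph).

## Known limitations

* Genomes are infinite and recombination free: no linkage, no diploidy,
  no explicit loci of incompatibility.
* Frequency dependence is phenomenological (graph degree as rarity); no
  explicit pathogen or sexual-conflict mechanics.
* The species concept is purely graph-topological; re-connected species
  are merged by bookkeeping, with no hybrid-zone dynamics.
* Populations beyond a few hundred individuals are computationally heavy
  because every birth touches a full matrix row and fissions require
  component checks.
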