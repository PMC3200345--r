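---
title: "Detecting parallel molecular evolution: models and methods"
author: "parallevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel molecular evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallevol)
```

# The scientific problem

When a trait evolves independently in two lineages — the motivating case is
high-frequency hearing in the two laryngeal-echolocating bat clades,
Yangochiroptera and Rhinolophoidea, which are paraphyletic in the species
phylogeny — a gene underlying that trait can accumulate the *same* amino-acid
replacements on both lineages.  Two signatures follow.  First, a tree built
from the protein sequence groups the trait-sharing lineages together, in
conflict with the species tree.  Second, ancestral-sequence reconstruction
reveals individual sites where both lineages replaced the same ancestral
residue with the same derived residue (parallel substitution), more often
than chance substitution would produce.

`parallevol` implements the full chain of analyses around these signatures:
per-site likelihood comparison of two topologies, greedy minimal-site
removal, marginal ancestral reconstruction, substitution mapping, the
Zhang–Kumar expected-count test for parallel and convergent changes,
codon branch-model likelihood-ratio tests of selective pressure, and
phylogenetically independent contrasts (PIC) for correlating per-lineage
substitution counts with a continuous trait such as frequency of best
hearing.  A simulation module generates alignments, codon alignments and
Brownian traits with recorded truth so every stage can be validated without
external data.

# Likelihood engine

## Substitution models

Amino-acid likelihoods use empirical exchangeability matrices (any set
shipped with **phangorn**, including the HIV-derived HIVb/HIVw matrices and
general matrices such as WAG, LG and JTT), combined with equilibrium
frequencies that may be the matrix's published values, user-supplied, or
counted from the data (+F).  Rate heterogeneity follows the standard
invariant-sites plus discrete-gamma mixture (+I+G).  Gamma categories use
equal weights with mean-of-category rates via `phangorn::discrete.gamma`;
we chose the mean-of-category discretization (rather than medians) because
it is the convention of the ML programs this package's results are meant to
be comparable with, and it keeps the bundled cross-check oracle exact.
With a proportion `pInv` of invariant sites the gamma rates are rescaled by
`1/(1 - pInv)` so branch lengths remain expected substitutions per site.

Codon models are Goldman–Yang: instantaneous rates between sense codons
differing at one position are proportional to the target codon frequency,
multiplied by `kappa` for transitions and by `omega` (dN/dS) for
nonsynonymous changes.  `omega` is a map from branch-class labels to
values, so one model expresses one-ratio, two-ratio, fixed-omega and
free-ratio branch models.  Codon frequencies default to F3x4.  Each
class's generator is scaled to one expected substitution per codon, the
branch-length convention of CODEML branch models.

## Pruning, scaling, numerics

Per-site likelihoods are computed by Felsenstein's pruning algorithm in
compiled code, with per-pattern rescaling whenever a partial likelihood
column drops below 1e-200 (log scalers are carried alongside, so results
are exact at any tree depth).  Alignment columns are pattern-compressed.
Rate categories are pruned separately and mixed in log space.

Branch lengths are optimized by cyclic one-dimensional Brent searches: a
rootward/tipward pass caches, for every edge, the partial likelihoods of
the data on both of its sides, making each trial length an O(states²
× patterns) evaluation.  Partials are refreshed every sweep and sweeps
repeat until the total log-likelihood changes by less than `tol` (default
1e-6).  Because the two child edges of a rooted binary root are
identifiable only through their sum, fitting happens on the unrooted tree
and the fitted merged length is split back in proportion to the input
root edges.  Branch lengths are bounded below at 1e-8.  On simulated data
the optimum agrees with `phangorn::optim.pml` to ~0.01 log-likelihood
units (see the test suite).

Codon branch-model fitting alternates the per-edge sweeps with
Nelder–Mead moves of the global parameters (`kappa` and shared omegas);
free-ratio models optimize `(length, omega)` jointly per edge.  The
parameter count np follows the codon-model convention: `2n - 3`
identifiable branch lengths, plus one for `kappa`, plus one per free
omega; `branchModelNp()` exposes the arithmetic so degrees of freedom can
be audited before a fit.  An optional `restarts` argument re-runs the
optimizer from jittered starting points; the default is a single start,
which in the strongly purifying regimes this package targets has been
sufficient (the likelihood surface is effectively unimodal there), and
keeps the free-ratio model — flagged expensive — tractable.

## Ancestral reconstruction

`ancestralML()` computes marginal empirical-Bayes posteriors per internal
node and site by combining the rootward and tipward partials at the node,
integrating over rate categories.  Under a reversible model the marginals
do not depend on where along the root split the root sits, but a rooted
topology is required so "internal node" is well defined; the natural
choice, used by all fixtures, is rooting on the non-bat outgroups.
`ancestralParsimony()` implements the Fitch/Hartigan down-pass (exact
minimal score for any node arity) and the classic final-set up-pass on
binary nodes; best states break ties by alphabet order, deterministically.

# Conflict sites and minimal removal

`siteSupport()` fits branch lengths on both candidate topologies over the
full alignment and reports, per site, the log-likelihood difference
`d = lnL(gene tree) - lnL(species tree)`; the d values sum to the total
difference by construction.  `minimalRemoval()` removes the highest-d site
(ties broken by ascending index), refits both topologies on the reduced
alignment — comparisons should be at each alignment's own optimum — and
repeats until the species tree is preferred.

One numerical subtlety is deliberate: the preference test uses a tolerance
(`preferTol`, default 1e-3 log-likelihood units).  When every genuinely
conflicting site has been removed, the two topologies often collapse to
the same near-polytomy and their optimized totals agree to optimizer
precision; a strict comparison would then be decided by rounding noise,
and on null data the removal set would fail to be empty about half the
time.  With the tolerance, "no advantage for the gene tree" counts as
species-tree-preferred, which is the scientifically intended reading.  Any
real conflicting site contributes far more than 1e-3.

`randomTopologyTest()` draws uniform random labelled topologies
(`ape::rtopology`), refits branch lengths on each, and reports the
empirical probability `(r + 1)/(n + 1)` that a random topology fits at
least as well as the observed tree; a Robinson–Foulds variant
(distance to a reference tree, via `phangorn::RF.dist`) is selectable
because the statistic behind published "observed tree vs random trees"
comparisons is not standardized.

# Parallel and convergent substitutions

Substitutions are mapped onto branches by comparing best reconstructed
states between each branch's parent and child (observed states at tips);
an option restricts calls to positions whose posterior exceeds a
threshold.  For a branch pair, a shared site is *parallel* if both
branches substitute X→Y with the same X and Y, *convergent* if the derived
states match but the ancestral states differ, *divergent* otherwise.

The Zhang–Kumar test asks whether the observed number of parallel (or
convergent) sites exceeds chance.  Per site, the ancestral-state
posteriors at the two parent nodes are combined with the branches'
mixture-averaged transition matrices to give the probability that both
branches independently substitute to the same derived state (from a common
ancestral state for parallel; from distinct ones for convergent).  Summing
over sites yields a Poisson mean; significance is the Poisson upper tail
P(X ≥ observed).  The Poisson form (not binomial) reflects that the mean
is a sum of many small per-site probabilities.  Because the count is
discrete and the null mean is typically far below one on conserved
proteins, the test is conservative: its realized type-I error sits below
the nominal level rather than at it.  The calibration checks in the test
suite therefore verify that the empirical null rejection rate does not
exceed the nominal level (binomial error allowed), which is the attainable
property for this class of test.

`scanParallelSites()` runs the whole chain — branch-length fit, ML
reconstruction, substitution mapping, per-pair Zhang–Kumar test — for
configured lineage pairs, and reports parallel-classified sites with their
pair's pooled significance.  Pooling across all sites of a pair is the
default; a `sites` argument supports testing site groups separately, since
published analyses sometimes report per-group probabilities.

# Selection tests

`table1Specs()` builds the standard ladder of seven branch models over the
five lineage classes of the bat system (a: bat stem, b: Yangochiroptera
stem, c: Rhinolophoidea stem, d: Yinpterochiroptera stem, e: fruit-bat
stem): one-ratio, free-ratio, focal-branch two-ratio models, and a model
with the fruit-bat-associated stems fixed at omega = 1.  `lrt()` computes
`2Δ(lnL)` against the chi-squared distribution with `df = Δnp`, and
reports the Bonferroni-corrected p (`min(1, m × p)`) alongside — never in
place of — the raw value.  `selectionReport()` fits a spec list, isolates
per-row failures, and tabulates estimates and tests.

# Trait correlation with phylogenetic correction

`countChanges()` sums mapped substitution events along the unique path
from an ancestral node (e.g. the bat common ancestor) to each tip.
`picCorrelation()` computes Felsenstein's standardized independent
contrasts for both variables (via `ape::pic`) and correlates them through
the origin — the standard practice, since each contrast's sign is
arbitrary; the t test uses `df = n_contrasts - 1`.  Soft polytomies are
resolved with zero-length branches; non-ultrametric trees are accepted but
flagged.  `traitCorrelation()` is the uncorrected Pearson counterpart.

# The synthetic study system

`batSpeciesTree()` ships an 18-taxon rooted phylogeny — six
Yangochiroptera, six Rhinolophoidea, three Old World fruit bats, and dog,
rabbit and human as outgroups — with the five branch classes attached, and
`batProteinTree()` the conflicting topology in which all echolocators form
one clade.  Branch lengths are short (maximum pairwise p-distance below
0.1), matching the strongly conserved regime of a hearing-channel protein.
Three choices deserve comment:

* **The conflicting split is nearly unresolved** (Yinpterochiroptera stem
  0.001 substitutions/site).  In the empirical setting the split in
  question is weakly supported, and removal of two sites flips the
  topology preference — which requires the genuine topological signal to
  be of the same order as two sites' worth of likelihood.
* **The echolocator stems (b, c) are the longest internal branches**
  (0.010) while the bat stem and fruit-bat stem are short.  At a site
  where all echolocators share a derived state, two equally parsimonious
  histories exist (parallel gains on b and c, versus a gain on the bat
  stem plus a reversal on the fruit-bat stem); the branch lengths
  determine which the reconstruction prefers, and the fixture encodes the
  empirically supported geometry in which the parallel history is the
  likelier one.
* **Conflict-site injection defaults to a low-exchangeability residue
  pair.**  Sites capable of flipping a whole-alignment topology preference
  are precisely sites whose repeated independent origin the model deems
  very unlikely; injecting a rare replacement (methionine to cysteine
  under HIVb) puts each synthetic conflict site in that decisive-d regime,
  so the minimal removal set is the injected set rather than a single
  site.  The parallel-site scans use the common methionine-to-isoleucine
  replacement, matching the flavour of empirically reported parallel
  sites.

`simulateAlignment()` draws the root from the model frequencies and
evolves sites branch-wise, either by exact transition-probability sampling
(fast; truth = node states plus forced events) or by Gillespie path
sampling when every individual event must be recorded.  Forced
("injected") sites are held invariant apart from their forced events, so
injected truth is unambiguous.  `simulateTraits()` runs Brownian motion
along the tree, optionally adding `beta ×` (per-tip substitution count) to
create trait–count association.

What the simulations do *not* emulate: indels and alignment error,
among-gene rate variation, selection regimes that vary over time within a
branch, and non-stationary composition.  Passing recovery tests on this
generator demonstrates that the inference machinery is correct and
calibrated under its own model class, not that real data satisfy that
model.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale chosen to
keep the full suite in the tens of minutes on one core: 600-site amino-acid
alignments for conflict and parallel scans (50 and 1 replicates
respectively), 300-site nulls (200 replicates), 5000 and 400-codon
selection fits, and hundreds of PIC replicates.  All simulation entry
points take explicit seeds and are fully deterministic given one; the
pipeline (`runPipeline()`) records the seed, a config hash and the package
version with every output bundle, and reruns are byte-identical.

# Known limitations

* Branch-model likelihood surfaces can in general be multimodal; for
  regimes far from the purifying one exercised here, use `restarts > 1`.
* The Zhang–Kumar expectations use mixture-averaged transition matrices;
  site-specific rate posteriors would sharpen the expectations slightly.
* Joint (rather than marginal) ancestral reconstruction is not
  implemented; marginal best states can in principle form a jointly
  suboptimal sequence.
* The free-ratio model's per-branch omegas on very short branches are
  weakly identified, as in any CODEML-style analysis.
* Exhaustive topology search is not provided; the package evaluates and
  compares fixed candidate topologies (random-topology null sets aside),
  by design.
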