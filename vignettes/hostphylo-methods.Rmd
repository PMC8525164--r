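---
title: "hostphylo: models, defaults and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hostphylo: models, defaults and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hostphylo` analyses the evolution of host-plant use on insect phylogenies:
host-breadth bookkeeping, phylogenetic signal, a randomized source-host
regression of host sharing on host phylogenetic distance, and ancestral
host-range reconstruction under DEC\*. This vignette is the package's
account of those methods: the models and their assumptions, the parameters
that matter and their defaults, what the synthetic-data generators do and
do not emulate, and the numerical and design choices a maintainer should
know about.

## Data model and preprocessing

The curated input is a table of records `(fly_species, host_species,
host_genus, host_family)` with an optional per-record status. Name
handling is purely lexical (trimming, whitespace collapsing); synonym
resolution and taxonomic standardization must happen upstream. Records
flagged `excluded_doubtful` or `excluded_unidentified` are retained but
inert. Two consistency rules are enforced hard: a host species belongs to
exactly one genus and a genus to exactly one family, and duplicate
`(fly, host species)` pairs are collapsed with a message, because breadth
counts and the interaction matrix silently change meaning if either is
violated.

Host breadth is the number of distinct host families per fly; the binary
polyphagy partitions score a fly 1 when it feeds on *strictly more than*
2, 3 or 4 families. The strict inequality matters: it is what makes the
partition counts (e.g. 27/24/22 polyphages out of 37 at thresholds 2/3/4
in a study-scale system) reproducible from the breadth profile.

## Trees and the strict-clock chronogram

All trees are `ape` `phylo` objects. Patristic distances (path sums, in
million years on the host tree) and the Brownian covariance matrix
\(V\) (shared root-to-ancestor path lengths) come from the tree as-is.

`strict_clock_chronogram()` converts a phylogram to relative time under a
single global rate by minimizing \(\sum_b (\ell_b - r\,t_b)^2\) over node
ages and the rate \(r\), with ages parameterized as fractions of the
parent age so parent-older-than-child holds by construction rather than by
clamping. Under an equal-rates clock the smoothing term of
penalized-likelihood dating vanishes, so this weighted least-squares fit
is its deterministic equivalent; on data simulated under a clock it
recovers relative node ages to ~1e-6. Only relative ages are identified
— the root age defaults to 1 and absolute ages are user configuration —
which is sufficient for DEC\* because rates are estimated jointly with the
time scale. Initialization uses each node's maximum tip depth (exact on
clock-like input, hence idempotence on ultrametric trees); optimization is
BFGS on logit-transformed fractions with a relative tolerance of 1e-14.

## Phylogenetic signal

Blomberg's K and Pagel's λ are implemented from their defining GLS/ML
algebra (see the README for the formulas) and cross-checked in the test
suite against an independent implementation (`phytools::phylosig`), which
is used only as an oracle, never as the engine.

Choices that matter:

* **Binary traits.** The polyphagy partitions are 0/1 characters analysed
  with the continuous-trait machinery, exactly as is common practice for
  signal screening; a warning marks the approximation. No
  threshold/liability model is provided.
* **λ search range.** λ is maximized over [0, 1], not up to the algebraic
  maximum; empirical binary partitions routinely sit at the λ = 1
  boundary, and both endpoints are evaluated explicitly so boundary optima
  are exact. The LRT against λ = 0 uses χ² with 1 df, one-sided; it is
  conservative at the boundary, so its realized type-I rate runs below
  the nominal 5% (the suite allows up to 7%).
* **Permutation p-value.** The K test uses the add-one estimator
  `p = (1 + #{K_perm ≥ K_obs})/(1 + n_perm)` (valid p > 0, one-sided
  toward high signal), default `n_perm = 10000`; identical seeds give
  identical p.
* **Degenerate inputs.** Constant traits are rejected. Zero-length
  terminal branches (possible after polytomy resolution) are jittered by
  1e-8 × tree height before inverting V, with a warning. A tree whose
  internal branches are all zero makes the likelihood flat in λ; this is
  detected (off-diagonal V numerically zero) and reported as
  `flat = TRUE` with `lambda = NA` instead of an arbitrary estimate.

## The host-sharing regression

Each run selects, for every fly with at least `min_hosts = 3` host genera,
one of its hosts uniformly as the source; every *other* genus in the
interaction matrix becomes a target row (response = attacked or not,
predictor = log10(patristic distance from source + 1), distance in Myr,
no rescaling). The target pool is the full set of genera attacked by at
least one fly: a pool restricted to each fly's own hosts would contain no
0-responses and the model would be unidentifiable. One pooled ML logistic
fit per run (base R IRLS, convergence tightened to 1e-10, 100-iteration
cap); runs showing separation or non-convergence are flagged and excluded
from pooling. Coefficients are averaged over the (default 1,000) runs and
intervals are 2.5/97.5 percentiles of the run-level coefficients — the
percentile convention is recorded in the output metadata. A per-fly
variant (separate regressions averaged) is deliberately not the default
because a single global equation is the quantity of interest.

**A caution on what the run-average estimates.** The randomized-source
procedure does *not* consistently estimate the slope of a generative model
in which each fly's attack probability decays with distance from a single
"seed" host. In the package's own validation, data simulated with slope
−1.5 (30 flies, 500 genera) are recovered attenuated — pooled slopes
between roughly −0.2 and −0.9 depending on the baseline rate and host-tree
shape — because host sets inevitably include genera far from the seed
(over a realistic distance range the attack-odds span, e^{|β1|·Δx} ≈ 40,
cannot dominate the ~50:1 far:near genus count ratio), and a source drawn
far from the seed contributes low-distance rows whose responses carry no
distance information. The fitted equation should therefore be read as a
descriptive summary of distance decay from *observed* hosts, not as an
estimate of a seed-based generative slope. The null case is well behaved:
with distance-independent associations the run-level slope distribution
centres on zero and its 95% interval covers zero in ≥ 90% of simulated
systems.

## DEC\*

The state space is every non-empty subset of the chosen host families up
to `max_size` (default: all of them — 511 states for 9 families), ordered
by size then lexicographically; the family count is capped at 12. The
anagenetic generator gains one family at rate *d* and loses one at rate
*e*, except that single-family ranges cannot be lost (DEC\* removes the
null range entirely rather than making it absorbing). Cladogenesis from a
multi-family range enumerates subset sympatry (one daughter a single
constituent family, the other the full range) and vicariance (one
daughter a single family, the other the remainder) in both daughter
orders, merges duplicates, and puts uniform probability on the distinct
ordered pairs; single-family ranges are inherited identically. Widespread
full sympatry and founder-event (+J) dispersal are excluded.

* **Likelihood.** Felsenstein pruning with per-node rescaling and
  accumulated log-scalers. Branch propagation uses the action of the
  matrix exponential on the partial vector: an eigendecomposition of the
  generator, computed once per parameter value and reused across branches,
  for state spaces up to 200 states (verified by reconstruction error,
  with automatic fallback), and otherwise uniformization on the sparse
  generator with the Poisson series truncated at tail mass 1e-14. The
  public `transition_probabilities()` is an independent dense matrix
  exponential; agreement of the two engines is exercised by the
  enumeration oracle in the tests, which reproduces pruning log-likelihoods
  and node marginals to < 1e-8 (in practice ~1e-14) on 4-tip instances.
* **Root prior.** Uniform over all allowed states by default, with a
  FitzJohn-style likelihood weighting (`"fitzjohn"`) as the alternative;
  which prior the original biogeography tooling uses in any given run is
  configuration there too, so both are exposed and the default documented.
* **Rate estimation.** Bounded L-BFGS-B on (log d, log e) in
  [1e-9, 10], three deterministic starts scaled by tree height; the best
  local fit is kept and bound-touching estimates are flagged, not
  rejected (tips that are all identical singletons legitimately drive
  d to the lower bound).
* **Ancestral states.** Marginal probabilities for the state *just before*
  each node's split, from below-partials combined through the
  cladogenesis table and above-partials propagated through the transposed
  propagator. Post-split corner states are not reported — one unambiguous
  per-node quantity. Ties in the most-probable state break to the lowest
  state index.
* **Tip ranges.** Diets are intersected with the selected main families;
  flies whose diet intersects none of them cannot enter (the null range is
  not a state), so the pipeline drops them with a log line. Trees must be
  binary (resolve polytomies first — zero-length resolution branches are
  handled) and ultrametric at relative tolerance 1e-6.

## What the generators emulate — and what they do not

`simulate_association_system()` builds a host-genus Yule chronogram
(rescaled to a root age of 150 Myr, an angiosperm-like depth, so patristic
distances are in realistic Myr), groups genera into families by cutting
the tree at the age where exactly the requested number of lineages exist,
expands genera into Poisson-sized species pools (mean ≈ 2.5 species per
genus), and lets each fly attack genera with probability
`plogis(beta0 + beta1 · log10(d + 1))` around a uniformly drawn seed
genus; defaults `beta0 = 1.7962`, `beta1 = −1.6633` mirror the scale of
empirically reported sharing equations. An optional breadth profile pins
the study-scale marginal structure — 8 monophages (confined to the seed's
family), 11 extreme polyphages (topped up to ≥ 20 families), the
remaining flies capped below the extreme floor by keeping the families
closest to their seed.

What this deliberately does not emulate: real taxonomy or host names;
phylogenetic conservatism of host use *on the fly tree* (seed genera are
independent across flies, so synthetic signal tables are expected to show
weak signal except as induced by the breadth classes); sampling biases of
pest-oriented databases; and — as discussed above — a generative process
whose slope the randomized-source regression would recover exactly.
Passing tests therefore demonstrate engine correctness and calibration,
not that real association data meet these models' assumptions.

`simulate_dec_history()` is an exact Gillespie implementation of the DEC\*
process (root drawn from the uniform prior, per-branch jump process,
cladogenetic draw at each node) and is validated against the transition
matrices (single-branch state frequencies within 2% over 10,000 draws).

## Validation design and problem sizes

The suite validates each claim at a deliberate scale: K calibration uses
500 Brownian simulations on 100-tip trees (mean K within [0.85, 1.15]);
λ boundary recovery uses 100 replicates at 200 tips (≥ 90% at each
boundary); test sizing (uniformity of permutation p-values, LRT type-I)
uses 200 replicates; DEC\* engine correctness uses 100 random parameter
draws against exhaustive enumeration at 1e-8; DEC\* rate recovery uses 50
forward simulations on 100-tip, height-10 chronograms with 4 families at
d = 0.05, e = 0.02 (factor-of-2 recovery; with these conditions the
realized rate sits near the 80% design target — the misses are interior
ML optima whose likelihood exceeds the truth's, i.e. honest sampling
spread, not optimizer failure). Root-state recovery uses the low-rate
regime d = 0.002, e = 0.001 (≈ 0.06 expected gains per root-to-tip path):
"low-rate" is the parsimony limit in which the modal marginal root state
should match the simulated root, and at appreciably higher rates (≈ 9
events tree-wide) it demonstrably does not — that regime tests nothing.

## Known limitations

* No phylogenetic correlation structure on flies in the sharing
  regression (rows are treated as independent within a run).
* Signal statistics treat 0/1 characters as Gaussian; use a
  threshold-model implementation if calibrated binary inference matters.
* DEC\* excludes +J founder events and time-stratified dispersal; ranges
  over more than 12 families are refused rather than approximated.
* The chronogram fit assumes a strict clock; no relaxed-clock or
  fossil-calibration support.
* Name handling is lexical only — synonymy must be resolved upstream.
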