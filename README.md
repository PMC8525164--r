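# hostphylo

Phylogenetic analysis of insect–host-plant associations in R.

Herbivorous insect lineages — the motivating system is the Dacini fruit
flies (*Bactrocera*, *Dacus*, *Zeugodacus*), whose larvae develop in fruit
and flower structures across hundreds of plant genera — vary enormously in
host breadth, from strict monophages to species attacking more than twenty
plant families. `hostphylo` provides a tested pipeline for asking, from a
curated fly × host association table plus fly and host phylogenies:

1. **Is host breadth phylogenetically conserved?** Host breadth (the number
   of host families used) is analysed both as a continuous character and as
   binary polyphagy partitions ("feeds on more than 2 / 3 / 4 families"),
   with two standard signal statistics computed on the insect tree.
2. **Does host phylogeny predict host sharing?** A randomized source-host
   logistic regression estimates how the probability that a host genus is
   attacked decays with its phylogenetic distance from a known host.
3. **What were the ancestral host families?** Maximum-likelihood ancestral
   host-range reconstruction under DEC\* — the
   dispersal–extinction–cladogenesis model with the null range disallowed —
   on a strict-clock chronogram of the insect tree.

A synthetic-data module generates association systems, trait data and DEC\*
range histories with known ground truth, so every stage is validated
without any external database.

## The statistics

**Blomberg's K** compares the trait variance taken at face value with the
variance after correcting for phylogenetic covariance. With tip values
\(y\), phylogenetic covariance matrix \(V\) (shared root-to-ancestor path
lengths) and GLS mean \(\hat a = (1^T V^{-1} y)/(1^T V^{-1} 1)\),

    K = [ MSE0 / MSE ] / E[MSE0/MSE | BM],
    MSE0 = (y - â1)'(y - â1)/(n-1),   MSE = (y - â1)' V⁻¹ (y - â1)/(n-1),
    E[MSE0/MSE | BM] = [tr(V) - n/(1'V⁻¹1)] / (n-1)

so K is calibrated to 1 under Brownian motion; K ≈ 0 means phylogenetic
independence. Significance comes from randomizing tip values
(`p = (1 + #{K_perm ≥ K_obs}) / (1 + n_perm)`).

**Pagel's λ** multiplies the off-diagonal of \(V\) by λ ∈ [0, 1] and
maximizes the multivariate-normal likelihood of the trait (mean and rate
profiled out analytically); λ̂ = 1 is Brownian structure, λ̂ = 0 a star
phylogeny. The test is a one-sided likelihood ratio against λ = 0 on one
degree of freedom.

**Host sharing.** Associations are compiled as a binary fly × host-genus
matrix. For each fly with ≥ 3 host genera, one host is drawn uniformly as
the *source*; every other genus becomes a row with response 1 if attacked
and predictor `x = log10(phylodistance + 1)`, distance in million years
from the source on the host chronogram. One pooled logistic fit

    logit(S) = β0 + β1 · log10(phylodistance + 1)

per run, 1,000 runs with fresh sources; reported coefficients are means
across runs with 2.5/97.5-percentile intervals, and
`Prob = exp(logit S)/(1 + exp(logit S))` gives the sharing-probability
curve.

**DEC\*.** Host ranges are non-empty subsets of the main host families
(at most 12; all 511 subsets of 9 families by default). Along branches a
CTMC gains families at rate *d* per family and loses them at rate *e*
(never below one family — the null range is disallowed). At speciation the
range is partitioned by subset sympatry or vicariance, uniformly over the
distinct ordered daughter pairs; widespread sympatry and founder-event
jumps are excluded. The likelihood is computed by Felsenstein pruning with
cladogenetic mixing, (d, e) are estimated by bounded ML, and per-node
marginal state probabilities are reported for the state just before each
split.

## Worked example

```r
library(hostphylo)

# a study-scale synthetic system: 37 flies, 286 host genera, 87 families,
# with 8 monophages and 11 extreme polyphages pinned
sys <- simulate_association_system(
  breadth_profile = list(n_monophages = 8, n_extreme = 11,
                         extreme_min_families = 20),
  seed = 2024)

prof <- host_breadth(sys$table)
sum(prof$n_host_families == 1)   # 8 monophagous flies  (21.62%)
sum(prof$n_host_families >= 20)  # 11 extreme polyphages (29.73%)

# randomized source-host regression against host phylogenetic distance
fit <- resample_regression(interaction_matrix(sys$table),
                           patristic_distances(sys$host_tree),
                           n_runs = 200, seed = 7)
fit
#> Host-sharing regression over 200 runs (32 flies):
#>   logit(S) = 0.4879 -1.3076 * log10(distance + 1)
#>   95% interval beta0: [-0.4031, 1.3331]  beta1: [-1.6664, -0.9320]
sharing_probability(fit, 10)     # 0.294: sharing probability at 10 Myr

# phylogenetic signal of a Brownian trait on a 37-tip tree
tr <- simulate_yule_tree(37, 1, seed = 99)
y  <- simulate_bm_trait(tr, 1, seed = 100)
blomberg_k_test(tr, y, n_perm = 1000, seed = 101)
#> blomberg_K: statistic = 0.5358, p = 0.000999 (n = 37)
pagel_lambda(tr, y)
#> Pagel's lambda = 1.0000 (logL -36.8668; logL0 -46.3431)
```

The negative slope says sharing probability declines with host distance;
the λ̂ = 1 fit recovers the Brownian structure the trait was simulated
under. The full pipeline — breadth profile, signal table, sharing
regression, chronogram, DEC\* reconstruction, each stage serialized with a
MANIFEST — runs from one config:

```r
run_pipeline(pipeline_preset("dacini", seed = 1), output_dir = "out/")
```

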