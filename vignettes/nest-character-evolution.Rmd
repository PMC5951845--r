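---
title: "Models and methods: nest-character evolution on family phylogenies"
author: "nestevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nest-character evolution on family phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Bird nests can be described along three largely independent dimensions: the
**structure** of the nest (seven states, from a bare scrape to cavities and
domed constructions), the **site** where it is placed (seven states, from the
ground to trees, cliffs and termite mounds), and the **attachment** approach
fixing it to its support (four states, with basal support overwhelmingly the
most common). At the family level these characters are naturally *set-valued*:
a family may contain species with different states (a polymorphic family), and
some families — brood parasites and mound builders — build no characterizable
nest at all and enter every analysis as missing data.

`nestevo` implements the three inferential components such data call for:

1. **Ancestral-state reconstruction** of each character under a k-state Markov
   (Mk) model, with Bayesian MCMC integrated over a *set* of candidate trees;
2. **Correlated evolution** between pairs of binary-recoded characters
   (Pagel's dependent vs independent models) compared by Bayes factors from
   harmonic-mean marginal likelihoods;
3. **Phylogenetic signal** for multi-state, set-valued characters by
   conventional Mantel tests and evolutionary-model-based (EM-) Mantel tests
   built on Bray–Curtis dissimilarity.

A synthetic-data module generates every input the pipeline needs — trees, tree
sets, single and polymorphic discrete traits, and correlated binary pairs — so
all of the above is testable end to end without external data.

# The Mk model and its likelihood

A character with $k$ states evolves along each branch as a continuous-time
Markov chain with generator $Q$. The default, equal-rates (ER) variant sets
every off-diagonal entry to a single rate $q$ (expected transitions per unit
branch length), giving the closed-form transition probabilities

$$P_{\text{same}}(t) = \tfrac1k + \tfrac{k-1}{k} e^{-kqt}, \qquad
  P_{\text{diff}}(t) = \tfrac1k\left(1 - e^{-kqt}\right).$$

The all-rates-different (ARD) variant has $k(k-1)$ free rates and uses the
matrix exponential (one eigendecomposition per likelihood evaluation, shared
across branches, with a scaling-and-squaring fallback when $Q$ is defective).

`tree_log_likelihood()` is the standard pruning (post-order dynamic
programming) algorithm with per-node rescaling against underflow. Set-valued
tips enter as indicator vectors: a polymorphic family contributes a 1 for each
observed state (the likelihood sums over them), and a missing family is an
all-ones vector that carries no information. The root partial is combined with
the root prior, uniform by default — the model is symmetric under ER and no
stationary argument favours any state; the prior is configurable for users
with external information.

# Bayesian sampling over a tree set

`mcmc_sample()` runs Metropolis–Hastings on the log-rates with independent
exponential priors (mean 0.1 by default — a weakly informative choice that
keeps rates positive and of the order of one transition per tree depth).
Proposals are symmetric sliding windows on the log scale; their width is
auto-adjusted every 100 iterations *during burn-in only*, multiplicatively,
until the empirical acceptance fraction sits in the 20–40% band, and is frozen
afterwards so that detailed balance holds for every retained sample.
Post-burn-in acceptance is reported per chain and a warning (not an error) is
raised if it leaves the band.

Uncertainty in the phylogeny is handled by treating the tree index as an
additional sampled parameter: each iteration proposes replacing the current
tree with one drawn uniformly from the supplied tree set and accepts by the
usual ratio. The posterior thus integrates over the tree set instead of
running a separate analysis per tree; clade-level summaries then naturally
carry a *support* weight (the fraction of retained samples whose tree contains
the clade).

Convergence is assessed programmatically rather than by inspecting trend
lines: `effective_sample_size()` implements the initial-positive-sequence
autocorrelation estimator and `convergence_diagnostic()` the split-chain
$\hat R$; the pipeline's gate is $\hat R < 1.05$ with ESS above 500 at
full-scale settings.

Iteration counts are configuration, not constants. The `"desk"` profile
(20,000 iterations, 5,000 burn-in, thinning 30, three chains) is sized for
interactive work and the test suite; the `"paper"` and `"paper_discrete"`
profiles reproduce full-scale analyses (20M/2M/10k and 200M/20M/10k) and
differ only in those numbers.

## Ancestral states

`reconstruct_ancestral_states()` computes, for every retained sample, the
marginal state probabilities at the most recent common ancestor of each
monitored tip set on *that sample's tree* (the standard up-down pass), and
averages over the samples in which the tip set is monophyletic. Monitored
clades default to the clades of the majority-rule consensus tree. Mapping
clades by MRCA-of-tip-set was chosen over restricting to the consensus
topology because it uses every sample and degrades gracefully when a clade is
present in only part of the tree set; the per-clade support makes that
weighting explicit.

`consensus_tree()` builds the majority-rule topology and fits branch lengths
by non-negative least squares to the mean patristic distance matrix of the
set (`phangorn::nnls.tree`); when every input tree is ultrametric the
ultrametric constraint is used, which makes branch lengths exactly
recoverable on an identical-tree set, otherwise the unrooted fit is used
(tip-to-tip distances cannot separate the two root-adjacent branches).

# Correlated evolution of binary characters

Multi-state characters are first recoded to binary with
`binary_recode()`: the ancestral category is a stated subset of the
vocabulary, and a family whose set contains *any* state outside it is coded
as the derived category — a polymorphic family straddling both categories is
assigned the later-derived state, consistent with reconstructing the derived
state as the more recent acquisition. The three canonical case studies
(scrape×ground, cup×non-tree-vegetation, cup-or-dome×non-basal) ship as
presets in `nest_recode_presets()`.

The joint state of two binary traits evolves over $\{00, 01, 10, 11\}$.
The *independent* model has four rates (each trait's gain and loss,
insensitive to the other trait); the *dependent* model has eight
context-dependent rates; simultaneous double transitions are structurally
zero in both. Four free rates for the independent model follow the classical
Discrete parameterization. Fitting reuses the same MH engine on the joint
four-state pruning likelihood, with tips missing one trait entering as
indicators over the compatible joint states.

Models are compared with $\mathrm{BF} = 2(\ln \mathrm{ML}_{\text{dep}} -
\ln \mathrm{ML}_{\text{indep}})$, where each marginal likelihood is the
harmonic mean of the sampled likelihoods computed stably in log space.
The harmonic-mean estimator is retained as the default because the
conventional decision rule (BF > 5 = strong support) is defined with it; its
high variance is a known limitation, which is why the package's calibration
experiments check the *sign and threshold* behaviour (strong-dependence
simulations must cross 5, independence simulations must not) rather than any
exact BF value. `transition_asymmetry()` summarizes directionality as
posterior probabilities of rate orderings, e.g. $\Pr[q_{34} > q_{12}]$ (the
gain of B is contingent on A being derived).

# Phylogenetic signal for set-valued characters

Trait dissimilarity between two families with state sets $A$ and $B$ is the
presence/absence Bray–Curtis value $1 - 2|A \cap B| / (|A| + |B|)$, which is
0 for identical sets, 1 for disjoint sets, and reduces to the 0/1 mismatch
metric on singletons. Phylogenetic distance is the patristic distance on the
majority-rule consensus tree (averaging patristic matrices over the tree set
changes nothing qualitative in the synthetic experiments and a flag-level
switch was judged not worth the interface surface; the consensus choice is
recorded here as the package's convention). Families with missing data are
dropped from both matrices before any test.

The **conventional Mantel test** permutes taxon labels (joint row/column
permutation of the trait matrix) and locates the empirical upper-triangle
Pearson correlation $r$ in the permutation null. P-values carry the add-one
correction, and the two-sided p doubles the smaller tail — both directions
are scientifically meaningful here, since a character can be *more* similar
among relatives than chance (conservatism) or, as nest attachment shows,
*less*.

The **EM-Mantel test** replaces the permutation null with a neutral-evolution
null: each replicate simulates the character on the tree under the fitted Mk
model (posterior-mean rate, MAP root state — point estimates, matching the
convention of driving the null with the values the Bayesian analysis
estimated), converts tips to singleton sets, and recomputes $r$. Simulated
traits are singletons by design: the neutral model produces one state per
tip, and within-family polymorphism has no generative model to draw on;
empirical polymorphism enters only through the empirical Bray–Curtis matrix.
Monomorphic simulated replicates have an undefined $r$ and are dropped with
a warning (they are logged and the p-value denominator shrinks accordingly).

# What the synthetic data emulate — and what they do not

`make_demo_dataset()` produces the study-shaped inputs: 242 families, a
pure-birth (Yule) base tree, and a tree set obtained by random NNI moves plus
multiplicative log-normal branch-length jitter (mean-one, so expected lengths
are preserved; ultrametricity is deliberately *not* restored, since none of
the methods relies on it). A clade containing ~45% of families plays the role
of the passerines. Structure and site are simulated under ER models rooted at
scrape and ground, with the rate solved from the closed form so that the root
state is retained by roughly one fifth of families at the tree height —
matching the reported scrape frequency. Attachment is allocated by exact
counts — 80% of characterizable families exclusively basal, 10% basal plus
another approach, 10% non-basal — with non-basal records placed inside the
passerine clade, because that character's distribution (near-fixation of
basal, derived approaches confined to passerines) is a reported pattern, not
the outcome of a symmetric-rates process. Six families are flagged missing
(brood parasites, a mound builder, no data). A species-level table allocates
10,978 species across the 242 families (skewed gamma weights,
largest-remainder rounding; the mean of 45 species per family is what
motivates the 50-species cap in the effective-state rule).

The generator does **not** emulate: unequal (ARD-like) preferences among
derived states, so "cup is the most common structure" arises only by chance;
correlated evolution among the three characters; rate variation across
lineages; or any taxonomy-driven structure in the species table. Passing
tests therefore demonstrate the *machinery* — likelihoods, samplers,
estimators, test calibration — under the stated generating conditions, not
the empirical claims about real birds.

## Calibration experiment sizes

The packaged experiments are sized for a single CPU: 200-tip trees for rate
recovery (20 replicates; 95% credible intervals must cover the simulating
rate in at least 18), Bayes-factor calibration with 20 replicates per regime,
and Mantel type-I calibration with 200 datasets of 199 replicates each.
Strong dependence is planted as "B gains essentially only after A is
derived" ($q_{12} = 0.01$ vs $q_{34} = 0.5$, with the other rates moderate)
— the sharply identifiable form of contingency, mirroring the empirical case
of non-basal attachment arising only in cup/dome lineages. The
hyper-conservatism experiment compares a trait simulated at $q/50$ against a
neutral null at $q = 2$ on a 200-tip unit-rate tree: at that rate the
neutral trait fully mixes over the tree depth (the regime where conventional
and EM nulls coincide), while the 50× slower trait keeps clade-structured
states, so its Mantel correlation exceeds the null mean. At much smaller
neutral rates the slowed trait degenerates to one or two isolated changes
and carries no detectable signal — a boundary worth remembering when
interpreting EM-Mantel results on very conserved real characters.

# Numerical choices

* Per-node rescaling in the pruning pass; log-scale accumulation everywhere.
* ER transition probabilities use the closed form (exact to machine
  precision against an independent matrix exponential); ARD and Pagel
  generators use one eigendecomposition per evaluation with an `expmat`
  fallback guarded by a reconstruction-error check.
* Harmonic means via log-sum-exp; the estimator is translation-equivariant
  in log space by construction.
* The ESS estimator truncates at the first non-positive autocorrelation
  pair and is capped at the sample size; constant series raise an error
  rather than returning a misleading number, as does split-$\hat R$ on
  constant or single chains.
* All randomness flows through explicit seeds; sub-seeds for chains and
  pipeline stages are derived with a fixed integer recurrence, so reruns are
  byte-identical and no global RNG state leaks.
* Ties in `derive_effective_states()` down-sampling are broken by sorting
  genera lexicographically and shuffling species within genus under the
  seed, making the rule invariant to input row order.

# Known limitations

* The harmonic-mean marginal likelihood is high-variance; Bayes factors
  near the threshold of 5 should be treated as inconclusive. A
  stepping-stone estimator would be the natural upgrade.
* The tree-index move resamples uniformly; for very large tree sets a
  locally weighted proposal would mix faster.
* EM-Mantel uses point estimates of rate and root state; an option to draw
  from the posterior per replicate would propagate that uncertainty.
* The effective-state rule implements the strict >10% thresholding, but a
  percentage's denominator (all families vs characterizable
  families) is ambiguous at the rounding level; both are available via
  `state_frequencies(denominator =)`.
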