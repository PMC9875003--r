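---
title: "Optimising budget-constrained breeding schemes with Gaussian-process surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimising budget-constrained breeding schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedopt)
```

## The problem

A genomic-selection breeding campaign turns a fixed budget $B$ into genetic
gain over $n_{gen}$ selection cycles. Two activities compete for that
budget: phenotyping (cost $C_p$ per plot) buys training data for the marker
prediction model, and creating new genotyped individuals (cost $C_n$ each)
buys selection opportunity. Given the constraints
$(B, C_p, C_n, n_{gen}, \mathrm{Pop}_{init})$, four decision variables
remain in the breeder's hands:

* `i_init` — the fraction of the founder generation retained as parents;
* `i` — the retained fraction in every later generation;
* `B_rep` — the fraction of $B$ spent on creating new individuals
  (the rest buys plots);
* `pheno_p` — the phenotyping period: trials happen at generation 1 and
  then every `pheno_p` generations.

The objective $u$ is the mean *true* genotypic value of the final
generation, $u = f(z) + \epsilon$, a stochastic quantity because meiosis,
plot errors and the various random allocations all perturb a campaign.
`breedopt` simulates this campaign exactly and maximises
$g(z) = E[u \mid z]$ over $z = (i_{init}, i, B_{rep}, pheno_p)$ with a
Gaussian-process surrogate, benchmarked against random search at the same
evaluation budget.

## The simulation model

### Founders, genome, trait

Founders are fully homozygous diploids (an inbred panel). The synthetic
generator (`simulate_founders()`) emulates a soybean-like setup: 20
chromosomes, each 1 Morgan, markers placed uniformly at random, and a
per-marker alt-allele frequency drawn from a uniform law on $[0.05, 0.5]$;
each founder is independently homozygous-alt with that probability.
Markers are generated without linkage disequilibrium — the source panel's
LD structure is deliberately not modelled (no founder LD model is stated
for the real panel; the flag is configurable via `maf_law` only in the
frequency dimension). Real panels can be read from a CSV dosage matrix or
a VCF plus a physical map; Morgan positions are a linear rescaling of
physical positions per chromosome.

The trait has $n_{qtn}$ causal markers drawn uniformly among the
$n_{snp}$; each effect is $\beta_m = a_m I_m$ with $a_m \sim Exp(1)$ and
$I_m = \pm 1$ equiprobably. Phenotypes are
$y_{sr} = G_s\beta + e_{sr}$, $e_{sr} \sim N(0, \sigma_e^2)$, with $G_s$
the 0/1/2 dosage vector. $\sigma_e^2$ is calibrated once on the founders
from the target initial heritability,
$\sigma_e^2 = \widehat{Var}(G_0\beta)(1/H_0^2 - 1)$ (n−1 sample
variance), and then frozen: later generations' realised heritability
floats as genetic variance erodes, which is the intended behaviour.

### Meiosis

Gametes are simulated without interference: the crossover count per
chromosome is Poisson with rate equal to the map length in Morgans,
positions are i.i.d. uniform, and the copied strand alternates at each
crossover, starting from a fair strand choice. Recombination fractions
therefore follow the Haldane map function $r = (1 - e^{-2d})/2$, which the
test suite verifies empirically. A marker lying exactly on a crossover
position (a measure-zero event) deterministically starts the next
segment; duplicate crossover positions are kept as zero-length segments.
The inner loop is compiled (Rcpp) but consumes R's RNG stream in exactly
the order of the pure-R reference path, so both produce bit-identical
gametes from the same seed — the tests assert this.

### Resource derivation

From $(B, C_p, C_n, n_{gen})$ and the decision variables:
$n_{new}^{tot} = \mathrm{round}(B \cdot B_{rep} / C_n)$ (halves up) and
$n_P^{tot} = \lfloor (B - n_{new}^{tot} C_n)/C_p \rfloor$. The effective
spend $B_{eff} = n_{new}^{tot} C_n + n_P^{tot} C_p$ satisfies
$B_{eff} \le B$ and $B - B_{eff} < C_p$ for every valid input (a tested
property). Plots are split evenly over the phenotyping generations
$\{1, 1 + pheno_p, \dots\}$ with the integer remainder scattered at
random, then $n_{P,1}$ is raised to 3 if smaller so the first prediction
model can always be fitted — this raise may exceed $n_P^{tot}$ by up to
3 plots and is the one place where the per-generation sum can differ from
the campaign total. Because founders are homozygous, repeating a
generation-1 cross would clone the same offspring, so generation 1
creates exactly one offspring per cross and the remaining
$n_{new}^{tot} - n_{C,1}$ individuals are split evenly over later
generations.

"Round to nearest" is implemented as half-away-from-zero everywhere,
never banker's rounding; `floor`/`ceiling` appear only where the
derivation explicitly calls for them.

### Prediction, selection, mating

At each phenotyping generation the marker model is refitted by ridge
regression of all plot records accumulated since generation 1 on centred
dosages with an unpenalised intercept. The penalty is not specified by
the procedure the package reproduces; we choose it by generalized
cross-validation on a 60-point log-spaced grid, computed from one
eigendecomposition of the weighted normal equations (replicated records
enter as duplicated rows via record weights — identical normal
equations, verified against a dense duplicated-row oracle). Degenerate
training sets (constant phenotypes) return a zero-effect model rather
than failing.

Selection keeps the `n_selected()` individuals with the highest
predicted values, ties broken by id for reproducibility. Parents are
mated by genetic distance: with $n_S \ge 4$ a travelling-salesperson
tour minimises the cycle's summed *inverse* effect-weighted Euclidean
distances (so consecutive mates are distant); each consecutive couple
plus the wrap-around is one cross. Tours are exact by enumeration up to
8 parents and greedy + 2-opt above (the 2-opt uses O(1) delta
evaluation; greedy construction is capped at 32 starts). Zero distances
between clonal parents are clamped at $10^{-12}$ so the tour avoids
adjacent clones. With 2–3 parents all pairs are crossed; a single parent
is selfed.

## The optimiser

The surrogate is a kriging model with constant mean and Gaussian kernel
$k(z, z') = \sigma^2 \exp(-d^2/2\theta^2)$, $d$ the Euclidean distance
between inputs min–max scaled to the unit hypercube. Because the
objective is stochastic, a relative nugget $g$ (observation noise
$\sigma^2 g$) is estimated jointly with $\theta$ by maximum marginal
likelihood (coarse grid then L-BFGS-B); $\sigma^2$ and the mean are
profiled out analytically. Noiseless interpolation of a noisy objective
destabilises expected improvement, which is why the nugget is estimated
rather than fixed at zero.

Acquisition is expected improvement
$EI(z) = E[\max(0, g(z) - \hat g_{max})]$ with the incumbent
$\hat g_{max}$ defined as the maximum *posterior mean* over the training
inputs (not the maximum observed value — the distinction matters under
noise). Batches of $q$ points use the constant-liar strategy: after each
proposal the model is updated (hyperparameters fixed within the batch)
with the lie $L = g_{min}$, the worst observed value, before the next EI
maximisation. Proposals closer than `filter_tol` ($10^{-3}$, scaled
units) to an existing training point are replaced by a random point to
avoid resampling. EI is maximised by focus search: repeated uniform
sampling in a box that halves around the incumbent each round (defaults
5 restarts × 3 rounds × 1000 points; integer dimensions never shrink
below one unit).

`pheno_p` is handled as a continuous GP dimension and rounded to an
integer at the objective interface and for filtering; the Gaussian
kernel assumes continuity and rounding at the boundary is the least
intrusive treatment.

A run evaluates 5 Latin-hypercube points, then `n_iter` iterations of
fit → propose `q` → evaluate (each evaluation gets its own derived seed,
so evaluation order cannot affect results). The recommendation is the
visited point with the highest posterior mean under the final model. The
random baseline draws points uniformly, padding its first iteration with
5 extra points so both methods spend exactly $5 + n_{iter} q$
evaluations; its recommendation is the best *observed* point. Failed
objective evaluations are recorded and replaced by a random point; runs
continue.

Default bounds (configurable): $i_{init}, i \in [0.01, 0.9]$,
$B_{rep} \in [0.05, 0.95]$, $pheno_p \in \{1, \dots, n_{gen}\}$. No
bounds are prescribed by the procedure being reproduced; these span all
qualitatively distinct schemes while excluding the degenerate
zero-selection corners.

## Evaluation designs

`run_experiment()` reproduces the two benchmark designs over the eight
scenarios ($H^2 \in \{0.3, 0.7\}$, $n_{gen} \in \{5, 10\}$,
$B \in \{200, 600\} \times n_{gen}$, $C_p = C_n = 1$): a thorough batch
(16 runs × 50 iterations × q = 8, 32 post-optimisation evaluation
campaigns, comparison between each method's *representative* run — the
one whose cumulative-maxima curve is closest in MSE to the across-run
average) and a pragmatic batch (~1024 runs × 15 iterations × q = 2, one
evaluation campaign per run, all cross-method pairs compared). Both are
parameterised, so desk-scale versions run in minutes. Pairing: run $k$
of both methods shares the founder/trait seed but not the optimiser
seed, which reduces founder-panel variance without changing either
method's marginal behaviour. Win proportions count strict wins over all
ordered pairs; ties are non-wins.

## What the synthetic world does and does not establish

The generator reproduces the stated panel geometry (homozygous founders,
20 × 1-Morgan chromosomes, uniform marker placement, configurable
frequency spectrum) but **not** linkage disequilibrium, population
structure, or the empirical frequency spectrum of a real panel. Two
consequences matter for interpreting green tests:

* Ridge prediction accuracy on LD-free markers is information-limited
  when the training set is smaller than the marker count: with 200
  noiseless records and 500 independent markers the attainable held-out
  rank correlation is about 0.4 (confirmed against glmnet and dense
  oracles), far below what real panels with LD exhibit. Tests therefore
  check exact agreement with dense oracles in that regime and
  near-perfect ranking only in the overdetermined regime.
* Absolute objective values are panel- and architecture-specific; only
  relative comparisons (Bayesian vs random at equal budget) transfer.

## Numerical choices

* Rounding: half-away-from-zero for "nearest"; documented floor/ceil
  elsewhere. Integer splitting always scatters remainders uniformly at
  random without replacement.
* GP jitter $10^{-10}$ on the correlation diagonal; posterior variances
  clamped at 0.
* Ridge GCV grid $10^{-4} \dots 10^8$ (60 points); degrees of freedom
  include the intercept.
* TSP inverse distances clamp $d \ge 10^{-12}$.
* All seeds are 32-bit; every derived seed pool is drawn through R's RNG
  from the user seed, making campaigns, runs and experiments bit
  reproducible.

## Known limitations

Single trait, purely additive architecture (no dominance, epistasis,
G×E, year/location effects); one selection criterion and one mating
design; non-overlapping generations; founder LD not modelled; YAML
configs are not supported (JSON only). The optimiser's focus-search
effort and GP bounds are heuristics chosen for a 4-dimensional space and
would need revisiting for higher-dimensional schemes.
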