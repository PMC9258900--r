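---
title: "Distilling pairwise models from generative protein sequence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling pairwise models from generative protein sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwdistill)
```

## The problem

Generative models of protein families assign a probability $p(s)$ to every
aligned sequence $s = (s_1, \dots, s_N)$ over $q = 21$ symbols (20 amino
acids plus the alignment gap).  Neural architectures — here an
autoregressive model with exact likelihood and a one-hidden-layer
variational autoencoder (VAE) — can in principle capture interactions of any
order among positions.  A recurring question is how much of what they learn
actually *is* higher-order, and how much is captured by the two classical
families: **independent (profile) models**, whose log probability is a sum
of single-position terms, and **pairwise (Potts) models**, which add
position-pair couplings.

`pwdistill` answers this operationally.  Viewing any model as an
energy-based model with $E(s) = -\log p(s)$ (up to a constant), it fits a
pairwise energy
$$E^{pw}(s) = -\sum_{i<j} J_{ij}(s_i, s_j) - \sum_i h_i(s_i) - C$$
to the original model's energies by minimizing
$$\mathcal{L}(J, h, C) = \mathbb{E}_{s \sim D}\left[(E^{M}(s) -
E^{pw}(s))^2\right],$$
where $D$ is either the uniform distribution $U$ over all $q^N$ sequences or
the original model's own distribution $M$.  The independent family is the
same fit with $J$ pinned at zero.  How well the distilled model reproduces
energies on held-out sequences, mutational-effect rankings and structural
couplings then quantifies how pairwise the original model really is — and
the choice of $D$ decides *where* in sequence space the approximation is
asked to be good.

## Interaction expansions and gauge freedom

Any energy over fixed-length sequences expands as $E(s) = \sum_{L \subseteq
\{1..N\}} f_L(s_L)$ over position subsets $L$.  The expansion is not unique:
one can, for instance, stash the whole energy into the order-$N$ term
(`degenerate_expansion()` demonstrates this).  Uniqueness is restored by the
**zero-sum gauge**, in which every coefficient tensor sums to zero along
each amino-acid axis; this is the orthogonal decomposition under the uniform
measure and pushes as much mass as possible to low orders.
`mobius_zero_sum_expansion()` computes it by brute-force enumeration
(conditional means with lower orders subtracted recursively) and serves as
the package's central oracle: the uniform-distribution minimizer of
$\mathcal{L}$ is exactly the order-$\le 2$ truncation of this expansion, a
fact the test suite asserts on enumerable models.  Distilling under $D = M$
instead corresponds to reading off the pairwise part in a *different* gauge,
one adapted to the region of sequence space the model actually inhabits.

`to_zero_sum_gauge()` re-expresses a pairwise or independent model in this
gauge without changing any energy (coupling row/column means fold into the
fields, field means into the constant).  All extraction routes return their
result in the zero-sum gauge so parameters are comparable across routes and
models; the constant $C$ is kept explicit because distillation must match
energies, not just probabilities.

## The three extraction routes

1. **`extract_exact()`** (oracle): weighted least squares over the full
   enumeration.  The pairwise energy is linear in $(J, h, C)$ with binary
   features, so the minimizer solves the normal equations; gauge freedom
   makes the design rank-deficient and the minimum-norm (pseudo-inverse)
   solution is taken before gauge fixing.  Feasible only for small $q^N$;
   it is the reference every other route is tested against.
2. **`extract_uniform_closed_form()`**: the Monte-Carlo version of the
   uniform minimizer.  The constant is (minus) the grand mean energy of
   uniform samples, fields come from single-site conditional means,
   couplings from pair conditional means with lower-order terms subtracted.
   We implement the conditional-average form that provably matches the
   least-squares minimizer (verified against `extract_exact()` in tests);
   conditional cells never observed fall back to the grand mean, i.e. a
   zero coefficient.
3. **`extract_sgd()`**: the general protocol, required when $D = M$.
   Prepare `n_samples` sequences from $D$ with their original energies,
   then run Adam: each step resamples a batch from the pool (individually,
   with replacement), replaces each batch member by a fresh uniform
   sequence with probability `uniform_mix_prob` (its original energy is
   computed on the fly — the loss needs it, and the mixing keeps rarely
   observed symbol combinations identifiable), and updates all parameters
   from a zero initialization.  An exponential moving average (EMA) of
   batch losses, initialized at the first batch loss, drives early
   stopping: training stops once the EMA has not improved within
   `patience_steps` steps, and the returned parameters are the checkpoint
   at the minimal EMA.  For the independent family the coupling gradient
   is simply discarded.

### Tunable parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `n_samples` | $10^7$ | prepared sample pool; aim for at least as many samples as parameters ($1{,}291{,}984$ at $N = 77$, $q = 21$) |
| `batch_size` | 10000 | Adam batch |
| `uniform_mix_prob` | 0.01 | per-sample uniform replacement probability |
| `ema_factor` | 0.9 | smoothing of the batch-loss EMA |
| `patience_steps` | 1000 | steps without a new EMA minimum before stopping |
| `step_size` | $10^{-3}$ | Adam learning rate ($\beta = (0.9, 0.999)$) |
| `max_steps` | $\infty$ | hard cap, for bounded desk-scale runs |
| `K_target` | 5000 | importance samples per energy when the original's energies are estimates |

The extraction objective is an ordinary linear least-squares problem, so
the step size affects speed, not the optimum; desk-scale examples in the
tests use 0.02 and converge in a few hundred steps, while the conservative
default suits large noisy runs.

## Original models

**Autoregressive model** (`train_ardca()`): $p(s) = \prod_i p(s_i \mid
s_{<i})$ with each conditional a softmax of a field plus couplings to
preceding positions.  Likelihood and ancestral sampling are exact, so its
energies carry no estimation error.  Training maximizes the weighted log
likelihood (weights normalized to sum to one) minus unnormalized penalties
$\lambda_J \lVert J\rVert^2 + \lambda_h \lVert h \rVert^2$ with defaults
$\lambda_J = 0.01$, $\lambda_h = 10^{-4}$, by full-batch L-BFGS from zero —
deterministic by construction.  The site order defaults to natural
left-to-right; an entropic order (ascending single-site entropy) is
available but not default, since nothing in the distillation depends on the
order beyond the likelihood it achieves.

**VAE** (`train_vae()`): encoder $s \mapsto (\mu, \log\sigma^2)$ through one
tanh layer, diagonal Gaussian posterior, standard normal prior, decoder
$z \mapsto$ per-position softmaxes through one tanh layer.  Training is
full-batch gradient descent on the weighted ELBO (one fresh
reparameterization draw per sequence per step) with weight decay on the
weight matrices only — decaying biases would prevent even the marginal
frequencies from being represented in the strong-decay limit.  A
consequence worth knowing: as weight decay grows the decoder converges to
its output-bias softmax, i.e. the per-position empirical marginals, not to
the uniform distribution.  Energies are importance-sampling estimates
(`vae_energy_importance()`, $K = 5000$ by default, log-sum-exp in log
space, deterministic given a seed) and are flagged as estimated via
`is_estimated_energy()` so evaluation code records the estimator settings.
The reparameterized ELBO and the IS estimator obey the usual Jensen
ordering, checked statistically in the tests; one-dimensional latent toys
are checked against Gauss–Hermite quadrature.  With untrained, large random
weights the IS weights become heavy-tailed and the estimator degrades — a
known property of importance sampling, which is why the estimator checks
use moderate weight scales and why $K$ is configurable for extraction
targets.

## Data handling

FASTA alignments are read via Biostrings; characters outside the 20
standard amino acids and `-` (including `.` and non-standard residues such
as `X`) become gaps, matching common preprocessing.  Codes are integers
$1..q$ with the gap at $q$; positions are 1-based throughout, which also
matches the `A42G` convention of mutation tables, so no index conversion
exists anywhere.  Preprocessing removes duplicate sequences (first
occurrence kept), splits 9:1 into train and test (nearest-integer test
size, at least one sequence), and labels the 10% of test sequences with the
largest minimum normalized Hamming distance to the training set as
"distant" (nearest-integer count; ties resolved by input order).
Reweighting uses the standard neighborhood count at 80% identity with gaps
as an ordinary symbol, the threshold exposed as a parameter.

## Evaluation

* `nrmse()` — RMSE between original and extracted energies divided by the
  range of the original energies on the evaluation set.
* `stratified_energy_report()` — NRMSE per stratum (test close / test
  distant / mutational) per extracted model, plus per-distance diagnostics:
  energies, absolute errors, and per-distance-bin standard deviations and
  RMSEs.  Bins are the distinct observed minimum distances — with $N
  \lesssim 100$ the distances are discrete, so smoothing would only blur
  them.  Empty strata are recorded as missing rather than raising.
* `mutational_spearman()` — Spearman rank correlation between *minus*
  energy and fitness, so that a model ranking fit mutants at low energy
  scores positively.
* `contact_scores()` / `ppv_curve()` — the standard coupling-based contact
  pipeline: zero-sum gauge, Frobenius norm of each coupling block excluding
  the gap state (for the protein alphabet), average product correction,
  ranking at a minimum sequence separation of 5.  Contact truth is consumed
  as a plain-text pair list; no structure parsing is included.
* `coupling_scatter()` — paired coupling entries of two models in the
  zero-sum gauge with their Pearson correlation.

## The synthetic generator, and what passing tests mean

`random_pairwise_model()` draws i.i.d. Gaussian couplings and fields at
stated scales.  `planted_threebody_model()` adds sparse three-body tensors
that are centered to zero sum along every axis, so they are *pure* order-3
content: under uniform weighting they are exactly invisible to pairwise
extraction and the residual loss equals their uniform variance — an
analytic prediction the suite asserts, with the $q=2$, $N=3$ parity energy
as the sharpest case (residual exactly 1).  `sample_model()` draws exactly
from $e^{-E}/Z$ by enumeration when $q^N$ is small and otherwise runs
parallel single-site heat-bath (Gibbs) chains whose conditionals are
computed from full energy evaluations, so the sampler is correct for any
exact-energy model including planted higher-order ones; defaults are one
independent chain per requested sequence and a burn-in of $100 N$ sweeps,
both configurable.  `synthetic_mutational_dataset()` builds single-mutant
tables with fitness $-E + \mathcal{N}(0, \sigma^2)$.

These generators emulate the *statistical* structure the method cares about
(planted interaction orders, known marginals, controlled noise) but not the
phylogenetic correlations, alignment artifacts, gap stretches or
experimental biases of real family data.  Green tests therefore certify the
machinery — estimators converge to their oracles, gauges preserve energies,
samplers match enumerations — not that any particular biological family is
well approximated by a pairwise model; that question is what the tool is
*for*, on real alignments.

## Numerical choices

* Enumeration oracles are capped at $10^6$ sequences (override exposed).
* The pseudo-inverse in `extract_exact()` drops eigenvalues below
  $10^{-10}$ of the largest — the null space is the exact gauge freedom, so
  the cutoff separates machine-zero modes from real curvature.
* Softmaxes and log-sum-exp are max-shifted; the IS estimator works
  entirely in log space.
* Degenerate inputs fail loudly: constant energies in `nrmse()`, constant
  vectors in `spearman()`, empty reference sets in Hamming distances,
  wild-type mismatches in mutation tables (naming the offending row).
* Ties: distance ties at the close/distant boundary go to the earlier
  index; contact-score ties rank lexicographically by (i, j).
* All stochastic operations take a seed and restore the caller's RNG
  state, so library calls never perturb user scripts.

Desk-scale problem sizes used throughout the tests and the acceptance
script — enumerable oracles at $N \le 5$, sampling routes at $N = 8$,
$q = 4$ with $10^5$ samples, training runs with a few thousand sequences —
were chosen so every check completes quickly on a laptop while staying in
the regime where the oracles are exact; the protocol constants themselves
(batch 10000, mixing 1%, EMA 0.9, patience 1000) are the reference
defaults.

## Limitations

* Distillation is capped at interaction order 2 by design; sparse
  higher-order extraction is out of scope.
* `extract_exact()` and the expansion oracle require enumerable sequence
  spaces; at protein scale only the sampling routes apply.
* VAE energies are estimates; their Monte-Carlo error enters the
  extraction targets, and heavy-tailed importance weights can degrade the
  estimate for poorly matched posteriors.
* The Gibbs sampler's full-energy conditionals cost $O(qN)$ energy
  evaluations per sweep per chain, which is fine for toys but not tuned
  for large planted models.
* Model files use RDS (exact round-trip); no cross-language container is
  provided.
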