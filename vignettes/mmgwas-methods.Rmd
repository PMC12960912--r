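---
title: "Matrix-free mixed-model association testing: models and methods"
author: "mmgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-free mixed-model association testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

For a binary trait on $N$ samples, `mmgwas` fits the logistic mixed model

$$\mathrm{logit}(\mu_i) = X_i\alpha + G_i\beta + b_i,\qquad
b \sim N(0,\ \tau\psi),$$

where $X$ are fixed covariates (always including an intercept), $G_i$ is the
allele count of the tested variant, and $\psi = \tfrac1M AA^\top$ is the
genetic relationship matrix (GRM) of $M$ standardized markers. Quantitative
traits use the identity link with an additional residual dispersion $\varphi$:
$Y = X\alpha + b + \varepsilon$, $\varepsilon \sim N(0, \varphi I)$. Some
presentations add a residual term inside the logit; a logit-scale residual has
no standard meaning in a Bernoulli model, so the binary model here is the pure
logistic GLMM above.

Step 1 fits the model under the null $\beta = 0$ once per trait; Step 2 then
score-tests millions of variants against that single fit. The defining
constraint at biobank scale is that the $N \times N$ GRM can never be formed:
it enters only through products $\psi v = \tfrac1M A(A^\top v)$, two
matrix–vector multiplications costing $O(MN)$ time and $O(N+M)$ extra memory.

### Genotype standardization

Column $j$ of $A$ is $(g_j - 2p_j)/\sqrt{2p_j(1-p_j)}$ with $p_j$ the
allele-1 frequency among non-missing calls and missing calls imputed to the
mean $2p_j$ (hence exactly zero after centering). The Hardy–Weinberg scaling
makes $\psi$ a correlation-like kinship estimator. Monomorphic columns are
dropped before standardization — they carry no relatedness information and
have an undefined scale. Allele 1 (the bim A1 allele) is the counted allele
throughout; the sign of every reported effect is relative to it.

## Step 1: null-model fitting

Each outer iteration solves linear systems in
$\Sigma = W^{-1} + \tau\psi$, where $W$ holds the diagonal GLM weights
($\mu_i(1-\mu_i)$ for binary traits, $1/\varphi$ for gaussian). All solves use
a diagonally (Jacobi) preconditioned conjugate gradient with
$\mathrm{diag}(\Sigma)_i = 1/W_i + \tau\psi_{ii}$; $\psi_{ii}$ is cached at
standardization time. On genotype-derived systems the iteration count grows
roughly like $\sqrt N$, which the test suite checks by comparing matched
simulations at $N = 200$ and $N = 3200$.

Binary traits follow penalized quasi-likelihood: with the current
$(\alpha, \hat b)$, form the working response
$z = \eta + (Y - \mu)/W$, solve the GLS system for $\alpha$ via PCG, update
$\hat b = \tau\psi\Sigma^{-1}(z - X\hat\alpha)$ and $\mu$, then take one
average-information REML step on $\tau$:

$$s(\tau) = \tfrac12\!\left(\tilde y^\top P\psi P\tilde y - \mathrm{tr}(P\psi)\right),
\qquad \mathrm{AI} = \tfrac12\,\tilde y^\top P\psi P\psi P\tilde y,$$

with $P = \Sigma^{-1} - \Sigma^{-1}X(X^\top\Sigma^{-1}X)^{-1}X^\top\Sigma^{-1}$
applied matrix-free. The update $\tau \leftarrow \max(0, \tau + s/\mathrm{AI})$
falls back to bounded bisection on the sign of $s$ whenever the AI is not
positive. Gaussian traits update $(\varphi, \tau)$ jointly with the analogous
two-component AI system (components $I$ and $\psi$); this joint Newton update
is how the dispersion is handled rather than a separate profiling pass.
Convergence is declared when the largest relative change across
$(\alpha, \tau, \varphi)$ falls below `tol`.

### Traces

The score needs $\mathrm{tr}(P\psi)$. Below `exact_trace_n` (default 2000)
samples it is computed exactly from the dense $\psi$ — for gaussian fits via a
one-time symmetric eigendecomposition (every $\Sigma = \varphi I + \tau\psi$
shares the eigenbasis, so per-iteration traces are $O(N)$ afterwards), for
binary fits via a Cholesky inverse of the dense $\Sigma$ per iteration (the
weights change every iteration). Above the cutoff a Hutchinson estimator with
`n_probes` (default 30) seeded Rademacher probes is used; each probe costs one
PCG solve. The 30-probe default gives a relative trace error under 5% at the
sizes where it activates, which perturbs $\hat\tau$ well below its sampling
error. Solves are never done densely regardless of the trace path.

### Numerical safeguards

* The inner PCG tolerance is clamped to a tenth of the outer tolerance —
  otherwise the outer iteration stalls at the solver noise floor and a fully
  converged iterate is misreported as non-convergence.
* Binary working weights are floored at `1e-10` so quasi-separation
  ($\mu \to 0/1$) cannot produce infinite working responses; hitting the
  floor raises a warning.
* Outer-loop solves are warm-started from the previous iteration, and the
  AI-REML step reuses the $\Sigma^{-1}X$, $\Sigma^{-1}\tilde y$ solves of the
  PQL update it is interleaved with.
* Non-convergence raises a classed error carrying the last iterate, never a
  silent result.
* Initialization: $\alpha$ from the fixed-effects-only GLM, $\tau_0 = 0.1$,
  $\hat b_0 = 0$.

### Variance ratio

Recomputing the exact score variance $\tilde G^\top P\tilde G$ per variant
would need a PCG solve per test. Instead, for 30 random markers with minor
allele count $\ge 20$ (seeded, drawn without replacement), the fit compares
the exact variance with the cheap no-GRM variance $\tilde G^\top W\tilde G$
and stores the mean ratio $r$; Step 2 multiplies every cheap variance by $r$.
At $\tau = 0$ the two variances coincide and $r = 1$ identically, which the
suite asserts to $10^{-3}$. The single-ratio scheme (no MAC stratification,
one ratio per trait) is a deliberate simplification; rare-variant-focused
analyses would stratify.

## Step 2: score tests

For each dosage or hard-call vector $G_j$ (values in $[0,2]$, counted on
allele 1, missing hard calls mean-imputed), the variant is residualized
against the covariates under the null weights,
$\tilde G = G_j - X(X^\top WX)^{-1}X^\top WG_j$, and the score and calibrated
variance are

$$T = \tilde G^\top \Sigma^{-1}\text{-weighted residuals},\qquad
\mathrm{var} = r\,\tilde G^\top W\tilde G .$$

For binary traits the weighted residual is simply $Y - \mu$; for gaussian
traits it carries the $1/\hat\varphi$ factor, so the standardized score
matches the classical linear-model test and `BETA` is the per-allele effect
in phenotype units. `p_value_NA` always records the two-sided normal
p-value for audit; `BETA = T/var` and `SE = 1/sqrt(var)` are on the link
scale.

### Saddlepoint correction

Under heavy case–control imbalance the normal approximation to $T$ fails far
in the tails. When the standardized score exceeds `spa_trigger` (default 2),
the p-value is recomputed from the exact cumulant generating function of
$S = \sum_i \tilde g_i Y_i$ under the null,
$K(t) = \sum_i \log(1 - \mu_i + \mu_i e^{\tilde g_i t})$: solve
$K'(\zeta) = s$ by safeguarded Newton with a bisection bracket, then apply
the Barndorff–Nielsen tail
$1 - \Phi\!\left(w + \tfrac1w\log\tfrac vw\right)$ with
$w = \mathrm{sign}(\zeta)\sqrt{2(\zeta s - K(\zeta))}$,
$v = \zeta\sqrt{K''(\zeta)}$. The two tails are evaluated separately at
$K'(0) \pm |q - K'(0)|/\sqrt r$ and summed (capped at 1); the $1/\sqrt r$
rescaling folds the variance-ratio calibration into the tail location and is
a no-op at $r = 1$. Within $|\zeta| < 10^{-4}$ of the mean the normal
p-value is returned — the saddlepoint expression degenerates there and the
normal is accurate. A failed root search falls back to the normal p-value
with `is_SPA_converged = FALSE`; p-values are floored at the smallest
positive double and never serialized as zero.

One property worth knowing: when the tested variant is an integer hard call
and the fitted probabilities are (nearly) constant, $S$ is lattice-valued
and the continuity-uncorrected saddlepoint — the convention here — estimates
the *mid-p* tail rather than the inclusive tail. With continuous imputed
dosages and covariate-heterogeneous risks the distribution is non-lattice
and the approximation matches an exact convolution of the per-sample
Bernoulli contributions to well under 10% deep into the $10^{-4}$ tail,
which is how the suite validates it. A related calibration fact: at
moderate two-sided levels (say $\alpha = 0.01$) the leading skewness error
of the normal approximation largely cancels between the two tails, so the
normal's measured excess there is modest; its failure — and the value of
the correction — grows rapidly toward the discovery thresholds where
decisions are actually made.

### Firth effect estimates

For rare variants or near-separation the score effect `T/var` is unstable
and the unpenalized MLE may diverge. Optionally (off by default, gated to
variants with $p <$ `firth_p_cutoff`, default 0.05, to bound cost), the
effect is re-estimated by maximizing the Jeffreys-penalized likelihood
$\ell(\theta) + \tfrac12\log\det I(\theta)$ over $(\alpha, \beta_j)$ with
Newton steps and step-halving; the penalized estimate is finite even under
complete separation and its SE comes from the penalized information.

### Chunking, batching, and determinism

Variants are split into equal contiguous blocks processed independently
(optionally via forked workers) and concatenated in input order. Chunking is
over variants, not samples: the score test decomposes naturally across
variants, and per-variant arithmetic is written to be block-size-independent
(column-by-column residualization, columnwise reductions), so any
chunk/worker configuration yields byte-identical output files. A trait
manifest (`trait_id`, `null_model`, `variance_ratio`, `output`) drives
multi-trait batches over a shared genotype source; sample-set mismatches
abort naming the offending trait.

## Distributed-operator contract and capacity planning

`grm_matvec_partitioned()` reproduces the algebra of a device-distributed
GRM product: disjoint column blocks $A_{:,s_i:e_i}$ produce partial products
$A_{:,s_i:e_i}(A_{:,s_i:e_i}^\top v)$ that are reduced in fixed ascending
partition order. The result is independent of the partition plan up to
floating-point reassociation (the suite quantifies this over random ragged
plans at $10^{-8}$ relative); actual multi-process or accelerator execution
is out of scope — the contract is what is tested. `plan_gpus(M, N, mem_gb)`
returns $\lceil 4MN/(\mathrm{mem\_gb}\times10^9)\rceil$ devices (at least
one): 4 bytes per stored value (single-precision storage of $A$ is the
planning assumption; this implementation computes in double precision) and
decimal gigabytes. The ceiling is used because a device count must cover the
matrix.

## The synthetic cohort generator

Tests and calibration experiments need cohorts with *known* relatedness and
phenotypes drawn *exactly* from the model, so the generator is first-class
code:

* **Genotypes** — founder haplotypes carry allele 1 with probability
  $p_j \sim U(\mathrm{maf\_range})$ (default $(0.05, 0.5)$); sib blocks
  (pairs or quads) receive one allele per parent per marker by Mendelian
  transmission, giving sib–sib GRM expectation $1/2$. Markers are
  independent: no linkage disequilibrium is simulated.
* **Polygenic effect** — $b = \sqrt{\tau/M}\,Az$ with $z \sim N(0, I_M)$,
  which has covariance exactly $\tau\psi$ for the realized GRM because $A/\sqrt M$
  is itself a symmetric factor of $\psi$; no $N\times N$ matrix is formed and
  Step-1 recovery tests are internally consistent by construction.
* **Phenotypes** — binary: $Y \sim \mathrm{Bernoulli}(\mathrm{expit}(\alpha_0
  + X\alpha + b))$ with $\alpha_0$ solved numerically so the expected case
  fraction hits the target prevalence; a one-time reseed guards against a
  degenerate all-control draw before erroring. Quantitative:
  $Y = X\alpha + b + \varepsilon$, $\varepsilon \sim N(0,1)$. Two default
  covariates (one standard normal, one Bernoulli(0.5), effects $(0.2, 0.3)$)
  stand in for age and sex; `alpha_true = numeric(0)` gives intercept-only
  cohorts. Case–control ascertainment (simulate a pool, keep exactly
  `n_cases` + `n_controls`) constructs extreme imbalance designs such as
  1:99.
* All randomness flows from the single `seed`; a fixed seed reproduces the
  cohort bitwise.

What the generator does **not** emulate — linkage disequilibrium, population
stratification and admixture, genotyping/imputation error processes, MAC/MAF
spectra of real arrays — bounds what green tests mean: they validate the
estimator and its calibration under the stated model, not robustness to
model violations handled upstream in real pipelines.

## Problem sizes and defaults used by the test suite

The suite exercises the study conditions at desk scale: operator and solver
oracles at $N \le 500$ against dense linear algebra; variance-component
recovery on 20 seeds of 500-sib-quad cohorts ($N = 2000$, $M = 3000$,
$\tau \in \{0.5, 1\}$, quantitative); score-test size over $10^4$ null
variants at $N = 2000$; SPA calibration at 200 cases / 19,800 controls with
$10^4$ null variants of MAF $\in (0.005, 0.05)$, tested in 1,000-variant
blocks; the exact-convolution SPA oracle at $N = 500$. The acceptance script
reruns the same machinery at moderately smaller sizes and prints every number
it reports.

## Known limitations

* PQL with a single AI-REML step per iteration underestimates $\tau$ for
  binary traits with strong random effects — a known property of the
  quasi-likelihood; quantitative fits are unbiased (and are what the
  recovery experiments use).
* One variance component; no leave-one-chromosome-out, no sparse-GRM
  two-stage fitting, no MAC-stratified variance ratios.
* The null-model JSON is this package's own format, not interoperable with
  other tools' model files.
* VCF/BGEN input, sex-chromosome handling, multi-allelic splitting, and
  set-based tests are out of scope.
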