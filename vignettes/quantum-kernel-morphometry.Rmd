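---
title: "Quantum and classical kernel classification of neuron morphometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum and classical kernel classification of neuron morphometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qkmorph)
```

## The problem

Morphological neuron types (M-types) — pyramidal, Purkinje, basket,
Martinotti cells and the like — are classically distinguished by scalar
morphometrics computed from digital reconstructions: total lengths and
surfaces, branch angles, bifurcation counts. `qkmorph` implements a
benchmarking pipeline for multiclass M-type classification from such a
feature table (14 classes, 43 positive-valued features by default), in
which support vector machines consume *precomputed Gram matrices* so that
classical kernel functions and quantum fidelity kernels flow through an
identical evaluation path. The pipeline stages are:

1. row filtering (missing values, zero soma surface, Mahalanobis outliers);
2. one of eleven feature rescaling transforms;
3. dimensionality reduction, either tree-impurity feature selection or
   established feature-extraction methods reduced to two components;
4. a kernel — one of four classical functions, or a fidelity kernel from a
   diagonal Pauli-Z feature map with one of seven static encodings, or a
   trained (aligned) quantum kernel;
5. a one-vs-one SVM evaluated by stratified 80/20 holdout and stratified
   5-fold cross-validation, over a declared benchmark grid.

Because curated M-type datasets are not freely redistributable, the package
ships a seeded synthetic morphometry generator as a first-class, tested
module; every downstream stage is exercised against its planted ground
truth.

## The quantum kernel model

A feature vector $x \in \mathbb{R}^n$ is encoded into an $n$-qubit state by
repetitions of a Hadamard layer followed by a diagonal phase gate,

$$\lvert\psi(x)\rangle = \bigl(U_{\Phi(x)}\,H^{\otimes n}\bigr)^{r}
\lvert 0^n\rangle, \qquad
U_{\Phi(x)} = \exp\Bigl(i \sum_{S} \phi_S(x) \prod_{i\in S} Z_i\Bigr),$$

with $r = 2$ repetitions by default and $S$ ranging over all singletons and
all qubit pairs ("full entanglement"). The kernel is the state fidelity
$K(x, \tilde x) = \lvert\langle\psi(x)\mid\psi(\tilde x)\rangle\rvert^2$ —
operationally, the probability of the all-zero outcome when
$U^\dagger(x)U(\tilde x)$ is applied to $\lvert 0^n\rangle$, which is how a
quantum processor estimates it from repeated measurements ("shots").

Because the generator of $U_{\Phi(x)}$ is diagonal in the computational
basis, no general-purpose circuit simulator is needed: `phase_table()`
evaluates the $2^n$ diagonal phases directly from sign-weighted sums of the
encoding functions, `walsh_hadamard()` applies $H^{\otimes n}$ in
$O(n 2^n)$ by the fast transform, and a statevector costs one phase
multiplication plus one transform per repetition. The engine is exact up to
floating point; the test suite pins it against an independent dense oracle
(kronecker-product generators exponentiated by eigendecomposition) to
$10^{-10}$ for all encodings at $n \le 3$.

All encodings share the singleton phase $\phi_{\{i\}}(x) = x_i$ and differ
in the pair phase $\phi_{\{i,j\}}$:

| encoding | $\phi_{\{i,j\}}(x)$ |
|---|---|
| `zz`, `default` | $(\pi - x_i)(\pi - x_j)$ |
| `k8`  | $\pi x_i x_j$ |
| `k9`  | $\tfrac{\pi}{2}(1 - x_i)(1 - x_j)$ |
| `k10` | $\exp\!\bigl(|x_i - x_j|^2 \,/\, (8/\ln\pi)\bigr)$ |
| `k11` | $\pi \,/\, (3\cos x_i \cos x_j)$ |
| `k12` | $\pi \cos x_i \cos x_j$ |

The printed two-argument forms are applied to every entangled pair; the
`default` product form $\prod_{j\in S}(\pi - x_j)$ coincides with `zz` on
pairs. `k11` is singular where $\cos x_i \cos x_j$ vanishes; the engine
refuses such inputs rather than clamping them, because the benchmark always
rescales into a bounded interval first and a silent clamp would hide a
configuration error.

**Basis ordering.** Amplitude index $b$ encodes qubit $i$ as the $i$-th
least significant bit. Fidelities are invariant to this choice; it is fixed
and documented so dense oracle constructions can compare amplitudes, not
just fidelities.

**Shot noise.** `kernel_matrix(mode = "shots")` replaces each off-diagonal
entry by $m/\texttt{shots}$ with $m \sim \mathrm{Binomial}(\texttt{shots},
K_{ij})$ (1024 shots by default), the exact sampling law of all-zero-outcome
frequencies on hardware without readout error. Sampled Grams can be
indefinite; `psd_projection()` clips negative eigenvalues and restores the
unit diagonal before the SVM sees them.

## Trained quantum kernels (alignment)

`train_quantum_kernel()` prepends a parametrized fiducial state to the
encoding: a single layer of $R_y(\lambda_q)$ rotations replaces the first
Hadamard layer, giving
$K_\lambda(x,\tilde x) = \lvert\langle 0^n\rvert U_\lambda^\dagger
D^\dagger(x) D(\tilde x) U_\lambda \lvert 0^n\rangle\rvert^2$ with $D$ the
data-encoding block. Two design points are genuine interpretations, chosen
once and documented:

* **Fiducial placement.** The fiducial is read as *state preparation*:
  $U_\lambda$ replaces the first Hadamard layer. At $\lambda_q = \pi/2$,
  $R_y(\pi/2)\lvert 0\rangle = H\lvert 0\rangle$, so the aligned kernel
  coincides exactly with the untrained feature map — a convenient,
  regression-pinned base case and the default starting point for training.
* **Multiclass reduction.** Alignment loss on a $k$-class problem is the
  sum of binary SVCLoss values over all one-vs-one class pairs with a
  shared $\lambda$, matching the all-pair reduction used by the SVM itself.

The loss is the soft-margin SVM dual optimum
$\sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i\alpha_j y_iy_j K_{ij}$,
solved as an explicit quadratic program (interior-point, `kernlab::ipop`)
and assembled here; minimizing it over $\lambda$ maximizes the attainable
margin. The optimizer is SPSA with two objective evaluations per iteration
and *constant* gains — at most 10 iterations, step size 0.05, perturbation
0.05 — honoring the protocol's two printed 0.05 values; a conventional
decaying-gain schedule is available behind `qka_config(decay = TRUE)`. The
returned $\lambda$ is the best *evaluated* point, so the reported loss
never exceeds the initial one.

## Preprocessing: formulas and numerical choices

The eleven rescalers are implemented from their defining formulas
(`fit_rescaler()` documents each). Non-obvious choices:

* **Standard scaler** uses the population (1/n) standard deviation, so a
  two-point feature $\{0, 2\}$ maps exactly to $\{-1, +1\}$.
* **Robust scaler** is $(x - Q_1)/(Q_3 - Q_1)$ *as defined here*, with
  `options$center = "median"` providing the conventional median-centered
  variant. Faithfulness to the stated form wins over convention.
* **Quantile maps** store an empirical quantile table at
  $\min(1000, n)$ uniformly spaced probabilities. CDF values of transformed
  points are clamped to $[1/(2n),\, 1 - 1/(2n)]$ so the normal target
  $\mu + \sigma\sqrt{2}\,\mathrm{erf}^{-1}(2p - 1)$ (computed via `qnorm`,
  which is that function) stays finite. Note the $\sigma\sqrt{2}$: the
  normal quantile requires it, and the implementation uses the correct
  form.
* **Box–Cox / Yeo–Johnson** estimate $\lambda$ per feature by profile
  likelihood (`stats::optimize` on $[-5, 5]$); Box–Cox refuses non-positive
  features. The Yeo–Johnson four-branch transform is cross-checked against
  `car::yjPower` in the tests.
* **Log-normal CDF transform** $\Phi(\ln x / \sigma)$ defaults to
  $\sigma = 1$ (configurable); the transform is only defined for
  $x \ge 0$ and errors otherwise.
* **Mahalanobis filter**: no cutoff is inherent to the method, so the
  default removes rows whose squared distance exceeds the
  $\chi^2_{43}$ quantile at $1 - \alpha$ with $\alpha = 0.025$,
  configurable, applied globally (not per class). The covariance is
  shrinkage-regularized (Schäfer–Strimmer scalar shrinkage via
  \pkg{corpcor}) because 43 features at a few hundred rows make the sample
  covariance ill-conditioned; `shrinkage = FALSE` errors on singular
  covariances instead of silently pseudo-inverting.
* **Filter order** is fixed — missing → zero-soma → Mahalanobis — and
  reports reconcile counts exactly; the zero-soma rule is strict equality
  with 0, so arbitrarily small positive surfaces survive.

## Dimensionality reduction

Tree importances are Gini impurity decreases aggregated over an ensemble —
random forest, a single decision tree, or gradient-boosted trees (100
trees/rounds by default, seeded; the ensembles themselves are delegated to
\pkg{randomForest}, \pkg{rpart}, \pkg{xgboost}). The package owns the
contract on top: importances are non-negative, cover every feature
(absent features score 0), and are normalized to sum to 1.
`select_top_k()` is a pure function with a documented tie-break (ascending
feature index).

Feature extraction is a thin uniform adapter over established
implementations: PCA, LDA, Gaussian random projection, truncated SVD,
Isomap (\pkg{vegan}) and classical MDS. Isomap and MDS have no
out-of-sample transform; they are flagged *transductive*, and the benchmark
grid embeds train and test jointly for them, recording the caveat on every
affected row — the honest alternative to silently refitting per fold. The
remaining catalogue names (ICA and ICA-with-PCA, NCA, t-SNE, the LLE
family, LTSA) have no R backend installed here; they remain registered grid
members that produce error-status rows, keeping the grid's enumeration
(11 rescalers × 14 extractors per algorithm) intact without fabricating
embeddings.

## Evaluation protocol

`holdout_split()` and `crossval_precomputed()` stratify by class. The
stated protocol says only "randomly chosen"; with 14 imbalanced classes an
unstratified split at desk-scale sample sizes routinely loses entire
classes from training folds, so stratification is the package's default
and only mode. Reports carry fold scores, their mean, standard deviation
*and* the 95% confidence half-width $1.96\,s/\sqrt{k}$, since both
dispersion conventions appear in common reporting. The one-vs-one SVM
(binary C-SVC solves delegated to \pkg{kernlab} on the precomputed
sub-Grams) votes across pairs with ties broken toward the lowest class
index — a documented, deterministic rule exercised by the all-zero-kernel
edge case. `C = 1` everywhere by default, recorded per benchmark row.

Grid cells that fail — Box–Cox on non-positive rescaled data, the `k11`
singularity, a missing extractor backend, a class too small for the fold
count — are recorded as rows with error status rather than aborting the
run. Exact-mode quantum cells refuse to run above a qubit guardrail
(default 10) and a 2 GiB statevector budget.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` draws positive, right-skewed features (log-normal),
one label per neuron from a multinomial over 14 M-type names, and plants
class signal in a small set of informative features (5 of 43 by default,
never the soma-surface column). Each informative feature grades the
classes by an independent random permutation of ranks, adjacent ranks
exactly one log-standard-deviation apart (`sdlog` 0.4, `location_step`
0.4). This choice has two motivations: morphometric magnitudes genuinely
grade across M-types over orders of magnitude, and a rank structure
survives quantile rescaling — each class maps to a narrow distinct
quantile band, whereas center structures that share coordinate values
collapse onto common modes under any monotone marginal transform. The
clean-data contract (a Euclidean 1-NN classifier above 80% on informative
features) is asserted in the tests.

`inject_artifacts()` plants exactly reconcilable artifacts in disjoint row
sets: one missing cell per affected row, exact zeros in the soma-surface
column, and multivariate outliers displaced 8–12 robust standard
deviations per feature from their class mean along independent random sign
patterns. The random signs matter: a group of outliers displaced along a
common direction inflates a single covariance eigendirection and masks
itself from the very filter it is meant to exercise.

The generator does **not** emulate: realistic marginal distributions of
named L-Measure features (the 43 names are generic, only `Soma_Surface`
is semantically meaningful), allometric correlations between features,
class imbalance of real archives, or reconstruction-protocol batch
effects. Passing tests therefore demonstrate that the pipeline recovers
planted structure under its stated assumptions — not that any particular
accuracy will transfer to real archive data.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: oracle
equivalence at 1–3 qubits, Gram invariants at 6 qubits × 40 points,
end-to-end recovery at 200 neurons × 5 qubits, alignment on a 24-point
2-qubit planted problem, and 1000-repeat shot-noise checks at 1024 shots.
Presets mirror the study's five sample sizes (260 / 626 / 1,143 / 2,080 /
22,691) for users who want them. Every stochastic stage takes an explicit
seed; per-purpose child streams inside the generator keep artifact
injection from perturbing feature draws, so any artifact on disk can be
re-derived bit-identically from its sidecar metadata.

## Known limitations

* Exact statevector simulation is exponential in qubits; the practical
  ceiling here is ~20 qubits and the benchmark guardrail defaults to 10.
* No noise model beyond binomial shot sampling: hardware-specific effects
  (decoherence, readout error, crosstalk) are out of scope.
* The fiducial ansatz is a single $R_y$ layer; richer covariant ansätze
  would require extending `fiducial_state()`.
* Transductive embeddings leak test-set geometry into the fit by
  construction; rows carry the caveat, but users comparing against
  inductive cells should weigh it.
* `svc_loss` scales as a dense QP in the number of training rows; at
  benchmark scale this is the dominant cost of alignment training.
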