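---
title: "Evolving wavelet neural network ensembles: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving wavelet neural network ensembles: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewnne)
```

## The classifier

`ewnne` fits binary classifiers for tabular biomedical data as wavelet
neural networks (WNNs) trained purely by evolutionary search, then combines
pools of them into pruned majority-voting ensembles. This vignette is the
package's own account of the method: the model, every tunable parameter
with its default and rationale, the numerical conventions, and what the
bundled synthetic-data generators do and do not emulate.

A WNN replaces the sigmoid hidden units of a conventional network with
*wavelons*: units whose activation is a wavelet — an oscillating, localised
basis function — of a dilated, translated and rotated combination of
inputs. The network output is

$$y(\mathbf{x}) = \theta + \sum_{j=1}^{m} wt_j\, \Psi_j(\mathbf{x})
  + \sum_{f=1}^{n} a_f x_f,$$

a bias plus the weighted wavelon responses plus direct input-to-output
shortcut connections. Each wavelon owns a set of *input slots*; slot $s$
points at feature $\mathrm{feat}(s)$ and carries a connection switch
$c_s \in \{0,1\}$, an input weight $w_s \in [-1,1]$, a dilation
$\alpha_s \in [0,1]$, an unbounded translation $\beta_s$, and a rotation
$R_s \in [-1,1]$. Only switched-on slots contribute:

$$\Psi_j(\mathbf{x}) = \prod_{s \in A_j} \psi\!\left(z_s + R_s\,
  z_{\mathrm{succ}(s)}\right), \qquad
  z_s = \frac{w_s\, x_{\mathrm{feat}(s)} - \beta_s}{\max(\alpha_s, 10^{-3})},$$

where $\mathrm{succ}(s)$ is the next switched-on slot, cyclically. A
wavelon with no connected slot, or with its activity flag off, contributes
exactly 0 — pruned units are truly silent rather than an empty product
of 1. Class labels are encoded 0 = control, 1 = diseased, and a record is
called diseased when $y \ge 0.5$ (the boundary goes to class 1; with MSE
fitness against 0/1 targets the midpoint is the natural cut).

### Wavelet functions

Four activations are available: Morlet $\cos(5t)\,e^{-t^2/2}$, Mexican hat
$(1-t^2)\,e^{-t^2/2}$, the first derivative of a Gaussian
$-t\,e^{-t^2/2}$, and the Haar step (1 on $[0,\tfrac12)$, $-1$ on
$[\tfrac12,1)$, 0 elsewhere). These are the standard WNN literature forms;
the Morlet carrier frequency is the conventional 5. Heterogeneous networks
(wavelet identity evolving per wavelon over the full set) suit
mixed-lexicon feature sets; homogeneous Mexican-hat networks are the
default elsewhere.

### The rotation realisation

Rotation parameters couple the wavelet arguments of *consecutive connected
slots* as a cyclic shear, $z'_s = z_s + R_s z_{\mathrm{succ}(s)}$. This is
one concrete realisation of "rotated" multidimensional wavelons — the
historical constructions vary and are often underspecified — and it is
deliberately isolated in a single place (`wavelon_response()` and the
matching compiled kernel) so an alternative coupling can be swapped in
without touching the evolution machinery. A genuine limitation follows
from it: every wavelet argument remains *linear* in the inputs, so a
$k$-wavelon network is a sum of $k$ Gaussian-enveloped plane-wave
interference patterns plus a linear term. See *Known limitations*.

## Phase I: the evolution strategy

All genome parameters evolve concurrently under a $(\mu+\lambda)$ elitist
evolution strategy; there are no gradients (they converge prematurely on
these landscapes) and no recombination.

| parameter | default | meaning / rationale |
|---|---|---|
| $\mu$, $\lambda$ | 1, 25 | parent/offspring counts; (1+25) for small nets, (3+20) for wide ones |
| generations | 2000 | fixed budget; no early stopping |
| mutation rate | 1% | per-gene selection probability |
| mutation magnitude | 10% | relative perturbation bound for continuous genes |
| wavelons $m$ | 4 | fixed at construction; 4–5 suits low-dimensional clinical panels |
| input slots per wavelon | `n_features` | fewer slots force sparser wavelons |
| $n_{runs}$ | 50 | independent restarts per fold |
| folds | 10 | stratified, patient-grouped cross-validation |

Mutation is typed: continuous genes $g \mapsto g + U(-0.1, 0.1)\cdot g$,
clamped back to range (translations are unbounded and never clamped; a
gene exactly 0 instead receives an additive $U(-0.01, 0.01)$ kick so it can
escape zero); binary genes invert; categorical genes (slot feature indices
and wavelet identities) resample uniformly among the *other* list members.
Two consequences worth knowing: mutation is applied per gene independently,
so the expected number of mutated genes per offspring is
$0.01 \times G$ for a $G$-gene genome — small genomes mutate very rarely
and benefit from a higher rate; and the multiplicative perturbation never
flips a continuous gene's sign, so sign patterns are set at initialisation
and explored across independent restarts rather than within a run. This is
the literal reading of perturbing "by a small percentage of the current
value", and restarts are cheap; both the toy-task test and the
cross-validation harness lean on restarts accordingly.

Populations are ranked by accuracy (descending) with mean squared error as
tie-break (ascending), a total order consistent with promoting a single
best individual; a Pareto-style non-dominated alternative would fit behind
the same interface but was not needed. Ranking ties beyond both keys keep
insertion order, which makes runs bit-reproducible.

Initialisation draws every bounded gene uniformly over its range.
Translations are unbounded, so they are drawn from a standard normal: with
z-scored inputs (see below) that is where translations are useful, and
mutation can walk them anywhere.

### Cross-validation harness and seeds

`run_phase1()` builds stratified folds; when patient identifiers exist,
whole individuals are dealt to folds so no individual ever spans a split
(records of one patient are highly correlated — record-level splitting
would leak). Fitness is evaluated on the fold-train split only; the
fold-validation split is touched once per run, to score the pooled genome
(`Te_acc`). Features are z-scored per fold, fitted on the fold-train split
only; the flag `standardize = FALSE` disables this. Standardisation is on
by default because the genome's initial ranges (unit weights, unit
dilations, standard-normal translations) presuppose centred,
unit-variance inputs.

Per-run seeds are drawn up-front from the master seed in one
`sample.int()` call, laid out fold-by-fold, and recorded in the manifest,
so any individual run can be replayed in isolation.

## Phase II: pruning the pool by genetic algorithm

A pool of `n_runs` evolved networks is pruned by a $(3+25)$ elitist GA over
bit masks (bit = classifier is in the ensemble). Three parents balance
premature convergence against selective pressure; the budget is 1000
generations at a 1% per-bit inversion rate. Mask mutation is realised as
independent per-bit inversion — the same "invert" rule the genome's binary
genes use — since inversion is what changes ensemble membership.

The fitness of a mask is
$\mathrm{FE} = \tfrac12(\overline{Tr}_{acc} + Ens(U))$: the mean
training-set accuracy of the selected classifiers plus the training-set
accuracy of their joint vote. The vote is *strict* majority over the
$k$ **active** classifiers (not the pool size — a heavily pruned ensemble
must still be able to reach a majority): class 1 needs strictly more than
$k/2$ votes, so an even split falls to control. Conventions chosen to keep
the GA total: an empty mask scores fitness 0 rather than erroring, and
ties between equal-fitness masks resolve toward fewer active classifiers,
which biases the search toward compact ensembles.

The held-out test set plays no role in the search; it is scored exactly
once, after the last generation, by the winning mask. The bundled tests
verify this by checking that the selected mask is identical whichever test
set is supplied.

## Performance measures

The positive class is **control**: TP counts correctly classified control
samples, TN correctly classified diseased samples, so a diseased sample
predicted control is a false positive. `confusion_counts()` takes an
explicit `positive` argument for the conventional usage, but every
reported table uses control-as-positive. Derived measures: accuracy
$(TP+TN)/(P+N)$, sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, and
the Matthews correlation coefficient
$(TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$.
Sensitivity and specificity are reported as not computable (printed `-`)
when their denominator is zero — a one-class test fold does this — and MCC
is defined as 0 when any denominator factor vanishes, the standard
convention. For multi-record individuals, record predictions aggregate to
a diagnosis by strict majority; an exact tie is control.

## Synthetic data

`two_spiral()` generates the classic two-interleaved-spirals benchmark:
97 points per spiral, angle $i\pi/16$, radius $6.5(104-i)/104$, class 1
the exact negation of class 0. It is deterministic at zero noise.

`synth_clinical()` emulates the structure of repeated-measurement clinical
cohorts: a class label per *individual*, a latent per-individual feature
mean drawn from a class-shifted Gaussian, and records scattered around the
latent mean. Variance components are chosen so each feature has unit
marginal variance; `within_patient_corr` is then exactly the intraclass
correlation and `effect_size` the class separation in marginal SD units on
every feature. What it does **not** emulate: heteroscedastic or heavy-tailed
features, feature-feature correlation beyond the shared latent mean, class
imbalance in records-per-individual, measurement drift, or informative
missingness. Passing tests on this generator therefore demonstrate the
machinery (search, pruning, grouping, aggregation) under clean Gaussian
conditions, not clinical-grade performance.

## Problem sizes used by the test suite

The evolutionary settings above are the method's operating defaults; the
test suite exercises the same code paths at reduced scale, chosen once:
toy separable tasks at 20 records × 300 generations; pruning-oracle
equivalence on 10-classifier pools over 50 records (enumeration of all
1023 masks vs a 5-restart, 1000-generation GA); and the full two-phase
pipeline on a 30-individual × 6-record cohort with a 2-SD effect at
3 folds × 10 runs × 200 generations, where the pruned ensemble's test
accuracy is compared with the mean individual accuracy. The two-spiral
learnability check runs the full criterion budget of 20 restarts × 2000
generations.

## Known limitations

* **Two-spiral representability.** With the shear-coupling rotation, every
  wavelet argument is linear in the inputs, and the Morlet carrier at
  frequency 5 supports only about five sign alternations inside its
  Gaussian envelope. The 97+97-point two-spiral task needs roughly
  thirteen alternations across its diameter, so a 2-wavelon Morlet network
  of this family — two enveloped plane-wave interference patterns plus a
  linear term — cannot separate it completely, for *any* optimiser. The
  bundled learnability test runs the full multi-restart evolutionary
  budget and documents this gap: it does not reach 100% training accuracy
  under this realisation. Alternative rotation constructions (full
  coordinate mixing before dilation, or a higher carrier frequency) live
  naturally behind `wavelon_response()` and would raise the ceiling.
* Sign-frozen continuous genes (see Phase I) make single runs sensitive to
  initialisation; always use restarts.
* The Phase II fitness uses training accuracy twice; with tiny training
  sets it can prefer overfit members. The tie-break toward smaller
  ensembles mitigates but does not remove this.
* Evolution cost scales linearly in records × generations × $\lambda$;
  the compiled forward pass keeps desk-scale runs in seconds, but the full
  50-run × 10-fold × 2000-generation protocol is an overnight computation
  on one core.
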