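---
title: "Models and methods behind qdrlart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qdrlart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qdrlart)
```

`qdrlart` implements a model-based reinforcement-learning framework for
adapting the dose per fraction in the final third of a lung-cancer
radiotherapy course, with the dose decision carried on a simulated quantum
register. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions taken where the problem was
genuinely open.

## The artificial radiotherapy environment

The environment is the 5-tuple (states, dose register, transition,
outcome estimator, reward), assumed Markov: the week-6 response depends on
the current state and the chosen dose only.

**State.** Five features per patient: IP10 (cytokine concentration,
arbitrary positive units), GLSZM-ZSV (dimensionless radiomics scalar),
tumor and lung gEUD (Gy), and the cxcr1-Rs2234671 genotype, encoded as an
allele count in {0, 1, 2} (the encoding is our choice; the literature
reports only that the SNP is used).

**Dose state transition.** The gEUD states advance by a process-driven
monotone rule rather than a learned map:

$$g_{n} = g_{n-1} + \kappa \,\Delta t \, d\left(1 + \frac{d}{\alpha/\beta}\right)$$

with $\alpha/\beta = 10$ Gy (tumor) and $4$ Gy (lung). The accrual rate is
proportional to the per-fraction dose times its linear-quadratic
enhancement; the proportionality constant is not fixed by theory, so each
tissue has a configurable constant $\kappa$ (units Gy per unit of
$d(1+d/(\alpha/\beta))$ per adaptation period). Defaults
$\kappa_{tumor} = 10$, $\kappa_{lung} = 3$ were chosen once so that a
standard 2 Gy/frac final third adds roughly 24 Gy to tumor gEUD and 9 Gy
to lung gEUD — plausible increments for a 60 Gy/30 frac regimen — and are
not revisited. Each decision step advances one adaptation period
($\Delta t = 1$, two weeks); multi-step episodes are counterfactual
continuations of the same rule.

**Biomarker transition.** IP10 and ZSV have no process model, so a dense
regression network (two tanh hidden layers of width 32, Adam, MSE on
standardized log values) maps (baseline state, first-phase dose) to the
mid-treatment values. In the pipeline the first-phase dose is the 2
Gy/frac protocol dose for every patient; a feature without training
variance is deliberately mapped to zero by the standardizer, so the
fitted net is invariant to it and the dose response at decision time is
carried entirely by the gEUD rule. This mirrors the hybrid
knowledge/data design: learned dynamics where no prior form exists,
enforced monotone physics where one does.

**Outcome estimator.** Each binary endpoint (LC on tumor gEUD, RP2 on
lung gEUD) follows a generic logistic

$$p = \frac{1}{1 + \exp\!\big((g(t_6) - \mu(s)) / T(s)\big)}$$

where $\mu(s)$ and $T(s)$ are the scalar outputs of two networks over the
patient's dose-independent biology (IP10, ZSV, genotype), trained
alternately — the $\mu$-net with the $T$-net frozen, then the reverse —
under binary cross-entropy until the loss improves by less than `tol`
(default 1e-5) or `max_rounds` (25) is reached. Three numerical choices
matter:

* **Sign.** As printed, the logistic decreases in $g$ for $T > 0$; the
  clinically established assumption is that more dose raises both tumor
  control and toxicity. $T$ is therefore reparameterized as
  $T = -(T_{min} + \mathrm{softplus}(u))$, strictly negative, making both
  endpoint probabilities nondecreasing in $g$ and hence in dose.
* **Identifiability.** If the head networks can read the endpoint's own
  gEUD (or the other organ's, which is collinear with dose), the pair
  $(\mu, T)$ is unidentified — $\mu$ can track $g$ and $T$ collapses
  toward zero, producing step-function fits and non-monotone dose
  response. The heads therefore see only the dose-independent features,
  $|T|$ is floored at $T_{min} = 0.5$ Gy, and the weights carry a light
  L2 penalty (1e-4 by default, 1e-3 at cohort scale). With these
  constraints the fitted curve matches the logistic maximum-likelihood
  fit of the same draw to within a few percent absolute probability
  (verified in the tests against `glm`).
* **Failure modes.** Single-class labels make the fit unidentified and
  raise an error rather than returning a degenerate curve.

**Reward.** The base utility $P^+ = p_{LC}(1 - p_{RP2})$ earns +10 inside
the clinically desirable region ($p_{LC} > 0.7$, $p_{RP2} < 0.172$), +5
inside the computationally desirable region ($p_{LC} > 0.5$,
$p_{RP2} < 0.5$), and −1 otherwise. The three printed regions do not
tile the unit square (e.g. $p_{LC} = 0.9, p_{RP2} = 0.3$ falls in none);
we evaluate them as an ordered if/else cascade, which makes the reward a
total function with range $[-1, 11]$. Boundaries are exclusive, as
printed. Episodes terminate on entering the clinical region or at the
step cap (default 10).

## The quantum decision layer

Doses live on an $n$-qubit register: basis state $|d\rangle$ at index $i$
(bitstrings are most-significant-bit first, our convention; the source
material never fixes endianness) is the $i$-th of $2^n$ evenly spaced
doses. The default register is 5 qubits over 1.0–4.1 Gy/frac (0.1
spacing); the range is our choice, bracketing standard fractionation,
since no grid range is published.

Two amplification mechanisms select the greedy dose:

* **Grover amplification**: starting from the uniform superposition, $k$
  iterations of phase oracle + inversion about the mean leave the marked
  amplitude at $\sin((2k+1)\arcsin(1/\sqrt{N}))$. The simulator applies
  the operators explicitly; tests compare against the closed form to
  1e-9. The default schedule $k = \lfloor \pi/4 \cdot \sqrt{N} \rfloor$
  is the textbook near-optimal count (unpublished in the source).
* **Controller circuit**: a fixed-depth alternative sized for hardware
  with short coherence — 2n qubits in four gate layers regardless of
  $n$: pre-control X gates write the marked string on the control
  register; a reverse X layer flips the main register to all ones; one
  CNOT per pair flips exactly the mains whose control is one, leaving
  the complement of the marked string; a second reverse layer restores
  it. Noiselessly the measurement returns the marked state with
  probability 1 (verified exhaustively for all marked strings up to
  n = 5). Replacing CNOTs by $CU3(\theta,\phi,\lambda)$ adds per-qubit
  flip probability $\sin^2(\theta/2)$; the angles are exposed as plain
  arguments so a per-episode schedule can be layered on top — the
  schedule itself is deliberately unspecified.

Measurement draws a multinomial over the exact marginal distribution of
the main register; the selected dose is the modal outcome, ties breaking
toward the lowest index (documented; arbitrary). Circuits export to
OpenQASM 2.0 and re-import, so an external hardware executor can be
plugged in as a `function(circuit, shots) -> counts`; no vendor calls are
bundled.

## The agent

A deep Q-net (three ReLU hidden layers of width 64) maps the standardized
5-feature state to one q-value per grid dose. Training is standard double
Q-learning: FIFO replay (capacity 1e4), minibatch 64, Adam at 1e-3,
$\gamma = 0.99$, epsilon annealed linearly 1.0 → 0.05, target network
synced every 100 updates. None of these are published for the original
system; they are conventional values chosen for stable desk-scale runs
and are all exposed in `train_config()`. The greedy arm routes through
the quantum layer, so training under the noiseless controller backend is
bit-reproducible given the seed. Reported recommendations average five
identically configured agents differing only in seed, with the standard
error of the mean as uncertainty (zero by convention for a single
member) and each member's maximal q-value as a confidence proxy.

All neural components share one dense-MLP engine written on plain
matrices (forward, backward, Adam); no deep-learning framework is used.

## WGAN-GP augmentation

Small cohorts are augmented by a Wasserstein GAN with gradient penalty
$\lambda\,\mathbb{E}[(\lVert\nabla_{\hat x} f\rVert - 1)^2]$ on uniform
real/fake interpolates, $\lambda = 10$, five critic steps per generator
step, Adam(5e-4, 0.5, 0.9) — the conventions of the method. Two
implementation choices are specific to this package:

* The critic has a single tanh hidden layer. For that architecture the
  gradient of the penalty with respect to the critic weights — a
  second-order quantity — has an exact closed form: with
  $h = \tanh(W_1 x + b_1)$, $D = \mathrm{diag}(1 - h^2)$ and input
  gradient $u = W_1^\top D w_2$, the chain rule through both the explicit
  $W_1^\top$ and the $x$-dependence of $D$ gives
  $\partial P/\partial w_2 = D W_1 v$,
  $\partial P/\partial W_1 = (D w_2)v^\top + \big((W_1 v)\odot w_2 \odot (-2h\odot(1-h^2))\big)x^\top$
  with $v = \partial P/\partial u$. The implementation is verified
  against finite differences to 1e-10 in the tests.
* The generator's weights are exponentially averaged (decay 0.999) and
  sampling uses the averaged generator: at these network sizes the raw
  adversarial dynamics oscillate visibly, and the average removes most
  of it (on a 2-D Gaussian toy the generated means land within 0.1
  training standard deviations of the truth; the variances remain
  underestimated by tens of percent, a known small-GAN limitation that
  the tests do not claim otherwise).

Generated records are clipped to the training support column-wise;
genotype is rounded into {0, 1, 2} and the binary outcomes into {0, 1}
(rounding a single 3-level variable is simpler and better conditioned
than one-hot at 5 features). Full records — states, dose and outcomes —
are augmented; restricting to states alone is possible by generating and
discarding columns. The default emission is 4000 records.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` draws baseline IP10 and ZSV from log-normals, gEUDs
from positive-truncated normals, genotype from Binomial(2, 0.3), and the
clinical dose from a truncated normal on the grid range; mid-treatment
values add gEUD increments and multiplicative biomarker noise. Binary
outcomes are drawn from the same logistic dose-response family the
environment fits (default $\mu_{LC} = 60$, $T_{LC} = -5$ on tumor gEUD;
$\mu_{RP2} = 25$, $T_{RP2} = -4$ on lung gEUD, the pneumonitis midpoint
shifted −1.5 Gy per risk allele), so higher dose raises both
probabilities and all four outcome classes occur. Units and scales for
IP10 and ZSV are arbitrary but configurable, as the source trials'
scales are not public.

Because the generator and the outcome estimator share a model family,
passing tests demonstrate correct mechanics and recoverability — not
clinical validity on real data, where the published headline numbers
(similarity scores of 0.54–0.71 Gy/frac, 58–61% good recommendations)
were computed on restricted trial cohorts and are out of reach of any
synthetic stand-in.

## The GLSZM zone-size variance

The ZSV feature is computed under the standard radiomics definition:
normalize the zone matrix to a probability distribution
$p(i,j)$, then take the variance of the zone size $j$,
$\sum_{i,j} p(i,j)(j - \mu)^2$ with $\mu = \sum_{i,j} j\,p(i,j)$. A
printed variant with a $1/(N_g L_z)$ prefactor instead of probability
normalization circulates in the literature; it is not the variance of
any distribution for non-uniform matrices, but is available behind
`normalization = "printed"` for comparison. ZSV is invariant to zero
padding and to the gray-level marginal; an all-zero matrix is an error.

## Problem sizes and determinism

Defaults target a single CPU: cohorts of a few hundred patients,
estimator fits of a few seconds, agent training of a few thousand
environment steps, WGAN runs of a few thousand generator updates. The
test suite and acceptance checks run at these scales. Every stochastic
component takes a seed and is bit-reproducible given it; the pipeline
derives stage seeds from the global seed and stamps every JSON artifact
with the configuration hash. The optimal-dose-recovery property is
checked on a 3-qubit (8-level) grid: at 0.1 Gy spacing the reward's
plateaus differ by ~0.01 within a region, so "within one grid step" is
not a resolvable criterion for any regression-based agent, while at
~0.44 Gy spacing it is.

## Known limitations

* No 3-D dose distributions: the environment's gEUD state is scalar; the
  full volume-weighted gEUD over voxel EQD2 exists as a standalone
  utility only.
* No DICOM/PET handling; ZSV is computed from a provided zone matrix.
* The biomarker transition carries no dose signal when trained at a
  constant protocol dose (by design; see above).
* The external quantum backend is an interface, not a vendor
  integration; no device noise or error mitigation is modelled.
* Policy-gradient methods, multimodal treatment, and per-patient
  sensitivity analysis are out of scope.
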