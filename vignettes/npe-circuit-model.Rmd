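---
title: "A rate-based microcircuit model of negative prediction-error neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rate-based microcircuit model of negative prediction-error neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npecircuit)
```

## The scientific problem

Neurons in layer 2/3 of rodent V1 include cells that respond only when
visual input is *weaker* than what the animal's own movement predicts —
negative prediction-error (nPE) neurons. `npecircuit` implements a
rate-based model of how such neurons can *emerge* in a microcircuit of
pyramidal cells (PCs) and PV, SOM and VIP interneurons: inhibitory
synaptic plasticity balances excitation and inhibition pathway by pathway,
so that fully predicted input (feedback), and unpredicted-but-present
input (playback), leave PCs at baseline, while an absent-but-predicted
input (mismatch) disinhibits the apical dendrite and drives a response.

## The model

Pyramidal cells have two compartments. The somatic rate obeys

$$\tau_E \frac{dr_{E,i}}{dt} = -r_{E,i} + [I_i - \Theta]_+ , \qquad
  I_i = \lambda_D\,[I^{syn}_{D,i} + c_i]_+ + (1-\lambda_E)\,I^{syn}_{E,i},$$

with somatic input $I^{syn}_E = x_E - w_{EP} r_P$ (external drive minus
PV-mediated inhibition) and dendritic input
$I^{syn}_D = x_D - w_{DS} r_S + w_{DE} r_E$ (motor prediction, SOM-mediated
inhibition, PC recurrence). The dendritic bracket $[\,\cdot\,]_+$
prevents an excess of dendritic inhibition from reaching the soma; it can
be disabled (`pc_params(dend_rect = FALSE)`) to study the variant without
the dendritic nonlinearity. A calcium event
$c_i = c \cdot H(I^0_{D,i} - \Theta_c)$ with
$I^0_D = \lambda_E I^{syn}_E + (1-\lambda_D) I^{syn}_D$ adds a fixed
current when total dendritic drive crosses threshold. PV, SOM and VIP
units are rectified linear rate units with a fast time constant.

Defaults (all exposed in `pc_params()` / `interneuron_params()`):
$\tau_E = 60$ ms, $\tau_i = 2$ ms, $\Theta = 14\,s^{-1}$,
$\lambda_D = 0.27$, $\lambda_E = 0.31$, $c = 7\,s^{-1}$,
$\Theta_c = 28\,s^{-1}$. The gain $g = 0.07\,(\mathrm{pA\,s})^{-1}$
converts rate-unit currents to pA in analyses only; the dynamics run
entirely in rate units.

**Connectivity.** Populations of 70 PCs and 10 PV/SOM/VIP cells are
randomly connected with literature-motivated probabilities
(`pathway_table()`). Every neuron of a type receives *exactly*
`round(N_pre p)` connections and each weight is the population mean
divided by that in-degree, so summed input — and hence the mean-field
operating point — is independent of population size. Plastic networks
draw initial weights from $U(0.5w, 1.5w)/k$.

**Inputs.** All units receive constant backgrounds. Non-plastic networks
solve the backgrounds analytically for the baseline operating point
$(r_E, r_P, r_S, r_V) = (1, 2, 2, 4)\,s^{-1}$
(`solve_background_inputs()`); plastic networks use the fixed backgrounds
$(x_E, x_D, x_P, x_S, x_V) = (28, 0, 2, 2, 2)\,s^{-1}$. Stimuli are
piecewise-constant 1-s phases: baseline ($v = m = 0$), feedback
($v = m > 0$), mismatch ($m > v$) and playback ($v > m$), with training
amplitudes uniform on $[0, 7]\,s^{-1}$ and test strength 7 (plastic) or
3.5 (non-plastic).

## Analytic balance constraints

For a linearized homogeneous network whose dendrites are silenced in
feedback and playback, requiring PCs to stay at baseline in both phases
fixes two interneuron pathways (`solve_constraints()`):

$$w_{PS} = V_P + w_{VS} M_P - \frac{1 + w_{PP}}{w_{EP}} V_E, \qquad
  w_{PV} = w_{SV} w_{PS} + (1 - w_{SV} w_{VS}) M_P,$$

where $V_X, M_X \in \{0,1\}$ describe the input routing. The package
verifies the equivalence of the two printed forms of the second
constraint on every call, and `linear_steady_state()` provides an
independent piecewise-linear fixed-point oracle against which the
simulated dynamics are tested to $10^{-6}$ relative accuracy.

## Plasticity

Four inhibitory connection classes learn (`plasticity_config()`):
PV→soma and SOM→dendrite weights follow inhibitory Hebbian rules with the
neuron's own pre-training baseline as target; SOM→PV and VIP→PV weights
follow either an approximate backpropagation of error (the deviation of
the PCs each PV neuron inhibits), its local feedback-alignment-style
approximation through the PV neuron's excitatory recurrent drive, or — in
configurations where PCs receive no visual input — a homeostatic rule on
the PV rate itself paired with an anti-Hebbian PC→PV rule. Updates are
applied every integration step (Euler on $\dot w$), masked to the
structural connectivity, and clipped at zero (Dale's principle).

### Numerical choices

* **Integration**: Heun's second-order Runge-Kutta; rates clamped
  nonnegative after every step. Default step 0.1 ms for test protocols,
  1 ms during training — both well inside the scheme's accurate window
  (0.05–2 ms), verified by an order-of-convergence test.
* **Heaviside convention**: a calcium event requires *strictly*
  suprathreshold dendritic drive ($H(0) = 0$); configurable
  (`pc_params(ca_at_threshold = TRUE)`).
* **Rate targets** $\rho_{E,0}$, $\rho_{P,0}$: default to the circuit's
  baseline operating-point rates, 1 s$^{-1}$ for PCs and 2 s$^{-1}$ for
  PV neurons. This choice is forced by a mean-field fixed-point argument:
  the initial baseline of the default plastic network sits near
  1.9 s$^{-1}$, and taking that *measured* rate as the target puts the
  self-consistent balanced solution at $w_{EP} \approx 0.6$, below the
  Dale-feasibility bound $w_{EP} > 1 + w_{PP}$ of the balance
  constraints — learning then runs away with $w_{PS}$ clipped at zero.
  With targets at the 1 and 2 s$^{-1}$ operating point the fixed point
  lies at $w_{EP} \approx 3.3$, $w_{PS} \approx 0.54$,
  $w_{PV} \approx 0.33$, comfortably feasible, and the PV baseline
  self-organizes to $\approx \rho_{P,0}$. Per-neuron measured targets
  remain available (`rho_e = NULL`).
* **Phase statistics**: responses are tail averages over the last 500 ms
  of each 1-s phase, excluding the transient onset/offset responses; the
  window is a parameter of `simulate_protocol()`.
* **Learning rates** are not published. The package defaults were chosen
  once so that (i) the weight change per 1-s stimulus is small compared
  with the weight scale — plasticity must not track individual stimuli,
  otherwise the convergence statistic is confounded by within-phase
  adaptation — and (ii) the default quasi-natural protocol converges
  within a few hundred stimuli. They are plain hyperparameters, exposed
  in `plasticity_config()`.
* **Dendritic correction $\epsilon = 0.1\,s^{-1}$**: the dendritic rule
  $\Delta w_{DS} \propto (A - \epsilon) r_S$ uses the rectified dendritic
  activity $A = [I^{syn}_D + c]_+$; $\epsilon$ trims the contribution of
  strong onset transients. The update is applied where the dendrite is
  active ($A > 0$). Applying the $-\epsilon r_S$ decay also to silent
  dendrites would make the rule erode dendritic inhibition during every
  baseline and playback phase (where SOM rates are highest); the summed
  SOM→dendrite weight then equilibrates *below* the strength needed to
  cancel the motor prediction for the strongest stimuli, and feedback
  responses leak through the dendrite at test. Gating the rule on
  dendritic activity preserves the rule's stated purpose and its fixed
  point ($A \approx \epsilon$ where active, silent otherwise) while
  making strong dendritic cancellation an attractor of learning.
* **Convergence criterion** (none is published): every 50 stimuli,
  training pauses for a frozen-weight probe — baseline, feedback and
  playback phases at the top training amplitude with plasticity off —
  and stops once the PC responses relative to the probe baseline are
  below 5% on population average *and* below 8% for every single cell,
  in both probe phases; otherwise it runs to the stimulus budget. Two
  details matter here. Probing with frozen weights is essential because
  the rules act as a fast feedback controller: statistics collected
  while plasticity is active understate the true imbalance severalfold.
  And the per-cell condition matters because balance is a cell-by-cell
  property — a population mean can look converged while a few cells
  with unlucky weight draws still sit outside the classification band.

## Training paradigms

`training_sequence()` generates quasi-natural training (QT: alternating
feedback and playback, each preceded by baseline), random-gain training
(RT: baselines alternating with phases whose $v$ and $m$ are independent
uniform draws) and coupled training (CT: feedback only). Training
playback uses $m = 0$ (the published description fixes only "visual input
not predicted by motor commands"); a partial-mismatch parameter exposes
other choices. Inter-stimulus baselines last 1 s — stimulus duration is
published, baseline duration is not.

## What the generator emulates — and what it does not

Stimulus protocols are scalar, piecewise-constant drives: the model
captures the *statistics of sensorimotor coupling* (which phases occur
during learning), not naturalistic time-varying stimuli, sensory noise,
or feature selectivity. Passing tests therefore demonstrate that the
plasticity rules balance the modeled pathways under these idealized
conditions; they do not show robustness to noisy or structured visual
input, nor do they address spiking dynamics or conductance-based
synapses.

## Problem sizes used in the test suite

The packaged tests train the default-size network (70 PCs) for the
headline emergence checks and use reduced populations (12–24 PCs) with
shorter stimulus budgets for the paradigm-comparison and sweep checks;
these sizes were chosen as the smallest at which classification
fractions are stable across seeds, and the size-invariant weight scaling
makes the operating points match the full-size network by construction.

## Validity regimes observed in this implementation

* **Local rule and connection density.** The local recurrent-drive rule
  is an alignment-based approximation: each PV neuron senses the error
  of the PCs it receives excitation from, not of those it inhibits. At
  the default connection probabilities (0.45 in, 0.6 out) the
  approximation balances the population mean, but the per-PV weights
  drift apart along weakly constrained directions and a fraction of PCs
  stays outside the classification band. When both PC-to-PV maps are
  dense (probability 0.9), the presynaptic and postsynaptic sets
  coincide almost fully, the approximation becomes accurate, and every
  PC classifies as nPE — which is the regime in which the rule is a
  stated substitute for backpropagation. Use
  `build_network(prob_overrides = c(pe = 0.9, ep = 0.9))` for this
  regime.
* **Reversed SOM/VIP routing (`f_som` near 0).** Because training to
  convergence enforces playback balance (playback phases are part of the
  training distribution and of the stopping probe), playback-responsive
  pPE cells do not survive convergence-stopped learning in the reversed
  configuration; the learned circuit instead expresses
  mismatch-positive cells through motor-driven SOM disinhibition of PV.
  pPE formation proper requires the symmetric protocol (training with
  mismatch instead of playback phases) or stopping before playback
  balance is reached.

## Known limitations

* The balance constraints require $w_{EP} > (1 + w_{PP}) V_E$ for
  Dale-compliant solutions; configurations violating this raise errors
  rather than silently clipping.
* Optogenetic manipulations are additive drive offsets; saturation
  effects can make rate fingerprints ambiguous, which is why
  `current_decomposition()` reports currents as the less ambiguous
  observable.
* Only one prediction-error polarity is learned per network; the
  symmetric pPE configuration is reachable by reversing SOM/VIP input
  routing (`input_config(f_som = 0)`), but simultaneous nPE+pPE learning
  is out of scope.
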