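---
title: "The A-GLIF model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The A-GLIF model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglif)
```

## The model

`aglif` implements an adaptive generalized leaky integrate-and-fire (A-GLIF)
point-neuron model for hippocampal CA1 pyramidal cells and interneurons. The
state is three-dimensional: the membrane potential $V$, an adaptation current
$I_{adap}$ standing for the outward (hyperpolarizing) intrinsic currents, and
a depolarizing current $I_{dep}$ standing for the inward ones. Between spike
events the state obeys the linear system

$$
\begin{aligned}
C_m \dot V &= \frac{C_m}{\tau_m}(V - E_L) - I_{adap} + I_{dep} + I_{stim},\\
\dot I_{adap} &= k_{adap}(V - E_L) - k_2 I_{adap},\\
\dot I_{dep} &= -k_1 I_{dep},
\end{aligned}
$$

with a spike registered whenever $V$ reaches the threshold $V_{th}$ while
$I_{stim} > I_{th}$ (the rheobase). After a spike the system is
re-initialized following a refractory gap $\Delta t_{ref}$ (2 ms by
default): $V$ restarts at the reset potential $V_r$, $I_{dep}$ at a constant
$I_{dep}^0$, and $I_{adap}$ at a value that depends on the stimulation
current and on the elapsed time since stimulation onset — this
current-dependence of the after-spike update is what lets a linear model
express accommodating, non-accommodating and blocking firing patterns.

Units are fixed throughout: mV, ms, pA, pF.

Two structural identities reduce the parameter count and are enforced by the
constructors rather than fitted: $k_{adap} = C_m k_1 k_2$ (which makes the
rescaled decay rates of the two currents equal) and $k_2 = -K/(C_m E_L)$,
which defines the positive scaling constant $K$. Parameter sets violating
either identity beyond a $10^{-9}$ relative tolerance are rejected, never
silently adjusted: the identities are part of the model definition, and a
quietly "repaired" file would misreport the cell it encodes.

## Nondimensional form and exact trajectories

With $\tilde t = t k_2$, $\tilde V = -V/E_L$ and currents rescaled by
$-k_2/(E_L k_{adap})$, the system depends on three parameters:
$\alpha = I_{stim}/K$ (scaled drive), $\beta = k_1/k_2$ and
$\delta = 1/(k_2 \tau_m)$; the time unit is $\tau = 1/k_2$ ms. The linear
system is solved in closed form by variation of constants. Writing
$A = (\delta+1)^2 - 4\beta$ and

$$
H_1(h) = \frac{2 e^{(\delta-1)h/2}\sinh(\sqrt{A}\,h/2)}{\sqrt{A}},\qquad
H_2(h) = 2 e^{(\delta-1)h/2}\cosh(\sqrt{A}\,h/2),
$$

every trajectory is an explicit combination of $H_1$, $H_2$ and
$e^{-\beta h}$; in particular the depolarizing-current response of the
potential, obtained from the particular solution
$p = (J+\beta I)^{-1}(-\beta, 0)^T e^{-\beta h}$ of the forced subsystem, is

$$
V_{dep}(h) = \beta\,\frac{(\beta-1)\bigl(H_2 - 2e^{-\beta h}\bigr) +
H_1\bigl[(\beta-1)(\delta+1) + 2\beta\bigr]}
{2\bigl(\beta^2 + (\beta-1)\delta\bigr)}\,I_{dep}^0 .
$$

This exactness matters twice: the simulator never accumulates integration
error, and the fitting cost can be evaluated by brute force at scale. The
closed form is validated in the test suite against a fixed-step RK4
integration (step $10^{-3}$, horizon 50 time units, 200 random stable
systems, $10^{-6}$ absolute agreement) and the RK4 oracle itself against
`deSolve`.

### Numerical edge cases

* For $A < 0$ the hyperbolic forms are replaced by the equivalent
  $\sin/\cos$ expressions so that outputs are exactly real; no complex
  arithmetic leaks out.
* For $|A| < 10^{-10}$ the removable singularity at the eigenvalue collision
  is evaluated through its series limit
  $H_1 \to h\,e^{(\delta-1)h/2}(1 + A h^2/24)$.
* The written-out solution also has removable singularities at
  $\beta = \delta$ and $\beta^2 + (\beta-1)\delta = 0$. Within $10^{-10}$ of
  either, the trajectory is evaluated exactly through the matrix exponential
  of the augmented system $[[M, b], [0, 0]]$ (with `Matrix::expm`), which is
  the analytic limit by construction and also covers non-diagonalizable
  Jacobians. Tests compare this branch against direct evaluations at
  $\pm 10^{-7}$ parameter offsets.

## Stability and the admissible parameter region

The Jacobian eigenvalues are $\lambda_1 = -\beta$ and
$\lambda_{2,3} = \bigl(\delta - 1 \pm \sqrt{(1+\delta)^2 - 4\beta}\bigr)/2$,
independent of the drive. `classify_stability()` labels the equilibrium as a
real-eigenvalue stable node ($\delta < \beta \le (1+\delta)^2/4$,
$0<\delta<1$), a damped focus ($\beta > (1+\delta)^2/4$, $0<\delta<1$), a
center ($\beta > 1$, $\delta = 1$), or unstable ($\beta<\delta$ with
$\delta\le 1$, or any $\beta$ with $\delta>1$ — the regime associated with
rebound spiking, which the model excludes). Measure-zero boundaries are
reported as `boundary_degenerate` instead of being forced into an open
region; when a parameter lands exactly on a boundary the honest answer is
"degenerate", and downstream code treats it as unusable for fitting.

Requiring that the subthreshold equilibrium stays below threshold for every
$I_{stim} < I_{th}$ yields the admissibility conditions checked by
`check_constraints()`: $0 < \delta < 1$,
$\alpha_{th} < (1+\tilde V_{th})(\delta-1)^2/4$ and
$\alpha_{th}/(1+\tilde V_{th}) + \delta < \beta \le (1+\delta)^2/4$, with
$\alpha_{th} = I_{th}/K$. The equivalent dimensional inequalities (a lower
bound on $K$ and a window on $k_{adap}$) are evaluated as redundant
cross-checks; a property test on $10^4$ random parameter draws confirms that
the two formulations never disagree (when the radicand of the dimensional
$K$ bound is negative the condition holds vacuously — the underlying
quadratic has no real root).

For subthreshold positive currents the trace relaxes to the equilibrium
$V_1^* = \alpha/(\beta-\delta) - 1$. For negative currents the equilibrium
is clamped: linear interpolation in $\alpha$ down to the potassium-reversal
floor $V_{min}$ (−90 mV) at the measured reference current
$I_{stim}^{neg}$, constant at $V_{min}$ below it. The simulator realizes
this by driving the closed form with the effective drive
$\alpha_{eff} = (\beta-\delta)(1 + V_1^*)$, which places the equilibrium at
the clamped value without altering the relaxation dynamics.

## The after-spike update: Monod rule, positivity, firing block

The after-spike adaptation value is interpolated by a saturating Monod-type
function of the elapsed time $\chi$ (ms) since the last instant the current
was at or below the rheobase:

$$
I_{adap}^0(\chi, I) = c + \frac{a\,e^{bI}\chi}{d + \chi},\qquad d > 0 .
$$

It is monotone in $\chi$ with the sign of $a$, monotone in $I$ with the sign
of $ab$, runs from $c$ at $\chi\to 0^+$ to the plateau $P(I) = c + a e^{bI}$,
and `monod_properties()` reports a positivity verdict: *global* when either
$a>0, c\ge 0$ or $a<0, b<0, c\ge -a$; *range-restricted* when positivity can
only be asserted over a supplied current range (for $a>0$ the plateau must
stay positive there; for $a<0$ both the intercept and the plateau must);
*fails* otherwise. Because $V$ is strictly decreasing in $I_{adap}^0$ (the
closed-form derivative is $-\beta H_1 < 0$ in the real-eigenvalue region),
an increasing update sequence directly produces lengthening inter-spike
intervals. The admissible update range is $[0, H]$ with
$H = \alpha/\beta + I_{dep}^0 + (\delta/\beta)(1 + V^0)$, the value at which
the post-reset slope of $V$ vanishes. Positivity is prioritized: negative
Monod values are clipped at zero, and values above $H$ are flagged but not
rejected, since outside the fitted current range the $H$ bound is advisory.
Out-of-range currents that drive the Monod function negative trigger a
vertical translation of the intercept (grid search over the mixing
coefficient $\eta \in [0,1]$, 101 points, minimizing the displacement
subject to positivity), with a fallback that zeroes the function at the
first spike time.

A *firing block* — the neuron stops firing long before the stimulation ends
and never recovers — is detected per current by
$t^{last}_{spk} + 2\,ISI_{last} < T$. Blocking currents are grouped into
maximal intervals of consecutive tested currents; the anchor points
$(I, t_{last} + ISI_{last}/2)$ at the interval endpoints define a straight
line $t = A I + B$ giving, for currents on the blocking side, the time past
which the update rule is undefined and the train terminates. When a single
current blocks, the interval is extended to the nearest firing current. The
validity threshold of each line is the midpoint between the nearest firing
current and the blocking endpoint adjacent to it; the midpoint is taken
between that firing current and the *blocking* endpoint (not the extended
interval endpoint), which is the only reading consistent across both the
degenerate and the two-current cases. A crossing at or past the cutoff is
discarded and the train is terminated with `blocked_at` set.

## Event-driven simulation

Both `simulate_constant()` and `simulate_piecewise()` share one engine.
Within a segment, threshold crossings of the closed form are bracketed on a
coarse grid (default 0.05 ms) and refined by bisection to $10^{-9}$ ms; a
test verifies spike times are invariant to $10^{-6}$ ms under halving the
scan step, so the grid only affects bracketing, never accuracy. Segment
boundary rules:

* downward step that stays above the rheobase: $V$ and $I_{adap}$ are
  continuous and $I_{dep}$ is re-seeded as
  $I_{adap} + \Theta^{\!*}\bar\alpha/\beta$, where $\Theta^{\!*}$ is the
  positive part of a finite-difference expression in the last two sampled
  potentials that keeps $\dot V > 0$ across the step. The sampling interval
  entering $\Theta$ is the trace step (default 0.1 ms) converted to
  nondimensional time, and the two potentials are evaluated exactly from the
  closed form of the previous segment. The instantaneous $I_{adap}(\bar t)$
  enters the re-seed (not the Monod value), matching the update's own
  notation when a spike coincides with the boundary.
* upward step between suprathreshold currents: the state is continuous and
  the stimulation-onset reference shifts forward,
  $t_{start} \leftarrow t_{start}(1 + (I_{prev}-I_{th})/I_{prev})$, which
  shortens the effective elapsed time entering subsequent Monod updates.
* step to or below the rheobase: the trace relaxes toward the (possibly
  clamped) equilibrium, $t_{start}$ resets to the end of the subthreshold
  epoch, and the next suprathreshold onset restarts from the first-spike
  conditions.
* a boundary falling inside a refractory gap is handled at the end of the
  gap (the state is undefined mid-reset); an upward step still applies its
  $t_{start}$ shift at that point.

During refractory gaps the recorded trace holds $V$ at the reset potential
and reports the currents as undefined. A single-segment protocol is executed
by exactly the same code path as a constant simulation, so their spike lists
are identical by construction — and asserted identical in the tests.

## Fitting pipeline

`fit_cell_ga()` fits a cell to per-current spike times. The cost focuses on
the first spike time and on containment of each experimental inter-spike
interval in the band $[ISI_{min}, ISI_{max}]$ implied by the admissible
adaptation range $[0, H]$ (both band edges are crossing times of the closed
form; an interval the model cannot re-fire within the scanned horizon
contributes the horizon itself as a finite penalty, keeping the cost
evaluable everywhere).

The search runs in a unit box decoded through
$(I_{th}, C_m, \delta, \alpha_{th}\text{-fraction}, \beta\text{-fraction},
I_{dep}^{start}, I_{dep}^0)$, so every candidate satisfies the stability
constraints by construction; $\tau_m$ and $K$ are derived fields of this
encoding. The rheobase interval is clamped by the data (above the highest
silent current below firing, below the lowest firing current). The genetic
algorithm is real-coded: tournament selection of size 3, blend crossover,
Gaussian mutation, elitism of one; the chromosome also carries one gene per
experimental inter-spike interval (as a fraction of $H$). The stop rule —
no relative improvement above 2% — is applied with a patience window
(default 10 consecutive stalled generations), because with elitism the best
cost is frequently flat between adjacent generations and a two-generation
reading would stop almost immediately.

The spike-timing cost alone leaves the pair $(\delta, \beta)$
under-identified: near-zero-cost solutions form a manifold, and different
points on it imply different adaptation dynamics. Three deterministic
refinement stages resolve this, all fitting only the experimental raster:

1. restarted Nelder-Mead polish of the structural genes on the spike cost;
2. a coarse-then-fine grid over the $(\delta, \beta)$ genes, re-optimizing
   the remaining genes at each node, scored by
   $\text{cost} + 10\times$ the RMS residual of a Monod fit to the inverted
   adaptation sequences — i.e. the model's own structural assumption that a
   single Monod function generates the per-spike updates;
3. model selection among the best candidates by agreement of the fully
   simulated raster with the data (spike counts first, then first-spike
   deviation), followed by a one-dimensional calibration of the fitted
   Monod intercept against the simulated raster, since a least-squares fit
   in adaptation space does not minimize error in spike-time space.

Per-spike adaptation values are recovered by inverting each experimental
interval on the closed form (the monotonicity of $V$ in $I_{adap}^0$
guarantees a unique root in $[0, H]$); the resulting sequences feed
`fit_monod()`, a bounded Levenberg-Marquardt minimization of the summed
squared residuals over all currents simultaneously, launched from a
deterministic multi-start grid around moment-style guesses and constrained
to the positivity conditions. Constant sequences are flagged as the
degenerate constant-interval case ($a = 0$) rather than fitted.

`validate_spike_trains()` applies the univariate Mann-Whitney U test with
continuity correction, per current and pooled over the (current, spike-time)
pairs. The bivariate spatial-rank extension and the Hotelling $t^2$ variant
are deliberately out of scope; the univariate test on the pooled pairs is
the documented substitution.

## Synthetic ground truth

`make_reference_cell()` draws complete cells from documented ranges
(resting potential −73 to −67 mV, threshold 16–22 mV above rest, reset
8–12 mV above rest, capacitance 120–220 pF, $\delta$ 0.02–0.04). $\beta$ is
placed near the top of its admissible window, where the two slow eigenvalues
are close and the inter-spike interval is strongly sensitive to the
adaptation value — the regime that produces pronounced accommodation — and
$K$ follows from the current at which the equilibrium reaches threshold
(95% of the lowest intended firing current), floored so $\alpha_{th}$ stays
inside its bound. Monod levels are drawn relative to the admissibility
bound $H$ (intercept 5–15% of $H$, plateau 78–88%), and for the adapting
phenotypes the current-sensitivity $b$ is chosen so the plateau tracks the
growth of $H$ with the stimulation, keeping accommodation visible across
the whole 200–1000 pA range. Five phenotypes are provided: adapting
($a>0, b>0$), adapting-saturating ($a>0, b<0$), non-adapting (small $a$,
near-constant intervals), blocking (adapting plus a synthesized block rule
cutting off 800 and 1000 pA between 200 and 280 ms), and high-threshold
(rheobase 500 pA, silent at 200–400 pA).

The generator emulates the constant-step protocol (200–1000 pA in 200 pA
increments, 400 ms steps) and optionally adds truncated-Gaussian jitter that
preserves ordering, refractory separation and per-current counts. It does
*not* emulate channel noise, spike waveforms, subthreshold oscillations or
trial-to-trial variability of real recordings — so passing the recovery
tests demonstrates that the pipeline identifies cells *within the model
family* from noiseless rasters, not that it fits arbitrary biological data.

## Problem sizes used by the test suite

Closed-form/RK4 agreement: 200 random stable systems, horizon 50 time
units, step $10^{-3}$. Stability map: $200\times200$ grid over
$(\beta,\delta) \in (0.015, 3]^2$. Subthreshold silence: 50 generated cells,
10 s horizon. Recovery: the five phenotype cells above, fitted at population
40 and 60 generations with the full refinement pipeline; recovery is judged
by exact per-current spike counts and first-spike agreement within 2 ms.
These sizes were chosen to exercise every code path at a scale where the
statistical claims are meaningful while the suite stays cheap to re-run
during development.

## Known limitations

* The model is linear between events; it cannot reproduce genuinely
  nonlinear subthreshold phenomena (resonance, rebound spiking is excluded
  by the admissible region).
* The firing-block rule is a data-driven straight line in the
  (current, time) plane; extrapolation far outside the tested currents is
  as trustworthy as any linear extrapolation.
* Continuously varying stimuli are approximated only as piecewise-constant
  protocols; synaptic conductance input is out of scope.
* Recovery guarantees are stated for noiseless synthetic rasters; with
  jitter, count agreement degrades gracefully but is no longer exact.
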