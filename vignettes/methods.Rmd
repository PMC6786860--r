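---
title: "Equation-oriented simulation of spiking networks: models, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equation-oriented simulation of spiking networks: models, methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling approach

`eqspike` is a clock-driven simulator for networks of spiking (and
non-spiking) model elements in which every model is written down as its
mathematical equations, as plain text with physical-unit annotations:

```
dv/dt = (ge + gi - (v - El))/taum : volt
dge/dt = -ge/taue : volt
dgi/dt = -gi/taui : volt
```

There are three kinds of entry: differential equations (`dX/dt = rhs :
unit`), subexpressions (`X = rhs : unit`, re-evaluated on demand), and
parameters (`X : unit`, per-instance state with no dynamics). The unit
annotation declares the dimension of the variable itself, so the
right-hand side of a differential entry must carry dimension unit/second.
Dimensional consistency is checked symbolically over the whole expression
tree before anything runs; inconsistent models are rejected with the two
conflicting dimensions named. Dimensions are vectors of seven exponents
over the SI base dimensions, and exponents may be fractional so that the
white-noise symbol `xi`, of dimension second^(-1/2), is first-class.

Identifiers in expressions resolve in order: model variables, then
namespace constants supplied by the user, then unit names (`-50*mV` works
inside any threshold, reset or initialization string). Numeric literals
are dimensionless. Single-character unit abbreviations are deliberately
not resolvable in expressions so that conventional variable names (gating
variables `m`, `h`, `n`; conductances `s`, `g`) never collide with units;
prefixed forms (`mV`, `ms`, `mS`, `cm2`) are available.

Model text is rewritten (`**` to `^`, word-form booleans to operators) and
parsed with the host language's parser; every downstream stage (dimension
inference, linearity detection, differentiation, kernel compilation)
operates on the resulting expression trees.

## Compilation and the execution schedule

Validated equations are compiled to vectorized kernels over named state
arrays (SI-scaled numeric vectors, one per variable per group). A kernel
evaluates one expression for all instances at once or for an index
subset; statement strings (reset code, synaptic event code) compile into
blocks of sequential assignments in which later statements see earlier
statements' writes. Code generation here means compilation to vectorized
host-runtime kernels grouped into schedule blocks; emitting native source
is out of scope.

Every timestep executes a fixed slot order:

1. summed (graded) synaptic updates and per-synapse integration,
2. group state updates,
3. threshold tests,
4. spike delivery (this step's spikes are enqueued, due spikes pop and
   run their event statements),
5. resets,
6. monitors.

Consequences of this order: integration in a step sees that step's graded
drive; zero-delay spikes are delivered within the step that produced
them; monitors record post-reset values (the alternative, sampling before
resets, was considered and rejected so that recorded traces never show
above-threshold values for a plain integrate-and-fire neuron). Events and
samples of step k are stamped with the step's start time k·dt.

Within one synaptic event statement, `+=` into a shared postsynaptic
variable accumulates contributions from all due synapses (duplicate-safe
aggregation). This is vectorized-per-statement semantics, not strictly
sequential per-synapse execution; the two differ only if one synapse
reads a variable that another due synapse wrote in the same statement,
which no fixture does.

## Integration methods

Method selection per group, unless overridden: **exact** when the system
is linear with constant coefficients and deterministic, **exponential
Euler** for other deterministic systems, **Euler–Maruyama** when `xi` is
present. `euler` and `rk4` are available explicitly.

*Exact.* Linearity is detected symbolically: subexpressions are inlined,
each right-hand side is differentiated with respect to each state
variable, and the derivative must be free of state variables; the
constant drive is the right-hand side at zero state. The affine update
x(t+dt) = M x(t) + k uses the matrix exponential of the augmented matrix
[[A, b], [0, 0]]·dt, which handles singular A (pure drive) without
special-casing. Only namespace constants and `(constant)`-flagged
parameters may appear in coefficients: a formally linear system whose
drive is a linked or synapse-written parameter changes between steps and
falls back to a per-step method (this matters for the ocular retina,
whose drive is a Gaussian of linked positions). Heterogeneous
(per-instance) coefficients get one (M, k) per distinct coefficient
tuple, computed at run start.

*Exponential Euler.* Each right-hand side is treated as locally affine in
its own variable, f = a − b x with b = −∂f/∂x evaluated at the current
state, and that variable is updated exactly over dt with the others
frozen: x' = x + f·(1 − e^(−b·dt))/b, with the b→0 limit handled by a
series branch below |b·dt| < 1e-12. This is exact for conditionally
linear systems such as Hodgkin–Huxley gating variables and is the
workhorse for the nonlinear fixtures.

*Euler–Maruyama.* The noise coefficient is extracted symbolically as
∂rhs/∂xi (xi must appear linearly, enforced); the update is
x' = x + f·dt + g·√dt·η with one standard normal per instance per step
from the global RNG stream.

Non-finite state after any step aborts with the variable name and time.

## Synapses, delays and graded interactions

Connectivity is expression-based: a boolean condition over `i`, `j` and
`_pre`/`_post`-suffixed variables is evaluated over the full
source×target cross product (chunked to bound memory), optionally thinned
by an independent Bernoulli draw per candidate pair. Creation order is
row-major and deterministic under a fixed seed. Explicit pair lists and
pure-probability connectivity are also supported.

Spike delivery uses a per-pathway ring-buffer queue. Delays are stored
per synapse in seconds and rounded to steps at run start as
floor(d/dt + 0.5) — ties round up, deliberately avoiding banker's
rounding — and a spike inserted with delay d steps pops exactly d steps
later. A population may carry several named pathways (the pitch fixture's
`direct` and `delayed`), each with its own delays and statements.

Graded interactions use summed variables: a subexpression entry named
`X_post` (or `X_pre`) with the `(summed)` flag sets — not increments —
variable X of each target instance to the sum of the expression over its
incoming synapses, every step, in slot 1, before the target integrates;
instances with no synapses get zero. Two populations summing into the
same target variable are rejected at run start. Per-synapse differential
equations (the slow graded synapse's activation) integrate in the same
slot with the pathway's own updater.

## Experiment protocols, snapshots and reproducibility

Protocol logic (loops, conditionals) is ordinary R around `run_network()`
— deliberately not a DSL. `store_network()`/`restore_network()` snapshot
and restore the clock, every state array, spike queues, monitor buffers
(truncating recorded data back to snapshot time) and the RNG state, so a
restored continuation is bit-identical. The bisection threshold search is
the flagship protocol: per iteration it restores, sets the membrane
potential to the per-instance estimate, simulates one trial, moves each
estimate down (spiked) or up (silent) by the current step, and halves the
step; after n iterations the estimate brackets the true threshold to
within step0·2^(1−n) provided it lies in the initial ±2·step0 range.

All randomness — `rand()`/`randn()` in expressions, connectivity
sampling, diffusion noise — draws from one global RNG stream;
(seed, model, dt, duration) fully determine every output. A single global
clock drives all objects (no per-object dt); none of the packaged
fixtures needs multiple clocks, and this is a deliberate simplification.
Durations round to whole steps with a warning beyond 1e-9·dt.

## The fixtures: what they emulate, and what they do not

**Pyloric circuit** (3 neurons: lumped AB/PD pacemaker, LP, PY). The
figure-level equations of the source model are not printed in the paper
body, so the fixture is a documented reconstruction: a Hindmarsh–Rose
three-variable burster in dimensionless form (standard parameters b=3,
d=5, s=4, x_rest=−1.6; one model time unit = 1 ms), mapped to membrane
potential by v = −40 mV + 20 mV·x, with the described regulation chain: a
calcium trace that jumps 0.1 at each spike (threshold x > 1, i.e.
−20 mV) and decays with τ = 300 ms; a slow variable z integrating
tanh((Ca − Ca_target)/0.2)/5 s; and two intrinsic conductances steered
oppositely by z (g excitatory toward a distant reversal, s inhibitory),
so each cell's long-run rate is pulled toward its label-specific calcium
target (ABPD 0.50, LP 0.30, PY 0.18 — pacemaker most active). Distant
reversals with small maximal conductances keep the drive nearly additive;
a conductance form with near-field reversals adds enough linear damping
to stabilize the burster's fixed point and silence it, which is why these
values were chosen. Fast graded synapses follow the printed condition
(five pairs); slow cholinergic synapses run pacemaker→LP and
pacemaker→PY per the circuit schematic. dt = 0.25 ms with exponential
Euler. The fixture reproduces structure and homeostatic adaptation, not
the published voltage traces; its constants live in
`pyloric_constants()`.

**Ocular pursuit.** Eye: critically damped second-order mechanics
(τ = 50 ms) around a resting position x0 that decays with 150 ms; object:
Ornstein–Uhlenbeck drift (τ = 500 ms, stationary sd 0.4 on a field of
view ~[−1, 1]); 100 retinal neurons with Gaussian tuning (width 0.25) to
the object's position in retinal coordinates, read through linked
variables; crossed projections to two motoneurons with weight ∝
eccentricity; each motoneuron spike kicks x0 by ±0.05. Gains were chosen
once so the closed loop tracks visibly better than the zero-weight
control under a paired (common-seed) comparison.

**Threshold finding.** 100 unconnected conductance-based neurons
(Traub–Miles-style Na/K/leak kinetics per membrane area, Cm = 1 μF/cm²,
leak 0.05 mS/cm² to −65 mV, g_K = 30 mS/cm², VT = −63 mV) with sodium
density swept 15→100 mS/cm². Rate functions use `exprel` so their
removable singularities are finite — the bisection grid can land exactly
on the crossover voltages. dt = 0.01 ms, 20 ms trials, 50 ms settling
before the stored reference state; bisection starts at −45 mV with a
25 mV step (bracketing the thresholds of the whole density range) and
runs 12 iterations so the final bracket (~0.012 mV) sits just above the
0.01 mV resolution of the scan oracle used in the tests.

**Pitch detection.** A stored waveform (pulse trains for tests; a
four-tone rising arpeggio for the demo) replaces live audio; `sound(t)`
is a user-registered function sampling it, exercising the extension
mechanism. The input cell is an integrate-and-fire neuron (τ = 1 ms, gain
5) with an adaptive threshold (rest 1, +0.1 per spike, τ = 10 ms) — the
increment and decay are sized so the cell keeps responding once per pulse
down to 2 ms periods instead of adapting to silence. Ten coincidence
detectors (τ = 1 ms, threshold 1.5, weight 1 per pathway) receive the
spike train twice, undelayed and with delay (j+1)·1 ms; only two near
coincident arrivals can fire a detector, so detector k prefers period
(k+1) ms. Harmonic detectors (multiples of the period) also respond;
edge effects make the fundamental's count strictly largest.

**CUBA benchmark.** 4000 leaky integrate-and-fire neurons (80%
excitatory), exponentially decaying current kicks (we = 1.62 mV,
wi = −9 mV, τm/τe/τi = 20/5/10 ms, Vt/Vr/El = −50/−60/−49 mV, 5 ms
refractory), Bernoulli(0.02) connectivity over all ordered pairs (mean
in-degree 80), 0.1 ms grid, exact integration — automatically selected in
the homogeneous variant. The heterogeneous variant draws each neuron's
three time constants uniformly in [90%, 110%] of the base values, forcing
per-instance update matrices.

## What passing tests show — and what they do not

The synthetic fixtures exercise the simulator's contracts: dimensional
validation, kernel-vs-interpreter equality, exact-vs-series integration,
queue exactness, summed-variable sums, snapshot round-trips, seeded
determinism, and the structural/qualitative behaviours stated for each
case study (connectivity sets, adaptation direction, tracking
improvement, period selectivity, in-degree statistics). They do not
validate biological parameter choices, reproduce published voltage
traces, or probe regimes the fixtures avoid (stiff systems, delays
comparable to simulation length, very large networks); the pyloric and
ocular constants are calibrations, not measurements.

## Numerical choices and limitations

Problem sizes used by the test suite: the CUBA in-degree check builds the
full 4000-neuron network; snapshot checks run 1000 neurons for 1 s; the
stochastic checks use 10⁴ paths; the sweep oracle batches 100×51
instances; the adaptation check runs the full 50 s pyloric simulation.
Quantity equality compares SI-scaled values exactly; tolerance is the
caller's concern. Dimension exponents are doubles (exact for the dyadic
rationals that occur in practice); offset and logarithmic units are out
of scope. The kernel layer is vectorized host-runtime evaluation, so
very small groups pay interpreter overhead per step; inline maps and
summed expressions are memoized and compiled once per run to keep the
3-neuron pyloric circuit's 200k-step run inexpensive. No implicit or
adaptive solvers are provided; stiff models must choose dt accordingly.
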