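---
title: "Simulating muscle force from a motor unit pool by twitch summation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating muscle force from a motor unit pool by twitch summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(mupsim)
```

## The model

A skeletal muscle is a pool of motor units (MUs): each motoneuron and the
muscle fibres it innervates. `mupsim` simulates muscle force from the bottom
up under three modelling assumptions:

1. **A single stimulus evokes one twitch.** Each MU's twitch is described by
   six parameters: lead time $T_{lead}$ (stimulus to force onset),
   half-contraction time $T_{hc}$, contraction time $T_c$ (onset to peak),
   half-relaxation time $T_{hr}$ (onset to half of peak during relaxation),
   total duration $T_{tot}$ and peak force $F_{max}$. All times are measured
   in ms; $T_{hc}$, $T_c$, $T_{hr}$ and $T_{tot}$ are counted from force
   onset. Two parameters (peak force and contraction time, the classical
   description) are not enough to capture the variety of twitch shapes seen
   across slow and fast units — in particular the long relaxation tails of
   slow units — which is exactly what drives their different tetanic
   behaviour.
2. **Within an MU, successive responses summate linearly and identically.**
   The force of MU $i$ under a stimulus train $t_{i1} < t_{i2} < \dots$ is
   $F_i(t) = \sum_j f_i(t - t_{ij})$ with a single fixed twitch shape $f_i$.
3. **Across MUs, forces add.** Whole-muscle force is the plain sum over the
   pool, reported together with the partial sums over the slow (S),
   fast-fatigue-resistant (FR) and fast-fatigable (FF) groups.

Assumptions 2 and 3 are simplifications: real tetani show twitch-to-twitch
variability, potentiation, sag and fatigue, and the mechanical summation of
MUs overlapping in the muscle is not exactly linear. None of these are
modelled here; the package simulates the linear-summation idealisation and
is structured so firing patterns, not contractile dynamics, are the
experimental variable.

## The six-parameter twitch curve

`twitch_6p()` builds a force-time curve that reproduces all six descriptors
exactly. With $\tau = t - T_{lead}$:

$$
F(\tau) = \begin{cases}
F_{max}\,(\tau/T_c)^m\, e^{m(1-\tau/T_c)} & 0 \le \tau \le T_c\\[4pt]
F_{max}\, e^{-c\,(\tau-T_c)^b} & T_c < \tau < T_{tot}\\[4pt]
0 & \text{otherwise.}
\end{cases}
$$

The rising piece is a normalized gamma-type pulse: it is 0 at onset, reaches
exactly $F_{max}$ with zero slope at $\tau = T_c$, and the exponent $m$ is
solved from the half-contraction constraint $F(T_{hc}) = F_{max}/2$
(`uniroot` on $(10^{-6}, 100)$, absolute tolerance $10^{-12}$; the defining
equation is monotone in $m$). Parameter sets with $T_{hc}/T_c$ close to 1
need $m$ beyond the bracket and are rejected with an explicit error rather
than extrapolated.

The relaxation piece is a stretched exponential whose two coefficients come
in closed form from the half-relaxation constraint $F(T_{hr}) = F_{max}/2$
and from the floor $F(T_{tot}) = \epsilon F_{max}$:

$$
b = \frac{\ln\!\big(\ln(1/\epsilon)/\ln 2\big)}
         {\ln\!\big((T_{tot}-T_c)/(T_{hr}-T_c)\big)},
\qquad
c = \frac{\ln 2}{(T_{hr}-T_c)^b}.
$$

**The relaxation floor $\epsilon$** (default 0.01) exists because a positive
exponential never reaches zero: the curve is truncated where it has decayed
to 1% of peak, which is what makes the finite duration $T_{tot}$ meaningful.
$\epsilon$ is configurable; anything well below half-maximum is admissible.

**When $b < 1$** (i.e. $T_{tot}-T_c$ more than $\ln(1/\epsilon)/\ln 2
\approx 6.64$ times $T_{hr}-T_c$) the relaxation piece leaves the peak with
infinite slope. The curve itself is still continuous and passes through all
six points, so the package accepts the parameters and signals a classed
warning (`mupsim_shallow_relaxation`) instead of failing; only curve points,
not derivatives, are constrained by the data. Bulk simulations build twitch
functions internally and muffle this warning to avoid repeating it once per
rebuild.

`twitch_2p()` provides the classical two-parameter curve
$F_{max}(\tau/T_c)e^{1-\tau/T_c}$ for comparison; it shares the peak but
has a rigid shape and an infinite tail (truncated only by the simulation
grid).

```{r twitch}
fn <- twitch_6p(twitch_params(2, 10, 20, 35, 80, 1))
fn
tt <- seq(0, 100, by = 0.1)
plot(tt, twitch_force(fn, tt), type = "l", xlab = "time (ms)",
     ylab = "force", ylim = c(0, 1))
lines(tt, twitch_force(twitch_2p(1, 20, 2), tt), lty = 2)
legend("topright", c("6-parameter", "2-parameter"), lty = 1:2, bty = "n")
```

## Stimulation regimes

Five firing regimes are provided, all parameterised in interpulse intervals
(IPIs; rate in Hz = 1000/IPI in ms):

* `regular_train()` — constant IPI; shared across the pool via
  `make_synchronous()` this is the constant-frequency nerve-stimulation
  protocol of physiological experiments.
* `irregular_train()` — successive IPIs drawn independently and uniformly
  between 50% and 150% of the mean. The uniform family is a modelling
  choice: it is the simplest distribution matching the stated variability
  bounds exactly, with no mass outside them. Degenerate bounds `c(1, 1)`
  recover the regular train, which the tests exploit.
* `make_regular_asynchronous()` — same IPI everywhere, but each MU's first
  spike is shifted by an independent uniform draw on $[0, 40]$ ms.
* `make_irregular_asynchronous()` — an independent irregular train per MU,
  each with its own mean IPI.
* `tc_scaled_mean_ipis()` — per-MU mean IPI $= 1.25\,T_c$, placing every
  unit on the steep portion of its force-frequency curve so all units
  produce similarly (un)fused tetani.

`size_principle_schedule()` composes irregular trains into Henneman's
recruitment order: first-stimulus times increase with peak-force rank across
the whole pool and last-stimulus targets decrease with it, so the weakest
unit works longest and the strongest shortest. The per-rank delays and
targets are user inputs — physiologically they encode how fast drive ramps
up and down; the `fig5` experiment uses a 50 ms spacing per rank on a
roughly 8 s active window as its demonstration default.

Pools and stimulation sets read and write the plain-text formats
`datatw.txt` (six whitespace-separated columns per MU:
$T_{lead}, T_{hc}, T_c, T_{hr}, T_{tot}, F_{max}$; S block first, then FR,
then FF, each sorted by increasing $F_{max}$) and `impulses.txt` (one column
per MU, either absolute times or a first-row recruitment delay followed by
consecutive IPIs). The two `impulses.txt` variants are numerically
ambiguous, so the format must always be named explicitly. Rectangular files
need a padding rule for unequal train lengths: the writer pads with -1, and
the reader terminates a train at any non-increasing time (times variant) or
non-positive interval (delay+IPI variant). Ten significant digits are
written, so round trips are faithful to text precision.

## The engine and its numerics

`simulate_mu()` evaluates the summation on a uniform grid
$t = 0, dt, \dots, T_{duration}$. For each stimulus only the grid window
covered by the twitch's support is touched, which makes long
low-rate simulations cheap; the result is numerically identical (to
$10^{-9}$ relative) to the naive double loop over all (stimulus, grid
point) pairs, and the test suite asserts exactly that equivalence against an
independent `outer()`-based reference.

Numerical choices that matter:

* **Grid step `dt = 0.1` ms** by default — far below the shortest
  half-contraction times of fast units (several ms), so twitch shapes are
  well resolved. It is configurable through `sim_config()`.
* **Sampling the peak.** A smooth peak falling between grid points is read
  up to $|F''(\mathrm{peak})|\,(dt/2)^2$ too low — a relative error of order
  $10^{-5}$–$10^{-4}$ at the default step. Peak-based quantities
  (force-frequency curves, gains) therefore carry this grid-phase jitter;
  the package's monotonicity tests allow for it explicitly (slack
  $2\times10^{-4}$, the computed bound for the default pool) rather than
  asserting exact ordering.
* **Truncation.** Stimuli after `duration` are ignored and responses
  straddling the end of the grid are cut. The six-parameter twitch is
  truncated at $T_{tot}$ by construction; the two-parameter model's
  exponential tail is bounded only by the grid.
* **Ties.** `peak_force()` returns the earliest grid time attaining the
  maximum.

`simulate_muscle()` returns per-MU series, the three group sums and the
total; conservation (total = sum of members, exactly, in one summation
order) and homogeneity (scaling all $F_{max}$ by $\alpha$ scales every
series by $\alpha$) are tested invariants.

```{r sim}
pool <- generate_pool(seed = 42)
stim <- make_synchronous(nrow(pool), regular_train(0, 20, 50))
trace <- simulate_muscle(pool, stim)
plot(trace)
```

## Derived analyses

**Force-frequency curve** (`force_frequency_curve()`): peak force of a
50-pulse regular train at 1, 10, 12.5, 16.6, 20, 25, 30, 33.3, 40, 50, 60,
75 and 100 Hz, normalized per series by the 1 Hz peak. At 1 Hz successive
responses of the truncated six-parameter twitch cannot overlap, so the
reference is that series' peak twitch force.

**Tetanic gain** (`tetanic_gain()`): the ratio of peak tetanic force at
100 Hz to that at 10 Hz, per MU, per group and for the whole muscle. Gains
are computed on group *sums* (not averages of member gains). Slow units,
with long relaxation relative to contraction, summate far more effectively:
on the default synthetic pool the S-group gain is roughly twice the fast
groups' (the acceptance script prints the exact values for its seed). The
gain is invariant under uniform force scaling but is *not* bounded by its
members' gains in general, since group peaks need not align in time.

**Fusion index** (`fusion_index()`): $1 - (\max - \min)/\max$ over a steady
window, 1 for a flat fused tetanus, 0 when force returns to zero between
stimuli. The window is the last 30% of the active period. The end of the
active period defaults to the end of force support, but for regime
comparisons it should be the time at which the *first* MU stops firing
(`compare_irregular_ripple()` does this): when the per-MU trains end at
scattered times, the decline of early-finishing units would otherwise be
counted as ripple and reverse the comparison. The metric itself is this
package's quantification; there is no standard definition of tetanic
fusion.

**Synchrony comparisons.** `compare_sync_async()` shows that shifting first
spikes (0–40 ms) lowers peak total force relative to synchronous firing at
the same rate — on the default 30-MU pool, in every one of 50 realisations,
by about 5–10%. This every-trial dominance is a pool-scale ensemble
property: with only a handful of units a lucky shift can align their
individual peaks better than synchrony does, so small-pool checks are
directional only. `compare_irregular_ripple()` shows the complementary
effect: *independent* irregular trains decorrelate the units' force
fluctuations and smooth the total, whereas one shared irregular pattern
makes the whole pool fluctuate coherently.

## The synthetic pool generator

The twitch parameters of real experimentally measured MU pools are not
publicly tabulated, so `generate_pool()` is a first-class module emulating
the statistical structure such datasets show:

* **Contraction times** uniform per type: S on $[20, 33.06]$ ms, FR on
  $[13.40, 19.00]$ ms, FF on $[13.01, 18.52]$ ms. These intervals are the
  exact inversions, through the $1.25\,T_c$ rule, of the physiological mean
  firing-rate windows 24.2–40.0 Hz (S), 42.1–59.7 Hz (FR) and 43.2–61.5 Hz
  (FF) observed for rat medial gastrocnemius MUs during natural movements —
  so a generated pool stimulated at its `tc_scaled_mean_ipis()` fires at
  realistic rates by construction.
* **Peak forces** follow an inverse power law $F_{max} = A\,T_c^{-\gamma}
  e^{\eta}$ with $\gamma = 2$ and lognormal jitter $\eta \sim N(0, 0.3^2)$:
  strong units are fast, but the relation is scattered rather than
  deterministic, as in real pools. The per-type amplitudes ($A$ = 800 S,
  8000 FR, 20000 FF) put the weakest S unit near 1 force unit and make FF
  units the strongest — force units are arbitrary and set by the input
  file.
* **Shape ratios** $T_{hc}/T_c \in [0.45, 0.65]$ for all types;
  $T_{hr}/T_c \in [1.5, 2.2]$ and $T_{tot}/T_c \in [4, 7]$ for S versus
  $[1.3, 1.8]$ and $[3, 5]$ for FR/FF — slow units relax relatively slower,
  which is what gives them their high tetanic gain. $T_{lead}$ is uniform
  on $[1, 4]$ ms. These ranges are declared defaults (editable via
  `default_type_profiles()`), chosen to be physiologically plausible for a
  mixed mammalian hind-limb muscle.
* Each type block is re-sorted by $F_{max}$ so the pool satisfies the file
  ordering convention, and regeneration under the same seed is
  bit-identical.

The default composition is 10/10/10 (equal types make group contrasts easy
to see); the preset `"rat-MG-realistic"` ships the experimentally estimated
8 S / 23 FR / 26 FF composition of the male rat medial gastrocnemius.

What the generator does *not* emulate: correlations between shape ratios
and force beyond the power law, fatigue-related properties, sag, doublets,
or day-to-day variability of real recordings. Tests passing on synthetic
pools therefore validate the simulator's mechanics and the qualitative
slow-versus-fast contrasts, not quantitative agreement with any particular
experimental pool — in particular, published whole-muscle gain figures
measured on unpublished experimental twitch sets cannot be reproduced,
only their ordering (S far above FR/FF).

## Problem sizes and reproducibility

The shipped test-and-analysis workloads use a 30-MU pool, 50-pulse trains,
`dt = 0.1` ms and 50-seed ensembles for the stochastic comparisons — enough
for every ensemble statement to be stable across seeds while keeping a full
run in tens of seconds. Every stochastic function takes a `seed` argument,
restores the caller's RNG state, and records the seed in its output where a
container exists; `run_simulation()` and `run_experiment()` write a
`manifest.json` (configuration echo, seed, package version) sufficient to
reproduce their outputs bit-identically.

## Known limitations

* Linear summation throughout: no saturation, no nonlinear MU interaction,
  no twitch-to-twitch variability, potentiation, sag or fatigue.
* No motoneuron model: firing patterns are inputs, not generated from an
  excitatory drive.
* The fusion index is a pragmatic ripple metric, not a standard quantity.
* The six-parameter curve constrains values, not slopes; for extreme
  duration ratios the relaxation branch leaves the peak non-smoothly
  (warned, not rejected).
* Only plain-text input formats are supported.
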