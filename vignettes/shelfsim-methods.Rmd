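---
title: "Shelf-life kinetics and quality-controlled logistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shelf-life kinetics and quality-controlled logistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfsim)
```

shelfsim simulates a sensor-network-driven smart warehouse for perishable
produce. This vignette is the package's account of the science it
implements: the kinetic shelf-life model, the lattice reconstruction of the
room's temperature field, the monitoring loop, the quality-controlled
logistics (QCL) optimizer, the transporter layer, and the synthetic
environment that replaces all hardware. It also records the numerical and
design choices made where more than one defensible option existed.

## The kinetic shelf-life model

Product quality is tracked through a single measurable quality factor
$c$ — for the built-in preset, tomato firmness in newtons, the standard
ripeness index for climacteric fruit. Decay is first order at a
temperature-dependent rate $k(T)$ given by the ratio form of the Arrhenius
law:

$$k(T) = k_\mathrm{ref}\,
  \exp\!\left[-\frac{E_a}{R}\left(\frac{1}{T}-\frac{1}{T_\mathrm{ref}}\right)\right],
  \qquad R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}},$$

with temperatures in kelvin internally (degrees Celsius at every
interface) and $E_a$ supplied in kJ/mol. Remaining shelf life follows from
the current quality factor $c'$ and the failure level $c_\mathrm{eq}$:

$$\mathrm{SL} = \frac{1}{k}\ln\frac{c'}{c_\mathrm{eq}},$$

clamped at zero once $c' \le c_\mathrm{eq}$.

The tomato-firmness preset is $k_\mathrm{ref} = 0.2\ \mathrm{day^{-1}}$ at
$T_\mathrm{ref} = 20\,^\circ$C, $E_a = 64.8$ kJ/mol, $c_0 = 12.4$ N,
$c_\mathrm{eq} = 3$ N. The canonical rate unit throughout the package is
day$^{-1}$: kinetic rate constants for produce are sometimes tabulated
with an s$^{-1}$ label, but only the per-day reading is dimensionally
consistent with day-scale shelf lives, and with it the preset yields
7.10 days of initial shelf life at 20 °C, 2.95 days (≈3) at 30 °C and
1.30 days (≈1.5) at 40 °C. We report 7.10 days as-is and do not round it
up to a headline figure.

Two first-order integration forms are provided behind the `form`
selector of `decay_step()`:

* `"exponential"` (default): $c' = c\,e^{-k\,\Delta t}$ — the unique form
  consistent with the logarithmic shelf-life expression above;
* `"equilibrium"`: $c' = c_\mathrm{eq} + (c - c_\mathrm{eq})\,e^{-k\,\Delta t}$,
  which decays towards the failure level rather than zero.

Under time-varying temperature the model integrates with a
piecewise-constant rate per sampling interval, matching the discrete
control loop: each interval uses the rate derived from that interval's
reading. Temperature-sensor accuracy $\pm a$ propagates into a rate
interval $[k(T-a),\,k(T+a)]$ and hence into shelf-life bounds
$\mathrm{SL}^-(k(T+a)) \le \mathrm{SL} \le \mathrm{SL}^+(k(T-a))$.

`fit_rate()` estimates $k$ from an observed $(t, c)$ series by ordinary
least squares on the linearized model ($-\ln(c/c_1)$ against $t$), the
conventional way decay rates are extracted from empirical firmness
series. The intercept is left free so multiplicative observation noise
does not bias the slope.

## Field reconstruction on the room lattice

The storage room ($l_1 \times l_2$ metres) is divided into an
$M_1 \times M_2$ lattice (default $5 \times 5$ over 6.3 m × 6.7 m). Rows
follow the y axis, columns the x axis; a sensor at $(x, y)$ maps to cell
$(\lfloor y/\Delta y\rfloor + 1,\ \lfloor x/\Delta x\rfloor + 1)$, with
two guards: positions on the far walls clamp into the last cell, and the
floor division tolerates $10^{-9}$ of floating-point slack so sensors
mounted exactly on a grid line land in the upper cell. With these rules
the eight reference wall sensors occupy the eight boundary cells
(1,2), (1,4), (2,1), (2,5), (4,1), (4,5), (5,2), (5,4).

Unmeasured cells are filled by contiguous-element averaging: a
Gauss–Seidel sweep (row-major, deterministic) repeatedly replaces every
derived cell by the mean of its available 4-neighbours, with measured
cells held fixed — a discrete Laplace fill. Convergence is declared when
the largest per-sweep change drops below 0.01 (°C or %RH), with a cap of
10 000 sweeps; the scheme inherits the discrete maximum principle, so
derived values never leave the range of the measured ones. The tests
check the fill against an exact linear solve of the same averaging
system on small lattices.

The inter-sensor-distance (Isd) characterization re-creates the error
study that motivates the sensor-count rule
$N_s = \mathrm{round}\{(l_1+l_2)/\mathrm{Isd}^*\}$: for each candidate
spacing (default 1–2.5 m in 0.25 m steps, 16 events each), a
fully-sensed truth field is compared against a reconstruction from wall
sensors spaced Isd apart. Because the package has no physical room, the
truth fields are synthetic smooth gradients (random plane plus one
sinusoidal bump) — the meaningful, reproducible surface here is the
monotone error-versus-spacing trend and the zero error at full coverage,
not any absolute error magnitude, which depends entirely on the room.

Sensor health follows a strict rule: battery strictly below 5 %, or a
working flag of 0, removes the node from the measured mask and emits an
intervention warning; a node at exactly 5 % is retained.

## The monitoring loop

Every `ts` seconds (default 300 s) each pallet's reading is compared
with the recommended storage values within accuracy-derived bands
(defaults: 20 ± 2 °C, 55.73 ± 3.5 %RH, 100 ± 20 lux). Band semantics are
symmetric and inclusive: a reading exactly on the edge raises no flag.
Only the temperature test selects the decay rate — inside the band the
reference rate $k_\mathrm{ref}$ is used, outside it the Arrhenius rate
at the reading — because the shelf-life model is temperature-driven;
humidity and light violations raise their intervention flags but do not
alter the kinetics, and corrective action for them is left to a human
operator. A missing reading carries the previous one forward and raises
the working flag. The loop runs while SL > 0; at constant temperature
its expiry time agrees with the closed form $(1/k)\ln(c_0/c_\mathrm{eq})$
to within one sampling interval.

## The QCL optimizer

The optimizer's substrate is the shelf-life cube
$\mathrm{SL}_{i,j,p}$ — the shelf life pallet $p$ would have if it sat in
cell $(i,j)$ under the current temperature field — together with a
companion quality cube $C_{i,j,p}$ holding the hypothetical quality after
one sampling interval at the cell's rate. The cube is frozen for the
duration of one optimization run; temperatures and quality factors are
not re-sampled mid-run.

Displacement is gated by a firmness-decrease trigger: if the drop
between two consecutive measurements, expressed per second, meets the
threshold $C_\mathrm{th}$, the optimizer starts. Two presets ship
(2.68 × 10⁻⁵ N/s for the 24 °C setting and 3.184 × 10⁻⁵ N/s for 26 °C);
they are stored verbatim as reprogrammable constants because no unit
reading of the kinetic preset reproduces them exactly, and deriving them
would misrepresent their provenance.

One selection subroutine over $n$ active pallets works as follows.
For each of the $n$ cyclic left shifts of the pallet-ID vector, pallets
are placed greedily in order: each takes the free cell maximizing its
own SL layer (its current cell counts as free; cells of other pallets
and cells already assigned within the order do not), and the assigned
SLs are summed into the order score $\mathrm{SLs}$. The order with the
highest score wins; its first ID is the "best pallet", which is
displaced to its assigned cell and excluded from further computation.
Iteration accounting is one iteration per greedy placement plus one per
order sum — $n(n+1)$ per subroutine (20 for $n=4$, 12 for $n=3$) — and
the final lone pallet costs a single placement with no sum, giving
$\sum_{n=2}^{N_p} n(n+1) + 1$ in total (39 for four pallets). This is
the unique simple accounting consistent with all three iteration counts
quoted above, and the executed counters are tested against the closed
form for $N_p \in \{2,\dots,6\}$.

Tie-breaks are deterministic by construction: cell argmaxes resolve
row-major (smallest row, then column) and equal order scores resolve to
the earliest cyclic shift. Because a pallet may stay put and the best
pallet is always placed first in its winning order, the summed shelf
life at the final cells can never fall below its value at the initial
cells; the suite asserts this on every seeded random scenario. The
registry enforces the capacity rule $N_p < M^2 - 3$ at construction.

In the end-to-end pipeline (`run_warehouse()`), a 2-hour cooldown
(configurable) follows each executed optimization: in a uniformly warm
room the trigger would otherwise re-fire on every tick and schedule
no-op optimizations. The cooldown is a pipeline policy, not part of the
optimizer itself.

## The transporter layer

Moves are communicated as fixed 12-byte strings
`[89, add_btT, add_btP, 89, 90, x1, y1, 90, 91, x2, y2, 91]` with
separators 89/90/91; decoding validates length, separators and lattice
bounds and distinguishes four rejection modes (bad length, bad
separator, out-of-range coordinate, addressed elsewhere), each of which
leaves the transporter idle.

Paths are planned on the lattice by breadth-first search over
4-neighbours around the encumbrance matrix (the moving pallet's own cell
is treated as free, every other pallet's cell as an obstacle). Neighbour
expansion is fixed — x-axis moves before y-axis, increasing index before
decreasing — so shortest paths and their tie-breaks are reproducible;
the suite checks optimality against an independent exhaustive
relaxation on small rooms.

The drive logic is modelled as a 4-heading state machine: a unit step
along the heading drives ahead (motor pair 0/1) with the wheel centred
at `Cp`; the opposite step reverses (1/0) without steering; a
perpendicular step steers once (`Cp ± Rs`, sign by turn direction) and
re-orients the heading. A 1-bit axis memory cannot encode four headings,
so the compass heading is the source of truth and the axis bit `Z`
(0 = x-travel, 1 = y-travel) is exposed alongside it for compatibility
with gate-level implementations. Steps that change both axes violate
the step-by-step path constraint and are rejected. Route replays derive
each new position from the emitted actuation — not from the plan — so
the simulation genuinely verifies that the drive logic tracks the path.

## The synthetic environment

`generate_room()` replaces the physical room. The latent temperature of
the room is a shared daily sinusoid (amplitude 1 °C, peaking
mid-afternoon) around a 21.3 °C mean, plus per-sensor AR(1) jitter
(lag-0.95, stationary sd tied to the configured 1.2 °C spread).
Window-adjacent sensors (S1 and S2 in the reference scenario) add an
overheating offset that ramps linearly from 9:00 to a daily peak drawn
from $\mathcal N(2.8, 0.8^2)$ °C at 16:00 and then relaxes at
0.1 °C/h — slow enough that a residual offset persists into the next
morning, as sun-warmed walls do. Relative humidity tracks temperature
inversely at −2.5 % per +3 °C around 55.73 %, with its own AR(1)
jitter. Illuminance is a day/night square wave (500/1 lux ± 20 %)
within the 1–1000 lux sensor range. Reported values add *bounded*
uniform measurement noise (±2 °C, ±3.5 %RH), so the reported-minus-latent
difference never exceeds the configured accuracy; batteries drain
linearly (0.5 %/day default) and a working-flag dropout probability
(default 0) can inject failures.

These defaults are the package's study conditions: over 100 seeds the
10-day room mean falls inside 21.3 ± 1.2 °C (and RH inside
55.73 ± 3 %) in at least 95 % of runs, which the acceptance suite
asserts. What the generator does *not* emulate: spatial correlation
between neighbouring wall sensors beyond the shared room trajectory,
door-opening transients, HVAC cycling, and radiative asymmetries other
than the single window ramp. Tests passing on this generator therefore
demonstrate correctness of the computation, not calibration to any
particular physical room.

## Numerical choices and degenerate inputs

* Rounding in the sensor-count rule uses round-half-away-from-zero
  (`floor(x + 0.5)`), so counts do not depend on banker's rounding.
* Shelf life is clamped at 0; quality is clamped at 0 under the
  exponential form; an expired-at-start pallet ($c_0 = c_\mathrm{eq}$)
  is legal and the monitoring loop returns immediately.
* Interpolation seeds derived cells with the measured mean before the
  first sweep; convergence tolerance 0.01, cap 10 000 sweeps.
* `fit_rate()` requires strictly increasing times and positive quality
  values; a two-point series returns the exact slope with no standard
  error.
* All randomness is seeded explicitly; identical seeds give
  byte-identical synthetic logs and identical end-to-end reports.

## Problem sizes used by the test suite

The suite runs entirely on generated data: 100-seed sweeps of the
10-day default profile for the statistical targets, 16 events per Isd
for the error characterization, 200 replicates for rate recovery,
exhaustive obstacle sets of size ≤ 2 (plus seeded denser instances) for
path-planner optimality, and 100 seeded route replays. These sizes keep
the full suite under a minute on one core while leaving each statistical
assertion with comfortable margin.

## Known limitations

* The optimizer is greedy over cyclic orders, not an exact assignment
  solver; it inherits the cyclic-greedy procedure's semantics rather than
  optimizing globally (an optimal transport/Hungarian assignment could
  score higher but would not reproduce the iteration accounting).
* The quality cube freezes quality at optimization time; a pallet's
  decay during its own transport is neglected, consistent with
  minute-scale moves against day-scale kinetics.
* Humidity and light affect flags only; psychrometric effects on the
  decay rate are out of scope.
* The drive model abstracts servo/DC electrical behaviour into the
  truth-table semantics; PWM duty cycles and wheel odometry are not
  simulated.
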