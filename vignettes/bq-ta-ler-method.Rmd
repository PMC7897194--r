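---
title: "Restraining torsion angles against 3J-couplings: the BQ-TA-LER method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraining torsion angles against 3J-couplings: the BQ-TA-LER method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqtaler)
```

## The problem

A measured three-bond scalar coupling reports on a molecular torsion
through the Karplus relation

$$ {}^3J(\theta) = a\cos^2\theta + b\cos\theta + c, $$

where $\theta$ is the dihedral in the coupling's own frame — a fixed
angular offset away from the backbone $\varphi$ or side-chain $\chi_1$
torsion it is attached to. Two difficulties make $^3J$ data awkward for
structure refinement. First, the relation is up to four-fold degenerate:
for a mid-range coupling there are four distinct dihedrals with the same
$J$, so no pointwise penalty can know which one to aim for. Second, the
measured value is a long-time, large-ensemble average; a single structure
that reproduces it may be physically wrong when the real system averages
over several rotamers.

The biquadratic time-averaging local-elevation restraint (BQ-TA-LER)
addresses both. It penalises a torsion only when the *instantaneous*
coupling $J(t)$ and an exponentially damped *memory average*
$\langle J\rangle_t$ are simultaneously outside a flat-bottom band
$[J^0-\Delta J^{fb},\ J^0+\Delta J^{fb}]$ around the target, on the same
side. The penalty is not a spring on $\theta$: it is energy deposited
into the local-elevation bin currently occupied by the torsion, so the
restraint drives the coordinate *away* from wherever it sits while the
data are violated, searching the whole circle for conformations — or
mixtures of conformations — that satisfy the average.

## The restraint term

The circle is divided into $N_{le}$ bins with centers
$\theta_i^0 = 2\pi i/N_{le}$ and width $\Delta\theta^0 = 2\pi/N_{le}$.
The restraining energy is a Gaussian comb

$$ V(\theta) = \sum_{i=1}^{N_{le}} K^{Jr}\,\omega_i(t)\,
   \exp\!\left(-\frac{(\theta-\theta_i^0)^2}{2(\Delta\theta^0)^2}\right), $$

with each deviation $\theta - \theta_i^0$ wrapped to its nearest periodic
image (the comb must live on a circle; with $N_{le} \ge 8$ truncating to
the nearest image changes the energy by less than $10^{-8}$ of a peak).
The weights are running time averages of the gated biquadratic factor:
while the angle occupies bin $i$ and both $J(t)$ and
$\langle J\rangle_t$ exceed $J^0 + \Delta J^{fb}$,

$$ S_i \mathrel{+}= \big(J - J^0 - \Delta J^{fb}\big)^2
   \big(\langle J\rangle_t - J^0 - \Delta J^{fb}\big)^2\, dt,
   \qquad \omega_i = S_i / t, $$

with the mirrored expression below $J^0 - \Delta J^{fb}$. Three
consequences matter in practice:

* **Self-limiting growth.** The $1/t$ normalisation makes $\omega_i$ the
  *average* violation intensity in bin $i$. Once the data are satisfied,
  every weight decays as $1/t$; the landscape is a memory, not a ratchet.
* **Both-sided gating.** If the instantaneous coupling swings above the
  band while the average is still below it, nothing is deposited. Only
  coherent violations count, which is what distinguishes a wrong rotamer
  from ordinary fluctuation.
* **Edge conventions.** The step function counts the boundary as a
  violation at the upper edge ($H(x;x_0)=1$ at $x=x_0$) and as satisfied
  at the lower edge (through $1-H$); at the exact edge the quadratic
  factor is zero anyway, so the distinction never contributes energy.

The damped average follows

$$ \langle J\rangle_t = \big[\tau_J(1-e^{-t/\tau_J})\big]^{-1}
   \int_0^t e^{-(t-t')/\tau_J}\, J(t')\, dt', $$

discretised by left rectangles with an exponential prefactor, a choice
made so that a constant signal is an exact fixed point at every time and
the first sample initialises the average to itself.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `K_Jr`    | 50   | kJ mol^-1 Hz^-4 | overall weight of the penalty |
| `dJ_fb`   | 1.0  | Hz   | flat-bottom half-width; the accepted Karplus uncertainty (1–2 Hz) |
| `tau_J`   | 500  | ps   | memory relaxation time of the damped average |
| `N_le`    | 36   | —    | grid intervals (10 degree bins) |

The number of grid intervals is not reported for the reference
application of the method; 36 gives bins comparable to typical torsional
fluctuation widths and makes the uniform-weight comb flat to better than
$10^{-3}$. Targets are always capped to the attainable range of their
Karplus curve before restraining (a 10.6 Hz backbone coupling against a
curve with a 9.7 Hz maximum is restrained to 9.7 Hz).

Two built-in parameter sets are provided: the backbone HN-HA set
(a = 6.4, b = −1.4, c = 1.9 Hz, maximum 9.7 Hz) and the side-chain HA-HB
set (a = 9.5, b = −1.6, c = 1.8 Hz, maximum 12.9 Hz). Offsets between
the molecular torsion and the coupling dihedral are fixed per coupling
kind: −60° for HN-HA (and the glycine Re hydrogen), +60° for the glycine
Si hydrogen, −120° for beta-2-type hydrogens (including Ile/Thr single
beta hydrogens) and 0° for beta-3-type hydrogens (including Val). These
reproduce all nine numerically printed structure-derived couplings in
the reference data (e.g. $\varphi=-79°\rightarrow 6.6$ Hz,
$\chi_1=-89°\rightarrow 10.5/1.8$ Hz). The Si-hydrogen offset follows by
elimination from the published coupling curves and has no independent
numeric check.

## The toy dynamics sampler

The restraint is exercised with Langevin dynamics on bare torsional
coordinates under cosine-series reference potentials
$V(\theta)=\sum_n k_n(1+\cos(n\theta-\delta_n))$. The integrator is the
BAOAB splitting — a deliberate substitution for the leap-frog/weak-coupling
scheme of full solvated simulations, because a bare one-dimensional
coordinate needs a sampler with the exact canonical distribution as its
stationary law, and BAOAB delivers that with very small time-step bias.
The step is 0.002 ps (matching the 2 fs molecular-dynamics convention),
the bath 308 K, friction 10 ps$^{-1}$. The torsional inertia default is
0.05 kJ mol$^{-1}$ ps$^2$ rad$^{-2}$: local-elevation combs at realistic
fill levels have curvatures around $10^3$ kJ mol$^{-1}$ rad$^{-2}$, and
this inertia keeps $\omega\,\Delta t$ comfortably below the stability
edge of the splitting while still decorrelating in a fraction of a
picosecond. Unrestrained sampling is verified against the Boltzmann
density by a Kolmogorov–Smirnov check at the 1% level with $10^5$
quarter-picosecond frames.

Within each step the update order is fixed: positions move, then the
damped average is updated, then the weight deposit is made, and the
force on the way out of the step uses the weights through the current
step. The reference application does not document its internal order;
this one is chosen so the force never uses information the average has
not yet seen.

## The demonstration scenarios

`fixture_scenarios()` returns three single-torsion systems that emulate
the qualitatively distinct regimes in which coupling data correct a
simulation. They are the package's study conditions: their parameters
are fixed here, once, and the acceptance workflow runs them as-is.

**Backbone relocation (`asn103_like`).** An HN-HA coupling with target
8.2 Hz in a double well: the starting well (−55°) yields ~3.3 Hz, a
second well at −145° yields ~8.4 Hz, and the ~42 kJ/mol barrier makes
unrestrained crossing a once-per-hundreds-of-nanoseconds event. The
restraint fills the wrong well within tens of picoseconds and the
trajectory spends the rest of the run in the data-consistent well. A
single-well version of this scenario is deliberately *not* used: with a
fast-relaxing unimodal landscape the gate reaches a mean-field steady
state that pins the average coupling just below the edge of the flat
bottom — the restraint stops pushing the moment the average enters the
band, so the stationary deviation is approximately $\Delta J^{fb}$ by
construction. Relocation between metastable wells, the situation the
method was built for, is what produces averages well inside the band.

**Escape into an unvisited rotamer (`thr89_like`).** A Thr-type HA-HB
coupling (target 9.5 Hz) in a three-well $\chi_1$ landscape whose deep
+60° well yields 3.4 Hz. The barriers (~44 kJ/mol) are high enough that
a 2 ns unrestrained run never leaves the starting well; the restrained
run deposits its way out and settles around −40° to −95°, sculpting the
−60° well (whose bottom at 12.9 Hz overshoots the target) into flanks
where the coupling straddles 9.5 Hz.

**Averaging across rotamers (`val99_like`).** A Val-type coupling with
target 6.3 Hz in a landscape whose accessible wells give 3.4 Hz
(±60°) and 12.9 Hz (180°), while the region around 0° — where a single
angle *could* produce 6.3 Hz — is strongly disfavoured. No accessible
single conformation matches the data; the restrained run alternates
between low- and high-coupling wells so that only the *average* agrees.
This is the hardest regime: the gate throttles its own deposits
quadratically as the average approaches the band, so the stationary
average sits close to the lower band edge. The reference application of
the method shows the same behaviour — its restrained average for the
valine case misses the experimental value by exactly the flat-bottom
width.

Restrained runs are 10 ns with $\tau_J = 200$ ps (1/50 of the run; the
guidance is $\tau_J$ at most 1/10, and the reference runs used 1/40);
unrestrained comparison runs are 2 ns. The restrained outcome is judged
on the mean instantaneous coupling over the production part of the run
(first 10% discarded), the same per-run average the method's reference
results report; the end value of the $\tau$-damped average is a window
of width $\sim\tau$ and in multistable systems carries substantial
end-phase noise.

What these scenarios do **not** emulate: solvent friction memory,
coupling between torsions, Cartesian force projection through the
dihedral geometry, and competition among hundreds of simultaneous
restraints. Passing them shows the restraint mechanics, gating and
escape behaviour are correct — not that a full protein refinement would
reproduce every experimental coupling.

## Observable analysis

The analysis half of the package mirrors the standard NMR-versus-
simulation toolbox:

* per-trajectory coupling means and RMSFs;
* cross-source means and population RMSDs for comparison tables;
* deviation histograms with $(k, k+1]$ Hz bins, deviations of at most
  1 Hz uncounted, and experimental values capped to the Karplus range
  first — the only convention that reproduces the reference histogram
  row (13, 2, 1, 0, 0) given printed deviations of exactly 1.0 and
  2.0 Hz;
* consensus stereo-specific assignment: each source votes for the
  pairing of the two unassigned experimental couplings with its two
  calculated ones that minimises the summed absolute deviation (ties
  abstain); at least 3 of 4 sources must agree, with an optional
  fallback source set mirroring the X-ray fallback used for one glycine;
* $S^2$ order parameters from the ensemble expression with
  $\mu_\alpha\mu_\beta/r^3$ averages over non-overlapping 1 ns windows
  (truncated final window discarded), reducing to the unit-vector
  Lipari–Szabo form for constraint-rigid bond lengths;
* $\langle r^{-3}\rangle^{-1/3}$ NOE distance averaging and violation
  histograms;
* hydrogen-bond occupancy by the strict 0.25 nm / 135° geometric
  criterion.

Reporting uses round-half-away-from-zero at one decimal, applied only at
the output layer; this is the convention that matches the printed
reference tables (a mean of 7.45 prints as 7.5).

## Numerical choices and degenerate inputs

* Karplus inversion solves the quadratic in $\cos\theta$ analytically;
  roots with $|\cos\theta| > 1 + 10^{-12}$ are discarded and values
  within $10^{-12}$ of $\pm 1$ clamped. Merged double roots are
  deduplicated with a $10^{-4}$ degree tolerance — arccos conditioning
  near $\pm 1$ spreads an exactly degenerate root over about $10^{-5}$
  degrees, so a tolerance at the root-spacing scale of the clamp window
  is required.
* Angles are degrees at every public interface, radians internally;
  torsions are reported in $(-180, 180]$.
* Bins are half-open, lower edge inclusive, and partition the circle
  exactly; an angle on a bin edge belongs to the upper bin.
* The damped average of a fresh state is the first instantaneous sample
  (the $t \to 0$ limit of the normalised integral).
* An infinite flat bottom turns the restraint off identically; a zero
  force constant leaves the trajectory bitwise identical to an
  unrestrained run with the same seed.
* Forces are monitored against a configurable divergence bound; crossing
  it raises an error naming the offending step.

## Known limitations

The generalized force is returned on the torsion itself; projecting it
onto Cartesian atom positions through the dihedral geometry is out of
scope, as are replica-averaged restraining, solvated protein dynamics
and pseudo-atom NOE bound corrections. The $S^2$ implementation assumes
the input vectors are already expressed in a body-fixed frame
(trajectory superposition is not performed). Window placement for $S^2$
is sequential and non-overlapping; the reference analysis does not state
its convention.
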