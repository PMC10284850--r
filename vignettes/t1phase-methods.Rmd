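---
title: "Methods: multi-phase field monolayers and T1 transition statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phase field monolayers and T1 transition statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`t1phase` simulates a two-dimensional confluent monolayer of `N` active
deformable cells. Each cell `i` is a scalar phase field `phi_i(x, t)` on a
periodic square domain `[0, L)^2`: `phi_i ~ +1` inside the cell, `-1`
outside, with a diffuse interface of width set by `epsilon`. The fields
evolve by conserved (mass-preserving) gradient dynamics with advection,

    d_t phi_i + v_i . grad phi_i = Lap( dF / dphi_i ),

where the free energy `F = F_CH + F_INT` has exactly two parts: the
Cahn-Hilliard energy

    F_CH = (1/Ca) sum_i int (eps/2) |grad phi_i|^2 + 1/(4 eps) (phi_i^2 - 1)^2,

a double-well bulk term plus interfacial energy whose weight `1/Ca` sets
the cell line tension (larger capillary number `Ca` means more deformable
cells), and the pairwise interaction energy

    F_INT = (1/In) sum_i int B(phi_i) sum_{j != i} w(phi_j),

which couples each cell's interior-and-interface indicator
`B(phi) = (phi + 1)/2` to the interaction potential
`w(phi) = 1 - (a+1) ((phi-1)/2)^2 + a ((phi-1)/2)^4` of every other cell.
`w` is 1 in a foreign cell's interior and 0 outside it, so overlap is
penalised; for `a = 1` the potential is a non-negative squared well (pure
repulsion), while `a > 1` adds an adhesive well (minimum `-1/24` at
`a = 1.5`).

Activity enters through the advection field `v_i = v0 B(phi_i) e_i`, with
`e_i = (cos theta_i, sin theta_i)` and the self-propulsion angle following

    d theta_i = sqrt(2 D_r) dW_i + alpha (beta_i - theta_i) dt.

`beta_i` is the orientation of the cell's elongation axis, the principal
eigenvector of the shape deformation tensor `S_i` (computed from the
quadratures of the field gradients). The axis is nematic (defined modulo
pi); by default `beta_i` is the representative nearest `theta_i`, so the
torque never exceeds the perpendicular. A `beta_rule = "literal"` switch
instead applies the signed-argument form `beta = +/- arg(eta+)`, which
reflects rather than rotates the target when `e . eta+ < 0`; we default to
the nearest-representative reading because the signed form can prescribe a
target nearly opposite to the elongation axis, while the alignment term is
described as relaxation *to* the axis. A passive mode replaces `v_i` by the
external shear profile of magnitude `0.5 |x1 - L/2|` directed along the x2
axis (the direction is a package choice; only the magnitude is fixed by
the model definition).

## Numerics

The solver is a uniform-grid Fourier-spectral semi-implicit scheme
(`src/core.cpp`, FFTW real-to-complex transforms with `FFTW_ESTIMATE`
planning so results are bit-reproducible). Per step, the stiff linear part
of `Lap dF/dphi_i` — the biharmonic term `(eps/Ca) Lap^2 phi_i` — and a
stabilising split term `sigma_stab Lap (phi^{n+1} - phi^n)` are treated
implicitly (a diagonal solve in Fourier space); the cubic well, the
interaction term and advection are explicit. `sigma_stab` defaults to
`2/(eps Ca)`, an upper bound for the explicitly treated linearised well
stiffness `|f''|/(eps Ca)`; this admits the default `tau = 0.005` on all
grids used here. Gradients in the advection term and the shape tensor use
centred differences: with `v_i = v0 B(phi_i) e_i` the discrete advection
term telescopes to zero sum over the periodic grid, so per-cell mass is
conserved to rounding error (the analytic identity
`int B(phi) e . grad phi = (e/2) . int grad((phi+1)^2/2) = 0`). Energies
and chemical potentials on the R side use spectral derivatives, making the
discrete chemical potential the exact adjoint of the discrete energy;
the test suite checks this Gateaux consistency to first order.

The time discretisation is first order; halving `tau` changes the final
energy of the single-cell relaxation test by under 1%. Blow-up (NaN) is
detected and aborts with a diagnostic naming the failing time.

All randomness flows from one R RNG seed: the per-chunk orientation
increments are drawn as a matrix with one row per cell, so results do not
depend on cell iteration order, and a run resumed from a saved state (with
its RNG state) is bit-identical to an uninterrupted run.

## Initial conditions

`init_voronoi_monolayer()` seeds a jittered lattice, applies periodic
Lloyd relaxation towards a centroidal Voronoi tessellation, and assigns
each cell the equilibrium profile `tanh(d/(sqrt(2) eps))` of the signed
distance to its Voronoi boundary offset inward by a per-cell margin. The
margin is Newton-adjusted so each diffuse mass equals
`coverage * L^2 / N` within 1%. `coverage < 1` leaves geometric gaps;
values slightly above 1 pre-compress the monolayer. Compression is the
default because the conserved dynamics deposits a few percent of each
cell's mass into a spatially uniform background (`phi` relaxes to slightly
above -1 outside the cells, a Gibbs-Thomson-like effect that grows with
interface curvature); without compensation the relaxed cell bodies no
longer tile the domain at the reduced geometry below.

`init_t1_fixture()` builds the deterministic four-cell diamond (A, B, C, D
with the B-D diagonal in contact and A-C separated) whose forward
simulation yields exactly one neighbour exchange, in both active and
passive-shear mode; for shear the diamond is pre-rotated 0.4 rad past the
-45 degree strain eigenframe so the flow's vorticity (0.25 rad per time
unit) carries the compression axis through A-C while the exchange
completes. The fixture weakens the repulsion (In = 0.7) so the
pre-strained overlaps do not scatter the quadruple before the exchange.

## Event detection and statistics

Contacts: cells i and j are in contact when
`max_x min(B(phi_i), B(phi_j)) >= contact_threshold` (default 0.15,
deliberately below the gap threshold 0.2 so a forming junctional gap
breaks the contact). Contact graphs are sampled at every save time
`tau_save`.

T1 events follow the 5-4-5 neighbour-relation rule: among the four cells
of an exchange the relation count drops from 5 (perimeter + one diagonal)
to 4 and returns to 5 with the other diagonal. The detector opens a
candidate when a pair (B, D) with at least two common neighbours
disappears, discards it if (B, D) returns first (a reversal), and closes
it when a previously unbonded pair of common neighbours (A, C) bonds with
the perimeter intact. With more than two common neighbours (rosette-like
junctions) the completing pair is whichever bonds first. Sub-save timing
is undefined by sampling; the default "boundary" convention takes
`t_start` = last save with (B, D) present and `t_end` = first save with
(A, C) present, so the duration is exactly the 5-to-4-to-5 time difference
and an integer multiple of `tau_save`; a "midpoint" convention (both ends
centred between bracketing saves, durations shorter by one save interval)
is available.

The epicenter is the geometric median (periodic metric) of the four
B-weighted centroids at the save nearest the event's temporal midpoint,
computed by Weiszfeld iteration to `1e-8 L` with multistart (the torus
makes the objective multimodal for spread-out points; epicenter quadruples
are clustered and unaffected).

The energy field is the total free energy density coarse-grained by
periodic convolution with a normalized disk of radius `r_avg` (the T1
"core" scale); the convolution preserves the spatial mean exactly. The
event-aligned profile samples this field at each epicenter, aligns
pre-event samples at `t - t_start < 0` and post-event samples at
`t - t_end > 0` (in-event samples are excluded, giving the discontinuity
at 0 whose two values are the mean energies at start and end), and
resamples in-event values onto a fixed 21-point 0-100% normalized-duration
grid by linear interpolation. Profile asymmetry is quantified by the
75%-of-peak crossings and by the times to rise from / decay to the domain
baseline. Durations get a maximum-likelihood Gamma fit
(`MASS::fitdistr`); duration versus peak epicenter energy uses Spearman
rank correlation, since the claim under test is monotone ("high-energy
transitions are faster"), not linear. Cell shape index is
perimeter/sqrt(area) of the `phi = 0` marching-squares contour (the
diffuse estimate from `int |grad B|` is biased by the interface width;
the geometric contour reproduces the disk value `2 sqrt(pi)`, the regular
pentagon 3.813 and the square 4.0 to 0.5% at the default resolution).
The tissue flow field averages each cell's centre-of-mass velocity with
its contact neighbours and interpolates by normalized periodic Gaussian
kernels (bandwidth half the mean nearest-centroid spacing; uniform
translation is reproduced exactly; collinear degenerate geometry falls
back to nearest-cell values). Chains group events whose epicenters lie
within `r_chain` (default two cell radii) and whose start times are
ordered within `dt_chain` (default twice the mean duration) by single
linkage.

## Study conditions at desk scale

The model reference geometry (`profile = "full"`: `L = 100`, `N = 100`,
`tau = 0.005`, `T = 150`) requires a 2048^2 grid to satisfy the
interface-resolution bound `dx <= epsilon/2` and is a multi-hour
single-CPU commitment. The packaged examples, tests and the acceptance
script use the documented desk profile chosen once:

* `L = 18`, `N = 13`, 256^2 grid (`dx = 0.070 <= epsilon/2`), `T = 60`,
  cell area ~25 (radius ~2.8, half the reference radius);
* `v0 = 1.0`: activity rescaled by the cell-radius ratio so the
  activity-to-line-tension ratio per cell matches the reference; with the
  raw value 0.5 the smaller cells sit closer to the jammed regime and the
  T1 rate drops to about half the reference 0.0105 events per cell per
  time unit, while the rescaled value restores it;
* `r_avg_frac = 0.055`, keeping `r_avg ~ 0.355` cell radii as at full
  scale;
* `coverage = 1.2` at initialization (see above).

What the desk conditions do and do not show: the topology of the
toolchain (detection, epicenters, profiles) is scale-independent and
exercised end to end; the qualitative T1 signature — energy rising to a
peak at the transition, sudden drop, slow relaxation, negative
duration-energy rank correlation, shape-index and velocity peaks — is
reproduced. Quantities carrying an absolute scale do not transfer: the
mean T1 duration at desk scale (~6 time units) exceeds the full-scale
reference values (~3.4-3.8), and the measured gap fraction is ~0 because
the uniform diffuse background of 13 cells (~0.03 each) keeps
`sum_i B(phi_i)` above the 0.2 gap threshold everywhere. The stochastic
simulation checks in the test suite therefore run these fixed, documented
conditions with a fixed seed.

## Known limitations

* First-order time stepping; the stabilising split slightly over-damps
  transients at the default `sigma_stab`.
* The background mass leak limits how small cells can be made relative to
  `epsilon`; desk-scale gap-fraction statistics are not meaningful.
* The contact criterion for diffuse cells is a necessary operational
  choice (threshold on pairwise indicator overlap); thresholds 0.15/0.2
  are configurable and all event statistics inherit this choice.
* Only T1 (quadruple) rearrangements are tracked; higher-order rosette
  resolutions are resolved greedily by first-bonding pair.
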