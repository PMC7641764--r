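---
title: "Methods: coarse-grained DNA thermodynamics and kinetics in crowded environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained DNA thermodynamics and kinetics in crowded environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crowdna)
```

## The scientific problem

Inside cells, 10-40% of the volume is occupied by macromolecules that
interact with nucleic acids, to first order, simply by taking up space.
crowdna is a desk-scale laboratory for asking how that excluded volume
changes the thermodynamics (melting temperatures, binding free energies)
and the kinetics (association and dissociation rates, strand-displacement
speed) of short DNA motifs: an 8-mer duplex, hairpins with a 6-bp stem and
4-nt or 10-nt loops, and a toehold-mediated strand-displacement system with
a 6-nt toehold and a 10-nt branch-migration domain. Crowders are inert
spheres of radius $r_c$ at excluded volume fraction
$\phi = N \tfrac{4}{3}\pi r_c^3 / L^3$; everything they do in this model,
they do through excluded volume alone.

## The coarse-grained model

Each nucleotide is a rigid body: a centre position plus an orthonormal
frame (base vector $\hat e_1$, base normal $\hat e_3$; the third axis is
implied by right-handedness). Two interaction sites flank the centre along
$\hat e_1$: a backbone site at $-0.40$ nm and a base site at $+0.40$ nm.
The potential has the structure familiar from nucleotide-level DNA models:

* **backbone connectivity** — FENE springs between consecutive backbone
  sites ($r_0 = 0.64$ nm, maximum extension $\pm 0.25$ nm, $k = 60$);
  stretching past the limit is an explicit *overstretch* error, never a
  silently clamped energy;
* **stacking** — a truncated, shifted and renormalised Morse well between
  sequential base sites, modulated by the squared cosine of the angle
  between the base normals;
* **hydrogen bonding** — the same Morse-times-squared-cosine form between
  the base sites of *native pairs only*, with anti-aligned normals pairing
  best. The averaged-strength convention is used throughout: every native
  pair has the same well depth `eps_hb`, and only designed pairs may bond,
  so no alternative secondary structure can interfere with the crowding
  signal;
* **excluded volume** — purely repulsive truncated-and-shifted
  Lennard-Jones (WCA) interactions between all other site pairs, between
  crowders and sites (diameter $r_c + r_\mathrm{site}$, additive radii,
  $r_\mathrm{site} = 0.30$ nm), and between crowders (diameter $2 r_c$).
  Electrostatics is omitted entirely: the model represents the high-salt
  regime in which backbone charges are screened.

Units are nm, ps, and $k_B T_0$ with $T_0 = 300$ K; temperatures are
always in kelvin. All pair terms act under minimum-image periodic boundary
conditions in a cubic box.

A native pair counts as *formed* when its hydrogen-bond energy is below
$-0.1\,\varepsilon_{HB}$ (the standard well-occupancy bond criterion; the
fraction is configurable and recorded in run metadata). The two order
parameters of every analysis are the formed-pair count $n_{bp}$ and the
minimum base-site distance $d_{min}$ over a native-pair subset.

### Calibration

The functional forms above are the package's own: published
nucleotide-level force fields are far more detailed (grooved geometry,
sequence-dependent stacking), and reproducing their absolute melting
temperatures is explicitly out of scope. The two well depths were
calibrated once so that the crowder-free 8-mer duplex melts two-state
*in its default 6 nm box* between 300 K and 360 K: `eps_hb = 9.5`,
`eps_st = 2.0`, with the Morse steepness `a_hb = 5` chosen wide enough
that base pairs can nucleate and re-zip on Monte Carlo timescales. That
in-box melting window is a tested property of the defaults, not a fit to
any published melting temperature. Consequences of the deliberately
forgiving hydrogen-bond well are discussed under *Limitations*.

## Equilibrium sampling

`run_mc()` is a Metropolis sampler whose move set is: single-nucleotide
translations and rotations, crowder translations, rigid whole-strand
translations/rotations, and pivot moves that rotate the chain segment on
one side of a nucleotide about its backbone site. All proposals are
symmetric, so detailed balance holds with respect to
$\exp(-E/k_BT)\,w(n_{bp})$ for any umbrella weights $w$. The rigid-strand
and pivot moves are the package's cluster moves for strongly bound states;
a full virtual-move cluster algorithm is not implemented, and the
detailed-balance test gates the move set that is.

Two practical lessons are baked into the implementation. First, rigid
moves of chains longer than half the box must account for interactions
between the chain and its own periodic image, so "internal" non-bonded
terms are always re-evaluated. Second, a single umbrella covering all of
$n_{bp} = 0\ldots N$ mixes poorly in this landscape (nucleation is
diffusion-limited and re-zipping slow), so the production estimator is the
**overlapping-window** one: sampling is restricted to one adjacent pair of
$n_{bp}$ states at a time, a short probe run sets a balancing weight
inside the window, and the free-energy profile is stitched from the
per-window population log-ratios,
$G(k{+}1) - G(k) = -\ln \pi_{k+1}/\pi_k$. Each window starts from an
equilibrated configuration of its upper state, walking down from the bound
fixture. Per-window errors come from a block bootstrap with block length
at least ten times the measured autocorrelation time, and accumulate in
quadrature along the profile. Wang-Landau refinement
(`adapt_umbrella_weights()`, per-visit penalties with flatness-triggered
amplitude decay) is retained for global umbrella adaptation on systems
that mix well.

Profiles are referenced to $G(1) = 0$; the standard binding free energy is
$\Delta G^\circ = -k_BT\,\ln\left(\sum_{n\ge1} e^{-G(n)} / e^{-G(0)}\right)$,
negative when binding is favourable, and independent of the reference.

**Reweighting and melting.** Each window's samples carry their energies,
so the profile can be re-stitched at a nearby temperature with Boltzmann
factors $\exp[-E(1/k_BT_2 - 1/k_BT_1)]$; the smallest per-window effective
sample size is reported and a floor is enforced. The duplex is
bimolecular, so in-box yields are extrapolated to bulk before locating the
melting temperature: with in-box bound probability $p$, mass action at
equal strand concentrations gives the bulk bound fraction $x$ solving
$x/(1-x)^2 = p/(1-p)$ (bulk melting corresponds to an in-box yield of
2/3). The correction is validated in the tests against an exact many-pair
partition-function enumeration rather than trusted as transcribed.
Van't Hoff analysis fits $\ln K$ against $1/T$; the slope gives
$-\Delta H/k_B$ and the intercept $\Delta S/k_B$.

## Dynamics

Kinetics use an overdamped Brownian propagator: every species takes
Gaussian free-diffusion trial displacements of per-axis variance
$2 D \Delta t$ (rotations of variance $4 D_{rot} \Delta t$ about a random
axis, $D_{rot} = D/\ell^2$ with the documented constant
$\ell = 0.5$ nm), filtered by a Metropolis acceptance on the potential.
This "dynamic Monte Carlo" propagator is exactly Boltzmann-stationary,
reproduces free diffusion exactly (MSD $= 6Dt$), and converges to
overdamped Langevin dynamics as $\Delta t \to 0$; rejections near steep
repulsions act as the short-range friction they physically are. Masses
are metadata only — the crowder mass rule $m = m_0 (r_c/r_0)^3$ (constant
density; a factor $\approx 27$ between the largest and smallest crowders
studied) is kept for completeness, and the model's own insensitivity
tests confirm that kinetics do not depend on it, which is what justifies
the overdamped choice. Crowder diffusion follows the Stokes-like rule
$D = D_0 r_0 / r_c$ with $D_0 = 0.24$ nm$^2$/ps, a deliberately fast
reference value; rates are therefore reported in simulation-time units
and, for crowding comparisons, as crowder-free-normalised ratios only.
The default timestep is $\Delta t = 0.003$ ps with an automated stability
pre-check (the RMS trial step must stay below a quarter of the smallest
excluded-volume core); kinetics runs use 0.005 ps, which passes the same
check.

## Forward flux sampling

Association is a rare event, so rates are composed as
$k = \Phi \prod_i P(\lambda_{i+1}\mid\lambda_i)$. The standard interface
ladders are: duplex and hairpin — complementary bases within 0.85 nm,
first base pair formed, fully formed duplex/stem; strand displacement —
toehold contact at 0.85 nm, first toehold pair, toehold fully paired
(6 bp), and full displacement (incumbent at 0 bp, invader at 16 bp). The
failure interface (return to the unbound basin) is zero formed pairs with
the pair distance beyond 2.5 nm on the same subset; this threshold is a
package decision (the basin needs an unambiguous definition) and the toy
checks are insensitive to it within $\pm 0.5$ nm. The initial flux counts
*effective positive* crossings — only crossings preceded by a basin visit
— per unit basin-side time; crossing configurations are stored, and each
staged probability fires fresh-noise trials from starting states drawn
uniformly with replacement (the estimator is conditional on the stored
crossing ensemble; Wilson binomial intervals are reported, and trials
that exhaust their step budget count as failures and are flagged).
Dissociation rates come from the detailed-balance relation
$k_{off} = k_{on}\, e^{\Delta G^\circ / k_B T}$ with $\Delta G^\circ$
sampled under the same crowding conditions.

FFS correctness is checked against analytically tractable systems: a 1D
double well (composed rate within a factor 1.2 of the direct
mean-first-passage rate; inserting an intermediate interface changes the
rate by less than statistical error) and the two-bead bonding toy — two
single-nucleotide strands with one native pair — whose bound probability
follows from a radial quadrature and whose association and dissociation
can both be simulated directly.

## Scaled particle theory

The analytic counterpart models the unfolded strand as a hard sphere of
effective radius $r_u$, the folded hairpin as a smaller sphere $r_f$, and
the duplex as a hard spherocylinder of radius $r_{sc}$ whose default
cylinder length $2 r_{sc}$ realises the two-adjacent-spheres picture of
the bound pair. The insertion work of a sphere of radius $R$ into a
hard-sphere fluid (radius $r_c$, packing $\phi$, $y = \phi/(1-\phi)$,
$s = R/r_c$) is the classic scaled-particle cubic
$$\beta W = -\ln(1-\phi) + 3ys + \left(3y + \tfrac92 y^2\right)s^2 +
\beta P v_c\, s^3,$$
with the SPT (compressibility) pressure
$\beta P v_c = \phi(1+\phi+\phi^2)/(1-\phi)^3$. For the spherocylinder the
sphere cubic is read as a linear form in the Steiner functionals — the
integral mean curvature over $4\pi$, the surface over $4\pi$, and
$3V/4\pi$, which for a sphere are $R$, $R^2$, $R^3$ — and evaluated with
the spherocylinder's $V$, $S$ and $M$; the expression reduces exactly to
the sphere result at zero length. Because the exact source expressions for
the convex-body case admit more than one transcription, the package treats
a Widom test-particle insertion Monte Carlo (equilibrated hard-sphere
fluid, $\beta W = -\ln\langle e^{-\beta\Delta U}\rangle$ with
$\Delta U \in \{0, \infty\}$) as the arbiter: tests enforce agreement
within 0.1 $k_BT$ for probes up to $2 r_c$ at $\phi \le 0.2$, the regime
where scaled particle theory is reliable.

Crowding-induced stability shifts follow as
$\Delta\Delta G_{hairpin} = \beta W(r_f) - \beta W(r_u)$ and
$\Delta\Delta G_{duplex} = \beta W_{sc} - 2\beta W(r_u)$ (negative =
crowding-stabilised), and `fit_effective_radii()` treats the radii as free
parameters fitted to measured $\Delta\Delta G(\phi, r_c)$ tables by
box-constrained multi-start least squares, exactly as effective radii are
treated in the literature. The end-to-end route to an initial radius uses
the documented convention radius $= \langle R_{ee}\rangle / 2$ from the
unbound ensemble (bound-heavy trajectories are refused).

## The synthetic systems, and what passing tests do and do not show

Every test system is generated programmatically: idealised ladder
duplexes (4-mer and 8-mer), hairpins whose loops are laid on exact
circular arcs satisfying the backbone constraint, a pre-displacement
three-strand complex, compact helical coils for unbound states, and
crowder packings by random sequential addition with Monte Carlo
relaxation and a lattice-start fallback for dense packings beyond the
sequential-addition jamming density. Defaults follow the published study
conditions: $\phi \in \{0.1, 0.2, 0.3, 0.4\}$ and $r_c$ from 0.85 to
2.56 nm in steps of 0.42 nm; the desk-scale trend comparisons use the
8-mer duplex in an $L = 6$ nm box at $\phi \in \{0, 0.3\}$ and
$r_c \in \{0.85, 2.56\}$, with thermodynamics sampled around 330 K and
kinetics at 310 K. Window production lengths of a few thousand sweeps per
window and FFS budgets of tens of crossings with 50-120 trials per stage
are the package's chosen problem sizes; they give per-condition
free-energy errors of a few tenths of $k_BT$ and rate errors of tens of
percent, adequate for the sign-and-ordering trend claims made here and
stated with every result.

The generator emulates excluded volume, connectivity and native-only
pairing. It does not emulate sequence heterogeneity, mismatched or
alternative base pairing, helical groove geometry, electrostatics at low
salt, attractive or polymeric crowders, or hydrodynamic interactions. A
passing trend test therefore shows that *entropic excluded volume alone*
produces the stated direction of change in this model — it does not claim
quantitative transfer to any particular experimental buffer.

## Numerical choices and degenerate inputs

Morse wells are truncated, shifted and renormalised so each minimum is
exactly $-\varepsilon$ and every potential is continuous at its cutoff.
Orientation frames are re-orthonormalised after every accepted rotation;
configuration files store positions to 6 decimals and orientation
components to 9 so that orthonormality (1e-8) survives a round trip
bit-stably. Packing uses a $10^{-6}$ contact slack against floating-point
violations. Unvisited order-parameter states, non-bracketing melting
curves, effective-sample-size floors, infeasible packings, overstretched
backbones and wrapped-coordinate MSD input are all explicit, classed
errors rather than silent degradation. Every stochastic stage takes an
explicit seed; study drivers derive per-job seeds from a master seed and
record them in all outputs.

## Known limitations

* The hydrogen-bond well is wide and only normal-modulated, which is what
  makes desk-scale equilibrium sampling tractable; one consequence is that
  partially bound states carry more statistical weight than in
  helix-resolved force fields, so the in-box melting transition is
  shallower and the free-energy profile is not steeply downhill towards
  the fully zipped state.
* In kinetics this shifts where crowding acts: the largest crowding gain
  in this model appears in the zipping stage (first pair to fully formed)
  rather than in the first-base-pair stage, although the first-base-pair
  probability does increase and the overall association speed-up is large
  (roughly 10-30x at $\phi = 0.3$, $r_c = 0.85$ nm). For the same reason
  the dissociation rate is suppressed strongly (the stabilisation deepens
  the bound well more than it lowers the association barrier), so on a
  logarithmic scale the $k_{off}$ change is comparable to, and at some
  seeds larger than, the $k_{on}$ change — unlike systems where crowding
  mainly stabilises the one-base-pair transition state. The package
  reports all per-stage gains and both relative rates so the attribution
  is transparent.
* Related: the crowders are soft (WCA) rather than strictly hard, so part
  of the excluded-volume stabilisation is carried by real repulsive
  contact energy. A van't Hoff decomposition of the crowded equilibria
  therefore books the stabilisation largely as enthalpy; the fitted
  entropy *decreases* slightly with $\phi$ in this model, even though the
  underlying hard-sphere mechanism is entropic.
* Strand-displacement branch migration is represented only through the
  staged interfaces; its micro-kinetics is out of scope, and full
  displacement runs are beyond the desk-scale budgets the package targets.
* The bulk extrapolation assumes ideal mass action between boxes;
  finite-concentration activity corrections are not modelled.
* Absolute times are simulation-time units with a deliberately fast
  diffusion reference; only rate *ratios* are meaningful across crowding
  conditions.
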