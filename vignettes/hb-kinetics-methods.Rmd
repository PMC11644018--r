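---
title: "Methods: hydrogen-bond kinetics, connectivity and lifetime estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond kinetics, connectivity and lifetime estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbkinetics)
```

This vignette is the package's own account of its science: the bond
definition, the correlators and the survival calculus behind the lifetime
estimator, the connectivity statistics, the synthetic generators that make
all of it testable without external data, the stand-in MD engine, and the
numerical and design choices that were genuinely open.

## The bond definition

A donor-H...acceptor arrangement counts as a hydrogen bond when three
conditions hold *simultaneously*, each a strict inequality:

* pair interaction energy `E < -8` kJ/mol,
* distance from the donor hydrogen to the acceptor oxygen `R < 0.25` nm,
* inclination of the donor OH bond to the O-O line `alpha < 30`
  degrees (a more linear `alpha < 20` variant is kept for sensitivity
  analysis; its bond set is nested inside the default's on every frame,
  which the tests assert).

The energetic condition makes the definition potential-dependent. The pair
energy is the sum of the nine site-site Coulomb terms at minimum image
plus the short-range terms of the same potential the trajectory was
generated with. When a third-party trajectory arrives without a known
potential, a Coulomb-only mode (charges −0.66 e / +0.33 e) is available
and recorded in the output metadata — energies then shift by the missing
short-range terms, so thresholds are comparable only within one mode.

Bond identity for time correlation is the *unordered molecule pair*, not
the (hydrogen, acceptor) triple: a donor that switches hydrogens between
frames keeps the bond "present". The per-molecule bond count n_HB counts
bond records, so a doubly bonded pair contributes two to each partner;
no cap at four is imposed.

Candidate search uses an O-O distance prefilter at `r_max + 0.12` nm.
The 0.12 nm margin is the maximum intramolecular O-H reach, so
`R < r_max` implies `d_OO < r_max + 0.12`: the prefilter cannot drop a
qualifying pair. The tests verify equivalence against an exhaustive
all-triples scan with independently coded geometry (law of cosines) and
energy (site-loop) oracles.

## Correlators and the survival calculus

With `hb_ij(t)` the pair indicator and `nb_i(t)` the monomer indicator,
the normalized correlator pools all sampled time origins:
the denominator is the total count of active (pair, origin) events, the
numerator the count still/again active at lag `t` — a ratio of pooled
sums, not a mean of per-origin ratios, so origins are weighted by how many
bonds they actually contain.

Three modes:

* **continuous** — active at *every stored frame* from origin to lag.
  Evaluated at the stored resolution (1 fs by default) with zero tolerance
  for gaps; no transient-break grace period.
* **intermittent** — active at origin and lag, regardless of what happened
  in between. Any pair present at both endpoints either never broke or
  restored the broken bond inside the window, so this endpoint definition
  realises "restores a temporarily broken bond" without tracking
  histories. Pair-level identity (above) means re-forming through the
  other hydrogen still counts as the same bond.
* **monomer** — continuous survival of the non-bonded state.

Origins are drawn uniformly *without replacement* from the frames that
leave the full lag window observable, so no lag is right-censored; the
default maximum lag is half the series (a quarter when segmenting, so the
default segmentation stays feasible). One hundred origins is the default
sampling depth.

Because H(t) is a survival probability, the mean lifetime is its time
integral. The estimator makes truncation explicit rather than assuming
the correlator has reached zero:

* trapezoidal quadrature on the computed window (O(dt^2) accurate — on an
  exact exponential sampled at 1 fs the error is below 0.5% for time
  constants from 10 fs up);
* if the terminal value exceeds 0.01, a single exponential is fitted to
  the terminal decade of the decay and integrated analytically; the tail's
  share is reported as `tail_fraction`;
* a terminal value above 0.5, or a flat tail that would need
  extrapolation, is an error ("window too short") — integrating it would
  be guesswork. The monomer correlator of a dilute gas is the canonical
  case and the pipeline reports it as a per-mode error record instead of
  aborting.

Independent correlation functions are obtained by splitting the series
into equal non-overlapping blocks (each at least twice the lag window),
integrating one correlator per block, and aggregating: mean, plus a 95%
Student-t half-width with N−1 degrees of freedom for bond lifetimes, or a
standard deviation for monomer lifetimes. Five blocks is the default, in
the 5–8 range typical for this analysis.

## Temperature-dependence fits

* **Two-exponential decay** `a exp(-t/tau1) + (1-a) exp(-t/tau2)` for the
  continuous correlator: Levenberg-Marquardt least squares with `a`
  constrained to [0, 1], multi-started on a decade grid of (tau1, tau2)
  initial pairs, best sum of squares reported, components ordered
  `tau1 <= tau2`. Single-exponential input collapses the components; that
  is flagged `degenerate`, not treated as an error. The raw
  Levenberg-Marquardt driver is used rather than an `nls`-object wrapper
  precisely because the degenerate optimum has a singular Jacobian.
* **TST law** `1/tau = A' T exp(-E/RT)`: nonlinear least squares on the
  reciprocal lifetime in ps^-1 (unweighted — the fit is on 1/tau, not on
  its logarithm; the linearized regression of `ln((1/tau)/T)` on `1/T`
  only supplies the starting point), R = 8.314 J/(mol K). Whether the
  original analysis weighted the points is not recoverable; unweighted is
  the documented choice, and on the packaged reference table it gives
  E = 9.99 kJ/mol, A' = 0.0295 ps^-1, adjusted R^2 = 0.998. Under 1%
  lifetime noise the activation energy is stable to a few percent while
  the prefactor inherits amplified uncertainty through the exponential
  correlation — the property tests budget ~4% and ~10% respectively.
* **Monomer linear law**: ordinary least squares of tau_nb on T,
  restricted to T <= 573 K by default because the linear regime ends where
  the continuous network is lost; the supercritical points follow a
  different, density-dominated behaviour (the 653 K -> 673 K fourfold jump).

Adjusted R^2 is reported for every fit as `1 - (1 - R^2)(n-1)/(n-p-1)`.

## Connectivity statistics

Clusters are connected components of the bond graph (isolated molecules
are singletons); patches are components of the subgraph induced on
molecules with `n_HB >= 4`, using only bonds between two such molecules.
"Four-bonded" is read as *at least* four so an occasional five-bonded
molecule does not fragment a patch; the threshold is a parameter. Two
printed definitions of the connectivity parameter P_g circulate — the
fraction of *molecules* engaged in clusters of at least five members, and
the fraction of *clusters* with at least five members. Both are
implemented; the molecule-fraction definition is the default and the mode
is always recorded on the result, never silently preferred. Components
come from igraph, relabelled in order of the smallest member index so
partitions are reproducible; tests check them against a hand-written
breadth-first search.

## Synthetic ground truth

`gen_markov_bond_states()` emulates the idealized kinetics of a bond
population: each entity is a two-state (bonded/broken) continuous-time
Markov chain observed at resolution dt, with an optional absorbing
"escaped" state modelling pairs that diffuse apart. Transition
probabilities per step are `1 - exp(-rate*dt)`; a broken entity leaves the
broken state with the combined-rate probability and then re-binds or
escapes in proportion to the rates (competing risks — equivalent to
independent per-transition draws to second order in `rate*dt`, and closer
to the continuous-time chain). Requests with `dt * rate > 0.1` are
rejected as too coarse. The analytic references are
`H_c(t) = exp(-k_break t)` and, without escape,
`H_int(t) = pi + (1-pi) exp(-(k_break+k_reform) t)` with
`pi = k_reform/(k_break+k_reform)`; with escape the intermittent
correlator decays to zero, which is the shape real supercritical data
show. The generator is validated against an event-driven (Gillespie-type)
sampler and a 2x2 rate-matrix exponential.

`gen_planted_configuration()` provides frames whose bond content is known
by construction: dimers realising a requested (R, alpha) to machine
precision; a tetrahedral pentamer whose centre donates two and accepts two
bonds (n_HB = 4, so patch detection returns exactly the centre); an
ice-like diamond-cubic lattice with protons on the O-O axes under a
uniform (polarized) ice-rules assignment, every molecule four-bonded; and
a monomer gas with all intermolecular O..H separations above 0.35 nm. The
default lattice O-O spacing is 0.295 nm: under the stand-in potential the
bonded-pair energy there is about −8.4 kJ/mol, comfortably inside the
energetic criterion, whereas at 0.28 nm the Lennard-Jones repulsion would
push it outside. What the planted fixtures do *not* emulate is real
water's thermal geometry distributions — passing on them shows the
detector and graph code are correct, not that the criteria are physically
tuned.

## The stand-in MD engine

The published analysis protocol this package follows used a modified
central-force flexible potential whose functional form and parameters are
not printed in the source we follow; the engine therefore implements a
*documented stand-in* with every protocol element that is printed:
partial charges −0.66 e (O) and +0.33 e (H) (dipole ~1.86 D at gas-phase
geometry), flexible 3-site molecules, NVE velocity-Verlet at 0.1 fs,
Ewald summation for electrostatics, shifted-force truncation for the
short-range terms, random initial placement with Boltzmann velocities,
velocity-scaling equilibration monitored by a temperature-trend test, and
frames stored every 1 fs.

Stand-in specifics, all overridable through `water_potential()`:

* harmonic OH stretch (r0 = 0.09572 nm) and HOH bend (theta0 = 104.52
  degrees). The stiffnesses (2e4 kJ/mol/nm^2; 300 kJ/mol/rad^2) are
  deliberately moderate: they are chosen so that a 0.1 fs step resolves
  every internal mode well enough for the total-energy stability ratio
  `max|E(t)-E(0)|/|E(0)|` of a 64-molecule run to sit inside 1e-5, the
  upper edge of the stability band the protocol reports. They are *not*
  spectroscopic water frequencies; the engine exists to exercise the
  pipeline, not to predict water.
* Lennard-Jones O-O (sigma = 0.3166 nm, eps = 0.65 kJ/mol) and a steep
  intermolecular O-H repulsion `c/r^16` (c = 8.4e-13 kJ mol^-1 nm^16).
  The latter plays the role the short-range O-H terms play in
  central-force-family models: it shields the bare Coulomb attraction
  between unlike sites, which with flexible bonds and no shield leads to
  a polarization catastrophe (an H collapsing onto a neighbouring O). The
  coefficient arrests approach near 0.15 nm while adding under 0.3 kJ/mol
  at hydrogen-bonding separations.
* Ewald splitting alpha = s/r_c with s = 3.2 and a reciprocal sphere up to
  2 s alpha; the real-space part carries the shifted-force modification,
  so the integrated Hamiltonian is exactly the computed one and energy
  conservation does not depend on the Ewald sum being fully converged.
  Accuracy itself is validated separately against the rock-salt Madelung
  constant (1.3e-6 relative) and a dipole-corrected direct lattice sum.
* Initialization rejects placements with O-O below 0.26 nm and follows
  with a capped steepest-descent relaxation; velocities are Boltzmann
  samples with net momentum removed and an exact rescale to the target
  kinetic temperature.
* Equilibration spends most of its step budget on chunked velocity
  rescaling *before* testing for convergence, because slow structural
  relaxation keeps converting potential energy into heat long after the
  instantaneous temperature looks right; it then requires a pure-NVE probe
  whose 10-block temperature trend has an insignificant slope (95%) and
  whose mean is within 5 K of target. The probe that passes is kept as
  the start of production.

Problem sizes used in the shipped tests and analyses — 64 molecules for
the stability contract (15 ps equilibration + 1 ps production), 24
molecules for the end-to-end demonstration — were chosen as the smallest
systems for which the protocol's stability and temperature bands are
meaningful; at 64 molecules the NVE temperature fluctuations are 2.5x
larger than at the published 400-molecule scale, so the ±10 K band is
applied to the run-mean and the block-to-block spread rather than to
every individual block. No claim is made that these runs reproduce the
published lifetime table; the table ships as data and feeds the fitting
layer.

## Numerical choices and degenerate inputs

* Minimum image maps every displacement component into (−L/2, L/2], with
  the boundary tie resolved to +L/2; coordinates are never wrapped on
  input, so wrapped and unwrapped trajectories analyse identically.
* Extended-XYZ I/O writes 12 significant digits; round-trips are lossless
  at analysis precision. Files must present molecules as consecutive
  O,H,H triplets; anything else is a parse error naming the frame.
* Pair energies are computed with the molecule indices in canonical order
  so that E(i,j) and E(j,i) are bit-identical.
* The lag-0 correlator value is 1 whenever any entity is active at an
  origin; an empty origin population is an explicit error, not NaN.
* Zero-rate Markov chains, empty bond sets, single-frame clusters and a
  detector fed fewer than two molecules all return well-defined empty or
  trivial results; tests pin these.

## Known limitations

* The energetic criterion inherits the stand-in potential; absolute bond
  populations from the MD module are not comparable with studies using
  the original central-force model, though the geometric criteria and the
  whole correlator/lifetime layer are potential-agnostic.
* The intermittent correlator uses endpoint presence; processes where a
  pair drifts apart and a *different* pair forms are counted correctly,
  but no attempt is made to distinguish re-formation from never-breaking
  within a window (the continuous correlator carries that information).
* Cubic boxes only; no thermostatted dynamics (NVE only); no
  reactive-flux rate-constant analysis.
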