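# hbkinetics

Hydrogen-bond (HB) kinetics and connectivity in water, from ambient to
supercritical conditions.

Water's anomalies trace back to its hydrogen-bond network. How long an
individual bond survives, how often a broken bond re-forms, and how long a
molecule persists with no bonds at all (a *monomer*) all change drastically
between cold dense liquid and hot low-density supercritical fluid — and
those changes track the structural reorganization of the network: the loss
of *patches* (connected regions of four-bonded molecules), then the
breakup of the percolating network into independent clusters. This package
implements the full analysis pipeline for quantifying that picture from
molecular-dynamics trajectories of 3-site water, for computational
chemists and physicists studying aqueous systems.

## What it computes

**Bond detection.** A pair is hydrogen-bonded when three conditions hold
simultaneously (strict inequalities): pair interaction energy
`E < -8 kJ/mol`, donor-H to acceptor-O distance `R < 0.25 nm`, and
inclination of the donor OH bond to the O–O line `alpha < 30°` (a more
linear `20°` variant is provided). Molecules in no bond are monomers.

**Connectivity.** Clusters (connected components of the bond graph),
patches (components of the subgraph of molecules with `n_HB >= 4`), the
mean bond count per molecule ⟨n_HB⟩, and the degree-of-connectivity
parameter P_g (fraction of molecules in clusters of ≥ 5 members; a
cluster-probability variant is also available).

**Time correlation functions.** With `hb_ij(t)` the pair-level bond
indicator and `nb_i(t)` the monomer indicator, the pipeline computes the
normalized autocorrelation functions

    H(t) = Σ hb_ij(t)·hb_ij(0) / Σ hb_ij(0)·hb_ij(0)

in *continuous* mode (bonded at every stored frame in `<0, t>`),
*intermittent* mode (bonded at both endpoints, breaks allowed in between),
and the monomer analogue M(t), pooled over ~100 random time origins.

**Lifetimes.** H(t) is a survival probability, so the mean lifetime is its
time integral, ⟨τ⟩ = ∫₀^∞ H(τ) dτ — evaluated by trapezoidal quadrature
with an explicit single-exponential tail correction, block-averaged over
N = 5–8 independent correlation functions, with 95% Student-t confidence
intervals.

**Temperature dependence.** Two-exponential fits of H_c(t); the
transition-state-theory (TST) law for the intermittent lifetime,
`1/⟨τ_int⟩ = A′·T·exp(−E≠/RT)`; and the linear law `⟨τ_nb⟩ = a·T + b` for
monomer persistence below 573 K.

**Ground truth and inputs.** A synthetic-data module generates two-state
Markov bond processes with known break/reform/escape rates (analytic
correlators) and planted geometric motifs (dimers at exact `R`/`alpha`,
tetrahedral pentamers, four-coordinated ice-like lattices, monomer gases).
A scaled-down NVE molecular-dynamics engine for flexible 3-site water
(Ewald electrostatics, shifted-force short-range terms, velocity Verlet at
0.1 fs) produces physically plausible trajectories; a packaged reference
table supplies published lifetimes at seven state points from 293 K /
0.997 kg/L to 673 K / 0.167 kg/L.

## Worked example

```r
library(hbkinetics)

# temperature dependence from the packaged reference lifetimes
tab <- hb_lifetimes()
fit_tst(tab$T_K, tab$tau_int_fs)
#> <hb_fit> tst: A_prime = 0.02955, E_act = 9.987; adj R^2 = 0.9981
fit_linear_monomer(tab$T_K, tab$tau_nb_fs)
#> <hb_fit> linear: slope = 0.05529, intercept = -10.99; adj R^2 = 0.9753
lifetime_ratio(tab, 673, 653, "tau_nb_fs")
#> [1] 3.980424
```

The TST activation energy of ~10 kJ/mol is the energetic cost of breaking
and re-forming a hydrogen bond; the monomer lifetime grows by ~0.055 fs per
kelvin up to 573 K and then roughly quadruples between the 653 K
(0.451 kg/L) and 673 K (0.167 kg/L) states, because in low-density
supercritical water unbound molecules sit in empty regions and collide
rarely.

Ground-truth check of the estimator pipeline on a synthetic bond process
(break rate 0.01/fs, i.e. a true mean continuous lifetime of 100 fs):

```r
bs <- gen_markov_bond_states(5000, k_break = 0.01, k_reform = 0.1,
                             dt = 1, n_steps = 2000, seed = 2024)
means <- segment_lifetimes(bs, "continuous", n_segments = 5,
                           n_origins = 50, max_lag = 200, seed = 2024)
aggregate_lifetimes(means)
#> <lifetime_estimate> 100.9 +/- 2.36 fs (N = 5, ci)
```

The numbered scripts under `analysis/` run the full study: `01` the
reference-table fits above, `02` the Markov ground-truth validation, `03`
detection/connectivity on planted motifs, `04` an end-to-end run on a
scaled-down MD trajectory (simulate → extended-XYZ → detect → correlate →
lifetimes). Each writes its tables under `results/`.

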