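---
title: "Size exclusion and client recruitment in biomolecular condensates: models and methods"
author: "condsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{condsieve methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condsieve)
```

## The physical problem

Biomolecular condensates are liquid-like assemblies of proteins and RNAs
whose scaffolds typically carry large intrinsically disordered regions
(IDRs). Because condensates are dynamic network fluids rather than fixed
gels, it is not obvious how they keep unwanted macromolecules
("intruders") out: transient holes are always opening. The resolution
implemented in this package is entropic. IDRs are flexible polymers with
enormous conformational entropy; any particle inserted into the condensate
removes volume that IDR conformations would otherwise explore, which costs
free energy. That cost grows with particle size and with IDR
concentration, and molecules lacking binding affinity for condensate
components are excluded by it. Clients overcome the barrier by binding.

`condsieve` provides four connected layers:

1. a closed-form **theory engine** that predicts the insertion free energy
   and partition coefficient of a neutral sphere from the IDR volume
   fraction;
2. a coarse-grained **sticker-spacer Langevin simulator**;
3. a hard-sphere **Widom insertion** estimator that measures insertion free
   energies in simulated configurations;
4. **analysis and fitting** tools that connect the two routes (coexistence
   profiles, partition coefficients, dissociation constants, global
   prefactor fits).

## The theory engine

A semidilute solution of self-avoiding chains at monomer volume fraction
$\phi$ has one characteristic mesh scale, the correlation length (blob
size)

$$\xi = c\,d\,\phi^{-\nu/(3\nu-1)},$$

where $d$ is the monomer diameter, $\nu = 0.588$ the Flory exponent, and
$c$ a prefactor of order one. The package defaults are $d = 0.6$ nm (twice
the 0.3 nm radius of an average amino acid) and $c = 0.68$, the value
calibrated on fully flexible bead-spring chains. In simulations, $\xi$ is
instead obtained from the measured osmotic pressure through the blob-picture
relation $\Pi = (3\nu - 1) k_B T/\xi^3$ (unit prefactor), i.e.
$\xi = [k_BT / ((3\nu-1)\Pi)]^{1/3}$; the printed form of this relation is
typographically ambiguous, and the package implements the inversion that
reproduces the reported $\xi$ range (2.79--6.10 nm) from the reported
pressures (0.25--0.024 MPa).

The free-energy cost of inserting a hard sphere of radius $R$ is the
unified expression

$$\frac{\Delta F}{k_BT} =
  a_1\left(\frac{R}{\xi}\right)^{3-1/\nu} +
  a_2\left(\frac{R}{\xi}\right)^{2} - \ln(1-\phi),$$

with $a_1 = 4.18$ and $a_2 = 7.24$ from a global fit to Widom insertion
into simulated self-avoiding polymer solutions. The first term is the
correlation-hole cost that dominates for probes smaller than a blob
(log-log slope $3 - 1/\nu \approx 1.30$); the second is the surface term
that dominates for large probes (slope 2); the third is the
volume-reduction cost of inserting even a point particle. For $R \gg \xi$,
substituting the blob-scaling law gives
$\Delta F/k_BT \sim R^2 \phi^{2\nu/(3\nu-1)}$: the barrier scales with the
intruder's *surface area* (the pressure-volume term cancels between
coexisting phases) and steeply with concentration ($\phi^{1.54}$). The
partition coefficient is $P = e^{-\Delta F/k_BT}$.

```{r}
predict_partitioning(c(1.9, 6.5, 8.9), phi = 0.036)
```

Recruitment balances binding against exclusion:

$$\frac{\Delta F_{\rm client}}{k_BT} =
 -\sum_i \frac{\rho_i}{K_{D,i}} + \frac{\Delta F_0}{k_BT},$$

with $\rho_i$ the density of binding sites of type $i$, $K_{D,i}$ their
per-site dissociation constant, and $\Delta F_0$ the neutral exclusion
barrier. `recruitment_free_energy()` also exposes the finite-valency
evaluator behind this limiting form (a Poisson-weighted binding sum with a
valency cap $n_{max}$ and interaction volume $\Omega$); the limiting form
is the default and is what the desk-scale validations use, since the
simulated clients are far from valency saturation.

### Composition conversion

`phi_from_composition()` converts a measured scaffold concentration to an
IDR volume fraction, treating each residue as a 0.3-nm-radius sphere
(molar route: concentration $\times$ residues per scaffold; mass route:
concentration $\times$ IDR mass fraction / 110 g/mol). The arithmetic is
exact, but published volume fractions for the same systems differ by
20--40% from this arithmetic (concentration estimates carry their own
assumptions), so when an independently reported $\phi$ exists the function
flags the discrepancy and the reported value should be passed directly to
`correlation_length()`. The package's own reproduction of the worked
examples therefore uses the reported $\phi$ values (3.6%, 5%) as inputs.

## The sticker-spacer simulator

Polymers are linear chains of volume-excluding spacer beads (type C)
decorated with attractive sticker patches (types A and B); neutral or
client particles are free beads (type D). Three architectures are built
in:

* **compact spacers**: 10 spacers of radius 1 nm on loose FENE bonds
  ($k = 0.129\,k_BT/\mathrm{nm}^2$, $r_{max} = 14.03$ nm), one sticker per
  spacer (A on the first five, B on the last five) on stiff harmonic bonds
  ($k_b = 100\,k_BT/\mathrm{nm}^2$, $r_b = 1$ nm), modelling folded
  modules;
* **IDR spacers**: 450 spacers of radius 0.3 nm (amino-acid scale) on
  harmonic bonds ($k_b = 692\,k_BT/\mathrm{nm}^2$, $r_b = 0.38$ nm, the
  C$\alpha$--C$\alpha$ distance), a sticker on every 8th spacer (A in the
  first half of the chain, B in the second);
* **spacers only**: the IDR chain with all stickers removed (the
  homogeneous-solution reference system).

The two decorated presets follow their published bead counts and radii; the
accompanying statement that they exclude identical per-polymer volume does
not hold as sphere arithmetic ($10 \cdot \frac{4\pi}{3} \approx 41.9$ vs
$450 \cdot \frac{4\pi}{3} 0.3^3 \approx 50.9$ nm$^3$) and is not enforced.

Interactions (all parameters in $k_BT$ units): unlike stickers attract via
the soft well $U_{AB}(r) = -\frac{U_0}{2}[1 + \cos(\pi r/r_0)]$ for
$r < r_0 = 0.3$ nm ($U_0 = 18.8$ or $18\,k_BT$ by preset); like stickers
repel so that A--B pairing is one-to-one; spacers and particles repel
through the WCA potential $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
\epsilon$ cut at its minimum $2^{1/6}\sigma$, $\sigma_{ij} = r_i + r_j$,
$\epsilon = 1\,k_BT$, acting on the pairs AA, BB, CC, DD, CD. Stickers are
virtual patches: they have no interaction with spacers or particles.
Client runs add $U_{AD}(r) = U_{BD}(r) = -\frac{\varepsilon}{2}[1 +
\cos\frac{\pi(r - R)}{r_a}]$ on $R - r_a \le r \le R + r_a$ with $R = 1.5$
nm and $r_a = 0.3$ nm. Directly bonded pairs are excluded from nonbonded
terms, the standard bead-spring convention (without it the 0.38-nm
backbone bonds would sit on an 899 $k_BT$ WCA shoulder and the model would
change meaning).

Dynamics integrate the underdamped Langevin equation
$m_i \ddot{\vec r}_i = -\gamma_i \dot{\vec r}_i - \nabla U + \vec f_i$
with the BAOAB splitting (velocity Verlet + exact Ornstein--Uhlenbeck
step), per-bead friction $\gamma_i = m_i/\tau$ with $\tau = 1$ ns, $T =
300$ K, $dt = 0.01$ ns, and the published masses (5.65/18.85/28.27 ag),
which give each bead its Stokes--Einstein diffusivity
$D_i = k_BT/(6\pi\eta r_i)$ for water viscosity. Internal units are nm,
ns, ag and $k_BT$; with these, pressure emerges naturally in MPa. With the
thermostat off the integrator is plain velocity Verlet, which is how the
energy-conservation test runs. The noise stream is an own-implementation
(splitmix64 + Box--Muller), so identical seeds give bit-identical
trajectories on any platform.

Neighbour search uses a Verlet pair list (0.4 nm skin, rebuilt when any
bead has moved more than half a skin) fed by a two-level cell scheme: a
compact cell list for the many small beads and a coarse one for the few
large-cutoff particles. The all-pairs evaluation remains available and the
test suite asserts exact agreement between the two paths.

**Initial placement** (not specified by the source methods beyond the
confinement region): chains are laid down as bond-length random walks
inside the confinement slab, overlaps are removed by a staged
force-capped push-off ($F_{cap}$ = 5 to 5000 $k_BT$/nm) followed by a
thermalised settle at $dt/10$, and velocities are re-zeroed. The
coexistence protocol then (i) ramps $U_0$ linearly from 0 to its target
while polymers are held by soft harmonic walls, (ii) equilibrates at full
$U_0$, (iii) removes the walls and relaxes, (iv) records production
frames. Particles are never confined.

**Pressure** is the time-averaged virial estimator
$\Pi = (N k_B T + \frac{1}{3}\langle\sum \vec r_{ij} \cdot \vec
f_{ij}\rangle)/V$, using the thermostat target temperature for the ideal
term, so a non-interacting system returns exactly $N k_B T/V$; errors come
from block averaging with a stationarity warning when the two halves
disagree by more than three combined standard errors.

## Widom insertion

`insert_hard_spheres()` estimates $F(R) = -k_BT\ln\langle
e^{-U(R)/k_BT}\rangle$ with hard-sphere probes: an insertion at a grid
point or random position is accepted when no volume-excluding bead centre
lies within $R + r_C$ (minimum image, periodic in all directions; stickers
are ignored as virtual patches). The default sampler is a deterministic
uniform grid, as in the source protocol (140^3 points over the dense slab
at production scale); a seeded random mode exists for convergence checks
and the tests require the two to agree within combined errors. Probe
centres can be restricted to an $x$-slab, optionally after recentring the
frame on the polymer centre of mass, so that "dense phase" means the
central plateau of the profile; plateau bounds are user-specified rather
than auto-detected. Standard errors come from per-frame block averaging;
when no insertion is accepted the result is flagged and reported as the
lower bound $\ln n_{\rm samples}$, never as a number pretending to be an
estimate. For homogeneous solutions held at pressure $\Pi$,
`pv_correction()` subtracts $\Pi \frac{4\pi}{3}R^3$, the pressure-volume
work that cancels between coexisting phases.

## Coexistence analysis

`density_profile()` histograms bead centres into 50 slabs along $x$ (the
published bin convention), converts counts to volume fractions with the
single-bead volume (no partial-overlap apportioning — a documented
convention that matches centre-count profiles at this bin width), recentres
every frame on the circular-mean polymer centre of mass, averages, and
symmetrizes about $x = 0$. Frames whose largest polymer cluster (single
linkage at $1.2(r_i + r_j)$ bead contact distance) holds less than half the
polymers are excluded and counted. Partition coefficients are
region-averaged ratios $P = \phi_{den}/\phi_{dil}$ with the dense region
$|x| < 10$ nm and dilute $|x| > 40$ nm for the 100-nm reference box,
rescaled proportionally for other boxes.

`measure_KD()` extracts the dissociation constant
$K_D = \rho_{client}\rho^{free}_{sticker}/\rho^{bound}_{sticker}$ from
dense-phase densities, counting a sticker as bound when it lies within
$R + r_a$ of a client centre — the reach of the client attraction. The
source does not state its own criterion, so this is a package convention;
its main consequence is that at weak attraction accidental contacts
inflate $\rho/K_D$ by roughly $\rho_{sticker} V_{reach}$, which is why the
qualitative recruitment validation checks monotonicity and ordering rather
than the weak-attraction sign of the theory curve. Total client density
stands in for free-client density, as multivalent clients are never
saturated.

## Fitting

The unified expression is linear in $(a_1, a_2)$ once $\nu$ is fixed, so
`fit_insertion_model()` is a (optionally per-point-error weighted) linear
least-squares fit of $\Delta F/k_BT + \ln(1-\phi)$ on
$(R/\xi)^{3-1/\nu}$ and $(R/\xi)^2$; $\nu$ stays fixed at 0.588 (a flag
exposes it for sensitivity analysis) and the loss is unweighted by default
since the source fit's weighting is unstated. `collapse_check()`
interpolates each system's entropy contribution onto a common $R/\xi$ grid
and reports the median relative spread — exactly zero is unattainable
because different systems sample different $R/\xi$ values, so "collapsed"
means a spread at the interpolation-error scale (~10^-3) versus order one
for unrescaled radii. `fit_scaling_prefactor()` is a log-log regression
with expected slope $-\nu/(3\nu-1) = -0.7696$. The default radii grid for
reduced replications is 18 values log-spaced from 0.50 to 2.48 nm, the
published insertion grid.

## Synthetic data and desk-scale study conditions

`synthetic_insertion_data()` generates insertion datasets directly from
the closed-form model with optional Gaussian noise (default scenarios: ten
systems spanning $\phi$ = 0.035--0.10, the published radii grid, noise
0.05 $k_BT$ — the parameter-recovery oracle). `generate_fixture()` builds
configurations with known structure (empty box, centred sphere,
non-overlapping hard-sphere gas at target $\phi$, uniform slab, and a
short-equilibrated mini polymer box) for estimator tests.

The coexistence validations run at desk scale, chosen once as the smallest
systems that robustly phase separate and leave measurable dilute phases:

* compact mini: 20 polymers + 24 particles in 80 x 18 x 18 nm, 8x10^4
  annealing steps, 4x10^4 + 4x10^4 equilibration, 1.2x10^5 production;
* IDR mini: 30 chains of 64 spacers (sticker every 8th) + 24 particles in
  60 x 15 x 15 nm, 2x10^5 annealing steps (shortened chains coarsen more
  slowly, so annealing is longer and initial confinement tighter),
  5x10^4 + 4x10^4 equilibration, 1x10^5 production;
* recruitment sweep: the compact condensate continued with
  $\varepsilon \in \{2, 6, 10\}\,k_BT$ for 10^5 re-equilibration plus
  6x10^5 production steps, analysing the second production half — client
  uptake is diffusion-limited and, at strong attraction, nearly
  irreversible, so the particle distribution needs several condensate
  traversal times (~3x10^5 steps) to relax;
* chain statistics: stickerless chains of 25/50/100 beads at reduced
  friction ($\tau = 50$ ns), which accelerates conformational sampling
  without touching equilibrium statistics. At these lengths the effective
  end-to-end scaling exponent is ~0.63 (a 24-chain calibration run gives
  0.627), approaching the asymptotic $\nu = 0.588$ from above — the usual
  excluded-volume swelling of short bead-spring chains, amplified here by
  the repulsion range exceeding the bond length ($\sigma/r_b = 1.6$).

What these runs demonstrate: phase separation, the directional contrast
(IDR spacers exclude more strongly than compact spacers at similar dense
phases), Widom-vs-coexistence consistency where particle exchange is fast,
and the intruder-to-client crossover. What they do not demonstrate: the
quantitative production-scale numbers (2.5-fold vs 14-fold exclusion, <3%
Widom/coexistence agreement), which require tens of replicates of 10^7+
steps; the desk-scale dense phases are smaller, their volume fractions
somewhat below the production-scale 7% (the shortened IDR chains
especially), and the neutral-particle partition of the IDR mini
re-equilibrates slowly after wall removal, so its measured $-\ln P$ is an
overestimate of the equilibrium barrier on these run lengths. The
directional conclusions are insensitive to all of this; the quantitative
cross-method check is therefore performed on the compact system, whose
particle exchange is fast within the run.

Real IDRs differ from these chains in sequence-specific interactions,
residue-size heterogeneity, hydrodynamics and solvent chemistry; passing
tests validate the framework's internal consistency and its polymer-theory
limits, not those chemical details.

## Numerical choices and degenerate inputs

* FENE overextension ($r \ge r_{max}$) and per-step displacements beyond
  half a box edge raise errors immediately — instability is never
  integrated through.
* Zero-acceptance Widom results and empty dilute regions are reported as
  flagged bounds, and an all-frames-multi-cluster profile is an error.
* Empty topologies, zero production steps and zero concentrations return
  well-defined degenerate results (empty state, single-frame trajectory,
  $\phi = 0$).
* Theory-side guards: $\phi \in (0,1)$ for the blob law, $\phi < 1$ for
  insertion, $K_D > 0$, finite $\Delta F$.
* The dense/dilute region defaults and the 1/50 bin width follow the
  source conventions; both are plain arguments.

## Limitations

No hydrodynamic interactions, no sequence-specific potentials, no
bond-breaking correction for very large intruders, no chemical-environment
partitioning of small molecules, no interfacial-tension or dynamic
(FRAP-like) observables, and no triclinic boxes in trajectory I/O. The
Widom estimator is hard-sphere only; soft-probe insertion energies are out
of scope.
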