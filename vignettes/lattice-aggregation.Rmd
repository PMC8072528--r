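---
title: "Modelling polypeptide aggregation on smooth and rough surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polypeptide aggregation on smooth and rough surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latfib)
```

## The model

Amyloid-like self-assembly of short peptides is far too slow for atomistic
simulation, and slower still near adsorbing surfaces.  `latfib` therefore
implements a deliberately minimal coarse-grained description: each
polypeptide is a self-avoiding chain of beads on a cubic lattice (spacing
$a = 1$), with one bead per residue drawn from a four-letter alphabet —
hydrophobic (H), polar (P), positively (+) and negatively (−) charged.
The default chain is the eight-bead sequence `+HHPPHH-`.

The total energy of $N$ chains is a sum of three contact terms,

$$E \;=\; \sum_{l}\sum_{i<j} e_{s_l(i) s_l(j)}\,\delta(r_{ij}-a)
      \;+\; \sum_{m<l}\sum_{i,j} e_{s_l(i) s_m(j)}\,\delta(r_{ij}-a)
      \;+\; \sum_{m}\sum_{i}\sum_{k} e^{\nu s}_{s_m(i)}\,\delta(r_{ik}-a),$$

where $\delta(x)$ is one at $x = 0$ and zero otherwise and all distances
are minimum-image.  The first term counts same-chain pairs that are *not
successive in sequence* (implemented literally as $|i-j| \ge 2$, so
$i,i{+}2$ pairs do count when they touch); the second all nearest-neighbour
pairs from different chains; the third all contacts between chain beads
and surface sites (plane beads and balls alike).  The bead–bead matrix
$e_{ij}$ (units of the hydrogen-bond energy $\varepsilon_H$; H–H $=-1.0$,
opposite charges $-0.7$, like charges $+0.35$, polar/charge–polar
$-0.2$, all hydrophobic–nonhydrophobic pairs $+0.2$) is returned by
`chain_interaction_table()`.  Temperature is measured in
$\varepsilon_H/k_B$ with $k_B = 1$; the aggregation studies use
$T = 0.49$–$0.58$.

Surfaces come in two chemistries.  A *hydrophilic* surface is a plane of
fixed Ps beads whose attraction to polar chain beads is the tunable
parameter $\varepsilon^{ps}$ (the Ps–P entry is $-\varepsilon^{ps}$; the
remaining entries are fixed at H $= 0.2$, $\pm = -0.2$).  A *hydrophobic*
surface is a plane of Hs beads with tunable Hs–H attraction
$-\varepsilon^{hs}$ and fixed P, $\pm = 0.2$.  Surface beads are frozen
and do not interact with each other.  The printed index ranges of the
surface term are typographically corrupted in the source material; we
implement the only reading consistent with its prose — every (chain bead,
surface site) pair at distance one contributes once, so a bead sitting in
a groove can collect several surface contacts.

## Geometry conventions

Sites are 0-based integer triples.  Bulk boxes are periodic on all three
axes.  With a surface the box becomes a slab: $x,y$ periodic, the surface
plane at $z = 0$, balls at $z = 1$ (and $2$), chains confined to
$1 \le z \le L_z - 1$ with a hard, non-interacting wall at the top.  This
is the standard slab setup for adsorption simulations; only the lateral
periodicity is dictated by the physics.

Box sizes are a convention, not a derivation: the physical system's
micromolar concentration has no unique image in lattice units, so
`default_box()` fixes the chain-bead number density at roughly
$0.0175\,a^{-3}$ — six chains of eight beads in a $14^3$ box, twelve in
$18^3$ — and every scan records the density it used in its metadata.

## Rough surfaces and their statistics

Rough surfaces are built by scattering balls (each occupying one lattice
site, like a chain bead) on the plane, uniformly without replacement and
with no minimum-separation constraint.  Three styles are supported:
single balls at height 1 (*S*), rigid double balls at heights 1 and 2
(*D*), and an equal mix (*DS*; an odd ball budget gives the extra column
to the single-ball type, a deterministic and unbiased tie-break).  The
height field $h_i \in \{0, 1, 2\}$ over the $N_s = L_x L_y$ columns gives

$$\bar h = \frac{1}{N_s}\sum_i h_i, \qquad
  \Theta = \sqrt{\frac{1}{N_s}\sum_i (h_i - \bar h)^2}, \qquad
  \Omega = N_b / N_s,$$

with $N_b$ the number of ball columns.  Because $\Theta$ depends only on
the height *counts*, the empirical statistic equals the closed form at
the realised coverage exactly: $\Theta_S = \sqrt{\Omega(1-\Omega)}$,
$\Theta_D = 2\sqrt{\Omega(1-\Omega)}$ and, at an exact equal split,
$\Theta_{DS} = \sqrt{2.5\,\Omega - 2.25\,\Omega^2}$.
`coverage_for_roughness()` inverts these (smaller root), which is how
roughness scans are parameterised by $\Theta$; the exact ball count is
$\mathrm{round}(\Omega N_s)$, so a regenerated profile reproduces the
target $\Theta$ up to that discretisation.  The coverages behind
published roughness values are not printed anywhere we could check; the
inversion (e.g. $\Theta_S = 0.458 \to \Omega = 0.30$) is a
reconstruction and is flagged as such.

```{r roughness}
sp <- surface_profile("S", dims = c(14, 14), chemistry = "Ps",
                      omega = 0.25, seed = 1)
roughness_stats(sp)$theta          # sqrt(0.25 * 0.75) = 0.4330
```

## Monte Carlo dynamics

Chains move by Metropolis Monte Carlo.  Local moves are tail rotation
(an end bead steps to a free neighbour of its anchor), corner flip (an
interior bead jumps to the fourth corner of its right-angle plaquette)
and crankshaft (a two-bead U-segment rotates by 90/180/270 degrees about
the axis through its anchors).  Global moves are a rigid 90-degree
rotation of one chain about a coordinate axis through a uniformly chosen
pivot bead (sense $\pm 90^\circ$ equiprobable) or a rigid translation by
one lattice unit; global and local attempts mix 1:9.

One design point deserves a note.  Selecting the local move *by bead*
("ends do tail rotations, corners flip, straight beads crankshaft")
cannot work as stated: the two middle beads of a U-segment are corner
beads, so a bead with collinear neighbours is never a crankshaft centre
and the crankshaft would be unreachable.  We therefore select the *kind*
first (uniformly among the three), then a uniformly chosen applicable
site for that kind.  Each kind is then its own inverse at equal a-priori
selection probability — corner flips are involutions, tail targets and
crankshaft rotation angles are drawn from symmetric candidate sets — and
geometrically impossible picks are consumed as null attempts (the
standard null-move convention).  Together with the acceptance rule
$\min(1, e^{-\Delta E/T})$ (not stated in the source material; it is the
only choice consistent with its use of "temperature") this gives detailed
balance, which the test suite verifies directly: on a four-bead chain in
a $4^3$ periodic box the sampled energy-level occupancies match the
exactly enumerated Boltzmann weights (chi-square, $10^6$ MCS).

The Monte Carlo step (MCS) is the model's time unit.  Whether the
original implementation counted one attempted move or one sweep
($N \times M$ attempts) per MCS is not determinable from the text; the
default here is **one attempt per MCS** (the literal reading), with a
sweep mode behind `mc_config(sweep_mode = TRUE)`.  Absolute times shift
by a constant factor between the modes; differences of
$\ln\tau_{agg}$ between conditions are mode-invariant.  All outputs
record the mode in their metadata.  No mapping of MCS to physical time is
attempted.

Energies are updated incrementally from the contact shells of moved
beads; the acceptance suite checks $|\Delta E_{\mathrm{incremental}} -
\Delta E_{\mathrm{full}}| < 10^{-9}$ over thousands of proposals in
bulk and on S/D/DS surfaces.  With the default tables every attainable
energy is an integer multiple of $0.05\,\varepsilon_H$, a grid property
the tests use as an exactness check.  All randomness flows through an
explicitly seeded 64-bit generator with modular draws, so trajectories
are bit-reproducible for a given seed across standard libraries.

## The aggregation criterion and $\tau_{agg}$

Fibril formation is detected against an environment-specific *reference
fibril*: the minimal-energy configuration found by simulated annealing
(geometric cooling, several restarts, recorded seeds) in the same
environment — bulk, hydrophilic or hydrophobic smooth surface at the
scan's attraction.  The environment matters because the minimal
morphology differs: on a strongly hydrophobic surface the chains flatten
into their compact native conformation (for a single chain at
$\varepsilon^{hs} = 2$, all four H beads sit in surface contact), while
hydrophilic surfaces preserve the bulk-like fibril.  For one chain the
annealed minimum is cross-checked against exhaustive enumeration of all
81,390 eight-bead self-avoiding conformations; exhaustive enumeration of
chain *pairs* is combinatorially out of reach at desk scale, so for
$N = 2$ the tests assert attainable bounds instead (the in-register
antiparallel extended dimer scores $-5.8\,\varepsilon_H$, hence
$E_{min} \le -5.8$).

The source material never defines the fibril-contact set precisely.  The
default operationalisation is the robust one: the trajectory's
inter-chain contact count relative to $Q_{fib}$, the reference's
inter-chain contact total.  A stricter mode
(`fibril_fraction(..., contact_mode = "typed")`) counts only contacts
whose bead-type pair occurs among the reference's contacts; the two
interpretations are never mixed within one scan.

A trajectory's *first passage* is the earliest MCS at which the fraction
reaches 80%.  The aggregation time pools first passages across
regenerated surface profiles: $\tau_{agg}$ is their arithmetic mean and
$\ln\tau_{agg}$ the log *of the mean* (not the mean of logs), with a
bootstrap SEM over trajectories.  Runs that never reach the criterion
are censored: excluded from the mean, always reported, and a censoring
fraction above 20% flags the estimate as a lower bound.

## Scans, replication and provenance

`run_scan()` drives the two experiment designs: attraction scans on
smooth surfaces ($\varepsilon^{ps}$ or $\varepsilon^{hs}$ on the x-axis)
and roughness scans ($\Theta$ on the x-axis at fixed attraction, for S,
D or DS styles).  Every point regenerates its surface profiles
(`profiles_per_point`, each with `runs_per_profile` trajectories); every
seed is derived by hashing the master seed with the condition, profile
and run indices, so scans are reproducible end to end and independent of
execution order.  `classify_regimes()` reads the weak/medium/strong
absorption boundaries off a summary curve — $\varepsilon_1$ at the grid
argmax of $\ln\tau_{agg}$, $\varepsilon_2$ at the argmin — and flags a
U-shape when an interior roughness point dips at least one pooled SEM
below the smooth-surface value and later rises again.  Classifications
are reported with their diagnostics, never as exact values.

## Desk scale versus production scale

The published aggregation-time curves are cluster-scale: $10^7$–$10^8$
MCS per trajectory, 100–150 trajectories per point, quoted at ~48 CPU
hours per rough-surface trajectory for twelve chains.  Nothing at desk
scale can or should reproduce those absolute numbers, and the package
does not pretend to.  What the desk-scale (default) budgets *do*
establish, and what the test suite pins down, is the machinery: exact
energies, exact roughness statistics, Boltzmann-correct sampling, exact
ground states at $N = 1$, and the strong-absorption regime property that
the median first passage grows monotonically with roughness
($\Theta_S \in \{0, 0.2, 0.4\}$ at $\varepsilon^{ps} = 1.4$, $T = 0.54$,
$N = 6$, 20 scaled-down trajectories per point, censored runs entering
the median at the budget cap — a conservative lower bound for a
monotonicity check).  The `paper_scale()` preset encodes the full
replication protocol (10 profiles × 15 runs, $10^8$ MCS) for cluster
execution.

What a green desk-scale run does **not** establish: absolute
$\ln\tau_{agg}$ values, the precise regime boundaries
$\varepsilon_{1,2}$ (which depend on sequence and $N$), or U-shape
statistics at production precision.  Those require the production
budgets above.

## Known limitations

* Contacts only; no distance-dependent potentials, bond angles, solvent
  or many-body terms.
* Roughness is uncorrelated (no fractal or patterned substrates) and the
  surface is rigid.
* Simulated annealing for $N \ge 2$ references is best-effort: restarts
  with recorded seeds, not a certificate of global optimality.
* MCS is an algorithmic clock, not physical time.
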