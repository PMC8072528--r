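# latfib

Lattice Monte Carlo simulation of polypeptide aggregation on smooth and
rough surfaces.

Protein aggregation into amyloid-like fibrils frequently happens at
interfaces — membranes, nanoparticles, engineered substrates — and both
the chemistry and the *topography* of the interface change the kinetics.
`latfib` is a compact simulation laboratory for that question: peptides
are self-avoiding chains of hydrophobic (H), polar (P) and charged (+/−)
beads on a cubic lattice, moved by Metropolis dynamics next to an
adsorbing surface whose attraction and roughness are tunable.  It is
aimed at anyone studying surface-modulated self-assembly who wants a
model small enough to validate exactly and fast enough to scan.

## Model

The energy of `N` chains is the contact sum

    E = Σ_l Σ_{i<j} e(s_i, s_j) δ(r_ij − a)        intra-chain (|i−j| ≥ 2)
      + Σ_{m<l} Σ_{i,j} e(s_i, s_j) δ(r_ij − a)    inter-chain
      + Σ_m Σ_i Σ_k e_νs(s_i) δ(r_ik − a)          chain–surface

in units of the hydrogen-bond energy ε_H (k_B = 1), with a 4×4 bead–bead
matrix (H–H = −1.0, +/− = −0.7, like charges +0.35, …) and surface
affinity rows whose tunable entries are −ε^ps (polar beads on hydrophilic
Ps surfaces) and −ε^hs (hydrophobic beads on hydrophobic Hs surfaces).
Rough surfaces scatter single (S), double (D) or mixed (DS) balls on the
plane; roughness is the standard deviation Θ of the resulting height
field h ∈ {0, 1, 2}, with closed forms such as Θ_S = √(Ω(1−Ω)) in the
ball-column fraction Ω.

Aggregation kinetics are measured as mean first-passage times: a
trajectory "aggregates" when it holds 80% of the inter-chain contacts of
an environment-specific minimal-energy reference fibril, and
τ_agg is the mean first passage pooled over regenerated surface
profiles (reported as ln τ_agg with a bootstrap SEM; censored runs are
reported, never silently dropped).

Exact desk-scale oracles back every moving part: exhaustive conformation
enumeration for ground states, closed-form roughness statistics,
Boltzmann-exact sampling checks on an enumerable system, and
incremental-vs-full energy agreement to 1e−9.

## Worked example

Six chains at T = 0.54 on a strongly absorbing hydrophilic surface
(ε^ps = 1.4): find the reference fibril, then compare smooth against a
slightly rough S-surface (Θ = 0.2).

```r
library(latfib)

model <- interaction_model(eps_ps = 1.4)
ref <- find_reference_fibril(6, model, environment = "Ps", seed = 1)
ref
#> <reference_fibril> Ps (anneal), N = 6, E_min = -64.90, Q_fib = 44

spec <- scan_spec(n_chains = 6, chemistry = "Ps", axis = "theta",
                  values = c(0, 0.2), style = "S", eps = 1.4,
                  temperature = 0.54, profiles_per_point = 2,
                  runs_per_profile = 3, max_mcs = 2e7,
                  measure_interval = 1e6, master_seed = 1, reference = ref)
out <- run_scan(spec)
out$summary[, c("value", "tau_agg", "ln_tau_agg", "sem", "n", "n_censored")]
#>   value  tau_agg ln_tau_agg      sem n n_censored
#> 1   0.0 143463.8   11.87384  26144.5 6          0
#> 2   0.2 582840.5   13.27567 176902.3 6          0
```

The reference fibril of the six chains carries 44 inter-chain contacts
at E = −64.9 ε_H; a trajectory stops when it first holds
⌈0.8 · 44⌉ = 36 of them.  At this strong attraction the slightly rough
surface already slows aggregation four-fold (ln τ_agg 11.9 → 13.3):
strong absorption pins chains between balls and restricts the lateral
diffusion that assembly needs.  At weaker attraction the same machinery
reproduces the opposite, catalytic regime (see the vignette; a
six-trajectory example is illustrative, not production statistics —
production scans use `paper_scale()` with 150 trajectories per point).

Single values are just as accessible:

```r
total_energy(extended_dimer <- system_state(
  rbind(cbind(2:9, 5L, 5L), cbind(9:2, 6L, 5L)),
  peptide_sequence(), simulation_box(14)), interaction_model())
#> <energy_breakdown> intra 0.000 + inter -5.800 + surf 0.000 = -5.800 (8 inter contacts)
```

A thin command-line front end (`exec/latfib`) exposes `simulate`,
`scan`, `ground-state`, `surface-gen` and `analyze` subcommands over
JSON configs mirroring `scan_spec()`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main pipeline from scratch —
annealing a reference fibril and running a reduced roughness scan
(profile generation → chain placement → Metropolis dynamics →
first-passage detection → τ_agg estimation) — and writes its JSON result
manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.
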