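# flipmsm

Kinetic analysis of damaged-base flipping in DNA from molecular-dynamics
trajectories, in R.

When an oxidized base such as thymine glycol (Tg) sits in a DNA duplex, it
can rotate out of the helix — *base flipping* — which is how repair enzymes
find it. The thermodynamics and kinetics of that motion are encoded in long
MD trajectories, and extracting them takes a standard but intricate chain
of estimators. `flipmsm` implements that chain end to end for anyone
analysing base-flipping (or comparable slow conformational) dynamics:

- **Collective variables**: center-of-mass separation between lesion and
  partner base, the flip pseudodihedral **CPDb** over four centers of mass
  (flanking base pairs, flanking phosphates, flipping pyrimidine ring),
  atom torsions, hydrogen-bond occupancy, RMSD/RMSF.
- **Featurization**: lesion–partner pairwise-distance matrices with
  segment-aware bookkeeping for multiple independent trajectories.
- **TICA**: solves C(τ)U = C(0)UΛ with a symmetrized estimator and
  regularized whitening; projects z(t)ᵀ = r(t)ᵀU; picks dimensions by
  cumulative kinetic variance Σλᵢ².
- **MSM**: k-means microstates, sliding-window counts, reversible
  maximum-likelihood transition matrix (detailed balance πᵢTᵢⱼ = πⱼTⱼᵢ),
  implied timescales tᵢ = −τ/ln λᵢ, Chapman–Kolmogorov validation with
  bootstrap 95% bands.
- **PCCA+** macrostates with free energies ΔG(s_I) = −k_BT ln Σ_{j∈I} πⱼ.
- **TPT**: committors, gross/net reactive flux fᵢⱼ = πᵢq⁻ᵢTᵢⱼq⁺ⱼ, rates,
  and deterministic bottleneck pathway decomposition with flux fractions.
- **meta-eABF**: a 1-D extended-system ABF + metadynamics sampler over
  analytic potentials with a CZAR free-energy estimator and barrier
  extraction.
- **Synthetic generators** (Markov chains, overdamped Langevin dynamics on
  multi-well landscapes, toy duplex geometries) with recorded ground truth,
  so every estimator is validated by parameter recovery.

## Worked example

Five metastable basins on a 2-D landscape, analysed exactly like an MD
data set — featurize, TICA, cluster, MSM, CK test, PCCA+, flux:

```r
library(flipmsm)

spec <- langevin_spec("five-basin-2D", n_steps = 2e5, seed = 3,
                      n_noise_dims = 3)
sim <- simulate_langevin(spec)

cfg <- run_config(tica_lag = 50, k = 150, msm_lag = 50, n_macrostates = 5,
                  ck_factors = 1:4, n_boot = 50, seed = 3)
res <- run_pipeline(cfg, features = sim$features)
print(res)
```

```
Base-flipping kinetic analysis pipeline
  TICA: 2 dims, eigenvalues 0.930 0.895 0.000 -0.002
  MSM: 150 active microstates at lag 50
  CK test: PASS
  macrostate dG (kcal/mol): 0.00 0.03 0.23 0.38 0.83 
  flux pathways:
    1-2-5  16.5%
    1-4-3-5  0.8%
    1-4-5  0.6%
    1-5  0.6%
```

Reading the output: TICA keeps the two slow directions of the landscape
(eigenvalues 0.93/0.90, the noise dimensions fall to ≈0); the CK test says
the 150-microstate model at lag 50 predicts its own coarse-grained
long-time behaviour; the five macrostate free energies are Boltzmann
inversions of the stationary weights (most stable state = 0 by
convention); and the flux decomposition lists the dominant reactive routes
from macrostate 1 (source) to 5 (sink) with their shares of the total
transition flux. `print(res$pcca)` tabulates microstate counts, stationary
weights and ΔG per macrostate, and

```r
micro <- unlist(res$msm$dtrajs)
ok <- micro %in% res$msm$active_set
label_agreement(sim$basins[ok] + 1L, res$pcca$crisp[match(micro[ok], res$msm$active_set)])
#> [1] 0.987
```

shows the kinetic macrostates recover the generator's ground-truth basins.

For real data, start from `read_trajectory("traj.pdb")`, build selections
with `atom_selection()` / `duplex_cv_selections()`, and use the same verbs;
PMFs on toy landscapes come from `meta_eabf()` → `estimate_pmf()` →
`extract_barriers()`.

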