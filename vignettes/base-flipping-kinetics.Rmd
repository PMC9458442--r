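---
title: "Kinetics of damaged-base flipping with Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of damaged-base flipping with Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Oxidative damage converts thymine into thymine glycol (Tg), a lesion whose
chiral C5/C6 centers yield distinct epimers with very different effects on
duplex DNA. A damaged base can rotate out of the helix ("base flipping"),
exposing it to repair enzymes; whether this happens spontaneously, and
through which intermediates, is a kinetics question that equilibrium
structures alone cannot answer. `flipmsm` implements the full kinetic
analysis chain used to answer it from molecular-dynamics trajectories:

1.  geometric collective variables (CVs) that monitor flipping — the
    center-of-mass (COM) separation between the lesion and its Watson–Crick
    partner, and the pseudodihedral **CPDb** built on four centers of mass
    (flanking base pairs; the two flanking phosphate groups; the
    six-membered ring of the flipping pyrimidine) — plus hydrogen-bond
    occupancy, RMSD and RMSF;
2.  pairwise-distance featurization of the lesion/partner atom groups;
3.  TICA (time-lagged independent component analysis) dimension reduction;
4.  k-means microstates, a reversible maximum-likelihood Markov state model
    (MSM), implied timescales and the Chapman–Kolmogorov (CK) test;
5.  PCCA+ metastable macrostates and free energies from stationary weights;
6.  transition-path-theory (TPT) committors, reactive flux, rates, and
    pathway decomposition;
7.  a meta-eABF (extended-system adaptive-biasing-force + metadynamics)
    sampler with a CZAR estimator for potentials of mean force (PMFs) and
    barrier heights on analytic landscapes.

A synthetic-data module generates every input with known ground truth, so
the whole chain is testable without microsecond MD.

## Models and estimators

**TICA.** For mean-free features $r(t)$ the lagged covariances are
$C_{ij}(\tau) = \langle r_i(t)\, r_j(t+\tau)\rangle$, averaged over all
lagged pairs $t = 1..N-\tau$ inside each trajectory segment (pairs never
straddle segment boundaries; the normalization is the number of pairs). The
generalized eigenproblem $C(\tau)U = C(0)U\Lambda$ is solved by whitening
with a truncated inverse square root of $C(0)$; projections are
$z^\top(t) = r^\top(t)U$. We use the symmetrized (reversible) estimator —
both time directions contribute — which guarantees real eigenvalues for
equilibrium data. Dimension selection follows cumulative *kinetic variance*:
the smallest $m$ with $\sum_{i\le m}\lambda_i^2 / \sum_{\lambda_i>0}
\lambda_i^2 \ge f$ (default $f = 0.9$); this is the standard quantitative
reading of "90% of kinetic information retained". Eigenvalue scaling of the
outputs (kinetic map) is available via `scale = TRUE` but off by default.

**Reversible MSM.** Sliding-window transition counts $C_{ij}$ at lag
$\tau$ are restricted to the largest strongly connected state set, and the
transition matrix maximizes $\prod T_{ij}^{C_{ij}}$ subject to detailed
balance $\pi_i T_{ij} = \pi_j T_{ji}$, via the standard self-consistent
fixed-point iteration on symmetric pair weights (converged when the
stationary vector moves by less than $10^{-10}$ relative). Implied
timescales are $t_i = -\tau/\ln\lambda_i(\tau)$.

**CK validation.** The model propagated as $T(\tau)^k$ is compared with a
model re-estimated at lag $k\tau$, both coarse-grained to macrostate
self-transition probabilities. Confidence bands come from trajectory
bootstrap (resampling whole segments, or contiguous blocks when only one
segment exists; default 100 replicates, 95% bands). The test passes when
every re-estimated probability lies inside the band. We chose the bootstrap
over a conjugate-posterior sampler: it reproduces both the point estimates
and the confidence level with one mechanism and no extra hyperparameters.

**PCCA+.** Memberships are built on the top-$M$ right eigenvectors with the
deterministic inner simplex algorithm (translate to the furthest row, then
successively deflate each chosen vertex direction); the linear map sending
the $M$ vertex microstates to simplex corners gives the membership matrix,
with small negative entries clipped and rows renormalized. No stochastic
inner optimization is used, so results are seed-free. Macrostates are
relabeled by decreasing stationary weight — macrostate 1 is always the most
stable. Free energies are $\Delta G(s_I) = -k_B T \ln \sum_{j\in s_I}\pi_j$
($k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$, default $T = 298$ K),
min-shifted to zero.

**TPT.** The forward committor solves the discrete boundary-value problem
by a linear solve; gross flux is $f_{ij} = \pi_i q^-_i T_{ij} q^+_j$, net
flux $f^+_{ij} = \max(0, f_{ij}-f_{ji})$, the rate is
$F/\sum_i \pi_i q^-_i$ per lag time. Pathways use iterative bottleneck
(widest-path) decomposition: the highest-min-capacity path is found by
binary search over edge weights plus a breadth-first search that expands
states in ascending order (so ties resolve to fewer edges, then lower state
indices), its capacity is subtracted, and its flux fraction recorded. An
exhaustive decomposition reconstructs the net flux matrix exactly. The
literature-style per-path "probabilities" are read as fractions of the total
A→B flux, the standard TPT convention. Macrostate-pair rates are block
fluxes divided by the source macrostate weight, per lag and (when a
ns-per-frame factor is supplied) per nanosecond.

**meta-eABF + CZAR.** A fictitious particle $\lambda$ is coupled to the CV
$\xi$ by $\tfrac12 k_u(\xi-\lambda)^2$; the adaptive force is the negative
running mean of the spring force in $\lambda$'s bin, ramped in over
`n_full = 200` samples, and metadynamics Gaussians (height 0.1 kcal/mol,
width 2 bins, stride 1000) are deposited along $\lambda$ on a grid. Because
the hills perturb the $\lambda$ marginal, the PMF is estimated by CZAR:
$A'(\xi) = -k_BT\,\partial\ln\tilde\rho(\xi)/\partial\xi +
k_u(\langle\lambda\rangle_\xi - \xi)$, integrated by the trapezoid rule and
min-shifted; per-bin errors come from block averaging over five time
blocks. Defaults follow common biasing-engine conventions: 5° bins for
angles / 0.1 Å for distances, $k_u = k_BT/\text{bin width}^2$ (thermal
coupling fluctuation of one bin), fictitious temperature equal to the
physical one. Unvisited interior bins raise an error rather than being
interpolated.

## The synthetic generators, and what they do and do not show

The generators stand in for six independent microsecond all-atom
simulations of a solvated duplex:

-   **Discrete chains** with known transition matrices exercise estimation
    (a reversible 5-state birth–death chain sampled for $10^6$ steps is
    recovered to $|\hat T_{ij}-T_{ij}| < 0.01$, $|\hat\pi_i - \pi_i| <
    0.005$).
-   **Overdamped Langevin dynamics**
    $x \leftarrow x - (\Delta t/\gamma)\nabla V + \sqrt{2k_BT\Delta
    t/\gamma}\,\xi$ on analytic potentials. The five-basin 2-D landscape is
    a sum of inverted Gaussians (centers roughly pentagonal, depths 3.7,
    2.9, 3.3, 2.9, 2.5 kcal/mol, common width 0.5 CV units, plus a steep
    confining wall) at $k_BT = 0.592$ kcal/mol (298 K),
    $\Delta t = 0.01$, $\gamma = 1$. Depths were chosen once so that the
    landscape shows five clear metastable basins with hundreds of
    interbasin transitions per $10^6$ steps; real macrostate populations
    are not known a priori, so the depths are package defaults and fully
    configurable. Ground-truth labels are by nearest basin center
    (simple and deterministic, though it assigns transition-region frames
    geometrically rather than kinetically). Optional fast AR(1) noise
    dimensions emulate kinetically irrelevant features.
-   **Toy duplexes** are idealized untwisted ladders of planar six-membered
    rings plus one backbone P per residue — *not* physical B-DNA. The
    backbone P sits radially behind each base so the flip axis (through the
    flanking phosphates), the in-helix ring and the partner ring are
    collinear: flip angle 0 is then the exact COM-distance minimum, and
    CPDb is *exactly* linear in the flip angle (rotation about the p2–p3
    axis adds to the torsion directly). The default twist is 0 because a
    tilted flip axis would sweep the ring into its neighbours; nonzero
    twists are allowed and the >0.5 Å interatomic-distance invariant is
    always enforced.

Passing tests on these generators show the *estimators* are correct and the
pipeline wiring is faithful; they do not show that any particular force
field, solvent model or sampling length suffices for real DNA — the
generators have no solvent, no sequence context, and Markovian dynamics by
construction.

## Numerical choices

-   TICA whitening truncates $C(0)$ eigendirections below
    $10^{-10}\times\mathrm{tr}\,C(0)$ (pairwise distances are strongly
    collinear); dropped counts are reported. Eigenvector signs follow a
    deterministic convention (largest-magnitude component positive).
-   Torsions use the IUPAC sign convention via `atan2`, wrapped to
    $(-180, 180]$; coincident or colinear defining points are errors.
-   k-means uses k-means++ seeding at a derived seed and Lloyd iterations;
    for long trajectories the centers are fitted on a subsample (default
    $2\times10^5$ frames) and all frames assigned to the nearest center.
    Duplicate-frame degeneracies are handled by jittering the init.
-   Sliding-window counting is used (the community default; it maximizes
    data use). Whether to stride instead is configurable at the counting
    call.
-   The reversible MLE requires every active state to have outgoing
    counts; states outside the largest strongly connected set are dropped
    and the dropped frame count is logged by the orchestrator.
-   One global integer seed; each stochastic component derives its own
    seed by a fixed offset, so stages are individually reproducible.
-   eABF note: with coupling stiffness $k_u$ the mean-force estimator
    targets the spring-mollified free energy (for a harmonic well of
    curvature $k$, curvature $k\,k_u/(k+k_u)$); CZAR's correction term
    removes most of this in the reported PMFs. The test suite checks both
    the mollified target and the practical 5%-level agreement with the
    analytic gradient.
-   Problem sizes used by the validation suite and the reproduction
    script: $4\times2.5\times10^5$ Langevin steps for the five-basin
    pipeline (300 microstates, MSM lag 50 frames, CK factors 1–4, 100
    bootstrap replicates), $6\times10^6$ steps for the 5 kcal/mol
    double-well PMF and $2.4\times10^7$ for the flat-potential closure
    test — lengths at which the estimators' block-average errors are
    comfortably below the 0.3 kcal/mol error scale quoted for the PMFs.

## Known limitations

-   PCCA+ uses the unoptimized inner-simplex memberships; for very fuzzy
    spectra a full simplex-volume optimization could sharpen boundaries.
-   The CK bands bootstrap segments; with a single short segment the block
    bootstrap underestimates long-range correlation.
-   The meta-eABF engine is 1-D by design (toy landscapes); reproducing
    all-atom DNA PMFs is explicitly out of scope.
-   No binary trajectory formats (DCD/XTC); PDB and delimited text only.

## A short worked example

```{r example}
library(flipmsm)

spec <- langevin_spec("five-basin-2D", n_steps = 2e5, seed = 3,
                      n_noise_dims = 3)
sim <- simulate_langevin(spec)

cfg <- run_config(tica_lag = 50, k = 150, msm_lag = 50, n_macrostates = 5,
                  ck_factors = 1:4, n_boot = 50, seed = 3)
res <- run_pipeline(cfg, features = sim$features)
print(res)

# how well do kinetic macrostates recover the ground-truth basins?
micro <- unlist(res$msm$dtrajs)
ok <- micro %in% res$msm$active_set
macro <- res$pcca$crisp[match(micro[ok], res$msm$active_set)]
label_agreement(sim$basins[ok] + 1L, macro)
```

The same stages are available as individual verbs —
`pairwise_distance_features()`, `tica()`, `kmeans_cluster()`,
`markov_model()`, `implied_timescales()`, `chapman_kolmogorov()`,
`pcca()`, `tpt()`, `decompose_pathways()`, `meta_eabf()`,
`estimate_pmf()`, `extract_barriers()` — for scripted analyses of real
trajectory data read with `read_trajectory()`.
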