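# photoswitchr

Analysis toolkit for reversibly switchable fluorescent proteins (RSFPs):
what makes a chromophore able to cis–trans isomerize, and how fast and how
completely a variant switches off. It is aimed at groups characterising
photoswitchable / photoconvertible protein variants who have
molecular-dynamics trajectories on one side and fluorescence or absorbance
measurements on the other.

The package implements four connected analyses:

1. **Dynamic network analysis of MD trajectories.** Each amino acid is one
   node and the chromophore is divided into three nodes (imidazolinone,
   phenyl, His66-derived fragment). Nodes are joined when any inter-atomic
   distance stays below 4 Å in more than 75 % of frames (sequence
   neighbours excluded); edges are weighted by the dynamical
   cross-correlation *C<sub>ij</sub>* of node displacements as
   *w<sub>ij</sub>* = −log |*C<sub>ij</sub>*|. Girvan–Newman
   edge-betweenness removal with Newman–Girvan modularity model selection
   yields communities of correlated motion, and the **co-membership
   criterion** classifies a variant as isomerization-competent when the
   phenyl and His66 nodes share a community.
2. **Bond-length alternation (BLA).** BLA = d(C<sub>imid</sub>–C<sub>bridge</sub>) −
   d(C<sub>bridge</sub>–C<sub>phenol</sub>) per frame, decomposed into a
   three-component Gaussian mixture by EM; the weight of the right-most
   component tracks the phenolic resonance form (BLA > 0).
3. **Photoswitching kinetics.** Off-switching obeys
   *I(t) = A e<sup>−kt</sup> + c*; the package fits *A*, *k*, *c* by
   Levenberg–Marquardt, reports the switching contrast
   *SC* = 100 *A*/(A + c), rate fold-changes between variants, and
   multi-cycle photostability (geometric per-cycle loss factor).
4. **Spectroscopy.** pKa from single-site Henderson–Hasselbalch titration
   fits, red-form extinction coefficients from paired band-maximum
   absorbance changes, and relative quantum yields from through-origin
   slopes of emission area vs absorbance.

A seeded synthetic-data generator (`trajectory_spec()` / `gen_*()`)
produces every input the pipeline consumes — trajectories with planted
correlated-motion groups and controllable contact geometry, noisy decay
traces with cycle-to-cycle bleaching, titrations, mixture samples — so the
whole pipeline is testable without external data.

## A worked example

```r
library(photoswitchr)

## 1. a planted trajectory in which the chromophore co-moves with group 1
gen  <- gen_trajectory(trajectory_spec(n_residues = 18, n_groups = 2,
                                       chromophore = "same", seed = 1))
traj <- superpose(gen$trajectory)
nm   <- build_node_map(traj, gen$fragment_table)
net  <- build_graph(contact_occupancy(traj, nm),
                    correlation_matrix(traj, nm), nm)
net
#> dyn_network: 21 nodes, 30 edges (cutoff 4.00 A, occupancy > 0.75, neighbours excluded)
part <- detect_communities(net)
part
#> community_partition: 2 communities, Q = 0.4571
co_membership(part, nm)
#> [1] TRUE

## 2. an off-switching trace at the fast-variant rate
fit <- fit_monoexp(gen_decay_trace(kinetic_spec(
  A = 0.98, k = 3.39, c = 0.02, dt = 0.0074, n_points = 200,
  noise_sigma = 0.005, seed = 5)))
fit
#> mono-exponential fit: I(t) = A exp(-k t) + c
#>   A = 0.9798 +/- 0.0015
#>   k = 3.386 +/- 0.012 1/s
#>   c = 0.01994 +/- 0.00069
#>   residual RMS 0.00496 (n = 200)
switching_contrast(fit)
#> [1] 98.00498
```

The network output says the planted two-group structure was recovered
(modularity Q ≈ 0.46 for two communities) and that the phenyl and His66
nodes co-move, i.e. the design is isomerization-competent. The kinetic fit
recovers the planted rate (3.39 s⁻¹) within its standard error, and the
switching contrast — the percent drop from initial to plateau fluorescence
— comes out at 98 %.

## Package layout

* `R/synthgen.R` — synthetic-data generator and plain-text writers
  (PDB, XYZ, TSV, CSV, JSON)
* `R/trajio.R` — structure/trajectory reading, Kabsch superposition,
  node mapping
* `R/dynnet.R` — occupancy, correlation, graph construction, communities,
  co-membership, reports
* `R/blamod.R` — BLA series and the three-Gaussian EM
* `R/photokin.R` — decay fits and derived kinetic quantities
* `R/spectro.R` — pKa, extinction coefficient, quantum yield
* `R/pipeline.R` — `run_network_pipeline()` and `run_demo()`
* `vignettes/photoswitching-analysis.Rmd` — full methods description

Fitted objects are ordinary S3 models with `print`, `summary`, `coef`,
`predict`, `residuals`, `plot` and `simulate` methods where meaningful.
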