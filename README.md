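# rigiditygraph

Statistical learning of protein mechanical-coupling networks from molecular
dynamics, and spectral analysis of the resulting rigidity graphs.

## The problem

Topology-based protein networks (an edge whenever two residues are within a
cutoff) capture collective vibrations but are blind to chemistry: contacts at
similar distances can carry very different interaction strengths during
dynamics. This package learns those strengths. A backbone/side-chain elastic
network model (bsENM) places coarse-grained sites at each residue's amide N,
carbonyl O, and one side-chain position, connects all site pairs within a
cutoff `l_c` (7.8 Å) by harmonic springs, and adjusts every spring constant
`k_ij` by self-consistent **fluctuation matching** until the model's predicted
inter-site distance variances equal those measured in an all-atom trajectory:

    var_model(l_ij) = e' (C_ii + C_jj − C_ij − C_ji) e,   C = kB·T · H⁺

with `H` the network Hessian. Many springs converge to `k = 0`: the mechanical
coupling network is much sparser than the contact network, and its coupling
strengths are heavy-tailed (Lomax-distributed, with power-law tails of
exponent 2 < γ < 3 — scale-free behaviour).

Summing learned spring constants between residues gives **rigidity graphs**:
adjacency `k_IJ`, degree `k_II`, Laplacian `L = D − A`, signless Laplacian
`K = D + A`, split into backbone–backbone (BB), backbone–side-chain (BS) and
side-chain–side-chain (SS) parts with `K = K_BB + K_BS + K_SS`. Across
consecutive trajectory windows the package computes mean-modes of the averaged
graph, their per-window contents `r = max_β |ν_β·ν^α'|`, selects **prominent
modes** (strength above the Tukey fence `Q3 + 1.5·IQR` *and* content in the
top quantile), extracts **mechanical hotspots** (residues with `ν_I² ≥ 0.1`),
and assigns each residue backbone/side-chain **rigidity scores**
`κ_I = ⟨r⟩·λ` from its characteristic mode. Heavy-tail (Lomax, Hill/power-law)
fits quantify the scale-free behaviour.

It is for structural bioinformaticians and molecular modellers who have
all-atom trajectories (PDB/DCD via bio3d) and want per-residue mechanical
couplings, hotspots and rigidity scores — plus a synthetic reference-network
generator that makes the whole pipeline testable without any trajectory.

## Worked example

Ground truth comes from the synthetic generator: a 30-residue self-avoiding
coil with known heavy-tailed spring constants and analytic fluctuation
targets.

```r
library(rigiditygraph)

ref  <- make_reference_enm(fixture_spec(n_residues = 30, seed = 7))
init <- build_initial_model(ref$cg, lc = 7.8, k0 = 1, targets = ref$targets)
fit  <- fluctuation_matching(init, ref$targets, tol = 1e-6)
fit$report
#> Fluctuation matching: 11 iterations, converged (max rel. mismatch 3.63e-07)
#>   springs at k = 0: 108 of 1042
```

The learner starts from uniform springs (`k0 = 1`) on all 1042 within-cutoff
pairs and, in 11 Newton iterations, reproduces every target variance to
better than 4e-7 relative error; 108 springs converge to exactly zero —
correctly identifying the generator's silent pairs (the recovered non-zero
constants match the reference to ~1e-5 relative error).

```r
ws <- make_window_series(ref, n_windows = 20, perturbation = 0.3, seed = 101)
st <- mean_mode_content(ws$graphs)
pm <- select_prominent_modes(st$spectrum$values, st$content_mean, 0.75)
pm
#> Prominent modes: 1, 2, 3 (fence 74.41, content >= 0.9562)
hotspot_residues(st$spectrum$vectors[, pm$modes[1]])
#> [1]  1 27
```

The window series multiplies spring strengths by lognormal noise and plants
one dominant persistent edge between residues 1 and 27; the top mean-mode of
the signless Laplacian is prominent (strength 5× above the fence, content
≈ 1) and localizes exactly on that pair — the planted mechanical hotspots.

```r
sp <- fit$model$springs
k_ns <- sp$k[sp$category == "nonskeleton" & sp$k > 0]
fit_lomax(k_ns)
#> Lomax fit: shape 0.9768, scale 0.1897 (n = 415, logLik -159.8)
fit_powerlaw_tail(k_ns)
#> Power-law tail: gamma 2.285, x_min 0.8077 (n_tail = 94, KS 0.04033)
```

The learned non-skeleton couplings are heavy-tailed with a power-law tail
exponent γ ≈ 2.3 — in the 2 < γ < 3 range typical of scale-free networks.

For real data, `map_trajectory()` converts a bio3d structure + trajectory to
CG coordinates, `split_windows()` + `compute_fluctuation_targets()` produce
per-window targets, and the same calls as above do the rest. A thin CLI over
these functions ships in `inst/cli/rigiditygraph`
(`map | learn | graphs | spectral | tailfit | synth`).

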