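# meadowpath

Integrated spatial analysis of a mapped plant population: **Bayesian
kriging** of environmental surfaces, **piecewise Mantel correlograms**, and
**Mantel path analysis** that assembles a signed network of abiotic–biotic
interactions with geographic space as a conditioning variable.

The package is written for plant and community ecologists who have (or
simulate) a fully mapped population — every individual geolocated, traits,
herbivory and neighbor densities recorded per plant, and environmental
variables sampled at scattered sites — and who want to ask what structures
the population in space: microhabitat preference, limited dispersal,
competition, or herbivory.

## The model and statistics

**Spatial interpolation.** Environmental observations follow a hierarchical
Gaussian process

Y_i | S ~ N(β + S(x_i), τ²),  S(x) ~ GP(0, σ² R(h; Φ)),  R(h; Φ) = exp(−h/Φ),

with constant trend β, partial sill σ², nugget τ² (relative nugget
τ²_rel = τ²/σ²) and correlation scale Φ in meters (effective range 3Φ).
Flat priors on β and on a discrete (Φ, τ²_rel) grid, reciprocal prior on
σ²; β and σ² are marginalized analytically and the (Φ, τ²_rel) posterior is
a normalized table. Surfaces come from posterior draws (default 100,000)
through the conditional Gaussian predictive, and leave-one-out
cross-validation checks calibration.

**Spatial structure.** Variables are standardized, turned into Euclidean
distance matrices, and profiled with Mantel correlograms in 2.5-m lag
classes (10,000 permutations by default); the autocorrelation range is read
from the initial run of significant (P ≤ 0.05) classes.

**Interaction network.** A pre-declared hypothesis graph (directed edges
with expected signs) is evaluated edge by edge with partial Mantel tests
conditioned on the adjacent variables, adding the geographic distance
matrix whenever either endpoint is spatially autocorrelated (C ~ A | Space + B).
Retained edges carry partial Mantel coefficients, 90% bootstrap
confidence intervals, and signs read from the value-scale partial
correlation (distance matrices cannot carry the direction of a relation).

Because field data of this kind are typically not deposited, the package
includes a synthetic-meadow generator (`generate_study()`) with known
causal ground truth — a 40 × 50 m domain, 234 plants, 71 environmental
sites by default — used by all calibration and recovery tests.

## Worked example

```r
library(meadowpath)

# a synthetic study with known truth
study <- generate_study(truth_config(seed = 7))
study
#> synthetic_study: 234 plants, 71 env sites on a 40 x 50 m domain (seed 7)

# krige soil moisture from the 71 sampled sites
field <- spatial_field(study$env_sites[, c("x", "y")],
                       study$env_sites$soil_moisture, "soil_moisture")
post <- log_marginal_posterior(field, parameter_grid())
post
#> posterior_table: 420 grid points over (phi, tau2_rel); mode phi = 11 m, tau2_rel = 0 (mass 0.072)

draws <- sample_posterior(post, 10000, seed = 1)
surface <- krige_predict(field, draws,
                         as.matrix(expand.grid(x = 0:40, y = 0:50)))

# spatial structure of a plant trait
analysis <- cbind(study$plant_env[, c("x", "y", "elevation", "soil_moisture", "vpd")],
                  study$plants[, -(1:2)])
cg <- correlogram(euclidean_dmat(standardize(analysis$rosette_diameter)),
                  euclidean_dmat(as.matrix(analysis[, c("x", "y")])),
                  n_perm = 999, seed = 2)
autocorr_range(cg)
#> [1] 13.75

# one edge of the interaction network
m <- partial_mantel(euclidean_dmat(standardize(analysis$elevation)),
                    euclidean_dmat(standardize(analysis$soil_moisture)),
                    list(euclidean_dmat(as.matrix(analysis[, c("x", "y")]))),
                    n_perm = 9999, seed = 3)
m
#> partial Mantel (| partial1): r = 0.3330, p = 0.0001 (greater, 9999 permutations)
```

The posterior table says the moisture surface is autocorrelated with modal
correlation scale ~11 m; the correlogram finds significant positive
autocorrelation in rosette size out to the 12.5–15 m lag class (range
13.75 m, the class midpoint); and elevation remains strongly associated
with soil moisture after conditioning on geographic distance (partial
Mantel r = 0.33, permutation p = 1e-4 — the generator's elevation→moisture
effect, whose negative direction is recovered on the value scale by
`evaluate_network()`).

The full pipeline — simulate, krige all three environmental variables,
extract surfaces at plant locations, correlograms, pairwise Mantel tests,
path network, manifest with per-file digests — is one call:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

or from a shell, `Rscript inst/scripts/meadowpath.R all --config run.yml`.

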