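# groovemapper

Tools for asking *where* a BH3 peptide binds on the apoptosis effector BAK
— and, more generally, for the class of analyses that question rests on.
BCL2-family effectors carry a canonical BH3-binding groove (helices
α3/α4/α5); some activator peptides (e.g. BMF and HRK BH3) appear instead to
engage a noncanonical α4/α6/α7 groove. The evidence for such a claim
typically combines:

1. **NMR chemical shift perturbation (CSP) mapping.** From ¹H,¹⁵N-HSQC
   titrations, the per-residue combined shift
   `CSP = sqrt((ΔδNH² + ΔδN²/25)/2)` is thresholded at the mean plus one
   standard deviation, and residues are classified as *shifted* (focal,
   dose-responsive moves), *attenuated* (peak intensity lost to the noise
   level), or unperturbed.
2. **Groove mapping and enrichment.** Classified residues are mapped onto
   structure-defined residue sets for the two grooves, with a permutation
   test for per-groove enrichment.
3. **Conformer-population stability.** Simulation ensembles are clustered
   on best-fit Cα RMSD (Kabsch superposition, proper rotations only) with
   average linkage terminated at ε = 2.0 Å; the population of the most
   populated cluster ranks candidate binding modes.
4. **Binding and release assays.** Steady-state SPR isotherms are fitted to
   the 1:1 Langmuir model `R_eq(C) = Rmax·C/(K_D + C)` with the QC rule that
   the top concentration be at least threefold above the fitted K_D, and
   liposome dequenching traces are reduced to
   `release % = (F_sample − F_blank)/(F_Triton − F_blank) × 100`.

Every analysis stage has a matching synthetic-data generator with known
ground truth (titration peak lists, cluster-structured conformer ensembles,
Langmuir isotherms, release traces), so the whole pipeline is testable end
to end without any deposited data. A YAML-driven `run_pipeline()` ties the
stages into one reproducible, hash-stable report.

## Worked example

```r
library(groovemapper)

## --- CSP mapping: a titration whose true perturbations sit in the
##     noncanonical groove (BAK residue numbering) ---------------------
noncan <- c(96, 98, 99, 113, 114, 118, 157, 161, 162, 163, 165, 166, 168)
specs  <- lapply(noncan, function(r)
  perturbation_spec(r, "shift", max_dH = 0.03, max_dN = 0.15))
series  <- gen_peak_titration(186, specs, noise_sd = 0.002, seed = 42)
profile <- profile_titration(series, noise_floor = 0.1)
attr(profile, "threshold")
#> [1] 0.0107
table(profile$class)
#>     shifted unperturbed
#>          13         173

mapping <- map_perturbations(profile, grooves = default_grooves())
groove_enrichment(mapping, n_permutations = 9999, seed = 1)$per_groove
#>         groove n_groove n_perturbed_in_groove fraction permutation_p
#> 1    canonical       23                     6    0.261        0.0021
#> 2 noncanonical       14                    13    0.929        0.0001
```

Thirteen of the fourteen noncanonical-groove residues are recovered above
the mean + 1 SD threshold (fraction 0.93, permutation p = 1e-4); the
canonical groove lights up only through the six residues the two grooves
share on α3/α4.

```r
## --- Steady-state SPR: truth K_D = 1000 nM, 8 two-fold dilutions ------
iso <- gen_isotherm(kd = 1000, rmax = 100, concentrations = 3200 / 2^(0:7),
                    noise_frac = 0.02, seed = 42)
fit <- fit_steady_state(iso)
#> K_D = 998 +/- 86 nM; Rmax = 101.7 RU; cmax/K_D = 3.21 (saturation ok: TRUE)

## --- Conformer populations: two clusters at design 0.65/0.35 ----------
cen <- gen_conformer_centers(20, 2, separation = 5, seed = 1)
ens <- gen_ensemble(cen, c(0.65, 0.35), 1000, jitter_sd = 0.25, seed = 2)
cl  <- average_linkage_cluster(pairwise_rmsd(ens), epsilon = 2.0)
cl$populations
#> [1] 0.647 0.353
top_population(cl)
#> $population       [1] 0.647
#> $representative_frame  [1] 564

## --- Liposome release: truth 46% -------------------------------------
tr <- gen_release_traces(0.46, noise_sd = 0.5, seed = 3)
summarize_release(list(BMF = tr))
#>   condition mean_percent sd_percent n_replicates
#> 1       BMF           46         NA            1
```

The fitted K_D (998 ± 86 nM) recovers the design value and passes the
threefold-saturation QC; the clustered top population (0.647) matches the
design 0.65 within binomial error; the release percentage inverts the
dequenching formula exactly.

## Command line

```sh
groovemapper simulate isotherm --kd 1000 --seed 1 --out demo
groovemapper fit-kd --isotherm demo/isotherm.csv --cmax 3200
groovemapper run --config run.yaml     # full pipeline -> report.json/.md
```

(The script installs to `<library>/groovemapper/cli/groovemapper`.)

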