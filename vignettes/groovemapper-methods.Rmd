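---
title: "Methods: CSP mapping, groove enrichment, conformer populations and binding assays"
author: "groovemapper developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP mapping, groove enrichment, conformer populations and binding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovemapper)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, the numerical
choices, and the known limitations. No empirical claim is made here that the
test suite does not itself compute.

## 1. Chemical shift perturbation analysis

A ¹H,¹⁵N-HSQC spectrum shows one peak per backbone amide. Titrating an
unlabeled peptide against the ¹⁵N-labeled protein perturbs peaks near (or
allosterically coupled to) the binding site. Two observable classes matter:

* **shifted** — focal, dose-responsive displacement of the peak
  (fast-exchange binding);
* **attenuated** — loss of peak intensity to the spectral noise level
  (intermediate-exchange broadening or induced disorder).

The per-residue statistic is the combined shift

$$\mathrm{CSP} = \sqrt{\frac{\Delta\delta_{NH}^2 + \Delta\delta_N^2/25}{2}},$$

which down-weights the ¹⁵N axis by its ~5-fold wider ppm dispersion.
`profile_titration()` measures the CSP between the apo point and the
*highest* titration ratio; intermediate ratios feed only a monotonicity
("dose-responsive") flag. The significance threshold is the **mean plus one
sample (n − 1) standard deviation** of the CSPs over assigned residues — a
deliberately conservative small-sample choice. Classification applies
**attenuation first** (intensity ratio at or below the user-supplied
`noise_floor` wins regardless of CSP), then **strict** `csp > threshold`
for the shifted call. A residue present in apo but unmatched at the top
ratio is treated as a disappeared peak: intensity ratio 0, CSP `NA`
(excluded from the mean/SD, since a peak at the noise level has no
measurable position).

The `noise_floor` is a required parameter, not a guess: the level at which
a real spectrum's peaks drown is instrument- and acquisition-dependent and
the analysis should not invent it.

### What the titration generator emulates

`gen_peak_titration()` draws apo peaks uniformly in realistic ppm windows
(¹H 6–10, ¹⁵N 100–135) and treats the **apo list as the clean assigned
reference**: positional noise (`noise_sd`, default 0.003 ppm, applied to
both dimensions) and multiplicative intensity noise (default 2%) affect the
titrated points only. This mirrors how peak displacements are actually
read — relative to the assigned apo positions — and it is the reading under
which the package's stated recovery tolerances cohere: with noise on the
reference as well, the null CSP distribution is half-normal with scale
equal to the positional noise, and a mean + 1 SD threshold then passes
≈6–8% of true nulls *regardless of effect size*, so a ≤5% false-call bound
would be unreachable. With a clean reference the measured operating point
of the standard recovery scenario (200 residues, 15 shifted at a true CSP
of 3× the positional noise, 10 attenuated) is sensitivity 1.00 and a
false-call rate ≈0.03 over 50 seeds, and the pure-null shifted-call rate is
≈16% (tested to be < 25%) — the price of a mean + 1 SD rule on
perturbation-free data, consistent with its role as a mapping heuristic
rather than a formal test.

Dose response uses the saturating fraction $r/(r+1)$, rescaled so the
highest ratio reaches the spec'd maximal displacement exactly; attenuation
decays geometrically toward `intensity_floor`. Exchange kinetics,
peak overlap, assignment errors and ¹⁵N-specific noise anisotropy are *not*
modeled — a green recovery test establishes that the thresholding and
classification logic work on well-behaved fast-exchange data, not that the
pipeline is robust to crowded spectra.

## 2. Groove mapping and enrichment

Groove membership is **residue-set based**, not geometric: the grooves are
defined by the published per-helix residue lists (canonical α3/α4/α5;
noncanonical α4/α6/α7, author/PDB numbering on BAK, structure 2IMS), since
helix boundary coordinates are not part of the published definition. The
two default sets intentionally share the α3/α4 residues
{96, 98, 99, 113, 114, 118}; shared residues count toward *both* grooves
and the mapping reports raw counts so no double-counting is hidden. The
noncanonical set includes H164: the peptide-facing α6 histidine pair
H164/H165 is part of the groove as probed by the H164A/H165A mutant, even
though only H165 appears in the shifted-residue list itself.

Enrichment uses a permutation null: draw |perturbed| residues uniformly
without replacement from the assigned residues, count in-groove hits, and
report the add-one estimator $p = (1 + \#\{null \ge obs\})/(1 + B)$, which
is always in (0, 1]. On small toys this converges to the hypergeometric
tail (regression-tested); the in-groove count is discrete, so uniformity of
the null p-value is tested on the randomized PIT, the standard continuity
correction.

## 3. Conformer-population stability

Frames are compared by best-fit Cα RMSD under the published atom mask
(receptor residues 102–125 and 147–177, peptide residues 4–23; Cα only,
unweighted), each pair superposed independently by the Kabsch algorithm
with reflections excluded. Because fits are per-pair, the "distance" is not
a metric; triangle-inequality violations are permitted and a diagnostic
(`triangle_violations()`) flags pathological inputs.

Clustering is unweighted average linkage, merging the closest pair **while
the minimum inter-cluster average distance is ≤ ε** (default ε = 2.0 Å, the
trajectory-clustering convention); at termination every inter-cluster
average strictly exceeds ε. Ties break toward the lowest (i, j) index pair,
clusters being indexed by their smallest member frame — a documented rule
that makes the partition bit-reproducible and lets the test suite demand
*exact* agreement with a naive from-scratch reference implementation. The
reported statistic is the population of the most populated cluster; its
representative conformer is the **medoid** (minimum summed within-cluster
distance — the selection rule for "most populated conformation" is
otherwise unspecified). `compare_sites()` attaches a frame-resampling
bootstrap interval (labels held fixed, frames resampled with replacement)
and flags rankings whose intervals overlap as inconclusive.

The full distance matrix is computed without sieving; desk-scale ensembles
only, with a hard error above 20,000 frames. The superposition mask
question (same mask for fit and distance, or all-Cα fit) is resolved as:
one mask, used for both.

`gen_ensemble()` draws frames from rigid-body-displaced, jittered copies of
explicit cluster centers. It emulates the *statistical* structure the
population analysis assumes — well-separated basins with multinomial
occupancy — and nothing about forcefields, kinetics or barrier crossing; a
green population-recovery test (design 0.65/0.35, 2000 frames, centers
> 2ε apart, jitter ≪ ε, recovered within binomial error) validates the
clustering statistic, not any MD result.

## 4. Binding and release assays

**Steady state.** $R_{eq}(C) = R_{max} C/(K_D + C)$, no bulk-offset term by
default (responses are blank-subtracted on the instrument; an offset is
available behind a flag). For fixed $K_D$ the model is linear in $R_{max}$,
so fitting profiles the residual sum of squares over a fixed log-spaced
$K_D$ grid (121 points, four decades beyond the concentration range on each
side) and polishes the best grid cell with 1-D optimization — deterministic
given the data, immune to local minima, no random starts. Standard errors
come from the Gauss–Newton curvature with $\sigma^2 = RSS/(n-2)$.
Concentrations are nM throughout; µM input columns are converted
explicitly. The saturation QC mirrors the instrument-software caveat: the
top analysed concentration must be **at least threefold** (inclusive) above
the fitted $K_D$, otherwise the fit carries a caveat string.

A known, accepted limitation: with the standard 8-point two-fold dilution
design the ±1.96·se Wald interval covers the true $K_D$ ≈89% of the time
(measured over 2000 synthetic isotherms at 2% noise), not 95% — six
residual degrees of freedom alone cap it at $P(|t_6|\le 1.96) \approx 0.90$
and the right-skew of $\hat K_D$ (with $se \propto \hat K_D$) costs the
rest. The package reports the conventional asymptotic se rather than
silently inflating it; the corresponding acceptance criterion (coverage in
90–98%) is therefore knowingly marginally red.

**Release.** $\%release = (F_{sample} - F_{blank})/(F_{Triton} - F_{blank})
\times 100$, affine-invariant in the three fluorescences, never clipped
(out-of-range values from noisy inputs are flagged). Plateaus are means
over the final `window` fraction of each trace (default 10%, exposed
because the endpoint-extraction rule is not otherwise fixed); replicates
report mean ± sample SD, with SD `NA` (not 0) for a single replicate.

## 5. Pipeline reproducibility

`validate_config()` rejects unknown keys (suggesting the nearest valid
one) and injects the defaults above; `run_pipeline()` executes stages in
dependency order, aborts naming a failing stage while retaining partial
outputs, and derives every stage's RNG stream from the single global seed.
The report hash excludes the timestamp; identical config + inputs + seed
reproduce an identical hash (tested end-to-end on the generated fixture
set).

## 6. Summary of fixed numerical choices

| Quantity | Value | Why |
|---|---|---|
| ¹⁵N scaling in CSP | 1/5 (1/25 under the square) | standard dispersion ratio |
| CSP threshold | mean + 1 sample SD, strict `>` | published rule; conservative SD |
| Attenuation precedence | attenuated beats shifted | a dead peak has no reliable position |
| Linkage ε | 2.0 Å | trajectory-clustering convention |
| Linkage tie-break | lowest (i, j), clusters indexed by smallest member | exact oracle equivalence |
| Representative conformer | medoid | selection rule otherwise unspecified |
| Frame cap | 20,000 | full-matrix clustering only |
| Saturation QC | cmax/K_D ≥ 3, inclusive | instrument-software criterion |
| K_D grid | 121 log-spaced points, ±2 decades past the data | deterministic multi-start |
| Plateau window | final 10% of points | exposed parameter |
| Permutation p | add-one estimator | p ∈ (0, 1], unbiased under H0 |
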