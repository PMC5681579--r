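---
title: "Mapping odor-evoked antennal activity with current source density analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping odor-evoked antennal activity with current source density analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactomap)
```

## The problem

An electroantennogram (EAG) sums the field potentials generated by
olfactory receptor neurons (ORNs) across the insect antenna. Because
different odorants activate ORNs housed in different regions of the
funiculus (the third antennal segment), an EAG recorded at a single site
is biased toward the selectivity of the nearest neurons. Recording the
EAG consecutively at several proximo-distal positions and inverting a
physical model of how surface currents generate potentials turns the
same preparation into a spatial mapping tool: the estimated current
source density (CSD) localizes which part of the antenna an odorant
activates.

`olfactomap` implements this inverse model together with its companions:
quantification of EAG amplitudes, kernel density maps and dominance
profiles of sensilla annotated from scanning electron microscopy (SEM),
and between-species comparison statistics. A synthetic-data generator
with known ground truth exercises every stage, so the whole pipeline is
testable without any recordings.

## The forward model and its inversion

A point current source $I_c$ in a medium of conductivity $\sigma$
produces a potential $\varphi = I_c / (4\pi\sigma r)$ at distance $r$.
ORN currents arise at the funiculus surface (the signal collapses as
soon as the electrode breaks the cuticle), so the model works on the
virtually unfolded 2D surface. Each of the $N$ electrode positions
$x_j$ is surrounded by a rectangular compartment of constant source
density $C_i$; the potential that compartment $i$ contributes at
electrode $j$ is

$$
F_{ij} \, C_i, \qquad
F_{ij} = \frac{1}{4\pi\sigma} \int_{-q}^{q} \int_{x_{lo,i}}^{x_{hi,i}}
  \frac{dx\,dy}{\sqrt{(x - x_j)^2 + y^2}},
$$

where $q$ is half the circumference of the elliptical cross-section
(estimated with Ramanujan's approximation
$\pi(3(a+b) - \sqrt{(3a+b)(a+3b)})$ from the measured funiculus width
and thickness) and the compartments tile the funiculus length with
spacing $h$ equal to the electrode spacing. The two end compartments are
half-width: essentially no olfactory sensilla lie proximal to the
arista, and nothing lies beyond the tip. Measured potentials
$\phi_j = \sum_i F_{ij} C_i$ then yield the sources by solving the
square linear system, sample by sample; response **areas** integrate
each compartment's source over the 1.5 s after stimulus onset
(sign-flipped so the canonical negative-going response gives positive
activation), and the **spatial barycenter** is the activation-weighted
mean electrode position.

Numerical choices worth knowing:

- $F_{ij}$ is evaluated in closed form with the rectangle antiderivative
  $u\ln(v + r) + v\ln(u + r)$ at the corners. The improper integral with
  the electrode inside the source compartment is finite and handled by
  the same expression; a numerically stable branch avoids catastrophic
  cancellation when $\ln(s + r)$ has $s < 0$. Tests compare every entry
  against an independent 1D-analytic + adaptive-quadrature oracle.
- The system is square ($N = 4$ compartments for 4 electrodes) and well
  conditioned (condition numbers of order 10 for realistic geometries);
  no regularization is used, and the inversion refuses to run if the
  condition number reaches $10^8$.
- $\sigma$ only scales the source units. Barycenters and area ratios are
  invariant to it, so its absolute calibration is irrelevant for
  mapping; the default (10) follows the conventional setting.
- The prose definition of $q$ (half-circumference) together with
  integration bounds $[-q, q]$ means the unfolded rectangle spans the
  full circumference. We keep the printed bounds; only relative
  magnitudes of $F$ change under the alternative reading, not
  barycenters.
- Response areas use the trapezoidal rule on the recording's own time
  base; barycenter weights are the positive parts of the areas, so net
  suppression never pulls the barycenter.

## EAG preprocessing and amplitudes

Traces (500 Hz, one per electrode position) are smoothed with a
zero-phase unit-area Gaussian kernel and control (solvent) responses are
subtracted; when a control was run both before and after the odor
series, the two are averaged. "20 ms width" is interpreted as the kernel
standard deviation, truncated at $\pm 4\sigma$ (the full-width
alternative is available through the `width_s` parameter). Edges are
reflect-padded so the baseline window is not distorted. The signed
amplitude is the post-stimulus minimum (0.5 s window) minus the
pre-stimulus mean (0.5 s window), which makes it invariant to DC
offsets; the antenna-level **absolute response amplitude** is the
largest magnitude across positions, and per-individual odor panels are
normalized to sum to 1 before comparative analyses.

## Sensilla maps

SEM annotations (normalized $x$ = proximo-distal, $y$ = ventro-dorsal
positions plus a morphotype label) become per-morphotype density fields
by summing unit-mass 2D Gaussian kernels (SD 2% of length, 5% of width,
truncated at $4\sigma$, clipped at the face boundary without
renormalization) on a 200 × 100 lattice. The **dominance index**
$(D_b + D_c - D_t)/(D_b + D_c + D_t)$ contrasts basiconic + clavate
against trichoid density along the proximo-distal axis; $D$'s are
y-averaged at each x bin, bins with zero total density are reported as
undefined (`NA`) rather than 0. The index is scale-invariant at fixed
$x$, so averaging versus summing over $y$ does not affect it. Profiles
are resolution-stable (tested: < 1% change between 200 and 400 x-bins).
Count summaries report per-individual and aggregated counts, the pooled
basiconic + clavate count (the two types are easily confused under SEM),
totals, and the (b+c)/trichoid ratio — both as the mean of
per-individual ratios and as the ratio of mean counts, which differ in
general. Densities per mm² require a user-supplied lateral-face area;
all count-based outputs work without one.

## Comparative statistics

Per-individual feature vectors (CSD barycenters per odorant, or
panel-normalized absolute amplitudes) are compared between species with
the **distance ratio**: mean Euclidean distance between groups divided
by the mean within-group distance, within-group pairs pooled over both
groups. A ratio of 1 means species are no more different than
individuals.

The bootstrap test against 1 required a design decision, because the
resampling unit determines calibration. Resampling *individuals* with
replacement duplicates some of them, and duplicated pairs contribute
zero within-group distances: every replicate ratio is inflated by
roughly $1/(1 - 1/n)$ and the null rejection rate explodes (about 95%
at $\alpha = 0.05$ in simulation with $n = 10$ per group). Excluding
duplicate pairs over-corrects (about 1%). The package therefore
bootstraps the *distance sets* — the between-group distances and the
pooled within-group distances are resampled with replacement and the
ratio of their means recomputed — which is approximately calibrated
(3–5% null rejection at $\alpha = 0.05$ over 1000 simulated null
pairs; recomputed by the acceptance suite). The p-value is one-sided
with add-one correction,
$p = (1 + \#\{\text{ratio}^* \le 1\})/(n_{boot} + 1)$, with 10,000
replicates by default, and is bit-reproducible given a seed. The
individual-resampling variant (duplicate pairs excluded, conservative)
remains available via `unit = "individuals"`. Pairwise species matrices
report raw p-values; no multiple-testing correction is applied.

Discriminant projections solve the between/within scatter generalized
eigenproblem (ridge $\varepsilon \cdot \mathrm{mean\,diag}(S_w)$ engages
when features exceed residual degrees of freedom); dominance-profile
PCA is a mean-centred `prcomp` with explained-variance fractions.

## The synthetic-data generator

`simulate_recording()` builds electrode potentials through the same
forward matrix from a compartmental source vector, so inversion tests
are honest round trips. Defaults emulate the study conditions: 4
electrode positions at $\{0, 1/3, 2/3, 1\}$, 500 Hz sampling, 200-ms
stimulus, 10 individuals per species cohort, 7-odorant panels. Where no
value is dictated by the experimental design, plausibility choices were
made once and are labelled as such: the temporal kernel is a
difference of exponentials with $\tau_{rise} = 50$ ms and
$\tau_{decay} = 400$ ms (responses decay substantially within the 1.5-s
integration window), noise is additive white Gaussian (mV), source
bumps are Gaussians on the normalized axis with total magnitude
normalized, and inter-individual variability is a small jitter of
source centres (SD 0.02) and amplitudes (SD 10%). Example geometry
dimensions shipped in `extdata` are synthetic plausibility values, not
measurements. `simulate_sensilla()` draws inhomogeneous Poisson point
patterns by thinning with default intensities emulating the observed
gradients: trichoid density zero proximal to $x = 0.15$ then increasing
disto-dorsally, clavate clustered ventro-proximally, basiconic broad
with depressed borders, coeloconic uniform.

What passing tests show — and what they do not: synthetic EAGs are
generated by the same physical model the inversion assumes, with white
noise and no drift, no breathing artefacts, no electrode-position
error, and no adaptation between consecutive stimulations. Recovery
performance on them (e.g. barycenter RMSE ≈ 0.01 normalized units at
SNR 10 over 100 individuals) is therefore an upper bound on what real
recordings can achieve, and validates the numerics, not the biology.

## Problem sizes and determinism

The validation suite uses problem sizes chosen to probe each claim
meaningfully: 1000 random source vectors for the forward/inverse round
trip, 20 random geometries (all 16 entries each) against the quadrature
oracle, 100 simulated individuals for the SNR-10 recovery RMSE, 100
noiseless cases for the sharpness contract, and 1000 simulated
same-distribution species pairs with 2000 bootstrap replicates each for
null calibration. All stochastic steps take explicit integer seeds, and
identical seeds reproduce trace files byte-for-byte.

## Worked example

```{r example, eval = FALSE}
geom <- read_geometry(system.file("extdata", "example_geometry.yaml",
                                  package = "olfactomap"))

# simulate one individual responding to an odorant activating x ~ 2/3
sim <- simulate_recording(sim_config(geom, center_norm = 2/3,
                                     noise_sd_mv = 0.01), seed = 1)
res <- csd_analyze(sim$recording, geom)
glance(res)       # barycenter ~ 0.66
tidy(res)         # per-compartment response areas
autoplot(res)

# two-species comparison on CSD barycenters across a 3-odorant panel
cfg_a <- sim_config(geom, center_norm = c(0.2, 0.5, 0.8),
                    noise_sd_mv = 0.01, n_individuals = 10,
                    species = "speciesA")
cfg_b <- sim_config(geom, center_norm = c(0.35, 0.65, 0.95),
                    noise_sd_mv = 0.01, n_individuals = 10,
                    species = "speciesB")
cohort <- simulate_cohort(cfg_a, cfg_b, seed = 2)
bootstrap_ratio_test(cohort$features, n_boot = 10000, seed = 3)
autoplot(lda_projection(cohort$features))
```

## Known limitations

- The conductor model is 2D (unfolded surface) with planar Euclidean
  distances; circumferential wrap-around and any interior conduction
  are ignored.
- The system is square by construction; arbitrary electrode counts work,
  but non-square (more compartments than electrodes) layouts and
  regularized inversions are out of scope.
- $\sigma$ is a single opaque scalar; no attempt is made to estimate it
  from data, and source units are therefore relative.
- The sensilla density maps do not correct for the known undercounting
  of coeloconic sensilla, which is a property of the annotation, not of
  the mapping.
- The bootstrap test's calibration was established by simulation under
  Gaussian nulls; heavy-tailed feature distributions may shift it.
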