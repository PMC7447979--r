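---
title: "Models and methods behind meiodecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiodecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodecon)
```

This vignette documents the models the package implements, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The deconvolution model

ssDNA ChIP coverage is recorded relative to hotspot centres (PRDM9 motif
midpoints), but the quantity of mechanistic interest is binding relative
to the DSB itself. Writing `s_l` for the SPO11-oligo count in 20-bp bin
`l` from the centre (bin `l` covers `[20(l-1/2), 20(l+1/2))`) and `b_k`
for the binding mass `20k` bp from the break, the expected Crick coverage
is the convolution

$$c_j \;=\; \sum_k s_{j-k}\, b_k,$$

because total binding at a given distance from the centre sums
contributions over all possible break positions. `deconvolve()` assembles
the Toeplitz matrix `t[j,k] = s[j-k]` over `k ∈ {-50,…,125}` (−1000 to
+2500 bp; binding is assumed zero outside) and solves the overdetermined
system by least squares via a Moore–Penrose pseudoinverse. Overfitting is
controlled by discarding singular values below `tol` times the largest
(`tol = 0.2` by default, matching `MASS::ginv`'s definition of its `tol`
argument). Strand polarity: positive `k` points along the 3′ ssDNA
overhang, so Watson-strand coverage is reflected (`x → −x`) before
solving; the two strand solutions are reported separately plus their
average. Strands are solved separately rather than jointly because the
per-strand curves are themselves of interest (their agreement on
mirror-symmetric input is a package invariant, and an exact identity in
the tests).

Background is estimated per strand as the mean coverage 4000–5000 bp on
the side *away* from the signal (left flank for Crick, right for Watson)
and subtracted, with negative values clamped to zero. The same flank
convention is used by the intensity estimator.

Numerical notes:

- The raw solution can carry small negative excursions (a regularisation
  artifact); they are kept in `b_crick`/`b_watson` but clamped to zero by
  `clamp_profile()` and inside `profile_stats()`.
- `profile_stats()` reports the peak as the midpoint of the maximum bin,
  ties broken towards the smallest `|bp|`; the median and central-95%
  bounds are interpolated treating each bin's mass as uniform over the
  bin. Under this bin convention a unit mass in bin `k = 4` has peak and
  median 80 bp, and uniform mass on `k ∈ {0..9}` has median 90 bp (the
  bin edges sit at 20k − 10, not at 20k).
- With the default regularisation and a DSB-offset spread of sd 150 bp,
  the truncated-SVD solve acts as a mild low-pass filter. Profiles with a
  sharp peak right next to a heavy one-sided shoulder (the DMC1 shape)
  have their recovered mode displaced by one 20-bp bin towards the
  shoulder; symmetric or broad profiles (RAD51, template RPA) recover
  without bias. The test suite pins this behaviour.

## Default binding kernels

The generator needs "true" binding profiles to convolve. Only two robust
summaries per protein are well established: DMC1 peaks 80 bp from the
break with median 420 bp; RAD51 peaks at 860 bp with median 800 bp; and
the repair-template RPA signal holds its central 95% of mass between
−560 and +740 bp. The default kernels are therefore *calibrated*, not
copied: a parametric shape is adjusted numerically until its binned
statistics hit those values exactly.

A single gamma shape cannot serve here: no gamma has mode > median (RAD51
needs 860 > 800), and a gamma with mode 80 / median 420 is nearly flat
from 50 to 400 bp, leaving the binned argmax undefined in practice. The
default family is instead a mixture of a narrow Gaussian cap at the mode
(weight 0.25; sd 50 bp for DMC1, 150 bp for RAD51) and a split-normal
body glued at the mode. The body width on the side *away* from the median
is fixed (100 bp for DMC1, 450 bp for RAD51 — the rise from the break and
the decay towards the dsDNA junction), and the width on the median side
is solved by root finding so the binned median lands on target; the cap
pins the argmax bin. The template-RPA kernel is a Gaussian whose two
parameters are solved so the binned 2.5%/97.5% quantiles equal −560 and
+740 bp (it straddles the break, as a displaced D-loop strand must). All
kernels live on the 20-bp grid over −1000…+2500 bp with unit area.

## What the generator emulates — and what it does not

`simulate_hotspots()` places motif centres ≥ 8 kb apart (the inclusion
rule used for skew analysis), assigns PRDM9 alleles, homolog fractions
`f` (a configurable share of hotspots is forced into the asymmetric
classes `f ≥ 0.9` / `f ≤ 0.1`), hotspot heats (SPO11-oligo counts) and
skew status. `simulate_coverage()` draws per-bin Poisson reads around the
expected profile — depth × (empirical per-hotspot DSB-offset distribution
∗ kernel) — with Watson as the mirror of Crick; hotspots with more oligos
get proportionally more reads so the aggregate stays exactly proportional
to the aggregate SPO11 distribution convolved with the kernel. Skewed
hotspots have one side's strand signal multiplied up and the other down,
conserving the total (the study describes the phenomenon, not a
generative mechanism, so the simplest mass-preserving distortion is
used). `simulate_outcomes()` resolves a Poisson number of DSBs per
hotspot as crossovers with a probability rising linearly towards the
telomere (mean `co_base_rate = 0.10`, end-to-end fold `co_gradient = 3`),
draws gamma-length conversion tracts anchored at the DSB, and censors
them by a Poisson SNP grid: crossovers report the informative-SNP pair
flanking the breakpoint plus the internal grid, non-crossovers the
minimal converted segment. `simulate_foci()` anchors DMC1/RAD51 focus
pairs on polyline axes with half-normal perpendicular offsets (sd 178 and
89 nm, i.e. median axis distances ~120 and ~60 nm), a lateral within-pair
displacement, and uniform background foci.

Default study conditions: 20-bp bins; coverage window ±5 kb; DSB offsets
truncated-Gaussian sd 150 bp bounded at ±1 kb; 100 reads per hotspot per
strand; 20 SPO11 oligos per hotspot; `tol = 0.2`; skew threshold 150 bp;
asymmetry threshold 0.9; 300 nm co-focus radius; 100,000 bootstrap
iterations; 10% mean crossover resolution; lifespan ratio 2.6; SNP
spacing 150 bp (a dense hybrid grid); 40% of hotspots skewed and 18%
asymmetric. Validation experiments use 2,000 hotspots (1,000 at depth 50
for the noise-recovery property); the pipeline smoke tests use 30.

Deliberately *not* emulated: raw reads, alignment and the ssDNA (ITR)
identification chemistry; mappability structure; PRDM9 motif sequence;
per-bin noise beyond (optionally overdispersed) Poisson counts, since the
real per-bin noise law of SSDS coverage is not characterised — the
`overdispersion` knob exists precisely because that is an open question.
Passing tests therefore demonstrate correctness of the estimators under
the assumed statistical structure, not robustness to artefacts real data
may carry.

## Downstream estimators

**Mixture model.** `fit_mixture()` regresses the unit-area RPA profile on
the unit-area DMC1 and RAD51 profiles with an intercept; proportions are
`β/(β+γ)`. Area normalisation makes the proportions invariant to each
assay's overall scale, which is the point: only shapes are comparable
across ChIP experiments. The fit uses the Crick-polarity solutions by
default (either strand works; they are mirror images in expectation).
Negative fitted coefficients are reported with a warning and undefined
proportions; numerically-zero negatives (|coef| below 1e-8 of the
coefficient scale) are clamped. `fixed_mixture_fit()` re-fits with the
proportions pinned, for shape comparisons against alternatives such as
50/50.

**Skew.** The half-signal point `m` is, by default, the centre of the
first bin at which the running strand-summed total within ±5 kb reaches
half — a bin-resolution rule; `interpolate = TRUE` instead spreads each
bin's mass uniformly. The bin rule was chosen because it reproduces the
discrete worked examples that define the operation, and the 150-bp skew
threshold is 7.5 bins wide, so sub-bin precision is immaterial. Mirroring
swaps strands and reflects coordinates; it is an involution, and
mirroring coverage exactly swaps the two strand solutions of the
deconvolution (tested as an identity).

**Lifespans.** With `c_b` the absolute crossover probability per DSB in
bin `b` (after rescaling so the DSB-weighted mean is 10%) and `R_b` the
repair-template RPA per DSB, the model is
`R_b = (1 − sf)(c_b L_co + (1 − c_b) L_nco)` with `sf` the assumed
sister-repair share, solved by least squares. Two facts worth stating
plainly: (i) the ratio `L_co/L_nco` is invariant to the overall scale of
`R` *and* to a bin-uniform `sf`, since `(1 − sf)` multiplies both
lifespans — scenario analyses that vary `sf` can only move the ratio if
the data proxy changes too; (ii) over four bins with `c` in 0.04–0.16 the
design is nearly collinear, so a single 1%-multiplicative-noise draw
leaves the ratio with a sampling sd of ~6%. The reference experiment
therefore reports the mean recovered ratio over 100 noise replicates
(sd ~0.6%), which measures the estimator's accuracy rather than one
draw's luck; `n_replicates = 1` restores the single draw.

**Crossover regression.** Predictors are standardised (mean 0, variance
1) before fitting; perfectly collinear columns are dropped with a
warning. Stepwise selection is bidirectional from the full model under
AIC (`stats::step`). AIC's per-variable false-inclusion rate is
`P(χ²₁ > 2) ≈ 0.157`, so with eight predictors a pure-noise response
yields an intercept-only model only ~25% of the time — about one noise
predictor survives on average. The tests assert that calibrated
behaviour, not a stricter one.

**Tract maps.** Each crossover contributes unit mass split equally over
the inter-SNP intervals between its informative pair, uniform per bp
within each interval (the alternative reading — uniform per bp across the
whole censored region — is available via `equal_per_interval = FALSE`;
the two differ only when internal SNP spacing is uneven). Containment
assumes every tract overlaps its DSB, so a breakpoint at `d` covers all
positions between 0 and `d`; containment at the break equals total mass
by construction. This overlap assumption is a documented limitation: a
minority of tracts (for example those initiated at secondary DSB peaks)
may violate it. Non-crossovers get unit mass uniform over the minimal
converted segment, regardless of length or resolution, smoothed with a
100-bp moving average before deconvolution.

**Foci.** Pairing is per-focus nearest neighbour across channels (not
mutual-nearest, not optimal matching) with a 300-nm radius; fractions are
monotone in the radius by construction. The on/off-axis cutoff is not a
fixed constant of the field, so it is a parameter (450 nm for the
uniformity analysis); distances of uniformly scattered points to a line
are uniform, which is what the KS test checks beyond the cutoff.

## Degenerate inputs and tie-breaks

Zero coverage deconvolves to zero (not an error); zero-mass profiles are
errors for statistics that need mass. Zero-read hotspots give `f = NA`
and are excluded from asymmetry classes. Equal-maximum bins break ties
towards the break site. Bins with identical crossover rates make the
lifespan system singular (error). A single hotspot holding more than a
bin's share of signal triggers a warning in `equal_signal_bins()`.
Per-bin moving averages shrink their window at profile edges rather than
padding.

## Reproducibility

Every stochastic function takes a seed; `run_pipeline()` fans a single
global seed out to fixed per-stage seeds so stages remain individually
reproducible, stamps outputs into a manifest with a config digest, and
never mutates another stage's inputs. Identical seed and configuration
give bit-identical outputs, asserted end to end in the tests.
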