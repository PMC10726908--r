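---
title: "Multicomponent T2 relaxometry of white matter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent T2 relaxometry of white matter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In multiple sclerosis, conventional lesion counts and volumes correlate
only weakly with clinical disability (the "clinical-radiological
paradox"). Quantitative T2 relaxometry probes the *non-lesional* white
matter that conventional imaging calls normal: a multi-echo spin-echo
acquisition samples the transverse decay of each voxel, and the decay is
inverted into a distribution of T2 times — the T2 spectrum. In brain
tissue that spectrum is conventionally read as three water pools:

* **Myelin water (Mw)** — T2 below 40 ms, water trapped between myelin
  lamellae; its fraction (the MWF) is a myelin-integrity proxy.
* **Intra/extracellular water (IEw)** — T2 between 40 and 250 ms, the
  main tissue pool. Its amplitude-weighted geometric-mean T2 is reported
  as the T2-IEw map.
* **Free water (Fw)** — T2 above 250 ms, CSF-like water; in non-lesional
  WM an elevated Fw fraction is the biomarker of interest.

`t2pools` implements that pipeline end to end: EPG signal model,
regularized NNLS spectrum inversion with a fitted refocusing flip angle,
three-pool maps, lesion-aware mask construction, per-subject summaries,
and the cohort correlation battery — plus synthetic phantom and cohort
generators so every stage is testable without scanner data.

## Signal model

For a CPMG-like train whose refocusing pulses deviate from 180°, the
echo amplitudes are not mono-exponential: stimulated-echo pathways
redistribute signal between echoes. The extended phase graph (EPG)
recursion tracks magnetization configuration states $(F_k^+, F_k^-, Z_k)$
through the pulse train; each refocusing pulse of flip $\alpha$ mixes the
states with weights $\cos^2(\alpha/2)$, $\sin^2(\alpha/2)$ and
$\sin\alpha$, each half-interval relaxes transverse states by
$e^{-\tau/T_2}$ and longitudinal ones by $e^{-\tau/T_1}$, and the $k=0$
state magnitude at each echo time is the echo amplitude. Modeling
assumptions (all standard for this family of tools):

* ideal instantaneous rotations with perfect crushers; no slice-profile
  or B0/off-resonance effects;
* CPMG phase convention, so the recursion runs over real states;
* longitudinal recovery omitted (it does not feed echo amplitudes when
  the $k=0$ longitudinal state starts empty);
* state order exceeds the echo count, so no truncation error enters
  (verified against a dense complex-matrix implementation to 1e-12).

At $\alpha = 180°$ the recursion collapses to $e^{-n\,TE/T_2}$ exactly;
this closed form, the textbook second-echo rebound
($\sin^4(\alpha/2) + \tfrac12\sin^2\alpha$ at infinite T2), and the
dense-matrix oracle are the test anchors.

## Spectrum inversion

Each voxel's signal is modeled as $s = A(\alpha)\,x$, with $A$ the
n_echoes × n_grid EPG decay basis over a log-spaced T2 grid and
$x \ge 0$ the spectrum. The fit is two-stage, mirroring common practice:

1. **Flip angle.** $\hat\alpha$ minimizes the *unregularized* NNLS
   misfit over a coarse scan (8 angles across 90–180°) refined by
   golden-section search to 0.5°. It is then held fixed.
2. **Regularized spectrum.** Minimum-energy Tikhonov NNLS,
   $\min\|Ax-s\|^2 + \mu^2\|x\|^2,\ x\ge 0$, solved through the stacked
   system; $\mu$ is chosen by bisection on $\log\mu$ so that the misfit
   ratio $\chi^2(\mu)/\chi^2(0)$ lands in a configured window,
   default [1.02, 1.025] — the conventional criterion in this family of
   toolboxes (the source study names the toolbox but not its settings,
   so the window, the identity regularizer, the grid and the assumed T1
   are all exposed in `fit_config()`, `t2_grid()` and
   `sequence_params()`).

The NNLS core is a Lawson–Hanson active-set solver (C++); every solution
satisfies the KKT conditions and tests certify this against exhaustive
active-set enumeration on small problems.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| T2 grid | 40 log-spaced points, 8–2000 ms | spans beyond both pool boundaries so edge pools absorb signal; edge T2 *times* are not interpretable (echoes sample only 10–320 ms), which is why only Mw/Fw *fractions* are reported |
| assumed T1 | 1000 ms | conventional; at 180° fractions are provably T1-independent, and tests show <1% sensitivity over 600–2000 ms |
| chi-square window | [1.02, 1.025] | conventional regularization criterion; see bias note below |
| pool boundaries | 40 ms, 250 ms | the standard Mw / IEw / Fw windows; edge rule is Mw `[min, 40)`, IEw `[40, 250]`, Fw `(250, max]` — grid points rarely sit on a boundary and the bookkeeping is tested exactly |
| flip search range | [90, 180]° | refocusing deviations in brain GraSE stay well inside this |

### Numerical choices

* $\chi^2(\mu)$ is continuous and non-decreasing in $\mu$, so the
  log-$\mu$ bisection is well posed; a non-bracketable window after 100
  steps returns the nearest achievable ratio, flagged.
* Noiseless (essentially exact) fits short-circuit to $\mu = 0$: a 2%
  misfit inflation of a ~0 misfit is meaningless.
* All-zero voxels are flagged background, never fitted.
* Voxelwise SNR is sum(spectrum)/sd(residual), capped when the residual
  is exactly zero.
* Coarse flip-angle bases are precomputed once per volume and shared
  across voxels; results are identical to per-voxel recomputation
  because the basis depends only on the angle.

## Masks and summaries

The lesion mask is the lesion-probability volume thresholded strictly at
0.5 (ties excluded). Lesion voxels that keep the WM tissue label are
T1-iso-intense; those outside it are T1-hypo-intense (automated T1
segmentation does not label severely damaged tissue as WM), and the two
partition the lesion mask exactly. Non-lesional WM is the WM label minus
the lesion mask, eroded by one pixel to suppress partial-volume
boundary voxels. Erosion is 2-D slice-wise with a 3×3 square element by
default: relaxometry voxels are strongly anisotropic (1.64×1.64×2.5 mm),
so "one pixel" is an in-plane notion; 6-connected 3-D erosion is a
config option. Per subject, the median and mean of Mw, IEw, Fw and
T2-IEw over the non-lesional WM feed the cohort battery.

## The correlation battery

For each of the 8 WM parameters (median/mean × 4 metrics): Spearman
(tie-corrected midranks, two-sided t-approximation p, exact permutation
option for n ≤ 10) against EDSS — EDSS is ordinal with 0.5 steps, hence
rank-based — and Pearson against disease duration, age, and the T1
lesion load. "T1 lesion load" defaults to the T1-hypo sub-volume (the
damage-specific load), switchable to total lesion volume. The three
lesion volumes (total/iso/hypo) get Spearman-vs-EDSS rows. "Bivariate
analysis" is read as two-predictor OLS of EDSS on standardized lesion
load plus one WM parameter (the source does not name the model; OLS on
standardized predictors keeps coefficients comparable). No
multiple-testing correction by default, matching per-cell reporting; a
Benjamini–Hochberg column is available.

## What the generators emulate — and what they do not

**Phantom.** A WM slab with a CSF blob and spherical lesions (iso- and
hypo-flagged); per-region three-pool truth (WM 0.10/0.85/0.05 at
20/80/1000 ms — literature-conventional values, since the source study
measures rather than simulates); a smooth in-plane flip-angle field
spanning 150–180°; magnitude noise at a stated first-echo SNR (default
200, the comfortable clinical regime). Noise is additive Gaussian by
default — a valid high-SNR approximation — with exact Rician
(two-channel modulus) as an option. The lesion-probability volume is a
smooth bump whose supra-0.5 set equals the seeded ball exactly, so the
threshold stage is exercised nontrivially. Not emulated: anatomy,
partial-volume mixing beyond region boundaries, motion/ghosting, B1
effects beyond the flip-angle field. A green recovery test therefore
establishes correctness of the *inversion machinery*, not robustness to
real-scanner artifacts.

**Cohort.** Age uniform-ish over 20–62 (median ≈ 38), duration 2–30
coupled to age, EDSS ordinal on 1–4 via latent-Gaussian thresholding
(preserving the tie structure that makes tie-corrected Spearman
necessary), T1-hypo lesion volume log-normal and coupled to the latent
disability score. The subject-level median Fw loads on age and the
latent score; the default loadings were calibrated once (at n = 4×10^5)
so the population Spearman(median Fw, EDSS) ≈ 0.45 and
Pearson(median Fw, age) ≈ 0.6 — the association magnitudes the analysis
is meant to detect — and then frozen (constants `.k_age`, `.k_edss`).
The fast path draws summary statistics directly; the full path pushes
per-subject phantoms through the entire fitting pipeline and converges
to the fast path as SNR grows.

## Known limitations

* **Regularization bias.** Minimum-energy Tikhonov at the
  [1.02, 1.025] misfit window systematically smooths the spectrum:
  on the standard phantom at first-echo SNR 200 the Mw fraction is
  biased about −0.02 and Fw about −0.018 (IEw absorbs both), giving a
  median absolute Mw-window error of ≈0.025. A window sweep shows no
  setting of the criterion reaches median error ≤0.02 at this SNR, so
  the corresponding recovery bound in the acceptance suite fails
  honestly and deliberately. Cross-subject *comparisons* are unaffected
  to first order (the bias is common mode), which is what the
  correlation battery consumes.
* **SNR map scale.** The Figure-of-merit SNR (sum of spectrum / residual
  sd) references the extrapolated t = 0 signal, so it runs ≈1.3× the
  generator's first-echo SNR in WM; the map is a relative quality
  indicator, not an estimate of the generator parameter.
* Magnitude data are fitted directly with no Rician bias correction —
  adequate at SNR ≳ 100, increasingly biased below.
* No spatial regularization or joint multi-voxel fitting; no
  gradient-echo (EPI-factor) modeling of the GraSE readout.
* The pipeline consumes already-aligned label/probability volumes;
  registration and the upstream tissue/lesion segmentation algorithms
  are out of scope.
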