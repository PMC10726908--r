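# t2pools

Multicomponent T2 relaxometry of brain white matter, with stimulated-echo
correction, for R.

## What it does, and for whom

In multiple sclerosis, lesion volumes on conventional MRI correlate only
weakly with disability — the clinical–radiological paradox. One way
around it is to interrogate the *non-lesional* white matter (WM) with
quantitative T2 relaxometry: a multi-echo spin-echo acquisition samples
each voxel's transverse decay, and inverting that decay yields a T2
*spectrum* that separates three water pools,

- **Mw** — myelin water, T2 < 40 ms (the myelin water fraction, MWF),
- **IEw** — intra/extracellular water, 40 ≤ T2 ≤ 250 ms, with its
  amplitude-weighted geometric-mean T2 (the T2-IEw map),
- **Fw** — free/CSF-like water, T2 > 250 ms.

`t2pools` is for imaging scientists who want that pipeline as tested,
scriptable R: signal model → voxelwise inversion → quantitative maps →
lesion-aware masks → per-subject summaries → cohort statistics, plus
synthetic phantoms and cohorts so everything runs and is verifiable with
no scanner data.

## The model in brief

Voxel signal: `s = A(α) x`, `x ≥ 0`, where column *j* of `A` holds the
echo amplitudes of a single-T2 species computed by the **extended phase
graph (EPG)** recursion at refocusing flip angle α — at α = 180° this is
`exp(-n·TE/T2)` exactly; below 180° stimulated echoes redistribute
signal, which is why α is *fitted* per voxel (coarse scan + golden
section on the unregularized misfit) rather than assumed. The spectrum
solves the minimum-energy Tikhonov NNLS problem

    min ‖A x − s‖² + μ²‖x‖²,  x ≥ 0,

with μ chosen so the misfit ratio χ²(μ)/χ²(0) lies in [1.02, 1.025]
(Lawson–Hanson active-set solver in C++). Fractions are the window
masses normalized so Mw + IEw + Fw = 1 per voxel. Cohort statistics:
Spearman (tie-corrected) against the ordinal EDSS disability score,
Pearson against disease duration, age and T1-hypo-intense lesion load,
and two-predictor OLS of EDSS on lesion load plus each WM parameter.
Details, assumptions and limitations: `vignettes/multicomponent-t2.Rmd`.

## Worked example

```r
library(t2pools)

# a small synthetic subject: 14 x 14 x 4 voxels, first-echo SNR 200
spec <- phantom_spec(
  shape = c(14L, 14L, 4L),
  wm_box = list(x = 2:13, y = 2:13, z = 1:4),
  csf_box = list(x = 10:12, y = 10:12, z = 2:3),
  lesions = list(list(center = c(5, 5, 2), radius = 1, t1_hypo = TRUE)),
  snr = 200, seed = 1L)
phantom <- generate_phantom(spec)

masks <- mask_set(phantom$tissue_labels, phantom$lesion_prob)
lesion_report(masks)

fit  <- fit_volume(phantom$echoes, masks$nonlesional_wm,
                   sequence_params(), t2_grid())
maps <- assemble_maps(fit)
summarize_subject(maps, masks$nonlesional_wm)

# a synthetic 20-subject cohort and the correlation battery
cohort  <- generate_cohort(cohort_spec(n_subjects = 20L, seed = 1L))
battery <- correlation_battery(cohort$summaries)
print(battery)
```

Output (verbatim):

```
mask_set: 14x14x4 volume | WM 551 vox | lesion 7 (iso 0 / hypo 7) | non-lesional WM 329
  sub_volume n_voxels volume_mm3 percent
1      total        7     47.068     100
2     t1_iso        0      0.000       0
3    t1_hypo        7     47.068     100
compartment_maps: 14x14x4 volume, 329 non-background voxels
  median Mw 0.078 | IEw 0.891 | Fw 0.033 | T2-IEw 78.7 ms
correlation_battery: 35 correlation cells, 8 bivariate models (T1 load = hypo)
  p < 0.05:
    median_iew vs age: r = -0.46 (p = 0.042)
    mean_iew vs age: r = -0.47 (p = 0.035)
    median_fw vs duration: r = 0.45 (p = 0.044)
    median_fw vs age: r = 0.53 (p = 0.015)
    mean_fw vs duration: r = 0.48 (p = 0.033)
    mean_fw vs age: r = 0.48 (p = 0.034)
    lesion_total_mm3 vs edss: r = 0.46 (p = 0.040)
    lesion_t1_hypo_mm3 vs edss: r = 0.57 (p = 0.009)
```

What it means: the 7-voxel seeded lesion is recovered entirely as
T1-hypo-intense (47.1 mm³ at the 1.64×1.64×2.5 mm voxel size); the
fitted WM medians sit near the phantom truth (0.10/0.85/0.05 at
T2-IEw 80 ms) up to the documented regularization bias (Mw and Fw pulled
down ~0.02, IEw absorbing it); and in the synthetic 20-subject cohort
the battery flags free water against age/duration and the T1-hypo lesion
load against EDSS — the association structure the generator is
calibrated to carry (population Spearman(median Fw, EDSS) ≈ 0.45,
Pearson(median Fw, age) ≈ 0.6; at n = 20 the per-sample values scatter
widely — this draw gives 0.23 and 0.53 — which is itself a faithful
picture of how noisy 20-subject correlation studies are).

NIfTI volumes and a command-line interface are available for scripted
use:

```sh
Rscript inst/cli/t2pools simulate-phantom --seed 1 --out sim/
Rscript inst/cli/t2pools mask --labels sim/labels.nii.gz \
    --lesion-prob sim/lesion_prob.nii.gz --out masks/
Rscript inst/cli/t2pools fit --echoes sim/echoes.nii.gz \
    --mask masks/nonlesional_wm.nii.gz --out maps/
Rscript inst/cli/t2pools correlate --table summaries.csv --out stats/
```

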