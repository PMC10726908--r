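#' Phantom specification
#'
#' Describes a synthetic multi-echo phantom: a WM slab containing a CSF
#' blob and focal lesions, per-region three-pool truth (fractions and T2
#' times), a smooth spatial refocusing-flip-angle deviation field, and a
#' first-echo signal-to-noise ratio. Defaults: 32 x 32 x 8 voxels, WM truth
#' Mw 0.10 @ 20 ms / IEw 0.85 @ 80 ms / Fw 0.05 @ 1000 ms, CSF
#' free-water-dominated, lesions with elevated free water, flip-angle field
#' spanning 150-180 degrees, SNR 200.
#'
#' @param shape Volume shape in voxels.
#' @param wm_box,csf_box Inclusive index ranges `list(x=, y=, z=)` of the WM
#'   slab and the CSF blob (CSF is carved out of the slab).
#' @param lesions List of lesions, each `list(center=, radius=, t1_hypo=)`;
#'   lesion balls must fall inside the WM slab.
#' @param pools Named list (`wm`, `csf`, `lesion`) of
#'   `list(frac = c(mw, iew, fw), t2 = c(...))`; fractions must sum to 1.
#' @param flip_range Range of the smooth flip-angle field, degrees.
#' @param snr First-echo SNR in WM (noise sd = mean WM first-echo signal /
#'   snr); `Inf` disables noise.
#' @param noise `"gaussian"` (additive, high-SNR approximation) or
#'   `"rician"` (modulus of a complex Gaussian).
#' @param params `sequence_params` for signal synthesis.
#' @param voxel_size Voxel edge lengths in mm.
#' @param seed Integer RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 8L),
                         wm_box = list(x = 5:28, y = 5:28, z = 2:7),
                         csf_box = list(x = 22:27, y = 22:27, z = 3:6),
                         lesions = list(
                           list(center = c(10, 10, 4), radius = 2,
                                t1_hypo = FALSE),
                           list(center = c(16, 17, 5), radius = 2,
                                t1_hypo = TRUE)),
                         pools = list(
                           wm = list(frac = c(0.10, 0.85, 0.05),
                                     t2 = c(20, 80, 1000)),
                           csf = list(frac = c(0, 0.05, 0.95),
                                      t2 = c(20, 80, 1500)),
                           lesion = list(frac = c(0.06, 0.70, 0.24),
                                         t2 = c(20, 90, 1000))),
                         flip_range = c(150, 180), snr = 200,
                         noise = c("gaussian", "rician"),
                         params = sequence_params(),
                         voxel_size = c(1.64, 1.64, 2.5), seed = 1L) {
  noise <- match.arg(noise)
  for (p in names(pools)) {
    if (abs(sum(pools[[p]]$frac) - 1) > 1e-9)
      stop_param("pool fractions of region '", p, "' must sum to 1")
    if (any(pools[[p]]$t2 <= 0)) stop_param("pool T2 times must be > 0")
  }
  if (!is.finite(snr) && !is.infinite(snr) || snr <= 0)
    stop_param("snr must be > 0")
  for (les in lesions) {
    lo <- les$center - les$radius
    hi <- les$center + les$radius
    if (lo[1] < min(wm_box$x) || hi[1] > max(wm_box$x) ||
        lo[2] < min(wm_box$y) || hi[2] > max(wm_box$y) ||
        lo[3] < 1 || hi[3] > shape[3])
      stop_param("lesion ball must fall inside the WM slab")
  }
  structure(list(shape = as.integer(shape), wm_box = wm_box,
                 csf_box = csf_box, lesions = lesions, pools = pools,
                 flip_range = flip_range, snr = snr, noise = noise,
                 params = params, voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth in-plane flip-angle deviation field spanning spec$flip_range
flip_field <- function(spec) {
  d <- spec$shape
  x <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1)
  y <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1)
  z <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1)
  f <- array(0, d)
  for (k in seq_len(d[3])) {
    # smooth saddle: low angles at one corner, nominal at the other
    s <- outer(sin(pi * x), cos(pi * y / 2)) * (0.8 + 0.2 * z[k])
    f[, , k] <- spec$flip_range[1] +
      diff(spec$flip_range) * (1 - (s - min(s)) / (max(s) - min(s)))
  }
  f
}

#' Generate a synthetic multi-echo phantom
#'
#' Per-voxel signal is the three-pool mixture of EPG echo trains at the
#' voxel's flip angle; magnitude noise is added at the specified first-echo
#' SNR. Alongside the 4-D echo volume the generator returns the exact truth
#' used for synthesis (fraction maps, pool T2 maps, flip-angle field), an
#' integer tissue-label volume (0 background, 1 WM, 2 non-WM; T1-hypo
#' lesions are labeled non-WM, mimicking how automated T1 segmentation
#' treats them), and a smooth lesion-probability volume whose
#' supra-0.5 region matches the seeded lesion balls.
#'
#' @param spec A `phantom_spec`.
#' @return List of class `phantom` with `echoes` (4-D array), `truth`
#'   (list: `mw_frac`, `iew_frac`, `fw_frac`, `t2_iew`, `flip_deg`,
#'   `region`), `tissue_labels`, `lesion_prob`, `noise_sd`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_param("spec must be a phantom_spec")
  d <- spec$shape
  region <- array("bg", d)
  region[spec$wm_box$x, spec$wm_box$y, spec$wm_box$z] <- "wm"
  region[spec$csf_box$x, spec$csf_box$y, spec$csf_box$z] <- "csf"
  lesion_id <- array(0L, d)
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    cx <- les$center
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if ((x - cx[1])^2 + (y - cx[2])^2 + (z - cx[3])^2 <= les$radius^2 &&
          region[x, y, z] == "wm") {
        region[x, y, z] <- "lesion"
        lesion_id[x, y, z] <- li
      }
    }
  }
  flip <- flip_field(spec)
  truth <- list(mw_frac = array(NA_real_, d), iew_frac = array(NA_real_, d),
                fw_frac = array(NA_real_, d), t2_iew = array(NA_real_, d),
                flip_deg = flip, region = region)
  n_ech <- spec$params$n_echoes
  echoes <- array(0, c(d, n_ech))
  idx_tissue <- which(region != "bg")
  ijk <- arrayInd(idx_tissue, d)
  sig_mat <- matrix(0, length(idx_tissue), n_ech)
  for (v in seq_along(idx_tissue)) {
    reg <- region[idx_tissue[v]]
    pool <- spec$pools[[if (reg == "csf") "csf" else if (reg == "lesion")
      "lesion" else "wm"]]
    a <- flip[idx_tissue[v]]
    dec <- .epg_basis_cpp(pool$t2, a, n_ech, spec$params$echo_spacing,
                          spec$params$t1_assumed)
    sig_mat[v, ] <- as.numeric(dec %*% pool$frac)
    truth$mw_frac[idx_tissue[v]] <- pool$frac[1]
    truth$iew_frac[idx_tissue[v]] <- pool$frac[2]
    truth$fw_frac[idx_tissue[v]] <- pool$frac[3]
    truth$t2_iew[idx_tissue[v]] <- pool$t2[2]
  }
  # first-echo SNR referenced to mean WM signal
  wm_first <- sig_mat[region[idx_tissue] == "wm", 1]
  noise_sd <- if (is.infinite(spec$snr)) 0 else mean(wm_first) / spec$snr
  sig_mat <- with_seed(spec$seed, {
    if (noise_sd == 0) {
      sig_mat
    } else if (spec$noise == "gaussian") {
      out <- sig_mat + matrix(rnorm(length(sig_mat), sd = noise_sd),
                              nrow(sig_mat))
      pmax(out, 0)  # magnitude data stays non-negative
    } else {
      n1 <- matrix(rnorm(length(sig_mat), sd = noise_sd), nrow(sig_mat))
      n2 <- matrix(rnorm(length(sig_mat), sd = noise_sd), nrow(sig_mat))
      sqrt((sig_mat + n1)^2 + n2^2)
    }
  })
  for (e in seq_len(n_ech)) {
    vol <- array(0, d)
    vol[idx_tissue] <- sig_mat[, e]
    echoes[, , , e] <- vol
  }
  labels <- array(0L, d)
  labels[region == "wm"] <- 1L
  labels[region == "csf"] <- 2L
  for (li in seq_along(spec$lesions)) {
    sel <- lesion_id == li
    labels[sel] <- if (spec$lesions[[li]]$t1_hypo) 2L else 1L
  }
  # smooth probability bumps: > 0.5 exactly on the seeded lesion balls
  prob <- array(0, d)
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    cx <- les$center
    # half-height isoline between r^2 and the next integer squared
    # distance, so {prob > 0.5} is exactly the seeded ball
    w2 <- les$radius^2 + 0.5
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      d2 <- (x - cx[1])^2 + (y - cx[2])^2 + (z - cx[3])^2
      bump <- 0.95 * exp(-d2 / w2 * log(0.95 / 0.5))
      prob[x, y, z] <- max(prob[x, y, z], bump)
    }
  }
  structure(list(echoes = echoes, truth = truth, tissue_labels = labels,
                 lesion_prob = prob, noise_sd = noise_sd, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %s, %d echoes | WM %d vox, CSF %d, lesion %d | SNR %g (%s)\n",
    paste(x$spec$shape, collapse = "x"), x$spec$params$n_echoes,
    sum(x$truth$region == "wm"), sum(x$truth$region == "csf"),
    sum(x$truth$region == "lesion"), x$spec$snr, x$spec$noise))
  invisible(x)
}

# calibration constants for the cohort generator (fixed once, empirically,
# against the stated population targets; see the methods vignette):
# attenuation of Pearson(fw, age) by the rank-to-age warp, and of
# Spearman(fw, EDSS) by ordinal coarsening + the normal rank transform
.k_age <- 0.978
.k_edss <- 0.941

#' Cohort specification
#'
#' Statistical model for a synthetic patient cohort. Age spans 20-62 years
#' (median near 38), disease duration 2-30 years and positively coupled to
#' age, EDSS is ordinal on 1-4 in 0.5 steps drawn by thresholding a latent
#' Gaussian disability score, and the T1-hypo focal-lesion volume is
#' log-normal and coupled to the latent score. The per-subject median WM
#' free-water fraction is a linear combination of the (standardized) age
#' and latent scores plus noise; the default loadings are calibrated so the
#' population Spearman(median Fw, EDSS) is about `target_r_fw_edss` and
#' Pearson(median Fw, age) about `target_r_fw_age`.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param target_r_fw_edss Population Spearman between median Fw and EDSS.
#' @param target_r_fw_age Population Pearson between median Fw and age.
#' @param r_lesion_edss Loading of the latent disability score on the
#'   log T1-hypo lesion volume (0 = no association).
#' @param rho_age_latent Correlation between age and the latent disability
#'   score.
#' @param fw_baseline,fw_sd Location and scale of the median Fw fraction.
#' @param lesion_volume_median,lesion_volume_log_sd Log-normal parameters
#'   of the T1-hypo lesion volume, mm^3.
#' @param seed Integer RNG seed.
#' @return List of class `cohort_spec`. Infeasible targets (combined
#'   loadings exceeding unit variance) are rejected with an explanation.
#' @export
cohort_spec <- function(n_subjects = 20L, target_r_fw_edss = 0.45,
                        target_r_fw_age = 0.6, r_lesion_edss = 0.55,
                        rho_age_latent = 0.3, fw_baseline = 0.06,
                        fw_sd = 0.015, lesion_volume_median = 1500,
                        lesion_volume_log_sd = 0.5, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 3L) stop_param("need n_subjects >= 3")
  if (abs(target_r_fw_edss) >= 1 || abs(target_r_fw_age) >= 1)
    stop_param("correlation targets must lie in (-1, 1)")
  # invert the calibrated attenuations to latent-scale loadings
  w_age <- target_r_fw_age / .k_age
  r_lat <- target_r_fw_edss / .k_edss
  w_lat <- (r_lat - w_age * rho_age_latent) / sqrt(1 - rho_age_latent^2)
  if (w_age^2 + w_lat^2 > 1)
    stop_param("infeasible correlation targets: the implied loadings ",
               sprintf("(age %.2f, latent %.2f)", w_age, w_lat),
               " exceed unit variance; lower the targets")
  structure(list(n_subjects = n_subjects,
                 target_r_fw_edss = target_r_fw_edss,
                 target_r_fw_age = target_r_fw_age,
                 r_lesion_edss = r_lesion_edss,
                 rho_age_latent = rho_age_latent,
                 fw_baseline = fw_baseline, fw_sd = fw_sd,
                 lesion_volume_median = lesion_volume_median,
                 lesion_volume_log_sd = lesion_volume_log_sd,
                 w_age = w_age, w_lat = w_lat,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

round_half <- function(x) round(x * 2) / 2

#' Generate a synthetic cohort (fast path)
#'
#' Draws the clinical covariates and per-subject WM summary statistics
#' directly from the cohort model, without synthesizing or fitting any
#' image. The returned table has the exact column layout the correlation
#' battery consumes. For the full path (per-subject phantoms pushed through
#' the fitting pipeline) see [cohort_full_path()].
#'
#' @param spec A `cohort_spec`.
#' @return List of class `cohort` with `clinical` (subject_id, edss,
#'   duration_years, age_years), `summaries` (clinical plus lesion volumes
#'   and the 8 WM parameters), and `latent` internals (for calibration
#'   tests).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_param("spec must be a cohort_spec")
  n <- spec$n_subjects
  with_seed(spec$seed, {
    z_age <- rnorm(n)
    u <- rnorm(n)
    latent <- spec$rho_age_latent * z_age +
      sqrt(1 - spec$rho_age_latent^2) * u
    age <- 20 + 42 * stats::pnorm(z_age)^1.15
    v <- rnorm(n)
    duration <- 2 + 28 * stats::pnorm(0.55 * z_age +
                                        sqrt(1 - 0.55^2) * v)^1.1
    edss <- pmin(pmax(round_half(1 + 3 * stats::pnorm(latent)^1.6), 1), 4)
    g <- spec$r_lesion_edss
    hypo <- exp(log(spec$lesion_volume_median) +
                  spec$lesion_volume_log_sd *
                  (g * latent + sqrt(1 - g^2) * rnorm(n)))
    iso <- hypo * (48 / 52) * exp(rnorm(n, sd = 0.3))
    total <- hypo + iso
    w_e <- sqrt(1 - spec$w_age^2 - spec$w_lat^2)
    fw <- spec$fw_baseline + spec$fw_sd *
      (spec$w_age * z_age + spec$w_lat * u + w_e * rnorm(n))
    fw <- pmax(fw, 0.005)
    mw <- pmax(rnorm(n, 0.10, 0.008), 0.01)
    t2_iew <- rnorm(n, 85, 3)
    iew <- 1 - mw - fw
    summaries <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      edss = edss, duration_years = duration, age_years = age,
      lesion_total_mm3 = total, lesion_t1_iso_mm3 = iso,
      lesion_t1_hypo_mm3 = hypo,
      median_mw = mw, median_iew = iew, median_fw = fw,
      median_t2_iew = t2_iew,
      mean_mw = mw + rnorm(n, sd = 0.002),
      mean_iew = iew + rnorm(n, sd = 0.002),
      mean_fw = fw + rnorm(n, sd = 0.002),
      mean_t2_iew = t2_iew + rnorm(n, sd = 0.5),
      stringsAsFactors = FALSE)
    structure(list(
      clinical = summaries[, c("subject_id", "edss", "duration_years",
                               "age_years")],
      summaries = summaries,
      latent = list(z_age = z_age, latent = latent)),
      class = "cohort")
  })
}

#' Null cohort specification
#'
#' All effect sizes zero: free water, lesion volumes and EDSS are mutually
#' independent. Used for type-I-error calibration of the battery.
#'
#' @param n_subjects Number of subjects.
#' @param seed RNG seed.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(n_subjects = 200L, seed = 1L) {
  cohort_spec(n_subjects = n_subjects, target_r_fw_edss = 0,
              target_r_fw_age = 0, r_lesion_edss = 0,
              rho_age_latent = 0, seed = seed)
}

#' Full-path cohort: per-subject phantoms through the fitting pipeline
#'
#' For each subject of a fast-path cohort, synthesizes a small phantom
#' whose WM pool truth carries the subject's Mw/Fw/T2-IEw values, runs
#' spectrum fitting, builds the lesion-aware mask set, and summarizes the
#' non-lesional WM. As SNR grows the fitted summaries converge to the
#' fast-path values (up to grid-discretization tolerance).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param shape Phantom shape per subject (kept small: every voxel is fit).
#' @param snr First-echo SNR of the per-subject phantoms.
#' @param config `fit_config` used for fitting.
#' @param verbose Print one line per subject.
#' @return List of class `cohort` with fitted `summaries` (same layout) and
#'   `clinical`; lesion volumes are carried over from the fast path.
#' @export
cohort_full_path <- function(cohort, shape = c(14L, 14L, 4L), snr = 200,
                             config = fit_config(), verbose = FALSE) {
  fast <- cohort$summaries
  grid <- t2_grid()
  rows <- vector("list", nrow(fast))
  for (i in seq_len(nrow(fast))) {
    s <- fast[i, ]
    frac <- c(s$median_mw, 1 - s$median_mw - s$median_fw, s$median_fw)
    ps <- phantom_spec(
      shape = shape,
      wm_box = list(x = 2:(shape[1] - 1), y = 2:(shape[2] - 1),
                    z = 1:shape[3]),
      csf_box = list(x = (shape[1] - 3):(shape[1] - 1),
                     y = (shape[2] - 3):(shape[2] - 1), z = 2:3),
      lesions = list(list(center = c(4, 4, 2), radius = 1,
                          t1_hypo = TRUE)),
      pools = list(
        wm = list(frac = frac, t2 = c(20, s$median_t2_iew, 1000)),
        csf = list(frac = c(0, 0.05, 0.95), t2 = c(20, 80, 1500)),
        lesion = list(frac = c(0.06, 0.70, 0.24), t2 = c(20, 90, 1000))),
      snr = snr, seed = cohort_subject_seed(i))
    ph <- generate_phantom(ps)
    masks <- mask_set(ph$tissue_labels, ph$lesion_prob,
                      voxel_size = ps$voxel_size)
    # fit only what the summary reads: the eroded non-lesional WM
    fit <- fit_volume(ph$echoes, masks$nonlesional_wm, ps$params, grid,
                      config)
    maps <- assemble_maps(fit)
    lr <- lesion_report(masks)
    lv <- setNames(lr$volume_mm3, lr$sub_volume)
    rows[[i]] <- summarize_subject(
      maps, masks$nonlesional_wm,
      clinical = s[c("subject_id", "edss", "duration_years", "age_years")],
      lesion_volumes = lv)
    if (verbose)
      message(sprintf("cohort_full_path: subject %d / %d", i, nrow(fast)))
  }
  summaries <- do.call(rbind, rows)
  structure(list(clinical = cohort$clinical, summaries = summaries,
                 latent = cohort$latent),
            class = "cohort")
}

# deterministic per-subject phantom seed (kept below 2^31)
cohort_subject_seed <- function(i) 100003L + 7L * as.integer(i)
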