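toy_maps <- function(fw_values) {
  n <- length(fw_values)
  d <- c(n, 1, 1)
  structure(list(
    mw_frac = array(0.1, d), iew_frac = array(0.85 - fw_values + 0.05, d),
    fw_frac = array(fw_values, d), t2_iew = array(80, d),
    snr = array(200, d), flip_deg = array(170, d),
    background = array(FALSE, d), grid = t2_grid(),
    boundaries = compartment_boundaries()), class = "compartment_maps")
}

test_that("summarize_subject computes masked medians and means", {
  maps <- toy_maps(rep(0.05, 4))
  mask <- array(TRUE, c(4, 1, 1))
  s <- summarize_subject(maps, mask)
  expect_equal(s$median_fw, 0.05)
  expect_equal(s$mean_fw, 0.05)

  maps2 <- toy_maps(c(0.02, 0.04, 0.30))
  s2 <- summarize_subject(maps2, array(TRUE, c(3, 1, 1)),
                          clinical = list(subject_id = "S1", edss = 2),
                          lesion_volumes = c(total = 10, t1_iso = 4,
                                             t1_hypo = 6))
  expect_equal(s2$median_fw, 0.04)
  expect_equal(s2$mean_fw, 0.12)
  expect_equal(s2$subject_id, "S1")
  expect_equal(s2$lesion_t1_hypo_mm3, 6)

  # undefined T2-IEw voxels excluded from that summary only
  maps3 <- toy_maps(c(0.1, 0.1))
  maps3$t2_iew[2, 1, 1] <- NA_real_
  s3 <- summarize_subject(maps3, array(TRUE, c(2, 1, 1)))
  expect_equal(s3$median_t2_iew, 80)
  expect_equal(s3$n_voxels, 2L)

  expect_error(summarize_subject(maps, array(FALSE, c(4, 1, 1))),
               "no fitted voxels")
})

test_that("summaries of the fitted standard phantom track the truth", {
  ph <- standard_phantom()
  maps <- standard_phantom_maps()
  ms <- mask_set(ph$tissue_labels, ph$lesion_prob)
  s <- summarize_subject(maps, ms$nonlesional_wm)
  # regularization biases Mw/Fw down and IEw up (see methods vignette);
  # bounds below are absolute and allow for that documented bias
  expect_lt(abs(s$median_fw - 0.05), 0.03)
  expect_lt(abs(s$median_mw - 0.10), 0.03)
  expect_lt(abs(s$median_iew - 0.85), 0.05)
  expect_lt(abs(s$median_t2_iew - 80), 6)
})

test_that("spearman_cor is tie-corrected and matches the oracles", {
  expect_equal(spearman_cor(1:6, c(2, 5, 9, 14, 20, 30))$r, 1)
  expect_equal(spearman_cor(1:4, 4:1)$r, -1)
  # tied example against the exact midrank/permutation oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  res <- spearman_cor(x, y, exact = TRUE)
  orc <- spearman_perm_oracle(x, y)
  expect_equal(res$r, orc$r, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  # hand midrank computation: rx = (1, 2.5, 2.5, 4), ry = (1, 3, 2, 4)
  # -> cov 4.5, variances 4.5 and 5, r = 4.5 / sqrt(22.5)
  expect_equal(res$r, 4.5 / sqrt(22.5), tolerance = 1e-12)
  # agreement with R's rho
  expect_equal(res$r, unname(cor(x, y, method = "spearman")))
  # zero variance flagged
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))$r))
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(501)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- spearman_cor(x, y)$r
    expect_equal(spearman_cor(exp(x), y)$r, r0)
    expect_equal(spearman_cor(x, y^3 + 5 * y)$r, r0)
    expect_equal(spearman_cor(rank(x), y)$r, r0)
  }
})

test_that("pearson_cor matches closed forms and cor.test", {
  x <- 1:5
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(c(-1, 0, 1), c(1, -2, 1))$r, 0)
  # hand-computed 5-point pair
  a <- c(1, 2, 4, 5, 8); b <- c(2, 1, 5, 4, 9)
  sab <- sum((a - mean(a)) * (b - mean(b)))
  r_hand <- sab / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- pearson_cor(a, b)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  ct <- cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  # sign property
  set.seed(502)
  v <- rnorm(10)
  expect_equal(pearson_cor(v, -3 * v + 2)$r, -1)
  expect_true(is.na(pearson_cor(rep(1, 5), 1:5)$r))
})

test_that("bivariate EDSS model separates the two predictors", {
  set.seed(503)
  lesion <- rnorm(40)
  wm <- rnorm(40)
  # EDSS exactly linear in lesion volume alone
  m1 <- suppressWarnings(  # lm flags the deliberately perfect fit
    bivariate_edss_model(2 + 0.5 * lesion, lesion, wm))
  expect_lt(abs(m1$coefficients[["wm"]]), 1e-10)
  expect_gt(m1$coef_p[["wm"]], 0.5)
  expect_lt(m1$coef_p[["lesion"]], 1e-10)
  # both predictors carry independent effects at n = 200
  n <- 200
  l2 <- rnorm(n); w2 <- rnorm(n)
  edss <- 2 + 0.4 * l2 + 0.4 * w2 + rnorm(n, sd = 0.8)
  m2 <- bivariate_edss_model(edss, l2, w2)
  expect_lt(m2$coef_p[["lesion"]], 0.05)
  expect_lt(m2$coef_p[["wm"]], 0.05)
  expect_gt(m2$r2, 0)
  # minimal n = 4 returns finite statistics
  m3 <- bivariate_edss_model(c(1, 2, 3, 2.5), c(0.1, 0.4, 0.9, 0.5),
                             c(5, 4, 2, 3))
  expect_true(is.finite(m3$r2) && is.finite(m3$model_p))
  # collinear predictors are flagged
  m4 <- bivariate_edss_model(edss, l2, 2 * l2 + 1e-9 * w2)
  expect_identical(m4$flag, "collinear")
  expect_true(is.na(m4$coefficients[["wm"]]))
})

test_that("three-subject battery matches hand computation", {
  cohort <- data.frame(
    subject_id = c("A", "B", "C"), edss = c(1, 2, 3.5),
    duration_years = c(5, 10, 20), age_years = c(30, 40, 50),
    lesion_total_mm3 = c(100, 300, 200),
    lesion_t1_iso_mm3 = c(60, 150, 80),
    lesion_t1_hypo_mm3 = c(40, 150, 120),
    median_mw = c(0.11, 0.10, 0.09), median_iew = c(0.85, 0.84, 0.83),
    median_fw = c(0.04, 0.06, 0.08), median_t2_iew = c(82, 80, 78),
    mean_mw = c(0.11, 0.10, 0.09), mean_iew = c(0.85, 0.84, 0.83),
    mean_fw = c(0.04, 0.06, 0.08), mean_t2_iew = c(82, 80, 78))
  bat <- correlation_battery(cohort)
  rows <- bat$correlations
  # monotone increasing fw vs edss: rank r = 1 by hand
  expect_equal(rows$r[rows$parameter == "median_fw" &
                        rows$covariate == "edss"], 1)
  # median_mw decreasing in age: Pearson of (0.11,0.10,0.09) vs (30,40,50)
  # is exactly -1 (both equally spaced)
  expect_equal(rows$r[rows$parameter == "median_mw" &
                        rows$covariate == "age"], -1)
  # fw vs age: perfectly linear too
  expect_equal(rows$r[rows$parameter == "median_fw" &
                        rows$covariate == "age"], 1)
  # fw vs duration by hand: cov/sds on (0.04,0.06,0.08) vs (5,10,20)
  fw <- c(0.04, 0.06, 0.08); dur <- c(5, 10, 20)
  r_hand <- sum((fw - mean(fw)) * (dur - mean(dur))) /
    sqrt(sum((fw - mean(fw))^2) * sum((dur - mean(dur))^2))
  expect_equal(rows$r[rows$parameter == "median_fw" &
                        rows$covariate == "duration"], r_hand)
  # lesion rows: hypo volumes (40,150,120) vs edss (1,2,3.5): ranks
  # (1,3,2) vs (1,2,3) -> rho = 0.5 by hand
  expect_equal(rows$r[rows$parameter == "lesion_t1_hypo_mm3"], 0.5)
})

test_that("battery has the full table shape and excludes missing rows", {
  co <- generate_cohort(cohort_spec(n_subjects = 30L, seed = 9L))
  tab <- co$summaries
  bat <- correlation_battery(tab)
  expect_equal(nrow(bat$correlations), 8L * 4L + 3L)
  expect_equal(nrow(bat$bivariate), 8L)
  expect_setequal(unique(bat$correlations$covariate[1:32]),
                  c("edss", "duration", "age", "t1_lesion_load"))
  # row-wise exclusion of missing values
  tab$median_fw[3] <- NA
  bat2 <- correlation_battery(tab)
  expect_equal(bat2$correlations$n[bat2$correlations$parameter ==
                                     "median_fw"], rep(29L, 4))
  # t1_load switch
  bat3 <- correlation_battery(tab, t1_load = "total")
  r_tot <- bat3$correlations$r[bat3$correlations$parameter == "median_mw" &
                                 bat3$correlations$covariate ==
                                   "t1_lesion_load"]
  r_hyp <- bat$correlations$r[bat$correlations$parameter == "median_mw" &
                                bat$correlations$covariate ==
                                  "t1_lesion_load"]
  expect_false(isTRUE(all.equal(r_tot, r_hyp)))
  # BH adjustment column appears on request
  expect_true("p_bh" %in%
                names(correlation_battery(tab, p_adjust = "BH")$correlations))
})
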