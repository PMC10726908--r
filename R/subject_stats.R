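#' Summarize quantitative maps over a mask for one subject
#'
#' Median and mean of the Mw, IEw, Fw fractions and T2-IEw over in-mask,
#' non-background voxels; T2-IEw voxels with an undefined value (empty IEw
#' window) are excluded from its summary only.
#'
#' @param maps `compartment_maps`.
#' @param mask Logical mask (typically the eroded non-lesional WM mask).
#' @param clinical Optional one-row list/data.frame with `subject_id`,
#'   `edss`, `duration_years`, `age_years` (carried through).
#' @param lesion_volumes Optional named vector/list with `total`, `t1_iso`,
#'   `t1_hypo` lesion volumes in mm^3 (carried through).
#' @return One-row data frame with `median_*` and `mean_*` of `mw`, `iew`,
#'   `fw`, `t2_iew`, `n_voxels`, plus any clinical/lesion columns supplied.
#' @export
summarize_subject <- function(maps, mask, clinical = NULL,
                              lesion_volumes = NULL) {
  if (!inherits(maps, "compartment_maps"))
    stop_param("maps must be a compartment_maps object")
  if (!identical(dim(mask), dim(maps$background)))
    stop_param("mask shape must match the maps")
  use <- mask & !maps$background
  if (!any(use)) stop_param("mask contains no fitted voxels")
  vals <- list(mw = maps$mw_frac[use], iew = maps$iew_frac[use],
               fw = maps$fw_frac[use], t2_iew = maps$t2_iew[use])
  out <- list(n_voxels = sum(use))
  for (m in names(vals)) {
    v <- vals[[m]][!is.na(vals[[m]])]
    out[[paste0("median_", m)]] <- if (length(v)) median(v) else NA_real_
    out[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
  }
  if (!is.null(lesion_volumes)) {
    out$lesion_total_mm3 <- as.numeric(lesion_volumes[["total"]])
    out$lesion_t1_iso_mm3 <- as.numeric(lesion_volumes[["t1_iso"]])
    out$lesion_t1_hypo_mm3 <- as.numeric(lesion_volumes[["t1_hypo"]])
  }
  if (!is.null(clinical)) {
    for (f in c("subject_id", "edss", "duration_years", "age_years"))
      if (!is.null(clinical[[f]])) out[[f]] <- clinical[[f]]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

cor_t_p <- function(r, n) {
  if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) NA_real_ else 0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Spearman rank correlation with tie correction
#'
#' Product-moment correlation of midranks; the two-sided p-value uses the
#' t-approximation with n - 2 degrees of freedom (adequate at cohort sizes
#' of a few tens; an exact permutation p is available for tiny n).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact If `TRUE` and n <= 10, p is computed by exhaustive
#'   permutation of `y` instead of the t-approximation.
#' @return List with `r`, `p`, `n`, `method`; `r` is NA (flagged) when
#'   either input has zero variance.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop_param("need equal-length inputs with n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, method = "rank-based"))
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (exact && n <= 10L) {
    perms <- permutations_of(n)
    robs <- abs(r)
    rs <- apply(perms, 1L, function(p) abs(suppressWarnings(
      stats::cor(rx, ry[p]))))
    p <- mean(rs >= robs - 1e-12)
  } else {
    p <- cor_t_p(r, n)
  }
  list(r = r, p = p, n = n, method = "rank-based")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p` (two-sided t-test, n - 2 df), `n`, `method`;
#'   `r` is NA when either input has zero variance.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop_param("need equal-length inputs with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, method = "linear"))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(r = r, p = cor_t_p(r, n), n = n, method = "linear")
}

#' Two-predictor linear model of EDSS
#'
#' Ordinary least squares of EDSS on standardized lesion volume and one
#' standardized WM relaxation parameter; coefficient p-values from
#' t-statistics, overall model F-test p, and R^2. Standardization makes the
#' two coefficients directly comparable. Nearly collinear predictors
#' (|r| > 0.999) are flagged and the coefficients suppressed.
#'
#' @param edss EDSS scores.
#' @param lesion_volume Lesion volumes (mm^3).
#' @param wm_parameter One WM summary parameter per subject.
#' @return List with `coefficients` (intercept, lesion, wm), `coef_p`,
#'   `model_p`, `r2`, `n`, `flag`.
#' @export
bivariate_edss_model <- function(edss, lesion_volume, wm_parameter) {
  ok <- is.finite(edss) & is.finite(lesion_volume) & is.finite(wm_parameter)
  edss <- edss[ok]; lesion_volume <- lesion_volume[ok]
  wm_parameter <- wm_parameter[ok]
  n <- length(edss)
  if (n <= 3L) stop_param("need n > 3 subjects")
  z <- function(v) (v - mean(v)) / sd(v)
  x1 <- z(lesion_volume); x2 <- z(wm_parameter)
  rp <- pearson_cor(x1, x2)
  if (!is.na(rp$r) && abs(rp$r) > 0.999) {
    return(list(coefficients = c(intercept = NA, lesion = NA, wm = NA),
                coef_p = c(intercept = NA, lesion = NA, wm = NA),
                model_p = NA_real_, r2 = NA_real_, n = n,
                flag = "collinear"))
  }
  fit <- stats::lm(edss ~ x1 + x2)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  co <- sm$coefficients
  list(coefficients = setNames(co[, 1], c("intercept", "lesion", "wm")),
       coef_p = setNames(co[, 4], c("intercept", "lesion", "wm")),
       model_p = model_p, r2 = sm$r.squared, n = n, flag = "ok")
}

wm_parameter_names <- function() {
  as.vector(outer(c("median", "mean"), c("mw", "iew", "fw", "t2_iew"),
                  paste, sep = "_"))
}

#' Cohort-level correlation battery
#'
#' For each of the 8 WM summary parameters (median/mean of Mw, IEw, Fw,
#' T2-IEw): Spearman correlation with EDSS and Pearson correlations with
#' disease duration, age, and the T1 focal-lesion load. Adds the Spearman
#' correlations of the total / T1-iso / T1-hypo lesion volumes with EDSS,
#' and a table of two-predictor EDSS models pairing the lesion load with
#' each WM parameter. Rows with missing fields are excluded pairwise. No
#' multiple-testing correction is applied by default; `p_adjust = "BH"`
#' adds a Benjamini-Hochberg column.
#'
#' @param cohort Data frame with columns `edss`, `duration_years`,
#'   `age_years`, `lesion_total_mm3`, `lesion_t1_iso_mm3`,
#'   `lesion_t1_hypo_mm3` and the 8 `median_*`/`mean_*` WM parameters.
#' @param t1_load `"hypo"` (default: the T1-hypo-intense lesion sub-volume
#'   is the "T1 lesion load") or `"total"`.
#' @param p_adjust `"none"` or `"BH"`.
#' @return List of class `correlation_battery` with data frames
#'   `correlations` (parameter, covariate, method, r, p, n) and `bivariate`
#'   (one row per WM parameter).
#' @export
correlation_battery <- function(cohort, t1_load = c("hypo", "total"),
                                p_adjust = c("none", "BH")) {
  t1_load <- match.arg(t1_load)
  p_adjust <- match.arg(p_adjust)
  if (nrow(cohort) < 3L) stop_param("need at least 3 subjects")
  load_col <- if (t1_load == "hypo") "lesion_t1_hypo_mm3"
              else "lesion_total_mm3"
  covs <- list(
    edss = list(col = "edss", fn = spearman_cor, method = "rank-based"),
    duration = list(col = "duration_years", fn = pearson_cor,
                    method = "linear"),
    age = list(col = "age_years", fn = pearson_cor, method = "linear"),
    t1_lesion_load = list(col = load_col, fn = pearson_cor,
                          method = "linear"))
  rows <- list()
  for (par in wm_parameter_names()) {
    for (cv in names(covs)) {
      res <- covs[[cv]]$fn(cohort[[par]], cohort[[covs[[cv]]$col]])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, covariate = cv, method = res$method,
        r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  for (lv in c("lesion_total_mm3", "lesion_t1_iso_mm3",
               "lesion_t1_hypo_mm3")) {
    res <- spearman_cor(cohort[[lv]], cohort$edss)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = lv, covariate = "edss", method = res$method,
      r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  }
  correlations <- do.call(rbind, rows)
  if (p_adjust == "BH")
    correlations$p_bh <- stats::p.adjust(correlations$p, method = "BH")

  biv <- lapply(wm_parameter_names(), function(par) {
    m <- tryCatch(
      bivariate_edss_model(cohort$edss, cohort[[load_col]], cohort[[par]]),
      error = function(e) list(
        coefficients = c(intercept = NA, lesion = NA, wm = NA),
        coef_p = c(intercept = NA, lesion = NA, wm = NA),
        model_p = NA_real_, r2 = NA_real_, n = nrow(cohort),
        flag = conditionMessage(e)))
    data.frame(parameter = par, coef_lesion = m$coefficients[["lesion"]],
               coef_wm = m$coefficients[["wm"]],
               p_lesion = m$coef_p[["lesion"]], p_wm = m$coef_p[["wm"]],
               model_p = m$model_p, r2 = m$r2, n = m$n, flag = m$flag,
               stringsAsFactors = FALSE)
  })
  structure(list(correlations = correlations,
                 bivariate = do.call(rbind, biv), t1_load = t1_load),
            class = "correlation_battery")
}

#' @export
print.correlation_battery <- function(x, ...) {
  cat(sprintf("correlation_battery: %d correlation cells, %d bivariate models (T1 load = %s)\n",
              nrow(x$correlations), nrow(x$bivariate), x$t1_load))
  sig <- x$correlations[!is.na(x$correlations$p) & x$correlations$p < 0.05, ]
  if (nrow(sig)) {
    cat("  p < 0.05:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s vs %s: r = %.2f (p = %.3f)\n", sig$parameter[i],
                  sig$covariate[i], sig$r[i], sig$p[i]))
  }
  invisible(x)
}
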