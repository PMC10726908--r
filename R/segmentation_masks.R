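#' Threshold a lesion-probability volume
#'
#' A voxel belongs to the focal-lesion mask iff its probability strictly
#' exceeds `threshold` (ties at exactly the threshold are excluded).
#'
#' @param prob_volume 3-D array of probabilities in [0, 1].
#' @param threshold Probability threshold (default 0.5).
#' @return Logical array of the same shape.
#' @export
threshold_lesion_probability <- function(prob_volume, threshold = 0.5) {
  if (any(prob_volume < 0 | prob_volume > 1, na.rm = TRUE))
    stop_param("lesion probabilities must lie in [0, 1]")
  prob_volume > threshold
}

#' Split a lesion mask by T1 tissue class
#'
#' Lesion voxels still carrying the WM tissue label are T1-iso-intense;
#' lesion voxels outside the WM label are T1-hypo-intense (more severe
#' tissue damage; automated T1 segmentation does not label them WM). The two
#' sub-masks partition the lesion mask exactly.
#'
#' @param lesion Logical lesion mask.
#' @param tissue_labels Integer label volume of the same shape.
#' @param wm_code Integer code of WM in `tissue_labels`.
#' @return List with logical masks `iso` and `hypo`.
#' @export
split_lesion_by_t1 <- function(lesion, tissue_labels, wm_code = 1L) {
  if (!identical(dim(lesion), dim(tissue_labels)))
    stop_param("lesion and tissue_labels must share one shape")
  list(iso = lesion & tissue_labels == wm_code,
       hypo = lesion & tissue_labels != wm_code)
}

# shift a 3-D logical array by (dx, dy, dz), padding with FALSE
shift_mask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- m[fx[okx], fy[oky], fz[okz]]
  out
}

#' Binary erosion of a mask
#'
#' `method = "2d"` (default) erodes slice-wise with a 3x3 square structuring
#' element: a voxel survives iff it and its 8 in-plane neighbours are all
#' true. The default is 2-D because relaxometry voxels are strongly
#' anisotropic (e.g. 1.64 x 1.64 x 2.5 mm), so "one pixel" is an in-plane
#' notion. `method = "3d"` uses the 6-connected cross element. Voxels
#' outside the volume count as false (masks shrink at the volume border).
#'
#' @param mask Logical 3-D array.
#' @param iterations Number of erosion passes (>= 0; 0 returns the input).
#' @param method `"2d"` or `"3d"`.
#' @return Eroded logical array.
#' @export
erode_mask <- function(mask, iterations = 1L, method = c("2d", "3d")) {
  method <- match.arg(method)
  if (iterations < 0) stop_param("iterations must be >= 0")
  offsets <- if (method == "2d") {
    g <- expand.grid(dx = -1:1, dy = -1:1)
    g$dz <- 0L
    g[!(g$dx == 0 & g$dy == 0), ]
  } else {
    data.frame(dx = c(-1, 1, 0, 0, 0, 0), dy = c(0, 0, -1, 1, 0, 0),
               dz = c(0, 0, 0, 0, -1, 1))
  }
  out <- mask
  for (it in seq_len(iterations)) {
    eroded <- out
    for (r in seq_len(nrow(offsets))) {
      eroded <- eroded & shift_mask(out, offsets$dx[r], offsets$dy[r],
                                    offsets$dz[r])
    }
    out <- eroded
  }
  out
}

#' Non-lesional WM mask
#'
#' WM label minus the lesion mask, then eroded to suppress partial-volume
#' voxels at the mask boundary.
#'
#' @param wm Logical WM mask.
#' @param lesion Logical lesion mask.
#' @param erosion_px Number of erosion passes (default 1; 0 returns the set
#'   difference unchanged).
#' @param method Erosion mode, see [erode_mask()].
#' @return Logical mask.
#' @export
make_nonlesional_wm <- function(wm, lesion, erosion_px = 1L,
                                method = c("2d", "3d")) {
  if (!identical(dim(wm), dim(lesion)))
    stop_param("wm and lesion must share one shape")
  erode_mask(wm & !lesion, iterations = erosion_px, method = method)
}

#' Build the full mask set for one subject
#'
#' Combines the tissue-label volume and the lesion-probability volume into
#' the masks the analysis consumes: the thresholded lesion mask, its
#' T1-iso/T1-hypo partition, and the eroded non-lesional WM mask.
#'
#' @param tissue_labels Integer label volume (WM = `wm_code`).
#' @param lesion_prob Lesion-probability volume in [0, 1], same shape.
#' @param wm_code WM label code.
#' @param threshold Lesion-probability threshold.
#' @param erosion_px Erosion passes for the non-lesional WM mask.
#' @param erosion_method `"2d"` or `"3d"`.
#' @param voxel_size Voxel edge lengths (dx, dy, dz) in mm.
#' @return Object of class `mask_set` with logical volumes `wm`, `lesion`,
#'   `lesion_t1_iso`, `lesion_t1_hypo`, `nonlesional_wm` and `voxel_size`.
#' @export
mask_set <- function(tissue_labels, lesion_prob, wm_code = 1L,
                     threshold = 0.5, erosion_px = 1L,
                     erosion_method = c("2d", "3d"),
                     voxel_size = c(1.64, 1.64, 2.5)) {
  if (!identical(dim(tissue_labels), dim(lesion_prob)))
    stop_param("tissue_labels and lesion_prob must share one shape")
  wm <- tissue_labels == wm_code
  lesion <- threshold_lesion_probability(lesion_prob, threshold)
  sub <- split_lesion_by_t1(lesion, tissue_labels, wm_code)
  structure(list(
    wm = wm, lesion = lesion, lesion_t1_iso = sub$iso,
    lesion_t1_hypo = sub$hypo,
    nonlesional_wm = make_nonlesional_wm(wm, lesion, erosion_px,
                                         match.arg(erosion_method)),
    voxel_size = voxel_size), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf(
    "mask_set: %s volume | WM %d vox | lesion %d (iso %d / hypo %d) | non-lesional WM %d\n",
    paste(dim(x$wm), collapse = "x"), sum(x$wm), sum(x$lesion),
    sum(x$lesion_t1_iso), sum(x$lesion_t1_hypo), sum(x$nonlesional_wm)))
  invisible(x)
}

#' Lesion volume report
#'
#' Total, T1-iso and T1-hypo lesion volumes in mm^3 (voxel count times voxel
#' volume) and their percentage shares of the total lesion volume.
#'
#' @param masks A `mask_set`.
#' @return Data frame with columns `sub_volume`, `n_voxels`, `volume_mm3`,
#'   `percent` (NA shares when the lesion mask is empty).
#' @export
lesion_report <- function(masks) {
  if (!inherits(masks, "mask_set")) stop_param("masks must be a mask_set")
  vv <- prod(masks$voxel_size)
  n <- c(total = sum(masks$lesion), t1_iso = sum(masks$lesion_t1_iso),
         t1_hypo = sum(masks$lesion_t1_hypo))
  vol <- n * vv
  pct <- if (n[["total"]] > 0) 100 * vol / vol[["total"]]
         else rep(NA_real_, 3)
  data.frame(sub_volume = names(n), n_voxels = as.integer(n),
             volume_mm3 = as.numeric(vol), percent = as.numeric(pct),
             row.names = NULL)
}
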