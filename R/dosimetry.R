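#' Sum per-fiber fluence-rate maps
#'
#' Light transport is linear, so the overall fluence rate at a voxel is the
#' elementwise sum of the per-fiber fluence rates.
#'
#' @param maps List of fluence-rate arrays on the same grid (at least one).
#' @return Array of the same dimensions, mW/cm^2.
#' @export
sum_fluence_rates <- function(maps) {
  if (length(maps) < 1L) stop("at least one fluence-rate map is required")
  d <- dim(maps[[1]])
  out <- array(0, dim = d)
  for (m in maps) {
    if (!identical(dim(m), d)) stop("fluence-rate maps are on different grids")
    out <- out + m
  }
  out
}

#' Fluence from fluence rate and illumination time
#'
#' `fluence (J/cm^2) = rate (mW/cm^2) * time (s) / 1000` — i.e. 1 mW/cm^2
#' sustained for 1000 s deposits 1 J/cm^2.
#'
#' @param rate_map Fluence-rate array, mW/cm^2.
#' @param time Illumination time, s (>= 0).
#' @return Fluence array, J/cm^2.
#' @export
compute_fluence <- function(rate_map, time) {
  if (time < 0) stop("time must be >= 0")
  rate_map * time / 1000
}

#' Effective treated volume
#'
#' Voxels whose fluence exceeds the therapeutic threshold (25 J/cm^2 by
#' default, the minimal fluence observed to produce a therapeutic effect).
#' The comparison is strict (`>`); set `strict = FALSE` for a `>=`
#' sensitivity variant.
#'
#' @param fluence Fluence array, J/cm^2.
#' @param grid The [voxel_grid()] carrying voxel geometry.
#' @param threshold Therapeutic fluence threshold, J/cm^2 (> 0).
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return List with `mask` (logical array) and `volume_cm3`.
#' @export
effective_treated_volume <- function(fluence, grid, threshold = 25,
                                     strict = TRUE) {
  if (threshold <= 0) stop("threshold must be > 0")
  mask <- if (strict) fluence > threshold else fluence >= threshold
  list(mask = mask,
       volume_cm3 = sum(mask) * voxel_volume_mm3(grid) / 1000)
}

#' Coverage index
#'
#' Percentage of the contoured target volume overlapped by the effective
#' treated volume.
#'
#' @param treated_mask,target_mask Logical arrays on the same grid; the
#'   target must be non-empty.
#' @return Percent in \[0, 100\].
#' @export
coverage_index <- function(treated_mask, target_mask) {
  if (!identical(dim(treated_mask), dim(target_mask)))
    stop("masks are on different grids")
  nt <- sum(target_mask)
  if (nt == 0) stop("target mask is empty")
  100 * sum(treated_mask & target_mask) / nt
}

#' High-dose region
#'
#' Strict-threshold mask of voxels above the display threshold (default
#' 250 J/cm^2), used to visualize the high-fluence sleeve around each
#' diffuser.
#'
#' @inheritParams effective_treated_volume
#' @param display_threshold Display threshold, J/cm^2 (> 0).
#' @return Logical array.
#' @export
high_dose_region <- function(fluence, display_threshold = 250) {
  if (display_threshold <= 0) stop("display_threshold must be > 0")
  fluence > display_threshold
}

#' Relative photosensitizer weighting (optional)
#'
#' Multiplies fluence by a per-tissue relative PpIX concentration factor
#' before thresholding: 1 for the tumor classes (necrotic, non-enhancing,
#' enhancing) and `1/ratio` for healthy classes and oedema, reflecting the
#' up-to-100:1 tumor-to-parenchyma PpIX concentration ratio. OFF by default
#' throughout the package — the effective treated volume is defined on
#' fluence alone; this hook supports sensitivity analyses only.
#'
#' @param fluence Fluence (or fluence-rate) array.
#' @param grid The label [voxel_grid()].
#' @param ratio Tumor-to-healthy concentration ratio (default 100).
#' @param tumor_labels Labels given weight 1.
#' @return Weighted array.
#' @export
ppix_weighted_fluence <- function(fluence, grid, ratio = 100,
                                  tumor_labels = tissue_labels[
                                    c("necrotic", "non_enhancing",
                                      "enhancing")]) {
  w <- array(1 / ratio, dim = grid$dims)
  w[grid$labels %in% tumor_labels] <- 1
  w[grid$labels == tissue_labels[["background"]]] <- 0
  fluence * w
}

#' Dosimetry summary of a treatment plan
#'
#' @param fluence Total fluence array, J/cm^2.
#' @param grid The [voxel_grid()].
#' @param target_mask Logical target array (contoured tumor); optional.
#' @param treatment_time Illumination time, s.
#' @param threshold Therapeutic threshold, J/cm^2.
#' @param display_threshold High-dose display threshold, J/cm^2.
#' @return One-row `dose_summary` data frame: `treated_volume_cm3`,
#'   `coverage_index_pct` (NA without a target), `treatment_time_s`,
#'   `threshold_J_cm2`, `high_dose_volume_cm3`.
#' @export
dose_summary <- function(fluence, grid, target_mask = NULL,
                         treatment_time, threshold = 25,
                         display_threshold = 250) {
  etv <- effective_treated_volume(fluence, grid, threshold)
  hd <- high_dose_region(fluence, display_threshold)
  ci <- if (!is.null(target_mask))
    coverage_index(etv$mask, target_mask) else NA_real_
  structure(data.frame(
    treated_volume_cm3 = etv$volume_cm3,
    coverage_index_pct = ci,
    treatment_time_s = treatment_time,
    threshold_J_cm2 = threshold,
    high_dose_volume_cm3 = sum(hd) * voxel_volume_mm3(grid) / 1000),
    class = c("dose_summary", "data.frame"))
}
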