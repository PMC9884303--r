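#' Hounsfield-unit fat window
#'
#' The adipose-tissue attenuation window. Both endpoints are inclusive: a
#' voxel at exactly -30 HU or exactly -190 HU counts as fat. Defaults are
#' the standard CT fat window of -190 to -30 HU.
#'
#' @param lo_hu lower bound (HU), default -190.
#' @param hi_hu upper bound (HU), default -30; must exceed `lo_hu`.
#' @return An object of class `fat_window`.
#' @examples
#' fat_window()            # -190..-30 HU
#' fat_window(-150, -50)
#' @export
fat_window <- function(lo_hu = -190, hi_hu = -30) {
  lo_hu <- as.numeric(lo_hu); hi_hu <- as.numeric(hi_hu)
  if (!is.finite(lo_hu) || !is.finite(hi_hu) || lo_hu >= hi_hu)
    stop("fat window requires finite lo_hu < hi_hu", call. = FALSE)
  structure(list(lo_hu = lo_hu, hi_hu = hi_hu), class = "fat_window")
}

#' @export
print.fat_window <- function(x, ...) {
  cat("<fat_window> [", x$lo_hu, ", ", x$hi_hu, "] HU (inclusive)\n", sep = "")
  invisible(x)
}

#' Select epicardial adipose tissue voxels
#'
#' EAT voxels are all voxels inside the pericardial sac, outside the heart
#' chambers, whose attenuation lies in the fat window (endpoints inclusive).
#' The chamber mask is intersected with the pericardium before subtraction,
#' so chamber voxels outside the sac are irrelevant.
#'
#' @param volume a [voxel_volume].
#' @param pericardium logical mask of the pericardial sac interior.
#' @param chambers logical mask of the heart chambers (need not be a subset
#'   of the pericardium).
#' @param window a [fat_window].
#' @return Logical mask of selected EAT voxels.
#' @export
select_eat_voxels <- function(volume, pericardium, chambers,
                              window = fat_window()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(window, "fat_window"))
  pericardium <- as_binary_mask(pericardium)
  chambers <- as_binary_mask(chambers)
  check_aligned(dim(volume$data), pericardium, chambers)
  pericardium & !(chambers & pericardium) &
    volume$data >= window$lo_hu & volume$data <= window$hi_hu
}

#' Volume of a mask in millilitres
#'
#' `volume_ml = voxel_count * dx * dy * dz / 1000`. For overlapping-slice
#' reconstructions `dz` must already be the inter-slice increment (see
#' [slice_increment()]); passing the slice thickness would double-count
#' tissue.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing in mm, `c(dx, dy, dz_increment)`.
#' @return Volume in ml.
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' compute_volume_ml(m, c(1, 1, 1.5))  # 1.5 ml
#' @export
compute_volume_ml <- function(mask, spacing) {
  mask <- as_binary_mask(mask)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive mm values", call. = FALSE)
  sum(mask) * prod(spacing) / 1000
}

#' Area of a 2-D mask in square centimetres
#'
#' @param mask logical 2-D array.
#' @param spacing pixel spacing in mm, `c(dx, dy)`.
#' @return Area in cm^2.
#' @export
compute_area_cm2 <- function(mask, spacing) {
  mask <- as_binary_mask(mask)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive mm values", call. = FALSE)
  sum(mask) * prod(spacing) / 100
}

#' Median attenuation over a mask
#'
#' Exact sample median of the HU values under the mask; for an even count
#' the midpoint of the two central values. An empty mask is an error rather
#' than a sentinel value - callers that tolerate empty depots must test
#' emptiness first.
#'
#' @param volume a [voxel_volume].
#' @param mask logical mask aligned to the volume.
#' @return Median attenuation in HU.
#' @export
median_attenuation <- function(volume, mask) {
  stopifnot(inherits(volume, "voxel_volume"))
  mask <- as_binary_mask(mask)
  check_aligned(dim(volume$data), mask)
  if (!any(mask))
    stop("undefined median: mask selects no voxels", call. = FALSE)
  stats::median(volume$data[mask])
}

#' Quantify epicardial adipose tissue
#'
#' Composition of [select_eat_voxels()], [compute_volume_ml()] and
#' [median_attenuation()]: EATV in ml and EATA as the median HU of the
#' selected voxels. When no voxel is selected, `volume_ml` is 0,
#' `voxel_count` 0 and `median_hu` `NA`.
#'
#' @inheritParams select_eat_voxels
#' @return A `fat_measurement`: list with `volume_ml`, `median_hu`,
#'   `voxel_count`.
#' @examples
#' vol <- voxel_volume(array(-70, c(4, 4, 4)), c(1, 1, 1.5))
#' peri <- array(TRUE, c(4, 4, 4))
#' cham <- array(FALSE, c(4, 4, 4)); cham[2:3, 2:3, 2:3] <- TRUE
#' quantify_eat(vol, peri, cham)  # 56 voxels
#' @export
quantify_eat <- function(volume, pericardium, chambers,
                         window = fat_window()) {
  eat <- select_eat_voxels(volume, pericardium, chambers, window)
  count <- sum(eat)
  med <- if (count > 0) median_attenuation(volume, eat) else NA_real_
  structure(list(volume_ml = compute_volume_ml(eat, volume$spacing),
                 median_hu = med, voxel_count = as.integer(count)),
            class = "fat_measurement")
}

#' @export
print.fat_measurement <- function(x, ...) {
  cat("<fat_measurement> EATV ", format(x$volume_ml, digits = 6), " ml; EATA ",
      ifelse(is.na(x$median_hu), "NA", format(x$median_hu, digits = 6)),
      " HU (", x$voxel_count, " voxels)\n", sep = "")
  invisible(x)
}

#' One CSV row for a fat measurement
#'
#' @param x a `fat_measurement`.
#' @param subject_id identifier written in the first column.
#' @return A one-row data frame `(subject_id, eatv_ml, eata_hu, voxel_count)`.
#' @export
fat_measurement_row <- function(x, subject_id = NA_character_) {
  stopifnot(inherits(x, "fat_measurement"))
  data.frame(subject_id = subject_id, eatv_ml = x$volume_ml,
             eata_hu = x$median_hu, voxel_count = x$voxel_count,
             stringsAsFactors = FALSE)
}
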