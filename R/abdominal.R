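#' Threshold fat on a single abdominal slice
#'
#' Pixels whose attenuation lies in the fat window (endpoints inclusive,
#' same semantics as the cardiac quantification). The slice must be 2-D.
#'
#' @param slice a 2-D [voxel_volume].
#' @param window a [fat_window()]; the default reuses the cardiac window.
#' @return Logical 2-D fat mask.
#' @export
segment_fat_2d <- function(slice, window = fat_window()) {
  stopifnot(inherits(slice, "voxel_volume"), inherits(window, "fat_window"))
  if (length(dim(slice$data)) != 2L)
    stop("segment_fat_2d expects a 2-D slice", call. = FALSE)
  slice$data >= window$lo_hu & slice$data <= window$hi_hu
}

#' Lean-tissue window
#'
#' Default HU window for lean (muscle/soft) tissue, used to derive the lean
#' mask when none is supplied: \[-29, +150\] HU, its floor abutting the fat
#' window ceiling.
#'
#' @param lo_hu,hi_hu window bounds in HU.
#' @return A `fat_window`-style list reused for lean tissue.
#' @export
lean_window <- function(lo_hu = -29, hi_hu = 150) fat_window(lo_hu, hi_hu)

#' Separate visceral from subcutaneous fat (inside-lean-tissue filter)
#'
#' The lean mask is morphologically closed (default 5 mm, bridging small
#' wall gaps), and the region enclosed by it is found by filling the
#' non-lean background from the image border: background pixels connected
#' to the border (face connectivity) are "outside"; everything else is the
#' enclosed interior. Fat pixels in the interior are visceral (VAT); all
#' other fat pixels - including any covered by the closed wall itself - are
#' subcutaneous (SAT). An open wall whose gap exceeds the closing diameter
#' encloses nothing, so all fat becomes SAT.
#'
#' @param fat_mask logical 2-D fat mask.
#' @param lean_mask logical 2-D lean-tissue mask.
#' @param spacing pixel spacing in mm.
#' @param closing_mm radius of the morphological closing applied to the lean
#'   mask before filling.
#' @return List of two disjoint logical masks, `vat` and `sat`, whose union
#'   is `fat_mask`.
#' @export
separate_vat_sat <- function(fat_mask, lean_mask, spacing, closing_mm = 5) {
  fat_mask <- as_binary_mask(fat_mask)
  lean_mask <- as_binary_mask(lean_mask)
  check_aligned(dim(fat_mask), lean_mask)
  stopifnot(closing_mm >= 0)
  closed <- if (closing_mm > 0 && any(lean_mask))
    close_mm(lean_mask, spacing, closing_mm) else lean_mask
  bg <- !closed
  lab <- label_components(bg, connectivity = "face")
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  interior <- bg & !(lab %in% border_labels)
  dim(interior) <- dim(fat_mask)
  vat <- fat_mask & interior
  list(vat = vat, sat = fat_mask & !vat)
}

#' Quantify abdominal fat on one slice
#'
#' Thresholds fat, separates VAT from SAT with the inside-lean-tissue
#' filter, and reports areas (cm^2) and median attenuations (HU). When no
#' lean mask is given, one is derived by thresholding the slice with
#' [lean_window()]. Empty depots report area 0 and a missing (`NA`) median.
#'
#' @param slice a 2-D [voxel_volume].
#' @param fat_win a [fat_window()].
#' @param lean_mask optional logical 2-D lean mask.
#' @param closing_mm closing radius passed to [separate_vat_sat()].
#' @return An `abdominal_measurement`: list with `vat_area_cm2`,
#'   `sat_area_cm2`, `vat_median_hu`, `sat_median_hu`, plus the `vat` and
#'   `sat` masks.
#' @export
quantify_abdominal <- function(slice, fat_win = fat_window(),
                               lean_mask = NULL, closing_mm = 5) {
  stopifnot(inherits(slice, "voxel_volume"))
  fat <- segment_fat_2d(slice, fat_win)
  if (is.null(lean_mask)) {
    lw <- lean_window()
    lean_mask <- slice$data >= lw$lo_hu & slice$data <= lw$hi_hu
  }
  parts <- separate_vat_sat(fat, lean_mask, slice$spacing, closing_mm)
  med <- function(m) if (any(m)) stats::median(slice$data[m]) else NA_real_
  structure(list(vat_area_cm2 = compute_area_cm2(parts$vat, slice$spacing),
                 sat_area_cm2 = compute_area_cm2(parts$sat, slice$spacing),
                 vat_median_hu = med(parts$vat),
                 sat_median_hu = med(parts$sat),
                 vat = parts$vat, sat = parts$sat),
            class = "abdominal_measurement")
}

#' @export
print.abdominal_measurement <- function(x, ...) {
  cat("<abdominal_measurement> VAT ", format(x$vat_area_cm2, digits = 5),
      " cm^2 (median ", ifelse(is.na(x$vat_median_hu), "NA",
                               format(x$vat_median_hu, digits = 4)),
      " HU); SAT ", format(x$sat_area_cm2, digits = 5),
      " cm^2 (median ", ifelse(is.na(x$sat_median_hu), "NA",
                               format(x$sat_median_hu, digits = 4)),
      " HU)\n", sep = "")
  invisible(x)
}
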