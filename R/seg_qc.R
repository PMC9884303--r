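#' Quality-check parameters
#'
#' Parameters of the morphological plausibility check for heart
#' segmentations: the heart mask is shrunk by `erode_mm`, reduced to its
#' largest 26-connected component, and grown by `dilate_mm`; any
#' segmentation volume outside the resulting region counts against
#' `cutoff_ml`. Defaults follow the published procedure (15 mm shrinkage,
#' 35 mm growth); the volume cut-off was never published and defaults to
#' 1 ml, chosen so multi-ml spurious blobs flag while intact anatomies do
#' not.
#'
#' @param erode_mm physical erosion distance in mm (> 0).
#' @param dilate_mm physical dilation distance in mm (> `erode_mm`).
#' @param cutoff_ml maximum tolerated volume outside the QC mask (>= 0).
#' @return A `qc_params` list.
#' @export
qc_params <- function(erode_mm = 15, dilate_mm = 35, cutoff_ml = 1.0) {
  stopifnot(erode_mm > 0, dilate_mm > erode_mm, cutoff_ml >= 0)
  structure(list(erode_mm = erode_mm, dilate_mm = dilate_mm,
                 cutoff_ml = cutoff_ml), class = "qc_params")
}

#' Build the plausibility (QC) mask from a heart mask
#'
#' `dilate(largest_component(erode(heart, erode_mm)), dilate_mm)`, with
#' erosion and dilation measured in Euclidean millimetres on the (possibly
#' anisotropic) grid, and components labelled with 26-neighbour
#' connectivity. If erosion empties the mask, an empty mask is returned with
#' attribute `eroded_empty = TRUE` (the caller flags such degenerate
#' geometry rather than erroring).
#'
#' @param heart_mask nonempty logical 3-D mask of the heart (pericardial
#'   interior including chambers).
#' @param spacing voxel spacing in mm.
#' @param params a [qc_params()].
#' @return Logical QC mask with logical attribute `eroded_empty`.
#' @export
build_qc_mask <- function(heart_mask, spacing, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  heart_mask <- as_binary_mask(heart_mask)
  if (!any(heart_mask)) stop("heart mask is empty", call. = FALSE)
  eroded <- erode_mm(heart_mask, spacing, params$erode_mm)
  if (!any(eroded)) {
    out <- array(FALSE, dim = dim(heart_mask))
    attr(out, "eroded_empty") <- TRUE
    return(out)
  }
  core <- largest_component(eroded, connectivity = "full")
  out <- dilate_mm(core, spacing, params$dilate_mm)
  attr(out, "eroded_empty") <- FALSE
  out
}

#' Check a segmentation against the QC mask
#'
#' Computes the volume of the segmentation lying outside the QC mask built
#' from `heart_mask`; the segmentation is flagged as potentially failed when
#' that volume exceeds `cutoff_ml`, or when the heart mask vanished under
#' erosion (an implausible anatomy in itself).
#'
#' @param segmentation logical 3-D mask under scrutiny (typically the same
#'   heart segmentation, possibly corrupted).
#' @param heart_mask logical 3-D heart mask defining the plausible region.
#' @param spacing voxel spacing in mm.
#' @param params a [qc_params()].
#' @return A `qc_report`: list with `outside_volume_ml`, `flagged`,
#'   `eroded_empty`, `cutoff_ml`.
#' @examples
#' ball <- array(FALSE, c(24, 24, 24))
#' ball[(slice.index(ball, 1) - 12)^2 + (slice.index(ball, 2) - 12)^2 +
#'      (slice.index(ball, 3) - 12)^2 <= 8^2] <- TRUE
#' qc_check(ball, ball, c(2, 2, 2), qc_params(4, 10, 0.5))
#' @export
qc_check <- function(segmentation, heart_mask, spacing,
                     params = qc_params()) {
  segmentation <- as_binary_mask(segmentation)
  heart_mask <- as_binary_mask(heart_mask)
  check_aligned(dim(heart_mask), segmentation)
  qc_mask <- build_qc_mask(heart_mask, spacing, params)
  eroded_empty <- isTRUE(attr(qc_mask, "eroded_empty"))
  outside <- compute_volume_ml(segmentation & !qc_mask, spacing)
  structure(list(outside_volume_ml = outside,
                 flagged = outside > params$cutoff_ml || eroded_empty,
                 eroded_empty = eroded_empty,
                 cutoff_ml = params$cutoff_ml),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> outside volume ", format(x$outside_volume_ml, digits = 4),
      " ml (cutoff ", x$cutoff_ml, " ml); ",
      if (x$flagged) "FLAGGED" else "passed",
      if (x$eroded_empty) " [eroded to empty]" else "", "\n", sep = "")
  invisible(x)
}

#' Batch QC over several segmentations
#'
#' @param segmentations named list of logical masks.
#' @param heart_masks named list of heart masks (recycled if length 1).
#' @param spacing voxel spacing in mm.
#' @param params a [qc_params()].
#' @return Data frame `(id, outside_ml, flagged, eroded_empty)`, one row per
#'   segmentation.
#' @export
qc_batch <- function(segmentations, heart_masks, spacing,
                     params = qc_params()) {
  if (length(heart_masks) == 1L)
    heart_masks <- rep(heart_masks, length(segmentations))
  stopifnot(length(heart_masks) == length(segmentations))
  ids <- names(segmentations)
  if (is.null(ids)) ids <- as.character(seq_along(segmentations))
  rows <- lapply(seq_along(segmentations), function(i) {
    rep_i <- qc_check(segmentations[[i]], heart_masks[[i]], spacing, params)
    data.frame(id = ids[i], outside_ml = rep_i$outside_volume_ml,
               flagged = rep_i$flagged, eroded_empty = rep_i$eroded_empty,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
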