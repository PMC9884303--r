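#' Voxel volume container
#'
#' A `voxel_volume` bundles a 2-D or 3-D numeric array of CT attenuation
#' values (Hounsfield units) with its physical voxel spacing in millimetres
#' and an (informational) physical origin. For cardiac stacks reconstructed
#' with overlapping slices, `spacing[3]` must be the inter-slice *increment*
#' (1.5 mm for 3 mm slices at 50 % overlap), not the slice thickness, so
#' that volume integration does not double-count tissue.
#'
#' @param data numeric array, 2-D or 3-D, of attenuation values (HU).
#' @param spacing numeric vector of per-axis voxel spacing in mm; length
#'   must equal the number of array dimensions and all entries must be > 0.
#' @param origin numeric vector of physical offsets in mm (informational).
#' @return An object of class `voxel_volume` with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' vol <- voxel_volume(array(-70, c(4, 4, 4)), spacing = c(1, 1, 1.5))
#' dim(vol$data)
#' @export
voxel_volume <- function(data, spacing, origin = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stop("`data` must be a 2-D or 3-D array", call. = FALSE)
  if (!is.numeric(data))
    stop("`data` must be numeric (HU values)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("`data` must contain only finite HU values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != length(dim(data)) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("`spacing` must be positive, one entry per array dimension",
         call. = FALSE)
  if (is.null(origin)) origin <- rep(0, length(spacing))
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n  HU range [", format(min(x$data)), ", ", format(max(x$data)),
      "]\n", sep = "")
  invisible(x)
}

#' Validate and coerce a binary mask
#'
#' Masks are plain logical arrays aligned to a `voxel_volume` grid. Numeric
#' arrays are accepted when every value is exactly 0 or 1; any other value is
#' an error (a segmentation with stray labels is not silently thresholded).
#'
#' @param x logical or 0/1 numeric array.
#' @return A logical array with the same dimensions.
#' @export
as_binary_mask <- function(x) {
  if (!is.array(x)) stop("mask must be an array", call. = FALSE)
  if (is.logical(x)) {
    if (anyNA(x)) stop("mask must not contain NA", call. = FALSE)
    return(x)
  }
  if (is.numeric(x)) {
    bad <- unique(x[!(x %in% c(0, 1))])
    if (length(bad))
      stop("mask is not binary; offending values: ",
           paste(utils::head(sort(bad), 5), collapse = ", "), call. = FALSE)
    return(array(x == 1, dim = dim(x)))
  }
  stop("mask must be logical or 0/1 numeric", call. = FALSE)
}

# internal: masks and volume must live on the same grid
check_aligned <- function(volume_dim, ..., what = "mask") {
  masks <- list(...)
  for (m in masks) {
    if (!identical(dim(m), as.integer(volume_dim)) &&
        !identical(as.integer(dim(m)), as.integer(volume_dim)))
      stop("alignment error: ", what, " dimensions (",
           paste(dim(m), collapse = "x"), ") do not match volume grid (",
           paste(volume_dim, collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Inter-slice increment of an overlapping-slice reconstruction
#'
#' @param thickness_mm reconstructed slice thickness in mm.
#' @param overlap fractional overlap between consecutive slices (0.5 for
#'   the 3 mm / 50 % protocol, giving a 1.5 mm increment).
#' @return The slice increment in mm.
#' @examples
#' slice_increment(3, 0.5)  # 1.5
#' @export
slice_increment <- function(thickness_mm, overlap = 0.5) {
  stopifnot(thickness_mm > 0, overlap >= 0, overlap < 1)
  thickness_mm * (1 - overlap)
}
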