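#' Cardiac phantom geometry
#'
#' Geometry descriptor for the synthetic thoracic phantom: a pericardial
#' sac modelled as an ellipsoid, heart chambers as a concentric inner
#' ellipsoid, the shell between them painted as epicardial fat. The default
#' grid is 128^3 voxels at 1 x 1 x 1.5 mm (the 1.5 mm axial spacing mirrors
#' 3 mm slices reconstructed at 50 % overlap), and the default shell encloses
#' roughly 105 ml of fat - an adult-scale depot.
#'
#' @param grid_dim integer triple of grid dimensions.
#' @param spacing voxel spacing in mm (dz is the slice increment).
#' @param outer_radii_mm pericardium ellipsoid semi-axes in mm.
#' @param inner_scale chamber ellipsoid semi-axes as a fraction of the outer.
#' @param center_mm ellipsoid centre in mm; default grid centre.
#' @param chest_wall_mm thickness of the chest-wall slabs painted at the
#'   x-extremes of the grid (0 disables them).
#' @return A list of validated shape parameters.
#' @export
cardiac_shape_params <- function(grid_dim = c(128L, 128L, 144L),
                                 spacing = c(1, 1, 1.5),
                                 outer_radii_mm = c(50, 45, 42),
                                 inner_scale = 0.902,
                                 center_mm = NULL,
                                 chest_wall_mm = 12) {
  grid_dim <- as.integer(grid_dim)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_dim) == 3L, all(grid_dim > 0),
            length(spacing) == 3L, all(spacing > 0),
            length(outer_radii_mm) == 3L, all(outer_radii_mm > 0),
            inner_scale > 0, inner_scale < 1, chest_wall_mm >= 0)
  extent <- grid_dim * spacing
  if (is.null(center_mm)) center_mm <- extent / 2
  if (any(center_mm - outer_radii_mm < 0) ||
      any(center_mm + outer_radii_mm > extent))
    stop("invalid geometry: ellipsoid exceeds grid bounds", call. = FALSE)
  if (chest_wall_mm > 0 &&
      (center_mm[1] - outer_radii_mm[1] <= chest_wall_mm ||
       center_mm[1] + outer_radii_mm[1] >= extent[1] - chest_wall_mm))
    stop("invalid geometry: pericardium touches the chest wall slabs",
         call. = FALSE)
  list(grid_dim = grid_dim, spacing = spacing,
       outer_radii_mm = as.numeric(outer_radii_mm),
       inner_radii_mm = as.numeric(outer_radii_mm) * inner_scale,
       center_mm = as.numeric(center_mm), chest_wall_mm = chest_wall_mm)
}

# internal: physical voxel-centre coordinates along one axis
axis_mm <- function(n, dx) (seq_len(n) - 0.5) * dx

# internal: normalised squared ellipsoid coordinate for every voxel
ellipsoid_u <- function(grid_dim, spacing, center, radii) {
  ex <- ((axis_mm(grid_dim[1], spacing[1]) - center[1]) / radii[1])^2
  ey <- ((axis_mm(grid_dim[2], spacing[2]) - center[2]) / radii[2])^2
  ez <- ((axis_mm(grid_dim[3], spacing[3]) - center[3]) / radii[3])^2
  outer(outer(ex, ey, `+`), ez, `+`)
}

#' Generate a synthetic cardiac CT phantom with ground truth
#'
#' Paints a thoracic scene on the grid: lung background (-800 HU), chest
#' wall slabs (+30 HU), chamber blood pool (+40 HU) and an epicardial fat
#' shell at `fat_center_hu`, then adds Gaussian HU noise clipped to
#' \[-1000, 1000\]. Ground truth is computed by exhaustive voxel count on
#' the painted fat label, independent of any HU windowing.
#'
#' @param shape a [cardiac_shape_params()] descriptor.
#' @param noise_sd_hu standard deviation of additive Gaussian HU noise.
#' @param seed integer seed; the phantom is bit-reproducible per seed.
#' @param fat_center_hu mean fat attenuation (must lie in -190..-30).
#' @return A list with `volume` (a [voxel_volume]) and `truth`, the latter
#'   containing `pericardium_mask`, `chamber_mask`, `fat_mask`,
#'   `true_eatv_ml`, `true_eata_hu`, `fat_center_hu`, `noise_sd_hu`.
#' @examples
#' ph <- generate_cardiac_phantom(cardiac_shape_params(grid_dim = c(48, 48, 32),
#'   outer_radii_mm = c(18, 16, 15)), noise_sd_hu = 0, seed = 1)
#' ph$truth$true_eatv_ml
#' @export
generate_cardiac_phantom <- function(shape = cardiac_shape_params(),
                                     noise_sd_hu = 10, seed,
                                     fat_center_hu = -70) {
  stopifnot(noise_sd_hu >= 0, !missing(seed))
  if (fat_center_hu < -190 || fat_center_hu > -30)
    stop("fat_center_hu must lie within the fat window [-190, -30]",
         call. = FALSE)
  gd <- shape$grid_dim; sp <- shape$spacing
  u_out <- ellipsoid_u(gd, sp, shape$center_mm, shape$outer_radii_mm)
  u_in <- ellipsoid_u(gd, sp, shape$center_mm, shape$inner_radii_mm)
  pericardium <- u_out <= 1
  chambers <- u_in <= 1
  fat <- pericardium & !chambers

  hu <- array(-800, dim = gd)  # lung background
  if (shape$chest_wall_mm > 0) {
    x_mm <- axis_mm(gd[1], sp[1])
    wall <- x_mm <= shape$chest_wall_mm |
      x_mm >= gd[1] * sp[1] - shape$chest_wall_mm
    hu[wall, , ] <- 30
  }
  hu[fat] <- fat_center_hu
  hu[chambers] <- 40

  set.seed(as.integer(seed))
  if (noise_sd_hu > 0) {
    hu <- hu + array(rnorm(length(hu), 0, noise_sd_hu), dim = gd)
    hu[hu < -1000] <- -1000
    hu[hu > 1000] <- 1000
  }

  truth <- list(pericardium_mask = pericardium, chamber_mask = chambers,
                fat_mask = fat,
                true_eatv_ml = sum(fat) * prod(sp) / 1000,
                true_eata_hu = if (any(fat)) stats::median(hu[fat]) else NA_real_,
                fat_center_hu = fat_center_hu, noise_sd_hu = noise_sd_hu)
  list(volume = voxel_volume(hu, sp), truth = truth)
}

#' Analytic ellipsoid-shell volume
#'
#' Volume in ml of the shell between two concentric ellipsoids,
#' `4/3 * pi * (a1*b1*c1 - a2*b2*c2) / 1000`; the continuum limit that the
#' discretised phantom fat volume approaches as voxel spacing shrinks.
#'
#' @param outer_radii_mm,inner_radii_mm semi-axes in mm.
#' @return Shell volume in ml.
#' @export
ellipsoid_shell_ml <- function(outer_radii_mm, inner_radii_mm) {
  4 / 3 * pi * (prod(outer_radii_mm) - prod(inner_radii_mm)) / 1000
}

#' Segmentation-failure descriptor
#'
#' @param mode one of `"add_blob"` (spurious material unioned in beyond the
#'   surface), `"delete_wedge"` (material removed at the surface),
#'   `"leak_to_chest_wall"` (a finger of material extending from the surface
#'   towards the chest wall).
#' @param magnitude_ml size of the corruption in ml (> 0).
#' @param offset_mm displacement of added material beyond the mask surface
#'   (>= 0; ignored for `delete_wedge`).
#' @param seed optional integer seed (failure placement is deterministic;
#'   kept for provenance).
#' @return A `failure_spec` list.
#' @export
failure_spec <- function(mode = c("add_blob", "delete_wedge",
                                  "leak_to_chest_wall"),
                         magnitude_ml, offset_mm = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(magnitude_ml > 0, offset_mm >= 0)
  structure(list(mode = mode, magnitude_ml = magnitude_ml,
                 offset_mm = offset_mm, seed = seed),
            class = "failure_spec")
}

# internal: surface anchor voxel of a mask along a signed axis direction
# (axis 1..3, sign +-1): the extreme foreground voxel, ties broken by
# proximity to the mask centroid in the other two dimensions.
surface_anchor <- function(mask, axis = 1L, sign = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  ext <- if (sign > 0) max(idx[, axis]) else min(idx[, axis])
  cand <- idx[idx[, axis] == ext, , drop = FALSE]
  cen <- colMeans(idx)
  others <- setdiff(1:3, axis)
  d2 <- (cand[, others[1]] - cen[others[1]])^2 +
        (cand[, others[2]] - cen[others[2]])^2
  cand[which.min(d2), ]
}

# internal: pick the axis direction with the most room for a ball of radius
# r_mm centred offset_mm beyond the mask surface; NULL if none fits.
blob_placement <- function(mask, spacing, offset_mm, r_mm) {
  extent <- dim(mask) * spacing
  best <- NULL
  for (axis in 1:3) for (sgn in c(1L, -1L)) {
    anchor <- surface_anchor(mask, axis, sgn)
    center <- (anchor - 0.5) * spacing
    center[axis] <- center[axis] + sgn * offset_mm
    slack <- min(center - r_mm, extent - center - r_mm)
    if (is.null(best) || slack > best$slack)
      best <- list(center_mm = center, slack = slack, axis = axis, sgn = sgn)
  }
  if (best$slack < 0) NULL else best
}

#' Inject a controlled segmentation failure
#'
#' Returns a corrupted copy of `mask`; the input is never modified. For
#' `add_blob`, a digital ball of exactly
#' `round(magnitude_ml * 1000 / voxel_volume)` background voxels (nearest to
#' a centre placed `offset_mm` beyond the mask surface along +x) is unioned
#' in, so the volume change matches `magnitude_ml` to within one voxel. For
#' `delete_wedge`, the same count of mask voxels nearest to the surface
#' anchor is removed. For `leak_to_chest_wall`, the blob centre is dragged
#' along +x from the surface so the added material forms a connecting finger.
#'
#' @param mask nonempty logical 3-D mask.
#' @param spec a [failure_spec()].
#' @param spacing voxel spacing in mm.
#' @return The corrupted logical mask.
#' @export
inject_segmentation_failure <- function(mask, spec, spacing) {
  stopifnot(inherits(spec, "failure_spec"))
  mask <- as_binary_mask(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  voxvol <- prod(spacing)
  k <- max(1L, as.integer(round(spec$magnitude_ml * 1000 / voxvol)))
  gd <- dim(mask)
  extent <- gd * spacing

  if (spec$mode == "delete_wedge") {
    anchor <- surface_anchor(mask)
    if (k >= sum(mask))
      stop("cannot delete ", spec$magnitude_ml,
           " ml: mask holds only ", sum(mask) * voxvol / 1000, " ml",
           call. = FALSE)
    idx <- which(mask, arr.ind = TRUE)
    d2 <- ((idx[, 1] - anchor[1]) * spacing[1])^2 +
          ((idx[, 2] - anchor[2]) * spacing[2])^2 +
          ((idx[, 3] - anchor[3]) * spacing[3])^2
    drop_rows <- order(d2, idx[, 1], idx[, 2], idx[, 3])[seq_len(k)]
    out <- mask
    out[idx[drop_rows, , drop = FALSE]] <- FALSE
    return(out)
  }

  # add_blob / leak_to_chest_wall: centre offset_mm beyond the surface,
  # along whichever axis direction leaves the most room for the ball
  r_nominal <- (3 * k * voxvol / (4 * pi))^(1 / 3)
  place <- blob_placement(mask, spacing, spec$offset_mm, r_nominal)
  if (spec$mode == "add_blob" && is.null(place))
    stop("placement error: blob would fall outside the grid", call. = FALSE)
  if (is.null(place))  # leak mode: clamp the centre inside the grid
    place <- local({
      anchor <- surface_anchor(mask)
      center <- pmin(pmax((anchor - 0.5) * spacing +
                            c(spec$offset_mm, 0, 0), r_nominal / 2),
                     extent - r_nominal / 2)
      list(center_mm = center)
    })
  center_mm <- place$center_mm

  dx2 <- (axis_mm(gd[1], spacing[1]) - center_mm[1])^2
  dy2 <- (axis_mm(gd[2], spacing[2]) - center_mm[2])^2
  dz2 <- (axis_mm(gd[3], spacing[3]) - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  bg <- which(!mask)
  if (length(bg) < k)
    stop("placement error: not enough background voxels for the blob",
         call. = FALSE)
  take <- bg[order(d2[bg], bg)[seq_len(k)]]  # exactly k voxels, ties by index
  out <- mask
  out[take] <- TRUE
  out
}

#' Abdominal phantom geometry
#'
#' A single L4-level slice: a central visceral fat disc, a closed lean-tissue
#' wall (abdominal musculature proxy), a subcutaneous fat annulus and air
#' outside. Defaults give a VAT area near 138 cm^2 on a 192 x 192 grid at
#' 1 x 1 mm with 5 mm slice thickness (informational).
#'
#' @param grid_dim integer pair.
#' @param spacing pixel spacing in mm.
#' @param r_vat_mm radius of the visceral fat disc.
#' @param wall_mm inner/outer radii of the lean wall annulus.
#' @param r_sat_mm outer radius of the subcutaneous fat annulus.
#' @param wall_gap_deg angular width (degrees) of a gap cut into the lean
#'   wall; must be 0 when `r_vat_mm > 0` (an open wall with enclosed
#'   visceral fat has no well-defined truth).
#' @param slice_thickness_mm informational slice thickness.
#' @return Validated shape parameter list.
#' @export
abdominal_shape_params <- function(grid_dim = c(192L, 192L),
                                   spacing = c(1, 1),
                                   r_vat_mm = 66.3,
                                   wall_mm = c(66.3, 72),
                                   r_sat_mm = 86,
                                   wall_gap_deg = 0,
                                   slice_thickness_mm = 5) {
  grid_dim <- as.integer(grid_dim); spacing <- as.numeric(spacing)
  stopifnot(length(grid_dim) == 2L, all(grid_dim > 0),
            length(spacing) == 2L, all(spacing > 0),
            r_vat_mm >= 0, length(wall_mm) == 2L, wall_mm[1] < wall_mm[2],
            r_vat_mm <= wall_mm[1], r_sat_mm >= wall_mm[2],
            wall_gap_deg >= 0, wall_gap_deg < 360)
  if (wall_gap_deg > 0 && r_vat_mm > 0)
    stop("invalid geometry: open lean wall with enclosed visceral fat",
         call. = FALSE)
  extent <- grid_dim * spacing
  center <- extent / 2
  if (r_sat_mm >= min(center))
    stop("invalid geometry: phantom exceeds grid bounds", call. = FALSE)
  list(grid_dim = grid_dim, spacing = spacing, center_mm = center,
       r_vat_mm = r_vat_mm, wall_mm = as.numeric(wall_mm),
       r_sat_mm = r_sat_mm, wall_gap_deg = wall_gap_deg,
       slice_thickness_mm = slice_thickness_mm)
}

#' Generate a synthetic abdominal CT slice with ground truth
#'
#' Paints visceral fat (default -88 HU), a lean wall (+40 HU), subcutaneous
#' fat (default -106 HU) and air (-1000 HU), plus clipped Gaussian noise.
#' Truth areas are exhaustive pixel counts times pixel area.
#'
#' @param shape an [abdominal_shape_params()] descriptor.
#' @param noise_sd_hu Gaussian HU noise standard deviation.
#' @param seed integer seed.
#' @param vat_hu,sat_hu painted fat attenuations; the visceral depot is
#'   painted denser (less negative) than the subcutaneous one, as observed
#'   on CT.
#' @return List with `slice` (2-D [voxel_volume]) and `truth`
#'   (`fat_mask`, `lean_wall_mask`, `vat_mask`, `sat_mask`, `true_vat_cm2`,
#'   `true_sat_cm2`, `true_vat_hu`, `true_sat_hu`).
#' @export
generate_abdominal_phantom <- function(shape = abdominal_shape_params(),
                                       noise_sd_hu = 8, seed,
                                       vat_hu = -88, sat_hu = -106) {
  stopifnot(noise_sd_hu >= 0, !missing(seed))
  gd <- shape$grid_dim; sp <- shape$spacing
  x <- axis_mm(gd[1], sp[1]) - shape$center_mm[1]
  y <- axis_mm(gd[2], sp[2]) - shape$center_mm[2]
  r <- sqrt(outer(x^2, y^2, `+`))
  vat <- r <= shape$r_vat_mm
  wall <- r > shape$wall_mm[1] & r <= shape$wall_mm[2]
  if (shape$wall_gap_deg > 0) {
    theta <- atan2(outer(rep(1, length(x)), y), outer(x, rep(1, length(y))))
    wall <- wall & !(abs(theta) <= shape$wall_gap_deg / 2 * pi / 180)
  }
  sat <- r > shape$wall_mm[2] & r <= shape$r_sat_mm

  hu <- array(-1000, dim = gd)
  hu[vat] <- vat_hu
  hu[wall] <- 40
  hu[sat] <- sat_hu
  set.seed(as.integer(seed))
  if (noise_sd_hu > 0) {
    hu <- hu + array(rnorm(length(hu), 0, noise_sd_hu), dim = gd)
    hu[hu < -1000] <- -1000
    hu[hu > 1000] <- 1000
  }
  px_cm2 <- prod(sp) / 100
  truth <- list(fat_mask = vat | sat, lean_wall_mask = wall,
                vat_mask = vat, sat_mask = sat,
                true_vat_cm2 = sum(vat) * px_cm2,
                true_sat_cm2 = sum(sat) * px_cm2,
                true_vat_hu = if (any(vat)) stats::median(hu[vat]) else NA_real_,
                true_sat_hu = if (any(sat)) stats::median(hu[sat]) else NA_real_)
  list(slice = voxel_volume(hu, sp), truth = truth)
}
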