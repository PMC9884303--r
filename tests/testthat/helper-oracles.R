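# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (triple loops, all-pairs scans) so they cannot share a
# defect with the implementation they check.

# naive voxel-by-voxel EAT quantification via explicit loops
naive_quantify_eat <- function(volume, pericardium, chambers, lo, hi) {
  d <- dim(volume$data)
  sel <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (pericardium[i, j, k] && !chambers[i, j, k]) {
      v <- volume$data[i, j, k]
      if (v >= lo && v <= hi) sel[i, j, k] <- TRUE
    }
  }
  hus <- volume$data[sel]
  list(mask = sel,
       volume_ml = sum(sel) * prod(volume$spacing) / 1000,
       median_hu = if (length(hus)) median(hus) else NA_real_,
       voxel_count = sum(sel))
}

# brute-force physical-distance dilation: voxel in result iff some mask
# voxel lies within r mm (pairwise distances)
brute_dilate <- function(mask, spacing, r) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- ((idx[, 1] - i) * spacing[1])^2 + ((idx[, 2] - j) * spacing[2])^2 +
      ((idx[, 3] - k) * spacing[3])^2
    if (min(dd) <= r^2) out[i, j, k] <- TRUE
  }
  out
}

# brute-force erosion: keep mask voxels farther than r mm from any in-grid
# background voxel
brute_erode <- function(mask, spacing, r) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(bg) == 0) return(mask)
  fg <- which(mask, arr.ind = TRUE)
  for (n in seq_len(nrow(fg))) {
    i <- fg[n, 1]; j <- fg[n, 2]; k <- fg[n, 3]
    dd <- ((bg[, 1] - i) * spacing[1])^2 + ((bg[, 2] - j) * spacing[2])^2 +
      ((bg[, 3] - k) * spacing[3])^2
    if (min(dd) > r^2) out[i, j, k] <- TRUE
  }
  out
}

# exhaustive all-pairs Kendall statistic with tau-b tie correction
kendall_allpairs <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  list(S = S, tau = S / sqrt((n0 - n1) * (n0 - n2)))
}

# closed-form OLS through the normal equations
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# digital ball fixture (physical mm radius on a spacing grid)
make_ball <- function(dims, center_vox, r_mm, spacing) {
  cx <- (center_vox - 0.5) * spacing
  x <- ((seq_len(dims[1]) - 0.5) * spacing[1] - cx[1])^2
  y <- ((seq_len(dims[2]) - 0.5) * spacing[2] - cx[2])^2
  z <- ((seq_len(dims[3]) - 0.5) * spacing[3] - cx[3])^2
  outer(outer(x, y, `+`), z, `+`) <= r_mm^2
}

# small cardiac phantom parameters for fast tests
small_cardiac <- function(grid = c(64L, 64L, 48L), radii = c(18, 16, 15),
                          spacing = c(1, 1, 1.5)) {
  cardiac_shape_params(grid_dim = grid, spacing = spacing,
                       outer_radii_mm = radii, chest_wall_mm = 4)
}

# group specs with arbitrary sizes but default marginals
sized_specs <- function(n_ngt, n_ifg = 0, n_igt = 0, n_cgi = 0, n_t2d = 0) {
  sp <- default_group_specs()
  sizes <- c(NGT = n_ngt, IFG = n_ifg, IGT = n_igt, CGI = n_cgi, T2D = n_t2d)
  for (g in names(sizes)) sp[[g]]$n <- as.integer(sizes[[g]])
  sp
}
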