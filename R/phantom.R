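# Synthetic CT phantom of a directional lead with known ground-truth
# orientation. The phantom models artifact phenomenology (angular HU
# patterns), not CT physics: a hyperdense shaft and windowed marker band, a
# 180-degree-periodic hypodense marker streak pattern with a first-harmonic
# intensity asymmetry, and a 120-degree-periodic one-sided dark-star pattern
# at the directional contact levels, plus seeded Gaussian HU noise.

#' Specify a synthetic lead phantom
#'
#' The marker band is a metal annulus with an angular window (absent metal) of
#' `window_angle_deg` centred opposite the facing direction, so the centre of
#' mass of the thresholded metal shifts *towards* the true orientation.
#' `A1_HU` is the first-harmonic brightness asymmetry of the marker artifact
#' (brighter towards the facing direction), `A2_HU` the depth of the two
#' marker dark streaks (at facing and facing + 180), and `A3_HU` the depth of
#' the three one-sided dark-star streaks at the inter-segment gap bearings
#' (facing + 60 + 120 m). Setting `window_angle_deg = 0` together with
#' `A1_HU = A3_HU = 0` produces a perfectly 180-degree-symmetric lead whose
#' ambiguity is genuinely unresolvable.
#'
#' @param yaw_true_deg ground-truth facing direction, degrees in (-180, 180],
#'   0 = anterior, counterclockwise from superior.
#' @param polar_deg tilt of the lead axis away from scanner z, `[0, 90)`.
#' @param tilt_azimuth_deg world bearing of the tilt (degrees from +x towards
#'   +y).
#' @param noise_sigma_HU standard deviation of i.i.d. Gaussian HU noise.
#' @param seed RNG seed for the noise (volumes are bit-reproducible).
#' @param voxel_mm isotropic voxel size.
#' @param volume_extent_mm world extents (x, y, z) of the volume, centred on
#'   the origin.
#' @param tip_world world position of the lead tip.
#' @param background_HU soft-tissue background value.
#' @param metal_HU metal value (must exceed the 2000 HU binarization
#'   threshold).
#' @param window_angle_deg angular width of the marker window, `[0, 180)`.
#' @param A1_HU,A2_HU,A3_HU artifact amplitudes, see above.
#' @param streak_sigma_deg angular Gaussian width of every dark streak.
#' @param artifact_radius_mm radius at which artifact intensity peaks.
#' @param artifact_radial_sigma_mm radial Gaussian width of the artifact
#'   annulus.
#' @param marker_axial_sigma_mm axial Gaussian envelope of the marker
#'   artifact.
#' @param star_axial_sigma_mm axial Gaussian envelope of each dark-star
#'   level.
#' @param core_radius_mm radius of the central stylet, metal regardless of the
#'   marker window.
#' @param shaft_extra_mm metal shaft continuation above the marker band.
#' @param smooth_sigma_mm optional 3D Gaussian smoothing (reconstruction-
#'   kernel stand-in); 0 disables.
#' @param lead a [lead_spec()] shared with the detector.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(yaw_true_deg = 0,
                         polar_deg = 0,
                         tilt_azimuth_deg = 0,
                         noise_sigma_HU = 15,
                         seed = 1L,
                         voxel_mm = 0.5,
                         volume_extent_mm = c(40, 40, 50),
                         tip_world = c(0, 0, -15),
                         background_HU = 40,
                         metal_HU = 3000,
                         window_angle_deg = 90,
                         A1_HU = 60,
                         A2_HU = 150,
                         A3_HU = 100,
                         streak_sigma_deg = 10,
                         artifact_radius_mm = 3,
                         artifact_radial_sigma_mm = 1.5,
                         marker_axial_sigma_mm = 1.5,
                         star_axial_sigma_mm = 1.0,
                         core_radius_mm = 0.2,
                         shaft_extra_mm = 5,
                         smooth_sigma_mm = 0,
                         lead = lead_spec()) {
  if (metal_HU <= 2000)
    stop_dbso("validation", "metal_HU must exceed the 2000 HU binarization threshold")
  if (background_HU >= 1000)
    stop_dbso("validation", "background_HU must be below 1000")
  if (window_angle_deg < 0 || window_angle_deg >= 180)
    stop_dbso("validation", "window_angle_deg must lie in [0, 180)")
  if (any(c(A1_HU, A2_HU, A3_HU) < 0) || noise_sigma_HU < 0)
    stop_dbso("validation", "amplitudes and noise sigma must be nonnegative")
  if (voxel_mm <= 0 || any(volume_extent_mm <= 0))
    stop_dbso("validation", "voxel size and volume extent must be positive")
  if (polar_deg < 0 || polar_deg >= 90)
    stop_dbso("validation", "polar_deg must lie in [0, 90)")
  spec <- as.list(environment())
  spec$yaw_true_deg <- wrap_pm180(yaw_true_deg)
  structure(spec, class = "phantom_spec")
}

# lead axis unit vector and in-plane frame of a phantom
phantom_axis <- function(spec) {
  p <- deg2rad(spec$polar_deg); az <- deg2rad(spec$tilt_azimuth_deg)
  u <- c(sin(p) * cos(az), sin(p) * sin(az), cos(p))
  c(list(u = u), lead_frame(u))
}

#' Evaluate the noise-free phantom HU field at world points
#'
#' Deterministic closed-form field underlying [generate_phantom()]; exposed so
#' tests can compare against analytic values. Metal regions evaluate exactly
#' to `metal_HU`; elsewhere the value is the background plus the artifact
#' terms.
#'
#' @param spec a [phantom_spec()].
#' @param xyz world point (length 3) or n x 3 matrix.
#' @return HU value(s).
#' @export
hu_field <- function(spec, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  ax <- phantom_axis(spec)
  dx <- xyz[, 1] - spec$tip_world[1]
  dy <- xyz[, 2] - spec$tip_world[2]
  dz <- xyz[, 3] - spec$tip_world[3]
  t <- dx * ax$u[1] + dy * ax$u[2] + dz * ax$u[3]
  rx <- dx - t * ax$u[1]; ry <- dy - t * ax$u[2]; rz <- dz - t * ax$u[3]
  r <- sqrt(rx^2 + ry^2 + rz^2)
  lead <- spec$lead
  mc <- lead$tip_to_marker_center_mm
  hl <- lead$marker_half_length_mm
  shaft_top <- mc + hl + spec$shaft_extra_mm
  yaw <- spec$yaw_true_deg
  # minimal angular distance to a bearing, degrees
  angd <- function(phi, b) {
    d <- (phi - b) %% 360
    far <- d > 180
    d[far] <- 360 - d[far]
    d
  }

  out <- rep(spec$background_HU, length(t))
  # artifact terms are negligible outside the annular envelope; restrict work
  near <- which(r < spec$artifact_radius_mm +
                  4 * spec$artifact_radial_sigma_mm & t > -4 & t < shaft_top + 4)
  if (length(near)) {
    tn <- t[near]; rn <- r[near]
    phi <- rad2deg(atan2(
      rx[near] * ax$e2[1] + ry[near] * ax$e2[2] + rz[near] * ax$e2[3],
      rx[near] * ax$e1[1] + ry[near] * ax$e1[2] + rz[near] * ax$e1[3]))
    s2 <- 2 * spec$streak_sigma_deg^2
    env_rad <- exp(-(rn - spec$artifact_radius_mm)^2 /
                     (2 * spec$artifact_radial_sigma_mm^2))
    # marker artifact: two dark streaks on the facing axis + first-harmonic
    # brightness asymmetry, under a shared axial/radial envelope
    env_mark <- exp(-(tn - mc)^2 / (2 * spec$marker_axial_sigma_mm^2)) * env_rad
    acc <- env_mark *
      (spec$A1_HU * cos(deg2rad(phi - yaw)) -
         spec$A2_HU * (exp(-angd(phi, yaw)^2 / s2) +
                         exp(-angd(phi, yaw + 180)^2 / s2)))
    # one-sided dark star at each directional level
    star_ang <- 0
    for (m in 0:2)
      star_ang <- star_ang +
        exp(-angd(phi, yaw + lead$star_gap_offset_deg + 60 + 120 * m)^2 / s2)
    for (tl in lead$tip_to_directional_levels_mm)
      acc <- acc - spec$A3_HU *
        exp(-(tn - tl)^2 / (2 * spec$star_axial_sigma_mm^2)) *
        env_rad * star_ang
    out[near] <- out[near] + acc

    in_marker <- abs(tn - mc) <= hl
    in_window <- in_marker & rn > spec$core_radius_mm &
      angd(phi, yaw + 180) <= spec$window_angle_deg / 2
    metal <- tn >= 0 & tn <= shaft_top & rn <= lead$shaft_radius_mm & !in_window
    out[near][metal] <- spec$metal_HU
  }
  out
}

#' Generate a synthetic phantom CT volume
#'
#' Evaluates [hu_field()] at every voxel centre of a volume centred on the
#' world origin and adds seeded Gaussian noise. The global RNG state is left
#' untouched.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `ct` (a [ct_volume()]) and `truth` (ground-truth
#'   record: `yaw_true_deg`, `polar_deg`, `tilt_azimuth_deg`, `tip_world`,
#'   `unit_dir`, `marker_center_world`, `candidate_pair`, `voxel_mm`, `seed`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- round(spec$volume_extent_mm / spec$voxel_mm)
  origin <- -(dims - 1) * spec$voxel_mm / 2
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  affine[1:3, 4] <- origin
  ax <- phantom_axis(spec)
  mc_world <- spec$tip_world + spec$lead$tip_to_marker_center_mm * ax$u
  half <- spec$volume_extent_mm / 2
  for (p in list(spec$tip_world, mc_world))
    if (any(abs(p) > half))
      stop_dbso("geometry", "lead (tip to marker) does not fit inside the volume")

  xs <- origin[1] + (seq_len(dims[1]) - 1) * spec$voxel_mm
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spec$voxel_mm
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spec$voxel_mm
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  vals <- hu_field(spec, pts)
  # CT voxels are volume averages, not point samples: anti-alias the sharp
  # metal boundary by averaging the field over a 3x3x3 sub-voxel grid wherever
  # a voxel can straddle the metal edge. Partial-volume mass at the windowed
  # marker is the very signal the COM methods measure.
  dxp <- pts[, 1] - spec$tip_world[1]
  dyp <- pts[, 2] - spec$tip_world[2]
  dzp <- pts[, 3] - spec$tip_world[3]
  tl <- dxp * ax$u[1] + dyp * ax$u[2] + dzp * ax$u[3]
  rl <- sqrt(pmax(0, dxp^2 + dyp^2 + dzp^2 - tl^2))
  shaft_top <- spec$lead$tip_to_marker_center_mm +
    spec$lead$marker_half_length_mm + spec$shaft_extra_mm
  h <- spec$voxel_mm
  edge <- which(rl < spec$lead$shaft_radius_mm + h &
                  tl > -h & tl < shaft_top + h)
  if (length(edge)) {
    off <- c(-h / 3, 0, h / 3)
    acc <- numeric(length(edge))
    sub <- expand.grid(off, off, off)
    for (s in seq_len(nrow(sub)))
      acc <- acc + hu_field(spec, cbind(pts[edge, 1] + sub[s, 1],
                                        pts[edge, 2] + sub[s, 2],
                                        pts[edge, 3] + sub[s, 3]))
    vals[edge] <- acc / nrow(sub)
  }
  vox <- array(vals, dim = dims)
  if (spec$noise_sigma_HU > 0 || spec$smooth_sigma_mm > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(spec$seed)
    if (spec$noise_sigma_HU > 0)
      vox <- vox + array(stats::rnorm(prod(dims), 0, spec$noise_sigma_HU),
                         dim = dims)
    if (spec$smooth_sigma_mm > 0)
      vox <- gaussian_smooth3(vox, spec$smooth_sigma_mm / spec$voxel_mm)
  }
  truth <- list(
    yaw_true_deg = spec$yaw_true_deg,
    polar_deg = spec$polar_deg,
    tilt_azimuth_deg = spec$tilt_azimuth_deg,
    tip_world = spec$tip_world,
    unit_dir = ax$u,
    marker_center_world = mc_world,
    candidate_pair = c(norm_deg180(spec$yaw_true_deg),
                       norm_deg180(spec$yaw_true_deg) + 180),
    voxel_mm = spec$voxel_mm,
    seed = spec$seed
  )
  list(ct = ct_volume(vox, affine), truth = truth)
}

# separable 3D Gaussian smoothing, sigma in voxels, truncated at 3 sigma
gaussian_smooth3 <- function(vox, sigma_vox) {
  if (sigma_vox <= 0) return(vox)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(-half:half)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    for (off in -half:half) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      sl <- switch(axis, a[idx, , ], a[, idx, ], a[, , idx])
      out <- out + k[off + half + 1] * sl
    }
    out
  }
  for (axis in 1:3) vox <- smooth_axis(vox, axis)
  vox
}

#' Define the standard phantom suite
#'
#' The default suite spans the full yaw circle in 15-degree steps crossed with
#' polar angles 0, 15, 30 and 45 degrees (96 phantoms), at the default noise
#' level (sigma 15 HU) and voxel size (0.5 mm), with `seed = seed_base +
#' index - 1` so regeneration is deterministic.
#'
#' @param yaw_deg,polar_deg grids of ground-truth yaw and polar angles.
#' @param noise_sigma_HU noise level shared by all phantoms.
#' @param voxel_mm voxel size shared by all phantoms.
#' @param seed_base offset added to the 0-based phantom index to form seeds.
#' @param ... further arguments passed to every [phantom_spec()].
#' @return A list of `phantom_spec`s (length `length(yaw) * length(polar)`),
#'   yaw varying fastest.
#' @export
phantom_suite <- function(yaw_deg = seq(0, 345, by = 15),
                          polar_deg = c(0, 15, 30, 45),
                          noise_sigma_HU = 15,
                          voxel_mm = 0.5,
                          seed_base = 0L,
                          ...) {
  specs <- list()
  i <- 0L
  for (pol in polar_deg) {
    for (yaw in yaw_deg) {
      specs[[i + 1L]] <- phantom_spec(
        yaw_true_deg = yaw, polar_deg = pol,
        noise_sigma_HU = noise_sigma_HU, voxel_mm = voxel_mm,
        seed = as.integer(seed_base + i), ...)
      i <- i + 1L
    }
  }
  specs
}

#' Write a phantom to disk
#'
#' Saves the volume as NIfTI and the ground-truth record as JSON; both files
#' are deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @param nifti_path output NIfTI path.
#' @param truth_path output truth JSON path; default replaces the NIfTI
#'   extension with `.json`.
#' @return the truth record, invisibly.
#' @export
write_phantom <- function(spec, nifti_path,
                          truth_path = sub("\\.nii(\\.gz)?$", ".json",
                                           nifti_path)) {
  ph <- generate_phantom(spec)
  save_nifti(ph$ct, nifti_path)
  jsonlite::write_json(ph$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(ph$truth)
}
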