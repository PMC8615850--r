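# Angular intensity profiles around the lead, automatic artifact-slice
# selection, candidate orientations from the 180-degree-periodic marker
# streaks, and the dark-star similarity score.

#' Sample an angular intensity profile around the lead
#'
#' HU values are sampled on a circle of radius `radius_mm` lying in the plane
#' perpendicular to the (refined) lead axis. Angle 0 is the in-plane
#' projection of world anterior; angles increase counterclockwise viewed from
#' superior. Sampling perpendicular to the lead axis (rather than on native
#' axial slices) makes the measured angle independent of the polar tilt, so no
#' trigonometric correction is needed afterwards.
#'
#' @param ct a [ct_volume()].
#' @param traj lead [make_trajectory()].
#' @param center world point at the centre of the circle (on the lead axis).
#' @param radius_mm circle radius; must exceed the shaft radius.
#' @param n_angles number of equally spaced samples over `[0, 360)` degrees.
#' @return An object of class `angular_profile`: `angles_deg`,
#'   `intensities_HU`, `radius_mm`, `center_world` and the in-plane frame
#'   `e1`, `e2`.
#' @export
angular_profile <- function(ct, traj, center, radius_mm = 3,
                            n_angles = 360) {
  fr <- lead_frame(traj$unit_dir)
  a_deg <- (seq_len(n_angles) - 1) * 360 / n_angles
  a <- deg2rad(a_deg)
  pts <- cbind(
    center[1] + radius_mm * (cos(a) * fr$e1[1] + sin(a) * fr$e2[1]),
    center[2] + radius_mm * (cos(a) * fr$e1[2] + sin(a) * fr$e2[2]),
    center[3] + radius_mm * (cos(a) * fr$e1[3] + sin(a) * fr$e2[3])
  )
  structure(
    list(angles_deg = a_deg,
         intensities_HU = sample_trilinear(ct, pts),
         radius_mm = radius_mm,
         center_world = as.numeric(center),
         e1 = fr$e1, e2 = fr$e2),
    class = "angular_profile"
  )
}

#' Pooled marker angular profile
#'
#' Averages [angular_profile()]s over a small slab of axial offsets around the
#' (auto-selected) marker centre and over neighbouring sampling radii. The
#' marker artifact extends over the marker band and an annular envelope, so
#' pooling keeps most of its amplitude while averaging down uncorrelated HU
#' noise; the harmonic phase (and hence the candidate bearing) gains roughly
#' the square root of the number of effectively independent circles in
#' precision.
#'
#' @inheritParams angular_profile
#' @param cfg a [detect_config()]; `profile_slab_half_mm`,
#'   `profile_slab_step_mm` and `profile_radii_delta_mm` control the pooling.
#' @return An `angular_profile` whose intensities are the pooled average.
#' @export
marker_profile <- function(ct, traj, center, cfg = detect_config()) {
  offs <- seq(-cfg$profile_slab_half_mm, cfg$profile_slab_half_mm,
              by = cfg$profile_slab_step_mm)
  acc <- NULL
  k <- 0
  for (t in offs) {
    for (dr in cfg$profile_radii_delta_mm) {
      p <- angular_profile(ct, traj, center + t * traj$unit_dir,
                           radius_mm = cfg$profile_radius_mm + dr,
                           n_angles = cfg$n_angles)
      acc <- if (is.null(acc)) p else {
        acc$intensities_HU <- acc$intensities_HU + p$intensities_HU
        acc
      }
      k <- k + 1
    }
  }
  acc$intensities_HU <- acc$intensities_HU / k
  acc$radius_mm <- cfg$profile_radius_mm
  acc$center_world <- as.numeric(center)
  acc
}

# complex circular harmonic sum c_m = sum I_k exp(i m a_k);
# amplitude 2|c_m|/n, phase arg(c_m)
harmonic <- function(profile, m) {
  a <- deg2rad(profile$angles_deg)
  z <- sum(profile$intensities_HU * exp(1i * m * a))
  list(z = z, amplitude = 2 * Mod(z) / length(a))
}

#' Candidate orientations from the marker streak artifact
#'
#' The hypodense marker streaks are 180-degree periodic, so their axis is read
#' off the phase of the second circular Fourier harmonic of the angular
#' profile: with `c2 = sum I(a_k) exp(2i a_k)`, the dark-streak axis is
#' `arg(-c2)/2` (the angle pair where intensity is lowest in the
#' 180-degree-periodic component). This gives sub-degree resolution and is
#' invariant to any constant offset, first-harmonic asymmetry, or affine
#' intensity rescaling of the profile. The facing candidate is the streak axis
#' plus the profile's streak-to-face offset; the inverse partner lies exactly
#' 180 degrees away.
#'
#' @param profile marker-level [angular_profile()].
#' @param spec a [lead_spec()] (supplies `marker_streak_offset_deg`).
#' @param cfg a [detect_config()]; `min_amplitude_HU` gates artifact absence.
#' @return An object of class `candidate_pair`: `theta_deg` in `[0, 180)`,
#'   `partner_deg = theta_deg + 180`, `second_harmonic_amplitude` (HU) and
#'   `quality` (amplitude over residual RMS after removing harmonics 0-2).
#' @export
candidate_orientations <- function(profile, spec = lead_spec(),
                                   cfg = detect_config()) {
  h2 <- harmonic(profile, 2)
  if (h2$amplitude < cfg$min_amplitude_HU)
    stop_dbso("no_artifact",
              sprintf("second-harmonic amplitude %.2f HU below %.2f HU: no usable marker artifact (polar angle too large or wrong level?)",
                      h2$amplitude, cfg$min_amplitude_HU))
  theta_streak <- norm_deg180(rad2deg(Arg(-h2$z)) / 2)
  theta <- norm_deg180(theta_streak + spec$marker_streak_offset_deg)
  # residual after removing harmonics 0..2 on the regular grid
  a <- deg2rad(profile$angles_deg)
  ii <- profile$intensities_HU
  fit <- rep(mean(ii), length(ii))
  for (m in 1:2) {
    cm <- cos(m * a); sm <- sin(m * a)
    fit <- fit + (2 / length(a)) * (sum(ii * cm) * cm + sum(ii * sm) * sm)
  }
  rms <- sqrt(mean((ii - fit)^2))
  structure(
    list(theta_deg = theta,
         partner_deg = theta + 180,
         second_harmonic_amplitude = h2$amplitude,
         quality = h2$amplitude / max(rms, 1e-9)),
    class = "candidate_pair"
  )
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat(sprintf("<candidate_pair> %.2f / %.2f deg (amplitude %.1f HU, quality %.2f)\n",
              x$theta_deg, x$partner_deg, x$second_harmonic_amplitude, x$quality))
  invisible(x)
}

# shared axial search: scan offsets along the lead axis around center0 and
# return the offset maximizing the m-th harmonic amplitude of the profile.
select_artifact_slice <- function(ct, traj, center0, cfg, m) {
  offs <- seq(-cfg$slice_search_mm, cfg$slice_search_mm,
              by = cfg$slice_search_step_mm)
  offs <- offs[order(abs(offs))]  # ties break towards offset 0
  amps <- vapply(offs, function(t) {
    ctr <- center0 + t * traj$unit_dir
    prof <- angular_profile(ct, traj, ctr, radius_mm = cfg$profile_radius_mm,
                            n_angles = cfg$n_angles)
    harmonic(prof, m)$amplitude
  }, numeric(1))
  best <- which.max(amps)
  if (amps[best] < cfg$min_amplitude_HU)
    stop_dbso("no_artifact",
              sprintf("no axial offset within +/- %.2f mm reaches harmonic-%d amplitude %.2f HU",
                      cfg$slice_search_mm, m, cfg$min_amplitude_HU))
  if (abs(abs(offs[best]) - cfg$slice_search_mm) < 1e-9)
    warn_dbso("truncated_search",
              "artifact amplitude still increasing at the slice-search boundary")
  list(center_world = center0 + offs[best] * traj$unit_dir,
       offset_mm = offs[best], amplitude = amps[best])
}

#' Auto-select the marker artifact slice
#'
#' Scans axial offsets of `slice_search_mm` (default +/- 1.5 mm in 0.25 mm
#' steps) along the lead axis around the nominal marker centre and returns the
#' position where the 180-degree-periodic streak artifact is most visible,
#' i.e. where the second-harmonic amplitude of the angular profile peaks.
#'
#' @param ct a [ct_volume()].
#' @param traj refined trajectory.
#' @param spec a [lead_spec()].
#' @param cfg a [detect_config()].
#' @return world point of the selected marker centre, with attributes
#'   `offset_mm` and `amplitude`.
#' @export
select_marker_slice <- function(ct, traj, spec = lead_spec(),
                                cfg = detect_config()) {
  sel <- select_artifact_slice(ct, traj, level_center(traj, spec, "marker"),
                               cfg, m = 2)
  structure(sel$center_world, offset_mm = sel$offset_mm,
            amplitude = sel$amplitude)
}

#' Auto-select a dark-star artifact slice
#'
#' Same axial search as [select_marker_slice()], at a directional contact
#' level, maximizing the amplitude of the third circular harmonic (the
#' dark-star streak pattern is 120-degree periodic).
#'
#' @inheritParams select_marker_slice
#' @param level 1-based directional level index.
#' @return world point of the selected slice centre, with attributes
#'   `offset_mm` and `amplitude`.
#' @export
select_star_slice <- function(ct, traj, spec = lead_spec(), level = 1,
                              cfg = detect_config()) {
  sel <- select_artifact_slice(ct, traj, level_center(traj, spec, level),
                               cfg, m = 3)
  structure(sel$center_world, offset_mm = sel$offset_mm,
            amplitude = sel$amplitude)
}

#' Dark-star streak similarity score
#'
#' For a hypothesised facing direction `theta`, the three one-sided dark-star
#' streaks are expected at bearings `theta + star_gap_offset + 60 + 120 m`
#' degrees (m = 0, 1, 2, the inter-segment gaps). The score is the mean
#' profile intensity minus the mean intensity inside windows of half-width
#' `star_window_deg` centred on those bearings, normalized by the profile
#' standard deviation: expected streaks that are indeed darker than average
#' yield a larger score. The score is exactly 120-degree periodic in `theta`;
#' the two inverse candidates (180 degrees apart) probe bearings offset by 60
#' degrees and therefore separate.
#'
#' @param profile directional-level [angular_profile()].
#' @param theta_deg hypothesised facing bearing (degrees).
#' @param spec a [lead_spec()].
#' @param cfg a [detect_config()].
#' @return dimensionless similarity score (0 for a flat profile).
#' @export
star_similarity <- function(profile, theta_deg, spec = lead_spec(),
                            cfg = detect_config()) {
  sdp <- stats::sd(profile$intensities_HU)
  if (!is.finite(sdp) || sdp < 1e-12) return(0)
  bearings <- theta_deg + spec$star_gap_offset_deg + 60 + 120 * (0:2)
  in_window <- rep(FALSE, length(profile$angles_deg))
  for (b in bearings)
    in_window <- in_window |
      (ang_diff_deg(profile$angles_deg, b) <= cfg$star_window_deg)
  (mean(profile$intensities_HU) - mean(profile$intensities_HU[in_window])) / sdp
}
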