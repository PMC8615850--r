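# Directional-lead geometry, trajectory construction/refinement and the
# polar-angle gate.

#' Directional-lead geometry profile
#'
#' Distances are measured along the lead axis from the tip. The default
#' profile describes a Cartesia-style directional lead: two three-segment
#' directional contact levels below one asymmetric stereotactic marker.
#' Dimensional constants other than the marker half-length are configuration
#' values to be verified against manufacturer documentation before clinical
#' use.
#'
#' @param name profile name.
#' @param tip_to_marker_center_mm distance tip to marker centre (mm).
#' @param tip_to_directional_levels_mm increasing distances from the tip to
#'   the centres of the segmented-contact levels (mm); all below the marker.
#' @param marker_streak_offset_deg angular offset between the dark-streak axis
#'   of the marker artifact and the marker's facing direction (degrees,
#'   normalized to (-180, 180]).
#' @param star_gap_offset_deg angular offset of the first expected dark-star
#'   streak from the facing direction; streaks are expected at
#'   `facing + star_gap_offset + 60 + 120 m` degrees, m = 0, 1, 2.
#' @param shaft_radius_mm metal shaft radius (mm).
#' @param marker_half_length_mm axial half-extent of the marker band (mm).
#' @return An object of class `lead_spec`.
#' @export
lead_spec <- function(name = "cartesia",
                      tip_to_marker_center_mm = 10.6,
                      tip_to_directional_levels_mm = c(2.75, 4.75),
                      marker_streak_offset_deg = 0,
                      star_gap_offset_deg = 0,
                      shaft_radius_mm = 0.65,
                      marker_half_length_mm = 1.5) {
  lv <- as.numeric(tip_to_directional_levels_mm)
  if (length(lv) < 1 || any(diff(lv) <= 0) || any(lv <= 0) ||
      any(lv >= tip_to_marker_center_mm))
    stop_dbso("config",
              "directional levels must be strictly increasing, positive and below the marker centre")
  if (tip_to_marker_center_mm <= 0 || shaft_radius_mm <= 0 ||
      marker_half_length_mm <= 0)
    stop_dbso("config", "lead dimensions must be positive")
  structure(
    list(name = name,
         tip_to_marker_center_mm = tip_to_marker_center_mm,
         tip_to_directional_levels_mm = lv,
         marker_streak_offset_deg = wrap_pm180(marker_streak_offset_deg),
         star_gap_offset_deg = wrap_pm180(star_gap_offset_deg),
         shaft_radius_mm = shaft_radius_mm,
         marker_half_length_mm = marker_half_length_mm),
    class = "lead_spec"
  )
}

#' Load a lead-geometry profile
#'
#' Profiles are YAML files with the fields of [lead_spec()]. `name` may be a
#' profile shipped with the package (`"cartesia"`) or a path to a YAML file.
#'
#' @param name profile name or path.
#' @return A [lead_spec()].
#' @export
load_lead_profile <- function(name = "cartesia") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "leads", paste0(name, ".yaml"),
                package = "dbsorient")
  if (!nzchar(path) || !file.exists(path))
    stop_dbso("config", sprintf("unknown lead profile: %s", name))
  p <- yaml::read_yaml(path)
  lead_spec(name = p$name,
            tip_to_marker_center_mm = p$tip_to_marker_center_mm,
            tip_to_directional_levels_mm = unlist(p$tip_to_directional_levels_mm),
            marker_streak_offset_deg = p$marker_streak_offset_deg %||% 0,
            star_gap_offset_deg = p$star_gap_offset_deg %||% 0,
            shaft_radius_mm = p$shaft_radius_mm,
            marker_half_length_mm = p$marker_half_length_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a trajectory from two points on the lead
#'
#' The direction points from the tip towards the proximal end and is flipped
#' to be superior-pointing so that the polar angle (angle to the scanner
#' z-axis) is well defined in `[0, 90]` degrees.
#'
#' @param tip world coordinates (mm) of the lead tip.
#' @param proximal a second, more proximal world point on the trajectory.
#' @return An object of class `trajectory` with `tip_world`, `unit_dir` and
#'   `polar_deg`.
#' @export
make_trajectory <- function(tip, proximal) {
  tip <- as.numeric(tip); proximal <- as.numeric(proximal)
  d <- proximal - tip
  if (sqrt(sum(d^2)) < 1e-9)
    stop_dbso("degenerate_trajectory", "tip and proximal point coincide")
  u <- .unit(d)
  if (u[3] < 0) u <- -u
  structure(
    list(tip_world = tip, unit_dir = u,
         polar_deg = rad2deg(acos(min(1, max(-1, u[3]))))),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> tip (%.2f, %.2f, %.2f) mm, polar %.2f deg\n",
              x$tip_world[1], x$tip_world[2], x$tip_world[3], x$polar_deg))
  invisible(x)
}

#' World position of a lead level
#'
#' @param traj a [make_trajectory()] result.
#' @param spec a [lead_spec()].
#' @param level `"marker"` or the 1-based index of a directional contact
#'   level.
#' @return world point `tip + d * unit_dir`, where `d` is the profile distance.
#' @export
level_center <- function(traj, spec, level = "marker") {
  d <- if (identical(level, "marker")) {
    spec$tip_to_marker_center_mm
  } else if (is.numeric(level) && length(level) == 1 && level >= 1 &&
             level <= length(spec$tip_to_directional_levels_mm)) {
    spec$tip_to_directional_levels_mm[[level]]
  } else {
    stop_dbso("config", sprintf("unknown lead level: %s", paste(level, collapse = ",")))
  }
  traj$tip_world + d * traj$unit_dir
}

#' Gate a trajectory on its polar angle
#'
#' Marker and star artifacts fade as the angle between the lead and the
#' scanner axis grows: up to 40 degrees detection is reliable (`"ok"`),
#' between 40 and 55 degrees results carry reduced confidence (`"warn"`), and
#' beyond 55 degrees the scan is rejected (`"refuse"`).
#'
#' @param traj a trajectory.
#' @param cfg a [detect_config()].
#' @return `"ok"`, `"warn"` or `"refuse"`.
#' @export
check_polar <- function(traj, cfg = detect_config()) {
  if (traj$polar_deg > cfg$polar_refuse_deg) "refuse"
  else if (traj$polar_deg > cfg$polar_warn_deg) "warn"
  else "ok"
}

#' Refine a lead trajectory from the CT hyperdensity
#'
#' For every native axial slice crossed by the tip-to-marker segment, the
#' centre of mass of suprathreshold (metal) voxels within `roi_radius_mm` of
#' the current trajectory is computed; ordinary least-squares lines x(z) and
#' y(z) are fitted and re-expressed as a tip plus unit direction. The fit is
#' iterated (the ROI follows the line) until the tip moves less than
#' `refine_tol_mm` or `refine_max_iter` is reached.
#'
#' Assumes the third voxel axis is the scanner z-axis (axial acquisition), as
#' is the case for standard postoperative CT.
#'
#' @param ct a [ct_volume()].
#' @param init initial [make_trajectory()] estimate.
#' @param spec a [lead_spec()] (supplies the tip-to-marker span).
#' @param cfg a [detect_config()].
#' @return A refined `trajectory`.
#' @export
refine_trajectory <- function(ct, init, spec = lead_spec(),
                              cfg = detect_config()) {
  traj <- init
  d <- ct$shape
  # world z of each axial slice (assumes axis 3 ~ z)
  kz <- vapply(seq_len(d[3]) - 1,
               function(k) (ct$affine %*% c(0, 0, k, 1))[3], numeric(1))
  # fit on the rotationally symmetric shaft only: the windowed marker band is
  # asymmetric by design and would bias the slice-wise centers of mass
  span_mm <- spec$tip_to_marker_center_mm - spec$marker_half_length_mm - 0.5
  for (iter in seq_len(cfg$refine_max_iter)) {
    z0 <- traj$tip_world[3]
    z1 <- traj$tip_world[3] + span_mm * traj$unit_dir[3]
    zlo <- min(z0, z1); zhi <- max(z0, z1)
    ks <- which(kz >= zlo - 1e-9 & kz <= zhi + 1e-9)
    coms <- matrix(NA_real_, nrow = length(ks), ncol = 3)
    n_ok <- 0
    for (m in seq_along(ks)) {
      k <- ks[m]
      sl <- ct$voxels[, , k]
      idx <- which(sl > cfg$metal_threshold_HU, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      w <- voxel_to_world(ct, cbind(idx[, 1] - 1, idx[, 2] - 1, k - 1))
      # trajectory intersection with this slice plane
      if (abs(traj$unit_dir[3]) < 1e-9) break
      t <- (kz[k] - traj$tip_world[3]) / traj$unit_dir[3]
      ctr <- traj$tip_world + t * traj$unit_dir
      keep <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 <= cfg$roi_radius_mm^2
      if (!any(keep)) next
      n_ok <- n_ok + 1
      coms[m, ] <- c(mean(w[keep, 1]), mean(w[keep, 2]), kz[k])
    }
    coms <- coms[stats::complete.cases(coms), , drop = FALSE]
    if (nrow(coms) < 5)
      stop_dbso("insufficient_artifact",
                sprintf("metal hyperdensity found in only %d slices (need >= 5)",
                        nrow(coms)))
    z <- coms[, 3]
    bx <- stats::lm.fit(cbind(1, z), coms[, 1])$coefficients
    by <- stats::lm.fit(cbind(1, z), coms[, 2])$coefficients
    new_dir <- .unit(c(bx[2], by[2], 1))
    z_tip <- init$tip_world[3]
    new_tip <- c(bx[1] + bx[2] * z_tip, by[1] + by[2] * z_tip, z_tip)
    moved <- sqrt(sum((new_tip - traj$tip_world)^2))
    traj <- make_trajectory(new_tip, new_tip + 10 * new_dir)
    if (moved < cfg$refine_tol_mm) break
  }
  traj
}
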