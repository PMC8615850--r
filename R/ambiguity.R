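# The four methods resolving the 180-degree ambiguity of the symmetric marker
# artifact (COM, COMsagittal, ASM, STARS) and the policy combining them.

method_result <- function(method, chosen_theta_deg, margin, degenerate,
                          details = list()) {
  structure(
    list(method = method,
         chosen_theta_deg = norm_deg360(chosen_theta_deg),
         margin = max(0, margin),
         degenerate = isTRUE(degenerate),
         details = details),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result> %-11s -> %7.2f deg (margin %.3f%s)\n",
              x$method, x$chosen_theta_deg, x$margin,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# binarized center of mass of a resampled slice, in in-plane (u, v) mm;
# returns NULL when no pixel exceeds the threshold
slice_binary_com <- function(slice, threshold) {
  mask <- slice$values > threshold
  if (!any(mask)) return(NULL)
  uu <- matrix(slice$u_mm, nrow = length(slice$u_mm), ncol = length(slice$v_mm))
  vv <- matrix(slice$v_mm, nrow = length(slice$u_mm), ncol = length(slice$v_mm),
               byrow = TRUE)
  c(mean(uu[mask]), mean(vv[mask]))
}

# pooled binarized COM over a stack of perpendicular slices at axial offsets
# t_offsets from `center` (a slab), in in-plane (u, v) mm
slab_binary_com <- function(ct, fr, unit_dir, center, t_offsets, extent_mm,
                            cfg) {
  su <- 0; sv <- 0; n <- 0
  for (t in t_offsets) {
    plane <- plane_spec(center + t * unit_dir, fr$e1, fr$e2,
                        extent_mm = extent_mm,
                        resolution_mm = cfg$resample_res_mm)
    slice <- resample_plane(ct, plane)
    mask <- slice$values > cfg$metal_threshold_HU
    if (!any(mask)) next
    uu <- matrix(slice$u_mm, nrow = length(slice$u_mm),
                 ncol = length(slice$v_mm))
    vv <- matrix(slice$v_mm, nrow = length(slice$u_mm),
                 ncol = length(slice$v_mm), byrow = TRUE)
    su <- su + sum(uu[mask]); sv <- sv + sum(vv[mask]); n <- n + sum(mask)
  }
  if (n == 0) return(NULL)
  c(su, sv) / n
}

#' Center-of-mass (COM) ambiguity method
#'
#' The CT is resampled perpendicular to the lead axis over the marker band
#' (0.1 mm pixels) and binarized at 2000 HU. The asymmetric metal of the
#' stereotactic marker shifts the centre of mass of the thresholded
#' hyperdensity away from the geometric lead centre; the candidate bearing
#' closer to the direction of that shift is chosen.
#'
#' The deviation is measured differentially: the pooled COM of the marker
#' slab minus the mean pooled COM of two reference slabs on the symmetric
#' shaft just below and above the marker. The reference slabs see the same
#' voxel grid and the same residual trajectory error as the marker, so
#' partial-volume bias and small trajectory misalignment cancel and only the
#' marker asymmetry remains.
#'
#' The margin is `|u_hat . d_hat| * |d| / deviation_scale_mm`: alignment of
#' the shift with the chosen bearing, scaled by the shift magnitude. Shifts
#' below `min_deviation_mm` are degenerate.
#'
#' @param ct a [ct_volume()].
#' @param traj refined trajectory.
#' @param marker_center world point of the (auto-selected) marker centre.
#' @param pair a [candidate_orientations()] result.
#' @param spec a [lead_spec()] (marker half-length sets the slab spans).
#' @param cfg a [detect_config()].
#' @return A `method_result`.
#' @export
com_method <- function(ct, traj, marker_center, pair, spec = lead_spec(),
                       cfg = detect_config()) {
  fr <- lead_frame(traj$unit_dir)
  hl <- spec$marker_half_length_mm
  step <- cfg$com_slab_step_mm
  gap <- cfg$com_ref_gap_mm
  span <- cfg$com_ref_span_mm
  ext <- c(cfg$com_extent_mm, cfg$com_extent_mm)
  com_marker <- slab_binary_com(ct, fr, traj$unit_dir, marker_center,
                                seq(-hl, hl, by = step), ext, cfg)
  if (is.null(com_marker))
    stop_dbso("no_marker", "no suprathreshold pixels in the marker slab")
  com_lo <- slab_binary_com(ct, fr, traj$unit_dir, marker_center,
                            seq(-hl - gap - span, -hl - gap, by = step),
                            ext, cfg)
  com_hi <- slab_binary_com(ct, fr, traj$unit_dir, marker_center,
                            seq(hl + gap, hl + gap + span, by = step),
                            ext, cfg)
  ref <- if (!is.null(com_lo) && !is.null(com_hi)) (com_lo + com_hi) / 2
         else com_lo %||% com_hi %||% c(0, 0)
  d <- com_marker - ref
  dn <- sqrt(sum(d^2))
  if (dn < cfg$min_deviation_mm)
    return(method_result("COM", pair$theta_deg, 0, TRUE,
                         details = list(deviation_mm = dn)))
  dhat <- d / dn
  u1 <- c(cos(deg2rad(pair$theta_deg)), sin(deg2rad(pair$theta_deg)))
  s1 <- sum(u1 * dhat)        # partner projects to -s1
  chosen <- if (s1 >= 0) pair$theta_deg else pair$partner_deg
  margin <- abs(s1) * dn / cfg$deviation_scale_mm
  method_result("COM", chosen, margin, margin < cfg$margin_floor,
                details = list(deviation_mm = dn,
                               deviation_bearing_deg =
                                 norm_deg360(rad2deg(atan2(d[2], d[1])))))
}

#' Sagittal center-of-mass (COMsagittal) ambiguity method
#'
#' Instead of a perpendicular slice, an in-line slice containing the lead axis
#' and the candidate axis is resampled (0.1 mm pixels): axially from 1.5 mm
#' below to 1.5 mm above the marker centre (the whole marker band),
#' transversely `comsag_half_width_mm` to either side. After binarization at
#' 2000 HU, the sign of the transverse COM component decides between the
#' candidate (positive side) and its partner. As in [com_method()], the
#' transverse COM component is referenced against the same measurement on the
#' symmetric shaft below and above the marker, cancelling the shared
#' partial-volume bias.
#'
#' @inheritParams com_method
#' @param spec a [lead_spec()] (marker half-length sets the axial span).
#' @return A `method_result`.
#' @export
com_sagittal_method <- function(ct, traj, marker_center, pair,
                                spec = lead_spec(), cfg = detect_config()) {
  fr <- lead_frame(traj$unit_dir)
  th <- deg2rad(pair$theta_deg)
  v1 <- cos(th) * fr$e1 + sin(th) * fr$e2
  hl <- spec$marker_half_length_mm
  inline_vcom <- function(axial_offset, axial_extent) {
    plane <- plane_spec(marker_center + axial_offset * traj$unit_dir,
                        traj$unit_dir, v1,
                        extent_mm = c(axial_extent,
                                      2 * cfg$comsag_half_width_mm),
                        resolution_mm = cfg$resample_res_mm)
    com <- slice_binary_com(resample_plane(ct, plane),
                            cfg$metal_threshold_HU)
    if (is.null(com)) NULL else com[2]
  }
  vm <- inline_vcom(0, 2 * hl)
  if (is.null(vm))
    stop_dbso("no_marker", "no suprathreshold pixels in the in-line marker slice")
  span <- cfg$com_ref_span_mm
  off <- hl + cfg$com_ref_gap_mm + span / 2
  vlo <- inline_vcom(-off, span)
  vhi <- inline_vcom(off, span)
  vref <- if (!is.null(vlo) && !is.null(vhi)) (vlo + vhi) / 2
          else vlo %||% vhi %||% 0
  vcom <- vm - vref
  if (abs(vcom) < cfg$min_deviation_mm)
    return(method_result("COMsagittal", pair$theta_deg, 0, TRUE,
                         details = list(v_com_mm = vcom)))
  chosen <- if (vcom > 0) pair$theta_deg else pair$partner_deg
  margin <- abs(vcom) / cfg$deviation_scale_mm
  method_result("COMsagittal", chosen, margin, margin < cfg$margin_floor,
                details = list(v_com_mm = vcom))
}

#' Asymmetric sampling of the marker (ASM) ambiguity method
#'
#' Intensities within the marker artifact are expected to be greater towards
#' the true orientation, so the heights of the two bright peaks of the angular
#' profile are compared: the peak height for a candidate is the maximum
#' intensity within `asm_peak_window_deg` of its bearing, and the candidate
#' with the higher peak wins. The margin is the peak-height difference in
#' units of the profile standard deviation.
#'
#' @param profile marker-level [angular_profile()] (the same auto-selected
#'   slice used for candidate detection).
#' @param pair a [candidate_orientations()] result.
#' @param cfg a [detect_config()].
#' @return A `method_result`.
#' @export
asm_method <- function(profile, pair, cfg = detect_config()) {
  peak <- function(theta) {
    w <- ang_diff_deg(profile$angles_deg, theta) <= cfg$asm_peak_window_deg
    max(profile$intensities_HU[w])
  }
  h1 <- peak(pair$theta_deg)
  h2 <- peak(pair$partner_deg)
  sdp <- stats::sd(profile$intensities_HU)
  margin <- abs(h1 - h2) / max(sdp, 1e-9)
  chosen <- if (h1 >= h2) pair$theta_deg else pair$partner_deg
  method_result("ASM", chosen, margin, margin < cfg$margin_floor,
                details = list(peak_theta_HU = h1, peak_partner_HU = h2))
}

#' Dark-star streak similarity (STARS) ambiguity method
#'
#' At each directional contact level the slice with the strongest
#' 120-degree-periodic streak pattern is auto-selected, and the
#' [star_similarity()] of both candidate solutions is evaluated and summed
#' across levels. The candidate whose expected streak bearings line up with
#' the observed dark streaks (larger summed score) wins; the margin is the
#' score difference.
#'
#' @inheritParams com_method
#' @param spec a [lead_spec()].
#' @return A `method_result`.
#' @export
stars_method <- function(ct, traj, spec = lead_spec(), pair,
                         cfg = detect_config()) {
  d <- ct$shape
  usable <- Filter(function(lv) {
    v <- world_to_voxel(ct, level_center(traj, spec, lv))
    all(v > -0.5) && all(v < d - 0.5)
  }, seq_along(spec$tip_to_directional_levels_mm))
  if (length(usable) == 0)
    stop_dbso("level_out_of_volume",
              "no directional contact level lies inside the volume")
  s1 <- 0; s2 <- 0; n_found <- 0
  for (lv in usable) {
    center <- tryCatch(
      as.numeric(select_star_slice(ct, traj, spec, lv, cfg)),
      dbsorient_error_no_artifact = function(e) NULL
    )
    if (is.null(center)) next
    n_found <- n_found + 1
    prof <- angular_profile(ct, traj, center,
                            radius_mm = cfg$profile_radius_mm,
                            n_angles = cfg$n_angles)
    s1 <- s1 + star_similarity(prof, pair$theta_deg, spec, cfg)
    s2 <- s2 + star_similarity(prof, pair$partner_deg, spec, cfg)
  }
  if (n_found == 0)
    return(method_result("STARS", pair$theta_deg, 0, TRUE,
                         details = list(score_theta = 0, score_partner = 0,
                                        n_levels = 0)))
  margin <- abs(s1 - s2)
  chosen <- if (s1 >= s2) pair$theta_deg else pair$partner_deg
  method_result("STARS", chosen, margin, margin < cfg$margin_floor,
                details = list(score_theta = s1, score_partner = s2))
}

#' Resolve the 180-degree ambiguity
#'
#' Runs all four methods. The final orientation follows the COM method, which
#' is the most reliable of the four; when COM is degenerate the decision falls
#' back, in order, to COMsagittal, STARS, then ASM, and the result is flagged
#' reduced-confidence. Any non-degenerate method disagreeing with the final
#' choice raises the mismatch flag so the user reviews the case. If all four
#' methods are degenerate the ambiguity is unresolved and an error carrying
#' both candidates is thrown.
#'
#' @inheritParams stars_method
#' @param marker_center world marker centre; auto-selected when `NULL`.
#' @param profile marker-level angular profile; recomputed when `NULL`.
#' @return An object of class `resolution`: `final_theta_deg`, `methods`
#'   (named list of the four `method_result`s), `mismatch`, `confidence`
#'   (`"ok"` or `"reduced"`), `source` (name of the deciding method).
#' @export
resolve <- function(ct, traj, spec = lead_spec(), pair, cfg = detect_config(),
                    marker_center = NULL, profile = NULL) {
  if (is.null(marker_center))
    marker_center <- as.numeric(select_marker_slice(ct, traj, spec, cfg))
  if (is.null(profile))
    profile <- marker_profile(ct, traj, marker_center, cfg)
  methods <- list(
    COM = com_method(ct, traj, marker_center, pair, spec, cfg),
    COMsagittal = com_sagittal_method(ct, traj, marker_center, pair, spec, cfg),
    ASM = asm_method(profile, pair, cfg),
    STARS = stars_method(ct, traj, spec, pair, cfg)
  )
  order <- c("COM", "COMsagittal", "STARS", "ASM")
  deciding <- NULL
  for (m in order) {
    if (!methods[[m]]$degenerate) { deciding <- m; break }
  }
  if (is.null(deciding))
    stop_dbso("unresolved",
              "all four ambiguity methods are degenerate; both solutions remain possible",
              candidates = c(pair$theta_deg, pair$partner_deg))
  final <- methods[[deciding]]$chosen_theta_deg
  mismatch <- any(vapply(methods, function(m)
    !m$degenerate && ang_diff_deg(m$chosen_theta_deg, final) > 1e-6,
    logical(1)))
  structure(
    list(final_theta_deg = final,
         methods = methods,
         mismatch = mismatch,
         confidence = if (deciding == "COM") "ok" else "reduced",
         source = deciding),
    class = "resolution"
  )
}

#' @export
print.resolution <- function(x, ...) {
  cat(sprintf("<resolution> final %.2f deg (%s, confidence %s%s)\n",
              x$final_theta_deg, x$source, x$confidence,
              if (x$mismatch) ", MISMATCH" else ""))
  for (m in x$methods) print(m)
  invisible(x)
}
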