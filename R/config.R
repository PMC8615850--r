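#' Detection configuration
#'
#' Collects every tunable threshold of the pipeline in one place. Defaults
#' follow the published procedure where one is stated (binarization threshold
#' 2000 HU, 0.1 mm resampling, polar-angle gates at 40 and 55 degrees); the
#' remainder are documented package choices.
#'
#' @param metal_threshold_HU binarization threshold separating metal
#'   hyperdensity from tissue (HU).
#' @param roi_radius_mm in-plane radius around the current trajectory estimate
#'   within which slice-wise centers of mass are taken during refinement;
#'   excludes skull and contralateral-lead hyperdensities.
#' @param refine_tol_mm trajectory-refinement convergence tolerance on the tip
#'   position (mm).
#' @param refine_max_iter maximum refinement iterations.
#' @param polar_warn_deg,polar_refuse_deg polar-angle gates: below warn is ok,
#'   between warn and refuse results are flagged reduced-confidence, above
#'   refuse the scan is rejected.
#' @param slice_search_mm,slice_search_step_mm axial search half-range and step
#'   for automatic artifact-slice selection (mm along the lead axis).
#' @param profile_radius_mm radius of the angular sampling circle (mm).
#' @param n_angles number of samples on the circle (1-degree grid by default).
#' @param profile_slab_half_mm,profile_slab_step_mm axial half-range and step
#'   of the profile pooling slab used by [marker_profile()].
#' @param profile_radii_delta_mm radius offsets pooled by [marker_profile()].
#' @param min_amplitude_HU minimum second-harmonic amplitude for a usable
#'   marker artifact; below it the artifact is considered absent.
#' @param resample_res_mm pixel spacing of perpendicular/in-line resampling.
#' @param com_extent_mm side length of the square perpendicular slice used by
#'   the center-of-mass method.
#' @param comsag_half_width_mm transverse half-width of the in-line slice.
#' @param com_slab_step_mm axial spacing of the perpendicular slices pooled
#'   into the marker and reference slabs of the COM method.
#' @param com_ref_gap_mm axial clearance between the marker band and each
#'   reference slab on the symmetric shaft.
#' @param com_ref_span_mm axial length of each reference slab.
#' @param min_deviation_mm center-of-mass deviations smaller than this are
#'   treated as degenerate (indistinguishable from the geometric centre).
#' @param deviation_scale_mm scale dividing COM deviations so that margins of
#'   the four methods are comparable dimensionless numbers.
#' @param margin_floor decisions with a normalized margin below this are
#'   flagged degenerate.
#' @param asm_peak_window_deg half-width of the peak-search window around each
#'   candidate bearing for the asymmetric-marker-sampling method.
#' @param star_window_deg half-width of the intensity windows centred on the
#'   expected dark-star streak bearings.
#' @param fill_HU out-of-volume fill value used when sampling.
#' @return An object of class `dbsorient_config` (a named list).
#' @export
detect_config <- function(metal_threshold_HU = 2000,
                          roi_radius_mm = 4,
                          refine_tol_mm = 0.01,
                          refine_max_iter = 5,
                          polar_warn_deg = 40,
                          polar_refuse_deg = 55,
                          slice_search_mm = 1.5,
                          slice_search_step_mm = 0.25,
                          profile_radius_mm = 3,
                          n_angles = 360,
                          profile_slab_half_mm = 1,
                          profile_slab_step_mm = 0.25,
                          profile_radii_delta_mm = c(-0.5, 0, 0.5),
                          min_amplitude_HU = 10,
                          resample_res_mm = 0.1,
                          com_extent_mm = 10,
                          comsag_half_width_mm = 5,
                          com_slab_step_mm = 0.25,
                          com_ref_gap_mm = 0.5,
                          com_ref_span_mm = 2,
                          min_deviation_mm = 0.02,
                          deviation_scale_mm = 0.1,
                          margin_floor = 0.05,
                          asm_peak_window_deg = 30,
                          star_window_deg = 15,
                          fill_HU = -1024) {
  cfg <- as.list(environment())
  if (cfg$polar_warn_deg > cfg$polar_refuse_deg)
    stop_dbso("config", "polar_warn_deg must not exceed polar_refuse_deg")
  if (cfg$slice_search_step_mm <= 0 || cfg$slice_search_mm < 0)
    stop_dbso("config", "slice search range/step must be positive")
  if (cfg$n_angles < 8)
    stop_dbso("config", "n_angles must be at least 8")
  structure(cfg, class = "dbsorient_config")
}
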