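# Pipeline orchestration and the machine-readable detection report.

#' Run the full orientation-detection pipeline
#'
#' Executes load -> trajectory -> refinement -> polar gate -> marker-slice
#' selection -> angular profile -> candidate orientations -> ambiguity
#' resolution, and assembles a structured report. A polar angle above the
#' refusal gate stops the pipeline with `gate = "refuse"` and no final
#' orientation; between the warn and refuse gates the result carries reduced
#' confidence.
#'
#' @param ct a [ct_volume()] or a path to a NIfTI file.
#' @param tip,head world coordinates (mm) of the lead tip and of a second,
#'   more proximal point on the trajectory.
#' @param lead a [lead_spec()] or the name of a shipped profile.
#' @param cfg a [detect_config()].
#' @param out optional path; when given, the report is written there as JSON.
#' @return An object of class `detection_report` (a named list; see
#'   [validate_report()] for the fields). Orientations are reported in
#'   degrees, 0 = anterior, counterclockwise from superior positive, range
#'   (-180, 180].
#' @export
run_detect <- function(ct, tip, head, lead = "cartesia",
                       cfg = detect_config(), out = NULL) {
  if (is.character(ct)) ct <- load_ct(ct, fill_HU = cfg$fill_HU)
  spec <- if (inherits(lead, "lead_spec")) lead else load_lead_profile(lead)
  init <- make_trajectory(tip, head)
  traj <- refine_trajectory(ct, init, spec, cfg)
  gate <- check_polar(traj, cfg)
  report <- list(
    tool = "dbsorient",
    version = as.character(utils::packageVersion("dbsorient")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    lead_profile = spec$name,
    angle_convention = "0 deg = anterior, counterclockwise viewed from superior positive, range (-180, 180]",
    polar_deg = traj$polar_deg,
    gate = gate,
    refined_tip_world = traj$tip_world,
    refined_unit_dir = traj$unit_dir,
    config = unclass(cfg)
  )
  if (gate == "refuse") {
    report$final_orientation_deg <- NULL
    report$candidate_pair <- NULL
    report$methods <- NULL
    report$mismatch <- NULL
    report$confidence <- NULL
  } else {
    marker_center <- select_marker_slice(ct, traj, spec, cfg)
    profile <- marker_profile(ct, traj, as.numeric(marker_center), cfg)
    pair <- candidate_orientations(profile, spec, cfg)
    res <- resolve(ct, traj, spec, pair, cfg,
                   marker_center = as.numeric(marker_center),
                   profile = profile)
    report$marker_center_world <- as.numeric(marker_center)
    report$marker_slice_offset_mm <- attr(marker_center, "offset_mm")
    report$candidate_pair <- c(pair$theta_deg, pair$partner_deg)
    report$second_harmonic_amplitude_HU <- pair$second_harmonic_amplitude
    report$methods <- lapply(res$methods, function(m)
      list(method = m$method, chosen_theta_deg = m$chosen_theta_deg,
           margin = m$margin, degenerate = m$degenerate))
    report$final_orientation_deg <- wrap_pm180(res$final_theta_deg)
    report$mismatch <- res$mismatch
    report$deciding_method <- res$source
    report$confidence <- if (gate == "warn" || res$confidence == "reduced")
      "reduced" else "ok"
  }
  report <- structure(report, class = "detection_report")
  validate_report(report)
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                         null = "null")
  report
}

#' @export
print.detection_report <- function(x, ...) {
  if (identical(x$gate, "refuse")) {
    cat(sprintf("<detection_report> REFUSED: polar angle %.1f deg exceeds the gate\n",
                x$polar_deg))
  } else {
    cat(sprintf("<detection_report> orientation %.2f deg (polar %.1f deg, gate %s, confidence %s%s)\n",
                x$final_orientation_deg, x$polar_deg, x$gate, x$confidence,
                if (isTRUE(x$mismatch)) ", MISMATCH" else ""))
  }
  invisible(x)
}

#' Structurally validate a detection report
#'
#' Checks the report against the shipped JSON schema
#' (`inst/schema/detection-report.json`): required fields, types and the
#' cross-field invariants (a refused report carries no orientation; the
#' mismatch flag is consistent with the per-method entries).
#'
#' @param report a `detection_report`.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  need <- c("tool", "version", "timestamp", "lead_profile",
            "angle_convention", "polar_deg", "gate", "refined_tip_world",
            "refined_unit_dir", "config")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop_dbso("validation",
              paste("report is missing fields:", paste(missing, collapse = ", ")))
  if (!report$gate %in% c("ok", "warn", "refuse"))
    stop_dbso("validation", "gate must be ok/warn/refuse")
  if (identical(report$gate, "refuse")) {
    if (!is.null(report$final_orientation_deg))
      stop_dbso("validation", "a refused report must not carry an orientation")
  } else {
    if (!is.numeric(report$final_orientation_deg) ||
        report$final_orientation_deg <= -180 ||
        report$final_orientation_deg > 180)
      stop_dbso("validation", "final orientation must lie in (-180, 180]")
    if (length(report$candidate_pair) != 2 || length(report$methods) != 4)
      stop_dbso("validation", "report must carry 2 candidates and 4 methods")
    chosen <- vapply(report$methods, function(m) m$chosen_theta_deg, numeric(1))
    degen <- vapply(report$methods, function(m) m$degenerate, logical(1))
    final360 <- norm_deg360(report$final_orientation_deg)
    mm <- any(!degen & ang_diff_deg(chosen, final360) > 1e-6)
    if (!identical(mm, report$mismatch))
      stop_dbso("validation", "mismatch flag inconsistent with method entries")
  }
  invisible(TRUE)
}

#' Run the detection pipeline over a phantom suite
#'
#' Generates each phantom, runs [run_detect()] with the ground-truth
#' trajectory endpoints as the two input coordinates, and scores every
#' ambiguity method (and the final orientation) against the truth record. A
#' method is correct when its chosen bearing is within 90 degrees of the true
#' yaw, i.e. it picked the right member of the candidate pair.
#'
#' @param suite list of [phantom_spec()]s, e.g. from [phantom_suite()].
#' @param cfg a [detect_config()].
#' @param out_csv,out_json optional paths for the per-phantom table (CSV) and
#'   the summary (JSON).
#' @param verbose print one line per phantom.
#' @return A list with `results` (per-phantom data.frame) and `summary`
#'   (per-method counts plus a per-polar-angle breakdown).
#' @export
run_suite <- function(suite, cfg = detect_config(), out_csv = NULL,
                      out_json = NULL, verbose = FALSE) {
  method_names <- c("COM", "COMsagittal", "ASM", "STARS")
  rows <- vector("list", length(suite))
  for (i in seq_along(suite)) {
    spec <- suite[[i]]
    ph <- generate_phantom(spec)
    tr <- ph$truth
    rep_i <- run_detect(ph$ct, tip = tr$tip_world,
                        head = tr$tip_world + 10 * tr$unit_dir,
                        lead = spec$lead, cfg = cfg)
    row <- data.frame(
      index = i, yaw_true_deg = tr$yaw_true_deg, polar_deg = tr$polar_deg,
      seed = tr$seed, gate = rep_i$gate,
      theta_deg = if (rep_i$gate == "refuse") NA_real_ else
        rep_i$candidate_pair[1],
      partner_deg = if (rep_i$gate == "refuse") NA_real_ else
        rep_i$candidate_pair[2],
      final_theta_deg = if (rep_i$gate == "refuse") NA_real_ else
        rep_i$final_orientation_deg,
      mismatch = if (rep_i$gate == "refuse") NA else rep_i$mismatch
    )
    yaw360 <- norm_deg360(tr$yaw_true_deg)
    for (mn in method_names) {
      if (rep_i$gate == "refuse") {
        row[[paste0(mn, "_theta_deg")]] <- NA_real_
        row[[paste0(mn, "_correct")]] <- NA
        row[[paste0(mn, "_degenerate")]] <- NA
      } else {
        m <- rep_i$methods[[mn]]
        row[[paste0(mn, "_theta_deg")]] <- m$chosen_theta_deg
        row[[paste0(mn, "_correct")]] <-
          ang_diff_deg(m$chosen_theta_deg, yaw360) < 90
        row[[paste0(mn, "_degenerate")]] <- m$degenerate
      }
    }
    row$final_correct <- if (rep_i$gate == "refuse") NA else
      ang_diff_deg(norm_deg360(row$final_theta_deg), yaw360) < 90
    row$final_abs_err_deg <- if (rep_i$gate == "refuse") NA_real_ else
      ang_diff_deg(norm_deg360(row$final_theta_deg), yaw360)
    rows[[i]] <- row
    if (verbose)
      cat(sprintf("phantom %3d: yaw %6.1f polar %4.1f -> final %s\n",
                  i, tr$yaw_true_deg, tr$polar_deg,
                  if (rep_i$gate == "refuse") "refused"
                  else sprintf("%6.1f", row$final_theta_deg)))
  }
  if (!length(rows)) {
    empty <- data.frame()
    summary <- list(n_total = 0L, n_analyzed = 0L, n_refused = 0L,
                    per_method = data.frame(method = method_names, n = 0L,
                                            correct = 0L, fraction = NA_real_),
                    per_polar = empty)
    if (!is.null(out_csv)) utils::write.csv(empty, out_csv, row.names = FALSE)
    if (!is.null(out_json))
      jsonlite::write_json(summary, out_json, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    return(list(results = empty, summary = summary))
  }
  results <- do.call(rbind, rows)
  analyzed <- results[results$gate != "refuse", , drop = FALSE]
  per_method <- do.call(rbind, lapply(method_names, function(mn) {
    ok <- analyzed[[paste0(mn, "_correct")]]
    data.frame(method = mn, n = length(ok), correct = sum(ok),
               fraction = if (length(ok)) mean(ok) else NA_real_)
  }))
  per_polar <- do.call(rbind, lapply(split(analyzed, analyzed$polar_deg),
    function(df) {
      out <- data.frame(polar_deg = df$polar_deg[1], n = nrow(df))
      for (mn in method_names)
        out[[paste0(mn, "_fraction")]] <- mean(df[[paste0(mn, "_correct")]])
      out
    }))
  summary <- list(n_total = nrow(results), n_analyzed = nrow(analyzed),
                  n_refused = sum(results$gate == "refuse"),
                  per_method = per_method, per_polar = per_polar)
  if (!is.null(out_csv)) utils::write.csv(results, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(summary, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  list(results = results, summary = summary)
}
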