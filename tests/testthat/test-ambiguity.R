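# The four ambiguity-resolution methods and the combination policy.

# a 20 mm cube at 0.5 mm voxels holding a symmetric metal cylinder along z
# (radius ~0.65 mm), optionally with an extra suprathreshold blob at
# `bearing` degrees, 1.5 mm off-axis, within the marker band only
cylinder_volume <- function(blob_bearing = NULL) {
  n <- 40
  coord <- ((seq_len(n) - 1) - (n - 1) / 2) * 0.5
  A <- diag(c(0.5, 0.5, 0.5, 1)); A[1:3, 4] <- -(n - 1) / 2 * 0.5
  vox <- array(40, dim = c(n, n, n))
  for (k in seq_len(n)) {
    xx <- matrix(coord, n, n); yy <- matrix(coord, n, n, byrow = TRUE)
    sl <- matrix(40, n, n)
    sl[xx^2 + yy^2 <= 0.65^2] <- 3000
    if (!is.null(blob_bearing) && abs(coord[k]) <= 1.0) {
      # bearing measured from anterior (+y), CCW from superior: e1 = +y,
      # e2 = -x for a superior-pointing axis
      cx <- -1.5 * sin(deg2rad(blob_bearing))
      cy <- 1.5 * cos(deg2rad(blob_bearing))
      sl[(xx - cx)^2 + (yy - cy)^2 <= 0.6^2] <- 3000
    }
    vox[, , k] <- sl
  }
  ct_volume(vox, A)
}

fake_pair <- function(theta) {
  structure(list(theta_deg = theta, partner_deg = theta + 180,
                 second_harmonic_amplitude = 50, quality = 5),
            class = "candidate_pair")
}

test_that("COM follows a constructed off-axis hyperdensity", {
  ct <- cylinder_volume(blob_bearing = 30)
  traj <- make_trajectory(c(0, 0, -8), c(0, 0, 8))
  m <- com_method(ct, traj, c(0, 0, 0), fake_pair(30))
  expect_equal(m$chosen_theta_deg, 30)
  expect_false(m$degenerate)
  # the blob bearing itself is recovered
  expect_lt(ang_diff_deg(m$details$deviation_bearing_deg, 30), 15)
})

test_that("COM is degenerate on a perfectly symmetric cylinder", {
  ct <- cylinder_volume()
  traj <- make_trajectory(c(0, 0, -8), c(0, 0, 8))
  m <- com_method(ct, traj, c(0, 0, 0), fake_pair(30))
  expect_true(m$degenerate)
})

test_that("COM resolves a noisy windowed-marker phantom", {
  ph <- small_phantom(yaw = 75, polar = 20, noise = 15, seed = 7L)
  traj <- refine_trajectory(ph$ct, truth_trajectory(ph$truth))
  mc <- as.numeric(select_marker_slice(ph$ct, traj))
  pair <- candidate_orientations(marker_profile(ph$ct, traj, mc))
  m <- com_method(ph$ct, traj, mc, pair)
  expect_lt(ang_diff_deg(m$chosen_theta_deg, 75), 90)
  expect_false(m$degenerate)
})

test_that("COMsagittal follows the transverse mass and degenerates on symmetry", {
  traj <- make_trajectory(c(0, 0, -8), c(0, 0, 8))
  ct_blob <- cylinder_volume(blob_bearing = 30)
  m <- com_sagittal_method(ct_blob, traj, c(0, 0, 0), fake_pair(30))
  expect_equal(m$chosen_theta_deg, 30)
  expect_false(m$degenerate)
  # mass towards the blob means the partner hypothesis sees negative v
  m_inv <- com_sagittal_method(ct_blob, traj, c(0, 0, 0), fake_pair(210))
  expect_equal(m_inv$chosen_theta_deg, 30)
  m_sym <- com_sagittal_method(cylinder_volume(), traj, c(0, 0, 0),
                               fake_pair(30))
  expect_true(m_sym$degenerate)
})

test_that("ASM compares peak heights in closed form", {
  prof <- synthetic_profile(function(a)
    100 + 20 * cos(deg2rad(a - 40)) + 50 * cos(2 * deg2rad(a - 40)))
  m <- asm_method(prof, fake_pair(40))
  expect_equal(m$chosen_theta_deg, 40)
  expect_false(m$degenerate)
  # no first harmonic: the two peaks are equal and the decision degenerates
  sym <- synthetic_profile(function(a) 100 + 50 * cos(2 * deg2rad(a - 40)))
  expect_true(asm_method(sym, fake_pair(40))$degenerate)
})

test_that("ASM resolves a noisy phantom with a first-harmonic asymmetry", {
  ph <- small_phantom(yaw = -60, polar = 15, noise = 15, seed = 3L)
  traj <- refine_trajectory(ph$ct, truth_trajectory(ph$truth))
  mc <- as.numeric(select_marker_slice(ph$ct, traj))
  prof <- marker_profile(ph$ct, traj, mc)
  pair <- candidate_orientations(prof)
  m <- asm_method(prof, pair)
  expect_lt(ang_diff_deg(m$chosen_theta_deg, norm_deg360(-60)), 90)
})

test_that("STARS follows the one-sided dark star and degenerates without it", {
  ph <- small_phantom(yaw = 120, polar = 10, noise = 0)
  traj <- truth_trajectory(ph$truth)
  m <- suppressWarnings(stars_method(ph$ct, traj, pair = fake_pair(120)))
  expect_equal(m$chosen_theta_deg, 120)
  expect_false(m$degenerate)
  # no star artifact at the contact levels
  ph0 <- small_phantom(yaw = 120, polar = 10, noise = 0, A3_HU = 0)
  m0 <- suppressWarnings(
    stars_method(ph0$ct, truth_trajectory(ph0$truth), pair = fake_pair(120)))
  expect_true(m0$degenerate)
})

test_that("swapping the candidate order never changes the chosen bearing", {
  ph <- small_phantom(yaw = 75, polar = 20, noise = 15, seed = 7L)
  traj <- refine_trajectory(ph$ct, truth_trajectory(ph$truth))
  mc <- as.numeric(select_marker_slice(ph$ct, traj))
  prof <- marker_profile(ph$ct, traj, mc)
  p1 <- fake_pair(75)
  p2 <- structure(list(theta_deg = 255, partner_deg = 75,
                       second_harmonic_amplitude = 50, quality = 5),
                  class = "candidate_pair")
  for (f in list(
    function(p) com_method(ph$ct, traj, mc, p),
    function(p) com_sagittal_method(ph$ct, traj, mc, p),
    function(p) asm_method(prof, p),
    function(p) suppressWarnings(stars_method(ph$ct, traj, pair = p)))) {
    expect_equal(norm_deg360(f(p1)$chosen_theta_deg),
                 norm_deg360(f(p2)$chosen_theta_deg))
  }
})

test_that("margins survive affine intensity rescaling (ASM, STARS)", {
  prof <- synthetic_profile(function(a)
    100 + 20 * cos(deg2rad(a - 40)) + 50 * cos(2 * deg2rad(a - 40)))
  scaled <- synthetic_profile(function(a)
    2.5 * (100 + 20 * cos(deg2rad(a - 40)) + 50 * cos(2 * deg2rad(a - 40))) + 300)
  expect_equal(asm_method(scaled, fake_pair(40))$margin,
               asm_method(prof, fake_pair(40))$margin, tolerance = 1e-9)
  ph <- small_phantom(yaw = 120, polar = 10, noise = 0)
  traj <- truth_trajectory(ph$truth)
  ct2 <- ct_volume(2 * ph$ct$voxels + 100, ph$ct$affine)
  m1 <- suppressWarnings(stars_method(ph$ct, traj, pair = fake_pair(120)))
  m2 <- suppressWarnings(stars_method(ct2, traj, pair = fake_pair(120)))
  expect_equal(m2$margin, m1$margin, tolerance = 1e-6)
})

test_that("COM margins survive a global translation of the volume", {
  ph <- small_phantom(yaw = 75, polar = 20, noise = 15, seed = 7L)
  shift <- c(13.2, -7.1, 4.4)
  A2 <- ph$ct$affine; A2[1:3, 4] <- A2[1:3, 4] + shift
  ct2 <- ct_volume(ph$ct$voxels, A2)
  traj1 <- truth_trajectory(ph$truth)
  traj2 <- make_trajectory(ph$truth$tip_world + shift,
                           ph$truth$tip_world + shift + 10 * ph$truth$unit_dir)
  mc1 <- ph$truth$marker_center_world
  mc2 <- mc1 + shift
  m1 <- com_method(ph$ct, traj1, mc1, fake_pair(75))
  m2 <- com_method(ct2, traj2, mc2, fake_pair(75))
  expect_equal(m2$margin, m1$margin, tolerance = 1e-9)
  s1 <- com_sagittal_method(ph$ct, traj1, mc1, fake_pair(75))
  s2 <- com_sagittal_method(ct2, traj2, mc2, fake_pair(75))
  expect_equal(s2$margin, s1$margin, tolerance = 1e-9)
})

test_that("resolve follows COM, flags mismatches, and falls back when degenerate", {
  ph <- small_phantom(yaw = 30, polar = 10, noise = 15, seed = 5L)
  traj <- refine_trajectory(ph$ct, truth_trajectory(ph$truth))
  mc <- as.numeric(select_marker_slice(ph$ct, traj))
  prof <- marker_profile(ph$ct, traj, mc)
  pair <- candidate_orientations(prof)
  res <- suppressWarnings(resolve(ph$ct, traj, pair = pair,
                                  marker_center = mc, profile = prof))
  expect_false(res$mismatch)
  expect_equal(res$confidence, "ok")
  expect_equal(res$source, "COM")
  expect_lt(ang_diff_deg(res$final_theta_deg, 30), 90)
  expect_true(ang_diff_deg(res$final_theta_deg, pair$theta_deg) < 1e-9 ||
                ang_diff_deg(res$final_theta_deg, pair$partner_deg) < 1e-9)

  # a detector whose star template is rotated 60 degrees contradicts STARS
  # while COM remains decisive: mismatch raised, final unchanged
  bad_spec <- lead_spec(star_gap_offset_deg = 60)
  res_mm <- suppressWarnings(resolve(ph$ct, traj, bad_spec, pair,
                                     marker_center = mc, profile = prof))
  expect_true(res_mm$mismatch)
  expect_equal(res_mm$final_theta_deg, res$final_theta_deg)

  # symmetric marker metal (no window) but decisive star artifact:
  # COM and COMsagittal degenerate, STARS decides with reduced confidence
  ph2 <- small_phantom(yaw = 30, polar = 0, noise = 0,
                       window_angle_deg = 0, A1_HU = 0)
  traj2 <- truth_trajectory(ph2$truth)
  mc2 <- as.numeric(select_marker_slice(ph2$ct, traj2))
  prof2 <- marker_profile(ph2$ct, traj2, mc2)
  pair2 <- candidate_orientations(prof2)
  res2 <- suppressWarnings(resolve(ph2$ct, traj2, pair = pair2,
                                   marker_center = mc2, profile = prof2))
  expect_true(res2$methods$COM$degenerate)
  expect_equal(res2$source, "STARS")
  expect_equal(res2$confidence, "reduced")
  expect_lt(ang_diff_deg(res2$final_theta_deg, 30), 90)
})

test_that("a fully symmetric lead leaves the ambiguity unresolved", {
  ph <- small_phantom(yaw = 30, polar = 0, noise = 0,
                      window_angle_deg = 0, A1_HU = 0, A3_HU = 0)
  traj <- truth_trajectory(ph$truth)
  mc <- as.numeric(select_marker_slice(ph$ct, traj))
  prof <- marker_profile(ph$ct, traj, mc)
  pair <- candidate_orientations(prof)
  expect_error(
    suppressWarnings(resolve(ph$ct, traj, pair = pair,
                             marker_center = mc, profile = prof)),
    class = "dbsorient_error_unresolved")
})
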