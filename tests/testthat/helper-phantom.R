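# Shared fixtures, all generated in code.

# compact phantom for unit tests: smaller volume, same lead geometry
small_phantom <- function(yaw = 30, polar = 0, noise = 0, seed = 1L,
                          voxel = 0.5, tip_world = c(0, 0, -13), ...) {
  generate_phantom(phantom_spec(
    yaw_true_deg = yaw, polar_deg = polar, noise_sigma_HU = noise,
    seed = seed, voxel_mm = voxel,
    volume_extent_mm = c(30, 30, 42), tip_world = tip_world, ...))
}

truth_trajectory <- function(truth) {
  make_trajectory(truth$tip_world, truth$tip_world + 10 * truth$unit_dir)
}

# angular profile built directly from an intensity function of bearing (deg)
synthetic_profile <- function(f, n = 360, radius = 3) {
  a <- (seq_len(n) - 1) * 360 / n
  structure(
    list(angles_deg = a, intensities_HU = f(a), radius_mm = radius,
         center_world = c(0, 0, 0), e1 = c(0, 1, 0), e2 = c(-1, 0, 0)),
    class = "angular_profile"
  )
}

# Rodrigues rotation of v about unit axis k by angle rad
.unit_test_rotate <- function(v, k, rad) {
  k <- k / sqrt(sum(k^2))
  v * cos(rad) + c(k[2] * v[3] - k[3] * v[2],
                   k[3] * v[1] - k[1] * v[3],
                   k[1] * v[2] - k[2] * v[1]) * sin(rad) +
    k * sum(k * v) * (1 - cos(rad))
}

# analytic center of mass of a disk of radius R with a wedge of full angle
# `window_deg` (between radii r0 and R) removed opposite the yaw bearing:
# the remainder's COM lies along yaw at this distance from the centre
analytic_window_com_mm <- function(R = 0.65, r0 = 0.2, window_deg = 90) {
  beta <- window_deg / 2 * pi / 180
  (2 * sin(beta) * (R^3 - r0^3) / 3) / (pi * R^2 - beta * (R^2 - r0^2))
}
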