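# Angle arithmetic in degrees. All user-facing bearings are measured from the
# in-plane projection of world anterior (+Y), increasing counterclockwise when
# viewed from superior (towards the patient's left).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize an angle to `[0, 360)` degrees
#' @param x angle(s) in degrees.
#' @return numeric vector in `[0, 360)`.
#' @keywords internal
norm_deg360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  y
}

norm_deg180 <- function(x) {
  y <- x %% 180
  y[y < 0] <- y[y < 0] + 180
  y
}

# wrap to (-180, 180]
wrap_pm180 <- function(x) {
  y <- norm_deg360(x)
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Smallest absolute angular difference
#'
#' @param a,b angles in degrees.
#' @param period circular period in degrees (360 for bearings, 180 for axes).
#' @return nonnegative difference in `[0, period/2]`.
#' @export
ang_diff_deg <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_dbso("geometry", "cannot normalize a zero vector")
  v / n
}

# In-plane frame perpendicular to the lead axis. e1 is the projection of world
# anterior (+Y); e2 = axis x e1 so that bearings increase counterclockwise when
# viewed from superior. Falls back to the +X projection when the axis is
# (numerically) parallel to anterior.
lead_frame <- function(unit_dir) {
  ant <- c(0, 1, 0)
  e1 <- ant - sum(ant * unit_dir) * unit_dir
  if (sqrt(sum(e1^2)) < 1e-8) {
    message("lead axis is parallel to anterior; using +X projection for the angular origin")
    rgt <- c(1, 0, 0)
    e1 <- rgt - sum(rgt * unit_dir) * unit_dir
  }
  e1 <- .unit(e1)
  e2 <- c(
    unit_dir[2] * e1[3] - unit_dir[3] * e1[2],
    unit_dir[3] * e1[1] - unit_dir[1] * e1[3],
    unit_dir[1] * e1[2] - unit_dir[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}
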