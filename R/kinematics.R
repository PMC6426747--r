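## Grasp-event detection and projected pro/supination angle from marker
## trajectories.  Lab frame: x right, y front (towards the drawer faces),
## z up; positions in mm.

#' Detect the grasp moment in a depth trajectory
#'
#' The depth (y) trajectory of the hand marker rises from the initial posture
#' and shows two local maxima per trial — the drawer grasp and the fully open
#' pull.  The grasp moment is the FIRST local maximum, not the global one.
#' The trace is smoothed with a centered moving average before peak
#' detection, and candidate peaks must exceed a minimum prominence (relative
#' to the higher of the lowest points on either side).  For a plateau
#' maximum the first frame of the plateau is returned.
#'
#' @param y Numeric vector of per-frame depth values (mm), >= 3 frames.
#' @param window Smoothing window in frames (centered moving average,
#'   default 5); smoothing is skipped on traces shorter than `3 * window`.
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   smoothed trace's total excursion (default 0.1).
#' @return 1-based frame index of the first qualifying local maximum.
#' @export
detect_grasp_frame <- function(y, window = 5L, min_prominence_frac = 0.1) {
  if (length(y) < 3) stop("at least 3 frames are required", call. = FALSE)
  if (!all(is.finite(y))) stop("trajectory must be finite", call. = FALSE)
  s <- y
  if (length(y) >= 3 * window && window > 1) {
    w <- as.integer(window)
    if (w %% 2 == 0) w <- w + 1L
    k <- rep(1 / w, w)
    sm <- stats::filter(y, k, sides = 2)
    # keep the raw values at the edges where the centered window runs out
    s <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  excursion <- max(s) - min(s)
  if (excursion == 0) stop("no local maximum found (flat trace)", call. = FALSE)
  thresh <- min_prominence_frac * excursion
  # run-length encode to handle plateaus: a peak run is higher than both of
  # its neighbouring runs; its first frame is the event candidate
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  for (j in seq_len(nr)) {
    if (j == 1 || j == nr) next                    # boundary runs are not interior
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
      left_min <- min(r$values[1:(j - 1)])
      right_min <- min(r$values[(j + 1):nr])
      prominence <- r$values[j] - max(left_min, right_min)
      if (prominence >= thresh) return(starts[j])
    }
  }
  stop("no local maximum found", call. = FALSE)
}

#' Projected pro/supination angle of the wrist axis
#'
#' The wrist axis vector v points from the ulnar (US) to the radial (RS)
#' styloid marker.  Its projection onto the plane of the drawer faces (the
#' x-z plane) gives the pro/supination angle as the four-quadrant angle of
#' (v_x, v_z) measured from the +z axis towards +x, wrapped to (-180, 180].
#' The angle is 0 when v points straight up (back of the hand to the right);
#' pronation tilts v towards +x and increases the angle, supination
#' decreases it.  The y components play no role.
#'
#' @param rs,us Numeric length-3 vectors (x, y, z) in mm.
#' @return Angle in degrees in (-180, 180].
#' @export
prosupination_angle <- function(rs, us) {
  stopifnot(length(rs) == 3, length(us) == 3)
  v <- rs - us
  if (!all(is.finite(v))) stop("marker positions must be finite", call. = FALSE)
  if (v[1] == 0 && v[3] == 0)
    stop("wrist axis has zero length in the x-z projection; angle undefined",
         call. = FALSE)
  a <- atan2(v[1], v[3]) * 180 / pi
  if (a <= -180) a <- a + 360
  a
}

#' Read a marker trajectory table
#'
#' Expects delimited text with columns `frame`, `marker`, `x`, `y`, `z`
#' (mm), one row per frame per marker; markers are the four arm landmarks
#' AC (acromion), RS/US (radial/ulnar styloid) and MC (third metacarpal /
#' capitulum).
#'
#' @param path Path to a CSV file.
#' @return A data.frame sorted by marker then frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[order(df$marker, df$frame), need, drop = FALSE]
}

# apparatus-setup arithmetic: shoulder-joint height approximated from the
# acromion marker, arm length from acromion to radial styloid in a t-pose
shoulder_height <- function(ac_z) 0.97 * ac_z
arm_length <- function(ac, rs) sqrt(sum((ac - rs)^2))
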