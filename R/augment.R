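#' Rotation specification for axis-rotation augmentation
#'
#' Augmentation draws, per segment, a random rotation angle uniform on
#' `angle_range` (degrees) and a random axis uniform on the unit sphere,
#' and rotates every sensor's (x, y, z) vector time series by it. This
#' emulates variability in how limbs and sensors are oriented between
#' participants and sessions.
#'
#' @param angle_range Length-2 numeric, degrees; default `c(-90, 90)`.
#' @param scope `"per_segment_global"` (one rotation shared by all sensor
#'   triplets of a segment; default) or `"per_sensor"` (an independent
#'   rotation per sensor).
#' @param seed Optional integer seed used by [augment_dataset()].
#' @return Object of class `har_rotation_spec`.
#' @export
rotation_spec <- function(angle_range = c(-90, 90),
                          scope = c("per_segment_global", "per_sensor"),
                          seed = NULL) {
  stopifnot(length(angle_range) == 2L, angle_range[1] <= angle_range[2])
  structure(list(angle_range = angle_range, scope = match.arg(scope),
                 seed = seed),
            class = "har_rotation_spec")
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis Nonzero 3-vector; normalized internally.
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 proper rotation matrix (orthogonal, determinant +1).
#' @examples
#' rotation_matrix(c(0, 0, 1), 90) %*% c(1, 0, 0)  # ~ (0, 1, 0)
#' @export
rotation_matrix <- function(axis, angle_deg) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) stop("rotation axis must be nonzero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Draw a uniformly distributed unit axis
#'
#' Uniform on the sphere via normalized standard normals.
#' @return Unit 3-vector.
#' @export
random_axis <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Rotate every (x, y, z) sensor triplet of a segment
#'
#' Channels are grouped into (sensor, modality) triplets by name; each
#' triplet's 3-vector at each time point is left-multiplied by the
#' rotation. Accelerometer and gyroscope triplets transform identically
#' (both are vectors under a frame rotation). With the default scope one
#' drawn rotation applies to all triplets of the segment.
#'
#' @param segment A [har_segment] whose channel count is divisible into
#'   complete (x, y, z) triplets.
#' @param spec A [rotation_spec()]; used for scope. Rotations are supplied
#'   via `rotations` or drawn from the current RNG state.
#' @param rotations Optional: a single 3x3 matrix (global scope) or named
#'   list of matrices keyed by sensor (per-sensor scope); if `NULL`, drawn
#'   randomly (angle uniform on `spec$angle_range`, axis uniform on the
#'   sphere).
#' @return The rotated segment, with the applied angle/axis recorded in
#'   attribute `rotation` of the segment (`$rotation`).
#' @export
rotate_segment <- function(segment, spec = rotation_spec(), rotations = NULL) {
  cn <- colnames(segment$values)
  key <- sub("_[xyz]$", "", cn)
  ax <- sub("^.*_", "", cn)
  triplets <- split(seq_along(cn), key)
  bad <- vapply(triplets, function(i)
    length(i) != 3L || !setequal(ax[i], c("x", "y", "z")), TRUE)
  if (any(bad))
    stop("channels do not form complete (x, y, z) triplets: ",
         paste(names(triplets)[bad], collapse = ", "))
  sensors <- unique(sub("_.*$", "", names(triplets)))
  draw <- function() {
    angle <- stats::runif(1, spec$angle_range[1], spec$angle_range[2])
    axis <- random_axis()
    list(R = rotation_matrix(axis, angle), angle = angle, axis = axis)
  }
  if (is.null(rotations)) {
    rot <- if (spec$scope == "per_segment_global") list(global = draw())
           else stats::setNames(lapply(sensors, function(s) draw()), sensors)
  } else {
    if (is.matrix(rotations)) rotations <- list(global = list(R = rotations))
    rot <- rotations
  }
  v <- segment$values
  for (nm in names(triplets)) {
    i <- triplets[[nm]][order(match(ax[triplets[[nm]]], c("x", "y", "z")))]
    R <- if (!is.null(rot$global)) rot$global$R
         else rot[[sub("_.*$", "", nm)]]$R
    v[, i] <- v[, i, drop = FALSE] %*% t(R)
  }
  segment$values <- v
  segment$rotation <- lapply(rot, function(r) r[c("angle", "axis")])
  segment
}

#' Augment a training set with one rotated copy of each segment
#'
#' Returns the original segments followed by one independently rotated
#' copy of each (output size exactly twice the input). Intended for
#' training data only; evaluation data is never augmented. Deterministic
#' for a given `spec$seed`.
#'
#' @param segments List of [har_segment] (a training split).
#' @param spec A [rotation_spec()].
#' @return List of `2 * length(segments)` segments; rotated copies carry
#'   `$rotation` provenance and a `_rot` suffix on their `segment_id`.
#' @export
augment_dataset <- function(segments, spec = rotation_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rotated <- lapply(segments, function(seg) {
    r <- rotate_segment(seg, spec)
    r$segment_id <- paste0(r$segment_id, "_rot")
    r
  })
  c(segments, rotated)
}
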