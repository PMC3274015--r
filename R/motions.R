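#' Catalogue of the eight leg-motion classes
#'
#' Returns the motion classes the classifier distinguishes, together with the
#' per-channel oscillation templates used by the signal simulator. Each
#' template describes one quasi-periodic repetition of the motion as a
#' raised-cosine burst carrying a small set of harmonics, with class- and
#' channel-specific amplitudes:
#'
#' * M1 -- standing without moving the legs (both channels near zero,
#'   sensor noise only);
#' * M2 -- moving only the lower leg backward (below-knee channel dominant);
#' * M3 -- moving lower and upper leg forward while bending the knee;
#' * M4 -- moving the straight leg forward;
#' * M5 -- moving the straight leg backward (kinematically the mirror of M4,
#'   hence deliberately similar to it);
#' * M6 -- opening the straight leg to the side;
#' * M7 -- squatting;
#' * M8 -- moving only the lower leg upward while sitting (deliberately
#'   similar to M2).
#'
#' The M4/M5 and M2/M8 pairs share nearly identical amplitude and harmonic
#' profiles, emulating the confusion structure observed between motions that
#' differ mainly in movement direction -- a distinction that energy- and
#' variance-based features are largely blind to.
#'
#' @return A tibble with one row per motion: `motion_id`, `name`,
#'   `amp_above`, `amp_below` (burst amplitudes, deg/s), `harmonics`
#'   (list-column of harmonic weights of the within-burst oscillation) and
#'   `direction` (sign of the initial swing).
#' @examples
#' motion_classes()
#' @export
motion_classes <- function() {
  tibble::tibble(
    motion_id = 1:8,
    name = c(
      "standing", "lower_leg_backward", "bent_knee_forward",
      "straight_leg_forward", "straight_leg_backward", "leg_sideways",
      "squat", "lower_leg_upward_sitting"
    ),
    amp_above = c(0, 6, 45, 52, 42, 33, 66, 9),
    amp_below = c(0, 55, 70, 50, 40, 31, 68, 44),
    harmonics = list(
      c(1, 0, 0), c(1, 0.20, 0.05), c(1, 0.45, 0.10), c(1, 0.32, 0.08),
      c(1, 0.24, 0.08), c(1, 0.60, 0.20), c(1, 0.15, 0.35), c(1, 0.26, 0.05)
    ),
    direction = c(1, -1, 1, 1, -1, 1, -1, 1)
  )
}

#' @rdname motion_classes
#' @param motion_id Integer motion identifier in `1..8`.
#' @return `motion_template()` returns the single matching row.
#' @export
motion_template <- function(motion_id) {
  if (length(motion_id) != 1L || is.na(motion_id) ||
      motion_id != as.integer(motion_id) || motion_id < 1 || motion_id > 8) {
    abort("`motion_id` must be a single integer in 1..8.")
  }
  motion_classes()[as.integer(motion_id), ]
}
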