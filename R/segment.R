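#' Detect outward and return motion bounds from the index-finger marker
#'
#' Implements the movement segmentation rule of the occiput-reaching task:
#' the onset of a phase is the first frame beginning a run of at least
#' `window_s` seconds in which the 3D position of the index-finger marker
#' changes continuously (3D speed above `speed_eps`), and the end of the
#' phase is the first subsequent frame beginning a run of at least
#' `window_s` seconds in which the position holds its value (speed at or
#' below `speed_eps`). Applied twice, the rule yields the outward phase
#' (rest to occiput) and the return phase (occiput to rest), separated by
#' the hold at the occiput.
#'
#' With noisy capture, literal sample-to-sample equality never occurs, so
#' "same value" is operationalized by the speed threshold; `speed_eps` can
#' be set near zero for noiseless data.
#'
#' @param pos n x 3 matrix of index-finger marker positions (mm).
#' @param fs sampling rate (Hz).
#' @param speed_eps speed threshold (mm/s) separating "changing" from
#'   "still".
#' @param window_s minimum sustained run length (s).
#' @return List with elements `outward` and `ret`, each a list
#'   `(onset_frame, end_frame, phase)`; frames are 1-based and
#'   `onset_frame < end_frame`.
#' @export
detect_motion_bounds <- function(pos, fs, speed_eps = 5, window_s = 0.2) {
  if (!is.matrix(pos) || ncol(pos) != 3)
    hr_stop("`pos` must be an n x 3 position matrix",
            "headreach_invalid_argument")
  n <- nrow(pos)
  w <- max(1L, round(window_s * fs))
  if (n <= 2 * w)
    hr_stop("series shorter than twice the detection window",
            "headreach_invalid_argument")
  v <- marker_speed(pos, fs)
  moving <- v > speed_eps

  first_run <- function(state, from) {
    x <- moving[from:n] == state
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= w)
    if (length(hit) == 0) return(NA_integer_)
    from + starts[hit[1]] - 1L
  }

  onset1 <- first_run(TRUE, 1L)
  if (is.na(onset1))
    hr_stop("no motion detected: no sustained above-threshold run",
            "headreach_no_motion")
  end1 <- first_run(FALSE, onset1 + 1L)
  if (is.na(end1))
    hr_stop("no motion end detected after outward onset",
            "headreach_no_motion")
  onset2 <- first_run(TRUE, end1 + 1L)
  if (is.na(onset2))
    hr_stop("no return motion detected after the hold",
            "headreach_no_motion")
  end2 <- first_run(FALSE, onset2 + 1L)
  if (is.na(end2))
    hr_stop("no motion end detected after return onset",
            "headreach_no_motion")
  list(outward = list(onset_frame = onset1, end_frame = end1,
                      phase = "outward"),
       ret = list(onset_frame = onset2, end_frame = end2, phase = "return"))
}

# 3D marker speed (mm/s), central differences with one-sided endpoints
marker_speed <- function(pos, fs) {
  n <- nrow(pos)
  d <- matrix(0, n, 3)
  d[2:(n - 1), ] <- (pos[3:n, ] - pos[1:(n - 2), ]) * fs / 2
  d[1, ] <- (pos[2, ] - pos[1, ]) * fs
  d[n, ] <- (pos[n, ] - pos[n - 1, ]) * fs
  sqrt(rowSums(d^2))
}

#' Maximum marker excursion within a phase
#'
#' Maximum Euclidean distance of a marker from its position at the phase
#' onset, over the frames of the phase. Used for the manubrium (sternal)
#' and occiput markers as trunk/head stillness covariates.
#'
#' @param pos n x 3 marker position matrix (mm).
#' @param bounds a single phase bounds list `(onset_frame, end_frame)` as
#'   produced by [detect_motion_bounds()].
#' @return Displacement in mm (>= 0).
#' @export
marker_displacement <- function(pos, bounds) {
  idx <- bounds$onset_frame:bounds$end_frame
  ref <- pos[bounds$onset_frame, ]
  max(sqrt(rowSums((pos[idx, , drop = FALSE] -
                      matrix(ref, length(idx), 3, byrow = TRUE))^2)))
}
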