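# Head-movement markers from the pose columns of a frame table.

pose_trans_cols <- function() c("pose_Tx", "pose_Ty", "pose_Tz")
pose_rot_cols <- function() c("pose_Rx", "pose_Ry", "pose_Rz")

check_pose <- function(frames, cols) {
  missing <- setdiff(cols, names(frames))
  if (length(missing)) {
    abort(sprintf("frame table lacks pose columns: %s",
                  paste(missing, collapse = ", ")),
          class = "dbm_bad_argument")
  }
  if (any(!is.finite(as.matrix(frames[cols])))) {
    abort("pose columns contain non-finite values.", class = "dbm_bad_argument")
  }
}

# Consecutive-frame pairs only: displacement is never computed across a gap
# left by quality-gated frames.
consecutive_pairs <- function(frames) {
  idx <- if ("frame" %in% names(frames)) frames$frame else seq_len(nrow(frames))
  which(diff(idx) == 1)
}

norm_diffs <- function(frames, cols) {
  m <- as.matrix(frames[cols])
  pairs <- consecutive_pairs(frames)
  if (!length(pairs)) return(numeric(0))
  d <- m[pairs + 1L, , drop = FALSE] - m[pairs, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Framewise head displacement
#'
#' Euclidean norm of the translation difference between consecutive frames,
#' in raw tracker units per frame.  Frames removed by the quality gate break
#' the chain: no displacement is computed across a gap in the `frame` index.
#'
#' @param frames Frame table with `pose_Tx/Ty/Tz` (and optionally `frame`).
#' @return Tibble `(frame, displacement)`, one row per consecutive pair
#'   (`frame` is the trailing frame of each pair).
#' @export
#' @examples
#' fr <- data.frame(frame = 1:3, pose_Tx = c(0, 3, 6),
#'                  pose_Ty = c(0, 4, 8), pose_Tz = 0)
#' framewise_displacement(fr)
framewise_displacement <- function(frames) {
  check_pose(frames, pose_trans_cols())
  if (nrow(frames) < 2L) {
    abort("need >= 2 frames for displacement.", class = "dbm_too_short")
  }
  idx <- if ("frame" %in% names(frames)) frames$frame else seq_len(nrow(frames))
  pairs <- consecutive_pairs(frames)
  tibble::tibble(
    frame = idx[pairs + 1L],
    displacement = norm_diffs(frames, pose_trans_cols())
  )
}

#' Head movement mean and standard deviation
#'
#' Arithmetic mean and sample SD (n − 1 denominator) of the framewise
#' displacements.
#'
#' @param displacements Numeric vector or the tibble from
#'   [framewise_displacement()].
#' @return Named list with `mean` and `sd` (`sd` is `NA` for a single value;
#'   both are `NA` for empty input).
#' @export
head_movement_stats <- function(displacements) {
  if (is.data.frame(displacements)) displacements <- displacements$displacement
  if (!length(displacements)) return(list(mean = NA_real_, sd = NA_real_))
  list(mean = mean(displacements),
       sd = if (length(displacements) >= 2L) sd(displacements) else NA_real_)
}

#' Head pose change mean
#'
#' Mean over consecutive frames of the Euclidean norm of the
#' `(Rx, Ry, Rz)` Euler-angle difference vector, in radians per frame.
#' Component-wise differences are used (small-angle regime of a seated,
#' camera-facing subject).
#'
#' @param frames Frame table with `pose_Rx/Ry/Rz` columns.
#' @return Mean angular change, or `NA` with fewer than two chained frames.
#' @export
head_pose_change <- function(frames) {
  check_pose(frames, pose_rot_cols())
  if (nrow(frames) < 2L) {
    abort("need >= 2 frames for pose change.", class = "dbm_too_short")
  }
  d <- norm_diffs(frames, pose_rot_cols())
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' The three head-movement markers for one response
#'
#' Applies the frame quality gate, then computes head movement mean, head
#' movement SD, and head pose change mean.  With fewer than two chained
#' valid frames all three are `NA` (missing, not zero).
#'
#' @param frames Frame table with pose and quality columns.
#' @param min_confidence Quality gate (default 0.70).
#' @return Tibble `(marker, value)` with three rows.
#' @export
movement_markers <- function(frames, min_confidence = 0.70) {
  valid <- filter_valid_frames(frames, min_confidence)
  out <- tibble::tibble(
    marker = c("head_movement_mean", "head_movement_sd", "head_pose_change_mean"),
    value = NA_real_
  )
  if (nrow(valid) < 2L) return(out)
  d <- norm_diffs(valid, pose_trans_cols())
  if (!length(d)) return(out)
  st <- head_movement_stats(d)
  a <- norm_diffs(valid, pose_rot_cols())
  out$value <- c(st$mean, st$sd, mean(a))
  out
}
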