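# Programmatic fixtures used across test files.

# Frame table with explicit AU activations: `active` is a list of integer AU
# vectors, one element per frame; every listed AU is set to `level`.
frames_with_aus <- function(active, level = 3, fps = 30) {
  au_ids <- c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L, 17L, 20L, 23L, 25L, 26L, 45L)
  n <- length(active)
  r <- matrix(0, n, length(au_ids),
              dimnames = list(NULL, sprintf("AU%02d_r", au_ids)))
  for (i in seq_len(n)) {
    if (length(active[[i]])) r[i, sprintf("AU%02d_r", active[[i]])] <- level
  }
  cmat <- 1 * (r > 1)
  colnames(cmat) <- sub("_r$", "_c", colnames(r))
  tibble::as_tibble(cbind(
    data.frame(frame = seq_len(n), timestamp = (seq_len(n) - 1) / fps,
               confidence = 0.99, success = 1),
    r, cmat
  ))
}

# Frame table with a pose path given as an n x 3 translation matrix (and
# optional rotation matrix), blank AUs.
frames_with_pose <- function(trans, rot = NULL) {
  n <- nrow(trans)
  fr <- frames_with_aus(rep(list(integer()), n))
  fr$pose_Tx <- trans[, 1]; fr$pose_Ty <- trans[, 2]; fr$pose_Tz <- trans[, 3]
  if (is.null(rot)) rot <- matrix(0, n, 3)
  fr$pose_Rx <- rot[, 1]; fr$pose_Ry <- rot[, 2]; fr$pose_Rz <- rot[, 3]
  fr
}

# Tidy marker table for one marker with given per-subject bin means.
marker_table_from_matrix <- function(m, marker = "overall_expressivity",
                                     condition = "neutral") {
  days <- c(baseline = 0, week2 = 14, week4 = 28)
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      study_day = unname(days),
      stimulus_class = condition,
      marker = marker,
      value = as.numeric(m[i, ])
    )
  })
}
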