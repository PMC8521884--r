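# Pipeline runners behind the command-line surface: each writes its outputs,
# the effective configuration and a run log into the output directory, so a
# run can be re-executed from what it leaves behind.

run_log <- function(dir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the simulation stage
#'
#' Simulates a cohort and writes `config.yaml`, `madrs.csv`, `markers.csv`
#' (the marker-level simulation), and — when rendering — `manifest.csv` plus
#' per-response OpenFace-dialect CSVs and amplitude traces under
#' `assessments/`.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [cohort_config()] with its seed set.
#' @param render Render raw per-response signals (default `FALSE`).
#' @param audio_format `"text"` (default) or `"wav"`.
#' @return The cohort object, invisibly.
#' @export
run_simulate <- function(out_dir, config = cohort_config(seed = 1),
                         render = FALSE, audio_format = c("text", "wav")) {
  audio_format <- match.arg(audio_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_log(out_dir, "simulate: n_subjects=%d seed=%d render=%s",
          config$n_subjects, config$seed, render)
  cohort <- simulate_cohort(config, render = render)
  write_config(config, file.path(out_dir, "config.yaml"))
  write_madrs_table(cohort$madrs, file.path(out_dir, "madrs.csv"))
  write_marker_table(
    cohort$markers[c("subject_id", "study_day", "stimulus_class", "marker", "value")],
    file.path(out_dir, "markers.csv"))
  if (render) {
    adir <- file.path(out_dir, "assessments")
    dir.create(adir, showWarnings = FALSE)
    manifest <- cohort$assessments[
      c("subject_id", "study_day", "position", "image_id", "valence_class",
        "sample_rate")]
    manifest$frames_file <- sprintf("%s_d%02d_p%02d.csv",
                                    manifest$subject_id, manifest$study_day,
                                    manifest$position)
    manifest$audio_file <- sub("\\.csv$",
                               if (audio_format == "wav") ".wav" else ".txt",
                               manifest$frames_file)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                     progress = FALSE)
    for (i in seq_len(nrow(cohort$assessments))) {
      write_openface_csv(cohort$assessments$frames[[i]],
                         file.path(adir, manifest$frames_file[i]))
      if (audio_format == "wav") {
        write_wav(cohort$assessments$audio[[i]],
                  file.path(adir, manifest$audio_file[i]))
      } else {
        write_amplitude_text(cohort$assessments$audio[[i]],
                             file.path(adir, manifest$audio_file[i]))
      }
    }
    run_log(out_dir, "simulate: wrote %d rendered responses", nrow(manifest))
  }
  run_log(out_dir, "simulate: %d marker rows, %d MADRS rows",
          nrow(cohort$markers), nrow(cohort$madrs))
  invisible(cohort)
}

#' Run the extraction stage
#'
#' Reads the manifest and per-response files written by a rendered
#' [run_simulate()] and writes the extracted tidy marker table.
#'
#' @param in_dir Directory of a rendered simulation run.
#' @param out_path Output CSV (default `markers_extracted.csv` in `in_dir`).
#' @return The extracted marker table, invisibly.
#' @export
run_extract <- function(in_dir, out_path = file.path(in_dir, "markers_extracted.csv")) {
  manifest_path <- file.path(in_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest at %s: run a rendered simulation first.",
                  manifest_path),
          class = "dbm_missing_input")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  adir <- file.path(in_dir, "assessments")
  assessments <- manifest |>
    dplyr::mutate(
      frames = purrr::map(.data$frames_file,
                          ~read_openface_csv(file.path(adir, .x))),
      audio = purrr::map2(.data$audio_file, .data$sample_rate, function(f, sr) {
        if (grepl("\\.wav$", f)) read_wav(file.path(adir, f))
        else read_amplitude_text(file.path(adir, f), sr)
      })
    )
  markers <- extract_markers(assessments)
  write_marker_table(markers, out_path)
  run_log(in_dir, "extract: %d responses -> %d marker rows (%d distinct markers)",
          nrow(manifest), nrow(markers), length(unique(markers$marker)))
  invisible(markers)
}

#' Run the analysis stage
#'
#' Reads a tidy marker table (and MADRS table when present), runs
#' [analyze_markers()] and the MADRS repeated-measures ANOVA, and writes
#' `results.csv` and `pairwise.csv`.
#'
#' @param in_dir Directory holding `markers.csv` (or
#'   `markers_extracted.csv`) and optionally `madrs.csv`.
#' @param out_dir Output directory (default `in_dir`).
#' @param alpha Significance level.
#' @param fdr_family FDR family passed to [analyze_markers()].
#' @return The `marker_results` table, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir = in_dir, alpha = 0.05,
                        fdr_family = "condition") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker_path <- file.path(in_dir, "markers_extracted.csv")
  if (!file.exists(marker_path)) marker_path <- file.path(in_dir, "markers.csv")
  if (!file.exists(marker_path)) {
    abort(sprintf("no marker table in %s.", in_dir), class = "dbm_missing_input")
  }
  markers <- read_marker_table(marker_path)
  results <- analyze_markers(markers, alpha = alpha, fdr_family = fdr_family)
  write_results_table(results, file.path(out_dir, "results.csv"))
  readr::write_csv(pairwise_contrasts(results),
                   file.path(out_dir, "pairwise.csv"), progress = FALSE)
  madrs_path <- file.path(in_dir, "madrs.csv")
  if (file.exists(madrs_path)) {
    madrs <- read_madrs_table(madrs_path)
    fit <- rm_anova(madrs_visit_matrix(madrs))
    readr::write_csv(glance(fit), file.path(out_dir, "madrs_anova.csv"),
                     progress = FALSE)
    run_log(out_dir, "analyze: MADRS F(%d, %d) = %.2f, p = %.3g",
            fit$df_num, fit$df_den, fit$statistic, fit$p.value)
  }
  run_log(out_dir, "analyze: %d result rows from %s", nrow(results), marker_path)
  invisible(results)
}

#' Run the reporting stage
#'
#' Renders the normalized trajectory figure from a run directory.
#'
#' @param in_dir Directory holding marker (and optionally MADRS) tables.
#' @param out_path Figure path (default `trajectories.png`).
#' @param condition Stimulus condition to plot.
#' @return The plot path, invisibly.
#' @export
run_report <- function(in_dir, out_path = file.path(in_dir, "trajectories.png"),
                       condition = "neutral") {
  marker_path <- file.path(in_dir, "markers_extracted.csv")
  if (!file.exists(marker_path)) marker_path <- file.path(in_dir, "markers.csv")
  markers <- read_marker_table(marker_path)
  madrs_path <- file.path(in_dir, "madrs.csv")
  madrs <- if (file.exists(madrs_path)) read_madrs_table(madrs_path) else NULL
  p <- plot_trajectories(markers, madrs, condition = condition)
  ggplot2::ggsave(out_path, p, width = 7, height = 4.5)
  run_log(in_dir, "report: wrote %s", out_path)
  invisible(out_path)
}
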