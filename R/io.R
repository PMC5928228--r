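#' Write perch events as CSV
#'
#' Columns: bird_id, day, perch_id, t_land_s, t_leave_s.
#'
#' @param events Perch-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("bird_id", "day", "perch_id", "t_land_s", "t_leave_s")
  utils::write.csv(as.data.frame(events)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read perch events from CSV
#' @param path CSV path with the columns written by [write_events_csv()].
#' @return A tibble of perch events.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bird_id", "day", "perch_id", "t_land_s", "t_leave_s")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  tibble::as_tibble(df)
}

#' Write rendition records as JSONL
#'
#' One JSON object per line, one line per rendition.
#'
#' @param renditions Rendition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_renditions_jsonl <- function(renditions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(renditions), con, verbose = FALSE)
  invisible(path)
}

#' Read rendition records from JSONL
#' @param path JSONL path.
#' @return A tibble of rendition records.
#' @export
read_renditions_jsonl <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
}

#' Write a stimulus-event log as CSV
#' @param stimuli Stimulus-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimuli_csv <- function(stimuli, path) {
  utils::write.csv(as.data.frame(stimuli), path, row.names = FALSE)
  invisible(path)
}

#' Write a stats report as JSON
#' @param report A named list (e.g. t-test or ANOVA results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# artifact directory for one experiment suite: per-experiment logs + summary
write_suite <- function(suite, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("perch_strobe", "perch_noise", "pitch_noise", "pitch_strobe")) {
    res <- suite[[nm]]
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    if (!is.null(res$events)) write_events_csv(res$events, file.path(d, "events.csv"))
    if (!is.null(res$renditions))
      write_renditions_jsonl(res$renditions, file.path(d, "renditions.jsonl"))
    write_stimuli_csv(res$stimuli, file.path(d, "stimuli.csv"))
    utils::write.csv(as.data.frame(res$metrics), file.path(d, "metrics.csv"),
                     row.names = FALSE)
  }
  write_stats_json(list(anova_strobe = suite$anova_strobe,
                        anova_noise = suite$anova_noise),
                   file.path(out_dir, "stats.json"))
  utils::write.csv(as.data.frame(suite$summary),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(out_dir)
}
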