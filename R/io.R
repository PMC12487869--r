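## File formats. All CSV files are UTF-8, '.' decimal, header row
## required; lines starting with '#' are metadata comments (package
## version, configuration hash, seed) and are skipped on read.

petkin_header <- function(seed = NULL, config_hash = NULL) {
  c(sprintf("# petkin %s", as.character(utils::packageVersion("petkin"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config_hash)) sprintf("# config: %s", config_hash))
}

write_csv_commented <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(petkin_header(seed, config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an arterial blood sample CSV
#'
#' Expected columns: `time_min`, `whole_blood_kBq_cc`, `plasma_kBq_cc`.
#'
#' @param path File path.
#' @return A [blood_sample_table()].
#' @export
read_blood_csv <- function(path) {
  df <- read_csv_commented(path)
  need <- c("time_min", "whole_blood_kBq_cc", "plasma_kBq_cc")
  if (!all(need %in% names(df)))
    stop_petkin("blood CSV '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  blood_sample_table(df$time_min, df$whole_blood_kBq_cc, df$plasma_kBq_cc)
}

#' Write an arterial blood sample CSV
#' @param x A [blood_sample_table()].
#' @param path File path.
#' @param ... Passed to the internal writer (`seed`, `config_hash`).
#' @export
write_blood_csv <- function(x, path, ...) {
  df <- data.frame(time_min = x$sample_time,
                   whole_blood_kBq_cc = x$whole_blood_activity,
                   plasma_kBq_cc = x$plasma_activity)
  write_csv_commented(df, path, ...)
}

#' Read a parent-fraction CSV
#'
#' Expected columns: `time_min`, `parent_fraction`.
#' @inheritParams read_blood_csv
#' @return A [parent_fraction_table()].
#' @export
read_parent_csv <- function(path) {
  df <- read_csv_commented(path)
  need <- c("time_min", "parent_fraction")
  if (!all(need %in% names(df)))
    stop_petkin("parent-fraction CSV '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  parent_fraction_table(df$time_min, df$parent_fraction)
}

#' Write a parent-fraction CSV
#' @param x A [parent_fraction_table()].
#' @inheritParams write_blood_csv
#' @export
write_parent_csv <- function(x, path, ...) {
  df <- data.frame(time_min = x$sample_time, parent_fraction = x$parent_fraction)
  write_csv_commented(df, path, ...)
}

#' Read regional time-activity curves from CSV
#'
#' Expected columns: `frame_start_min`, `frame_end_min`, then one activity
#' column (kBq/cm3) per region.
#'
#' @param path File path.
#' @return Named list of [tac()] objects.
#' @export
read_tac_csv <- function(path) {
  df <- read_csv_commented(path)
  need <- c("frame_start_min", "frame_end_min")
  if (!all(need %in% names(df)))
    stop_petkin("TAC CSV '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  sched <- frame_schedule(df$frame_start_min, df$frame_end_min)
  rois <- setdiff(names(df), need)
  if (length(rois) == 0L) stop_petkin("TAC CSV '%s' has no region columns", path)
  out <- lapply(rois, function(r) tac(r, sched, df[[r]]))
  names(out) <- rois
  out
}

#' Write regional time-activity curves to CSV
#' @param tacs Named list of [tac()] objects sharing one schedule.
#' @inheritParams write_blood_csv
#' @export
write_tac_csv <- function(tacs, path, ...) {
  sched <- tacs[[1]]$schedule
  df <- data.frame(frame_start_min = sched$frame_start,
                   frame_end_min = sched$frame_end)
  for (tc in tacs) df[[tc$roi_name]] <- tc$activity
  write_csv_commented(df, path, ...)
}

#' Read a PMOD-style .tac file
#'
#' Whitespace-delimited with a header line such as
#' `start[seconds] end[seconds] roi1 roi2 ...` (or `[minutes]`); times are
#' converted to minutes.
#'
#' @param path File path.
#' @return Named list of [tac()] objects.
#' @export
read_tac_pmod <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop_petkin("PMOD .tac file '%s' is empty", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  unit <- regmatches(hdr[1], regexpr("\\[[^]]+\\]", hdr[1]))
  scale <- if (length(unit) && grepl("sec", unit, ignore.case = TRUE)) 1 / 60 else 1
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(vals) != length(hdr))
    stop_petkin("PMOD .tac '%s': %d header fields but %d data columns",
                path, length(hdr), ncol(vals))
  sched <- frame_schedule(vals[, 1] * scale, vals[, 2] * scale)
  rois <- gsub("\\[[^]]+\\]", "", hdr[-(1:2)])
  out <- lapply(seq_along(rois), function(j) tac(rois[j], sched, vals[, j + 2]))
  names(out) <- rois
  out
}

#' Serialize a fitted input-function component to JSON
#'
#' Writes explicit parameter names and units so fitted blood models can be
#' archived and re-read without the raw samples.
#'
#' @param input An [make_input_function()] result.
#' @param path Output JSON path.
#' @export
write_input_json <- function(input, path) {
  ser_plasma <- function(m) list(
    peak_time_min = m$peak_time,
    pre_peak_times_min = m$pre_times,
    pre_peak_values_kBq_cc = m$pre_values,
    amplitudes_kBq_cc = m$A,
    rates_per_min = m$lambda)
  doc <- list(
    model = "metabolite-corrected plasma input",
    plasma = ser_plasma(input$plasma),
    whole_blood = ser_plasma(input$whole_blood),
    parent_fraction = list(form = "PF(t) = 1 - a * pgamma(t, shape, rate)",
                           a = input$parent$a, shape = input$parent$shape,
                           rate_per_min = input$parent$rate),
    free_fraction = input$f_p)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an input function back from JSON
#' @param path JSON path written by [write_input_json()].
#' @return An `input_function`.
#' @export
read_input_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_plasma <- function(m, col) structure(
    list(peak_time = m$peak_time_min, pre_times = m$pre_peak_times_min,
         pre_values = m$pre_peak_values_kBq_cc, A = m$amplitudes_kBq_cc,
         lambda = m$rates_per_min, rss = NA_real_, column = col),
    class = "plasma_curve")
  parent <- structure(list(a = doc$parent_fraction$a,
                           shape = doc$parent_fraction$shape,
                           rate = doc$parent_fraction$rate_per_min,
                           rss = NA_real_),
                      class = "parent_fraction_model")
  make_input_function(de_plasma(doc$plasma, "plasma_activity"), parent,
                      de_plasma(doc$whole_blood, "whole_blood_activity"),
                      doc$free_fraction %||% NA_real_)
}
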