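# Plain-text interchange formats.  CSVs carry their timing anchors as
# '# key: value' comment lines above the header so every file is
# self-contained; timestamps are ISO-8601, epoch indices 0-based over
# half-open intervals [t, t + delta).

LEGACY_STAGE_MAP <- c(
  "W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3", "R" = "R",
  "Stage W" = "W", "Stage N1" = "N1", "Stage N2" = "N2", "Stage N3" = "N3",
  "Stage R" = "R",
  "Stage 1" = "N1", "Stage 2" = "N2", "Stage 3+4" = "N3", "Stage REM" = "R",
  "1" = "N1", "2" = "N2", "3+4" = "N3", "REM" = "R")

read_commented_csv <- function(path, required_keys) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  missing <- setdiff(required_keys, names(meta))
  if (length(missing))
    stop(sprintf("%s: missing '# %s:' metadata line", path,
                 paste(missing, collapse = "', '# ")), call. = FALSE)
  body_lines <- which(!is_comment & nzchar(trimws(lines)))
  tab <- utils::read.csv(text = paste(lines[body_lines], collapse = "\n"),
                         stringsAsFactors = FALSE)
  list(meta = meta, table = tab, line_of_row = body_lines[-1])
}

#' Read a 30-s hypnogram CSV
#'
#' Expects columns \code{epoch_index} (0-based) and \code{stage}, preceded
#' by \code{# lights_off:} (and optionally \code{# lights_on:}) ISO-8601
#' metadata lines.  Legacy stage tokens (\code{Stage 1}, \code{Stage 2},
#' \code{Stage 3+4}, \code{Stage REM}, \code{Stage W}, bare \code{3+4},
#' \code{REM}, ...) are mapped onto W/N1/N2/N3/R; an unknown token is a
#' parse error naming the offending line.
#'
#' @param path CSV path.
#' @return A [hypnogram()] object.
#' @export
read_hypnogram <- function(path) {
  parsed <- read_commented_csv(path, "lights_off")
  tab <- parsed$table
  if (!all(c("epoch_index", "stage") %in% names(tab)))
    stop(sprintf("%s: expected columns epoch_index, stage", path),
         call. = FALSE)
  tok <- trimws(as.character(tab$stage))
  mapped <- unname(LEGACY_STAGE_MAP[tok])
  bad <- which(is.na(mapped))
  if (length(bad))
    stop(sprintf("%s line %d: unknown stage token '%s'", path,
                 parsed$line_of_row[bad[1]], tok[bad[1]]), call. = FALSE)
  ord <- order(tab$epoch_index)
  hypnogram(mapped[ord], parsed$meta$lights_off,
            lights_on = parsed$meta$lights_on)
}

#' Write a hypnogram CSV
#'
#' @param h A [hypnogram()] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram30"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lights_off: %s", format_iso8601(h$lights_off)),
               sprintf("# lights_on: %s", format_iso8601(h$lights_on)),
               "epoch_index,stage",
               sprintf("%d,%s", seq_along(h$stages) - 1L, h$stages)), con)
  invisible(path)
}

#' Read a 2-min activity-count CSV
#'
#' Expects columns \code{epoch_index} (0-based) and \code{count} (integer
#' in 0--31), preceded by a \code{# start:} ISO-8601 metadata line.
#' Non-integer or out-of-range counts are parse errors naming the line.
#'
#' @param path CSV path.
#' @return An [activity_series()].
#' @export
read_activity <- function(path) {
  parsed <- read_commented_csv(path, "start")
  tab <- parsed$table
  if (!all(c("epoch_index", "count") %in% names(tab)))
    stop(sprintf("%s: expected columns epoch_index, count", path),
         call. = FALSE)
  cnt <- suppressWarnings(as.numeric(tab$count))
  bad <- which(!is.finite(cnt) | cnt != round(cnt) | cnt < 0 | cnt > 31)
  if (length(bad))
    stop(sprintf("%s line %d: activity count '%s' is not an integer in [0, 31]",
                 path, parsed$line_of_row[bad[1]],
                 as.character(tab$count[bad[1]])), call. = FALSE)
  ord <- order(tab$epoch_index)
  activity_series(cnt[ord], parsed$meta$start)
}

#' Write an activity-count CSV
#'
#' @param a An [activity_series()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_activity <- function(a, path) {
  stopifnot(inherits(a, "activity_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# start: %s", format_iso8601(a$start)),
               "epoch_index,count",
               sprintf("%d,%d", seq_along(a$counts) - 1L, a$counts)), con)
  invisible(path)
}

#' Read a discriminant model from JSON
#'
#' Expects an object with \code{label}, \code{coefficients} (5 numbers in
#' window order) and \code{threshold}.
#'
#' @param path JSON path.
#' @return A [discriminant_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$coefficients))
    stop(sprintf("%s: missing 'coefficients'", path), call. = FALSE)
  discriminant_model(x$coefficients,
                     threshold = if (is.null(x$threshold)) 1 else x$threshold,
                     label = if (is.null(x$label)) "from_file" else x$label)
}

#' Write a discriminant model to JSON
#'
#' @param model A [discriminant_model()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  jsonlite::write_json(list(label = model$label,
                            coefficients = model$coefficients,
                            threshold = model$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a scored sleep/wake series to CSV
#'
#' Emits \code{epoch_index, count, z, label} with the scoring provenance
#' (model label, coefficients, threshold, edge policy) as comment lines, so
#' a run can be reproduced from its output alone.
#'
#' @param s An [score_series()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scored <- function(s, path) {
  stopifnot(inherits(s, "sw_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# model: %s", attr(s, "model_label")),
    sprintf("# coefficients: %s",
            paste(format(attr(s, "coefficients"), digits = 17),
                  collapse = " ")),
    sprintf("# threshold: %s", format(attr(s, "threshold"), digits = 17)),
    sprintf("# edge_policy: %s", attr(s, "edge_policy")),
    "epoch_index,count,z,label",
    sprintf("%d,%s,%s,%s", s$epoch_index, format(s$count, digits = 17),
            format(s$z, digits = 17), s$label)), con)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' A manifest has columns \code{subject_id}, \code{hypnogram},
#' \code{activity} (paths, resolved relative to the manifest) and optional
#' \code{age} and \code{group}.  Ids must be unique and every referenced
#' file must exist.
#'
#' @param path Manifest CSV path.
#' @return Data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "hypnogram", "activity")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop(sprintf("%s: duplicate subject_id '%s'", path,
                 tab$subject_id[anyDuplicated(tab$subject_id)]), call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  tab$hypnogram <- resolve(tab$hypnogram)
  tab$activity <- resolve(tab$activity)
  for (col in c("hypnogram", "activity")) {
    miss <- which(!file.exists(tab[[col]]))
    if (length(miss))
      stop(sprintf("%s: %s file not found for subject '%s': %s", path, col,
                   tab$subject_id[miss[1]], tab[[col]][miss[1]]),
           call. = FALSE)
  }
  tab
}

#' Load the recordings listed in a manifest
#'
#' @param manifest A path or a [read_manifest()] result.
#' @return List of subjects (id, hypnogram, activity, age, group) directly
#'   usable by [validate_cohort()], [assemble_training_set()] and
#'   [optimize_sleep_rules()] (after collapsing/scoring).
#' @export
load_cohort <- function(manifest) {
  tab <- if (is.character(manifest)) read_manifest(manifest) else manifest
  lapply(seq_len(nrow(tab)), function(i)
    list(id = tab$subject_id[i],
         hypnogram = read_hypnogram(tab$hypnogram[i]),
         activity = read_activity(tab$activity[i]),
         age = if ("age" %in% names(tab)) tab$age[i] else NA,
         group = if ("group" %in% names(tab)) tab$group[i] else NA))
}

#' Write a simulated cohort to disk
#'
#' Writes each subject's hypnogram and activity CSVs plus a manifest
#' consumable by the scoring, validation, optimization and derivation
#' stages.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(cohort, function(s) {
    hp <- sprintf("%s_hypnogram.csv", s$id)
    ap <- sprintf("%s_activity.csv", s$id)
    write_hypnogram(s$hypnogram, file.path(dir, hp))
    write_activity(s$activity, file.path(dir, ap))
    sprintf("%s,%s,%s", s$id, hp, ap)
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("subject_id,hypnogram,activity", rows), manifest)
  invisible(manifest)
}

flatten_report <- function(x) {
  if (inherits(x, "validation_report"))
    return(list(agreement_pct = x$agreement_pct,
                sensitivity_pct = x$sensitivity_pct,
                specificity_pct = x$specificity_pct,
                cells = as.list(x$cells), n_epochs = x$n_epochs))
  if (inherits(x, "sleep_parameters")) return(unclass(x))
  if (inherits(x, "cohort_validation"))
    return(list(per_subject = x$per_subject, summary = x$summary,
                model_label = x$model_label, edge_policy = x$edge_policy))
  x
}

#' Write a report to JSON or CSV
#'
#' JSON serializes any of the package's report objects at full precision
#' (values round-trip to better than 1e-9); CSV is available for tabular
#' reports (data frames, per-subject tables, summaries).
#'
#' @param x A report object or data frame.
#' @param path Output path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  x <- flatten_report(x)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
  } else {
    tab <- if (is.data.frame(x)) x else
      if (!is.null(x$per_subject)) x$per_subject else
        as.data.frame(x, stringsAsFactors = FALSE)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return Parsed list (data frames restored column-wise).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
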