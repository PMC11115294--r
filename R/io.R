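#' Write a trial to a TRC marker file
#'
#' Tab-delimited TRC (Track Row Column) format as used by optical motion
#' capture tooling: a four-line header carrying DataRate, NumFrames,
#' NumMarkers and Units (mm), a marker-name row, a coordinate-label row,
#' then one row per frame with frame number, time and X/Y/Z per marker.
#'
#' @param trial a `trial_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  fs <- trial$sampling_rate
  nf <- n_frames(trial)
  nm <- names(trial$markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", fs, fs, nf,
                     length(nm), fs, nf), con)
  writeLines(paste(c("Frame#", "Time",
                     unlist(lapply(nm, function(m) c(m, "", "")))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", unlist(lapply(seq_along(nm), function(i)
    paste0(c("X", "Y", "Z"), i)))), collapse = "\t"), con)
  coords <- do.call(cbind, trial$markers)
  block <- cbind(seq_len(nf), (seq_len(nf) - 1) / fs, coords)
  lines <- apply(format(block, trim = TRUE, digits = 12, scientific = FALSE),
                 1, paste, collapse = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a TRC marker file
#'
#' Parses the TRC dialect written by [write_trc()] (and standard capture
#' exports): the header supplies the sampling rate and units (m is
#' converted to mm), the marker-name row supplies the marker map.
#'
#' @param path TRC file path.
#' @param participant_id,side optional labels to attach.
#' @param metadata optional named list of participant covariates.
#' @return A `trial_recording`.
#' @export
read_trc <- function(path, participant_id = NA_character_,
                     side = NA_character_, metadata = list()) {
  lines <- readLines(path)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1]))
    hr_stop(sprintf("%s: malformed TRC header (line 1)", path),
            "headreach_parse_error")
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_names)
  fs <- suppressWarnings(as.numeric(hdr[["DataRate"]]))
  units <- hdr[["Units"]]
  if (is.na(fs))
    hr_stop(sprintf("%s: missing DataRate (line 3)", path),
            "headreach_parse_error")
  if (!units %in% c("mm", "m"))
    hr_stop(sprintf("%s: unknown units '%s' (line 3)", path, units),
            "headreach_parse_error")
  marker_row <- strsplit(lines[4], "\t")[[1]]
  nm <- marker_row[-(1:2)]
  nm <- nm[nm != ""]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  mat <- tryCatch(
    do.call(rbind, lapply(data_lines, function(l)
      as.numeric(strsplit(l, "\t")[[1]]))),
    warning = function(w)
      hr_stop(sprintf("%s: non-numeric data row", path),
              "headreach_parse_error"))
  if (any(is.na(mat)) || ncol(mat) != 2 + 3 * length(nm))
    hr_stop(sprintf("%s: frame rows inconsistent with %d markers",
                    path, length(nm)), "headreach_parse_error")
  scale_f <- if (units == "m") 1000 else 1
  markers <- setNames(lapply(seq_along(nm), function(i)
    mat[, 2 + (i - 1) * 3 + 1:3, drop = FALSE] * scale_f), nm)
  trial_recording(participant_id, side, limb = infer_limb(nm),
                  sampling_rate = fs, markers = markers, metadata = metadata)
}

infer_limb <- function(marker_names) {
  if ("RELB" %in% marker_names) "right"
  else if ("LELB" %in% marker_names) "left"
  else NA_character_
}

#' Write trials to a long-format CSV
#'
#' One row per trial x frame x marker with columns `trial_id`, `frame`,
#' `marker`, `x`, `y`, `z` (mm); several trials may share one file.
#'
#' @param trials list of `trial_recording` objects (or one recording).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(trials, path) {
  if (inherits(trials, "trial_recording")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    tid <- if (!is.null(tr$trial_id)) tr$trial_id else tr$participant_id
    do.call(rbind, lapply(names(tr$markers), function(m)
      data.frame(trial_id = tid, frame = seq_len(n_frames(tr)), marker = m,
                 x = tr$markers[[m]][, 1], y = tr$markers[[m]][, 2],
                 z = tr$markers[[m]][, 3])))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$trial_id, df$frame, df$marker), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read trials from a long-format CSV
#'
#' @param path CSV with columns `trial_id`, `frame`, `marker`, `x`, `y`,
#'   `z` (as written by [write_long_csv()]).
#' @param fs sampling rate of the recordings (Hz); the long format does not
#'   carry it.
#' @param covariates optional data.frame keyed by `trial_id` with columns
#'   among `participant_id`, `side`, `sex`, `age`, `bmi`,
#'   `months_post_onset`.
#' @return List of `trial_recording` objects.
#' @export
read_long_csv <- function(path, fs = 100, covariates = NULL) {
  df <- read.csv(path)
  need <- c("trial_id", "frame", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    hr_stop(sprintf("%s: long CSV must have columns %s", path,
                    paste(need, collapse = ", ")),
            "headreach_parse_error")
  lapply(split(df, df$trial_id), function(d) {
    nf <- max(d$frame)
    markers <- lapply(split(d, d$marker), function(m) {
      if (nrow(m) != nf)
        hr_stop(sprintf("%s: trial %s marker %s has %d frames, expected %d",
                        path, d$trial_id[1], m$marker[1], nrow(m), nf),
                "headreach_parse_error")
      unname(as.matrix(m[order(m$frame), c("x", "y", "z")]))
    })
    meta <- list(); pid <- NA_character_; side <- NA_character_
    if (!is.null(covariates)) {
      row <- covariates[covariates$trial_id == d$trial_id[1], , drop = FALSE]
      if (nrow(row) == 1) {
        pid <- row$participant_id
        if ("side" %in% names(row)) side <- row$side
        for (f in intersect(c("sex", "age", "bmi", "months_post_onset"),
                            names(row)))
          meta[[f]] <- row[[f]]
      }
    }
    tr <- trial_recording(pid, side, infer_limb(names(markers)), fs,
                          markers, meta)
    tr$trial_id <- as.character(d$trial_id[1])
    tr
  })
}

#' Write the per-trial covariate table
#'
#' @param trials list of `trial_recording` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = if (!is.null(tr$trial_id)) tr$trial_id else NA,
               participant_id = tr$participant_id, side = tr$side,
               limb = tr$limb,
               sex = tr$metadata$sex %||% NA,
               age = tr$metadata$age %||% NA,
               bmi = tr$metadata$bmi %||% NA,
               months_post_onset = tr$metadata$months_post_onset %||% NA)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a batch of trial files
#'
#' Reads TRC and/or long-CSV marker files into validated recordings: marker
#' names are aliased onto the canonical set, units normalized to mm,
#' required markers checked, and sampling rates checked for consistency
#' across the batch.
#'
#' @param paths character vector of `.trc` and/or `.csv` files.
#' @param covariates optional covariate data.frame (see [read_long_csv()]);
#'   for TRC files it is matched on the file's base name as `trial_id`.
#' @param fs sampling rate assumed for long-CSV files.
#' @return List of `trial_recording` objects.
#' @export
read_trial_files <- function(paths, covariates = NULL, fs = 100) {
  trials <- list()
  for (p in paths) {
    if (grepl("\\.trc$", p, ignore.case = TRUE)) {
      tr <- read_trc(p)
      tr$trial_id <- sub("\\.[^.]+$", "", basename(p))
      if (!is.null(covariates)) {
        row <- covariates[covariates$trial_id == tr$trial_id, , drop = FALSE]
        if (nrow(row) == 1) {
          tr$participant_id <- row$participant_id
          if ("side" %in% names(row)) tr$side <- row$side
          for (f in intersect(c("sex", "age", "bmi", "months_post_onset"),
                              names(row)))
            tr$metadata[[f]] <- row[[f]]
        }
      }
      trials[[length(trials) + 1]] <- tr
    } else if (grepl("\\.csv$", p, ignore.case = TRUE)) {
      trials <- c(trials, read_long_csv(p, fs = fs, covariates = covariates))
    } else {
      hr_stop(sprintf("%s: unsupported file type", p),
              "headreach_parse_error")
    }
  }
  rates <- vapply(trials, function(tr) tr$sampling_rate, numeric(1))
  if (length(unique(rates)) > 1)
    hr_stop(sprintf("sampling-rate mismatch across batch: %s",
                    paste(unique(rates), collapse = ", ")),
            "headreach_rate_mismatch")
  for (tr in trials) canonical_markers(tr)   # marker validation
  trials
}
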