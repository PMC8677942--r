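.csvColumns <- c("subject_id", "eye", "visit_index", "recording_index",
                 "n_flashes", "duration_ms", "n_samples", "stimulus_time_ms",
                 "sample_index", "potential_uv", "label", "eye_class",
                 .covariateCols)

#' Write a waveform table (long-form CSV)
#'
#' One row per sample, with the per-recording metadata repeated on each row.
#' Column order is fixed; numbers are written in a 17-significant-digit
#' representation so that [readWaveformCSV()] inverts the file exactly and a
#' write/read/write cycle is byte-identical. Missing covariates are written
#' as `NA`.
#'
#' @param x An [ERGRecordingSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeWaveformCSV <- function(x, path) {
  stopifnot(is(x, "ERGRecordingSet"))
  cd <- as.data.frame(recordInfo(x))
  uv <- potentials(x)
  n_samples <- nrow(uv)
  rows <- lapply(seq_len(ncol(uv)), function(j) {
    data.frame(subject_id = cd$subject_id[j], eye = cd$eye[j],
               visit_index = cd$visit_index[j],
               recording_index = cd$recording_index[j],
               n_flashes = cd$n_flashes[j],
               duration_ms = .fmtNum(cd$duration_ms[j]),
               n_samples = n_samples,
               stimulus_time_ms = .fmtNum(cd$stimulus_time_ms[j]),
               sample_index = seq_len(n_samples) - 1L,
               potential_uv = .fmtNum(uv[, j]),
               label = cd$label[j], eye_class = cd$eye_class[j],
               age_years = .fmtNum(cd$age_years[j]),
               gender = ifelse(is.na(cd$gender[j]), "NA", cd$gender[j]),
               logmar = .fmtNum(cd$logmar[j]),
               hvf_md_db = .fmtNum(cd$hvf_md_db[j]),
               rnfl_um = .fmtNum(cd$rnfl_um[j]),
               gclipl_um = .fmtNum(cd$gclipl_um[j]),
               stringsAsFactors = FALSE)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.csvColumns, collapse = ","), con)
  if (length(rows)) {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    write.table(out, con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read a waveform table (long-form CSV)
#'
#' Inverse of [writeWaveformCSV()]. Each (subject, eye, visit, recording)
#' group becomes one recording; the file's `n_samples` must match the number
#' of rows in the group and `sample_index` must run 0..n_samples-1, otherwise
#' the offending record is named in the error.
#'
#' @param path CSV file path.
#' @return An [ERGRecordingSet-class]. A header-only file yields a
#'   zero-recording set (430-sample default grid).
#' @export
readWaveformCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character", eye = "character",
                                 label = "character", eye_class = "character",
                                 gender = "character"))
  miss <- setdiff(.csvColumns, colnames(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    return(ERGRecordingSet(matrix(numeric(), 430, 0),
                           data.frame(subject_id = character(),
                                      eye = character())))
  }
  key <- .recordId(tab$subject_id, tab$eye, tab$visit_index, tab$recording_index)
  groups <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  n_samples <- unique(tab$n_samples)
  if (length(n_samples) != 1)
    stop("all records in one file must share n_samples")
  uv <- matrix(NA_real_, n_samples, length(groups))
  info <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    id <- names(groups)[g]
    if (length(idx) != n_samples)
      stop(sprintf("record %s: expected %d samples, found %d",
                   id, n_samples, length(idx)))
    idx <- idx[order(tab$sample_index[idx])]
    if (!identical(as.integer(tab$sample_index[idx]), seq_len(n_samples) - 1L))
      stop(sprintf("record %s: sample_index must run 0..%d", id, n_samples - 1L))
    first <- idx[1]
    meta <- tab[first, setdiff(.csvColumns, c("sample_index", "potential_uv",
                                              "n_samples"))]
    if (nrow(unique(tab[idx, c("duration_ms", "stimulus_time_ms", "label",
                               "eye_class", "n_flashes")])) != 1)
      stop(sprintf("record %s: metadata varies across its rows", id))
    uv[, g] <- tab$potential_uv[idx]
    info[[g]] <- meta
  }
  ERGRecordingSet(uv, do.call(rbind, info))
}

#' Write a waveform table (JSON dialect)
#'
#' Array of record objects with scalar metadata and `samples` as a numeric
#' array; full-precision numbers, so the JSON round-trips exactly.
#'
#' @inheritParams writeWaveformCSV
#' @return `path`, invisibly.
#' @export
writeWaveformJSON <- function(x, path) {
  stopifnot(is(x, "ERGRecordingSet"))
  cd <- as.data.frame(recordInfo(x))
  uv <- potentials(x)
  recs <- lapply(seq_len(ncol(uv)), function(j) {
    meta <- as.list(cd[j, , drop = FALSE])
    meta$n_samples <- nrow(uv)
    meta$samples <- unname(uv[, j])
    meta
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17),
                           na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a waveform table (JSON dialect)
#'
#' @inheritParams readWaveformCSV
#' @return An [ERGRecordingSet-class].
#' @export
readWaveformJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(recs) == 0)
    return(ERGRecordingSet(matrix(numeric(), 430, 0),
                           data.frame(subject_id = character(), eye = character())))
  n_samples <- unique(vapply(recs, function(r) length(r$samples), integer(1)))
  if (length(n_samples) != 1)
    stop("all records in one file must share the sample count")
  ns_meta <- vapply(recs, function(r) as.integer(r$n_samples %||% n_samples),
                    integer(1))
  bad <- which(ns_meta != n_samples)
  if (length(bad))
    stop(sprintf("record %d: n_samples=%d but %d samples present",
                 bad[1], ns_meta[bad[1]], n_samples))
  uv <- vapply(recs, function(r) as.numeric(r$samples), numeric(n_samples))
  info <- do.call(rbind, lapply(recs, function(r) {
    r$samples <- NULL; r$n_samples <- NULL
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  ERGRecordingSet(matrix(uv, nrow = n_samples), info)
}
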