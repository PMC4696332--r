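# Readers and writers: EDF / TSV-matrix recordings, cohort tables, marker
# tables. All file-format dialects live here.

.NUMERIC_COHORT_COLS <- c(
  "age", "education", "mmse",
  "babcock", "avlt_immediate", "avlt_delayed",
  "hippocampal_volume_l", "hippocampal_volume_r",
  "wscore_frontal_l", "wscore_frontal_r",
  "wscore_parietal_l", "wscore_parietal_r",
  "wscore_temporal_l", "wscore_temporal_r",
  "wscore_thalamus_l", "wscore_thalamus_r",
  "wscore_hippamyg_l", "wscore_hippamyg_r",
  "rel_delta", "rel_theta", "rel_alpha1", "rel_alpha2", "rel_alpha3",
  "rel_beta1", "rel_beta2", "rel_gamma",
  "a3_a2_ratio", "theta_gamma_ratio"
)

#' Read a multichannel EEG recording
#'
#' Reads either an EDF file or a plain delimited numeric matrix
#' (channels x samples, tab-separated, no header) accompanied by a JSON
#' sidecar `<path>.json` declaring `fs` (Hz), `channels` (labels, one per
#' matrix row) and `units` (must be `"microvolts"`). Channel labels are
#' matched case-insensitively against the 10-20 montage; a leading
#' `"EEG "` prefix in EDF labels is stripped.
#'
#' @param path file path (`.edf` or a delimited matrix).
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @return An [EEGRecording-class]; reference is `"as-recorded"` unless the
#'   sidecar declares otherwise.
#' @export
#' @examples
#' rec <- generateEEG(subjectSpec(seed = 1), duration = 10)
#' f <- file.path(tempdir(), "demo.edf")
#' writeEdf(rec, f)
#' readRecording(f)
readRecording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"

  if (format == "edf") {
    raw <- .readEdf(path)
    labels <- sub("^EEG[ _]+", "", raw$channels)
    return(EEGRecording(raw$samples, fs = raw$fs, channels = labels))
  }

  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("matrix recording requires a JSON sidecar at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar must declare the sampling rate 'fs'")
  if (is.null(meta$channels)) stop("sidecar must declare 'channels'")
  units <- meta$units %||% "microvolts"
  if (!identical(tolower(units), "microvolts"))
    stop("sidecar units must be 'microvolts', got: ", units)
  # scan(), not read.table: recordings have tens of thousands of columns
  firstLine <- readLines(path, n = 1)
  ncols <- length(strsplit(firstLine, "\t", fixed = TRUE)[[1]])
  vals <- scan(path, what = numeric(), sep = "\t", quiet = TRUE)
  if (length(vals) %% ncols != 0)
    stop("ragged matrix: rows of unequal length in ", path)
  m <- matrix(vals, ncol = ncols, byrow = TRUE)
  if (nrow(m) != length(meta$channels))
    stop(sprintf("sidecar declares %d channels but matrix has %d rows",
                 length(meta$channels), nrow(m)))
  if (anyNA(m)) stop("matrix contains non-numeric cells")
  reference <- meta$reference %||% "as-recorded"
  EEGRecording(m, fs = meta$fs, channels = meta$channels,
               reference = reference)
}

#' Write a recording as a TSV matrix plus JSON sidecar
#'
#' @param rec an [EEGRecording-class].
#' @param path output path for the tab-separated channels x samples matrix;
#'   the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeRecordingMatrix <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  lines <- vapply(seq_len(nrow(rec@samples)), function(i)
    paste(format(rec@samples[i, ], digits = 15, trim = TRUE,
                 scientific = FALSE), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  jsonlite::write_json(
    list(fs = rec@fs, channels = rec@channels, units = "microvolts",
         reference = rec@reference),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-subject cohort table
#'
#' Reads a tab-separated table with a header row, one row per subject:
#' an `id` column (required, unique), demographic and clinical covariates,
#' EEG marker columns and an optional `outcome` column restricted to the
#' levels `non-converter`, `AD-converter`, `nonAD-converter`. Known numeric
#' columns are coerced; unparseable cells become `NA` with a warning. Empty
#' strings encode missing values.
#'
#' @param path delimited text file.
#' @return A `data.frame` with one row per subject.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "", quote = "", comment.char = "")
  if (nrow(tab) == 0) stop("cohort table has a header but no subjects: ", path)
  if (!"id" %in% names(tab)) stop("cohort table must have an 'id' column")
  if (anyDuplicated(tab$id))
    stop("duplicate subject ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))

  for (col in intersect(names(tab), .NUMERIC_COHORT_COLS)) {
    raw <- tab[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      warning(sprintf("column '%s': %d unparseable cell(s) set to missing",
                      col, sum(bad)))
    tab[[col]] <- num
  }
  if ("outcome" %in% names(tab)) {
    known <- is.na(tab$outcome) | tab$outcome %in% .OUTCOME_LEVELS
    if (!all(known))
      stop("unknown outcome label(s): ",
           paste(unique(tab$outcome[!known]), collapse = ", "),
           " (expected ", paste(.OUTCOME_LEVELS, collapse = ", "), ")")
    tab$outcome <- factor(tab$outcome, levels = .OUTCOME_LEVELS)
  }
  if ("risk_group" %in% names(tab))
    tab$risk_group <- factor(tab$risk_group, levels = .RISK_LEVELS)
  tab
}

#' Write a cohort/marker table
#'
#' Tab-separated, one row per subject, stable column order (as given).
#' Missing values are emitted as empty strings, never sentinel numbers, so
#' the table round-trips through [readCohort()].
#'
#' @param cohort a non-empty `data.frame` with an `id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMarkers <- function(cohort, path) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a data.frame with at least one subject")
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "")
  invisible(path)
}
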