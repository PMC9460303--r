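#' Read an RR-interval file
#'
#' Two plain-text dialects are auto-detected from the first row:
#' a header-less single column of RR intervals in milliseconds (one per
#' line), or a two-column CSV `t_s,rr_ms` with a header line, in which case
#' the `rr_ms` column is used and beat times are recomputed from the
#' intervals.
#'
#' @param path Path to the file.
#' @param subject_id,run_id Labels attached to the returned series.
#' @return An [rr_series()], with input order preserved.
#' @export
read_rr_file <- function(path, subject_id = "S1", run_id = "R1") {
  if (!file.exists(path)) {
    stop(sprintf("read_rr_file: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("read_rr_file: %s is empty", path), call. = FALSE)
  }
  two_col <- grepl(",", lines[[1]], fixed = TRUE)
  if (two_col) {
    dat <- read.csv(text = paste(lines, collapse = "\n"),
                    header = TRUE, colClasses = "character")
    if (!"rr_ms" %in% names(dat)) {
      stop("read_rr_file: two-column dialect requires an 'rr_ms' column",
           call. = FALSE)
    }
    raw <- dat$rr_ms
    line_no <- seq_along(raw) + 1L
  } else {
    raw <- trimws(lines)
    line_no <- seq_along(raw)
  }
  rr <- suppressWarnings(as.numeric(raw))
  if (anyNA(rr)) {
    bad <- line_no[which(is.na(rr))[1]]
    stop(sprintf("read_rr_file: non-numeric RR value at line %d of %s",
                 bad, path), call. = FALSE)
  }
  if (any(rr <= 0)) {
    bad <- line_no[which(rr <= 0)[1]]
    stop(sprintf("read_rr_file: non-positive RR interval at line %d of %s",
                 bad, path), call. = FALSE)
  }
  rr_series(rr, subject_id = subject_id, run_id = run_id)
}

#' Write an RR-interval file
#'
#' Writes the single-column dialect understood by [read_rr_file()], one RR
#' interval per line with three decimal places (lossless round-trip at that
#' precision).
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rr_file <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series$rr_ms) == 0L) {
    stop("write_rr_file: series has no intervals", call. = FALSE)
  }
  writeLines(sprintf("%.3f", series$rr_ms), con = path)
  invisible(path)
}

#' Read a study from a manifest CSV
#'
#' The manifest is a CSV with columns `subject_id`, `run_id`, `path`; each
#' row names one RR file (relative paths are resolved against the manifest's
#' directory).
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A [study_set()].
#' @export
read_study_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("read_study_manifest: file not found: %s", manifest_path),
         call. = FALSE)
  }
  man <- read.csv(manifest_path, colClasses = "character")
  need <- c("subject_id", "run_id", "path")
  if (!all(need %in% names(man))) {
    stop("read_study_manifest: manifest needs columns subject_id, run_id, path",
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  runs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_rr_file(p, subject_id = man$subject_id[i], run_id = man$run_id[i])
  })
  study_set(runs, provenance = sprintf("manifest: %s", manifest_path))
}

#' Write a study to RR files plus a manifest
#'
#' @param study A [study_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(study$runs, function(r) {
    fn <- sprintf("rr_%s_%s.txt", r$subject_id, r$run_id)
    write_rr_file(r, file.path(dir, fn))
    data.frame(subject_id = r$subject_id, run_id = r$run_id, path = fn,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
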