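#' Read and write BCG records as two-column CSV
#'
#' Records are stored as plain text with columns `time_s` and `amplitude`;
#' label intervals travel in a companion `<record>_labels.csv` with columns
#' `start_s`, `end_s`, `label`.
#'
#' @param record A `bcg_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bcg_record <- function(record, path) {
  stopifnot(inherits(record, "bcg_record"))
  n <- length(record$samples)
  readr::write_csv(tibble(time_s = (seq_len(n) - 1) / record$fs,
                          amplitude = record$samples), path)
  readr::write_csv(record$label_intervals, labels_path(path))
  invisible(path)
}

labels_path <- function(path) {
  sub("\\.csv$", "_labels.csv", path)
}

#' @rdname write_bcg_record
#' @param subject_id Subject id to attach to the record read back.
#' @export
read_bcg_record <- function(path, subject_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    abort("Record CSV needs columns `time_s` and `amplitude`.",
          class = "bcgaf_input_error")
  }
  dt <- diff(df$time_s[1:2])
  fs <- round(1 / dt)
  lp <- labels_path(path)
  labels <- if (file.exists(lp)) {
    readr::read_csv(lp, show_col_types = FALSE)
  } else {
    tibble(start_s = numeric(0), end_s = numeric(0), label = character(0))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("-(AF|NAF)$", "", sub("\\.csv$", "", basename(path)))
  }
  new_bcg_record(samples = df$amplitude, fs = fs, subject_id = subject_id,
                 label_intervals = labels)
}

#' Write / read a store of preprocessed segment pairs
#'
#' Each pair is one CSV holding the 3000-sample 24-s segment and the
#' 125-sample 1-s segment (padded with NA to equal length), plus a manifest.
#'
#' @param pairs A segment-pair tibble from [segment_record()].
#' @param dir Output directory.
#' @return The manifest tibble, invisibly (with a `file` column).
#' @export
write_segment_pairs <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    f <- file.path(dir, paste0(pairs$segment_id[i], ".csv"))
    s24 <- pairs$seg24[[i]]
    s1 <- pairs$seg1[[i]]
    readr::write_csv(tibble(seg24 = s24,
                            seg1 = c(s1, rep(NA_real_, length(s24) - length(s1)))),
                     f)
    files[i] <- f
  }
  manifest <- dplyr::select(pairs, !dplyr::any_of(c("seg24", "seg1", "peaks",
                                                    "rhythm_feat")))
  manifest$file <- files
  readr::write_csv(manifest, file.path(dir, "segments.csv"))
  invisible(manifest)
}

#' @rdname write_segment_pairs
#' @export
read_segment_pairs <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "segments.csv"),
                              show_col_types = FALSE)
  segs <- purrr::map(manifest$file, function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE)
    list(seg24 = df$seg24, seg1 = df$seg1[!is.na(df$seg1)])
  })
  manifest$seg24 <- purrr::map(segs, "seg24")
  manifest$seg1 <- purrr::map(segs, "seg1")
  manifest
}
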