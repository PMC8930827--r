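#' @name study_io
#' @title Study container on disk
#' @description
#' A study is stored as a plain-text directory container: `study.json`
#' with the study-level metadata, one CSV per recording under
#' `recordings/` (columns = channels, one row per sample), a JSON sidecar
#' per recording with its sampling rate and labels, and
#' `ground_truth.json` when the study is synthetic. Plain text keeps the
#' container portable and diffable; recordings are written in full double
#' precision.
NULL

#' Write a study to a directory container
#'
#' @param study An `lfp_study` (from [generate_study()]) or a plain list of
#'   [lfp_recording()]s.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for the sample values (default 8; use
#'   `NA` for full precision).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, digits = 8) {
  recs <- if (inherits(study, "lfp_study")) study$recordings else study
  dir.create(file.path(dir, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- list(sessions = unname(lapply(recs, function(r)
    list(id = r$session_id, state = r$state,
         file = file.path("recordings", paste0(r$session_id, ".csv"))))))
  for (r in recs) {
    df <- as.data.frame(r$data)
    if (!is.na(digits)) df <- signif(df, digits)
    write.csv(df, file.path(dir, "recordings", paste0(r$session_id, ".csv")),
              row.names = FALSE)
    side <- list(fs = r$fs, channels = r$channels, state = r$state,
                 session_id = r$session_id)
    jsonlite::write_json(side,
                         file.path(dir, "recordings",
                                   paste0(r$session_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (inherits(study, "lfp_study")) {
    gt <- study$ground_truth
    gt_json <- list(
      signs = gt$signs,
      models = lapply(gt$models, function(m)
        list(A = m$A, sigma = m$sigma, fs = m$fs, channels = m$channels)))
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         digits = NA)
  }
  jsonlite::write_json(meta, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one recording from a study container
#'
#' Channels are reordered to the requested montage order; a montage channel
#' missing from the file is an error.
#'
#' @param path Path to a recording CSV written by [write_study()] (its
#'   JSON sidecar must sit next to it).
#' @param channels Expected montage order; `NULL` keeps the stored order.
#' @return An [lfp_recording()].
#' @export
read_recording <- function(path, channels = LFPGC_CHANNELS) {
  side_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(path)) stop("no such recording: ", path)
  if (!file.exists(side_path)) stop("missing metadata sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dat <- as.matrix(read.csv(path, check.names = FALSE))
  if (any(!is.finite(dat))) stop("recording contains NaN/Inf samples: ", path)
  stored <- colnames(dat)
  if (!is.null(channels)) {
    missing <- setdiff(channels, stored)
    if (length(missing))
      stop("recording ", path, " is missing montage channel(s): ",
           paste(missing, collapse = ", "))
    dat <- dat[, channels, drop = FALSE]
  }
  lfp_recording(dat, fs = side$fs, channels = colnames(dat),
                state = side$state, session_id = side$session_id)
}

#' Read a full study container
#'
#' @param dir Directory written by [write_study()].
#' @param channels Montage order passed to [read_recording()].
#' @return A list of class `lfp_study` (without ground truth unless
#'   `ground_truth.json` is present).
#' @export
read_study <- function(dir, channels = LFPGC_CHANNELS) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  recs <- lapply(meta$sessions$file, function(f)
    read_recording(file.path(dir, f), channels = channels))
  names(recs) <- meta$sessions$id
  out <- list(recordings = recs, ground_truth = NULL, spec = NULL)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    out$ground_truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  structure(out, class = "lfp_study")
}
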