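#' Construct a multichannel recording
#'
#' The basic data container: one subject's channels x samples matrix together
#' with its sampling rate, channel labels and group membership.
#'
#' @param data numeric matrix, channels in rows, samples in columns; all
#'   values must be finite.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param subject_id subject label.
#' @param group group membership, 1 or 2.
#' @param channel_labels character vector, one label per channel; defaults to
#'   `"ch001"`, `"ch002"`, ...
#' @return a `recording` object.
#' @examples
#' r <- recording(matrix(rnorm(400), nrow = 4), sample_rate = 100)
#' r
#' @export
recording <- function(data, sample_rate, subject_id = "s01", group = 1L,
                      channel_labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (any(!is.finite(data))) stop("recording data must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  if (!group %in% c(1L, 2L)) stop("group must be 1 or 2")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%03d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels must match the number of rows of data")
  }
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id), group = as.integer(group),
         data = data, sample_rate = sample_rate,
         channel_labels = as.character(channel_labels)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> subject %s (group %d): %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$sample_rate,
    ncol(x$data) / x$sample_rate))
  invisible(x)
}

#' Write a cohort to a plain-text container
#'
#' One CSV matrix (channels x samples, no header) per subject plus a manifest
#' CSV (`subject_id`, `group`, `file`, `sample_rate`).
#'
#' @param cohort list of [recording()] objects, as from [generate_cohort()].
#' @param dir output directory, created if missing.
#' @return invisibly, the manifest data frame.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    stopifnot(inherits(rec, "recording"))
    files[i] <- sprintf("%s.csv", rec$subject_id)
    utils::write.table(rec$data, file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    group = vapply(cohort, `[[`, 0L, "group"),
    file = files,
    sample_rate = vapply(cohort, `[[`, 0, "sample_rate"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the per-subject matrices.
#' @return list of [recording()] objects.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(file.path(dir, manifest$file[i]),
                                     sep = ",", header = FALSE))
    dimnames(m) <- NULL
    recording(m, sample_rate = manifest$sample_rate[i],
              subject_id = manifest$subject_id[i],
              group = manifest$group[i])
  })
}
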