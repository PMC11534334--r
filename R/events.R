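#' Construct a stimulus event table
#'
#' Events are stored as a plain data.frame with columns `onset` (seconds from
#' recording start), `condition` (`"high_pp"` / `"low_pp"`), `word_id`, and
#' `presentation` (presentation index during wake encoding, or cue count
#' during sleep). Onsets must be strictly increasing.
#'
#' @param onset numeric vector of onsets in seconds, strictly increasing.
#' @param condition character vector (recycled).
#' @param word_id identifier vector (recycled).
#' @param presentation integer vector (recycled).
#' @return data.frame of class `event_set`.
#' @export
event_set <- function(onset, condition = "high_pp", word_id = seq_along(onset),
                      presentation = 1L) {
  onset <- as.numeric(onset)
  if (length(onset) && any(diff(onset) <= 0)) {
    stopf("event onsets must be strictly increasing")
  }
  df <- data.frame(onset = onset,
                   condition = rep_len(as.character(condition), length(onset)),
                   word_id = rep_len(word_id, length(onset)),
                   presentation = rep_len(as.integer(presentation), length(onset)),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_set", "data.frame")
  df
}

#' Read a stimulus event table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row and at least the
#' columns `onset` and `condition`.
#'
#' @param path file path.
#' @return an `event_set` data.frame sorted by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("onset", "condition") %in% names(df))) {
    stopf("event table '%s' must have columns 'onset' and 'condition'", path)
  }
  if (is.null(df$word_id)) df$word_id <- seq_len(nrow(df))
  if (is.null(df$presentation)) df$presentation <- 1L
  if (is.unsorted(df$onset, strictly = TRUE)) {
    stopf("event onsets in '%s' are not strictly increasing", path)
  }
  event_set(df$onset, df$condition, df$word_id, df$presentation)
}

#' Write a stimulus event table to TSV
#'
#' @param events an `event_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Sleep-stage annotation over 30-s epochs
#'
#' @param labels character vector of AASM stage labels
#'   (`W`, `N1`, `N2`, `N3`, `REM`), one per contiguous 30-s epoch starting
#'   at t = 0.
#' @param epoch_s epoch duration in seconds (30 by convention).
#' @return data.frame of class `stage_annotation` with columns
#'   `epoch_index`, `start`, `end`, `label`.
#' @export
stage_annotation <- function(labels, epoch_s = 30) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  n <- length(labels)
  df <- data.frame(epoch_index = seq_len(n),
                   start = (seq_len(n) - 1) * epoch_s,
                   end = seq_len(n) * epoch_s,
                   label = labels, stringsAsFactors = FALSE)
  class(df) <- c("stage_annotation", "data.frame")
  df
}

#' Read / write stage annotations as TSV
#' @param path file path.
#' @return a `stage_annotation`.
#' @export
read_stages <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stopf("stage table '%s' needs a 'label' column", path)
  epoch_s <- if ("end" %in% names(df) && nrow(df)) df$end[1] - df$start[1] else 30
  stage_annotation(df$label, epoch_s = epoch_s)
}

#' @rdname read_stages
#' @param stages a `stage_annotation`.
#' @export
write_stages <- function(stages, path) {
  utils::write.table(as.data.frame(stages), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Keep only events falling in allowed sleep stages
#'
#' An event is retained when its onset lies inside a 30-s epoch whose stage
#' label is in `allowed`. Events beyond the staged range are excluded with a
#' warning. The cueing convention keeps events in N2/N3.
#'
#' @param events an `event_set`.
#' @param stages a `stage_annotation` covering the event range.
#' @param allowed character vector of allowed stage labels.
#' @return filtered `event_set` (subset of the input).
#' @export
mask_by_stage <- function(events, stages, allowed = c("N2", "N3")) {
  if (nrow(events) == 0 || length(allowed) == 0) return(events[integer(0), ])
  epoch_s <- stages$end[1] - stages$start[1]
  idx <- floor(events$onset / epoch_s) + 1
  beyond <- idx > nrow(stages) | idx < 1
  if (any(beyond)) {
    warnf("%d event(s) beyond the staged range excluded", sum(beyond))
  }
  keep <- !beyond
  keep[keep] <- stages$label[idx[keep]] %in% allowed
  events[keep, , drop = FALSE]
}
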