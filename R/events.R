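# Event container: a plain data.frame, one row per detected or annotated
# event. Intervals are half-open [start_s, end_s) in seconds from the
# start of the recording; segment_id is the 1-based 30-s window index.

#' Construct an event table
#'
#' @param kind `"spindle"` or `"kcomplex"` (recycled).
#' @param segment_id 1-based segment index.
#' @param start_s,end_s event interval in seconds, half-open, `end_s > start_s`.
#' @param peak_value detector peak statistic: squared CWT magnitude
#'   (microvolt^2) for spindles, trough amplitude (microvolt, negative)
#'   for K-complexes. `NA` for annotations without one.
#' @param peak_time_s time of the peak statistic in seconds.
#' @return A `data.frame` with class `sw_events` prepended, sorted by
#'   `start_s`.
#' @export
sw_events <- function(kind = character(), segment_id = integer(),
                      start_s = numeric(), end_s = numeric(),
                      peak_value = NA_real_, peak_time_s = NA_real_) {
  n <- max(length(kind), length(segment_id), length(start_s), length(end_s))
  if (n == 0L) {
    df <- data.frame(kind = character(), segment_id = integer(),
                     start_s = numeric(), end_s = numeric(),
                     peak_value = numeric(), peak_time_s = numeric(),
                     stringsAsFactors = FALSE)
    class(df) <- c("sw_events", class(df))
    return(df)
  }
  kind <- rep_len(as.character(kind), n)
  if (!all(kind %in% c("spindle", "kcomplex"))) {
    stop("`kind` must be 'spindle' or 'kcomplex'", call. = FALSE)
  }
  df <- data.frame(kind = kind,
                   segment_id = rep_len(as.integer(segment_id), n),
                   start_s = rep_len(as.numeric(start_s), n),
                   end_s = rep_len(as.numeric(end_s), n),
                   peak_value = rep_len(as.numeric(peak_value), n),
                   peak_time_s = rep_len(as.numeric(peak_time_s), n),
                   stringsAsFactors = FALSE)
  if (any(df$end_s <= df$start_s)) {
    stop("all events must satisfy end_s > start_s", call. = FALSE)
  }
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sw_events", class(df))
  df
}

#' Combine event tables
#'
#' `rbind` for [sw_events()] tables, preserving class and start order;
#' `NULL` and empty tables are dropped.
#'
#' @param ... `sw_events` tables.
#' @return A single `sw_events` table.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(parts) == 0L) return(sw_events())
  df <- do.call(rbind, lapply(parts, function(d) {
    class(d) <- "data.frame"
    d
  }))
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sw_events", class(df))
  df
}
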