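#' Read a raw app log
#'
#' Reads a delimited click log in one of two dialects. The *event* dialect
#' has one row per page view with columns `user_id`, `timestamp`, `page`.
#' The *click* dialect has one row per click with columns `user_id`,
#' `timestamp`, `source`, `destination`; it is expanded into page-view
#' events by emitting each destination page and prepending each user's
#' first source page once, so a trail of `k` clicks yields `k + 1` page
#' views. Comma- vs tab-separation is chosen from the file extension
#' (`.tsv`/`.tab` read as TSV, anything else as CSV).
#'
#' Timestamps must be ISO-8601; values without a timezone are taken as UTC
#' so that inactivity gaps are zone-stable. Rows are sorted by
#' (`user_id`, `timestamp`) on ingest, so per-user event order does not
#' depend on how users' rows were interleaved in the file.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param dialect `"auto"` (detect from columns), `"event"`, or `"click"`.
#' @param tz Timezone applied to timestamps lacking an offset.
#'
#' @return A tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct, UTC) and `page` (character), sorted by user then time.
#'   An empty file yields an empty tibble with a warning.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "user_id,timestamp,source,destination",
#'   "u1,2017-09-01T08:00:00Z,Coach,Track",
#'   "u1,2017-09-01T08:01:00Z,Track,Route"
#' ), f)
#' read_app_log(f)$page  # "Coach" "Track" "Route"
read_app_log <- function(path, dialect = c("auto", "event", "click"),
                         tz = "UTC") {
  dialect <- match.arg(dialect)
  reader <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("empty log file: ", path))
    return(tibble::tibble(user_id = character(), timestamp = empty_utc(),
                          page = character()))
  }
  if (dialect == "auto") {
    dialect <- if (all(c("source", "destination") %in% names(raw))) "click" else "event"
  }
  required <- switch(dialect,
    event = c("user_id", "timestamp", "page"),
    click = c("user_id", "timestamp", "source", "destination")
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("log is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ts <- parse_iso8601(raw$timestamp, tz = tz)
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad)) {
    abort(paste0("unparseable timestamp(s) at line(s) ",
                 paste(bad + 1L, collapse = ", "),
                 " (expected ISO-8601)"))
  }
  raw$timestamp <- ts

  events <- if (dialect == "event") {
    dplyr::select(raw, "user_id", "timestamp", "page")
  } else {
    raw |>
      dplyr::arrange(.data$user_id, .data$timestamp) |>
      dplyr::group_by(.data$user_id) |>
      dplyr::reframe(
        timestamp = c(.data$timestamp[1], .data$timestamp),
        page = c(.data$source[1], .data$destination)
      )
  }
  events |>
    dplyr::arrange(.data$user_id, .data$timestamp) |>
    tibble::as_tibble()
}

#' Write / read an event stream as line-delimited JSON
#'
#' One JSON object per line with keys `user_id`, `timestamp` (ISO-8601,
#' UTC, second precision) and `page`; the pair round-trips an event
#' tibble exactly when timestamps are whole seconds.
#'
#' @param events Event tibble as returned by [read_app_log()].
#' @param path Destination (ndjson) file.
#' @return `write_event_log()` returns `events` invisibly;
#'   `read_event_log()` returns the event tibble.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(c("user_id", "timestamp", "page") %in% names(events)))
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(
      user_id = events$user_id[i],
      timestamp = format(events$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      page = events$page[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(events)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(tibble::tibble(user_id = character(), timestamp = empty_utc(),
                          page = character()))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    user_id = vapply(recs, `[[`, character(1), "user_id"),
    timestamp = parse_iso8601(vapply(recs, `[[`, character(1), "timestamp")),
    page = vapply(recs, `[[`, character(1), "page")
  )
}

#' Write / read a labelled transition matrix as CSV
#'
#' The matrix is stored with a leading `state` column holding row labels
#' and one column per destination state. Probabilities are written at
#' full precision, so a write followed by [read_transition_matrix()]
#' reproduces the matrix bit-identically.
#'
#' @param mat Square numeric matrix with identical row and column names.
#' @param path Destination CSV file.
#' @return `write_transition_matrix()` returns `mat` invisibly;
#'   `read_transition_matrix()` returns a named numeric matrix.
#' @export
write_transition_matrix <- function(mat, path) {
  if (!is.matrix(mat) || nrow(mat) == 0) {
    abort("expected a non-empty matrix")
  }
  if (nrow(mat) != ncol(mat)) {
    abort(sprintf("matrix must be square (got %d x %d)", nrow(mat), ncol(mat)))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("matrix must carry row and column state labels")
  }
  out <- tibble::as_tibble(mat, rownames = "state")
  readr::write_csv(out, path)
  invisible(mat)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    state = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$state
  if (nrow(mat) != ncol(mat) || !identical(rownames(mat), colnames(mat))) {
    abort("file does not contain a square labelled matrix")
  }
  mat
}

# ISO-8601 parser; bare datetimes are interpreted in `tz`, results in UTC.
# readr's own parse warning is dropped: failures become row-level errors
# at the call sites.
parse_iso8601 <- function(x, tz = "UTC") {
  out <- suppressWarnings(readr::parse_datetime(x, locale = readr::locale(tz = tz)))
  attr(out, "tzone") <- "UTC"
  out
}

empty_utc <- function() {
  as.POSIXct(character(), tz = "UTC")
}
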