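#' Segment an event stream into sessions by inactivity gap
#'
#' Apps that log no session identifier need sessions reconstructed from
#' timestamps: a new session starts whenever the gap to the user's
#' previous event is *strictly greater* than `gap` minutes, so a gap of
#' exactly `gap` minutes stays within the session ("no longer than 30
#' minutes of inactivity"). Sessions of different users never merge.
#'
#' With `collapse_repeats = TRUE` (the default) consecutive identical
#' pages inside a session are merged into a single state occurrence, as
#' required for a chain whose transition matrix has an empty diagonal;
#' switch it off for logs where page refreshes are meaningful. The
#' reported `length` is the trail length after collapsing; `n_events`
#' keeps the raw event count so events are conserved across the
#' partition.
#'
#' @param events Event tibble with columns `user_id`, `timestamp`,
#'   `page` (see [read_app_log()]).
#' @param gap Inactivity threshold in minutes (or a [difftime]).
#'   Default 30.
#' @param collapse_repeats Merge consecutive duplicate pages within a
#'   session. Default `TRUE`.
#'
#' @return A tibble with one row per session: `user_id`,
#'   `session_index` (ordinal per user), `start`, `end`, `n_events`
#'   (raw events), `trail` (list of page labels, exit not included) and
#'   `length` (trail length).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   user_id = "u1",
#'   timestamp = as.POSIXct("2017-09-01 08:00:00", tz = "UTC") +
#'     60 * c(0, 10, 50),
#'   page = c("Coach", "Track", "Coach")
#' )
#' sessionize(ev)$length  # 40-min gap splits: 2 1
sessionize <- function(events, gap = 30, collapse_repeats = TRUE) {
  if (inherits(gap, "difftime")) gap <- as.numeric(gap, units = "mins")
  if (!is.numeric(gap) || length(gap) != 1 || is.na(gap) || gap < 0) {
    abort("`gap` must be a single non-negative number of minutes")
  }
  gap_secs <- gap * 60
  if (nrow(events) == 0) {
    return(tibble::tibble(
      user_id = character(), session_index = integer(),
      start = empty_utc(), end = empty_utc(),
      n_events = integer(), trail = list(), length = integer()
    ))
  }
  sessions <- events |>
    dplyr::arrange(.data$user_id, .data$timestamp) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      .gap = as.numeric(.data$timestamp) - dplyr::lag(as.numeric(.data$timestamp)),
      session_index = cumsum(is.na(.data$.gap) | .data$.gap > gap_secs)
    ) |>
    dplyr::group_by(.data$user_id, .data$session_index) |>
    dplyr::summarise(
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_events = dplyr::n(),
      trail = list(.data$page),
      .groups = "drop"
    )
  if (collapse_repeats) {
    sessions$trail <- lapply(sessions$trail, function(tr) rle(tr)$values)
  }
  sessions$length <- lengths(sessions$trail)
  dplyr::arrange(sessions, .data$user_id, .data$session_index)
}

#' Keep sessions whose trail length falls in a range
#'
#' Trail length is counted on the (possibly collapsed) trail, excluding
#' the exit state; bounds are inclusive. Used with the defaults 2--20 to
#' drop one-tap sessions and extreme outliers before visualization.
#'
#' @param sessions Session tibble from [sessionize()].
#' @param min_len,max_len Inclusive length bounds; `min_len >= 1`,
#'   `max_len >= min_len` (`Inf` allowed).
#' @return The filtered session tibble, original order preserved.
#' @export
filter_sessions <- function(sessions, min_len = 2, max_len = 20) {
  if (min_len < 1) abort("`min_len` must be at least 1")
  if (max_len < min_len) abort("`max_len` must be >= `min_len`")
  dplyr::filter(sessions, .data$length >= min_len, .data$length <= max_len)
}
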