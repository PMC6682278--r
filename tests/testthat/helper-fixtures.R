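# Small chains and session builders shared across the suite.

# 3-page chain with every transition positive, used for likelihood oracles.
toy_chain <- function() {
  P <- matrix(c(
    0.1, 0.4, 0.3, 0.2,
    0.3, 0.1, 0.4, 0.2,
    0.2, 0.3, 0.1, 0.4,
    0,   0,   0,   0
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "B", "C", "Exit"), c("A", "B", "C", "Exit")))
  markov_model(P, pi = c(A = 0.5, B = 0.3, C = 0.2))
}

# deterministic two-step chain: first -> second -> exit
det_chain <- function(first, second) {
  s <- c(first, second, "Exit")
  P <- matrix(0, 3, 3, dimnames = list(s, s))
  P[first, second] <- 1
  P[second, "Exit"] <- 1
  markov_model(P, pi = stats::setNames(1, first))
}

sessions_from_trails <- function(trails, user_id = "u1") {
  tibble::tibble(
    user_id = user_id,
    session_index = seq_along(trails),
    trail = trails,
    length = lengths(trails)
  )
}

# events for one user at given offsets (minutes from an arbitrary origin)
events_at <- function(minutes, pages, user_id = "u1") {
  tibble::tibble(
    user_id = user_id,
    timestamp = as.POSIXct("2017-09-01 08:00:00", tz = "UTC") + minutes * 60,
    page = pages
  )
}

# best-match label agreement over all cluster relabelings
best_match_accuracy <- function(truth, assignments, k) {
  perms <- perms_of(seq_len(k))
  max(vapply(perms, function(p) mean(p[truth] == assignments), numeric(1)))
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  unlist(lapply(seq_along(x), function(i) {
    lapply(perms_of(x[-i]), function(p) c(x[i], p))
  }), recursive = FALSE)
}

# all trails of the given lengths over a page alphabet (exit not included)
enumerate_trails <- function(pages, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, c(rep(list(pages), len),
                                   stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      as.character(unlist(grid[i, ], use.names = FALSE))))
  }
  out
}
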