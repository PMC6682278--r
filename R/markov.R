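#' Construct a first-order Markov chain model over app pages
#'
#' A fitted or hand-specified navigation model is a first-order Markov
#' chain over the app's pages plus a surrogate absorbing *exit* state
#' appended as the last row/column: leaving the app is modelled as a
#' transition into `exit_label`, whose own row is all zero by convention
#' and never sampled from.
#'
#' @param P Square numeric matrix with identical row/column labels, the
#'   exit state last. Non-exit rows must sum to 1 within `row_tol`
#'   unless they are all-zero ("dangling": states with no observed
#'   outgoing transition).
#' @param pi Named initial state distribution. Names may cover only the
#'   page states; missing entries are taken as 0 and the exit state must
#'   carry no mass. Must sum to 1 within `1e-9`.
#' @param exit_label Label of the absorbing exit state. Default `"Exit"`.
#' @param counts Optional matrix of raw transition counts with the same
#'   labels as `P`.
#' @param n_sessions Optional number of sessions the model was fitted on.
#' @param row_tol Tolerance for non-exit row sums. Use a loose value for
#'   matrices transcribed from rounded published tables.
#'
#' @return An object of class `markov_model`: a list with elements
#'   `states` (page labels, exit excluded), `exit_label`, `P`, `pi`,
#'   `counts`, `n_sessions` and `dangling` (labels of all-zero non-exit
#'   rows).
#' @export
#' @examples
#' P <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "Exit"), c("A", "B", "Exit")))
#' m <- markov_model(P, pi = c(A = 1))
#' simulate_session(m, seed = 1)  # always c("A", "B")
markov_model <- function(P, pi, exit_label = "Exit", counts = NULL,
                         n_sessions = NA_integer_, row_tol = 1e-6) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || nrow(P) < 2) {
    abort("`P` must be a square matrix with at least 2 states")
  }
  if (is.null(rownames(P)) || !identical(rownames(P), colnames(P))) {
    abort("`P` must have identical row and column state labels")
  }
  all_states <- rownames(P)
  if (anyDuplicated(all_states)) abort("state labels must be unique")
  if (!exit_label %in% all_states) {
    abort(sprintf("exit state '%s' not found among the states", exit_label))
  }
  if (all_states[length(all_states)] != exit_label) {
    abort(sprintf("exit state '%s' must be the last row/column", exit_label))
  }
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  if (any(P[exit_label, ] != 0)) {
    abort("the exit row must be all zero (absorbing exit convention)")
  }
  states <- all_states[-length(all_states)]
  rs <- rowSums(P)[states]
  dangling <- names(rs)[rs == 0]
  off <- abs(rs - 1) > row_tol & rs != 0
  if (any(off)) {
    abort(paste0("non-exit row(s) do not sum to 1: ",
                 paste(names(rs)[off], collapse = ", ")))
  }

  pi_full <- stats::setNames(numeric(length(all_states)), all_states)
  if (is.null(names(pi)) || !all(names(pi) %in% all_states)) {
    abort("`pi` must be named with known state labels")
  }
  pi_full[names(pi)] <- pi
  if (pi_full[exit_label] != 0) abort("`pi` must place no mass on the exit state")
  if (any(pi_full < 0) || abs(sum(pi_full) - 1) > 1e-9) {
    abort("`pi` must be a probability distribution summing to 1")
  }
  if (!is.null(counts)) {
    if (!is.matrix(counts) || !identical(dimnames(counts), dimnames(P))) {
      abort("`counts` must share the state labels of `P`")
    }
  }
  structure(
    list(states = states, exit_label = exit_label, P = P, pi = pi_full,
         counts = counts, n_sessions = as.integer(n_sessions),
         dangling = dangling),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("First-order Markov chain: %d pages + '%s'\n",
              length(x$states), x$exit_label))
  cat("  pages:", paste(x$states, collapse = ", "), "\n")
  if (!is.na(x$n_sessions)) cat(sprintf("  fitted on %d sessions\n", x$n_sessions))
  if (length(x$dangling)) {
    cat("  dangling (no outgoing transitions):",
        paste(x$dangling, collapse = ", "), "\n")
  }
  top <- tidy(x) |>
    dplyr::filter(.data$probability > 0) |>
    dplyr::arrange(dplyr::desc(.data$probability)) |>
    head(5)
  if (nrow(top)) {
    cat("  strongest transitions:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s -> %s  %.2f\n", top$from[i], top$to[i],
                  top$probability[i]))
    }
  }
  invisible(x)
}

# States occurring in any trail, in stable sorted order.
observed_states <- function(sessions) {
  sort(unique(unlist(sessions$trail, use.names = FALSE)))
}

check_known_states <- function(labels, states, exit_label) {
  unknown <- setdiff(labels, c(states, exit_label))
  if (length(unknown)) {
    abort(paste0("unknown state label(s): ", paste(unknown, collapse = ", ")))
  }
}

#' Count observed page transitions, including exits
#'
#' Every adjacent pair in a trail contributes one count, and each
#' session additionally contributes one count from its final page into
#' the exit state, so a trail of `k` pages contributes exactly `k`
#' counts and a length-1 trail contributes a single page-to-exit count.
#'
#' @param sessions Session tibble with a `trail` list-column
#'   (see [sessionize()]).
#' @param states Character vector of page labels fixing the state order.
#'   Defaults to the sorted set of pages observed in the trails.
#' @param exit_label Label for the surrogate exit state.
#' @return An integer matrix of transition counts over
#'   `c(states, exit_label)`, exit row all zero.
#' @export
count_transitions <- function(sessions, states = NULL, exit_label = "Exit") {
  states <- states %||% observed_states(sessions)
  if (exit_label %in% states) {
    abort(sprintf("exit label '%s' must not be a page state", exit_label))
  }
  trails <- sessions$trail
  check_known_states(unique(unlist(trails, use.names = FALSE)), states, exit_label)
  all_states <- c(states, exit_label)
  from <- unlist(trails, use.names = FALSE)
  to <- unlist(lapply(trails, function(tr) c(tr[-1], exit_label)),
               use.names = FALSE)
  M <- table(factor(from, levels = all_states),
             factor(to, levels = all_states))
  M <- matrix(as.integer(M), nrow = length(all_states),
              dimnames = list(all_states, all_states))
  M
}

#' Row-normalize transition counts into probabilities
#'
#' Divides each row by its sum; rows with no outgoing counts (always
#' including the exit row) are left all-zero and reported in the
#' `dangling` attribute. Zeros are preserved: no smoothing is applied at
#' this stage.
#'
#' @param counts Count matrix from [count_transitions()].
#' @return A row-stochastic numeric matrix with attribute `dangling`
#'   naming the all-zero rows.
#' @export
normalize_counts <- function(counts) {
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  P <- matrix(as.numeric(P), nrow = nrow(counts), dimnames = dimnames(counts))
  attr(P, "dangling") <- rownames(counts)[rs == 0]
  P
}

#' Estimate the initial state distribution
#'
#' The probability that a session starts on each page, estimated as the
#' share of sessions whose first visited state is that page. The exit
#' state always has mass 0.
#'
#' @inheritParams count_transitions
#' @return A named numeric vector over `c(states, exit_label)` summing
#'   to 1.
#' @export
estimate_initial <- function(sessions, states = NULL, exit_label = "Exit") {
  if (nrow(sessions) == 0) abort("cannot estimate initial distribution from 0 sessions")
  states <- states %||% observed_states(sessions)
  firsts <- vapply(sessions$trail, `[[`, character(1), 1)
  check_known_states(unique(firsts), states, exit_label)
  all_states <- c(states, exit_label)
  tab <- table(factor(firsts, levels = all_states))
  stats::setNames(as.numeric(tab) / nrow(sessions), all_states)
}

#' Fit a first-order Markov chain to session trails
#'
#' Composition of [count_transitions()], [normalize_counts()] and
#' [estimate_initial()]: counts all within-trail and trail-to-exit
#' transitions, row-normalizes them into a transition matrix and
#' estimates the initial distribution from first visited states.
#'
#' @inheritParams count_transitions
#' @return A [markov_model()] object carrying the transition matrix,
#'   initial distribution and raw counts.
#' @export
#' @examples
#' sess <- tibble::tibble(trail = list(c("A", "B"), c("A", "B"), "B"))
#' m <- fit_markov(sess)
#' m$P["A", "B"]  # 1
#' m$pi[["A"]]    # 2/3
fit_markov <- function(sessions, states = NULL, exit_label = "Exit") {
  states <- states %||% observed_states(sessions)
  M <- count_transitions(sessions, states, exit_label)
  P <- normalize_counts(M)
  pi <- estimate_initial(sessions, states, exit_label)
  dangling <- attr(P, "dangling")
  attr(P, "dangling") <- NULL
  markov_model(P, pi, exit_label = exit_label, counts = M,
               n_sessions = nrow(sessions))
}

#' Log-likelihood of a trail under a Markov chain
#'
#' The likelihood of a session trail is the product of its per-step
#' transition probabilities, e.g. `L({s0, s3, s1, exit}) = p[0,3] *
#' p[3,1] * p[1,exit]`; this returns its natural logarithm. The exit
#' state is appended to the trail when absent, so the final
#' page-to-exit step is always scored. Any step with probability 0
#' yields `-Inf`. By default the initial-state probability is *not*
#' included, matching the product form above; set `include_initial =
#' TRUE` to add `log pi` of the first state.
#'
#' @param model A [markov_model()].
#' @param trail Character vector of visited states.
#' @param include_initial Add the log initial-state probability.
#' @return A single numeric log-probability (possibly `-Inf`).
#' @export
sequence_log_likelihood <- function(model, trail, include_initial = FALSE) {
  if (length(trail) == 0) abort("`trail` must contain at least one state")
  check_known_states(unique(trail), model$states, model$exit_label)
  if (trail[length(trail)] != model$exit_label) {
    trail <- c(trail, model$exit_label)
  }
  if (length(trail) < 2) abort("`trail` must have at least 2 states including exit")
  idx <- match(trail, rownames(model$P))
  steps <- log(model$P[cbind(idx[-length(idx)], idx[-1])])
  ll <- sum(steps)
  if (include_initial) ll <- ll + log(model$pi[[trail[1]]])
  ll
}

#' Simulate session trails from a Markov chain
#'
#' Draws the first page from the initial distribution (exit excluded),
#' then repeatedly draws the next state from the current page's row of
#' the transition matrix until the exit state is drawn or `max_len`
#' pages have been emitted. Row weights are normalized at sampling
#' time, so matrices transcribed from rounded tables whose printed rows
#' sum to 0.99--1.01 are handled sensibly. The returned trails exclude
#' the exit state.
#'
#' @param model A [markov_model()].
#' @param n Number of sessions to simulate.
#' @param max_len Maximum number of pages per trail; trails cut off at
#'   this length are flagged `truncated`.
#' @param seed Optional integer seed; the global RNG state is left
#'   untouched when it is supplied.
#' @return `simulate_sessions()` returns a tibble with columns
#'   `session_index`, `trail` (list of character), `length` and
#'   `truncated`. `simulate_session()` returns a single character trail
#'   with attribute `truncated`.
#' @export
simulate_sessions <- function(model, n, max_len = 100, seed = NULL) {
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive integer")
  if (!is.numeric(max_len) || max_len < 1) abort("`max_len` must be >= 1")
  run <- function() simulate_sessions_impl(model, as.integer(n), as.integer(max_len))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_sessions_impl <- function(model, n, max_len) {
  all_states <- rownames(model$P)
  m <- length(all_states)
  exit_i <- m
  pi_pages <- model$pi[-m]
  if (sum(pi_pages) <= 0) abort("initial distribution has no mass on pages")
  mat <- matrix(NA_integer_, nrow = n, ncol = max_len)
  mat[, 1] <- sample.int(m - 1L, n, replace = TRUE, prob = pi_pages)
  active <- seq_len(n)
  step <- 1L
  while (length(active) && step < max_len) {
    cur <- mat[active, step]
    nxt <- integer(length(cur))
    for (s in sort(unique(cur))) {
      row <- model$P[s, ]
      if (sum(row) <= 0) {
        abort(sprintf("dangling state '%s' reached during simulation: no outgoing transitions",
                      all_states[s]))
      }
      sel <- which(cur == s)
      nxt[sel] <- sample.int(m, length(sel), replace = TRUE, prob = row)
    }
    step <- step + 1L
    cont <- nxt != exit_i
    if (any(cont)) mat[active[cont], step] <- nxt[cont]
    active <- active[cont]
  }
  truncated <- logical(n)
  truncated[active] <- TRUE
  trails <- lapply(seq_len(n), function(i) {
    idx <- mat[i, ]
    all_states[idx[!is.na(idx)]]
  })
  tibble::tibble(
    session_index = seq_len(n),
    trail = trails,
    length = lengths(trails),
    truncated = truncated
  )
}

#' @rdname simulate_sessions
#' @export
simulate_session <- function(model, max_len = 100, seed = NULL) {
  out <- simulate_sessions(model, 1L, max_len = max_len, seed = seed)
  trail <- out$trail[[1]]
  attr(trail, "truncated") <- out$truncated[1]
  trail
}

#' Summarize page views across sessions
#'
#' Absolute view counts per page across all trails, with each page's
#' relative share of total views in percent. Shares sum to 100.
#'
#' @inheritParams count_transitions
#' @return A tibble with columns `page`, `views` and `share` (percent),
#'   sorted by decreasing views.
#' @export
page_view_summary <- function(sessions) {
  if (nrow(sessions) == 0) abort("no sessions supplied")
  pages <- unlist(sessions$trail, use.names = FALSE)
  tab <- sort(table(pages), decreasing = TRUE)
  tibble::tibble(
    page = names(tab),
    views = as.integer(tab),
    share = as.integer(tab) / length(pages) * 100
  )
}

#' @method tidy markov_model
#' @export
tidy.markov_model <- function(x, ...) {
  all_states <- rownames(x$P)
  out <- tibble::tibble(
    from = rep(all_states, times = length(all_states)),
    to = rep(all_states, each = length(all_states)),
    probability = as.numeric(x$P)
  )
  if (!is.null(x$counts)) out$count <- as.integer(x$counts)
  out$from <- factor(out$from, levels = all_states)
  out$to <- factor(out$to, levels = all_states)
  dplyr::arrange(out, .data$from, .data$to) |>
    dplyr::mutate(from = as.character(.data$from), to = as.character(.data$to))
}

#' @method glance markov_model
#' @export
glance.markov_model <- function(x, ...) {
  tibble::tibble(
    n_pages = length(x$states),
    exit_label = x$exit_label,
    n_sessions = x$n_sessions,
    n_transitions = if (is.null(x$counts)) NA_integer_ else sum(x$counts),
    n_dangling = length(x$dangling)
  )
}

#' @method autoplot markov_model
#' @export
autoplot.markov_model <- function(object, label_digits = 2, ...) {
  all_states <- rownames(object$P)
  df <- tidy(object)
  df$from <- factor(df$from, levels = rev(all_states))
  df$to <- factor(df$to, levels = all_states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$probability > 0,
                                  formatC(.data$probability,
                                          digits = label_digits,
                                          format = "f"), "")),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "to", y = "from", fill = "p",
                  title = "Transition probabilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
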