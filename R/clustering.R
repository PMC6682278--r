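#' Cluster session trails with a hard-EM mixture of Markov chains
#'
#' Groups session trails into `k` clusters, each represented by its own
#' first-order Markov chain, using classification (hard) EM:
#'
#' 1. assign every trail to a uniformly random cluster;
#' 2. build each cluster's transition matrix from its assigned trails
#'    (exit appended), adding `pseudocount` to every non-exit-row cell
#'    before normalization;
#' 3. score every trail under every cluster chain as the sum of log
#'    per-step transition probabilities and reassign it to the argmax
#'    cluster (ties go to the lowest cluster index);
#' 4. repeat until the assignment vector is identical to the previous
#'    iteration's, or `max_iter` is reached.
#'
#' The pseudocount keeps every admissible transition at nonzero
#' probability inside every cluster; without it a trail containing a
#' transition unseen in a cluster scores `-Inf` there and reassignment
#' stalls. A cluster left empty by a reassignment is re-seeded with the
#' currently worst-fitting trail so `k` components survive to the end.
#' Initial distributions are estimated per cluster but, like the
#' per-trail scores, are not part of the likelihood used for
#' assignment.
#'
#' @param sessions Session tibble with a `trail` list-column.
#' @param k Number of clusters (`1 <= k <= nrow(sessions)`).
#' @param seed Optional integer seed making the fit reproducible; the
#'   global RNG state is left untouched when supplied.
#' @param max_iter Iteration cap; if reached without a repeated
#'   assignment vector the result is flagged `converged = FALSE`.
#' @param pseudocount Smoothing constant added to every non-exit-row
#'   cell of each cluster's count matrix. Default 0.5.
#' @param n_restarts Number of independent random initializations; the
#'   fit with the highest total assigned log-likelihood is returned.
#' @param states Page labels fixing the state order; defaults to the
#'   sorted pages observed in the trails.
#' @param exit_label Label for the surrogate exit state.
#'
#' @return An object of class `trail_clusters`: a list with `k`,
#'   `models` (one [markov_model()] per cluster, pseudocount-smoothed),
#'   `assignments` (per-session cluster index), `n_iter`, `converged`,
#'   `logLik` (total assigned log-likelihood), `logLik_trace` (one
#'   value per iteration of the winning restart), `pseudocount`,
#'   `seed`, `states`, `exit_label` and `n_sessions`.
#' @export
#' @examples
#' sess <- tibble::tibble(trail = c(
#'   rep(list(c("A", "B")), 5), rep(list(c("C", "D")), 5)
#' ))
#' cl <- cluster_sequences(sess, k = 2, seed = 1)
#' table(cl$assignments)  # 5 and 5
cluster_sequences <- function(sessions, k, seed = NULL, max_iter = 100,
                              pseudocount = 0.5, n_restarts = 1,
                              states = NULL, exit_label = "Exit") {
  n <- nrow(sessions)
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a positive integer")
  k <- as.integer(k)
  if (k > n) abort(sprintf("`k` (%d) exceeds the number of sessions (%d)", k, n))
  if (max_iter < 1) abort("`max_iter` must be at least 1")
  if (pseudocount < 0) abort("`pseudocount` must be non-negative")
  if (n_restarts < 1) abort("`n_restarts` must be at least 1")
  states <- states %||% observed_states(sessions)
  if (exit_label %in% states) {
    abort(sprintf("exit label '%s' must not be a page state", exit_label))
  }
  check_known_states(unique(unlist(sessions$trail, use.names = FALSE)),
                     states, exit_label)
  all_states <- c(states, exit_label)
  m <- length(all_states)

  # flat encoding of all transitions: session id, from-index, to-index
  trails_idx <- lapply(sessions$trail, function(tr) match(tr, all_states))
  sid <- rep.int(seq_len(n), lengths(trails_idx))
  from_i <- unlist(trails_idx, use.names = FALSE)
  to_i <- unlist(lapply(trails_idx, function(ix) c(ix[-1], m)), use.names = FALSE)
  cell <- (to_i - 1L) * m + from_i

  run_all <- function() {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- hard_em_once(n, k, m, sid, cell, max_iter, pseudocount)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  # final per-cluster chains rebuilt from the final assignment
  models <- lapply(seq_len(k), function(c) {
    in_c <- which(best$assignments == c)
    sub <- sessions[in_c, , drop = FALSE]
    M <- count_transitions(sub, states, exit_label)
    Msm <- M
    Msm[seq_len(m - 1), ] <- Msm[seq_len(m - 1), ] + pseudocount
    P <- normalize_counts(Msm)
    attr(P, "dangling") <- NULL
    if (pseudocount == 0) {
      # unsmoothed: dangling rows possible, tolerated by the constructor
      P <- normalize_counts(M)
      attr(P, "dangling") <- NULL
    }
    markov_model(P, estimate_initial(sub, states, exit_label),
                 exit_label = exit_label, counts = M,
                 n_sessions = length(in_c))
  })

  structure(
    list(k = k, models = models, assignments = best$assignments,
         n_iter = best$n_iter, converged = best$converged,
         logLik = best$logLik, logLik_trace = best$trace,
         pseudocount = pseudocount, seed = seed, states = states,
         exit_label = exit_label, n_sessions = n),
    class = "trail_clusters"
  )
}

# One hard-EM run from a fresh random assignment. Works on the flat
# transition encoding; returns assignments, iteration count and the
# total-assigned-log-likelihood trace.
hard_em_once <- function(n, k, m, sid, cell, max_iter, pseudocount) {
  assign_cur <- sample.int(k, n, replace = TRUE)
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  ll <- NULL
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    logP <- cluster_log_matrices(assign_cur, k, m, sid, cell, pseudocount)
    ll <- vapply(seq_len(k), function(c) {
      as.numeric(rowsum(logP[[c]][cell], sid))
    }, numeric(n))
    if (n == 1) ll <- matrix(ll, nrow = 1)
    assign_new <- max.col(ll, ties.method = "first")
    assign_new <- repair_empty_clusters(assign_new, ll, k)
    trace <- c(trace, sum(ll[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_cur)) {
      converged <- TRUE
      assign_cur <- assign_new
      break
    }
    assign_cur <- assign_new
  }
  # score the final assignment under chains built from that assignment,
  # so logLik is self-consistent even on max_iter expiry
  logP <- cluster_log_matrices(assign_cur, k, m, sid, cell, pseudocount)
  ll_fin <- vapply(seq_len(k), function(c) {
    as.numeric(rowsum(logP[[c]][cell], sid))
  }, numeric(n))
  if (n == 1) ll_fin <- matrix(ll_fin, nrow = 1)
  list(assignments = assign_cur, n_iter = n_iter, converged = converged,
       logLik = sum(ll_fin[cbind(seq_len(n), assign_cur)]), trace = trace)
}

# Per-cluster log transition matrices from the current assignment,
# pseudocount-smoothed on non-exit rows.
cluster_log_matrices <- function(assignment, k, m, sid, cell, pseudocount) {
  lapply(seq_len(k), function(c) {
    sel <- assignment[sid] == c
    M <- matrix(tabulate(cell[sel], nbins = m * m), nrow = m)
    M[seq_len(m - 1), ] <- M[seq_len(m - 1), ] + pseudocount
    rs <- rowSums(M)
    P <- M / ifelse(rs == 0, 1, rs)
    log(P)
  })
}

# Re-seed each empty cluster with the worst-fitting trail from a
# cluster that can spare one, keeping k components alive.
repair_empty_clusters <- function(assignment, ll, k) {
  repeat {
    sizes <- tabulate(assignment, nbins = k)
    empty <- which(sizes == 0)
    if (!length(empty)) return(assignment)
    assigned_ll <- ll[cbind(seq_along(assignment), assignment)]
    donor_ok <- sizes[assignment] > 1
    if (!any(donor_ok)) return(assignment)
    worst <- which(donor_ok)[which.min(assigned_ll[donor_ok])]
    assignment[worst] <- empty[1]
  }
}

#' Classify a new trail against fitted cluster chains
#'
#' Scores the trail's log-likelihood under every cluster's Markov chain
#' and returns the argmax cluster; ties are broken by the lowest
#' cluster index.
#'
#' @param model A `trail_clusters` fit from [cluster_sequences()].
#' @param trail Character vector of visited states.
#' @return A list with `cluster` (integer index) and `log_lik`
#'   (numeric vector of per-cluster log-likelihoods).
#' @export
classify_trail <- function(model, trail) {
  ll <- vapply(model$models, sequence_log_likelihood, numeric(1), trail = trail)
  list(cluster = which.max(ll), log_lik = ll)
}

#' Total assigned log-likelihood of a cluster fit
#'
#' Sum over sessions of the log-likelihood of each trail under the
#' chain of its assigned cluster. For the sessions the model was
#' fitted on this equals the fit's `logLik`.
#'
#' @param model A `trail_clusters` fit.
#' @param sessions The session tibble the model was fitted on.
#' @return A single numeric value.
#' @export
total_log_likelihood <- function(model, sessions) {
  if (nrow(sessions) != model$n_sessions) {
    abort("`sessions` must be the sessions the model was fitted on")
  }
  sum(vapply(seq_len(nrow(sessions)), function(i) {
    sequence_log_likelihood(model$models[[model$assignments[i]]],
                            sessions$trail[[i]])
  }, numeric(1)))
}

#' @export
print.trail_clusters <- function(x, ...) {
  cat(sprintf("Mixture of %d Markov chains over %d sessions (hard EM)\n",
              x$k, x$n_sessions))
  cat(sprintf("  iterations: %d (%s), total log-likelihood: %.2f\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$logLik))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy trail_clusters
#' @export
tidy.trail_clusters <- function(x, ...) {
  tibble::tibble(
    session = seq_len(x$n_sessions),
    cluster = x$assignments
  )
}

#' @method glance trail_clusters
#' @export
glance.trail_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_sessions = x$n_sessions,
    n_iter = x$n_iter,
    converged = x$converged,
    logLik = x$logLik,
    pseudocount = x$pseudocount
  )
}

#' @method autoplot trail_clusters
#' @export
autoplot.trail_clusters <- function(object, sessions, min_len = 2,
                                    max_len = 20, ...) {
  tab <- cluster_trail_table(object, sessions, min_len, max_len)
  long <- tab |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::unnest_longer("trail", values_to = "page", indices_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$row,
                                     fill = .data$page)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "action", y = "session", fill = "page",
                  title = "Session trails by cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

# Shared by the heatmap export and autoplot: filtered sessions with
# their cluster, grouped by cluster and sorted by trail length within.
cluster_trail_table <- function(model, sessions, min_len = 2, max_len = 20) {
  if (nrow(sessions) != model$n_sessions) {
    abort("`sessions` must be the sessions the model was fitted on")
  }
  sessions |>
    dplyr::mutate(session = dplyr::row_number(),
                  cluster = model$assignments,
                  length = lengths(.data$trail)) |>
    dplyr::filter(.data$length >= min_len, .data$length <= max_len) |>
    dplyr::arrange(.data$cluster, .data$length, .data$session) |>
    dplyr::select("cluster", "session", "length", "trail")
}
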