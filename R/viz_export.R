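#' Threshold-filter a navigation graph's edges
#'
#' Keeps the transitions with probability at least `cutoff` (default
#' 0.13, which gives a readable figure on the packaged reference
#' model). With `keep_max_incoming = TRUE`, any page all of whose
#' incoming edges fall below the cutoff additionally retains its single
#' highest-probability incoming edge, flagged as an exception, so no
#' visited page is left visually isolated; ties on the maximum go to
#' the earlier source state in state order.
#'
#' @param model A [markov_model()].
#' @param cutoff Minimum probability for an edge to be kept, in
#'   `[0, 1]`.
#' @param keep_max_incoming Keep the best incoming edge of otherwise
#'   isolated pages.
#' @return A tibble of edges: `from`, `to`, `probability`, `exception`
#'   (logical), in state order.
#' @export
#' @examples
#' threshold_edges(start2cycle_model())
threshold_edges <- function(model, cutoff = 0.13, keep_max_incoming = TRUE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1) {
    abort("`cutoff` must be a single probability in [0, 1]")
  }
  edges <- tidy(model) |>
    dplyr::filter(.data$from != model$exit_label, .data$probability > 0) |>
    dplyr::select("from", "to", "probability")
  keep <- edges$probability >= cutoff
  exception <- logical(nrow(edges))
  if (keep_max_incoming) {
    for (page in model$states) {
      incoming <- which(edges$to == page)
      if (length(incoming) && all(edges$probability[incoming] < cutoff)) {
        best <- incoming[which.max(edges$probability[incoming])]
        keep[best] <- TRUE
        exception[best] <- TRUE
      }
    }
  }
  out <- edges[keep, , drop = FALSE]
  out$exception <- exception[keep]
  state_order <- rownames(model$P)
  out |>
    dplyr::arrange(match(.data$from, state_order), match(.data$to, state_order)) |>
    tibble::as_tibble()
}

#' Export a navigation graph as d3-style node-link JSON
#'
#' Writes a `{"nodes": [...], "links": [...]}` document consumable by
#' browser graph renderers. Nodes carry the state label, initial-state
#' probability, an `is_exit` flag and (when a [page_view_summary()] is
#' supplied) the page's share of total views. Links carry source,
#' target, probability at full precision and the threshold-exception
#' flag, so the edge set round-trips exactly through
#' [read_graph_json()].
#'
#' @param model A [markov_model()].
#' @param edges Edge tibble from [threshold_edges()].
#' @param path Destination JSON file.
#' @param views Optional [page_view_summary()] tibble to attach view
#'   shares.
#' @return The node/link list, invisibly.
#' @export
export_graph_json <- function(model, edges, path, views = NULL) {
  all_states <- rownames(model$P)
  unknown <- setdiff(unique(c(edges$from, edges$to)), all_states)
  if (length(unknown)) {
    abort(paste0("edge states not in the model: ", paste(unknown, collapse = ", ")))
  }
  nodes <- tibble::tibble(
    id = all_states,
    initial_prob = as.numeric(model$pi),
    is_exit = all_states == model$exit_label
  )
  if (!is.null(views)) {
    nodes$view_share <- views$share[match(nodes$id, views$page)]
  }
  links <- tibble::tibble(
    source = edges$from,
    target = edges$to,
    probability = edges$probability,
    exception = edges$exception %||% logical(nrow(edges))
  )
  doc <- list(nodes = nodes, links = links)
  jsonlite::write_json(doc, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(doc)
}

#' @rdname export_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  nodes <- tibble::as_tibble(doc$nodes)
  links <- if (is.data.frame(doc$links) && nrow(doc$links)) {
    tibble::as_tibble(doc$links)
  } else {
    tibble::tibble(source = character(), target = character(),
                   probability = numeric(), exception = logical())
  }
  list(nodes = nodes, links = links)
}

#' Export a navigation graph in GraphViz DOT format
#'
#' One directed edge per retained transition, labelled with its
#' probability; exception edges are drawn dashed and the exit node as a
#' double circle.
#'
#' @inheritParams export_graph_json
#' @return The DOT lines, invisibly.
#' @export
export_graph_dot <- function(model, edges, path) {
  q <- function(x) paste0("\"", x, "\"")
  lines <- c(
    "digraph navigation {",
    "  rankdir=LR;",
    paste0("  ", q(model$exit_label), " [shape=doublecircle];"),
    vapply(seq_len(nrow(edges)), function(i) {
      style <- if (isTRUE(edges$exception[i])) ", style=dashed" else ""
      sprintf("  %s -> %s [label=\"%.2f\"%s];",
              q(edges$from[i]), q(edges$to[i]), edges$probability[i], style)
    }, character(1)),
    "}"
  )
  writeLines(lines, path)
  invisible(lines)
}

#' Export a cluster trail table for heatmap rendering
#'
#' One row per session with trail length in `[min_len, max_len]`:
#' the assigned cluster, the session's row index, its length and its
#' page labels in order as `action_1 ... action_N` columns (empty past
#' the trail's end). Rows are grouped by cluster and sorted by trail
#' length within each cluster, the layout used to eyeball what each
#' cluster's sessions have in common.
#'
#' @param model A `trail_clusters` fit from [cluster_sequences()].
#' @param sessions The session tibble the model was fitted on.
#' @param min_len,max_len Inclusive trail-length bounds (default
#'   2--20).
#' @param path Destination CSV file.
#' @return The exported tibble, invisibly.
#' @export
export_cluster_heatmap <- function(model, sessions, min_len = 2,
                                   max_len = 20, path) {
  tab <- cluster_trail_table(model, sessions, min_len, max_len)
  width <- if (nrow(tab)) max(tab$length) else 0
  wide <- tab
  for (j in seq_len(width)) {
    wide[[sprintf("action_%d", j)]] <-
      vapply(tab$trail, function(tr) if (length(tr) >= j) tr[j] else "",
             character(1))
  }
  wide$trail <- NULL
  readr::write_csv(wide, path)
  invisible(wide)
}
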