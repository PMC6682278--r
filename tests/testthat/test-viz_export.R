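test_that("threshold filtering keeps strong edges and drops weak ones", {
  m <- start2cycle_model()
  edges <- threshold_edges(m, cutoff = 0.13)
  has <- function(from, to) any(edges$from == from & edges$to == to)
  expect_true(has("Routes", "Route"))    # 0.66
  expect_false(has("Routes", "Team"))    # 0.05
  expect_true(all(edges$probability[!edges$exception] >= 0.13))
  expect_true(all(edges$probability > 0 & edges$probability <= 1))
  expect_false(any(duplicated(edges[c("from", "to")])))
})

test_that("otherwise-isolated pages keep exactly their best incoming edge", {
  m <- start2cycle_model()
  edges <- threshold_edges(m, cutoff = 0.13)
  trophies_in <- edges[edges$to == "Trophies", ]
  expect_equal(nrow(trophies_in), 1)
  expect_equal(trophies_in$from, "Routes")   # 0.06, the max incoming
  expect_true(trophies_in$exception)
  personal_in <- edges[edges$to == "Personal", ]
  expect_equal(nrow(personal_in), 1)
  expect_equal(personal_in$from, "Bug report")  # 0.29, over the cutoff
  expect_false(personal_in$exception)

  bare <- threshold_edges(m, cutoff = 0.13, keep_max_incoming = FALSE)
  expect_equal(nrow(bare[bare$to == "Trophies", ]), 0)
})

test_that("a zero cutoff keeps every positive edge; bounds are enforced", {
  m <- start2cycle_model()
  all_edges <- threshold_edges(m, cutoff = 0)
  expect_equal(nrow(all_edges), sum(m$P > 0))
  expect_error(threshold_edges(m, cutoff = 1.1), "\\[0, 1\\]")
  expect_error(threshold_edges(m, cutoff = -0.1), "\\[0, 1\\]")
})

test_that("max-incoming ties break toward the earlier source state", {
  s <- c("A", "B", "C", "Exit")
  P <- matrix(0, 4, 4, dimnames = list(s, s))
  P["A", "C"] <- 0.05; P["A", "Exit"] <- 0.95
  P["B", "C"] <- 0.05; P["B", "Exit"] <- 0.95
  P["C", "Exit"] <- 1
  m <- markov_model(P, pi = c(A = 0.5, B = 0.5))
  edges <- threshold_edges(m, cutoff = 0.13)
  c_in <- edges[edges$to == "C", ]
  expect_equal(nrow(c_in), 1)
  expect_equal(c_in$from, "A")
})

test_that("graph JSON round-trips nodes and edge probabilities exactly", {
  m <- start2cycle_model()
  edges <- threshold_edges(m)
  f <- withr::local_tempfile(fileext = ".json")
  export_graph_json(m, edges, f, views = NULL)
  back <- read_graph_json(f)
  expect_equal(nrow(back$nodes), length(m$states) + 1)
  expect_equal(back$nodes$id, rownames(m$P))
  expect_identical(back$links$probability, edges$probability)
  expect_equal(back$links$source, edges$from)
  expect_equal(back$links$target, edges$to)
  expect_equal(back$links$exception, edges$exception)
  expect_true(back$nodes$is_exit[back$nodes$id == "Exit"])
})

test_that("an empty edge list exports a nodes-only document", {
  m <- det_chain("A", "B")
  edges <- threshold_edges(m, cutoff = 1)[0, ]
  f <- withr::local_tempfile(fileext = ".json")
  export_graph_json(m, edges, f)
  back <- read_graph_json(f)
  expect_equal(nrow(back$nodes), 3)
  expect_equal(nrow(back$links), 0)
})

test_that("DOT export writes one labelled line per edge", {
  m <- start2cycle_model()
  edges <- threshold_edges(m)
  f <- withr::local_tempfile(fileext = ".dot")
  export_graph_dot(m, edges, f)
  lines <- readLines(f)
  expect_equal(sum(grepl(" -> ", lines, fixed = TRUE)), nrow(edges))
  expect_true(any(grepl("\"Routes\" -> \"Route\" \\[label=\"0.66\"", lines)))
})

test_that("cluster heatmap rows are the filtered sessions, grouped and sorted", {
  ch <- make_archetype_chains()
  sess <- dplyr::bind_rows(lapply(ch, function(m) simulate_sessions(m, 40, seed = 77)))
  cl <- cluster_sequences(sess, k = 3, seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- export_cluster_heatmap(cl, sess, path = f)
  census <- sum(lengths(sess$trail) >= 2 & lengths(sess$trail) <= 20)
  expect_equal(nrow(tab), census)
  expect_true(all(tab$length >= 2 & tab$length <= 20))
  expect_false(is.unsorted(tab$cluster))
  for (k in unique(tab$cluster)) {
    expect_false(is.unsorted(tab$length[tab$cluster == k]))
  }
  on_disk <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(on_disk), census)
  expect_equal(on_disk$action_1, tab$action_1)
})

test_that("a one-cluster heatmap keeps each retained session as a row", {
  sess <- sessions_from_trails(list(c("A", "B"), c("A", "B", "A"), "A"))
  cl <- cluster_sequences(sess, k = 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- export_cluster_heatmap(cl, sess, path = f)
  expect_equal(nrow(tab), 2)  # the length-1 session is filtered out
  expect_equal(tab$cluster, c(1L, 1L))
})
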