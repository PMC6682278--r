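test_that("transition counting adds within-trail pairs and one exit per session", {
  s <- sessions_from_trails(list(c("A", "B")))
  M <- count_transitions(s, states = c("A", "B"))
  expect_equal(M["A", "B"], 1L)
  expect_equal(M["B", "Exit"], 1L)
  expect_equal(sum(M), 2L)

  s1 <- sessions_from_trails(list("A"))
  M1 <- count_transitions(s1, states = c("A", "B"))
  expect_equal(M1["A", "Exit"], 1L)
  expect_equal(sum(M1), 1L)
})

test_that("total counts equal the summed trail lengths (conservation)", {
  sims <- simulate_sessions(toy_chain(), 1000, seed = 3)
  M <- count_transitions(sims, states = toy_chain()$states)
  expect_equal(sum(M), sum(sims$length))
  expect_true(all(M["Exit", ] == 0))
})

test_that("unknown trail states raise an error naming the label", {
  s <- sessions_from_trails(list(c("A", "Zzz")))
  expect_error(count_transitions(s, states = c("A", "B")), "Zzz")
  expect_error(estimate_initial(sessions_from_trails(list("Qqq")), states = "A"), "Qqq")
})

test_that("row normalization divides by row sums and flags dangling rows", {
  M <- matrix(c(2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "Exit"), c("A", "B", "Exit")))
  P <- normalize_counts(M)
  expect_equal(unname(P["A", ]), c(0.5, 0.5, 0))
  expect_equal(unname(P["B", ]), c(0, 0, 0))
  expect_setequal(attr(P, "dangling"), c("B", "Exit"))
})

test_that("initial distribution is the share of first visited states", {
  trails <- c(rep(list("Coach"), 634), rep(list("Track"), 120),
              rep(list("Competition"), 70))
  s <- sessions_from_trails(trails)
  pi <- estimate_initial(s, states = c("Coach", "Competition", "Track"))
  expect_equal(pi[["Coach"]], 634 / 824)
  expect_equal(pi[["Exit"]], 0)
  expect_equal(sum(pi), 1)

  s_all_a <- sessions_from_trails(list(c("A", "B"), c("A", "B")))
  expect_equal(estimate_initial(s_all_a)[["A"]], 1)
  expect_error(estimate_initial(sessions_from_trails(list())), "0 sessions")
})

test_that("fitting composes counting, normalization and the initial estimate", {
  s <- sessions_from_trails(list(c("A", "B"), c("A", "B"), "B"))
  m <- fit_markov(s)
  expect_s3_class(m, "markov_model")
  expect_equal(m$P["A", "B"], 1)
  expect_equal(m$P["B", "Exit"], 1)
  expect_equal(m$pi[["A"]], 2 / 3)
  expect_equal(sum(m$counts), sum(lengths(s$trail)))

  single <- fit_markov(sessions_from_trails(list("A")))
  expect_equal(single$P["A", "Exit"], 1)
  expect_equal(single$pi[["A"]], 1)
})

test_that("fitted rows are stochastic to numerical precision", {
  sims <- simulate_sessions(toy_chain(), 400, seed = 9)
  m <- fit_markov(sims, states = toy_chain()$states)
  rs <- rowSums(m$P)[m$states]
  expect_true(all(abs(rs - 1) < 1e-9))
})

test_that("log-likelihood equals a brute-force per-step product on all short trails", {
  chain <- toy_chain()
  oracle <- function(trail) {
    trail <- c(trail, "Exit")
    p <- 1
    for (i in seq_len(length(trail) - 1)) {
      p <- p * chain$P[trail[i], trail[i + 1]]
    }
    log(p)
  }
  for (tr in enumerate_trails(c("A", "B", "C"), 6)) {
    expect_equal(sequence_log_likelihood(chain, tr), oracle(tr))
  }
})

test_that("zero-probability steps give -Inf and deterministic chains give 0", {
  d <- det_chain("A", "B")
  expect_equal(sequence_log_likelihood(d, c("A", "B")), 0)
  expect_equal(sequence_log_likelihood(d, c("B", "A")), -Inf)
  expect_error(sequence_log_likelihood(d, character(0)), "at least one")
})

test_that("the initial term is excluded by default and added on request", {
  chain <- toy_chain()
  tr <- c("A", "B")
  expect_equal(
    sequence_log_likelihood(chain, tr, include_initial = TRUE),
    sequence_log_likelihood(chain, tr) + log(chain$pi[["A"]])
  )
})

test_that("appending a state never increases a trail's likelihood", {
  chain <- toy_chain()
  trails <- withr::with_seed(21, replicate(30, {
    sample(c("A", "B", "C"), sample(1:5, 1), replace = TRUE)
  }, simplify = FALSE))
  for (tr in trails) {
    base <- sequence_log_likelihood(chain, tr)
    for (s in c("A", "B", "C")) {
      expect_lte(sequence_log_likelihood(chain, c(tr, s)), base)
    }
  }
})

test_that("simulation absorbs, truncates, and is reproducible by seed", {
  forced <- markov_model(
    matrix(c(0, 1, 0, 0), 2, byrow = TRUE,
           dimnames = list(c("A", "Exit"), c("A", "Exit"))),
    pi = c(A = 1)
  )
  sims <- simulate_sessions(forced, 50, seed = 1)
  expect_true(all(vapply(sims$trail, identical, logical(1), "A")))
  expect_false(any(sims$truncated))

  looper <- markov_model(
    matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE,
           dimnames = list(c("A", "B", "Exit"), c("A", "B", "Exit"))),
    pi = c(A = 1)
  )
  capped <- simulate_sessions(looper, 10, max_len = 3, seed = 2)
  expect_true(all(capped$length == 3))
  expect_true(all(capped$truncated))

  expect_identical(simulate_sessions(toy_chain(), 100, seed = 7),
                   simulate_sessions(toy_chain(), 100, seed = 7))
})

test_that("sampling a dangling page is reported by name", {
  P <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "Exit"), c("A", "B", "Exit")))
  dangling <- markov_model(P, pi = c(A = 1))
  expect_error(simulate_sessions(dangling, 5, seed = 1), "dangling state 'B'")
})

test_that("simulated start pages follow the initial distribution", {
  m <- start2cycle_model()
  sims <- simulate_sessions(m, 20000, seed = 12)
  frac <- mean(vapply(sims$trail, `[[`, character(1), 1) == "Coach")
  expect_lt(abs(frac - m$pi[["Coach"]]), 0.01)
})

test_that("fitting recovers a known chain from enough simulated transitions", {
  chain <- toy_chain()
  sims <- simulate_sessions(chain, 8000, seed = 4)
  M <- count_transitions(sims, states = chain$states)
  expect_true(all(rowSums(M)[chain$states] > 5000))
  m <- fit_markov(sims, states = chain$states)
  expect_lt(max(abs(m$P - chain$P)), 0.02)
})

test_that("page views count occurrences with shares summing to 100", {
  s <- sessions_from_trails(list(c("A", "B", "A"), "B"))
  pv <- page_view_summary(s)
  expect_equal(pv$views[pv$page == "A"], 2L)
  expect_equal(sum(pv$views), 4L)
  expect_equal(sum(pv$share), 100)

  one <- page_view_summary(sessions_from_trails(list("A")))
  expect_equal(one$share, 100)

  sim <- simulate_sessions(toy_chain(), 500, seed = 19)
  expect_equal(sum(page_view_summary(sim)$share), 100, tolerance = 1e-9)
})

test_that("tidy and glance expose the fitted model in long form", {
  m <- fit_markov(sessions_from_trails(list(c("A", "B"), "A")))
  td <- tidy(m)
  expect_equal(nrow(td), 9)
  expect_named(td, c("from", "to", "probability", "count"))
  expect_equal(td$probability[td$from == "A" & td$to == "B"], 0.5)
  g <- glance(m)
  expect_equal(g$n_sessions, 2L)
  expect_equal(g$n_transitions, 3L)
})

test_that("model validation enforces the absorbing-exit conventions", {
  P <- matrix(c(0, 1, 0, 0.5), 2, byrow = TRUE,
              dimnames = list(c("A", "Exit"), c("A", "Exit")))
  expect_error(markov_model(P, pi = c(A = 1)), "exit row")
  P2 <- matrix(c(0.5, 0.2, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("A", "Exit"), c("A", "Exit")))
  expect_error(markov_model(P2, pi = c(A = 1)), "sum to 1")
  P3 <- matrix(c(0, 1, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("A", "Exit"), c("A", "Exit")))
  expect_error(markov_model(P3, pi = c(A = 0.5, Exit = 0.5)), "exit")
})
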