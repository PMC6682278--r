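#' Reference navigation model of the Start2Cycle field trial
#'
#' The published 9-page transition matrix of the *Start2Cycle* cycling
#' app (25-day field trial, 22 users, 824 sessions), packaged as a
#' [markov_model()]. Probabilities are stored exactly as printed, with
#' unobserved transitions as 0; printed rows sum to 1 only up to
#' two-decimal rounding (0.99--1.01), which the constructor is told to
#' tolerate and which simulation handles by normalizing row weights at
#' sampling time.
#'
#' The initial distribution puts the published 0.769 on *Coach*; the
#' published sources only give the complement (0.231) in total, so its
#' split -- *Track* 0.15, *Competition* 0.081 -- is an emulation choice
#' reflecting the observation that resumed sessions most often restart
#' on those two pages.
#'
#' @return A [markov_model()] over the 9 app pages plus `"Exit"`.
#' @export
#' @examples
#' m <- start2cycle_model()
#' m$P["Coach", "Track"]  # 0.20
start2cycle_model <- function() {
  P <- read_transition_matrix(
    system.file("extdata", "start2cycle_transitions.csv",
                package = "clicktrails", mustWork = TRUE)
  )
  pi <- unlist(jsonlite::read_json(
    system.file("extdata", "start2cycle_initial.json",
                package = "clicktrails", mustWork = TRUE)
  ))
  markov_model(P, pi, exit_label = "Exit", row_tol = 0.02)
}

#' Archetype session chains for the synthetic log generator
#'
#' Three well-separated Markov chains over the 9-page state space, one
#' per session archetype observed in the field trial:
#'
#' * `gamification` -- Coach to the Competition/Team leaderboards (with
#'   an occasional Trophies check), bouncing back to Coach between
#'   looks;
#' * `route_tracking` -- Coach to Track, then reviewing the ridden
#'   route on Route/Routes, returning to Coach between loops;
#' * `bug_report` -- Coach to Personal to Bug report, then back via
#'   Track or Coach, usually followed by exit.
#'
#' Transition values are design choices. Each archetype routes through
#' the shared Coach hub every few steps, where the three chains send
#' users to disjoint wings; sessions rarely end directly on the start
#' page (users who open the app do something), with exits concentrated
#' on the wing pages instead. Exit masses are set so the default
#' mixture's mean trail length is about 5 actions, and the chains
#' differ by an L1 row distance of at least 1 on three or more rows,
#' which keeps mixture components recoverable by likelihood-based
#' clustering.
#'
#' @return Named list of three [markov_model()] objects sharing one
#'   state space.
#' @export
make_archetype_chains <- function() {
  pages <- start2cycle_pages()
  chain <- function(rows, pi) {
    n <- length(pages)
    P <- matrix(0, n + 1, n + 1,
                dimnames = list(c(pages, "Exit"), c(pages, "Exit")))
    for (from in names(rows)) P[from, names(rows[[from]])] <- rows[[from]]
    # pages never visited by the archetype drop straight to exit
    zero <- rowSums(P)[pages] == 0
    P[pages[zero], "Exit"] <- 1
    markov_model(P, pi, exit_label = "Exit")
  }
  list(
    gamification = chain(
      rows = list(
        Coach = c(Competition = 0.585, Team = 0.375, Exit = 0.04),
        Competition = c(Coach = 0.41, Team = 0.25, Trophies = 0.03, Exit = 0.31),
        Team = c(Coach = 0.44, Competition = 0.25, Exit = 0.31),
        Trophies = c(Coach = 0.50, Exit = 0.50)
      ),
      pi = c(Coach = 0.90, Competition = 0.10)
    ),
    route_tracking = chain(
      rows = list(
        Coach = c(Track = 0.96, Exit = 0.04),
        Track = c(Route = 0.42, Coach = 0.29, Exit = 0.29),
        Route = c(Routes = 0.33, Coach = 0.28, Track = 0.09, Exit = 0.30),
        Routes = c(Route = 0.36, Coach = 0.28, Exit = 0.36)
      ),
      pi = c(Coach = 0.90, Track = 0.10)
    ),
    bug_report = chain(
      rows = list(
        Coach = c(Personal = 0.95, Exit = 0.05),
        Personal = c("Bug report" = 0.56, Coach = 0.24, Exit = 0.20),
        "Bug report" = c(Track = 0.42, Coach = 0.28, Exit = 0.30),
        Track = c(Coach = 0.36, Exit = 0.64)
      ),
      pi = c(Coach = 0.90, Personal = 0.10)
    )
  )
}

start2cycle_pages <- function() {
  c("Trophies", "Bug report", "Coach", "Competition", "Personal",
    "Route", "Routes", "Team", "Track")
}

#' Configure the synthetic field-trial log generator
#'
#' Parameterizes [generate_log()]. The defaults emulate the scale of
#' the trial the package's reference data comes from: 22 users whose
#' per-user session counts are overdispersed (zero-truncated negative
#' binomial with mean 37 and SD 29.35), sessions drawn from a mixture
#' of the three [make_archetype_chains()] archetypes, within-session
#' gaps of seconds to minutes and between-session gaps of at least 40
#' minutes, so that 30-minute sessionization recovers the generated
#' session boundaries exactly. Timestamps are whole seconds starting
#' from `start_time`.
#'
#' @param n_users Number of users.
#' @param session_mean,session_sd Mean and SD of per-user session
#'   counts (negative binomial; `session_sd^2 > session_mean`).
#' @param archetypes Named list of [markov_model()] chains sharing one
#'   state space.
#' @param mixture_weights Named per-archetype session probabilities,
#'   summing to 1. The default mix makes bug-report sessions rare.
#' @param intra_gap Range (seconds) of gaps between events within a
#'   session; must stay strictly below 30 minutes.
#' @param inter_gap Range (seconds) of gaps between a user's
#'   consecutive sessions; must stay strictly above 30 minutes.
#' @param start_time First event time (POSIXct, UTC).
#' @param max_len Maximum trail length passed to the simulator.
#' @param seed Optional integer seed; with a seed the generated log is
#'   byte-identical across runs.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_users = 22,
                             session_mean = 37,
                             session_sd = 29.35,
                             archetypes = make_archetype_chains(),
                             mixture_weights = c(gamification = 0.45,
                                                 route_tracking = 0.40,
                                                 bug_report = 0.15),
                             intra_gap = c(2, 300),
                             inter_gap = c(2400, 72000),
                             start_time = as.POSIXct("2017-09-01 08:00:00",
                                                     tz = "UTC"),
                             max_len = 100,
                             seed = NULL) {
  if (n_users < 1) abort("`n_users` must be at least 1")
  if (session_sd^2 <= session_mean) {
    abort("`session_sd^2` must exceed `session_mean` (overdispersion)")
  }
  if (is.null(names(archetypes)) || !length(archetypes)) {
    abort("`archetypes` must be a named list of markov_model objects")
  }
  spaces <- lapply(archetypes, function(m) rownames(m$P))
  if (length(unique(spaces)) != 1) {
    abort("all archetype chains must share one state space")
  }
  if (!setequal(names(mixture_weights), names(archetypes))) {
    abort("`mixture_weights` names must match `archetypes` names")
  }
  if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-9) {
    abort("`mixture_weights` must be non-negative and sum to 1")
  }
  if (length(intra_gap) != 2 || intra_gap[1] <= 0 || intra_gap[1] > intra_gap[2]) {
    abort("`intra_gap` must be an increasing positive range in seconds")
  }
  if (length(inter_gap) != 2 || inter_gap[1] > inter_gap[2]) {
    abort("`inter_gap` must be an increasing range in seconds")
  }
  if (intra_gap[2] >= 30 * 60) {
    abort("`intra_gap` must stay strictly below the 30-minute session threshold")
  }
  if (inter_gap[1] <= 30 * 60) {
    abort("`inter_gap` must stay strictly above the 30-minute session threshold")
  }
  structure(
    list(n_users = as.integer(n_users), session_mean = session_mean,
         session_sd = session_sd, archetypes = archetypes,
         mixture_weights = mixture_weights[names(archetypes)],
         intra_gap = intra_gap, inter_gap = inter_gap,
         start_time = start_time, max_len = as.integer(max_len), seed = seed),
    class = "generator_config"
  )
}

#' Generate a ground-truth-labelled synthetic app log
#'
#' For each user, draws an overdispersed session count, then per
#' session draws an archetype from the mixture, simulates a trail from
#' that archetype's chain and lays the events out in time with
#' within-session gaps below and between-session gaps above the
#' 30-minute sessionization threshold. The emitted event stream is
#' therefore exactly recoverable by [sessionize()], and every event
#' carries a known session and archetype.
#'
#' @param config A [generator_config()].
#' @return A list with two tibbles: `events` (`user_id`, `timestamp`,
#'   `page`; the raw log) and `truth` (one row per generated session:
#'   `user_id`, `session_index`, `archetype`, `trail`, `length`,
#'   `start`, `end`).
#' @export
#' @examples
#' sim <- generate_log(generator_config(n_users = 2, seed = 1))
#' nrow(sim$truth) == nrow(sessionize(sim$events))  # boundaries recovered
generate_log <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must come from generator_config()")
  }
  run <- function() generate_log_impl(config)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

generate_log_impl <- function(config) {
  n_users <- config$n_users
  mu <- config$session_mean
  size <- mu^2 / (config$session_sd^2 - mu)
  counts <- rnbinom(n_users, mu = mu, size = size)
  while (any(counts == 0)) {   # zero-truncate: every user has >= 1 session
    counts[counts == 0] <- rnbinom(sum(counts == 0), mu = mu, size = size)
  }
  total <- sum(counts)
  arch_names <- names(config$archetypes)
  arch <- sample(arch_names, total, replace = TRUE,
                 prob = config$mixture_weights)
  trails <- vector("list", total)
  for (a in arch_names) {
    idx <- which(arch == a)
    if (length(idx)) {
      trails[idx] <- simulate_sessions(config$archetypes[[a]], length(idx),
                                       max_len = config$max_len)$trail
    }
  }
  truth <- tibble::tibble(
    user_id = rep(sprintf("u%03d", seq_len(n_users)), counts),
    session_index = unlist(lapply(counts, seq_len), use.names = FALSE),
    archetype = arch,
    trail = trails,
    length = lengths(trails)
  )

  # timestamps: sessions laid out sequentially per user
  len <- truth$length
  intra <- round(runif(sum(pmax(len - 1L, 0L)),
                       config$intra_gap[1], config$intra_gap[2]))
  offsets <- vector("list", total)
  pos <- 0L
  for (i in seq_len(total)) {
    k <- len[i] - 1L
    offsets[[i]] <- c(0, cumsum(intra[pos + seq_len(k)]))
    pos <- pos + k
  }
  duration <- vapply(offsets, function(o) o[length(o)], numeric(1))
  inter <- round(runif(total, config$inter_gap[1], config$inter_gap[2]))
  starts <- numeric(total)
  i <- 1L
  for (u in seq_len(n_users)) {
    t0 <- as.numeric(config$start_time)
    for (s in seq_len(counts[u])) {
      starts[i] <- t0
      t0 <- t0 + duration[i] + inter[i]
      i <- i + 1L
    }
  }
  truth$start <- as.POSIXct(starts, tz = "UTC", origin = "1970-01-01")
  truth$end <- as.POSIXct(starts + duration, tz = "UTC", origin = "1970-01-01")

  events <- tibble::tibble(
    user_id = rep(truth$user_id, len),
    timestamp = as.POSIXct(rep(starts, len) + unlist(offsets, use.names = FALSE),
                           tz = "UTC", origin = "1970-01-01"),
    page = unlist(trails, use.names = FALSE)
  )
  events <- dplyr::arrange(events, .data$user_id, .data$timestamp)
  list(events = events, truth = truth)
}
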