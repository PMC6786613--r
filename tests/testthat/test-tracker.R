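# The tracker is fed hand-built world snapshots so expected values can be
# derived by hand-tracing the reign rule.

feed <- function(tracker, snapshots) {
  for (s in snapshots) tracker <- record_network_state(s, tracker)
  tracker
}

test_that("a run without patrons yields size 0 and duration 0", {
  tr <- new_network_tracker()
  w <- make_world(rep(100, 5))
  tr <- feed(tr, rep(list(w), 10))
  expect_identical(finalize_network_metrics(tr), list(size = 0L, duration = 0L))
})

test_that("a single persistent network reports its size and tenure", {
  # patron 1 holds 7 clients for 12 consecutive steps, never surpassed
  w <- make_world(c(900, rep(50, 9)),
                  params = sim_params(n_households = 10),
                  patron = c(NA, rep(1L, 7), NA, NA),
                  n_clients = c(7L, rep(0L, 9)),
                  formed = c(3L, rep(NA, 9)))
  tr <- feed(new_network_tracker(), rep(list(w), 12))
  expect_identical(finalize_network_metrics(tr), list(size = 7L, duration = 12L))
})

test_that("reign turnover follows the hand-traced rule", {
  # A (3 clients) reigns steps 1-50; B (5 clients) reigns steps 51-400:
  # the run-max network is B's and its duration is 350
  base <- sim_params(n_households = 10)
  wA <- make_world(c(900, 900, rep(50, 8)), params = base,
                   patron = c(NA, NA, 1L, 1L, 1L, rep(NA, 5)),
                   n_clients = c(3L, 0L, rep(0L, 8)),
                   formed = c(1L, rep(NA, 9)))
  wB <- make_world(c(900, 2000, rep(50, 8)), params = base,
                   patron = c(NA, NA, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
                   n_clients = c(3L, 5L, rep(0L, 8)),
                   formed = c(1L, 51L, rep(NA, 8)))
  tr <- feed(new_network_tracker(), c(rep(list(wA), 50), rep(list(wB), 350)))
  expect_identical(finalize_network_metrics(tr), list(size = 5L, duration = 350L))
})

test_that("ties break by formation step, then lowest patron id", {
  base <- sim_params(n_households = 6)
  w <- make_world(c(900, 900, rep(40, 4)), params = base,
                  patron = c(NA, NA, 1L, 1L, 2L, 2L),
                  n_clients = c(2L, 2L, 0L, 0L, 0L, 0L),
                  formed = c(8L, 4L, NA, NA, NA, NA))
  tr <- record_network_state(w, new_network_tracker())
  expect_identical(tr$reign_patron, 2L)  # earlier-formed wins
  w$formed <- c(4L, 4L, NA, NA, NA, NA)
  tr <- record_network_state(w, new_network_tracker())
  expect_identical(tr$reign_patron, 1L)  # equal formation: lowest id
})

test_that("a re-formed network after dissolution counts as a new reign", {
  base <- sim_params(n_households = 5)
  w1 <- make_world(c(900, rep(50, 4)), params = base,
                   patron = c(NA, 1L, 1L, NA, NA), n_clients = c(2L, 0L, 0L, 0L, 0L),
                   formed = c(1L, rep(NA, 4)))
  gap <- make_world(rep(100, 5), params = base)
  w2 <- w1; w2$formed <- c(9L, rep(NA, 4))
  tr <- feed(new_network_tracker(), c(rep(list(w1), 5), list(gap), rep(list(w2), 4)))
  # run-max size 2 first attained by the formation-step-1 network; its
  # longest reign is 5, not 5 + 4 across the dissolution
  expect_identical(finalize_network_metrics(tr), list(size = 2L, duration = 5L))
})

test_that("network size never exceeds households minus one in real runs", {
  for (seed in 1:5) {
    r <- run_simulation(sim_params(n_households = 30, n_steps = 300,
                                   carrying_capacity = 15000), seed = seed)
    expect_lte(r$largest_network_size, 29)
    expect_lte(r$largest_network_duration, 300)
    expect_gte(r$largest_network_duration,
               as.integer(r$largest_network_size > 0))
  }
})
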