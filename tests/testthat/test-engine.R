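test_that("init_world starts every household at the initial herd", {
  w <- init_world(sim_params(), seed = 1)
  expect_length(w$herd, 100)
  expect_true(all(w$herd == 60))
  expect_true(all(w$alive))
  expect_identical(total_animals(w), 6000)
  expect_identical(w$step, 0L)
  expect_true(all(is.na(w$patron)))

  w1 <- init_world(sim_params(n_households = 1), seed = 1)
  expect_identical(total_animals(w1), 60)

  a <- init_world(small_params(), seed = 9)
  b <- init_world(small_params(), seed = 9)
  expect_identical(a, b)
})

test_that("herd growth is multiplicative below capacity and frozen at it", {
  p <- sim_params(n_households = 3, carrying_capacity = 1e6)
  w <- make_world(c(60, 60, 60), params = p)
  set.seed(1)
  w <- grow_herds(w)
  expect_equal(w$herd, rep(66, 3))

  pc <- sim_params(n_households = 3, carrying_capacity = 180)
  wc <- make_world(c(60, 60, 60), params = pc)  # total equals capacity
  set.seed(1)
  wc <- grow_herds(wc)
  expect_equal(wc$herd, rep(60, 3))
})

test_that("sequential capacity re-check can block later households", {
  # two households, herds 9000 and 100, capacity 10000: if the large herd
  # grows first (9900, total 10000) the small one is blocked; if the small
  # one grows first both grow
  p <- sim_params(n_households = 2, carrying_capacity = 10000)
  seen <- character(0)
  for (seed in 1:40) {
    w <- make_world(c(9000, 100), params = p)
    set.seed(seed)
    w <- grow_herds(w)
    out <- paste(w$herd, collapse = ",")
    expect_true(out %in% c("9900,100", "9900,110"))
    seen <- union(seen, out)
  }
  expect_setequal(seen, c("9900,100", "9900,110"))
})

test_that("disasters scale herds by the intensity with the event probability", {
  p0 <- sim_params(n_households = 4, disaster_prob = 0)
  w <- make_world(c(100, 200, 300, 400), params = p0)
  set.seed(3)
  expect_equal(apply_disasters(w)$herd, c(100, 200, 300, 400))

  p1 <- sim_params(n_households = 4, disaster_prob = 1)
  w <- make_world(c(100, 200, 300, 400), params = p1)
  set.seed(3)
  expect_equal(apply_disasters(w)$herd, c(50, 100, 150, 200))

  pu <- sim_params(n_households = 200, disaster_prob = 1, uniform_intensity = TRUE)
  w <- make_world(rep(100, 200), params = pu)
  set.seed(3)
  w <- apply_disasters(w)
  expect_true(all(w$herd >= 0 & w$herd <= 100))
  expect_gt(var(w$herd), 0)
})

test_that("patron transfers conserve animals and lift the client", {
  p <- sim_params(n_households = 2)
  w <- make_world(c(900, 50), params = p,
                  patron = c(NA, 1L), n_clients = c(1L, 0L), formed = c(1L, NA))
  before <- total_animals(w)
  set.seed(2)
  w <- resolve_poverty(w)
  expect_equal(w$herd, c(840, 110))
  expect_equal(total_animals(w), before)
})

test_that("unsupported destitute households die; merely poor ones persist", {
  p <- sim_params(n_households = 3)
  w <- make_world(c(1.5, 100, 200), params = p)  # nobody above 800
  set.seed(5)
  w <- resolve_poverty(w)
  expect_false(w$alive[1])
  expect_identical(w$herd[1], 0)
  expect_equal(total_animals(w), 300)

  w2 <- make_world(c(30, 100, 200), params = p)
  set.seed(5)
  w2 <- resolve_poverty(w2)
  expect_true(w2$alive[1])
  expect_true(is.na(w2$patron[1]))

  # with deaths disabled the destitute household survives unlinked
  pnd <- sim_params(n_households = 3, deaths = FALSE)
  w3 <- make_world(c(1.5, 100, 200), params = pnd)
  set.seed(5)
  w3 <- resolve_poverty(w3)
  expect_true(w3$alive[1])
})

test_that("a poor household links to a patron above the threshold", {
  p <- sim_params(n_households = 3)
  w <- make_world(c(50, 900, 700), params = p)
  set.seed(8)
  w <- resolve_poverty(w)
  expect_identical(w$patron[1], 2L)  # only household 2 exceeds 800
  expect_equal(w$herd, c(110, 840, 700))
  expect_identical(w$n_clients[2], 1L)
  expect_identical(w$formed[2], 1L)
})

test_that("patron-floor check dissolves networks below 500 only", {
  p <- sim_params(n_households = 7)
  w <- make_world(c(480, rep(40, 5), 5000), params = p,
                  patron = c(NA, rep(1L, 5), NA),
                  n_clients = c(5L, rep(0L, 5), 0L),
                  formed = c(2L, rep(NA, 6)))
  w <- update_patron_status(w)
  expect_identical(w$n_clients[1], 0L)
  expect_true(all(is.na(w$patron)))

  w2 <- make_world(c(500, rep(40, 5), 5000), params = p,
                   patron = c(NA, rep(1L, 5), NA),
                   n_clients = c(5L, rep(0L, 5), 0L),
                   formed = c(2L, rep(NA, 6)))
  w2 <- update_patron_status(w2)
  expect_identical(w2$n_clients[1], 5L)  # strict < comparison

  w3 <- make_world(c(5000, rep(40, 5), 900), params = p,
                   patron = c(NA, rep(1L, 5), NA),
                   n_clients = c(5L, rep(0L, 5), 0L),
                   formed = c(2L, rep(NA, 6)))
  expect_identical(update_patron_status(w3)$n_clients[1], 5L)
})

test_that("undisturbed growth matches the closed form initial*(1+g)^t", {
  p <- sim_params(disaster_prob = 0, carrying_capacity = 1e9,
                  networks = FALSE, deaths = FALSE, n_steps = 10)
  r <- run_simulation(p, seed = 1)
  w <- init_world(p, seed = 1)
  for (t in 1:10) w <- step_world(w)
  expect_equal(w$herd, rep(60 * 1.1^10, 100), tolerance = 1e-12)
  expect_equal(unname(60 * 1.1^10), 155.6246, tolerance = 1e-4)
  expect_identical(r$final_gini, 0)      # equal multiplicative growth
  expect_identical(r$end_population, 100L)
})

test_that("capacity binding from step 0 freezes all herds", {
  p <- sim_params(disaster_prob = 0, carrying_capacity = 6000,
                  networks = FALSE, deaths = FALSE, n_steps = 25)
  w <- init_world(p, seed = 4)
  for (t in 1:25) w <- step_world(w)
  expect_true(all(w$herd == 60))
})

test_that("stepping is deterministic under a shared seed", {
  p <- small_params(disaster_prob = 0.2)
  w1 <- init_world(p, seed = 11)
  for (t in 1:20) w1 <- step_world(w1)
  w2 <- init_world(p, seed = 11)
  for (t in 1:20) w2 <- step_world(w2)
  expect_identical(w1, w2)
  expect_identical(run_simulation(p, seed = 11),
                   run_simulation(p, seed = 11))
})

test_that("per-step accounting balances and herds stay non-negative", {
  p <- sim_params(n_households = 40, n_steps = 150, carrying_capacity = 8000,
                  disaster_prob = 0.15)
  r <- run_simulation(p, seed = 13, record_series = TRUE)
  s <- attr(r, "series")
  prev <- c(2400, s$total[-nrow(s)])
  # transfers cancel out; only growth, disasters and deaths move the total
  expect_equal(s$total - prev, s$growth - s$disaster_loss - s$death_loss,
               tolerance = 1e-9)
  expect_true(all(s$total >= 0))
  expect_true(all(s$largest_size <= s$alive))
})

test_that("link symmetry and role exclusivity hold at the end of every step", {
  p <- sim_params(n_households = 30, carrying_capacity = 4000,
                  disaster_prob = 0.15)
  w <- init_world(p, seed = 17)
  for (t in 1:120) {
    w <- step_world(w)
    expect_links_consistent(w)
  }
})

test_that("high-risk regimes decline and low-risk regimes grow (median herd)", {
  base <- sim_params(n_households = 400, carrying_capacity = 1e15,
                     networks = FALSE, deaths = FALSE, n_steps = 200)
  hi <- base; hi$disaster_prob <- 0.20   # 1.1 * 0.9 < 1
  lo <- base; lo$disaster_prob <- 0.05   # 1.1 * 0.975 > 1
  set.seed(23)
  raw_hi <- herdnet:::.sim_run_cpp(unclass(hi), FALSE, 0, 0L, FALSE)
  set.seed(23)
  raw_lo <- herdnet:::.sim_run_cpp(unclass(lo), FALSE, 0, 0L, FALSE)
  expect_lt(median(raw_hi$herd), 1)
  expect_gt(median(raw_lo$herd), 60)
})
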