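test_that("batches are reproducible and order-independent", {
  p <- small_params(disaster_prob = 0.1)
  a <- run_batch(p, n_runs = 4, base_seed = 5)
  b <- run_batch(p, n_runs = 4, base_seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a), 4L)
  # replicate 2 of a 2-run batch equals replicate 2 of a 4-run batch
  c2 <- run_batch(p, n_runs = 2, base_seed = 5)
  expect_identical(c2[2, -1], a[2, -1])
})

test_that("without disasters or interaction every run is flat", {
  # non-binding capacity: equal multiplicative growth keeps herds identical
  p <- sim_params(disaster_prob = 0, networks = FALSE, deaths = FALSE,
                  n_steps = 40, carrying_capacity = 1e9)
  b <- run_batch(p, n_runs = 3, base_seed = 1)
  expect_true(all(b$final_gini == 0))
  expect_true(all(b$end_population == 100))
  expect_true(all(b$largest_network_size == 0))
})

test_that("sweep tables have one row per combination and replicate", {
  p <- small_params()
  s1 <- run_sweep(capacities = 4000, disaster_probs = 0.1, n_runs = 1,
                  params = p, base_seed = 2)
  expect_identical(nrow(s1), 1L)
  s8 <- run_sweep(capacities = c(2000, 4000), disaster_probs = c(0.05, 0.2),
                  n_runs = 2, params = p, base_seed = 2)
  expect_identical(nrow(s8), 8L)
  expect_identical(
    dplyr::count(s8, carrying_capacity, disaster_prob)$n, rep(2L, 4))
  expect_s3_class(s8, "herd_sweep")
  agg <- summarize_sweep(s8)
  expect_identical(nrow(agg), 4L)
  manual <- mean(s8$largest_network_size[s8$carrying_capacity == 2000 &
                                           s8$disaster_prob == 0.05])
  expect_identical(agg$mean_network_size[agg$carrying_capacity == 2000 &
                                           agg$disaster_prob == 0.05], manual)
})

test_that("the inequality-baseline sweep never forms networks or kills", {
  g <- run_gini_sweep(capacities = 3000, disaster_probs = c(0.1, 0.2),
                      n_runs = 2, params = small_params(), base_seed = 3)
  expect_true(all(g$largest_network_size == 0))
  expect_true(all(g$end_population == 20))
  expect_true(all(is.finite(g$final_gini)))
})

test_that("the sensitivity sweep uses the 10 x 4 regression grid", {
  s <- run_regression_sweep(n_runs = 1, params = small_params(), base_seed = 4)
  expect_identical(nrow(s), 40L)
  expect_setequal(unique(s$carrying_capacity), seq(5000, 50000, by = 5000))
  expect_setequal(unique(s$disaster_prob), c(0.01, 0.05, 0.10, 0.15))
})

test_that("a degenerate shift trigger elevates as soon as any network exists", {
  r <- capacity_shift_run(low_capacity = 3000, high_capacity = 30000,
                          trigger_size = 1,
                          params = sim_params(n_households = 25, n_steps = 200),
                          seed = 3)
  expect_gt(r$elevated_steps, 0)
  expect_gt(r$largest_network_size, 0)
})

test_that("at 20% disaster frequency the shifted run still collapses", {
  r <- capacity_shift_run(params = sim_params(n_households = 50, n_steps = 2000),
                          disaster_prob = 0.20, seed = 8)
  expect_identical(r$end_population, 0L)
  expect_identical(r$elevated_steps, 0L)
})

test_that("shift configuration is validated", {
  expect_error(capacity_shift_run(low_capacity = 50000, high_capacity = 10000))
  expect_error(capacity_shift_run(trigger_size = 0))
  expect_error(run_simulation(small_params(), 1, shift = list(high = 1)))
})
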