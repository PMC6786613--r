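#' Factorial parameter sweep over carrying capacity and disaster frequency
#'
#' Runs `n_runs` replicates at every combination of the supplied carrying
#' capacities and disaster probabilities (full factorial). The default
#' grids are the headline experiment: capacities 5,000 to 50,000 in steps
#' of 5,000 crossed with disaster frequencies 5, 10, 15 and 20%, 100
#' replicates each (5,000 runs in total). Per-run seeds are derived once
#' from `base_seed`, so any subset of the sweep is reproducible
#' independently of execution order.
#'
#' @param capacities Numeric vector of carrying capacities.
#' @param disaster_probs Numeric vector of per-household disaster
#'   probabilities.
#' @param n_runs Replicates per combination.
#' @param params Base [sim_params()]; its `carrying_capacity` and
#'   `disaster_prob` are overridden cell by cell.
#' @param base_seed Integer root seed.
#' @param engine Passed to [run_simulation()].
#' @return A tibble of class `herd_sweep` with one row per run:
#'   `carrying_capacity`, `disaster_prob`, `replicate`, `seed`,
#'   `final_gini`, `largest_network_size`, `largest_network_duration`,
#'   `end_population`.
#' @examples
#' run_sweep(capacities = 10000, disaster_probs = 0.1, n_runs = 2,
#'           params = sim_params(n_steps = 50), base_seed = 1)
#' @export
run_sweep <- function(capacities = seq(5000, 50000, by = 5000),
                      disaster_probs = c(0.05, 0.10, 0.15, 0.20),
                      n_runs = 100,
                      params = sim_params(),
                      base_seed = 1,
                      engine = "cpp") {
  stopifnot(length(capacities) >= 1, length(disaster_probs) >= 1, n_runs >= 1)
  grid <- tidyr::expand_grid(carrying_capacity = as.numeric(capacities),
                             disaster_prob = as.numeric(disaster_probs))
  seeds <- matrix(derive_seeds(base_seed, nrow(grid) * n_runs),
                  nrow = nrow(grid))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(ci) {
    p <- params
    p$carrying_capacity <- grid$carrying_capacity[ci]
    p$disaster_prob <- grid$disaster_prob[ci]
    validate_sim_params(p)
    purrr::map_dfr(seq_len(n_runs), function(r) {
      res <- run_simulation(p, seed = seeds[ci, r], engine = engine)
      dplyr::mutate(res,
                    carrying_capacity = p$carrying_capacity,
                    disaster_prob = p$disaster_prob,
                    replicate = r, .before = 1)
    })
  })
  class(out) <- c("herd_sweep", class(out))
  out
}

#' Inequality-baseline sweep (no interaction, no deaths)
#'
#' The wealth-inequality variant of the sweep: households grow their herds
#' and suffer disasters but never interact, form networks, or die, so the
#' final Gini index measures the inequality the environment alone
#' generates. Defaults follow [run_sweep()].
#'
#' @inheritParams run_sweep
#' @return A `herd_sweep` tibble (see [run_sweep()]); with interaction
#'   disabled, `largest_network_size` and `largest_network_duration` are 0
#'   and `end_population` equals `n_households`.
#' @export
run_gini_sweep <- function(capacities = seq(5000, 50000, by = 5000),
                           disaster_probs = c(0.05, 0.10, 0.15, 0.20),
                           n_runs = 100,
                           params = sim_params(),
                           base_seed = 1,
                           engine = "cpp") {
  params$networks <- FALSE
  params$deaths <- FALSE
  run_sweep(capacities, disaster_probs, n_runs, params, base_seed, engine)
}

#' Sensitivity-analysis sweep for the multiple regression
#'
#' The sweep underlying the standardized-coefficient regressions: carrying
#' capacities 5,000 to 50,000 in steps of 5,000 crossed with disaster
#' frequencies 1, 5, 10 and 15% (4,000 runs at the default 100 replicates).
#'
#' @inheritParams run_sweep
#' @return A `herd_sweep` tibble (see [run_sweep()]).
#' @export
run_regression_sweep <- function(n_runs = 100,
                                 params = sim_params(),
                                 base_seed = 1,
                                 engine = "cpp") {
  run_sweep(capacities = seq(5000, 50000, by = 5000),
            disaster_probs = c(0.01, 0.05, 0.10, 0.15),
            n_runs = n_runs, params = params,
            base_seed = base_seed, engine = engine)
}

#' Per-combination means of a sweep
#'
#' @param sweep A `herd_sweep` tibble from [run_sweep()].
#' @return A tibble with one row per (capacity, disaster probability)
#'   combination: replicate count and the means of the final Gini index,
#'   largest-network size and duration, and end population.
#' @export
summarize_sweep <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$carrying_capacity, .data$disaster_prob) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_gini = mean(.data$final_gini),
      mean_network_size = mean(.data$largest_network_size),
      mean_network_duration = mean(.data$largest_network_duration),
      mean_end_population = mean(.data$end_population),
      .groups = "drop"
    )
}

#' Capacity-shift experiment (single run)
#'
#' Starts at a low carrying capacity; at the end of any step in which some
#' patron holds at least `trigger_size` clients, capacity is raised to
#' `high_capacity`, and it reverts to the low value once no network of
#' that size remains. Defaults reproduce the headline experiment: 10,000
#' raised to 50,000 on a 20-client network, at 10% disaster frequency.
#'
#' @param low_capacity Base carrying capacity (animals).
#' @param high_capacity Elevated carrying capacity (animals).
#' @param trigger_size Client count that triggers (and sustains) elevation.
#' @param params Base [sim_params()]; `carrying_capacity` is set to
#'   `low_capacity` and `disaster_prob` to `disaster_prob`.
#' @param disaster_prob Per-household disaster probability.
#' @param seed Integer seed.
#' @param engine Passed to [run_simulation()].
#' @return A one-row tibble as from [run_simulation()], plus
#'   `elevated_steps`, the number of steps spent at the elevated capacity.
#' @export
capacity_shift_run <- function(low_capacity = 10000,
                               high_capacity = 50000,
                               trigger_size = 20,
                               params = sim_params(),
                               disaster_prob = 0.10,
                               seed = 1,
                               engine = "cpp") {
  stopifnot(low_capacity < high_capacity, trigger_size >= 1)
  params$carrying_capacity <- as.numeric(low_capacity)
  params$disaster_prob <- as.numeric(disaster_prob)
  validate_sim_params(params)
  run_simulation(params, seed = seed, engine = engine,
                 shift = list(high = high_capacity, trigger = trigger_size))
}

#' Capacity-shift experiment (replicated)
#'
#' @inheritParams capacity_shift_run
#' @param n_runs Number of replicates (the headline experiment uses 20).
#' @param base_seed Integer root seed (per-run seeds derived as in
#'   [run_batch()]).
#' @return A tibble with one row per replicate, as [capacity_shift_run()].
#' @export
capacity_shift_batch <- function(n_runs = 20,
                                 low_capacity = 10000,
                                 high_capacity = 50000,
                                 trigger_size = 20,
                                 params = sim_params(),
                                 disaster_prob = 0.10,
                                 base_seed = 1,
                                 engine = "cpp") {
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(base_seed, n_runs)
  purrr::map_dfr(seq_len(n_runs), function(i) {
    res <- capacity_shift_run(low_capacity, high_capacity, trigger_size,
                              params, disaster_prob, seed = seeds[i],
                              engine = engine)
    dplyr::mutate(res, replicate = i, .before = 1)
  })
}
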