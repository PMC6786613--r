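# shared fixtures and independent oracles

small_params <- function(...) {
  sim_params(n_households = 20, n_steps = 50, carrying_capacity = 5000, ...)
}

# brute-force pairwise Gini, independent of the production implementation
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# brute-force Pearson correlation from first principles
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hand-built world for phase-level tests (bypasses init_world defaults)
make_world <- function(herd, params = sim_params(n_households = length(herd)),
                       patron = rep(NA_integer_, length(herd)),
                       n_clients = integer(length(herd)),
                       formed = rep(NA_integer_, length(herd)),
                       alive = rep(TRUE, length(herd)),
                       step = 0L) {
  w <- init_world(params)
  w$herd <- as.numeric(herd)
  w$alive <- alive
  w$patron <- as.integer(patron)
  w$n_clients <- as.integer(n_clients)
  w$formed <- as.integer(formed)
  w$total <- sum(w$herd[w$alive])
  w$step <- step
  w
}

# link symmetry + role exclusivity checks on an end-of-run state
expect_links_consistent <- function(state, exclusive = TRUE) {
  n <- length(state$herd)
  for (j in seq_len(n)) {
    expect_identical(sum(!is.na(state$patron) & state$patron == j),
                     as.integer(state$n_clients[j]))
    if (!state$alive[j]) {
      expect_true(is.na(state$patron[j]))
      expect_identical(state$n_clients[j], 0L)
    }
    if (!is.na(state$patron[j])) expect_true(state$patron[j] != j)
    if (exclusive && state$n_clients[j] > 0L) {
      expect_true(is.na(state$patron[j]))
    }
  }
}
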