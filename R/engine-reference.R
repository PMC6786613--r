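# Naive reference engine.
#
# Deliberately literal, loop-per-agent implementation of the per-step
# schedule. It exists as an independently written oracle for the optimized
# C++ engine: both consume R's RNG stream with an identical draw protocol
# and identical floating-point expression order, so for the same seed they
# must produce bit-identical runs.
#
# Draw protocol per step (n = number of alive households, id order):
#   1. growth: n uniforms; visiting order = order() of those uniforms;
#      each visit grows the herd iff the running system total is still
#      below the current carrying capacity.
#   2. disasters: one uniform per alive household (id order); on an event,
#      one further uniform for the intensity when uniform_intensity is on.
#      If global disasters are enabled: one more uniform (plus intensity
#      draw on event).
#   3. poverty resolution (networks on): n uniforms for the visiting
#      permutation; one uniform per patron search that has at least one
#      eligible candidate.
#   4. patron-floor check: no draws.

#' Initialize a simulation world
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer; when supplied, seeds R's RNG so the run is
#'   reproducible.
#' @return A `sim_world` list: per-household state vectors (`herd`, `alive`,
#'   `patron`, `n_clients`, `formed`), the running animal total, the current
#'   carrying capacity, the step counter and a network tracker.
#' @examples
#' w <- init_world(sim_params(n_steps = 10), seed = 1)
#' total_animals(w)  # 100 households x 60 animals
#' @export
init_world <- function(params, seed = NULL) {
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_households
  structure(
    list(
      params = params,
      herd = rep(params$initial_herd, n),
      alive = rep(TRUE, n),
      patron = rep(NA_integer_, n),
      n_clients = integer(n),
      formed = rep(NA_integer_, n),
      total = sum(rep(params$initial_herd, n)),
      capacity = params$carrying_capacity,
      shift = NULL,       # optional list(high=, trigger=) for capacity shift
      step = 0L,
      tracker = new_network_tracker(),
      record_events = FALSE,
      events = list(),
      last_growth = 0, last_disaster_loss = 0,
      last_transfer = 0, last_death_loss = 0
    ),
    class = "sim_world"
  )
}

#' Total animals held by living households
#'
#' Recomputed from scratch (not the engine's running total), so it can be
#' used to check conservation.
#'
#' @param world A `sim_world`.
#' @return A single non-negative number.
#' @export
total_animals <- function(world) sum(world$herd[world$alive])

log_event <- function(world, event, household, partner, amount) {
  if (world$record_events) {
    world$events[[length(world$events) + 1L]] <-
      list(step = world$step + 1L, event = event,
           household = household, partner = partner, amount = amount)
  }
  world
}

#' Herd growth phase
#'
#' Visits living households in a fresh random order; each grows its herd by
#' the growth rate if and only if the system total is still below carrying
#' capacity at its visiting moment (the grant that reaches capacity may
#' overshoot it; later households are then blocked).
#'
#' @param world A `sim_world`.
#' @return The updated world.
#' @export
grow_herds <- function(world) {
  ids <- which(world$alive)
  world$last_growth <- 0
  if (length(ids) == 0L) return(world)
  g <- world$params$growth_rate
  rnd <- world$params$round_herds
  u <- stats::runif(length(ids))
  for (i in ids[order(u)]) {
    if (world$total < world$capacity) {
      nh <- world$herd[i] * (1 + g)
      if (rnd) nh <- floor(nh + 0.5)
      world$last_growth <- world$last_growth + (nh - world$herd[i])
      world$total <- world$total + (nh - world$herd[i])
      world$herd[i] <- nh
    }
  }
  world
}

#' Disaster phase
#'
#' Each living household independently suffers a disaster with probability
#' `disaster_prob`, losing a `disaster_intensity` fraction of its herd (or a
#' Uniform(0,1) fraction under the uniform-intensity variant). With global
#' disasters enabled, one additional system-wide draw strikes every
#' household at once.
#'
#' @param world A `sim_world`.
#' @return The updated world.
#' @export
apply_disasters <- function(world) {
  p <- world$params
  world$last_disaster_loss <- 0
  for (i in which(world$alive)) {
    if (stats::runif(1) < p$disaster_prob) {
      intensity <- if (p$uniform_intensity) stats::runif(1) else p$disaster_intensity
      nh <- world$herd[i] * (1 - intensity)
      if (p$round_herds) nh <- floor(nh + 0.5)
      world$last_disaster_loss <- world$last_disaster_loss + (world$herd[i] - nh)
      world$total <- world$total + (nh - world$herd[i])
      world$herd[i] <- nh
    }
  }
  if (p$global_disasters && any(world$alive)) {
    if (stats::runif(1) < p$disaster_prob) {
      intensity <- if (p$uniform_intensity) stats::runif(1) else p$disaster_intensity
      for (i in which(world$alive)) {
        nh <- world$herd[i] * (1 - intensity)
        if (p$round_herds) nh <- floor(nh + 0.5)
        world$last_disaster_loss <- world$last_disaster_loss + (world$herd[i] - nh)
        world$total <- world$total + (nh - world$herd[i])
        world$herd[i] <- nh
      }
    }
  }
  world
}

#' Poverty-resolution phase (transfers, patronage, deaths)
#'
#' In a fresh random visiting order, each living household whose herd is
#' below the poverty threshold: (a) receives `transfer_amount` animals from
#' its patron if it has one (and the patron can cover the transfer);
#' (b) otherwise picks a patron uniformly at random among living households
#' whose herd exceeds the patron threshold and that are not themselves
#' clients, receives the transfer, and a link is formed; (c) if no eligible
#' patron exists, deaths are enabled, and its herd is below the death
#' threshold, it dies and is removed. Households that currently hold
#' clients of their own never become clients. Transfers conserve the total.
#' No-op when networks are disabled.
#'
#' @param world A `sim_world`.
#' @return The updated world.
#' @export
resolve_poverty <- function(world) {
  p <- world$params
  world$last_transfer <- 0
  world$last_death_loss <- 0
  if (!p$networks) return(world)
  ids <- which(world$alive)
  if (length(ids) == 0L) return(world)
  u <- stats::runif(length(ids))
  for (i in ids[order(u)]) {
    if (!world$alive[i]) next
    if (world$herd[i] >= p$poverty_threshold) next
    pat <- world$patron[i]
    if (!is.na(pat)) {
      if (world$herd[pat] >= p$transfer_amount) {
        world$herd[pat] <- world$herd[pat] - p$transfer_amount
        world$herd[i] <- world$herd[i] + p$transfer_amount
        world$last_transfer <- world$last_transfer + p$transfer_amount
        world <- log_event(world, "transfer", i, pat, p$transfer_amount)
      }
    } else if (world$n_clients[i] == 0L) {
      cand <- if (p$client_patrons) {
        which(world$alive & world$herd > p$patron_threshold)
      } else {
        which(world$alive & world$herd > p$patron_threshold &
                is.na(world$patron))
      }
      cand <- cand[cand != i]
      k <- length(cand)
      if (k > 0L) {
        j <- cand[min(k, floor(stats::runif(1) * k) + 1)]
        world$herd[j] <- world$herd[j] - p$transfer_amount
        world$herd[i] <- world$herd[i] + p$transfer_amount
        world$last_transfer <- world$last_transfer + p$transfer_amount
        world$patron[i] <- j
        if (world$n_clients[j] == 0L) world$formed[j] <- world$step + 1L
        world$n_clients[j] <- world$n_clients[j] + 1L
        world <- log_event(world, "formed", i, j, p$transfer_amount)
      } else if (p$deaths && world$herd[i] < p$death_threshold) {
        world$last_death_loss <- world$last_death_loss + world$herd[i]
        world$total <- world$total - world$herd[i]
        world <- log_event(world, "death", i, NA_integer_, world$herd[i])
        world$herd[i] <- 0
        world$alive[i] <- FALSE
      }
    }
    # a household that holds clients neither seeks a patron nor dies here;
    # it faces the patron-floor check at the end of the step instead
  }
  world
}

#' Patron-floor check (end-of-step bookkeeping)
#'
#' Every patron whose herd has dropped below the patron floor loses patron
#' status: all its client links dissolve (clients keep previously received
#' animals). No-op when networks are disabled.
#'
#' @param world A `sim_world`.
#' @return The updated world.
#' @export
update_patron_status <- function(world) {
  p <- world$params
  if (!p$networks) return(world)
  for (j in which(world$alive & world$n_clients > 0L)) {
    if (world$herd[j] < p$patron_floor) {
      clients <- which(!is.na(world$patron) & world$patron == j)
      world$patron[clients] <- NA_integer_
      world$n_clients[j] <- 0L
      world$formed[j] <- NA_integer_
      world <- log_event(world, "dissolved", j, NA_integer_, length(clients))
    }
  }
  world
}

#' Advance the world by one time step
#'
#' Applies, in order: herd growth, disasters, poverty resolution, the
#' patron-floor check; then records the network state into the tracker,
#' applies the capacity-shift rule if one is configured, and increments the
#' step counter.
#'
#' @param world A `sim_world`.
#' @return The updated world.
#' @export
step_world <- function(world) {
  world <- grow_herds(world)
  world <- apply_disasters(world)
  world <- resolve_poverty(world)
  world <- update_patron_status(world)
  world$tracker <- record_network_state(world, world$tracker)
  if (!is.null(world$shift)) {
    elevated <- any(world$alive & world$n_clients >= world$shift$trigger)
    world$capacity <- if (elevated) world$shift$high else world$params$carrying_capacity
  }
  world$step <- world$step + 1L
  world
}

# Full reference run; same return shape as the C++ engine.
sim_run_ref <- function(params, shift = NULL, record_series = FALSE,
                        record_events = FALSE) {
  world <- init_world(params)
  world$shift <- shift
  world$record_events <- record_events
  n_steps <- params$n_steps
  series <- if (record_series) {
    list(total = numeric(n_steps), alive = integer(n_steps),
         largest_size = integer(n_steps), growth = numeric(n_steps),
         disaster_loss = numeric(n_steps), transfer = numeric(n_steps),
         death_loss = numeric(n_steps), capacity = numeric(n_steps))
  }
  elevated_steps <- 0L
  for (t in seq_len(n_steps)) {
    world <- step_world(world)
    if (!is.null(world$shift) && world$capacity == world$shift$high) {
      elevated_steps <- elevated_steps + 1L
    }
    if (record_series) {
      series$total[t] <- world$total
      series$alive[t] <- sum(world$alive)
      series$largest_size[t] <- world$tracker$reign_size[t]
      series$growth[t] <- world$last_growth
      series$disaster_loss[t] <- world$last_disaster_loss
      series$transfer[t] <- world$last_transfer
      series$death_loss[t] <- world$last_death_loss
      series$capacity[t] <- world$capacity
    }
  }
  net <- finalize_network_metrics(world$tracker)
  list(
    herd = world$herd, alive = world$alive, patron = world$patron,
    n_clients = world$n_clients,
    end_population = sum(world$alive),
    largest_network_size = net$size,
    largest_network_duration = net$duration,
    elevated_steps = elevated_steps,
    series = series,
    events = world$events
  )
}
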