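#' Simulation parameters for the pastoral household model
#'
#' Bundles every model constant, variant flag and run-length setting for a
#' single simulation run. Defaults are the headline study conditions: 100
#' households starting with 60 animals each, 10% herd growth per step, a 50%
#' herd loss when a disaster strikes, strict thresholds of 60 (poverty),
#' 800 (patron eligibility), 500 (patron floor) and 2 (death), a 60-animal
#' patron-to-client transfer, and 2,000 time steps. The default carrying
#' capacity of 25,000 animals corresponds to the middle of the studied
#' 5,000--50,000 range (and to roughly 250 animals per household, close to
#' recent Mongolian herding averages); the default disaster frequency of 10%
#' is the focal intermediate-risk setting.
#'
#' Herd sizes are non-negative reals by default (no rounding to whole
#' animals; see `round_herds` for the count-valued variant), and all
#' thresholds are strict comparisons (`< 60`, `> 800`, `< 500`, `< 2`).
#'
#' @param n_households Number of herding households (agents).
#' @param initial_herd Animals per household at step 0.
#' @param growth_rate Fractional herd growth per time step while the system
#'   total is below carrying capacity.
#' @param disaster_prob Per-household probability of an environmental
#'   disaster each time step.
#' @param disaster_intensity Fraction of the herd lost in a disaster
#'   (ignored when `uniform_intensity = TRUE`).
#' @param uniform_intensity If `TRUE`, each disaster draws its intensity
#'   afresh from Uniform(0, 1) instead of using `disaster_intensity`.
#' @param carrying_capacity Maximum total number of animals the shared
#'   pasture sustains; herd growth halts while the system total is at or
#'   above it.
#' @param poverty_threshold Herd size below which a household seeks support.
#' @param patron_threshold Herd size above which a household may accept new
#'   clients.
#' @param patron_floor Herd size below which a patron loses its status and
#'   its client links dissolve (checked at the end of each step).
#' @param transfer_amount Animals transferred from patron to client per
#'   support event.
#' @param death_threshold Herd size below which an unsupported poor
#'   household dies and is removed.
#' @param n_steps Number of time steps per run.
#' @param networks Enable patron-client interaction (poverty resolution,
#'   transfers, deaths). Disabled for the inequality-baseline variant.
#' @param deaths Enable household death/removal. Disabled for the
#'   inequality-baseline variant.
#' @param global_disasters If `TRUE`, an additional system-wide disaster is
#'   drawn once per step at `disaster_prob` and strikes every household
#'   simultaneously. Off by default: the per-step schedule and the model's
#'   own expected-loss arithmetic (`disaster_prob * disaster_intensity`)
#'   account for individual disasters only.
#' @param client_patrons If `TRUE`, any living household whose herd
#'   exceeds the patron threshold can accept a client, including households
#'   that are currently clients themselves, so networks can be layered. If
#'   `FALSE` (default), patron and client roles are mutually exclusive
#'   (strict star-shaped networks): a linked client is never eligible as a
#'   patron. Households that currently hold clients never request a patron
#'   under either setting, which rules out two-household support cycles.
#'   Role exclusivity is the default; in practice the layered variant
#'   splits client flow over several patrons and shrinks the largest
#'   network without otherwise changing the headline dynamics.
#' @param round_herds If `TRUE`, herds are count-valued: after every growth
#'   and disaster update the herd is rounded half-up to a whole number of
#'   animals. Off by default (real-valued herds keep the arithmetic free of
#'   an extra discretization rule), but the count-valued variant changes the
#'   high-risk regime qualitatively: collapsing herds pile up at one animal
#'   instead of scattering over ever-smaller fractions, so measured
#'   inequality collapses when average losses reach average growth. See the
#'   package vignette.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(carrying_capacity = 10000, disaster_prob = 0.05)
#' p
#' @export
sim_params <- function(n_households = 100L,
                       initial_herd = 60,
                       growth_rate = 0.10,
                       disaster_prob = 0.10,
                       disaster_intensity = 0.50,
                       uniform_intensity = FALSE,
                       carrying_capacity = 25000,
                       poverty_threshold = 60,
                       patron_threshold = 800,
                       patron_floor = 500,
                       transfer_amount = 60,
                       death_threshold = 2,
                       n_steps = 2000L,
                       networks = TRUE,
                       deaths = TRUE,
                       global_disasters = FALSE,
                       round_herds = FALSE,
                       client_patrons = FALSE) {
  p <- list(
    n_households = as.integer(n_households),
    initial_herd = as.numeric(initial_herd),
    growth_rate = as.numeric(growth_rate),
    disaster_prob = as.numeric(disaster_prob),
    disaster_intensity = as.numeric(disaster_intensity),
    uniform_intensity = isTRUE(uniform_intensity),
    carrying_capacity = as.numeric(carrying_capacity),
    poverty_threshold = as.numeric(poverty_threshold),
    patron_threshold = as.numeric(patron_threshold),
    patron_floor = as.numeric(patron_floor),
    transfer_amount = as.numeric(transfer_amount),
    death_threshold = as.numeric(death_threshold),
    n_steps = as.integer(n_steps),
    networks = isTRUE(networks),
    deaths = isTRUE(deaths),
    global_disasters = isTRUE(global_disasters),
    round_herds = isTRUE(round_herds),
    client_patrons = isTRUE(client_patrons)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fail <- function(msg) stop("invalid sim_params: ", msg, call. = FALSE)
  num1 <- function(field) {
    x <- p[[field]]
    if (length(x) != 1 || !is.finite(x)) fail(paste0("`", field, "` must be a single finite number"))
    x
  }
  for (f in c("initial_herd", "carrying_capacity", "poverty_threshold",
              "patron_threshold", "patron_floor", "transfer_amount",
              "death_threshold")) {
    if (num1(f) < 0) fail(paste0("`", f, "` must be non-negative (animals)"))
  }
  if (p$n_households < 1) fail("`n_households` must be at least 1")
  if (p$n_steps < 1) fail("`n_steps` must be at least 1")
  if (num1("growth_rate") <= 0) fail("`growth_rate` must be positive")
  if (num1("disaster_prob") < 0 || p$disaster_prob > 1) fail("`disaster_prob` must lie in [0, 1]")
  if (num1("disaster_intensity") < 0 || p$disaster_intensity > 1) fail("`disaster_intensity` must lie in [0, 1]")
  if (p$carrying_capacity <= 0) fail("`carrying_capacity` must be positive")
  if (!(p$death_threshold < p$poverty_threshold)) fail("`death_threshold` must be below `poverty_threshold`")
  if (!(p$poverty_threshold < p$patron_floor)) fail("`poverty_threshold` must be below `patron_floor`")
  if (!(p$patron_floor < p$patron_threshold)) fail("`patron_floor` must be below `patron_threshold`")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  households: %d, initial herd: %g, growth: %g/step\n",
              x$n_households, x$initial_herd, x$growth_rate))
  if (x$uniform_intensity) {
    cat(sprintf("  disasters: p = %g per household-step, intensity ~ U(0,1)\n", x$disaster_prob))
  } else {
    cat(sprintf("  disasters: p = %g per household-step, intensity %g\n",
                x$disaster_prob, x$disaster_intensity))
  }
  if (x$global_disasters) cat("  system-wide disasters: enabled\n")
  cat(sprintf("  carrying capacity: %g animals\n", x$carrying_capacity))
  cat(sprintf("  thresholds: poverty < %g, patron > %g, floor < %g, death < %g; transfer %g\n",
              x$poverty_threshold, x$patron_threshold, x$patron_floor,
              x$death_threshold, x$transfer_amount))
  cat(sprintf("  steps: %d; networks: %s; deaths: %s%s\n",
              x$n_steps, x$networks, x$deaths,
              if (x$round_herds) "; count-valued herds" else ""))
  invisible(x)
}
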