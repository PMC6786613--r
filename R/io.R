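default_config <- function() {
  c(unclass(sim_params()),
    list(
      experiment = "run",
      capacities = seq(5000, 50000, by = 5000),
      disaster_probs = c(0.05, 0.10, 0.15, 0.20),
      n_runs = 100L,
      base_seed = 1L,
      low_capacity = 10000,
      high_capacity = 50000,
      trigger_size = 20L,
      engine = "cpp",
      out_dir = "results",
      verbose = TRUE
    ))
}

#' Load and validate an experiment configuration
#'
#' Builds a run configuration with three levels of precedence: package
#' defaults (the headline study conditions), then the config file, then
#' explicit overrides (e.g. parsed command-line flags). Unknown keys and
#' invalid parameter combinations are rejected with the offending key
#' named.
#'
#' @param path Optional path to a YAML or JSON configuration file (format
#'   chosen by extension; `.json` is parsed as JSON, anything else as
#'   YAML).
#' @param overrides Named list of values taking precedence over the file.
#' @return A named list of class `herd_config` containing every
#'   [sim_params()] field plus experiment selection (`experiment` is one
#'   of `"run"`, `"sweep"`, `"gini-sweep"`, `"shift"`, `"regress"`),
#'   grids, `n_runs`, `base_seed`, capacity-shift settings, `engine` and
#'   `out_dir`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  apply_layer <- function(cfg, layer, origin) {
    if (length(layer) == 0) return(cfg)
    if (is.null(names(layer)) || any(names(layer) == ""))
      stop("configuration entries from ", origin, " must be named")
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown) > 0)
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    modifyList(cfg, layer)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(parsed)) parsed <- list()
    cfg <- apply_layer(cfg, parsed, paste0("file '", path, "'"))
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  cfg$experiment <- match.arg(cfg$experiment,
                              c("run", "sweep", "gini-sweep", "shift", "regress"))
  # validate the simulation fields by constructing the params object
  config_params(cfg)
  if (cfg$n_runs < 1) stop("invalid configuration: `n_runs` must be at least 1")
  if (cfg$low_capacity >= cfg$high_capacity)
    stop("invalid configuration: `low_capacity` must be below `high_capacity`")
  structure(cfg, class = "herd_config")
}

config_params <- function(cfg) {
  sim_params(
    n_households = cfg$n_households, initial_herd = cfg$initial_herd,
    growth_rate = cfg$growth_rate, disaster_prob = cfg$disaster_prob,
    disaster_intensity = cfg$disaster_intensity,
    uniform_intensity = cfg$uniform_intensity,
    carrying_capacity = cfg$carrying_capacity,
    poverty_threshold = cfg$poverty_threshold,
    patron_threshold = cfg$patron_threshold,
    patron_floor = cfg$patron_floor,
    transfer_amount = cfg$transfer_amount,
    death_threshold = cfg$death_threshold,
    n_steps = cfg$n_steps, networks = cfg$networks, deaths = cfg$deaths,
    global_disasters = cfg$global_disasters
  )
}

sweep_csv_names <- c(
  carrying_capacity = "capacity", disaster_prob = "disaster_prob",
  replicate = "replicate", seed = "seed", final_gini = "gini",
  largest_network_size = "net_size",
  largest_network_duration = "net_duration",
  end_population = "end_population"
)

#' Write experiment results to CSV
#'
#' Writes a per-run table (`runs.csv`, header: capacity, disaster_prob,
#' replicate, seed, gini, net_size, net_duration, end_population), a
#' per-combination aggregate table (`summary.csv`) when the input is a
#' sweep, a regression summary (`regression.csv`) for `herd_ols` objects,
#' and a `metadata.json` echoing the full configuration so the batch can
#' be regenerated bit-exactly. Given identical inputs, output files are
#' byte-identical.
#'
#' @param result A `herd_sweep` tibble, a [run_batch()] /
#'   [capacity_shift_batch()] tibble, or a `herd_ols` object.
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration (e.g. from [load_config()]) echoed
#'   into `metadata.json`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  if (inherits(result, "herd_ols")) {
    path <- file.path(out_dir, "regression.csv")
    tab <- dplyr::mutate(tidy(result), response = result$response,
                         r = result$r, r.squared = result$r.squared,
                         n = result$n)
    readr::write_csv(tab, path)
    paths <- c(paths, path)
  } else if (is.data.frame(result)) {
    tab <- result
    keep <- intersect(names(sweep_csv_names), names(tab))
    out <- tab[, keep, drop = FALSE]
    names(out) <- unname(sweep_csv_names[keep])
    extra <- setdiff(names(tab), names(sweep_csv_names))
    if (length(extra) > 0) out <- dplyr::bind_cols(out, tab[, extra, drop = FALSE])
    path <- file.path(out_dir, "runs.csv")
    readr::write_csv(out, path)
    paths <- c(paths, path)
    if (inherits(result, "herd_sweep") && nrow(result) > 0) {
      spath <- file.path(out_dir, "summary.csv")
      readr::write_csv(summarize_sweep(result), spath)
      paths <- c(paths, spath)
    }
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  meta <- list(
    package = "herdnet",
    version = as.character(utils::packageVersion("herdnet")),
    config = if (is.null(config)) NULL else unclass(config)
  )
  mpath <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, mpath)
  invisible(paths)
}
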