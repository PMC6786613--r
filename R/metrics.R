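#' Gini index of a wealth vector
#'
#' Population (uncorrected) Gini coefficient of inequality,
#' \eqn{G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar x)}. Ranges from 0 (perfect
#' equality) to \eqn{(n-1)/n} (one owner holds everything); the upper bound
#' approaches 1 as \eqn{n \to \infty}.
#'
#' @param x Non-negative numeric vector of wealths (here: herd sizes).
#' @return A single number in `[0, 1)`.
#' @examples
#' gini(c(5, 5, 5, 5))    # 0
#' gini(c(0, 0, 0, 100))  # 0.75 = (n-1)/n
#' gini(c(1, 2, 3, 4))    # 0.25
#' @export
gini <- function(x) {
  if (!is.numeric(x) || length(x) < 1) stop("`x` must be a non-empty numeric vector")
  if (anyNA(x)) stop("`x` must not contain missing values")
  if (any(x < 0)) stop("wealths must be non-negative")
  if (all(x == 0)) stop("Gini index is undefined when all wealths are zero")
  n <- length(x)
  xs <- sort(x)
  # identical to the mean-absolute-difference form, in O(n log n)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
}

#' Create an empty network tracker
#'
#' A tracker accumulates, once per completed step, the identity and size of
#' the currently largest patron-client network, from which the run's two
#' network metrics are derived: the maximum number of clients any patron
#' held simultaneously, and the longest consecutive stretch of steps during
#' which that run-maximal network was the reigning largest in the system.
#'
#' @return An object of class `network_tracker`.
#' @seealso [record_network_state()], [finalize_network_metrics()]
#' @export
new_network_tracker <- function() {
  structure(
    list(reign_patron = integer(0),  # NA when no network exists that step
         reign_formed = integer(0),  # step at which the reigning network formed
         reign_size = integer(0)),
    class = "network_tracker"
  )
}

#' Record the per-step network state into a tracker
#'
#' Identifies the largest network at the end of the current step (ties are
#' broken in favour of the earliest-formed network, then the lowest patron
#' id) and appends it to the tracker.
#'
#' @param world A simulation world (see [init_world()]), or any list with
#'   elements `alive`, `n_clients` and `formed`.
#' @param tracker A [new_network_tracker()] object.
#' @return The updated tracker.
#' @export
record_network_state <- function(world, tracker) {
  pats <- which(world$alive & world$n_clients > 0L)
  if (length(pats) == 0L) {
    tracker$reign_patron <- c(tracker$reign_patron, NA_integer_)
    tracker$reign_formed <- c(tracker$reign_formed, NA_integer_)
    tracker$reign_size <- c(tracker$reign_size, 0L)
    return(tracker)
  }
  sizes <- world$n_clients[pats]
  best <- pats[sizes == max(sizes)]
  if (length(best) > 1L) {
    formed <- world$formed[best]
    best <- best[formed == min(formed)]
    best <- best[1L]  # lowest id among remaining ties
  }
  tracker$reign_patron <- c(tracker$reign_patron, best)
  tracker$reign_formed <- c(tracker$reign_formed, world$formed[best])
  tracker$reign_size <- c(tracker$reign_size, world$n_clients[best])
  tracker
}

#' Final network metrics from a completed tracker
#'
#' @param tracker A tracker filled by [record_network_state()].
#' @return A list with `size` (maximum simultaneous clients of any patron
#'   over the run) and `duration` (longest consecutive reign, in steps, of
#'   the network that attained that maximum; a network is identified by its
#'   patron and formation step, so a re-formed network after dissolution
#'   counts as new).
#' @export
finalize_network_metrics <- function(tracker) {
  sizes <- tracker$reign_size
  if (length(sizes) == 0L || max(sizes) == 0L) {
    return(list(size = 0L, duration = 0L))
  }
  run_max <- max(sizes)
  first <- which(sizes == run_max)[1L]
  pat <- tracker$reign_patron[first]
  formed <- tracker$reign_formed[first]
  is_max_net <- !is.na(tracker$reign_patron) &
    tracker$reign_patron == pat & tracker$reign_formed == formed
  r <- rle(is_max_net)
  list(size = as.integer(run_max),
       duration = as.integer(max(r$lengths[r$values])))
}
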