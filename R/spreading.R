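# Cascade susceptible-infected (SI) dynamics and spreading efficiency.

#' Run a cascade SI spreading process
#'
#' Synchronous discrete-time SI dynamics: at every step each infected
#' node transmits to each of its susceptible neighbours independently
#' with probability `prob` (the probability of contagion, constant and
#' equal for every infected node), so a susceptible node with `k`
#' infected neighbours at the start of the step becomes infected with
#' probability `1 - (1 - prob)^k`. Newly infected nodes become
#' infectious at the next step, and infected nodes never recover. The
#' process stops when the whole largest connected component is infected
#' or after `max_steps` steps.
#'
#' With `prob = 1` the infected set advances as an exact breadth-first
#' front, so the time to full infection equals the largest shortest-path
#' distance from any node to the seed set.
#'
#' @param g An `igraph` network; dynamics run on its largest connected
#'   component.
#' @param seeds A `seed_set` or an integer vector of 0-based node ids.
#' @param prob Probability of contagion in `(0, 1]`.
#' @param max_steps Step cap guaranteeing termination for tiny `prob`.
#' @param rng_seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `"si_result"`: list with
#'   `infected_count_by_step` (index 1 is time 0, i.e. the seeds),
#'   `time_to_full` (steps, or `NA` if not reached), `reached`,
#'   `n_nodes`, `seeds`, `prob`.
#' @export
run_si <- function(g, seeds, prob, max_steps = 1e6, rng_seed = NULL) {
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob <= 0 || prob > 1)
    stop("prob must lie in (0, 1]", call. = FALSE)
  g <- ensure_ids(g)
  if (!igraph::is_connected(g)) g <- largest_connected_component(g)
  seed_ids <- if (inherits(seeds, "seed_set")) seeds$nodes else as.integer(seeds)
  if (length(seed_ids) == 0L) stop("empty seed set", call. = FALSE)
  seed_idx <- internal_index(g, seed_ids)
  n <- igraph::vcount(g)
  adj <- adjacency_list(g)
  with_rng(rng_seed, {
    infected <- logical(n)
    infected[seed_idx] <- TRUE
    counts <- integer(max(16L, 2L))
    counts[1L] <- sum(infected)
    t <- 0L
    while (any(!infected) && t < max_steps) {
      sus <- which(!infected)
      k_inf <- vapply(adj[sus], function(nb) sum(infected[nb]), integer(1))
      p_inf <- 1 - (1 - prob)^k_inf
      newly <- sus[runif(length(sus)) < p_inf]
      infected[newly] <- TRUE
      t <- t + 1L
      if (t + 1L > length(counts)) counts <- c(counts, integer(length(counts)))
      counts[t + 1L] <- sum(infected)
    }
    reached <- all(infected)
    structure(list(
      infected_count_by_step = counts[seq_len(t + 1L)],
      time_to_full = if (reached) t else NA_integer_,
      reached = reached,
      n_nodes = n,
      seeds = seeds,
      prob = prob), class = "si_result")
  })
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<SI run> %d nodes, prob %.3g: %s\n", x$n_nodes, x$prob,
              if (x$reached) sprintf("fully infected after %d steps", x$time_to_full)
              else sprintf("NOT fully infected (%d steps run)",
                           length(x$infected_count_by_step) - 1L)))
  invisible(x)
}

#' Spreading efficiency of a completed SI run
#'
#' The number of steps needed to infect the entire largest connected
#' component (lower is more efficient). Runs that did not reach full
#' infection within their step cap return `NA` with a warning, so they
#' can be excluded explicitly rather than silently dropped.
#'
#' @param result An `si_result` from [run_si()].
#' @return Integer number of steps, or `NA` if full infection was not
#'   reached.
#' @export
spreading_efficiency <- function(result) {
  if (!inherits(result, "si_result")) stop("expected an si_result", call. = FALSE)
  if (!result$reached) {
    warning("SI run did not infect the full component within its step cap",
            call. = FALSE)
    return(NA_integer_)
  }
  result$time_to_full
}
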