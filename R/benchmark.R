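# Orchestration: networks x strategies x runs, outperformance rankings
# and degeneracy (seed-set overlap) matrices.

#' Per-run outperformance counts
#'
#' For one run, the number of competing strategies each strategy
#' strictly outperformed: `count(a) = #\{b != a : time(a) < time(b)\}`.
#' Ties award no point to either side. `NA` times (runs that exhausted
#' their step cap) are excluded from all comparisons and receive `NA`.
#'
#' @param times Named numeric vector of spreading times, one per
#'   strategy.
#' @return Named integer vector of counts in `[0, k - 1]`.
#' @export
#' @examples
#' outperformance_counts(c(A = 1, B = 2, C = 3))  # A 2, B 1, C 0
outperformance_counts <- function(times) {
  if (length(times) == 0L) stop("empty time vector", call. = FALSE)
  ok <- !is.na(times)
  counts <- rep(NA_integer_, length(times))
  names(counts) <- names(times)
  counts[ok] <- vapply(times[ok], function(t) sum(times[ok] > t), integer(1))
  counts
}

#' Aggregate run records into an outperformance ranking
#'
#' Records are grouped by `group_cols`; within a group every comparison
#' cell (one combination of network, `g`, `s` and run index) yields
#' per-strategy outperformance counts, which are summed over all cells.
#' Strategies are then ranked by descending total score; with `k`
#' strategies the top receives rank value `k - 1` and the bottom 0,
#' tied totals sharing the better value.
#'
#' @param records Data frame with columns `strategy`, `time_to_full`
#'   and any of `network`, `g`, `s`, `run`, `category`, `size`.
#' @param group_cols Character vector of grouping columns (default:
#'   whichever of `category`, `size` are present, else `network`).
#' @return Data frame with the grouping columns plus `strategy`,
#'   `score`, `rank` (0 = bottom). Attribute `n_excluded` reports how
#'   many records carried `NA` times.
#' @export
aggregate_ranking <- function(records, group_cols = NULL) {
  stopifnot(is.data.frame(records),
            all(c("strategy", "time_to_full") %in% names(records)))
  if (is.null(group_cols)) {
    group_cols <- intersect(c("category", "size"), names(records))
    if (length(group_cols) == 0L)
      group_cols <- intersect("network", names(records))
  }
  cell_cols <- setdiff(intersect(c("network", "g", "s", "run"), names(records)),
                       group_cols)
  n_excluded <- sum(is.na(records$time_to_full))
  strategies <- unique(records$strategy)
  group_key <- if (length(group_cols) == 0L) rep("all", nrow(records))
               else do.call(paste, c(records[group_cols], sep = "\r"))
  out <- do.call(rbind, lapply(split(records, group_key), function(grp) {
    if (!all(strategies %in% grp$strategy))
      stop("group is missing strategies: ",
           paste(setdiff(strategies, grp$strategy), collapse = ", "),
           call. = FALSE)
    cell_key <- if (length(cell_cols) == 0L) rep("all", nrow(grp))
                else do.call(paste, c(grp[cell_cols], sep = "\r"))
    score <- numeric(length(strategies)); names(score) <- strategies
    for (cell in split(grp, cell_key)) {
      times <- stats::setNames(cell$time_to_full, cell$strategy)
      counts <- outperformance_counts(times)
      counts <- counts[!is.na(counts)]
      score[names(counts)] <- score[names(counts)] + counts
    }
    k <- length(strategies)
    rank_value <- k - rank(-score, ties.method = "min")
    head_cols <- grp[1, group_cols, drop = FALSE]
    cbind(head_cols[rep(1, k), , drop = FALSE],
          data.frame(strategy = strategies, score = as.numeric(score),
                     rank = as.integer(rank_value), row.names = NULL))
  }))
  rownames(out) <- NULL
  out <- out[order(do.call(paste, c(out[group_cols], sep = "\r")), -out$score), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Degeneracy coefficient of two seed sets
#'
#' `Degeneracy(A, B) = |A intersect B| / |A union B|`: the Jaccard
#' overlap of the two node sets. 1 means identical sets, 0 disjoint
#' sets. (Not to be confused with k-degeneracy in graph theory.)
#'
#' @param a,b `seed_set`s or integer vectors of node ids; both
#'   nonempty.
#' @return A number in `[0, 1]`.
#' @export
degeneracy_coefficient <- function(a, b) {
  na <- if (inherits(a, "seed_set")) a$nodes else as.integer(a)
  nb <- if (inherits(b, "seed_set")) b$nodes else as.integer(b)
  if (length(na) == 0L || length(nb) == 0L)
    stop("degeneracy coefficient is undefined for empty seed sets",
         call. = FALSE)
  length(intersect(na, nb)) / length(union(na, nb))
}

#' Mean pairwise degeneracy matrix over networks
#'
#' Entry (i, j) is the mean over networks of the degeneracy coefficient
#' between strategy i's and strategy j's seed sets on the same network.
#' The matrix is symmetric with unit diagonal.
#'
#' @param seed_sets Either one named list (strategy -> `seed_set`) or a
#'   list of such lists (one per network, identical strategy rosters).
#' @return A square numeric matrix with strategy dimnames.
#' @export
degeneracy_matrix <- function(seed_sets) {
  if (length(seed_sets) > 0L && inherits(seed_sets[[1]], "seed_set"))
    seed_sets <- list(seed_sets)
  if (length(seed_sets) == 0L) stop("no seed sets given", call. = FALSE)
  roster <- names(seed_sets[[1]])
  for (sets in seed_sets) {
    if (!identical(sort(names(sets)), sort(roster)))
      stop("strategy rosters differ across networks", call. = FALSE)
  }
  k <- length(roster)
  acc <- matrix(0, k, k, dimnames = list(roster, roster))
  for (sets in seed_sets) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j < i) next
        d <- if (i == j) 1 else
          degeneracy_coefficient(sets[[roster[i]]], sets[[roster[j]]])
        acc[i, j] <- acc[i, j] + d
        if (j > i) acc[j, i] <- acc[j, i] + d
      }
    }
  }
  acc / length(seed_sets)
}

#' Benchmark configuration
#'
#' @param category Category acronym for generated batches (e.g.
#'   `"LD-LC"`); ignored when `graph_files` is given.
#' @param size `"Small"`, `"Medium"` or `"Large"`.
#' @param n_networks,n_runs Numbers of networks and of SI runs per
#'   (network, strategy, g).
#' @param g_grid Probabilities of contagion to simulate.
#' @param s_rule `"communities"` (seed-set size = number of detected
#'   communities) or a numeric vector of proportions of the LCC size
#'   (rounded half-up, minimum 1).
#' @param rng_seed Master seed; all per-network/strategy/run seeds are
#'   derived from it.
#' @param graph_files Optional character vector of network files to
#'   load instead of generating.
#' @param max_steps Step cap per SI run.
#' @return A validated list of class `"benchmark_config"`.
#' @export
benchmark_config <- function(category = "LD-LC", size = "Small",
                             n_networks = 30, n_runs = 30,
                             g_grid = c(0.25, 0.5, 0.75, 1),
                             s_rule = "communities", rng_seed = 1,
                             graph_files = NULL, max_steps = 1e6) {
  stopifnot(n_networks >= 1, n_runs >= 1, length(g_grid) >= 1,
            all(g_grid > 0 & g_grid <= 1))
  if (is.character(s_rule)) {
    s_rule <- match.arg(s_rule, "communities")
  } else {
    stopifnot(is.numeric(s_rule), all(s_rule > 0 & s_rule <= 1))
  }
  structure(list(category = category, size = size,
                 n_networks = as.integer(n_networks),
                 n_runs = as.integer(n_runs),
                 g_grid = as.numeric(g_grid), s_rule = s_rule,
                 rng_seed = as.integer(rng_seed),
                 graph_files = graph_files,
                 max_steps = max_steps),
            class = "benchmark_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Run the full seeding benchmark
#'
#' End-to-end pipeline: generate (or load) networks, reduce each to its
#' largest connected component, detect communities once per network,
#' build the ten strategies' seed sets, run `n_runs` SI processes per
#' (network, strategy, g), and aggregate outperformance rankings and
#' the mean degeneracy matrix. Fully reproducible from
#' `config$rng_seed`.
#'
#' @param config A [benchmark_config()].
#' @return An object of class `"benchmark_result"`: list with
#'   `records` (long data frame: network, category, size, strategy, g,
#'   s, run, time_to_full), `ranking` (see [aggregate_ranking()]),
#'   `degeneracy` (named list of matrices, one per seed-size rule),
#'   `seed_sets`, `partitions`, `config`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  strategies <- seeding_strategies()
  if (is.null(config$graph_files)) {
    networks <- generate_category_batch(config$category, config$size,
                                        config$n_networks,
                                        rng_seed = config$rng_seed)
    grouping <- c("category", "size")
  } else {
    networks <- lapply(config$graph_files, read_graph_file)
    names(networks) <- basename(config$graph_files)
    grouping <- c("network", "g", "s")
  }
  records <- list()
  seed_sets_by_s <- list()
  partitions <- list()
  for (i in seq_along(networks)) {
    lcc <- largest_connected_component(networks[[i]])
    net_name <- igraph::graph_attr(lcc, "name") %||% sprintf("network-%03d", i)
    part <- detect_communities(lcc, rng_seed = derive_seed(config$rng_seed, i, 1))
    partitions[[net_name]] <- part
    s_values <- if (identical(config$s_rule, "communities")) {
      stats::setNames(part$n_communities, "communities")
    } else {
      stats::setNames(pmax(1L, as.integer(round_half_up(
        config$s_rule * igraph::vcount(lcc)))),
        paste0("p", config$s_rule))
    }
    for (si in seq_along(s_values)) {
      s_label <- names(s_values)[si]
      s <- s_values[[si]]
      sets <- lapply(seq_along(strategies), function(j) {
        select_seeds(lcc, strategies[j], s, partition = part,
                     rng_seed = derive_seed(config$rng_seed, i, si, j))
      })
      names(sets) <- strategies
      seed_sets_by_s[[s_label]][[net_name]] <- sets
      for (gi in seq_along(config$g_grid)) {
        gval <- config$g_grid[gi]
        for (j in seq_along(strategies)) {
          for (r in seq_len(config$n_runs)) {
            res <- run_si(lcc, sets[[j]], gval, max_steps = config$max_steps,
                          rng_seed = derive_seed(config$rng_seed, i, si, j,
                                                 gi, r))
            records[[length(records) + 1L]] <- data.frame(
              network = net_name,
              category = igraph::graph_attr(lcc, "category") %||% NA_character_,
              size = igraph::graph_attr(lcc, "size_class") %||% NA_character_,
              strategy = strategies[j], g = gval, s = s, s_rule = s_label,
              run = r, time_to_full = res$time_to_full)
          }
        }
      }
    }
  }
  records <- do.call(rbind, records)
  n_unreached <- sum(is.na(records$time_to_full))
  if (n_unreached > 0L)
    warning(sprintf("%d run(s) exhausted max_steps and are excluded from rankings",
                    n_unreached), call. = FALSE)
  ranking <- aggregate_ranking(records, group_cols = grouping)
  degeneracy <- lapply(seed_sets_by_s, function(per_net)
    degeneracy_matrix(unname(per_net)))
  structure(list(records = records, ranking = ranking,
                 degeneracy = degeneracy, seed_sets = seed_sets_by_s,
                 partitions = partitions, config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark> %d networks, %d records\n",
              length(x$partitions), nrow(x$records)))
  print(x$ranking)
  invisible(x)
}
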