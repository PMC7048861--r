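# Seed-set selection: five centralized strategies, four decentralized,
# one random. All selections operate on the largest connected component
# and are deterministic given rng_seed.

#' Names of the ten seeding strategies
#'
#' Centralized: `degree`, `betweenness`, `closeness`, `pagerank`,
#' `kcore`. Decentralized: `voterank`, `ambassadors`, `community_hubs`,
#' `random_hubs`. Plus `random`.
#'
#' @return Character vector of length 10.
#' @export
seeding_strategies <- function() {
  c("degree", "betweenness", "closeness", "pagerank", "kcore",
    "voterank", "ambassadors", "community_hubs", "random_hubs", "random")
}

new_seed_set <- function(strategy, nodes, rng_seed) {
  structure(list(strategy = strategy, nodes = as.integer(nodes),
                 s = length(nodes), rng_seed = rng_seed),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed set> %s, s = %d: %s\n", x$strategy, x$s,
              paste(x$nodes, collapse = " ")))
  invisible(x)
}

# Ordered top-s selection with uniform random resolution of score ties:
# a random secondary sort key realizes a uniform draw within every tied
# block, in particular the block cut by the size threshold.
top_s_random_ties <- function(ids, score, s) {
  tie_key <- sample.int(length(ids))
  ids[order(-score, tie_key)][seq_len(s)]
}

#' Select a seed set by a named strategy
#'
#' Dispatches to the ten strategy rules:
#' \describe{
#'   \item{degree/betweenness/closeness/pagerank}{the `s` nodes with the
#'     highest centrality; ties are resolved by a uniform seeded draw
#'     within the tied block. PageRank uses damping 0.85.}
#'   \item{kcore}{`s` nodes drawn uniformly from the maximal k-core; if
#'     the core is smaller than `s` the remainder is drawn from the
#'     (k-1)-core, recursing down the shells.}
#'   \item{voterank}{iterative Vote-Rank (see [voterank_trace()]).}
#'   \item{ambassadors}{communities sorted by decreasing size; cycling
#'     through them, pick per community the unselected member with the
#'     highest external degree (edges leaving its community) until `s`
#'     nodes are picked; exhausted communities are skipped.}
#'   \item{community_hubs}{same cycling, picking the highest internal
#'     degree (edges inside the community).}
#'   \item{random_hubs}{repeatedly draw a uniform node and take its
#'     highest-degree not-yet-selected neighbour (draws whose neighbours
#'     are all selected are skipped), until `s` distinct nodes are found
#'     (at most `50 * s` draws).}
#'   \item{random}{`s` nodes uniformly without replacement.}
#' }
#'
#' @param g An `igraph` network; selection uses its largest connected
#'   component.
#' @param strategy One of [seeding_strategies()].
#' @param s Seed-set size (`1 <= s <=` LCC size).
#' @param partition An [detect_communities()] partition; required for
#'   `ambassadors` and `community_hubs`.
#' @param rng_seed Integer seed.
#' @return A `seed_set`: ordered node ids in selection order.
#' @export
select_seeds <- function(g, strategy, s, partition = NULL, rng_seed = 1) {
  strategy <- match.arg(strategy, seeding_strategies())
  g <- ensure_ids(g)
  if (!igraph::is_connected(g)) g <- largest_connected_component(g)
  ids <- node_ids(g)
  n <- length(ids)
  s <- as.integer(s)
  if (is.na(s) || s < 1L || s > n)
    stop(sprintf("seed-set size s = %d outside [1, %d]", s, n), call. = FALSE)
  if (strategy %in% c("ambassadors", "community_hubs") && is.null(partition))
    stop(sprintf("strategy '%s' requires a community partition", strategy),
         call. = FALSE)
  nodes <- with_rng(rng_seed, switch(
    strategy,
    degree = top_s_random_ties(ids, igraph::degree(g), s),
    betweenness = top_s_random_ties(ids, igraph::betweenness(g), s),
    closeness = top_s_random_ties(ids, igraph::closeness(g), s),
    pagerank = top_s_random_ties(
      ids, igraph::page_rank(g, damping = 0.85)$vector, s),
    kcore = select_kcore(g, ids, s),
    voterank = voterank_nodes(g, s),
    ambassadors = select_by_community(g, partition, s, external = TRUE),
    community_hubs = select_by_community(g, partition, s, external = FALSE),
    random_hubs = select_random_hubs(g, ids, s),
    random = ids[sample.int(n, s)]))
  new_seed_set(strategy, nodes, rng_seed)
}

select_kcore <- function(g, ids, s) {
  core <- igraph::coreness(g)
  sel <- integer(0)
  for (k in sort(unique(core), decreasing = TRUE)) {
    if (length(sel) >= s) break
    shell <- ids[core == k]
    take <- min(s - length(sel), length(shell))
    sel <- c(sel, shell[sample.int(length(shell), take)])
  }
  sel
}

select_random_hubs <- function(g, ids, s) {
  deg <- igraph::degree(g)
  adj <- adjacency_list(g)
  n <- length(ids)
  sel <- integer(0)
  draws <- 0L
  while (length(sel) < s) {
    draws <- draws + 1L
    if (draws > 50L * s)
      stop(sprintf(
        "random_hubs: could not find %d distinct hubs in %d draws", s, draws - 1L),
        call. = FALSE)
    u <- sample.int(n, 1L)
    nb <- adj[[u]]
    nb <- nb[!(ids[nb] %in% sel)]       # duplicates skipped at the pick
    if (length(nb) == 0L) next
    top <- nb[deg[nb] == max(deg[nb])]
    sel <- c(sel, ids[top[sample.int(length(top), 1L)]])
  }
  sel
}

select_by_community <- function(g, partition, s, external) {
  ids <- node_ids(g)
  mem <- align_membership(g, partition) - 1L   # back to 0-based labels
  ei <- external_internal_degrees(g, mem)
  score <- if (external) ei$external else ei$internal
  tie_key <- sample.int(length(ids))
  sizes <- table(mem)
  comm_order <- as.integer(names(sizes))[order(-as.integer(sizes),
                                               as.integer(names(sizes)))]
  sel_idx <- integer(0)
  while (length(sel_idx) < s) {
    picked_any <- FALSE
    for (cm in comm_order) {
      if (length(sel_idx) >= s) break
      members <- which(mem == cm)
      members <- setdiff(members, sel_idx)
      if (length(members) == 0L) next
      best <- members[order(-score[members], tie_key[members])][1L]
      sel_idx <- c(sel_idx, best)
      picked_any <- TRUE
    }
    if (!picked_any) stop("not enough nodes to select from communities",
                          call. = FALSE)
  }
  ids[sel_idx]
}

# External/internal degree of every node under a 0-based membership
# vector aligned with vertex order.
external_internal_degrees <- function(g, mem) {
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  same <- mem[ends[, 1]] == mem[ends[, 2]]
  n <- igraph::vcount(g)
  internal <- tabulate(c(ends[same, 1], ends[same, 2]), nbins = n)
  external <- tabulate(c(ends[!same, 1], ends[!same, 2]), nbins = n)
  list(external = external, internal = internal)
}

#' External and internal degree of a node under a partition
#'
#' External degree counts edges leaving the node's community, internal
#' degree edges inside it; they sum to the node's total degree.
#'
#' @param g An `igraph` network.
#' @param partition An `sb_partition` (or membership vector).
#' @param v Node id (0-based).
#' @return Named numeric vector `c(external = , internal = )`.
#' @export
external_internal_degree <- function(g, partition, v) {
  g <- ensure_ids(g)
  idx <- internal_index(g, v)
  mem <- align_membership(g, partition) - 1L
  ei <- external_internal_degrees(g, mem)
  c(external = ei$external[idx], internal = ei$internal[idx])
}

voterank_nodes <- function(g, s) {
  trace <- voterank_trace_impl(g, s)
  trace$node
}

#' Vote-Rank selection trace
#'
#' Iterative Vote-Rank: every node starts with voting ability 1; a
#' node's voting score is the sum of its neighbours' abilities. The
#' highest-scoring unselected node is picked (seeded uniform tie
#' break), its ability is zeroed, and each of its neighbours loses
#' `1 / <k>` ability (floored at 0), where `<k>` is the initial mean
#' degree of the network. Because all abilities start at 1, the first
#' pick is always a maximum-degree node.
#'
#' @param g An `igraph` network (its LCC is used).
#' @param s Number of nodes to select.
#' @param rng_seed Integer seed (tie breaks).
#' @return Data frame with columns `node`, `score` in selection order.
#' @export
voterank_trace <- function(g, s, rng_seed = 1) {
  g <- ensure_ids(g)
  if (!igraph::is_connected(g)) g <- largest_connected_component(g)
  if (s > igraph::vcount(g)) stop("s exceeds the number of nodes", call. = FALSE)
  with_rng(rng_seed, voterank_trace_impl(g, s))
}

voterank_trace_impl <- function(g, s) {
  ids <- node_ids(g)
  adj <- adjacency_list(g)
  n <- length(ids)
  ability <- rep(1, n)
  decrement <- 1 / mean(igraph::degree(g))   # fixed at the initial mean degree
  selectable <- rep(TRUE, n)
  out_node <- integer(s); out_score <- numeric(s)
  for (i in seq_len(s)) {
    score <- vapply(seq_len(n), function(v) {
      if (!selectable[v]) return(-Inf)
      sum(ability[adj[[v]]])
    }, numeric(1))
    top <- which(score == max(score))
    pick <- top[sample.int(length(top), 1L)]
    out_node[i] <- ids[pick]; out_score[i] <- score[pick]
    selectable[pick] <- FALSE
    ability[pick] <- 0
    nb <- adj[[pick]]
    ability[nb] <- pmax(0, ability[nb] - decrement)
  }
  data.frame(node = out_node, score = out_score)
}
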