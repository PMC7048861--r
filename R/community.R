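# Community detection (Louvain) and Newman-Girvan modularity.

#' Detect communities by modularity maximization (Louvain)
#'
#' Runs multi-level (Louvain) modularity optimization at resolution 1.
#' Node processing order is randomized by a seeded shuffle, so results
#' are reproducible given `rng_seed`. Community ids are relabelled
#' 0..Nc-1 in order of first appearance along increasing node id. The
#' reported modularity is computed by the package's own
#' [modularity_q()].
#'
#' An edgeless graph yields the singleton partition with modularity 0.
#'
#' @param g An undirected `igraph` network.
#' @param rng_seed Integer seed for the node shuffle.
#' @return An object of class `"sb_partition"`: list with `membership`
#'   (integer community per node, named by 0-based node id),
#'   `n_communities`, `modularity`, `rng_seed`.
#' @export
detect_communities <- function(g, rng_seed = 1) {
  g <- ensure_ids(g)
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  ids <- node_ids(g)
  if (igraph::ecount(g) == 0L) {
    mem <- seq_along(ids) - 1L
  } else {
    mem <- with_rng(rng_seed, {
      perm <- sample.int(igraph::vcount(g))
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, resolution = 1)
      igraph::membership(cl)[match(igraph::V(g)$name, igraph::V(gp)$name)]
    })
    ord <- order(ids)
    mem <- as.integer(mem)
    first_seen <- unique(mem[ord])
    mem <- match(mem, first_seen) - 1L
  }
  names(mem) <- as.character(ids)
  q <- if (igraph::ecount(g) == 0L) 0 else modularity_q(g, mem)
  structure(list(membership = mem,
                 n_communities = length(unique(mem)),
                 modularity = q,
                 rng_seed = rng_seed),
            class = "sb_partition")
}

#' @export
print.sb_partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$modularity))
  invisible(x)
}

# Normalize an assignment (sb_partition, named vector, or vector aligned
# with vertex order) into an integer vector aligned with V(g).
align_membership <- function(g, assignment) {
  g <- ensure_ids(g)
  if (inherits(assignment, "sb_partition")) assignment <- assignment$membership
  if (!is.null(names(assignment))) {
    idx <- match(igraph::V(g)$name, names(assignment))
    if (anyNA(idx))
      stop("assignment is missing node(s): ",
           paste(igraph::V(g)$name[is.na(idx)], collapse = ", "),
           call. = FALSE)
    assignment <- assignment[idx]
  } else if (length(assignment) != igraph::vcount(g)) {
    stop("assignment length does not match the number of nodes", call. = FALSE)
  }
  as.integer(as.factor(assignment))
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ e_c / N_e - (d_c / 2 N_e)^2 \right]}
#' with \eqn{e_c} the number of intra-community edges and \eqn{d_c} the
#' total degree of community \eqn{c}. Implemented directly from the
#' edge list (independently of any community-detection backend).
#'
#' @param g An undirected `igraph` with at least one edge.
#' @param assignment An `sb_partition`, a vector named by node id, or a
#'   vector aligned with vertex order.
#' @return Modularity in `[-1, 1]`.
#' @export
modularity_q <- function(g, assignment) {
  g <- ensure_ids(g)
  ne <- igraph::ecount(g)
  if (ne == 0L) stop("modularity needs at least one edge", call. = FALSE)
  mem <- align_membership(g, assignment)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  same <- mem[ends[, 1]] == mem[ends[, 2]]
  e_c <- tapply(same, mem[ends[, 1]], sum)
  e_c_full <- numeric(max(mem)); e_c_full[as.integer(names(e_c))] <- e_c
  deg <- igraph::degree(g)
  d_c <- tapply(deg, mem, sum)
  d_c_full <- numeric(max(mem)); d_c_full[as.integer(names(d_c))] <- d_c
  sum(e_c_full / ne - (d_c_full / (2 * ne))^2)
}

#' Community sizes in descending order
#'
#' @param partition An `sb_partition`.
#' @return Data frame with columns `community`, `size`, sorted by
#'   decreasing size, ties by increasing community id.
#' @export
community_sizes_sorted <- function(partition) {
  if (!inherits(partition, "sb_partition"))
    stop("expected an sb_partition", call. = FALSE)
  tab <- table(partition$membership)
  out <- data.frame(community = as.integer(names(tab)),
                    size = as.integer(tab))
  out <- out[order(-out$size, out$community), , drop = FALSE]
  rownames(out) <- NULL
  out
}
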