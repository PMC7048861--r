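# Scale-free network generation with tunable clustering, category
# calibration, and structural summaries.

# Cyclic anchor-priority budget used by grow_network(). Anchor
# candidates are consumed in ascending (id mod slots, id) order, which
# concentrates triadic closure on a stable minority of nodes; this
# anchor discipline is what lets the mean clustering coefficient reach
# high values even when many edges are added per node, matching the
# behaviour of reference implementations of this generator family. The
# slot budget grows with the candidate-set size m so that the anchor
# elite stays a small fraction of the m candidates.
anchor_slots <- function(m) {
  if (m <= 4L) 8L else if (m <= 19L) 32L else if (m <= 76L) 128L else 512L
}

#' Grow a scale-free network with tunable clustering
#'
#' Growth model: the graph starts from `m` isolated nodes; every new node
#' attaches exactly `m` edges. The node first draws `m` distinct
#' candidate targets with probability proportional to degree (the
#' preferential-attachment pool also lists each initial node once).
#' Candidates are consumed in a fixed cyclic priority order as
#' *anchors*; after the first (always preferential) attachment, each
#' remaining edge is, with probability `p_triad`, a triad-formation step
#' that connects to a uniformly random not-yet-connected neighbour of
#' the latest anchor, and otherwise the next preferential attachment.
#' Exhausted or duplicate candidates are redrawn from the pool, so the
#' result is always a connected simple graph with exactly
#' `(n - m) * m` edges.
#'
#' Raising `p_triad` from 0 to 1 raises the expected mean clustering
#' coefficient monotonically while preserving the skewed degree
#' distribution of preferential attachment.
#'
#' @param n Number of nodes (integer, > `m`).
#' @param m Edges added per new node (integer >= 1, < `n`).
#' @param p_triad Triad-formation probability in `[0, 1]`.
#' @param rng_seed Integer seed; `NULL` uses (and advances) the ambient
#'   RNG stream.
#' @return An undirected simple `igraph` with vertex names `"0"` ...
#'   `"n-1"` and graph attributes `gen_m`, `gen_p_triad`.
#' @export
#' @examples
#' g <- grow_network(200, 2, 0.5, rng_seed = 1)
#' igraph::ecount(g)  # (200 - 2) * 2 = 396
grow_network <- function(n, m, p_triad = 0, rng_seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1L || m >= n)
    stop("invalid generation parameters: need 1 <= m < n", call. = FALSE)
  if (!is.numeric(p_triad) || length(p_triad) != 1L ||
      is.na(p_triad) || p_triad < 0 || p_triad > 1)
    stop("invalid generation parameters: p_triad must lie in [0, 1]",
         call. = FALSE)
  with_rng(rng_seed, {
    n_edges <- (n - m) * m
    ef <- integer(n_edges); et <- integer(n_edges)
    adj <- vector("list", n)
    pool <- integer(m + 2L * n_edges)
    pool[seq_len(m)] <- seq_len(m)
    plen <- m
    slot <- (seq_len(n) - 1L) %% anchor_slots(m)   # cyclic anchor priority
    e <- 0L
    for (v in (m + 1L):n) {
      cand <- integer(0)
      while (length(cand) < m) {
        x <- pool[sample.int(plen, 1L)]
        if (!(x %in% cand)) cand <- c(cand, x)
      }
      cand <- cand[order(slot[cand], cand)]
      ci <- 1L
      nbrs <- integer(0)
      anchor <- 0L
      for (j in seq_len(m)) {
        target <- NA_integer_
        if (j > 1L && runif(1) < p_triad) {
          tf <- setdiff(adj[[anchor]], c(v, nbrs))
          if (length(tf) > 0L) target <- tf[sample.int(length(tf), 1L)]
        }
        if (is.na(target)) {     # preferential-attachment step
          while (ci <= m) {
            x <- cand[ci]; ci <- ci + 1L
            if (!(x %in% nbrs)) { target <- x; break }
          }
          tries <- 0L
          while (is.na(target)) {  # candidates exhausted: redraw
            x <- pool[sample.int(plen, 1L)]
            tries <- tries + 1L
            if (x != v && !(x %in% nbrs)) {
              target <- x
            } else if (tries > 200L) {
              free <- setdiff(seq_len(v - 1L), nbrs)
              target <- free[sample.int(length(free), 1L)]
            }
          }
          anchor <- target
        }
        e <- e + 1L
        ef[e] <- v; et[e] <- target
        adj[[v]] <- c(adj[[v]], target)
        adj[[target]] <- c(adj[[target]], v)
        nbrs <- c(nbrs, target)
        pool[plen + 1L] <- target; plen <- plen + 1L
      }
      pool[(plen + 1L):(plen + m)] <- v
      plen <- plen + m
    }
    g <- igraph::make_graph(rbind(ef, et), n = n, directed = FALSE)
    igraph::V(g)$name <- as.character(seq_len(n) - 1L)
    g <- igraph::set_graph_attr(g, "gen_m", m)
    igraph::set_graph_attr(g, "gen_p_triad", p_triad)
  })
}

# Mean local clustering coefficient, counting degree-<2 nodes as 0.
mean_clustering <- function(g) {
  igraph::transitivity(g, type = "average", isolates = "zero")
}

#' Choose the per-node edge budget matching a density target
#'
#' Returns the integer `m` minimizing `|(n - m) m - d n (n - 1) / 2|`,
#' i.e. the edge budget whose exact generated edge count comes closest
#' to the requested density `d`. Ties prefer the smaller `m`. Because
#' the generator can realize at most about `n^2 / 4` edges, a target
#' whose best achievable edge count falls below half of the requested
#' one is reported as infeasible.
#'
#' @param n Number of nodes.
#' @param target_density Desired density in `(0, 1)`.
#' @return Integer `m`.
#' @export
choose_m_for_density <- function(n, target_density) {
  n <- as.integer(n)
  if (!is.numeric(target_density) || target_density <= 0 || target_density >= 1)
    stop("target_density must lie in (0, 1)", call. = FALSE)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  target_edges <- target_density * n * (n - 1) / 2
  m <- seq_len(n - 1L)
  achieved <- (n - m) * m
  best <- m[which.min(abs(achieved - target_edges))]
  if ((n - best) * best < target_edges / 2)
    stop(sprintf(
      "no feasible m: target density %.3f needs %.0f edges but at most %d are attainable",
      target_density, target_edges, max(achieved)), call. = FALSE)
  best
}

#' Calibrate the triad-formation probability to a clustering target
#'
#' Estimates the mean clustering coefficient at `p_triad = 0` and `1`
#' (averaging `reps` seeded realizations, common random numbers across
#' probe points) and bisects the monotone response until the achieved
#' mean is within `tolerance` of `target_clustering`.
#'
#' @param n,m Generation sizes, as in [grow_network()].
#' @param target_clustering Desired mean clustering coefficient.
#' @param tolerance Acceptable absolute deviation of the achieved mean.
#' @param reps Realizations averaged per probe point.
#' @param rng_seed Integer seed; realizations at probe point use seeds
#'   `rng_seed`, `rng_seed + 1`, ... so the response is a deterministic
#'   function of `p_triad`.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated `p_triad`, with attribute `achieved` giving
#'   the mean clustering realized there.
#' @export
calibrate_triad_probability <- function(n, m, target_clustering,
                                        tolerance = 0.02, reps = 5,
                                        rng_seed = 1, max_iter = 20) {
  if (target_clustering < 0 || target_clustering > 1)
    stop("target_clustering must lie in [0, 1]", call. = FALSE)
  probe <- function(p) {
    mean(vapply(seq_len(reps), function(r) {
      mean_clustering(grow_network(n, m, p, rng_seed = rng_seed + r - 1L))
    }, numeric(1)))
  }
  done <- function(p, achieved) structure(p, achieved = achieved)
  c_lo <- probe(0)
  if (abs(c_lo - target_clustering) <= tolerance) return(done(0, c_lo))
  c_hi <- probe(1)
  if (abs(c_hi - target_clustering) <= tolerance) return(done(1, c_hi))
  if (target_clustering < c_lo || target_clustering > c_hi)
    stop(sprintf(
      "clustering target %.3f outside achievable bracket [%.3f, %.3f] for n=%d, m=%d",
      target_clustering, c_lo, c_hi, n, m), call. = FALSE)
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    c_mid <- probe(mid)
    if (abs(c_mid - target_clustering) <= tolerance) return(done(mid, c_mid))
    if (c_mid < target_clustering) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration did not reach clustering %.3f within tolerance %.3f (bracket [%.3f, %.3f])",
    target_clustering, tolerance, c_lo, c_hi), call. = FALSE)
}

# ---------------------------------------------------------------------
# Categories

CATEGORY_ACRONYMS <- c("LD-LC", "LD-MC", "LD-HC", "MD-MC", "MD-HC", "HD-HC")
SIZE_NODES <- c(Small = 200L, Medium = 1000L, Large = 2000L)

class_of <- function(x) {
  if (x <= 0.1) "Low" else if (x <= 0.2) "Medium" else "High"
}

#' Classify a network by density and clustering coefficient
#'
#' Classes use the intervals Low = `[0, 0.1]`, Medium = `(0.1, 0.2]`,
#' High = `(0.2, 1]` for both measures. Three of the nine combinations
#' (MD-LC, HD-LC, HD-MC) cannot be realized as connected networks by the
#' growth model; they are still classified but flagged with
#' `generatable = FALSE`.
#'
#' @param density Graph density in `[0, 1]`.
#' @param clustering Mean clustering coefficient in `[0, 1]`.
#' @return A list of class `"network_category"` with fields
#'   `density_class`, `clustering_class`, `acronym`, `generatable`.
#' @export
#' @examples
#' categorize(0.02, 0.40)$acronym  # "LD-HC"
categorize <- function(density, clustering) {
  for (x in c(density, clustering)) {
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1)
      stop("density and clustering must lie in [0, 1]", call. = FALSE)
  }
  dc <- class_of(density); cc <- class_of(clustering)
  acr <- paste0(substr(dc, 1, 1), "D-", substr(cc, 1, 1), "C")
  structure(list(density_class = dc, clustering_class = cc,
                 acronym = acr,
                 generatable = acr %in% CATEGORY_ACRONYMS),
            class = "network_category")
}

#' @export
print.network_category <- function(x, ...) {
  cat(sprintf("<network category> %s (density %s, clustering %s)%s\n",
              x$acronym, x$density_class, x$clustering_class,
              if (x$generatable) "" else " [not generatable]"))
  invisible(x)
}

#' Reference calibration targets per category and size
#'
#' Default (density, clustering) targets used by
#' [generate_category_batch()]: achievable interior points of each
#' category's class ranges for this generator, one pair per network
#' size. Users may override both targets per call.
#'
#' @return A data frame with columns `acronym`, `size`, `density`,
#'   `clustering`.
#' @export
category_targets <- function() {
  targets <- rbind(
    c("LD-LC", "Small", 0.03, 0.10), c("LD-MC", "Small", 0.08, 0.16),
    c("LD-HC", "Small", 0.02, 0.40), c("MD-MC", "Small", 0.11, 0.20),
    c("MD-HC", "Small", 0.18, 0.31), c("HD-HC", "Small", 0.46, 0.55),
    c("LD-LC", "Medium", 0.04, 0.10), c("LD-MC", "Medium", 0.04, 0.15),
    c("LD-HC", "Medium", 0.08, 0.43), c("MD-MC", "Medium", 0.11, 0.19),
    c("MD-HC", "Medium", 0.15, 0.36), c("HD-HC", "Medium", 0.36, 0.43),
    c("LD-LC", "Large", 0.03, 0.08), c("LD-MC", "Large", 0.05, 0.14),
    c("LD-HC", "Large", 0.08, 0.29), c("MD-MC", "Large", 0.11, 0.19),
    c("MD-HC", "Large", 0.18, 0.34), c("HD-HC", "Large", 0.25, 0.35))
  data.frame(acronym = targets[, 1], size = targets[, 2],
             density = as.numeric(targets[, 3]),
             clustering = as.numeric(targets[, 4]),
             stringsAsFactors = FALSE)
}

#' Generate a batch of networks in one density/clustering category
#'
#' Picks the edge budget `m` from the density target, calibrates
#' `p_triad` once against the clustering target, then grows `count`
#' networks with per-network seeds `rng_seed`, `rng_seed + 1`, ...
#'
#' @param acronym One of `"LD-LC"`, `"LD-MC"`, `"LD-HC"`, `"MD-MC"`,
#'   `"MD-HC"`, `"HD-HC"`.
#' @param size `"Small"` (200 nodes), `"Medium"` (1000) or `"Large"`
#'   (2000).
#' @param count Number of networks.
#' @param rng_seed Integer seed.
#' @param density_target,clustering_target Optional overrides of the
#'   [category_targets()] defaults.
#' @param tolerance,calib_reps Calibration controls, see
#'   [calibrate_triad_probability()].
#' @return A list of `igraph` networks; each carries graph attributes
#'   `name`, `category`, `size_class`, `gen_m`, `gen_p_triad`.
#' @export
generate_category_batch <- function(acronym, size, count, rng_seed = 1,
                                    density_target = NULL,
                                    clustering_target = NULL,
                                    tolerance = 0.02, calib_reps = 3) {
  size <- match.arg(size, names(SIZE_NODES))
  if (!acronym %in% CATEGORY_ACRONYMS)
    stop(sprintf(
      "unknown or non-generatable category '%s' (valid: %s)",
      acronym, paste(CATEGORY_ACRONYMS, collapse = ", ")), call. = FALSE)
  n <- SIZE_NODES[[size]]
  ref <- category_targets()
  ref <- ref[ref$acronym == acronym & ref$size == size, ]
  density_target <- density_target %||% ref$density
  clustering_target <- clustering_target %||% ref$clustering
  m <- choose_m_for_density(n, density_target)
  p <- calibrate_triad_probability(n, m, clustering_target,
                                   tolerance = tolerance, reps = calib_reps,
                                   rng_seed = rng_seed)
  lapply(seq_len(count), function(i) {
    g <- grow_network(n, m, as.numeric(p), rng_seed = rng_seed + i - 1L)
    g <- igraph::set_graph_attr(g, "name",
                                sprintf("%s-%s-%03d", acronym, size, i))
    g <- igraph::set_graph_attr(g, "category", acronym)
    igraph::set_graph_attr(g, "size_class", size)
  })
}

#' Largest connected component
#'
#' Node-induced subgraph on the largest component; among equally large
#' components the one containing the smallest node id wins.
#'
#' @param g An `igraph` network.
#' @return The LCC as an `igraph`, vertex ids preserved.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph has no components", call. = FALSE)
  g <- ensure_ids(g)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    ids <- node_ids(g)
    min_id <- vapply(big, function(k) min(ids[comp$membership == k]), numeric(1))
    big <- big[which.min(min_id)]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Structural summary of a network
#'
#' Density, mean degree, mean clustering, community structure (via
#' [detect_communities()]), diameter, mean shortest path length and
#' degree assortativity. On disconnected input the two distance fields
#' are computed on the largest connected component and flagged by
#' `distances_on_lcc`.
#'
#' @param g An `igraph` network.
#' @param rng_seed Seed passed to community detection.
#' @return A one-row data frame.
#' @export
structural_summary <- function(g, rng_seed = 1) {
  g <- ensure_ids(g)
  n <- igraph::vcount(g); ne <- igraph::ecount(g)
  connected <- igraph::is_connected(g)
  gd <- if (connected) g else largest_connected_component(g)
  part <- detect_communities(g, rng_seed = rng_seed)
  data.frame(
    n_nodes = n,
    n_edges = ne,
    density = if (n > 1) 2 * ne / (n * (n - 1)) else 0,
    mean_degree = if (n > 0) 2 * ne / n else 0,
    mean_clustering = mean_clustering(g),
    n_communities = part$n_communities,
    modularity = part$modularity,
    diameter = igraph::diameter(gd, directed = FALSE, unconnected = FALSE),
    mean_shortest_path = igraph::mean_distance(gd, directed = FALSE),
    assortativity = suppressWarnings(igraph::assortativity_degree(g)),
    distances_on_lcc = !connected)
}
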