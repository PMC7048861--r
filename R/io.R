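# File I/O: graph readers/writers, result export, experiment
# configuration files, and closed-form test fixtures.

#' Read a network from a file
#'
#' Supported formats: whitespace- or comma-delimited edge lists (two
#' label columns, `#` comments), GraphML and GML (parsed by
#' \pkg{igraph}). The result is always a simple undirected network:
#' directed edges are symmetrized, duplicate edges collapsed, and
#' self-loops dropped (their count is reported via `message()` and the
#' graph attribute `n_self_loops_dropped`). Original node labels are
#' mapped to 0-based consecutive ids (numeric labels in numeric order,
#' otherwise lexicographic); the original label is kept in the vertex
#' attribute `label`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edgelist"`, `"graphml"` or
#'   `"gml"`.
#' @return An `igraph` network.
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "graphml", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", gml = "gml", "edgelist")
  }
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    keep <- which(trimws(lines) != "")
    tokens <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
    bad <- which(lengths(tokens) != 2L)
    if (length(bad) > 0L)
      stop(sprintf("malformed edge list: line %d of %s does not have two fields",
                   keep[bad[1]], path), call. = FALSE)
    el <- matrix(unlist(tokens), ncol = 2, byrow = TRUE)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    g <- igraph::read_graph(path, format = format)
  }
  normalize_graph(g)
}

# Symmetrize, simplify, and relabel with 0-based ids.
normalize_graph <- function(g) {
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L) message(n_loops, " self-loop(s) dropped")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)) - 1L)
  num <- suppressWarnings(as.numeric(labels))
  ord <- if (!anyNA(num)) order(num) else order(labels)
  g <- igraph::permute(g, match(seq_along(ord), ord))
  igraph::V(g)$label <- labels[ord]
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  igraph::set_graph_attr(g, "n_self_loops_dropped", n_loops)
}

#' Write a network to a file
#'
#' The edge-list format writes two space-separated 0-based node ids
#' per line; GraphML and GML delegate to [igraph::write_graph()].
#'
#' @param g An `igraph` network.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"edgelist"`, `"graphml"` or
#'   `"gml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("auto", "edgelist", "graphml", "gml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", gml = "gml", "edgelist")
  }
  g <- ensure_ids(g)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), path)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Export a community partition as CSV
#'
#' @param partition An `sb_partition`.
#' @param path Output path; columns `node`, `community`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "sb_partition"))
  df <- data.frame(node = as.integer(names(partition$membership)),
                   community = as.integer(partition$membership))
  df <- df[order(df$node), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write benchmark outputs to a directory
#'
#' Writes `runs.csv` (long-format run records), `ranking.csv`,
#' one `degeneracy-<rule>.csv` per seed-size rule (square matrix with
#' strategy names as header row and first column), and
#' `manifest.json` recording the configuration, master seed and
#' package version. Output is deterministic: identical inputs yield
#' byte-identical files.
#'
#' @param result A `benchmark_result` from [run_benchmark()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "runs.csv")
  utils::write.csv(result$records, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "ranking.csv")
  utils::write.csv(result$ranking, p, row.names = FALSE)
  paths <- c(paths, p)
  for (label in names(result$degeneracy)) {
    p <- file.path(out_dir, sprintf("degeneracy-%s.csv", label))
    m <- result$degeneracy[[label]]
    df <- data.frame(strategy = rownames(m), as.data.frame(m, optional = TRUE),
                     check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "seedbench",
    version = as.character(utils::packageVersion("seedbench")),
    config = unclass(result$config),
    rng_seed = result$config$rng_seed,
    n_records = nrow(result$records))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a benchmark configuration file
#'
#' YAML or JSON with keys matching [benchmark_config()] arguments
#' (`category`, `size`, `n_networks`, `n_runs`, `g_grid`, `s_rule`,
#' `rng_seed` or `seed`, `graph_files`).
#'
#' @param path Config file path.
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.null(raw$seed) && is.null(raw$rng_seed)) raw$rng_seed <- raw$seed
  raw$seed <- NULL
  known <- names(formals(benchmark_config))
  do.call(benchmark_config, raw[intersect(names(raw), known)])
}

#' Build a closed-form test network
#'
#' Deterministic fixtures whose exact edge sets follow from their
#' parameters: `star` (hub id 0 plus `k` leaves), `path` and `cycle`
#' (`k` nodes), `two_cliques_bridge` (two `k`-cliques joined by one
#' edge), `dyad` (a single edge), `grid` (`k` x `k2` lattice).
#'
#' @param builder Fixture family name.
#' @param k Primary size parameter (see above).
#' @param k2 Second dimension for `grid` (defaults to `k`).
#' @return An `igraph` network with 0-based ids.
#' @export
build_fixture <- function(builder = c("star", "path", "cycle",
                                      "two_cliques_bridge", "dyad", "grid"),
                          k = 4, k2 = NULL) {
  builder <- match.arg(builder)
  k <- as.integer(k)
  if (builder != "dyad" && (is.na(k) || k < 1L))
    stop("invalid fixture size", call. = FALSE)
  g <- switch(builder,
    star = igraph::make_star(k + 1L, mode = "undirected", center = 1),
    path = igraph::make_lattice(length = k, dim = 1),
    cycle = igraph::make_ring(k),
    two_cliques_bridge = {
      g1 <- igraph::make_full_graph(k)
      g2 <- igraph::make_full_graph(k)
      g <- igraph::disjoint_union(g1, g2)
      igraph::add_edges(g, c(1, k + 1L))
    },
    dyad = igraph::make_graph(c(1, 2), directed = FALSE),
    grid = igraph::make_lattice(dimvector = c(k, (k2 %||% k))))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  g
}
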