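# Internal helpers: RNG scoping and node-id bookkeeping.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. If `seed` is NULL the
# ambient RNG stream is used (and advanced), which lets seeded wrappers
# drive unseeded workers deterministically.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a base seed and integer context
# (network index, strategy index, run index, ...). Plain polynomial hash;
# keeps every derived seed strictly below 2^31.
derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  h <- 0
  for (x in parts) h <- (h * 7919 + (as.numeric(x) %% 104729) + 1) %% 2147483629
  as.integer(h)
}

# Ensure a graph carries 0-based consecutive integer ids in V(g)$name.
ensure_ids <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  }
  g
}

# 0-based integer node ids of a graph.
node_ids <- function(g) {
  g <- ensure_ids(g)
  as.integer(igraph::V(g)$name)
}

# Map 0-based ids to internal 1-based vertex indices, erroring on misses.
internal_index <- function(g, ids) {
  g <- ensure_ids(g)
  idx <- match(as.character(ids), igraph::V(g)$name)
  if (anyNA(idx)) {
    stop("node id(s) not present in the network: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# Integer adjacency list (internal 1-based indices).
adjacency_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
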