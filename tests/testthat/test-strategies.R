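# Seed-set selection strategies.

test_that("canonical single-seed picks: hub, bridge, full cover", {
  star <- build_fixture("star", 5)
  expect_equal(select_seeds(star, "degree", 1, rng_seed = 1)$nodes, 0L)
  p3 <- build_fixture("path", 3)
  expect_equal(select_seeds(p3, "betweenness", 1, rng_seed = 1)$nodes, 1L)
  g <- random_connected_graph(9, 0.5, 2)
  all_nodes <- as.integer(igraph::V(g)$name)
  for (strat in seeding_strategies()) {
    part <- detect_communities(g, 1)
    ss <- select_seeds(g, strat, length(all_nodes), partition = part,
                       rng_seed = 5)
    expect_setequal(ss$nodes, all_nodes)
  }
})

test_that("seed sets satisfy size, distinctness and membership on random fixtures", {
  strategies <- seeding_strategies()
  for (i in 1:12) {
    g <- random_connected_graph(15 + 2 * i, 0.15, i)
    ids <- as.integer(igraph::V(g)$name)
    part <- detect_communities(g, i)
    s <- min(4L, igraph::vcount(g))
    for (strat in strategies) {
      ss <- select_seeds(g, strat, s, partition = part, rng_seed = 100 + i)
      expect_s3_class(ss, "seed_set")
      expect_length(ss$nodes, s)
      expect_equal(anyDuplicated(ss$nodes), 0L)
      expect_true(all(ss$nodes %in% ids))
      # deterministic under the same seed
      ss2 <- select_seeds(g, strat, s, partition = part, rng_seed = 100 + i)
      expect_identical(ss$nodes, ss2$nodes)
    }
  }
})

test_that("degree strategy returns a top-s degree multiset", {
  g <- random_connected_graph(40, 0.15, 11)
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  s <- 6L
  ss <- select_seeds(g, "degree", s, rng_seed = 4)
  expect_equal(sort(unname(deg[as.character(ss$nodes)]), decreasing = TRUE),
               sort(deg, decreasing = TRUE)[seq_len(s)],
               ignore_attr = TRUE)
})

test_that("errors: unknown strategy, oversize s, missing partition", {
  g <- build_fixture("cycle", 6)
  expect_error(select_seeds(g, "krusty", 2), "arg")
  expect_error(select_seeds(g, "degree", 7), "outside")
  expect_error(select_seeds(g, "ambassadors", 2), "partition")
  expect_error(select_seeds(g, "community_hubs", 2), "partition")
})

test_that("kcore selection fills from the maximal core downwards", {
  # K5 with a pendant path: coreness 4 inside the clique, < 4 outside
  g <- igraph::make_full_graph(5)
  g <- igraph::add_vertices(g, 2)
  g <- igraph::add_edges(g, c(5, 6, 6, 7))
  igraph::V(g)$name <- as.character(0:6)
  core <- igraph::coreness(g)
  top_core <- as.integer(igraph::V(g)$name[core == max(core)])
  ss <- select_seeds(g, "kcore", 3, rng_seed = 8)
  expect_true(all(ss$nodes %in% top_core))
  ss_all <- select_seeds(g, "kcore", 6, rng_seed = 8)
  expect_true(all(top_core %in% ss_all$nodes[1:5]))   # core exhausted first
})

test_that("community strategies take one node per community, largest first", {
  # three cliques of sizes 5, 4, 3 chained by single bridges
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(4),
                              igraph::make_full_graph(3))
  g <- igraph::add_edges(g, c(1, 6, 6, 10))
  igraph::V(g)$name <- as.character(0:11)
  mem <- c(rep(0L, 5), rep(1L, 4), rep(2L, 3))
  names(mem) <- as.character(0:11)
  part <- structure(list(membership = mem, n_communities = 3L,
                         modularity = modularity_q(g, mem), rng_seed = 1L),
                    class = "sb_partition")
  for (strat in c("ambassadors", "community_hubs")) {
    ss <- select_seeds(g, strat, 3, partition = part, rng_seed = 2)
    expect_equal(mem[as.character(ss$nodes)], c(`?` = 0L, `?` = 1L, `?` = 2L),
                 ignore_attr = TRUE)      # one per community, sizes descending
    ss5 <- select_seeds(g, strat, 5, partition = part, rng_seed = 2)
    expect_setequal(unique(mem[as.character(ss5$nodes[1:3])]), 0:2)
  }
  # ambassadors pick boundary nodes: in community 1 the bridging node 5
  # has external degree 1 within... both 5 and 9 have external degree 1;
  # in community 0 only node 0 touches the bridge
  amb <- select_seeds(g, "ambassadors", 3, partition = part, rng_seed = 2)
  expect_equal(amb$nodes[1], 0L)
  # community hubs pick interior high-degree nodes; in community 0 all
  # clique members tie at internal degree 4 so any is acceptable
  hub <- select_seeds(g, "community_hubs", 3, partition = part, rng_seed = 2)
  expect_true(mem[as.character(hub$nodes[1])] == 0L)
})

test_that("external plus internal degree equals total degree everywhere", {
  g <- build_fixture("two_cliques_bridge", 3)
  mem <- c(rep(0L, 3), rep(1L, 3)); names(mem) <- as.character(0:5)
  part <- structure(list(membership = mem), class = "sb_partition")
  ei <- external_internal_degree(g, part, 0)
  expect_equal(unname(ei), c(1, 2))      # bridge endpoint
  ei <- external_internal_degree(g, part, 1)
  expect_equal(unname(ei), c(0, 2))      # interior node
  # brute force over random graphs/partitions
  for (i in 1:4) {
    g <- random_connected_graph(8, 0.4, 20 + i)
    ids <- as.integer(igraph::V(g)$name)
    set.seed(i)
    mem <- sample(0:2, length(ids), replace = TRUE)
    names(mem) <- as.character(ids)
    part <- structure(list(membership = mem), class = "sb_partition")
    el <- igraph::as_edgelist(g, names = TRUE)
    for (v in ids) {
      touches <- el[el[, 1] == as.character(v) | el[, 2] == as.character(v), ,
                    drop = FALSE]
      other <- ifelse(touches[, 1] == as.character(v), touches[, 2], touches[, 1])
      expected_ext <- sum(mem[other] != mem[as.character(v)])
      expected_int <- sum(mem[other] == mem[as.character(v)])
      ei <- external_internal_degree(g, part, v)
      expect_equal(unname(ei), c(expected_ext, expected_int))
    }
  }
})

test_that("voterank follows the ability-depletion rule", {
  star <- build_fixture("star", 4)      # hub 0 + 4 leaves, <k> = 8/5
  tr <- voterank_trace(star, 2, rng_seed = 1)
  expect_equal(tr$node[1], 0L)          # first pick is the max-degree node
  expect_equal(tr$score[1], 4)          # score = degree while abilities are 1
  expect_true(tr$node[2] %in% 1:4)      # then any leaf
  # after zeroing the hub, every leaf's neighbourhood ability is 0
  expect_equal(tr$score[2], 0)

  # step-by-step verification against an independent state simulation
  for (i in 1:4) {
    g <- random_connected_graph(12, 0.3, 40 + i)
    adj <- lapply(igraph::as_adj_list(g), as.integer)
    kmean <- mean(igraph::degree(g))
    ids <- as.integer(igraph::V(g)$name)
    s <- 4L
    tr <- voterank_trace(g, s, rng_seed = i)
    ability <- rep(1, length(ids))
    picked <- integer(0)
    for (step in seq_len(s)) {
      scores <- vapply(seq_along(ids), function(v) sum(ability[adj[[v]]]),
                       numeric(1))
      scores[match(picked, ids)] <- -Inf
      sel_idx <- match(tr$node[step], ids)
      expect_equal(tr$score[step], scores[sel_idx])
      expect_equal(scores[sel_idx], max(scores))   # an argmax was selected
      picked <- c(picked, tr$node[step])
      ability[sel_idx] <- 0
      nb <- adj[[sel_idx]]
      ability[nb] <- pmax(0, ability[nb] - 1 / kmean)
    }
  }
})

test_that("random_hubs returns max-degree neighbours of sampled nodes", {
  star <- build_fixture("star", 6)
  # on a star every node's highest-degree neighbour is determined:
  # leaves point at the hub, the hub at some leaf
  ss <- select_seeds(star, "random_hubs", 2, rng_seed = 3)
  expect_true(0L %in% ss$nodes)   # hub is almost surely picked within 2 draws
  g <- random_connected_graph(20, 0.25, 5)
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  ss <- select_seeds(g, "random_hubs", 5, rng_seed = 6)
  # the first pick faces no exclusions: it must be the maximum-degree
  # neighbour of at least one node
  v1 <- ss$nodes[1]
  witnesses <- sapply(seq_along(adj), function(u) {
    nb <- as.integer(igraph::V(g)$name[as.integer(adj[[u]])])
    v1 %in% nb && deg[as.character(v1)] == max(deg[as.character(nb)])
  })
  expect_true(any(witnesses))
  # with s = n the fallback to unselected neighbours covers every node
  full <- select_seeds(g, "random_hubs", igraph::vcount(g), rng_seed = 6)
  expect_setequal(full$nodes, as.integer(igraph::V(g)$name))
})
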