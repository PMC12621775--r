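# Zip codes, zip code trees, and tree-based seed distances.

g1_seeds <- function() {
  data.frame(read_offset = c(0L, 4L, 5L),
             node = c(1L, 2L, 4L), orient = 1L,
             offset = c(3L, 0L, 0L))
}

test_that("zip codes record the snarl-tree path to a position", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  z2 <- compute_zipcode(idx, graph_pos(2, 1, 0))
  kinds <- vapply(z2$records, `[[`, character(1), "kind")
  expect_equal(kinds, c("chain", "snarl", "chain", "node"))
  z1 <- compute_zipcode(idx, graph_pos(1, 1, 2))
  kinds1 <- vapply(z1$records, `[[`, character(1), "kind")
  expect_equal(kinds1, c("chain", "node"))
  expect_equal(z1$records[[1]]$prefix, 0)
  # two positions on one node differ only in the final offset record
  za <- compute_zipcode(idx, graph_pos(4, 1, 0))
  zb <- compute_zipcode(idx, graph_pos(4, 1, 2))
  expect_identical(za$records[-length(za$records)],
                   zb$records[-length(zb$records)])
})

test_that("zip sort keys order seeds along chains and within nodes", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  key <- function(n, o, f) zip_sort_key(compute_zipcode(idx, graph_pos(n, o, f)))
  expect_true(key(1, 1, 0) < key(1, 1, 3))       # same-node offset order
  expect_true(key(1, 1, 0) < key(4, 1, 0))       # chain order
  expect_true(key(2, 1, 0) != key(3, 1, 0))      # sibling alleles distinct
})

test_that("the zip code tree holds the expected items and distances", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  tr <- build_zip_tree(g1_seeds(), idx)
  types <- vapply(tr$items, `[[`, character(1), "type")
  expect_equal(sum(types == "seed"), 3L)
  expect_true("snarl_start" %in% types && "snarl_end" %in% types)
  expect_true(all(tr$dists >= 0 | !is.finite(tr$dists)))
  # distances from the last seed: seed 2 at 0, seed 1 at 1
  td <- tree_distances(tr, 3L)
  expect_equal(td$seed, c(2L, 1L))
  expect_equal(td$distance, c(0, 1))
  # first seed has no predecessors
  expect_equal(nrow(tree_distances(tr, 1L)), 0L)
})

test_that("parallel-allele seeds never yield each other", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  seeds <- data.frame(read_offset = c(4L, 4L), node = c(2L, 3L),
                      orient = 1L, offset = 0L)
  tr <- build_zip_tree(seeds, idx)
  expect_equal(nrow(tree_distances(tr, 2L)), 0L)
  expect_equal(nrow(tree_distances(tr, 1L)), 0L)
})

test_that("single-seed trees carry the seed with its chain boundaries", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  tr <- build_zip_tree(data.frame(read_offset = 0L, node = 1L, orient = 1L,
                                  offset = 1L), idx)
  types <- vapply(tr$items, `[[`, character(1), "type")
  expect_equal(types, c("chain_start", "seed", "chain_end"))
})

test_that("identical seed sets produce byte-identical trees", {
  g <- rand_graph(4)
  idx <- build_distance_index(g, snarl_decompose(g))
  idx$coords <- panmap:::index_coords(idx)
  set.seed(99)
  pos <- all_positions(g)
  sel <- sample(nrow(pos), 12L)
  seeds <- data.frame(read_offset = seq_along(sel) * 10L,
                      node = pos$node[sel], orient = pos$orient[sel],
                      offset = pos$offset[sel])
  t1 <- build_zip_tree(seeds, idx)
  t2 <- build_zip_tree(seeds, idx)
  expect_identical(serialize(t1$items, NULL), serialize(t2$items, NULL))
  expect_identical(t1$dists, t2$dists)
})

test_that("tree distances are sound against the exact oracle", {
  # acyclic fixtures: yielded == oracle; cyclic: >= oracle, Inf never yielded
  for (seed in 1:6) {
    cyclic <- seed %% 2L == 0L
    g <- rand_graph(seed, with_cycles = cyclic)
    idx <- build_distance_index(g, snarl_decompose(g))
    om <- oracle_dist_mats(g)
    pos <- all_positions(g)
    set.seed(seed)
    sel <- sample(nrow(pos), min(15L, nrow(pos)))
    seeds <- data.frame(read_offset = seq_along(sel) * 5L,
                        node = pos$node[sel], orient = pos$orient[sel],
                        offset = pos$offset[sel])
    tr <- build_zip_tree(seeds, idx, labels = FALSE)
    for (s in seq_len(nrow(seeds))) {
      td <- tree_distances(tr, s)
      for (r in seq_len(nrow(td))) {
        u <- td$seed[r]
        exact <- oracle_position_dist(
          om,
          graph_pos(seeds$node[u], seeds$orient[u], seeds$offset[u]),
          graph_pos(seeds$node[s], seeds$orient[s], seeds$offset[s]))
        expect_true(is.finite(exact))   # infinite pairs never linked
        expect_gte(td$distance[r], exact - 1e-9)
        expect_equal(td$distance[r], exact)
      }
    }
  }
})
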