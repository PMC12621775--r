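# Co-linear chaining: gap cost, DP optimality, decoy exclusion.

test_that("gap cost follows the stated form", {
  p <- chaining_params()
  expect_equal(gap_cost(5, 5, 29, p), 0)
  expect_equal(gap_cost(10, 0, 29, p), 0.01 * 29 * 10 + 0.5 * log2(10))
  expect_equal(gap_cost(10, 0, 29, p), 4.5609, tolerance = 1e-4)
  expect_equal(gap_cost(3, Inf, 29, p), Inf)
})

test_that("a zero-gap co-linear anchor set chains into one full chain", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  idx$coords <- panmap:::index_coords(idx)
  anchors <- data.frame(read_offset = c(0L, 4L, 5L),
                        node = c(1L, 2L, 4L), orient = 1L,
                        offset = c(0L, 0L, 0L), k = c(4L, 1L, 3L),
                        walk = 1L, wpos = c(0L, 4L, 5L), dir = 1L)
  tr <- build_zip_tree(anchors, idx, labels = FALSE)
  cp <- chaining_params(match_bonus = 1)
  chains <- chain_anchors(anchors, tr, cp)
  expect_length(chains, 1L)
  expect_equal(length(chains[[1]]$anchors), 3L)
  expect_equal(chains[[1]]$score, 8)  # covered bases x match bonus, no gaps
})

test_that("a decoy on the parallel allele is excluded from the chain", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  idx$coords <- panmap:::index_coords(idx)
  # read follows node 2; decoy anchor sits on node 3
  anchors <- data.frame(read_offset = c(0L, 4L, 4L, 5L),
                        node = c(1L, 2L, 3L, 4L), orient = 1L,
                        offset = 0L, k = c(4L, 1L, 1L, 3L),
                        walk = c(1L, 1L, 2L, 1L), wpos = c(0L, 4L, 4L, 5L),
                        dir = 1L)
  tr <- build_zip_tree(anchors, idx, labels = FALSE)
  chains <- chain_anchors(anchors, tr, chaining_params())
  best <- chains[[1]]
  picked_nodes <- anchors$node[best$anchors]
  expect_true(xor(2L %in% picked_nodes, 3L %in% picked_nodes))
})

test_that("DP chain score equals exhaustive enumeration on random trials", {
  g <- rand_graph(11, backbone = 120L, with_cycles = FALSE)
  idx <- build_distance_index(g, snarl_decompose(g))
  idx$coords <- panmap:::index_coords(idx)
  cp <- chaining_params(frag_max_read_gap = 10000, frag_max_graph_gap = 10000,
                        lookback = 100L)
  n_match <- 0L
  for (trial in 1:50) {
    anchors <- chain_trial_anchors(g, idx, n_anchors = sample(3:8, 1L), seed = trial)
    anchors <- anchors[!duplicated(anchors$read_offset), , drop = FALSE]
    if (nrow(anchors) < 2L) next
    tr <- build_zip_tree(anchors, idx, labels = FALSE)
    chains <- chain_anchors(anchors, tr, cp)
    got <- if (length(chains)) chains[[1]]$score else -Inf
    # oracle: exhaustive enumeration over the same distance provider
    Dss <- anchor_addr_distances(idx, anchors)
    rs <- anchors$read_offset + 1L
    re <- rs + anchors$k - 1L
    want <- oracle_best_chain(rs, re, Dss, k = 5L, cp)
    expect_equal(got, want, tolerance = 1e-9,
                 info = sprintf("trial %d", trial))
    n_match <- n_match + 1L
  }
  expect_gt(n_match, 30L)
})

test_that("adding a zero-gap co-linear anchor never lowers the best score", {
  g <- rand_graph(7, backbone = 100L, with_cycles = FALSE)
  idx <- build_distance_index(g, snarl_decompose(g))
  idx$coords <- panmap:::index_coords(idx)
  hindex <- panmap:::walk_only_index(g)
  cp <- chaining_params()
  for (trial in 1:10) {
    set.seed(trial)
    w <- hindex$walks[[1]]
    wlen <- nchar(w$seq)
    wc <- sort(sample(0:(wlen - 6L), 5L))
    mk <- function(wcs) {
      pos <- lapply(wcs, function(x) panmap:::wc_to_pos(hindex, 1L, x, 1L))
      data.frame(read_offset = as.integer(wcs),
                 node = vapply(pos, `[[`, integer(1), "node"),
                 orient = vapply(pos, `[[`, integer(1), "orient"),
                 offset = vapply(pos, `[[`, integer(1), "offset"),
                 k = 5L, walk = 1L, wpos = wcs, dir = 1L)
    }
    a1 <- mk(wc[-3])
    a2 <- mk(wc)      # one extra perfectly co-linear anchor
    s1 <- chain_anchors(a1, build_zip_tree(a1, idx, labels = FALSE), cp)[[1]]$score
    s2 <- chain_anchors(a2, build_zip_tree(a2, idx, labels = FALSE), cp)[[1]]$score
    expect_gte(s2, s1 - 1e-9)
  }
})

test_that("empty anchor sets chain to nothing", {
  g1 <- example_graph("bubble")
  idx <- build_distance_index(g1, snarl_decompose(g1))
  empty <- data.frame(read_offset = integer(0), node = integer(0),
                      orient = integer(0), offset = integer(0), k = integer(0),
                      walk = integer(0), wpos = integer(0), dir = integer(0))
  tr <- build_zip_tree(empty, idx)
  expect_length(chain_anchors(empty, tr, chaining_params()), 0L)
})
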