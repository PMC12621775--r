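# Snarl/chain decomposition against the definitional brute-force oracle.

test_that("is_separable matches the definition on the bubble graph", {
  g1 <- example_graph("bubble")
  expect_true(is_separable(g1, node_side(1, "R"), node_side(4, "L")))
  expect_false(is_separable(g1, node_side(1, "R"), node_side(2, "R")))
  expect_error(is_separable(g1, node_side(1, "L"), node_side(1, "R")),
               class = "invalid_pair")
  # cross-check a handful of pairs against the independent BFS oracle
  sa <- side_adj(g1)
  for (a_n in 1:4) for (b_n in 1:4) {
    if (a_n == b_n) next
    for (a_s in c("L", "R")) for (b_s in c("L", "R")) {
      expect_equal(
        is_separable(g1, node_side(a_n, a_s), node_side(b_n, b_s)),
        bfs_separable_oracle(sa, a_n, a_s, b_n, b_s),
        info = sprintf("%d%s-%d%s", a_n, a_s, b_n, b_s))
    }
  }
})

expect_chain_nodes <- function(tree, expected) {
  root <- tree$chains[[tree$roots[1]]]
  expect_identical(root$nodes, expected)
}

test_that("toy graphs decompose to the expected snarl trees", {
  g1 <- example_graph("bubble")
  t1 <- snarl_decompose(g1)
  expect_chain_nodes(t1, c(1L, 4L))
  sn <- t1$snarls[[t1$chains[[t1$roots[1]]]$snarl_ids[1]]]
  expect_equal(sn$start, list(node = 1L, side = "R"))
  expect_equal(sn$end, list(node = 4L, side = "L"))
  expect_setequal(sn$content, c(2L, 3L))

  t2 <- snarl_decompose(example_graph("inversion"))
  expect_chain_nodes(t2, c(1L, 3L))
  sn2 <- t2$snarls[[t2$chains[[t2$roots[1]]]$snarl_ids[1]]]
  expect_equal(sn2$content, 2L)

  # single node, no edges: one root chain, zero snarls
  t0 <- snarl_decompose(variation_graph(c("1" = "ACGT")))
  expect_length(t0$snarls, 0L)
  expect_chain_nodes(t0, 1L)
})

test_that("leaf snarls are those whose child chains are single nodes", {
  t1 <- snarl_decompose(example_graph("bubble"))
  ls <- leaf_snarls(t1)
  expect_length(ls, 1L)
  expect_setequal(ls[[1]]$content, c(2L, 3L))
  # SNP nested inside an insertion: only the inner snarl is a leaf
  gfa <- paste(sep = "\n",
    "S\t1\tGGG", "S\t2\tAC", "S\t3\tA", "S\t4\tT", "S\t5\tCC", "S\t6\tGGG",
    "L\t1\t+\t6\t+\t0M",             # insertion absent
    "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M", "L\t2\t+\t4\t+\t0M",
    "L\t3\t+\t5\t+\t0M", "L\t4\t+\t5\t+\t0M", "L\t5\t+\t6\t+\t0M",
    "P\thapA\t1+,6+\t*", "P\thapB\t1+,2+,3+,5+,6+\t*",
    "P\thapC\t1+,2+,4+,5+,6+\t*")
  tn <- snarl_decompose(parse_gfa(gfa))
  ls2 <- leaf_snarls(tn)
  expect_length(ls2, 1L)
  expect_setequal(ls2[[1]]$content, c(3L, 4L))
  # snarl-free graph
  t0 <- snarl_decompose(variation_graph(c("1" = "ACGT")))
  expect_length(leaf_snarls(t0), 0L)
})

check_partitions <- function(graph, tree) {
  # node partition: every node in exactly one chain
  all_nodes <- unlist(lapply(tree$chains, `[[`, "nodes"))
  expect_equal(sort(all_nodes), sort(as.integer(names(graph$seqs))))
  # edge partition: every edge in exactly one snarl (or leftover)
  n_owned <- sum(vapply(real_snarls(tree), function(s) nrow(s$edges), integer(1)))
  expect_equal(n_owned + nrow(tree$leftover_edges), nrow(graph$edges))
  expect_equal(nrow(tree$leftover_edges), 0L)
}

check_definitional <- function(graph, tree) {
  sa <- side_adj(graph)
  for (sn in real_snarls(tree, include_trivial = FALSE)) {
    expect_true(bfs_separable_oracle(sa, sn$start$node, sn$start$side,
                                     sn$end$node, sn$end$side))
    interior <- oracle_interior(graph, sa, sn$start$node, sn$start$side,
                                sn$end$node, sn$end$side)
    expect_setequal(sn$content, interior)
    # minimality: no side strictly inside separable with either boundary
    for (nd in interior) for (s in c("L", "R")) {
      expect_false(bfs_separable_oracle(sa, sn$start$node, sn$start$side, nd, s))
      expect_false(bfs_separable_oracle(sa, nd, s, sn$end$node, sn$end$side))
    }
  }
}

test_that("random graphs decompose into definitionally valid snarls", {
  for (seed in 1:25) {
    g <- rand_graph(seed)
    tr <- snarl_decompose(g)
    check_partitions(g, tr)
    check_definitional(g, tr)
  }
})

test_that("every brute-force separable-minimal pair is a snarl boundary or conflicts with one", {
  for (seed in 1:8) {
    g <- rand_graph(seed, backbone = 40L)
    tr <- snarl_decompose(g)
    bnd <- unlist(lapply(real_snarls(tr), function(s) {
      c(paste0(s$start$node, s$start$side), paste0(s$end$node, s$end$side))
    }))
    sp <- panmap:::separable_pairs(g)
    sa <- side_adj(g)
    for (i in which(sp$minimal)) {
      p <- sp$pairs[i, ]
      # verify against the independent oracle too
      expect_true(bfs_separable_oracle(sa, p[1], c("L", "R")[p[2] + 1],
                                       p[3], c("L", "R")[p[4] + 1]))
      k1 <- paste0(p[1], c("L", "R")[p[2] + 1])
      k2 <- paste0(p[3], c("L", "R")[p[4] + 1])
      accepted <- k1 %in% bnd && k2 %in% bnd
      # under the canonical tie-break an unaccepted minimal pair must at
      # least share a boundary slot with an accepted snarl (a conflict)
      expect_true(accepted || k1 %in% bnd || k2 %in% bnd ||
                    any(p[1] %in% unlist(lapply(real_snarls(tr), `[[`, "content"))),
                  info = sprintf("seed %d pair %s-%s", seed, k1, k2))
    }
  }
})

test_that("decomposition is invariant under node relabeling (up to relabeling)", {
  g <- rand_graph(3)
  ids <- as.integer(names(g$seqs))
  # reverse the id space: new id = max + 1 - old
  m <- max(ids) + 1L
  relab <- function(x) m - x
  g2 <- variation_graph(
    setNames(g$seqs, relab(ids)),
    data.frame(node1 = relab(g$edges$node1), side1 = g$edges$side1,
               node2 = relab(g$edges$node2), side2 = g$edges$side2),
    lapply(g$walks, function(w) {
      w$nodes <- relab(w$nodes); w
    }))
  t1 <- snarl_decompose(g)
  t2 <- snarl_decompose(g2)
  snarl_set <- function(tr, f = identity) {
    sort(vapply(real_snarls(tr), function(s) {
      paste(sort(c(paste0(f(s$start$node), s$start$side),
                   paste0(f(s$end$node), s$end$side))), collapse = "~")
    }, character(1)))
  }
  expect_identical(snarl_set(t2), snarl_set(t1, relab))
})
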