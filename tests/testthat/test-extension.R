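# Alignment kernels and chain extension.

test_that("wavefront alignment handles the degenerate and forced cases", {
  sc <- aln_scoring(match = 1L, mismatch = 4L, gap_open = 6L, gap_extend = 1L)
  r <- wfa_align("ACGT", "ACGT", sc)
  expect_true(r$ok)
  expect_equal(r$score, 4)
  expect_equal(r$ops, "=")
  expect_equal(r$lens, 4L)
  # one forced deletion: 3*match - gap_open - gap_extend
  r2 <- wfa_align("ACGT", "AGT", sc)
  expect_true(r2$ok)
  expect_equal(r2$score, 3 - 6 - 1)
  expect_equal(sum(r2$lens[r2$ops == "I"]), 1L)
})

test_that("wavefront scores equal the full affine DP on random pairs", {
  sc <- aln_scoring()
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (trial in 1:150) {
    n <- sample(5:120, 1L)
    t <- paste0(sample(bases, n, replace = TRUE), collapse = "")
    # mutate into the query at <= 20% edit rate
    q <- strsplit(t, "")[[1]]
    n_ed <- rbinom(1L, n, 0.15)
    if (n_ed > 0) for (e in seq_len(n_ed)) {
      i <- sample(length(q), 1L)
      op <- sample(3L, 1L)
      if (op == 1L) q[i] <- sample(bases, 1L)
      else if (op == 2L && length(q) > 2L) q <- q[-i]
      else q <- append(q, sample(bases, 1L), after = i)
    }
    q <- paste0(q, collapse = "")
    r <- wfa_align(q, t, sc)
    expect_true(r$ok)
    expect_equal(r$score, oracle_affine_score(q, t, sc),
                 info = sprintf("trial %d", trial))
    # reported CIGAR reproduces the reported score and consumes both strings
    expect_equal(panmap:::cigar_score(r$ops, r$lens, sc), r$score)
    expect_equal(sum(r$lens[r$ops %in% c("=", "X", "I")]), nchar(q))
    expect_equal(sum(r$lens[r$ops %in% c("=", "X", "D")]), nchar(t))
  }
})

test_that("wavefront alignment fails cleanly past the cost ceiling", {
  sc <- aln_scoring()
  r <- wfa_align("AAAAAAAA", "TTTTTTTT", sc, max_cost = 3)
  expect_false(r$ok)
})

test_that("local haplotype enumeration finds both alleles of the bubble", {
  g1 <- example_graph("bubble")
  walks <- enumerate_local_haplotypes(g1, graph_pos(1, 1, 3), graph_pos(4, 1, 0))
  expect_length(walks, 2L)
  expect_setequal(vapply(walks, `[[`, character(1), "string"), c("A", "C"))
  # adjacent positions on one node: a single empty-string walk
  w2 <- enumerate_local_haplotypes(g1, graph_pos(1, 1, 1), graph_pos(1, 1, 2))
  expect_length(w2, 1L)
  expect_equal(w2[[1]]$string, "")
  # the cap is respected
  w3 <- enumerate_local_haplotypes(g1, graph_pos(1, 1, 3), graph_pos(4, 1, 0),
                                   limit = 1L)
  expect_length(w3, 1L)
})

test_that("banded graph alignment agrees with walk enumeration + full DP", {
  sc <- aln_scoring()
  for (which in c("bubble", "inversion")) {
    g <- example_graph(which)
    ends <- if (which == "bubble") list(graph_pos(1, 1, 3), graph_pos(4, 1, 0))
            else list(graph_pos(1, 1, 2), graph_pos(3, 1, 0))
    for (q in c("A", "C", "T", "AC", "")) {
      r <- banded_graph_align(q, g, ends[[1]], ends[[2]], band_width = 50L,
                              scoring = sc)
      # oracle: exhaustive walks (independent DFS through edge table was
      # exercised above); score each with the R full DP
      walks <- panmap:::graph_walks_between(g, ends[[1]], ends[[2]], 60L)
      want <- max(vapply(walks, function(w) {
        if (nchar(w$string) == 0L && nchar(q) == 0L) 0
        else oracle_affine_score(q, w$string, sc)
      }, numeric(1)))
      expect_true(r$ok)
      expect_equal(r$score, want, info = sprintf("%s q=%s", which, q))
    }
  }
})

test_that("banded graph alignment of the exact walk string is all matches", {
  g2 <- example_graph("inversion")
  # walk 1+,2-,3+ spells GAT | CAA | CA; between (1,+,2) and (3,+,0) -> "CAA"
  r <- banded_graph_align("CAA", g2, graph_pos(1, 1, 2), graph_pos(3, 1, 0),
                          band_width = 10L)
  expect_true(r$ok)
  expect_equal(r$ops, "=")
  expect_equal(r$score, 3)
})

test_that("x-drop tail extension aligns true continuations and clips noise", {
  g1 <- example_graph("bubble")
  hindex <- panmap:::walk_only_index(g1)
  # tail identical to hapA continuation after (1,+,1): "TTAACA"
  r <- xdrop_tail_align("TTAACA", g1, graph_pos(1, 1, 1), "right",
                        x_drop = 20L, hindex = hindex)
  expect_equal(r$query_used, 6L)
  expect_equal(r$ops, "=")
  # random tail unrelated to the graph: clipped at/near the anchor
  r2 <- xdrop_tail_align("GGGGGGGG", g1, graph_pos(1, 1, 1), "right",
                         x_drop = 10L, hindex = hindex)
  expect_lte(r2$query_used, 1L)
  # empty tail
  r3 <- xdrop_tail_align("", g1, graph_pos(1, 1, 1), "right", hindex = hindex)
  expect_equal(r3$query_used, 0L)
  expect_length(r3$ops, 0L)
})

mk_chain <- function(seeds) list(anchors = seq_len(nrow(seeds)), seed_df = seeds,
                                 score = 0, frame = "fwd")

test_that("a perfect read extends to the full-walk alignment", {
  g1 <- example_graph("bubble")
  hindex <- panmap:::walk_only_index(g1)
  # read = hapA; anchors at walk offsets 0 and 5, k = 3
  seeds <- data.frame(read_offset = c(0L, 5L), node = c(1L, 4L), orient = 1L,
                      offset = c(0L, 1L), k = 3L, walk = 1L, wpos = c(0L, 5L),
                      dir = 1L)
  al <- extend_chain("GATTAACA", mk_chain(seeds), g1, extension_params(),
                     hindex)
  expect_s3_class(al, "graph_alignment")
  expect_equal(al$path$node, c(1L, 2L, 4L))
  expect_equal(al$path$orient, c(1L, 1L, 1L))
  expect_equal(al$ops, "=")
  expect_equal(al$score, 8)
  expect_equal(al$q_start, 0L)
  expect_equal(al$q_end, 8L)
})

test_that("a read with a SNP inside the bubble picks the matching allele", {
  g1 <- example_graph("bubble")
  hindex <- panmap:::walk_only_index(g1)
  sc <- aln_scoring()
  # hapB read: GATT C ACA, anchored outside the bubble
  seeds <- data.frame(read_offset = c(0L, 5L), node = c(1L, 4L), orient = 1L,
                      offset = c(0L, 1L), k = 3L,
                      walk = c(1L, 1L), wpos = c(0L, 5L), dir = 1L)
  al <- extend_chain("GATTCACA", mk_chain(seeds), g1, extension_params(), hindex)
  expect_equal(al$path$node, c(1L, 3L, 4L))
  expect_equal(al$ops, "=")
  # a base neither allele spells: best path has exactly one mismatch
  al2 <- extend_chain("GATTGACA", mk_chain(seeds), g1, extension_params(), hindex)
  expect_equal(sum(al2$lens[al2$ops == "X"]), 1L)
  expect_equal(al2$score, 7 * sc$match - sc$mismatch)
})

test_that("a read over the inversion takes node 2 in reverse", {
  g2 <- example_graph("inversion")
  hindex <- panmap:::walk_only_index(g2)
  # hapB = GAT CAA CA (node 2 reversed)
  seeds <- data.frame(read_offset = c(0L, 6L), node = c(1L, 3L), orient = 1L,
                      offset = c(0L, 0L), k = 2L, walk = 2L, wpos = c(0L, 6L),
                      dir = 1L)
  al <- extend_chain("GATCAACA", mk_chain(seeds), g2, extension_params(), hindex)
  expect_equal(al$path$node, c(1L, 2L, 3L))
  expect_equal(al$path$orient, c(1L, -1L, 1L))
  expect_equal(al$ops, "=")
})

test_that("reported scores always equal the score implied by the CIGAR", {
  sc <- aln_scoring()
  g <- rand_graph(5, backbone = 80L)
  p <- seeding_params(k = 7L, w = 3L)
  hindex <- build_minimizer_index(g, p)
  idx <- build_distance_index(g, snarl_decompose(g))
  idx$coords <- panmap:::index_coords(idx)
  set.seed(1)
  hap <- hindex$walks[[1]]
  for (trial in 1:10) {
    st <- sample(nchar(hap$seq) - 40L, 1L)
    read <- substr(hap$seq, st, st + 39L)
    seeds <- select_seeds(read, hindex, p)
    if (nrow(seeds) < 2L) next
    tr <- build_zip_tree(seeds, idx, labels = FALSE, items = FALSE)
    chains <- chain_anchors(seeds, tr, chaining_params())
    if (!length(chains)) next
    ch <- chains[[1]]
    ch$seed_df <- seeds[ch$anchors, , drop = FALSE]
    al <- extend_chain(read, ch, g, extension_params(), hindex)
    expect_false(is.null(al))
    core <- al$ops != "S"
    expect_equal(panmap:::cigar_score(al$ops[core], al$lens[core], sc), al$score)
    # read accounting: clips + consumed query = read length
    expect_equal(sum(al$lens[al$ops %in% c("=", "X", "I", "S")]), nchar(read))
  }
})
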