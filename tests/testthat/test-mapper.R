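# End-to-end mapping, MAPQ, and GAF serialization.

toy_params <- function() {
  mapper_params(seeding = seeding_params(k = 3L, w = 1L, hard_hit_cap = 50L),
                chaining = chaining_params(frag_max_read_gap = 30,
                                           frag_max_graph_gap = 30))
}

test_that("an error-free read maps to the full haplotype path", {
  g1 <- example_graph("bubble")
  p <- toy_params()
  idx <- build_indexes(g1, p)
  alns <- map_read("GATTAACA", g1, idx, p, name = "r1")
  expect_gt(length(alns), 0L)
  expect_equal(alns[[1]]$path$node, c(1L, 2L, 4L))
  expect_equal(alns[[1]]$ops, "=")         # zero clips
  expect_equal(alns[[1]]$mapq, 60L)
})

test_that("a read unrelated to the graph stays unmapped", {
  g1 <- example_graph("bubble")
  p <- toy_params()
  idx <- build_indexes(g1, p)
  # sequence disjoint from the graph's 3-mer content
  expect_length(map_read("GGGGGGGGGGGG", g1, idx, p), 0L)
})

test_that("a read that loops twice visits the repeated node twice", {
  g3 <- example_graph("loop")
  p <- toy_params()
  idx <- build_indexes(g3, p)
  # hapB spells GAT CGA CGA TT
  alns <- map_read("GATCGACGATT", g3, idx, p, name = "loopy")
  expect_gt(length(alns), 0L)
  expect_equal(sum(alns[[1]]$path$node == 2L), 2L)
  expect_equal(alns[[1]]$ops, "=")
})

test_that("MAPQ follows the declared formula", {
  expect_equal(compute_mapq(100, NA), 60L)
  expect_equal(compute_mapq(100, 100), 0L)
  expect_equal(compute_mapq(100, 50, min_possible = 0), 30L)
  expect_error(compute_mapq(10, 50), class = "contract_violation")
})

test_that("GAF output round-trips through the parser", {
  g1 <- example_graph("bubble")
  p <- toy_params()
  idx <- build_indexes(g1, p)
  reads <- c(r1 = "GATTAACA", r2 = "GATTCACA")
  alns <- map_reads(reads, g1, idx, p)
  lines <- write_gaf(alns, NULL, graph = g1, reads = reads)
  expect_length(lines, 2L)
  gaf <- read_gaf(lines)
  expect_equal(gaf$name, c("r1", "r2"))
  expect_equal(gaf$path, c(">1>2>4", ">1>3>4"))
  expect_equal(gaf$qstart, c(0L, 0L))
  expect_equal(gaf$qend, c(8L, 8L))
  expect_equal(gaf$matches, c(8L, 8L))
  expect_equal(gaf$block, c(8L, 8L))
  pp <- parse_gaf_path(gaf$path[1])
  expect_equal(pp$node, c(1L, 2L, 4L))
  expect_equal(pp$orient, c(1L, 1L, 1L))
})

test_that("inversion alignments serialize with the '<' glyph", {
  g2 <- example_graph("inversion")
  p <- toy_params()
  idx <- build_indexes(g2, p)
  alns <- map_read("GATCAACA", g2, idx, p, name = "inv")
  expect_gt(length(alns), 0L)
  lines <- write_gaf(list(alns), NULL, graph = g2,
                     reads = c(inv = "GATCAACA"))
  expect_match(lines[1], "<2", fixed = TRUE)
})

test_that("unmapped reads produce no GAF record and are counted", {
  g1 <- example_graph("bubble")
  p <- toy_params()
  idx <- build_indexes(g1, p)
  reads <- c(good = "GATTAACA", bad = "GGGGGGGGGG")
  alns <- map_reads(reads, g1, idx, p)
  expect_equal(attr(alns, "n_unmapped"), 1L)
  expect_length(write_gaf(alns, NULL, graph = g1, reads = reads), 1L)
})

test_that("mapping is deterministic end to end", {
  g <- rand_graph(9, backbone = 120L)
  p <- mapper_params(seeding = seeding_params(k = 9L, w = 4L))
  idx <- build_indexes(g, p)
  sim <- simulate_reads(g, read_sim_params(n_reads = 8L, len_min = 40L,
                                           len_max = 90L, preset = "hifi",
                                           seed = 3L))
  a1 <- map_reads(sim$reads, g, idx, p)
  a2 <- map_reads(sim$reads, g, idx, p)
  l1 <- write_gaf(a1, NULL, graph = g, reads = sim$reads)
  l2 <- write_gaf(a2, NULL, graph = g, reads = sim$reads)
  expect_identical(l1, l2)
})
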