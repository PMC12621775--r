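# Minimizer index and weighted seed selection.

spell_from_graph <- function(graph, pos, k) {
  # all spellings of the k-mer starting at `pos` along embedded walks (a
  # position on a shared node may continue differently per haplotype);
  # independent of the index's own projection code
  hindex <- panmap:::walk_only_index(graph)
  occ <- panmap:::pos_walk_occ(hindex, pos)
  stopifnot(length(occ$walk) > 0)
  out <- character(0)
  for (i in seq_along(occ$walk)) {
    lo <- min(occ$wc[i], occ$wc[i] + occ$dir[i] * (k - 1L))
    hi <- max(occ$wc[i], occ$wc[i] + occ$dir[i] * (k - 1L))
    if (lo < 0L || hi >= nchar(hindex$walks[[occ$walk[i]]]$seq)) next
    out <- c(out, panmap:::span_string(hindex, occ$walk[i], lo, hi, occ$dir[i]))
  }
  unique(out)
}

test_that("every indexed minimizer position spells its k-mer", {
  g1 <- example_graph("bubble")
  p <- seeding_params(k = 3L, w = 2L, hard_hit_cap = 100L)
  idx <- build_minimizer_index(g1, p)
  expect_gt(nrow(idx$occ), 0L)
  for (r in seq_len(nrow(idx$occ))) {
    o <- idx$occ[r, ]
    w <- idx$walks[[o$walk]]
    kmer <- substr(w$seq, o$ws + 1L, o$ws + 3L)
    canon <- if (o$sw > 0L) kmer else revcomp(kmer)
    # the canonical k-mer, spelled from its stored graph position along
    # some haplotype walk
    spelled <- spell_from_graph(g1, graph_pos(o$cnode, o$corient, o$coff), 3L)
    expect_true(canon %in% spelled)
  }
})

test_that("w = 1 indexes every k-mer of a single haplotype", {
  g <- variation_graph(c("1" = "ACGTACGT"),
                       walks = list(list(name = "h", role = "haplotype",
                                         nodes = 1L, orients = 1L)))
  idx <- build_minimizer_index(g, seeding_params(k = 3L, w = 1L))
  expect_equal(nrow(idx$occ), 6L)
  expect_setequal(idx$occ$ws, 0:5)
})

test_that("parameter errors are raised", {
  expect_error(seeding_params(k = 35L), class = "parameter_error")
  g <- variation_graph(c("1" = "ACGT"))  # no walks
  expect_error(build_minimizer_index(g, seeding_params(k = 3L, w = 1L)),
               class = "parameter_error")
})

test_that("selected seeds are exact k-mer matches, both strands", {
  for (seed in 1:6) {
    g <- rand_graph(seed, backbone = 80L)
    p <- seeding_params(k = 7L, w = 5L)
    idx <- build_minimizer_index(g, p)
    hap <- walk_sequence(g, g$walks[[1]])
    read <- substr(hap, 10L, 45L)
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") read else revcomp(read)
      seeds <- select_seeds(rd, idx, p)
      expect_gt(nrow(seeds), 0L)
      for (i in seq_len(nrow(seeds))) {
        expect_true(
          substr(rd, seeds$read_offset[i] + 1L, seeds$read_offset[i] + 7L) %in%
            spell_from_graph(g, graph_pos(seeds$node[i], seeds$orient[i],
                                          seeds$offset[i]), 7L),
          info = sprintf("seed %d strand %s seed-graph mismatch", i, strand))
      }
    }
  }
})

test_that("reads shorter than k yield an empty seed set", {
  g1 <- example_graph("bubble")
  p <- seeding_params(k = 5L, w = 2L)
  idx <- build_minimizer_index(g1, p)
  expect_equal(nrow(select_seeds("ACG", idx, p)), 0L)
})

test_that("the hard hit cap filters repetitive minimizers monotonically", {
  # a graph whose haplotype is a perfect tandem repeat: every minimizer is
  # highly repetitive
  rep_seq <- strrep("ACGTGGTA", 12L)
  g <- variation_graph(c("1" = rep_seq),
                       walks = list(list(name = "h", role = "haplotype",
                                         nodes = 1L, orients = 1L)))
  read <- substr(rep_seq, 1L, 40L)
  p_lo <- seeding_params(k = 5L, w = 2L, hard_hit_cap = 1L)
  p_hi <- seeding_params(k = 5L, w = 2L, hard_hit_cap = 100L)
  idx <- build_minimizer_index(g, p_hi)
  s_lo <- select_seeds(read, idx, p_lo)
  s_hi <- select_seeds(read, idx, p_hi)
  expect_equal(nrow(s_lo), 0L)        # every minimizer above the low cap
  expect_gt(nrow(s_hi), 0L)           # raising the cap only adds seeds
  key <- function(s) paste(s$read_offset, s$node, s$orient, s$offset)
  expect_true(all(key(s_lo) %in% key(s_hi)))
})
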