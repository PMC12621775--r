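# Synthetic pangenome/read generation and evaluation.

test_that("an event-free simulation is a single-node chain", {
  g <- simulate_graph(graph_sim_params(backbone_len = 200L, snp_rate = 0,
                                       indel_rate = 0, n_inversions = 0L,
                                       n_duplications = 0L, n_haplotypes = 3L,
                                       seed = 1L))
  expect_length(g$seqs, 1L)
  tr <- snarl_decompose(g)
  expect_length(tr$snarls, 0L)
  seqs <- vapply(g$walks, function(w) walk_sequence(g, w), character(1))
  expect_length(unique(seqs), 1L)
})

test_that("a single SNP produces one bubble snarl", {
  g <- simulate_graph(graph_sim_params(backbone_len = 200L, snp_rate = 0,
                                       indel_rate = 0, n_inversions = 0L,
                                       n_duplications = 0L, n_haplotypes = 6L,
                                       seed = 2L))
  # inject one SNP by re-simulating with a rate yielding exactly one site
  set.seed(2)
  g2 <- NULL
  for (s in 1:50) {
    cand <- simulate_graph(graph_sim_params(backbone_len = 200L,
                                            snp_rate = 0.005, indel_rate = 0,
                                            n_inversions = 0L,
                                            n_duplications = 0L,
                                            n_haplotypes = 6L, seed = s))
    if (length(cand$seqs) == 4L) { g2 <- cand; break }
  }
  expect_false(is.null(g2))
  tr <- snarl_decompose(g2)
  real <- real_snarls(tr, include_trivial = FALSE)
  expect_length(real, 1L)
  expect_length(real[[1]]$content, 2L)
})

test_that("generation is deterministic per seed", {
  p <- graph_sim_params(backbone_len = 500L, seed = 7L, n_haplotypes = 4L,
                        n_inversions = 1L, inversion_len = 40L,
                        n_duplications = 1L, duplication_len = 30L)
  expect_identical(write_gfa(simulate_graph(p)), write_gfa(simulate_graph(p)))
  g <- simulate_graph(p)
  rp <- read_sim_params(n_reads = 10L, len_min = 50L, len_max = 100L, seed = 5L)
  expect_identical(simulate_reads(g, rp)$reads, simulate_reads(g, rp)$reads)
})

test_that("all generated graphs validate and decompose", {
  for (seed in 1:10) {
    g <- rand_graph(seed)
    expect_true(validate_graph(g))
    tr <- snarl_decompose(g)
    all_nodes <- unlist(lapply(tr$chains, `[[`, "nodes"))
    expect_setequal(all_nodes, as.integer(names(g$seqs)))
  }
})

test_that("error-free reads are exact haplotype substrings", {
  g <- rand_graph(3, backbone = 300L)
  rp <- read_sim_params(n_reads = 20L, len_min = 40L, len_max = 80L,
                        sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 9L)
  sim <- simulate_reads(g, rp)
  haps <- vapply(Filter(function(w) w$role == "haplotype", g$walks),
                 function(w) walk_sequence(g, w), character(1))
  names(haps) <- vapply(Filter(function(w) w$role == "haplotype", g$walks),
                        `[[`, character(1), "name")
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    frag <- substr(haps[[t$hap]], t$start + 1L, t$end)
    if (t$strand == "-") frag <- revcomp(frag)
    expect_identical(sim$reads[[t$name]], frag)
  }
})

test_that("injected error rates match their nominal values", {
  g <- simulate_graph(graph_sim_params(backbone_len = 4000L, snp_rate = 0,
                                       indel_rate = 0, n_inversions = 0L,
                                       n_duplications = 0L, n_haplotypes = 2L,
                                       seed = 4L))
  rp <- read_sim_params(n_reads = 14L, len_min = 1500L, len_max = 1500L,
                        sub_rate = 0.05, ins_rate = 0, del_rate = 0, seed = 11L)
  sim <- simulate_reads(g, rp)
  hap <- walk_sequence(g, g$walks[[1]])
  n_mm <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    frag <- substr(walk_sequence(g, g$walks[[match(t$hap,
      vapply(g$walks, `[[`, character(1), "name"))]]), t$start + 1L, t$end)
    if (t$strand == "-") frag <- revcomp(frag)
    a <- strsplit(sim$reads[[t$name]], "")[[1]]
    b <- strsplit(frag, "")[[1]]
    n_mm <- n_mm + sum(a != b)
    n_bases <- n_bases + length(b)
  }
  expect_gt(n_bases, 10000L)
  expect_lt(abs(n_mm / n_bases - 0.05), 0.01)
})

test_that("evaluation credits correct mappings and flags shifted ones", {
  g <- rand_graph(6, backbone = 300L)
  p <- mapper_params(seeding = seeding_params(k = 9L, w = 4L))
  idx <- build_indexes(g, p)
  sim <- simulate_reads(g, read_sim_params(n_reads = 12L, len_min = 60L,
                                           len_max = 120L, preset = "hifi",
                                           seed = 2L))
  alns <- map_reads(sim$reads, g, idx, p)
  gaf <- read_gaf(write_gaf(alns, NULL, graph = g, reads = sim$reads))
  ev <- evaluate_mappings(gaf, sim$truth, g)
  expect_equal(ev$summary$n_correct, ev$summary$n_mapped)
  # shift truth intervals far away: everything becomes incorrect
  bad_truth <- sim$truth
  span <- bad_truth$end - bad_truth$start
  hap_len <- nchar(walk_sequence(g, g$walks[[1]]))
  bad_truth$start <- pmax(0L, hap_len - span - bad_truth$start)
  bad_truth$end <- bad_truth$start + span
  ev2 <- evaluate_mappings(gaf, bad_truth, g)
  expect_lt(ev2$summary$n_correct, ev$summary$n_correct)
  # a GAF read absent from truth is an error
  expect_error(evaluate_mappings(gaf, sim$truth[-1, ], g),
               class = "evaluation_error")
})

test_that("a fixture with known wrong placements counts them exactly", {
  g <- rand_graph(8, backbone = 300L)
  p <- mapper_params(seeding = seeding_params(k = 9L, w = 4L))
  idx <- build_indexes(g, p)
  sim <- simulate_reads(g, read_sim_params(n_reads = 10L, len_min = 60L,
                                           len_max = 100L, preset = "hifi",
                                           seed = 3L))
  alns <- map_reads(sim$reads, g, idx, p)
  gaf <- read_gaf(write_gaf(alns, NULL, graph = g, reads = sim$reads))
  ev0 <- evaluate_mappings(gaf, sim$truth, g)
  # corrupt the truth of exactly 3 mapped reads
  mapped <- ev0$per_read$name[ev0$per_read$mapped & ev0$per_read$correct]
  stopifnot(length(mapped) >= 3L)
  bad <- sim$truth
  hap_len <- nchar(walk_sequence(g, g$walks[[1]]))
  for (nm in mapped[1:3]) {
    i <- which(bad$name == nm)
    span <- bad$end[i] - bad$start[i]
    bad$start[i] <- (bad$start[i] + hap_len %/% 2L) %% (hap_len - span)
    bad$end[i] <- bad$start[i] + span
  }
  ev <- evaluate_mappings(gaf, bad, g)
  expect_equal(ev0$summary$n_correct - ev$summary$n_correct, 3L)
})
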