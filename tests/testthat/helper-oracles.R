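# Independent oracles used across the test suite. These deliberately avoid
# the package's own algorithmic code paths: distances come from Dijkstra on
# the oriented-node graph via igraph, separability from a plain R BFS on
# the biedged side graph, alignment scores from a full-matrix affine DP,
# and chain scores from exhaustive subset enumeration.

# ---- distance oracle ---------------------------------------------------

# Directed oriented-node graph: vertex "n+"/"n-"; edge weight = length of
# the target node. Returns the one-step-aware distance matrix C where
# C[u, v] = min bases strictly after u through v inclusive over non-empty
# walks (so C[u, u] is the shortest cycle through u).
oracle_dist_mats <- function(graph) {
  ids <- as.integer(names(graph$seqs))
  lens <- setNames(nchar(graph$seqs), names(graph$seqs))
  verts <- as.vector(rbind(paste0(ids, "+"), paste0(ids, "-")))
  e <- graph$edges
  from <- character(0); to <- character(0); w <- numeric(0)
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      ox <- if (e$side1[r] == "R") "+" else "-"
      oy <- if (e$side2[r] == "L") "+" else "-"
      flip <- function(o) if (o == "+") "-" else "+"
      from <- c(from, paste0(e$node1[r], ox), paste0(e$node2[r], flip(oy)))
      to <- c(to, paste0(e$node2[r], oy), paste0(e$node1[r], flip(ox)))
      w <- c(w, lens[[as.character(e$node2[r])]], lens[[as.character(e$node1[r])]])
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = TRUE, vertices = data.frame(name = verts))
  D <- igraph::distances(g, mode = "out", weights = igraph::E(g)$weight)
  D <- D[verts, verts, drop = FALSE]
  # C[u, ] = min over successors s of (w(u,s) + D[s, ]) -- exact for u == v
  C <- matrix(Inf, length(verts), length(verts),
              dimnames = list(verts, verts))
  el <- igraph::as_data_frame(g, what = "edges")
  for (u in verts) {
    sel <- el$from == u
    if (!any(sel)) next
    acc <- rep(Inf, length(verts))
    for (r in which(sel)) {
      acc <- pmin(acc, el$weight[r] + D[el$to[r], verts])
    }
    C[u, ] <- acc
  }
  list(D = D, C = C, lens = lens)
}

# exact position-to-position distance from the oracle matrices
oracle_position_dist <- function(om, a, b) {
  if (a$node == b$node && a$orient == b$orient && a$offset == b$offset) return(0)
  len_a <- om$lens[[as.character(a$node)]]
  len_b <- om$lens[[as.character(b$node)]]
  u <- paste0(a$node, ifelse(a$orient > 0L, "+", "-"))
  v <- paste0(b$node, ifelse(b$orient > 0L, "+", "-"))
  d <- (len_a - 1 - a$offset) + (om$C[u, v] - len_b) + b$offset
  if (a$node == b$node && a$orient == b$orient && b$offset > a$offset) {
    d <- min(d, b$offset - a$offset - 1)
  }
  max(d, 0)
}

# all positions of a graph (both orientations, every offset)
all_positions <- function(graph) {
  ids <- as.integer(names(graph$seqs))
  out <- list()
  for (nd in ids) {
    len <- nchar(graph$seqs[[as.character(nd)]])
    for (o in c(1L, -1L)) {
      out[[length(out) + 1L]] <- data.frame(node = nd, orient = o,
                                            offset = 0:(len - 1L))
    }
  }
  do.call(rbind, out)
}

# ---- separability oracle (plain R BFS on the biedged side graph) -------

side_adj <- function(graph) {
  ids <- sort(as.integer(names(graph$seqs)))
  idx <- setNames(seq_along(ids), ids)
  n <- length(ids)
  adj <- vector("list", 2L * n)
  add <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v)
    if (u != v) adj[[v]] <<- c(adj[[v]], u)
  }
  e <- graph$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      u <- 2L * idx[[as.character(e$node1[r])]] - 2L + (e$side1[r] == "R")
      v <- 2L * idx[[as.character(e$node2[r])]] - 2L + (e$side2[r] == "R")
      add(u + 1L, v + 1L)
    }
  }
  list(adj = adj, idx = idx, ids = ids, n = n)
}

# side index: 2*(i-1) + (side=="R") + 1
bfs_separable_oracle <- function(sa, a_node, a_side, b_node, b_side) {
  ia <- sa$idx[[as.character(a_node)]]; ib <- sa$idx[[as.character(b_node)]]
  a <- 2L * (ia - 1L) + (a_side == "R") + 1L
  b <- 2L * (ib - 1L) + (b_side == "R") + 1L
  opp_a <- 2L * (ia - 1L) + (a_side != "R") + 1L
  opp_b <- 2L * (ib - 1L) + (b_side != "R") + 1L
  seen <- logical(2L * sa$n)
  queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nbr <- sa$adj[[u]]
    un <- (u - 1L) %/% 2L + 1L
    if (un != ia && un != ib) {
      internal <- if (u %% 2L == 1L) u + 1L else u - 1L
      nbr <- c(nbr, internal)
    }
    for (v in nbr) {
      if (!seen[v]) {
        if (v == opp_a || v == opp_b) return(FALSE)
        seen[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  seen[b]
}

# interior node ids of a separable pair per the oracle BFS
oracle_interior <- function(graph, sa, a_node, a_side, b_node, b_side) {
  ia <- sa$idx[[as.character(a_node)]]; ib <- sa$idx[[as.character(b_node)]]
  a <- 2L * (ia - 1L) + (a_side == "R") + 1L
  seen <- logical(2L * sa$n)
  queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nbr <- sa$adj[[u]]
    un <- (u - 1L) %/% 2L + 1L
    if (un != ia && un != ib) {
      internal <- if (u %% 2L == 1L) u + 1L else u - 1L
      nbr <- c(nbr, internal)
    }
    for (v in nbr) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
  }
  touched <- unique((which(seen) - 1L) %/% 2L + 1L)
  setdiff(sa$ids[touched], c(a_node, b_node))
}

# ---- alignment oracle: full-matrix gap-affine global DP ----------------

oracle_affine_score <- function(q, t, sc) {
  n <- nchar(q); m <- nchar(t)
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  NEG <- -1e9
  oe <- sc$gap_open + sc$gap_extend
  ext <- sc$gap_extend
  M_prev <- c(0, -sc$gap_open - ext * seq_len(m))
  I_prev <- rep(NEG, m + 1L)
  for (i in seq_len(n)) {
    sub <- ifelse(qc[i] == tc & qc[i] %in% c("A", "C", "G", "T"),
                  sc$match, -sc$mismatch)
    I_cur <- pmax(M_prev - oe, I_prev - ext)
    diag <- c(NEG, M_prev[seq_len(m)] + sub)
    A <- pmax(diag, I_cur)
    A[1] <- max(A[1], -sc$gap_open - ext * i)
    M_cur <- numeric(m + 1L)
    M_cur[1] <- A[1]
    P <- M_cur[1]              # running max of M[j'] + j' * ext
    for (j in seq_len(m)) {
      M_cur[j + 1L] <- max(A[j + 1L], P - sc$gap_open - (j + 1L) * ext + ext)
      P <- max(P, M_cur[j + 1L] + j * ext)
    }
    M_prev <- M_cur
    I_prev <- I_cur
  }
  M_prev[m + 1L]
}

# ---- chaining oracle: exhaustive enumeration ---------------------------

# best chain score over all ordered anchor subsets; D = start-to-start
# graph distances (Inf = unreachable), items sorted by read start
oracle_best_chain <- function(rs, re, Dss, k, cp) {
  n <- length(rs)
  best <- -Inf
  score_chain <- function(sel) {
    s <- (re[sel[1]] - rs[sel[1]] + 1) * cp$match_bonus
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        i <- sel[t - 1]; j <- sel[t]
        if (rs[j] <= rs[i] || re[j] <= re[i]) return(-Inf)
        dg <- Dss[i, j]
        if (!is.finite(dg) || dg <= 0) return(-Inf)
        dr <- rs[j] - rs[i]
        if (rs[j] - re[i] - 1 > cp$max_read_gap) return(-Inf)
        if (dg - (re[i] - rs[i] + 1) > cp$max_graph_gap) return(-Inf)
        g <- abs(dr - dg)
        cost <- if (g == 0) 0 else cp$c_lin * k * g + cp$c_log * log2(g)
        cov <- re[j] - max(re[i], rs[j] - 1)
        s <- s + cov * cp$match_bonus - cost
      }
    }
    s
  }
  subsets <- function(prefix, rest) {
    if (length(prefix)) {
      sc <- score_chain(prefix)
      if (sc > best) best <<- sc
    }
    if (!length(rest)) return()
    for (t in seq_along(rest)) {
      subsets(c(prefix, rest[t]), rest[rest > rest[t]])
    }
  }
  subsets(integer(0), seq_len(n))
  best
}

# ---- random graph family ----------------------------------------------

# small random pangenome in the package's generator family; node count is
# kept low and node sequences short so all-pairs position checks stay cheap
rand_graph <- function(seed, backbone = 60L, snps = 0.05, with_cycles = TRUE) {
  for (s in seed + c(0L, 1000L, 2000L, 3000L)) {
    g <- tryCatch(simulate_graph(graph_sim_params(
      backbone_len = backbone, snp_rate = snps, indel_rate = 0.015,
      indel_len_max = 4L,
      n_inversions = if (with_cycles && seed %% 2L == 0L) 1L else 0L,
      inversion_len = 6L,
      n_duplications = if (with_cycles && seed %% 3L == 0L) 1L else 0L,
      duplication_len = 5L,
      n_haplotypes = 4L, seed = s)), generation_error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  stop("could not generate a random graph for seed ", seed)
}

# full oracle distance matrix over a position table
oracle_dist_matrix <- function(graph, pos) {
  om <- oracle_dist_mats(graph)
  n <- nrow(pos)
  O <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    pa <- graph_pos(pos$node[i], pos$orient[i], pos$offset[i])
    for (j in seq_len(n)) {
      O[i, j] <- oracle_position_dist(
        om, pa, graph_pos(pos$node[j], pos$orient[j], pos$offset[j]))
    }
  }
  O
}

# snarl records without the structural NULL holes (chain ids share the
# numbering), optionally excluding trivial snarls
real_snarls <- function(tree, include_trivial = TRUE) {
  Filter(function(s) !is.null(s) && (include_trivial || !s$trivial),
         tree$snarls)
}

# chaining trial data on root-chain nodes of a simulated graph, and the
# DP's address-difference distance provider
chain_trial_anchors <- function(g, idx, n_anchors, k = 5L, seed = 1L) {
  set.seed(seed)
  hindex <- panmap:::walk_only_index(g)
  w <- hindex$walks[[1]]
  wlen <- nchar(w$seq)
  co <- w$coords
  depth1 <- vapply(co$node, function(n) {
    nrow(idx$tree$ancestry[[as.character(n)]]) == 1L
  }, logical(1))
  usable <- which(depth1[seq_len(wlen - k + 1L)] &
                    depth1[pmin(seq_len(wlen - k + 1L) + k - 1L, wlen)])
  wc <- sort(sample(usable - 1L, min(n_anchors, length(usable))))
  read_off <- pmax(0L, wc + sample(-3:3, length(wc), replace = TRUE))
  pos <- lapply(wc, function(x) panmap:::wc_to_pos(hindex, 1L, x, 1L))
  data.frame(read_offset = as.integer(read_off),
             node = vapply(pos, `[[`, integer(1), "node"),
             orient = vapply(pos, `[[`, integer(1), "orient"),
             offset = vapply(pos, `[[`, integer(1), "offset"),
             k = k, walk = 1L, wpos = wc, dir = 1L)
}

anchor_addr_distances <- function(idx, anchors) {
  addr <- idx$coords$addr_fwd[panmap:::ov_label(anchors$node, anchors$orient)] +
    anchors$offset
  outer(addr, addr, function(a, b) b - a)
}

random_seq <- function(n) paste0(sample(c("A","C","G","T"), n, replace = TRUE),
                                 collapse = "")

mutate_seq <- function(t, rate) {
  bases <- c("A", "C", "G", "T")
  q <- strsplit(t, "")[[1]]
  n_ed <- rbinom(1L, nchar(t), rate)
  if (n_ed > 0) for (e in seq_len(n_ed)) {
    i <- sample(length(q), 1L)
    op <- sample(3L, 1L)
    if (op == 1L) q[i] <- sample(bases, 1L)
    else if (op == 2L && length(q) > 2L) q <- q[-i]
    else q <- append(q, sample(bases, 1L), after = i)
  }
  paste0(q, collapse = "")
}
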