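# Hierarchical minimum-distance index over the snarl tree.
#
# Every snarl-tree structure (chain, snarl, and a per-component root record)
# is contracted to a small directed graph over *oriented node* vertices:
# vertex "n+" means "just finished traversing node n forward". Edge weights
# include the length of the target node, so a shortest path u -> v equals
# the number of bases strictly after u up to and including v. Child
# structures contribute summary edges between their end vertices, so
# matrices are built bottom-up (leaf structures first) with Dijkstra on the
# contracted graphs. A query propagates "distance from position a to
# finished-vertex" vectors up both ancestor paths and combines them at each
# common structure.
#
# Distance convention: the number of bases strictly between two positions
# (0 for adjacent bases); Inf is the unreachable sentinel.

# Directed oriented edges induced by one adjacency edge row (both directions).
edge_to_oriented <- function(n1, s1, n2, s2, node_len) {
  ox <- ifelse(s1 == "R", 1L, -1L)   # exit through s1
  oy <- ifelse(s2 == "L", 1L, -1L)   # enter through s2
  data.frame(
    from = c(ov_label(n1, ox), ov_label(n2, -oy)),
    to = c(ov_label(n2, oy), ov_label(n1, -ox)),
    w = c(node_len[as.character(n2)], node_len[as.character(n1)]),
    stringsAsFactors = FALSE)
}

# Distance matrix over a small directed weighted graph, plus the shortest
# proper cycle through each vertex (the diagonal of M is 0 by convention,
# which hides cycles).
contracted_matrix <- function(verts, edf) {
  if (nrow(edf)) edf <- edf[is.finite(edf$w), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edf, directed = TRUE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  M <- igraph::distances(g, mode = "out", weights = igraph::E(g)$w,
                         algorithm = "dijkstra")
  M <- M[verts, verts, drop = FALSE]
  cyc <- setNames(rep(Inf, length(verts)), verts)
  if (nrow(edf)) {
    for (r in seq_len(nrow(edf))) {
      u <- edf$from[r]
      cyc[u] <- min(cyc[u], edf$w[r] + M[edf$to[r], u])
    }
  }
  list(M = M, cyc = cyc)
}

# All four oriented end labels of a chain.
chain_end_labels <- function(ch) {
  k <- length(ch$nodes)
  unique(c(ov_label(ch$nodes[1], ch$orients[1]),
           ov_label(ch$nodes[1], -ch$orients[1]),
           ov_label(ch$nodes[k], ch$orients[k]),
           ov_label(ch$nodes[k], -ch$orients[k])))
}

#' Build the minimum-distance index
#'
#' Bottom-up construction over the snarl tree: every chain and snarl stores
#' a matrix of minimum internal distances between the oriented ends of its
#' children (and its boundary nodes); one extra record per connected
#' component ties the root chains together.
#'
#' @param graph a `variation_graph`.
#' @param tree the [snarl_decompose()] result for `graph`.
#' @return A `distance_index` object.
#' @export
build_distance_index <- function(graph, tree) {
  if (!identical(sort(as.integer(names(graph$seqs))), tree$node_ids)) {
    pm_stop("index_mismatch", "snarl tree does not match graph")
  }
  node_len <- setNames(nchar(graph$seqs), names(graph$seqs))
  nstruct <- length(tree$kind)
  structs <- vector("list", nstruct)

  # bottom-up: children always have larger structure ids
  for (sid in rev(seq_len(nstruct))) {
    if (tree$kind[sid] == 1L) {  # chain
      ch <- tree$chains[[sid]]
      k <- length(ch$nodes)
      verts <- unique(as.vector(vapply(seq_len(k), function(t) {
        c(ov_label(ch$nodes[t], 1L), ov_label(ch$nodes[t], -1L))
      }, character(2))))
      edfs <- list()
      snl <- ch$snarl_ids
      for (t in seq_along(snl)) {
        sm <- structs[[snl[t]]]$M
        labs <- intersect(rownames(sm), verts)
        for (u in labs) {
          fin <- labs[is.finite(sm[u, labs]) & labs != u]
          if (length(fin)) {
            edfs[[length(edfs) + 1L]] <- data.frame(
              from = u, to = fin, w = sm[u, fin], stringsAsFactors = FALSE)
          }
        }
      }
      edf <- if (length(edfs)) do.call(rbind, edfs) else
        data.frame(from = character(0), to = character(0), w = numeric(0))
      cm <- contracted_matrix(verts, edf)
      structs[[sid]] <- list(kind = "chain", verts = verts, M = cm$M,
                             cyc = cm$cyc)
    } else {  # snarl
      sn <- tree$snarls[[sid]]
      nodes <- unique(c(sn$start$node, sn$end$node,
                        unlist(lapply(sn$child_chains, function(cc) {
                          ch <- tree$chains[[cc]]
                          c(ch$nodes[1], ch$nodes[length(ch$nodes)])
                        })),
                        sn$edges$node1, sn$edges$node2))
      verts <- unique(as.vector(rbind(ov_label(nodes, 1L), ov_label(nodes, -1L))))
      edfs <- list()
      if (nrow(sn$edges)) {
        for (r in seq_len(nrow(sn$edges))) {
          edfs[[length(edfs) + 1L]] <- edge_to_oriented(
            sn$edges$node1[r], sn$edges$side1[r],
            sn$edges$node2[r], sn$edges$side2[r], node_len)
        }
      }
      for (cc in sn$child_chains) {
        cm <- structs[[cc]]$M
        labs <- chain_end_labels(tree$chains[[cc]])
        for (u in labs) {
          fin <- labs[is.finite(cm[u, labs]) & labs != u]
          if (length(fin)) {
            edfs[[length(edfs) + 1L]] <- data.frame(
              from = u, to = fin, w = cm[u, fin], stringsAsFactors = FALSE)
          }
        }
      }
      edf <- if (length(edfs)) do.call(rbind, edfs) else
        data.frame(from = character(0), to = character(0), w = numeric(0))
      edf <- edf[edf$from %in% verts & edf$to %in% verts, , drop = FALSE]
      cm <- contracted_matrix(verts, edf)
      structs[[sid]] <- list(kind = "snarl", verts = verts, M = cm$M,
                             cyc = cm$cyc)
    }
  }

  # per-component record: root chain summaries + unassigned edges
  comp_of_chain <- integer(0)
  node_comp <- setNames(rep(NA_integer_, length(tree$node_ids)), tree$node_ids)
  comp_g <- igraph::graph_from_data_frame(
    d = if (nrow(graph$edges)) {
      data.frame(from = as.character(graph$edges$node1),
                 to = as.character(graph$edges$node2))
    } else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(tree$node_ids)))
  memb <- igraph::components(comp_g)$membership
  node_comp[names(memb)] <- as.integer(memb)
  comps <- sort(unique(node_comp))
  comp_structs <- vector("list", length(comps))
  lo <- tree$leftover_edges
  for (cp in comps) {
    cnodes <- as.integer(names(node_comp)[node_comp == cp])
    rchains <- tree$roots[vapply(tree$roots, function(cid) {
      tree$chains[[cid]]$nodes[1] %in% cnodes
    }, logical(1))]
    verts <- unique(unlist(lapply(rchains, function(cid) {
      chain_end_labels(tree$chains[[cid]])
    })))
    edfs <- list()
    if (!is.null(lo) && nrow(lo)) {
      sel <- lo$node1 %in% cnodes
      for (r in which(sel)) {
        edfs[[length(edfs) + 1L]] <- edge_to_oriented(
          lo$node1[r], lo$side1[r], lo$node2[r], lo$side2[r], node_len)
      }
    }
    if (length(edfs)) {
      extra <- unique(c(unlist(lapply(edfs, `[[`, "from")),
                        unlist(lapply(edfs, `[[`, "to"))))
      verts <- unique(c(verts, extra))
    }
    for (cid in rchains) {
      cm <- structs[[cid]]$M
      labs <- chain_end_labels(tree$chains[[cid]])
      for (u in labs) {
        fin <- labs[is.finite(cm[u, labs]) & labs != u]
        if (length(fin)) {
          edfs[[length(edfs) + 1L]] <- data.frame(
            from = u, to = fin, w = cm[u, fin], stringsAsFactors = FALSE)
        }
      }
    }
    edf <- if (length(edfs)) do.call(rbind, edfs) else
      data.frame(from = character(0), to = character(0), w = numeric(0))
    cm <- contracted_matrix(verts, edf)
    comp_structs[[cp]] <- list(kind = "component", verts = verts, M = cm$M,
                               cyc = cm$cyc)
  }

  # precompute per-structure vertex metadata for fast queries
  decorate <- function(st) {
    st$vnode <- vapply(st$verts, ov_node, integer(1))
    st$vlen <- as.numeric(node_len[as.character(st$vnode)])
    st$rev <- match(vapply(st$verts, ov_flip, character(1)), st$verts)
    st
  }
  structs <- lapply(structs, decorate)
  comp_structs <- lapply(comp_structs, decorate)

  # ancestor structure-id path per node: chain, snarl, chain, ..., root chain
  anc_path <- lapply(tree$node_ids, function(nd) {
    out <- integer(0)
    cid <- tree$node_chain[as.character(nd)]
    repeat {
      out <- c(out, cid)
      ps <- tree$chains[[cid]]$parent_snarl
      if (is.na(ps)) break
      out <- c(out, ps)
      cid <- tree$snarls[[ps]]$parent_chain
    }
    out
  })
  names(anc_path) <- tree$node_ids

  # per-node query plans: for each ancestor level, where the previous
  # level's vertices sit in this level's vertex vector
  qplan <- vector("list", length(tree$node_ids))
  names(qplan) <- tree$node_ids
  for (nd in tree$node_ids) {
    path <- anc_path[[as.character(nd)]]
    prev_verts <- c(ov_label(nd, 1L), ov_label(nd, -1L))
    levels <- vector("list", length(path) + 1L)
    for (i in seq_along(path)) {
      st <- structs[[path[i]]]
      m <- match(prev_verts, st$verts)
      sel <- which(!is.na(m))
      levels[[i]] <- list(id = as.character(path[i]), sid = path[i],
                          sp_prev = sel, sp_cur = m[sel])
      prev_verts <- st$verts
    }
    st <- comp_structs[[node_comp[[as.character(nd)]]]]
    m <- match(prev_verts, st$verts)
    sel <- which(!is.na(m))
    levels[[length(path) + 1L]] <- list(id = "comp", sid = NA_integer_,
                                        sp_prev = sel, sp_cur = m[sel])
    qplan[[as.character(nd)]] <- levels
  }

  structure(list(graph_nodes = tree$node_ids, node_len = node_len,
                 structs = structs, comp_structs = comp_structs,
                 node_comp = node_comp, anc_path = anc_path, qplan = qplan,
                 tree = tree),
            class = "distance_index")
}

check_pos <- function(index, pos) {
  len <- index$node_len[as.character(pos$node)]
  if (is.na(len)) pm_stop("bounds_error", "unknown node %d", pos$node)
  if (pos$offset < 0L || pos$offset >= len) {
    pm_stop("bounds_error", "offset %d out of range for node %d", pos$offset, pos$node)
  }
  invisible(len)
}

# Propagate a "bases after position x through finished vertex" vector up
# the ancestor path of x's node, using the precomputed query plan. Returns
# a list of numeric vectors, one per level, named by level id.
propagate_levels <- function(index, pos) {
  nd <- as.character(pos$node)
  len <- as.numeric(index$node_len[[nd]])
  plan <- index$qplan[[nd]]
  cp <- index$node_comp[[nd]]
  lv <- vector("list", length(plan))
  # order matches plan construction: (n,+), (n,-)
  dprev <- if (pos$orient > 0L) c(len - 1 - pos$offset, Inf) else
    c(Inf, len - 1 - pos$offset)
  for (i in seq_along(plan)) {
    pl <- plan[[i]]
    st <- if (is.na(pl$sid)) index$comp_structs[[cp]] else index$structs[[pl$sid]]
    nv <- length(st$verts)
    dnew <- rep(Inf, nv)
    sp <- pl$sp_prev; sc <- pl$sp_cur
    if (length(sp)) {
      dnew[sc] <- pmin(dnew[sc], dprev[sp])
      for (t in seq_along(sp)) {
        v <- dprev[sp[t]]
        if (is.finite(v)) dnew <- pmin(dnew, v + st$M[sc[t], ])
      }
    }
    lv[[i]] <- dnew
    dprev <- dnew
  }
  names(lv) <- vapply(plan, `[[`, character(1), "id")
  lv
}

#' Minimum graph distance between two positions
#'
#' The minimum number of bases strictly between position `a` (read in its
#' orientation) and position `b` over all walks; 0 when `b` is the next
#' base, `Inf` when unreachable, and 0 for identical positions.
#'
#' @param index a `distance_index`.
#' @param a,b `graph_pos` objects.
#' @return Numeric distance (possibly `Inf`).
#' @export
min_distance <- function(index, a, b) {
  check_pos(index, a)
  len_b <- as.numeric(check_pos(index, b))
  rb <- graph_pos(b$node, -b$orient, len_b - 1L - b$offset)
  combine_propagated(index, a, b,
                     propagate_levels(index, a),
                     propagate_levels(index, rb))
}

# combination step shared by min_distance and min_distance_matrix:
# la = propagated levels for a; lb = propagated levels for rev(b)
combine_propagated <- function(index, a, b, la, lb) {
  if (a$node == b$node && a$orient == b$orient && a$offset == b$offset) return(0)
  if (index$node_comp[[as.character(a$node)]] !=
      index$node_comp[[as.character(b$node)]]) return(Inf)
  len_a <- as.numeric(index$node_len[[as.character(a$node)]])
  best <- Inf
  same_node <- a$node == b$node
  if (same_node && a$orient == b$orient && b$offset > a$offset) {
    best <- b$offset - a$offset - 1
  }
  if (same_node) {
    # direct re-entry through a self-connecting edge on the boundary sides
    ex <- if (a$orient > 0L) "R" else "L"
    en <- if (b$orient > 0L) "L" else "R"
    if (any(has_edge_index(index, a$node, ex, b$node, en))) {
      best <- min(best, (len_a - 1 - a$offset) + b$offset)
    }
  }
  common <- intersect(names(la), names(lb))
  len_n <- len_a
  for (nm in common) {
    st <- if (nm == "comp") {
      index$comp_structs[[index$node_comp[[as.character(a$node)]]]]
    } else index$structs[[as.integer(nm)]]
    da <- la[[nm]]
    db <- lb[[nm]][st$rev]  # distance-to-b from start of each vertex
    cand <- da + db - st$vlen
    if (same_node) {
      cand[st$vnode == a$node] <- Inf
      # direct route from finishing (n, o_a) to re-entering (n, o_b)
      # through this structure (U-turns via adjacent snarls, cycles)
      u <- match(ov_label(a$node, a$orient), st$verts)
      v <- match(ov_label(b$node, b$orient), st$verts)
      if (!is.na(u) && !is.na(v)) {
        route <- if (u == v) st$cyc[u] else st$M[u, v]
        if (is.finite(route)) {
          cand2 <- (len_a - 1 - a$offset) + (route - len_n) + b$offset
          if (cand2 < best) best <- cand2
        }
      }
    }
    m <- suppressWarnings(min(cand, na.rm = TRUE))
    if (m < best) best <- m
  }
  max(best, 0)
}

#' All-pairs minimum distances between a set of positions
#'
#' Batched form of [min_distance()]: each position's level propagation is
#' computed once and reused across all ordered pairs.
#'
#' @param index a `distance_index`.
#' @param positions data frame with columns `node`, `orient`, `offset`.
#' @return Numeric matrix `D` with `D[i, j] = min_distance(pos_i, pos_j)`.
#' @export
min_distance_matrix <- function(index, positions) {
  n <- nrow(positions)
  pos <- lapply(seq_len(n), function(i) {
    graph_pos(positions$node[i], positions$orient[i], positions$offset[i])
  })
  for (p in pos) check_pos(index, p)
  la <- lapply(pos, function(p) propagate_levels(index, p))
  lb <- lapply(pos, function(p) {
    len <- as.numeric(index$node_len[[as.character(p$node)]])
    propagate_levels(index, graph_pos(p$node, -p$orient, len - 1L - p$offset))
  })
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- combine_propagated(index, pos[[i]], pos[[j]], la[[i]], lb[[j]])
    }
  }
  D
}

# edge lookup against the original graph edges retained in the tree
has_edge_index <- function(index, n1, s1, n2, s2) {
  e <- index$tree$all_edges
  if (is.null(e) || !nrow(e)) return(FALSE)
  swap <- n1 > n2 | (n1 == n2 & s1 > s2)
  a_n <- ifelse(swap, n2, n1); a_s <- ifelse(swap, s2, s1)
  b_n <- ifelse(swap, n1, n2); b_s <- ifelse(swap, s1, s2)
  any(e$node1 == a_n & e$side1 == a_s & e$node2 == b_n & e$side2 == b_s)
}
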