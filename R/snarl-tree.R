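# Snarl/chain decomposition of a bidirected variation graph.
#
# A snarl is a subgraph delimited by two boundary node sides that are
# *separable* (cutting both boundary nodes into their component sides
# disconnects the subgraph between them from the rest of the graph) and
# *minimal* (no side strictly inside is separable with either boundary).
# Chains are maximal runs of nodes with snarls between consecutive nodes;
# nesting of chains inside snarls yields the snarl tree.
#
# The decomposition here is definition-driven: all separable side pairs are
# enumerated by brute-force biedged reachability (C++ kernel), filtered to
# minimal pairs, and greedily nested under a canonical tie-break (smaller
# node ids first), which makes the result deterministic.

# Map node ids to contiguous 1..n indices; edge matrix for the C++ kernels.
graph_index <- function(graph) {
  ids <- sort(as.integer(names(graph$seqs)))
  idx <- seq_along(ids)
  names(idx) <- as.character(ids)
  list(ids = ids, idx = idx, n = length(ids))
}

edges_matrix <- function(graph, gi) {
  e <- graph$edges
  if (nrow(e) == 0L) return(matrix(integer(0), ncol = 4))
  cbind(gi$idx[as.character(e$node1)], ifelse(e$side1 == "L", 0L, 1L),
        gi$idx[as.character(e$node2)], ifelse(e$side2 == "L", 0L, 1L))
}

#' Test whether two node sides are separable
#'
#' Two sides on distinct nodes are separable if cutting their nodes into
#' component sides leaves the subgraph between the two sides disconnected
#' from the rest of the graph.
#'
#' @param graph a `variation_graph`.
#' @param a,b `node_side` objects on distinct nodes.
#' @return Logical.
#' @export
is_separable <- function(graph, a, b) {
  if (a$node == b$node) {
    pm_stop("invalid_pair", "boundary sides must be on distinct nodes")
  }
  gi <- graph_index(graph)
  em <- edges_matrix(graph, gi)
  is_separable_cpp(gi$n, em,
                   gi$idx[as.character(a$node)], ifelse(a$side == "L", 0L, 1L),
                   gi$idx[as.character(b$node)], ifelse(b$side == "L", 0L, 1L))
}

# Enumerate separable side pairs (node-id space) with interiors.
separable_pairs <- function(graph) {
  gi <- graph_index(graph)
  em <- edges_matrix(graph, gi)
  sp <- separable_pairs_cpp(gi$n, em)
  p <- sp$pairs
  if (nrow(p) == 0L) {
    return(list(pairs = p, interiors = list(), key = character(0),
                minimal = logical(0)))
  }
  # translate indices back to node ids
  p[, 1] <- gi$ids[p[, 1]]
  p[, 3] <- gi$ids[p[, 3]]
  interiors <- lapply(sp$interiors, function(v) gi$ids[v])
  key <- paste(p[, 1], p[, 2], p[, 3], p[, 4])
  list(pairs = p, interiors = interiors, key = key, minimal = sp$minimal)
}

pair_key <- function(n1, s1, n2, s2) {
  swap <- n1 > n2
  ifelse(swap, paste(n2, s2, n1, s1), paste(n1, s1, n2, s2))
}

#' Decompose a variation graph into nested snarls and chains
#'
#' @param graph a `variation_graph`.
#' @return A `snarl_tree` object: lists of chains and snarls, node-to-chain
#'   assignments, and per-node snarl-tree ancestry.
#' @export
snarl_decompose <- function(graph) {
  gi <- graph_index(graph)
  sp <- separable_pairs(graph)
  p <- sp$pairs

  # --- minimality filter (computed alongside the pair enumeration) -----
  minim <- which(sp$minimal)

  # --- greedy canonical nesting ----------------------------------------
  # Canonical tie-break among the (formally non-unique) decompositions:
  # prefer boundary pairs with the smaller node ids.
  if (length(minim)) {
    lo_n <- pmin(p[minim, 1], p[minim, 3])
    hi_n <- pmax(p[minim, 1], p[minim, 3])
    isz <- vapply(sp$interiors[minim], length, integer(1))
    ord <- minim[order(lo_n, hi_n, isz, p[minim, 2], p[minim, 4])]
  } else ord <- integer(0)

  acc <- list()        # accepted snarls: list(a_node, a_side, b_node, b_side, I)
  slot_used <- character(0)  # "node.side" boundary slots
  for (i in ord) {
    a_n <- p[i, 1]; a_s <- p[i, 2]; b_n <- p[i, 3]; b_s <- p[i, 4]
    I <- sp$interiors[[i]]
    sa <- paste0(a_n, ".", a_s); sb <- paste0(b_n, ".", b_s)
    if (sa %in% slot_used || sb %in% slot_used) next
    compatible <- TRUE
    for (s2 in acc) {
      I2 <- s2$I
      bnds <- c(a_n, b_n); bnds2 <- c(s2$a_node, s2$b_node)
      nested_in <- all(I %in% I2) && all(bnds %in% I2)
      contains <- all(I2 %in% I) && all(bnds2 %in% I)
      disjoint <- !any(I %in% I2) && !any(I2 %in% I) &&
        !any(bnds %in% I2) && !any(bnds2 %in% I)
      if (!(nested_in || contains || disjoint)) { compatible <- FALSE; break }
    }
    if (!compatible) next
    acc[[length(acc) + 1L]] <- list(a_node = a_n, a_side = a_s,
                                    b_node = b_n, b_side = b_s, I = I)
    slot_used <- c(slot_used, sa, sb)
  }

  build_snarl_tree(graph, gi, acc)
}

# Assemble chains/snarls/ancestry from the accepted snarl set.
build_snarl_tree <- function(graph, gi, acc) {
  ns <- length(acc)
  isz <- vapply(acc, function(s) length(s$I), integer(1))

  # parent snarl of each accepted snarl: smallest interior strictly containing
  # this snarl's interior and boundaries
  parent_acc <- rep(NA_integer_, ns)
  if (ns) {
    for (i in seq_len(ns)) {
      span_i <- c(acc[[i]]$I, acc[[i]]$a_node, acc[[i]]$b_node)
      cands <- which(vapply(seq_len(ns), function(j) {
        j != i && length(acc[[j]]$I) > length(acc[[i]]$I) &&
          all(span_i %in% acc[[j]]$I)
      }, logical(1)))
      if (length(cands)) parent_acc[i] <- cands[which.min(isz[cands])]
    }
  }

  # node-level connected components (for root chains)
  comp_g <- igraph::graph_from_data_frame(
    d = if (nrow(graph$edges)) {
      data.frame(from = as.character(graph$edges$node1),
                 to = as.character(graph$edges$node2))
    } else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(gi$ids)))
  comp <- igraph::components(comp_g)$membership
  comp <- setNames(as.integer(comp), names(comp))

  chains <- list(); snarls <- list()
  kind <- integer(0)  # per structure id: 1 = chain, 2 = snarl
  new_chain <- function() { length(kind) + 1L }

  # edge assignment: innermost accepted snarl covering both endpoints
  e <- graph$edges
  side_chr <- function(s) ifelse(s == 0L, "L", "R")
  covers <- function(sn, node, side) {
    node %in% sn$I ||
      (node == sn$a_node && side == side_chr(sn$a_side)) ||
      (node == sn$b_node && side == side_chr(sn$b_side))
  }
  edge_owner <- rep(NA_integer_, nrow(e))
  if (nrow(e) && ns) {
    for (k in seq_len(nrow(e))) {
      cand <- which(vapply(seq_len(ns), function(j) {
        covers(acc[[j]], e$node1[k], e$side1[k]) &&
          covers(acc[[j]], e$node2[k], e$side2[k])
      }, logical(1)))
      if (length(cand)) edge_owner[k] <- cand[which.min(isz[cand])]
    }
  }

  # scope nodes for each accepted snarl / each root component
  scope_nodes <- function(j) {
    inner <- acc[[j]]$I
    kids <- which(!is.na(parent_acc) & parent_acc == j)
    for (kk in kids) inner <- setdiff(inner, acc[[kk]]$I)
    inner
  }
  all_interiors <- unique(unlist(lapply(acc, `[[`, "I")))
  top <- which(is.na(parent_acc))
  top_interior <- unique(unlist(lapply(acc[top], `[[`, "I")))

  # build chains for one scope: returns list of chain descriptors
  # links: per snarl j in scope, connects (a_node via a_side) to (b_node via b_side)
  make_chains <- function(nodes, scope_snarls) {
    nodes <- sort(nodes)
    linkL <- setNames(rep(NA_integer_, length(nodes)), nodes)
    linkR <- linkL
    for (j in scope_snarls) {
      s <- acc[[j]]
      if (s$a_side == 0L) linkL[as.character(s$a_node)] <- j
      else linkR[as.character(s$a_node)] <- j
      if (s$b_side == 0L) linkL[as.character(s$b_node)] <- j
      else linkR[as.character(s$b_node)] <- j
    }
    visited <- setNames(rep(FALSE, length(nodes)), nodes)
    out <- list()
    # linear chains first: start at free-sided endpoints (canonical: smallest id)
    repeat {
      endpoints <- nodes[!visited[as.character(nodes)] &
                           (is.na(linkL[as.character(nodes)]) |
                              is.na(linkR[as.character(nodes)]))]
      if (!length(endpoints)) break
      start <- min(endpoints)
      # orientation: exit through the occupied side; forward if exiting right
      sL <- linkL[as.character(start)]; sR <- linkR[as.character(start)]
      if (is.na(sL) && is.na(sR)) {  # isolated node chain
        visited[as.character(start)] <- TRUE
        out[[length(out) + 1L]] <- list(nodes = start, orients = 1L,
                                        snarl_acc = integer(0), circular = FALSE)
        next
      }
      if (!is.na(sR)) { ori <- 1L; nxt <- sR } else { ori <- -1L; nxt <- sL }
      ch_nodes <- start; ch_ori <- ori; ch_sn <- integer(0)
      visited[as.character(start)] <- TRUE
      cur <- start
      while (!is.na(nxt)) {
        s <- acc[[nxt]]
        ch_sn <- c(ch_sn, nxt)
        other_n <- if (s$a_node == cur) s$b_node else s$a_node
        other_s <- if (s$a_node == cur) s$b_side else s$a_side
        # entered through side other_s: forward if entering left
        o2 <- if (other_s == 0L) 1L else -1L
        ch_nodes <- c(ch_nodes, other_n); ch_ori <- c(ch_ori, o2)
        visited[as.character(other_n)] <- TRUE
        cur <- other_n
        exit_s <- if (o2 > 0L) "R" else "L"
        nxt2 <- if (exit_s == "R") linkR[as.character(cur)] else linkL[as.character(cur)]
        if (!is.na(nxt2) && nxt2 == nxt) nxt2 <- NA_integer_  # same snarl back: stop
        nxt <- nxt2
      }
      # canonical orientation: smaller end-node id leftmost
      if (ch_nodes[length(ch_nodes)] < ch_nodes[1]) {
        ch_nodes <- rev(ch_nodes); ch_ori <- rev(-ch_ori); ch_sn <- rev(ch_sn)
      }
      out[[length(out) + 1L]] <- list(nodes = ch_nodes, orients = ch_ori,
                                      snarl_acc = ch_sn, circular = FALSE)
    }
    # circular chains / leftovers
    repeat {
      rest <- nodes[!visited[as.character(nodes)]]
      if (!length(rest)) break
      start <- min(rest)
      sR <- linkR[as.character(start)]
      ch_nodes <- start; ch_ori <- 1L; ch_sn <- integer(0)
      visited[as.character(start)] <- TRUE
      cur <- start; nxt <- sR
      while (!is.na(nxt)) {
        s <- acc[[nxt]]
        other_n <- if (s$a_node == cur) s$b_node else s$a_node
        other_s <- if (s$a_node == cur) s$b_side else s$a_side
        if (other_n == start) { ch_sn <- c(ch_sn, nxt); break }  # closed cycle
        ch_sn <- c(ch_sn, nxt)
        o2 <- if (other_s == 0L) 1L else -1L
        ch_nodes <- c(ch_nodes, other_n); ch_ori <- c(ch_ori, o2)
        visited[as.character(other_n)] <- TRUE
        cur <- other_n
        exit_s <- if (o2 > 0L) "R" else "L"
        nxt <- if (exit_s == "R") linkR[as.character(cur)] else linkL[as.character(cur)]
      }
      circ <- length(ch_sn) == length(ch_nodes)  # wraparound snarl present
      out[[length(out) + 1L]] <- list(nodes = ch_nodes, orients = ch_ori,
                                      snarl_acc = ch_sn, circular = circ)
    }
    out
  }

  # recursive materialization -------------------------------------------
  snarl_id_of_acc <- rep(NA_integer_, ns)
  node_chain <- setNames(rep(NA_integer_, gi$n), gi$ids)
  node_pos <- node_chain
  node_orient <- node_chain

  materialize_chain <- function(desc, parent_snarl, rank_in_parent) {
    cid <- length(kind) + 1L
    kind[[cid]] <<- 1L
    chains[[cid]] <<- list(id = cid, nodes = desc$nodes, orients = desc$orients,
                           snarl_ids = integer(0), circular = desc$circular,
                           parent_snarl = parent_snarl,
                           rank_in_parent = rank_in_parent)
    for (t in seq_along(desc$nodes)) {
      nd <- as.character(desc$nodes[t])
      node_chain[nd] <<- cid; node_pos[nd] <<- t
      node_orient[nd] <<- desc$orients[t]
    }
    sn_ids <- integer(0)
    for (t in seq_along(desc$snarl_acc)) {
      sn_ids <- c(sn_ids, materialize_snarl(desc$snarl_acc[t], cid, 2L * t))
    }
    chains[[cid]]$snarl_ids <<- sn_ids
    cid
  }

  materialize_snarl <- function(j, parent_chain, rank) {
    sid <- length(kind) + 1L
    kind[[sid]] <<- 2L
    s <- acc[[j]]
    snarl_id_of_acc[j] <<- sid
    snarls[[sid]] <<- list(
      id = sid,
      start = list(node = s$a_node, side = side_chr(s$a_side)),
      end = list(node = s$b_node, side = side_chr(s$b_side)),
      content = s$I, parent_chain = parent_chain, rank = rank,
      child_chains = integer(0), trivial = length(s$I) == 0L,
      edges = e[!is.na(edge_owner) & edge_owner == j, , drop = FALSE])
    kids <- which(!is.na(parent_acc) & parent_acc == j)
    sc <- scope_nodes(j)
    descs <- make_chains(sc, kids)
    cc <- integer(0)
    for (t in seq_along(descs)) {
      cc <- c(cc, materialize_chain(descs[[t]], sid, t))
    }
    snarls[[sid]]$child_chains <<- cc
    sid
  }

  roots <- integer(0)
  leftover_edges <- e[is.na(edge_owner), , drop = FALSE]
  for (cp in sort(unique(comp))) {
    cnodes <- as.integer(names(comp)[comp == cp])
    scope <- setdiff(cnodes, top_interior)
    scope_sn <- top[vapply(acc[top], function(s) s$a_node %in% scope, logical(1))]
    descs <- make_chains(scope, scope_sn)
    for (d in descs) roots <- c(roots, materialize_chain(d, NA_integer_, NA_integer_))
  }

  # ancestry per node: levels of (structure id, rank)
  ancestry <- vector("list", gi$n)
  names(ancestry) <- gi$ids
  chain_prefix <- function(cid) {
    ch <- chains[[cid]]
    if (is.na(ch$parent_snarl)) return(matrix(integer(0), ncol = 2))
    sn <- snarls[[ch$parent_snarl]]
    rbind(chain_prefix(sn$parent_chain),
          c(sn$parent_chain, sn$rank),
          c(ch$parent_snarl, ch$rank_in_parent))
  }
  # cache per chain
  pref_cache <- list()
  for (nd in gi$ids) {
    cid <- node_chain[as.character(nd)]
    key <- as.character(cid)
    if (is.null(pref_cache[[key]])) pref_cache[[key]] <- chain_prefix(cid)
    anc <- rbind(pref_cache[[key]],
                 c(cid, 2L * node_pos[as.character(nd)] - 1L))
    ancestry[[as.character(nd)]] <- anc
  }

  structure(list(chains = chains, snarls = snarls, kind = unlist(kind),
                 roots = roots, node_chain = node_chain, node_pos = node_pos,
                 node_orient = node_orient, ancestry = ancestry,
                 leftover_edges = leftover_edges, all_edges = e,
                 node_ids = gi$ids),
            class = "snarl_tree")
}

#' Leaf snarls of a snarl tree
#'
#' Snarls whose child chains are all single nodes (no nested snarls).
#'
#' @param tree a `snarl_tree`.
#' @return List of snarl records.
#' @export
leaf_snarls <- function(tree) {
  Filter(function(s) {
    !is.null(s) && all(vapply(s$child_chains, function(c) {
      length(tree$chains[[c]]$snarl_ids) == 0L
    }, logical(1)))
  }, tree$snarls)
}

#' Snarl tree as JSON
#'
#' Nested chain/snarl dump for debugging.
#' @param tree a `snarl_tree`.
#' @return JSON string.
#' @export
snarl_tree_json <- function(tree) {
  chain_obj <- function(cid) {
    ch <- tree$chains[[cid]]
    items <- list()
    for (t in seq_along(ch$nodes)) {
      items[[length(items) + 1L]] <- list(node = ch$nodes[t],
                                          orient = orient_chr(ch$orients[t]))
      if (t <= length(ch$snarl_ids)) {
        items[[length(items) + 1L]] <- snarl_obj(ch$snarl_ids[t])
      }
    }
    list(type = "chain", circular = ch$circular, items = items)
  }
  snarl_obj <- function(sid) {
    s <- tree$snarls[[sid]]
    list(type = "snarl",
         start = paste0(s$start$node, s$start$side),
         end = paste0(s$end$node, s$end$side),
         children = lapply(s$child_chains, chain_obj))
  }
  jsonlite::toJSON(lapply(tree$roots, chain_obj), auto_unbox = TRUE, pretty = TRUE)
}

#' @export
print.snarl_tree <- function(x, ...) {
  cat(sprintf("snarl tree: %d chains, %d snarls, %d root chain(s)\n",
              sum(x$kind == 1L), sum(x$kind == 2L), length(x$roots)))
  invisible(x)
}
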