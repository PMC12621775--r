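# Two-pass co-linear chaining over seeds.
#
# Anchors (exact k-mer matches) are chained by dynamic programming that
# maximizes newly covered read bases minus a Minimap2-style gap cost on the
# difference between read distance and graph distance. Graph distances come
# from zip-code-derived linear coordinates: every oriented node carries a
# prefix address relative to its component's root chain (computed once from
# the distance index), so the distance between co-linear anchors is an
# address difference; anchors on parallel snarl alleles are recognized from
# their snarl-tree ancestry and cannot be linked (unless the snarl is
# tangled, i.e. its children are mutually reachable through cycles).
# Pass 1 links anchors under tight gap limits into fragments; pass 2 links
# fragments under looser limits into chains; a final stitching step joins
# chains across graph cycles using exact distance-index queries.

#' Chaining parameters
#'
#' @param match_bonus score per newly covered read base.
#' @param c_lin,c_log gap cost coefficients: `c_lin*k*g + c_log*log2(g)`.
#' @param frag_max_read_gap,frag_max_graph_gap pass-1 (fragment) gap limits.
#' @param max_read_gap,max_graph_gap pass-2 (chain) gap limits.
#' @param lookback maximum predecessors scanned per item in the DP.
#' @param n_chains number of chains carried forward.
#' @return A `chaining_params` list.
#' @export
chaining_params <- function(match_bonus = 1, c_lin = 0.01, c_log = 0.5,
                            frag_max_read_gap = 60, frag_max_graph_gap = 60,
                            max_read_gap = 10000, max_graph_gap = 10000,
                            lookback = 500L, n_chains = 4L) {
  stopifnot(match_bonus >= 0, c_lin >= 0, c_log >= 0,
            frag_max_read_gap >= 0, frag_max_graph_gap >= 0,
            max_read_gap >= 0, max_graph_gap >= 0, lookback >= 1, n_chains >= 1)
  structure(as.list(environment()), class = "chaining_params")
}

#' Minimap2-style gap cost
#'
#' With `g = |read_gap - graph_gap|`: 0 when `g == 0`, otherwise
#' `c_lin * k * g + c_log * log2(g)`. An infinite graph gap forbids the
#' link (infinite cost).
#'
#' @param read_gap read-distance between seeds (bases).
#' @param graph_gap graph-distance between seeds (bases; may be `Inf`).
#' @param k seed length (scales the linear term).
#' @param params a [chaining_params()] list.
#' @return Numeric cost (possibly `Inf`).
#' @export
gap_cost <- function(read_gap, graph_gap, k, params = chaining_params()) {
  if (!is.finite(graph_gap)) return(Inf)
  g <- abs(read_gap - graph_gap)
  if (g == 0) return(0)
  params$c_lin * k * g + params$c_log * log2(g)
}

# Per-graph chaining caches: oriented-node prefix addresses for the forward
# and reverse frames, ancestry matrices, and structure kind/tangled flags.
index_coords <- function(index) {
  tree <- index$tree
  nodes <- tree$node_ids
  # ancestry matrix, padded
  depth <- max(vapply(tree$ancestry, nrow, integer(1)))
  anc <- matrix(-1L, nrow = length(nodes), ncol = 2L * depth,
                dimnames = list(as.character(nodes), NULL))
  for (i in seq_along(nodes)) {
    a <- tree$ancestry[[as.character(nodes[i])]]
    for (r in seq_len(nrow(a))) {
      anc[i, 2L * r - 1L] <- a[r, 1L]
      anc[i, 2L * r] <- a[r, 2L]
    }
  }
  kind <- tree$kind
  tangled <- logical(length(kind))
  for (sid in which(kind == 2L)) {
    sn <- tree$snarls[[sid]]
    if (length(sn$child_chains) < 2L) next
    st <- index$structs[[sid]]
    labsets <- lapply(sn$child_chains, function(cc) {
      intersect(chain_end_labels(tree$chains[[cc]]), st$verts)
    })
    tg <- FALSE
    for (i in seq_along(labsets)) {
      for (j in seq_along(labsets)) {
        if (i == j) next
        if (any(is.finite(st$M[labsets[[i]], labsets[[j]], drop = FALSE]))) {
          tg <- TRUE
          break
        }
      }
      if (tg) break
    }
    tangled[sid] <- tg
  }
  # frame sources: per component, the two ends of its first root chain
  addr_fwd <- numeric(0); addr_rev <- numeric(0)
  node_len <- index$node_len
  for (cp in sort(unique(index$node_comp))) {
    cnodes <- nodes[index$node_comp[as.character(nodes)] == cp]
    rchains <- tree$roots[vapply(tree$roots, function(cid) {
      tree$chains[[cid]]$nodes[1] %in% cnodes
    }, logical(1))]
    ch <- tree$chains[[rchains[1]]]
    kk <- length(ch$nodes)
    src_f <- graph_pos(ch$nodes[1], ch$orients[1], 0L)
    src_r <- graph_pos(ch$nodes[kk], -ch$orients[kk], 0L)
    lab_f <- ov_label(src_f$node, src_f$orient)
    lab_r <- ov_label(src_r$node, src_r$orient)
    for (nd in cnodes) {
      for (o in c(1L, -1L)) {
        lab <- ov_label(nd, o)
        p <- graph_pos(nd, o, 0L)
        addr_fwd[lab] <- if (lab == lab_f) 0 else min_distance(index, src_f, p) + 1
        addr_rev[lab] <- if (lab == lab_r) 0 else min_distance(index, src_r, p) + 1
      }
    }
  }
  list(anc = anc, kind = kind, tangled = tangled,
       addr_fwd = addr_fwd, addr_rev = addr_rev, depth = depth)
}

# anchor metadata in one frame: rs/re (1-based read span), ga_s/ga_e
anchor_meta <- function(anchors, co, frame = c("fwd", "rev")) {
  frame <- match.arg(frame)
  addr <- if (frame == "fwd") co$addr_fwd else co$addr_rev
  ga_s <- addr[ov_label(anchors$node, anchors$orient)] + anchors$offset
  ga_e <- ga_s + anchors$k - 1
  list(rs = anchors$read_offset + 1L,
       re = anchors$read_offset + anchors$k,
       ga_s = as.numeric(ga_s), ga_e = as.numeric(ga_e))
}

# traceback of chain_dp results into disjoint item chains, best first
dp_traceback <- function(dp, prev, max_chains = Inf) {
  n <- length(dp)
  used <- logical(n)
  out <- list()
  ord <- order(-dp)
  for (j in ord) {
    if (used[j]) next
    chain <- integer(0)
    cur <- j
    ok <- TRUE
    while (cur != 0L) {
      if (used[cur]) { ok <- FALSE; break }  # merges into a consumed chain
      chain <- c(cur, chain)
      cur <- prev[cur]
    }
    if (!ok) next
    used[chain] <- TRUE
    out[[length(out) + 1L]] <- list(items = chain, score = dp[j])
    if (length(out) >= max_chains) break
  }
  out
}

#' Chain anchors through the zip code tree
#'
#' Two DP passes (fragments under tight gap limits, then chains of
#' fragments under loose limits), followed by cycle-aware stitching of
#' chains whose link is invisible to the linear coordinates but finite in
#' the graph (loops traversed repeatedly).
#'
#' @param anchors data frame of seeds (from [select_seeds()]), with a `k`
#'   column.
#' @param tree a `zip_code_tree` over these anchors (carries the distance
#'   index).
#' @param params a [chaining_params()] list.
#' @return List of chains, each `list(anchors = row indices into `anchors`,
#'   score, frame)`, sorted by decreasing score.
#' @export
chain_anchors <- function(anchors, tree, params = chaining_params()) {
  if (nrow(anchors) == 0L) return(list())
  index <- tree$index
  co <- index$coords
  if (is.null(co)) co <- index_coords(index)
  anc_all <- co$anc[as.character(anchors$node), , drop = FALSE]

  all_chains <- list()
  for (frame in c("fwd", "rev")) {
    am <- anchor_meta(anchors, co, frame)
    ok <- is.finite(am$ga_s)
    if (!any(ok)) next
    idx <- which(ok)
    o <- idx[order(am$rs[idx], am$ga_s[idx], anchors$node[idx])]
    rs <- am$rs[o]; re <- am$re[o]
    ga_s <- am$ga_s[o]; ga_e <- am$ga_e[o]
    anc <- anc_all[o, , drop = FALSE]
    iscore <- as.numeric(anchors$k[o]) * params$match_bonus
    kmed <- as.integer(round(median(anchors$k)))

    # pass 1: fragments
    p1 <- chain_dp_cpp(rs, re, ga_s, ga_e, anc, anc, co$kind, co$tangled,
                       iscore, params$match_bonus, params$c_lin, params$c_log,
                       kmed, params$frag_max_read_gap,
                       params$frag_max_graph_gap, params$lookback)
    frags <- dp_traceback(p1$dp, p1$prev)
    if (!length(frags)) next
    # pass 2: chains of fragments
    f_first <- vapply(frags, function(f) f$items[1], integer(1))
    f_last <- vapply(frags, function(f) f$items[length(f$items)], integer(1))
    f_rs <- rs[f_first]; f_re <- re[f_last]
    f_gs <- ga_s[f_first]; f_ge <- ga_e[f_last]
    f_anc_s <- anc[f_first, , drop = FALSE]
    f_anc_e <- anc[f_last, , drop = FALSE]
    f_score <- vapply(frags, `[[`, numeric(1), "score")
    fo <- order(f_rs, f_gs)
    p2 <- chain_dp_cpp(f_rs[fo], f_re[fo], f_gs[fo], f_ge[fo],
                       f_anc_s[fo, , drop = FALSE], f_anc_e[fo, , drop = FALSE],
                       co$kind, co$tangled, f_score[fo],
                       params$match_bonus, params$c_lin, params$c_log,
                       kmed, params$max_read_gap, params$max_graph_gap,
                       params$lookback)
    chains2 <- dp_traceback(p2$dp, p2$prev, max_chains = 4L * params$n_chains)
    for (chn in chains2) {
      aidx <- unlist(lapply(chn$items, function(t) frags[[fo[t]]]$items))
      all_chains[[length(all_chains) + 1L]] <-
        list(anchors = o[aidx], score = chn$score, frame = frame)
    }
  }
  if (!length(all_chains)) return(list())

  # drop duplicate chains found in both frames (same anchor sets)
  keys <- vapply(all_chains, function(c) paste(c$anchors, collapse = ","),
                 character(1))
  all_chains <- all_chains[!duplicated(keys)]
  all_chains <- all_chains[order(-vapply(all_chains, `[[`, numeric(1), "score"),
                                 vapply(all_chains, function(c) min(anchors$read_offset[c$anchors]), numeric(1)))]

  all_chains <- stitch_loop_chains(anchors, all_chains, index, params)
  # drop chains fully contained in a better chain's read span
  spans <- lapply(all_chains, function(c) {
    range(anchors$read_offset[c$anchors])
  })
  keep <- rep(TRUE, length(all_chains))
  for (i in seq_along(all_chains)) {
    if (!keep[i]) next
    for (j in seq_along(all_chains)) {
      if (i == j || !keep[j]) next
      if (spans[[j]][1] >= spans[[i]][1] && spans[[j]][2] <= spans[[i]][2] &&
          all_chains[[j]]$score <= all_chains[[i]]$score &&
          length(intersect(all_chains[[j]]$anchors, all_chains[[i]]$anchors)) > 0) {
        keep[j] <- FALSE
      }
    }
  }
  all_chains <- all_chains[keep]
  head(all_chains, params$n_chains)
}

# Join chains across cycles: linear addresses cannot see a link that goes
# backwards through a loop, so verify candidate joins with exact distance
# queries and merge when the gap is sound.
stitch_loop_chains <- function(anchors, chains, index, params) {
  if (length(chains) < 2L) return(chains)
  changed <- TRUE
  while (changed && length(chains) > 1L) {
    changed <- FALSE
    ord <- order(vapply(chains, function(c) min(anchors$read_offset[c$anchors]),
                        numeric(1)))
    chains <- chains[ord]
    for (i in seq_len(length(chains) - 1L)) {
      A <- chains[[i]]
      a_last <- A$anchors[length(A$anchors)]
      a_re <- anchors$read_offset[a_last] + anchors$k[a_last]
      for (j in seq_along(chains)) {
        if (i == j) next
        B <- chains[[j]]
        b_first <- B$anchors[1]
        read_gap <- anchors$read_offset[b_first] - a_re
        if (read_gap < -anchors$k[b_first] || read_gap > params$max_read_gap) next
        if (anchors$read_offset[b_first] <= anchors$read_offset[a_last]) next
        pa <- graph_pos(anchors$node[a_last], anchors$orient[a_last],
                        anchors$offset[a_last])
        pb <- graph_pos(anchors$node[b_first], anchors$orient[b_first],
                        anchors$offset[b_first])
        d <- min_distance(index, pa, pb)
        if (!is.finite(d) || d > params$max_graph_gap) next
        graph_gap <- d + 1 - anchors$k[a_last]  # start-to-start minus span
        g <- abs(read_gap - graph_gap)
        cost <- if (g == 0) 0 else
          params$c_lin * anchors$k[a_last] * g + params$c_log * log2(max(g, 1))
        overlap <- max(0, a_re - anchors$read_offset[b_first])
        merged <- A$score + B$score - cost - params$match_bonus * overlap
        if (merged <= max(A$score, B$score)) next
        chains[[i]] <- list(anchors = c(A$anchors, B$anchors),
                            score = merged, frame = A$frame)
        chains[[j]] <- NULL
        changed <- TRUE
        break
      }
      if (changed) break
    }
  }
  chains[order(-vapply(chains, `[[`, numeric(1), "score"))]
}
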