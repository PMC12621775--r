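# Zip codes and the zip code tree.
#
# A zip code records a position's placement on the snarl tree (the ancestor
# list from the root chain down to the node, with the rank of each item in
# its parent and chain prefix offsets), so that seeds can be sorted and
# given graph distances without touching the graph. The zip code tree is
# the ordered sequence of seeds and the snarl/chain boundaries that contain
# them, in snarl-tree pre/post-order, with minimum-distance edge labels
# taken from the distance index. Distances between seeds are exact here,
# cycles included: the tree's order provides the partial order for
# chaining, and the labels come from the hierarchical index.

#' Compute the zip code of a position
#'
#' @param index a `distance_index`.
#' @param pos a `graph_pos`.
#' @return A `zipcode` object: list of records from the root chain down to
#'   the node, each with the structure id, kind, rank within its parent, a
#'   chain prefix offset where applicable, and the item length.
#' @export
compute_zipcode <- function(index, pos) {
  check_pos(index, pos)
  tree <- index$tree
  anc <- tree$ancestry[[as.character(pos$node)]]
  if (is.null(anc)) pm_stop("consistency_error", "node %d not indexed", pos$node)
  recs <- list()
  # ancestry rows are (structure id, rank) from root chain down; the final
  # row addresses the node within its chain
  for (r in seq_len(nrow(anc))) {
    sid <- anc[r, 1]; rank <- anc[r, 2]
    kind <- if (tree$kind[sid] == 1L) "chain" else "snarl"
    rec <- list(structure = sid, kind = kind, rank = rank)
    if (kind == "chain" && r == nrow(anc)) {
      # chain prefix offset of the node item: min bases from the chain's
      # left end up to (excluding) this node, by forward traversal
      ch <- tree$chains[[sid]]
      t <- (rank + 1L) %/% 2L
      st <- index$structs[[sid]]
      lab1 <- ov_label(ch$nodes[1], ch$orients[1])
      labt <- ov_label(ch$nodes[t], ch$orients[t])
      pre <- if (t == 1L) 0 else {
        v <- st$M[lab1, labt]
        if (is.finite(v)) v - index$node_len[[as.character(ch$nodes[t])]] +
          index$node_len[[as.character(ch$nodes[1])]] else Inf
      }
      rec$prefix <- pre
    }
    recs[[r]] <- rec
  }
  recs[[length(recs) + 1L]] <- list(
    structure = NA_integer_, kind = "node", rank = NA_integer_,
    node = pos$node, orient = pos$orient, offset = pos$offset,
    length = as.integer(index$node_len[[as.character(pos$node)]]))
  structure(list(records = recs, pos = pos), class = "zipcode")
}

#' Totally ordered sort key for a zip code
#'
#' Sorting seeds by this key groups them by shared snarl-tree ancestry and
#' orders them along chains; no graph access is needed once zip codes are
#' computed.
#'
#' @param zip a `zipcode`.
#' @return A character key; lexicographic order is the zip order.
#' @export
zip_sort_key <- function(zip) {
  parts <- character(0)
  for (rec in zip$records) {
    if (rec$kind == "node") {
      o <- if (rec$orient > 0L) rec$offset else rec$length - 1L - rec$offset
      parts <- c(parts, sprintf("%09d", o),
                 if (rec$orient > 0L) "f" else "r")
    } else {
      parts <- c(parts, sprintf("%06d", rec$rank))
    }
  }
  paste(parts, collapse = "/")
}

# internal: ancestry key pieces for a node (structure ids root-first)
node_struct_path <- function(index, node) {
  rev(index$anc_path[[as.character(node)]])
}

#' Build the zip code tree (forest) for a set of seeds
#'
#' One tree per connected component that contains seeds; each tree lists
#' chain/snarl boundary items for every structure holding at least one seed,
#' with seeds in zip-code order, and labels adjacent items with minimum
#' graph distances from the distance index.
#'
#' @param seeds data frame with columns `node`, `orient`, `offset`,
#'   `read_offset` (one row per seed).
#' @param index a `distance_index`.
#' @param labels compute edge distance labels (`TRUE` for the full tree;
#'   `FALSE` skips label computation when only order is needed).
#' @param items build the explicit boundary-item sequence (`FALSE` returns
#'   a lightweight forest handle whose order and distances are consumed
#'   through the cached zip-code coordinates, as the mapper does).
#' @return A `zip_code_tree` object.
#' @export
build_zip_tree <- function(seeds, index, labels = TRUE, items = TRUE) {
  n <- nrow(seeds)
  if (n == 0L) {
    return(structure(list(items = list(), seeds = seeds), class = "zip_code_tree"))
  }
  if (!items) {
    return(structure(list(items = NULL, seeds = seeds, index = index),
                     class = "zip_code_tree"))
  }
  keys <- character(n)
  for (i in seq_len(n)) {
    keys[i] <- zip_sort_key(compute_zipcode(
      index, graph_pos(seeds$node[i], seeds$orient[i], seeds$offset[i])))
  }
  comp <- index$node_comp[as.character(seeds$node)]
  ord <- order(comp, keys, seeds$read_offset)

  items <- list()
  emit <- function(type, structure = NA_integer_, seed = NA_integer_) {
    items[[length(items) + 1L]] <<- list(type = type, structure = structure,
                                         seed = seed)
  }
  open <- integer(0)  # stack of open structure ids (root-first path)
  prev_comp <- NA_integer_
  for (i in ord) {
    path <- node_struct_path(index, seeds$node[i])
    if (!identical(prev_comp, comp[[i]])) {
      while (length(open)) {
        sid <- open[length(open)]
        emit(if (index$tree$kind[sid] == 1L) "chain_end" else "snarl_end", sid)
        open <- open[-length(open)]
      }
      prev_comp <- comp[[i]]
    }
    keep <- 0L
    while (keep < min(length(open), length(path)) &&
           open[keep + 1L] == path[keep + 1L]) keep <- keep + 1L
    while (length(open) > keep) {
      sid <- open[length(open)]
      emit(if (index$tree$kind[sid] == 1L) "chain_end" else "snarl_end", sid)
      open <- open[-length(open)]
    }
    if (keep < length(path)) {
      for (sid in path[(keep + 1L):length(path)]) {
        emit(if (index$tree$kind[sid] == 1L) "chain_start" else "snarl_start", sid)
        open <- c(open, sid)
      }
    }
    emit("seed", seed = i)
  }
  while (length(open)) {
    sid <- open[length(open)]
    emit(if (index$tree$kind[sid] == 1L) "chain_end" else "snarl_end", sid)
    open <- open[-length(open)]
  }

  tree <- structure(list(items = items, seeds = seeds, index = index),
                    class = "zip_code_tree")
  if (labels) tree$dists <- zip_tree_edge_labels(tree)
  tree
}

# representative position of a tree item, for edge labels
item_position <- function(tree, item) {
  idx <- tree$index
  if (item$type == "seed") {
    s <- tree$seeds[item$seed, ]
    return(graph_pos(s$node, s$orient, s$offset))
  }
  sid <- item$structure
  if (idx$tree$kind[sid] == 1L) {
    ch <- idx$tree$chains[[sid]]
    k <- length(ch$nodes)
    if (grepl("start", item$type)) {
      graph_pos(ch$nodes[1], ch$orients[1], 0L)
    } else {
      graph_pos(ch$nodes[k], ch$orients[k],
                as.integer(idx$node_len[[as.character(ch$nodes[k])]]) - 1L)
    }
  } else {
    sn <- idx$tree$snarls[[sid]]
    if (grepl("start", item$type)) {
      o <- if (sn$start$side == "R") 1L else -1L
      graph_pos(sn$start$node, o,
                as.integer(idx$node_len[[as.character(sn$start$node)]]) - 1L)
    } else {
      o <- if (sn$end$side == "L") 1L else -1L
      graph_pos(sn$end$node, o, 0L)
    }
  }
}

# minimum distances between consecutive tree items
zip_tree_edge_labels <- function(tree) {
  items <- tree$items
  if (length(items) < 2L) return(numeric(0))
  out <- numeric(length(items) - 1L)
  for (i in seq_len(length(items) - 1L)) {
    p1 <- item_position(tree, items[[i]])
    p2 <- item_position(tree, items[[i + 1L]])
    out[i] <- min_distance(tree$index, p1, p2)
  }
  out
}

#' Distances from earlier seeds to one seed through the zip code tree
#'
#' Yields the seeds preceding `from_seed` in tree order together with their
#' minimum graph distance (seed start to seed start, bases strictly
#' between), skipping unreachable pairs, ordered by non-decreasing
#' distance. A lookback cap and a distance cap bound the scan.
#'
#' @param tree a `zip_code_tree`.
#' @param from_seed row index of the target seed in `tree$seeds`.
#' @param lookback maximum number of predecessor seeds scanned.
#' @param max_dist drop pairs farther than this.
#' @return data frame with columns `seed`, `distance`.
#' @export
tree_distances <- function(tree, from_seed, lookback = 500L, max_dist = Inf) {
  idx_of_seed <- which(vapply(tree$items, function(it) {
    identical(it$seed, as.integer(from_seed)) ||
      (!is.na(it$seed) && it$seed == from_seed)
  }, logical(1)))
  if (!length(idx_of_seed)) {
    pm_stop("consistency_error", "seed %d not in tree", from_seed)
  }
  s2 <- tree$seeds[from_seed, ]
  p2 <- graph_pos(s2$node, s2$orient, s2$offset)
  res_seed <- integer(0); res_d <- numeric(0)
  count <- 0L
  for (i in rev(seq_len(idx_of_seed - 1L))) {
    it <- tree$items[[i]]
    if (it$type != "seed") next
    count <- count + 1L
    if (count > lookback) break
    s1 <- tree$seeds[it$seed, ]
    d <- min_distance(tree$index, graph_pos(s1$node, s1$orient, s1$offset), p2)
    if (is.finite(d) && d <= max_dist) {
      res_seed <- c(res_seed, it$seed)
      res_d <- c(res_d, d)
    }
  }
  o <- order(res_d, res_seed)
  data.frame(seed = res_seed[o], distance = res_d[o])
}

#' @export
print.zip_code_tree <- function(x, ...) {
  depth <- 0L
  for (it in x$items) {
    if (grepl("_end$", it$type)) depth <- depth - 1L
    pad <- strrep("  ", depth)
    if (it$type == "seed") {
      s <- x$seeds[it$seed, ]
      cat(sprintf("%sseed %d (%d,%s,%d) read@%d\n", pad, it$seed, s$node,
                  orient_chr(s$orient), s$offset, s$read_offset))
    } else {
      cat(sprintf("%s%s %d\n", pad, it$type, it$structure))
    }
    if (grepl("_start$", it$type)) depth <- depth + 1L
  }
  invisible(x)
}
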