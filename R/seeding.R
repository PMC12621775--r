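# Weighted minimizer seeding over haplotype walk sequences.
#
# The index stores (w,k)-minimizers of every embedded walk, keyed by a
# canonical (strand-folded) 64-bit hash, with each occurrence recorded as a
# walk coordinate so seeds can later be projected to graph positions and
# followed along haplotypes during extension. Seed selection weights
# minimizers by 1/(1+count)^e so rare minimizers are used first, skips
# minimizers above a hard occurrence cap, and stops once the selected
# minimizers cover a configured fraction of the total minimizer weight.

#' Seeding parameters
#'
#' @param k k-mer length (must be <= 31).
#' @param w minimizer window (number of consecutive k-mers).
#' @param hard_hit_cap minimizers with more graph occurrences are skipped.
#' @param weight_downweight exponent in the 1/(1+count)^e minimizer weight.
#' @param score_fraction stop once selected minimizers reach this fraction
#'   of total minimizer weight.
#' @return A `seeding_params` list.
#' @export
seeding_params <- function(k = 29L, w = 11L, hard_hit_cap = 500L,
                           weight_downweight = 0.8, score_fraction = 0.9) {
  if (k > 31L) pm_stop("parameter_error", "k must be <= 31")
  stopifnot(k >= 1, w >= 1, hard_hit_cap >= 1, weight_downweight >= 0,
            score_fraction > 0, score_fraction <= 1)
  structure(list(k = as.integer(k), w = as.integer(w),
                 hard_hit_cap = as.integer(hard_hit_cap),
                 weight_downweight = weight_downweight,
                 score_fraction = score_fraction),
            class = "seeding_params")
}

# Per-walk base-level coordinate arrays: for every base of the walk
# sequence, the graph node, orientation, and oriented-node offset.
walk_coords <- function(graph, walk) {
  lens <- as.integer(nchar(graph$seqs[as.character(walk$nodes)]))
  starts <- cumsum(c(0L, lens[-length(lens)]))
  node <- rep(walk$nodes, lens)
  orient <- rep(walk$orients, lens)
  off <- unlist(lapply(lens, function(l) 0:(l - 1L)), use.names = FALSE)
  list(node = node, orient = orient, off = off, starts = starts, lens = lens)
}

#' Build a minimizer index over a graph's walks
#'
#' @param graph a `variation_graph` with at least one haplotype walk.
#' @param params a [seeding_params()] list.
#' @return A `minimizer_index`.
#' @export
build_minimizer_index <- function(graph, params = seeding_params()) {
  walks <- graph$walks
  if (!any(vapply(walks, function(w) w$role == "haplotype", logical(1)))) {
    pm_stop("parameter_error", "graph has no haplotype walks to index")
  }
  winfo <- vector("list", length(walks))
  occ_list <- vector("list", length(walks))
  for (wi in seq_along(walks)) {
    wseq <- walk_sequence(graph, walks[[wi]])
    co <- walk_coords(graph, walks[[wi]])
    mm <- minimizers_cpp(wseq, params$k, params$w)
    winfo[[wi]] <- c(walks[[wi]], list(seq = wseq, coords = co))
    if (length(mm$pos)) {
      ws <- mm$pos - 1L  # 0-based start on walk
      # canonical k-mer graph start (for dedupe across walks): forward
      # strand starts at ws, reverse strand starts at flipped ws + k - 1
      j <- ifelse(mm$strand > 0L, ws + 1L, ws + params$k)
      cn <- co$node[j]
      corient <- ifelse(mm$strand > 0L, co$orient[j], -co$orient[j])
      clen <- as.integer(nchar(graph$seqs[as.character(cn)]))
      coff <- ifelse(mm$strand > 0L, co$off[j], clen - 1L - co$off[j])
      occ_list[[wi]] <- data.table::data.table(
        hash = mm$hash, walk = wi, ws = ws, sw = mm$strand,
        cnode = cn, corient = corient, coff = coff)
    }
  }
  occ <- data.table::rbindlist(occ_list[!vapply(occ_list, is.null, logical(1))])
  if (nrow(occ) == 0L) {
    pm_stop("parameter_error", "no minimizers extracted (walks shorter than k+w-1?)")
  }
  occ <- unique(occ, by = c("hash", "cnode", "corient", "coff"))
  counts <- occ[, list(count = .N), by = "hash"]
  data.table::setkey(occ, hash)
  data.table::setkey(counts, hash)
  # per-node walk occurrences (for haplotype-restricted extension)
  node_occ <- data.table::rbindlist(lapply(seq_along(walks), function(wi) {
    co <- winfo[[wi]]$coords
    data.table::data.table(node = walks[[wi]]$nodes,
                           worient = walks[[wi]]$orients,
                           walk = wi, step = seq_along(walks[[wi]]$nodes),
                           start = co$starts, len = co$lens)
  }))
  data.table::setkey(node_occ, node)
  structure(list(params = params, occ = occ, counts = counts,
                 walks = winfo, node_occ = node_occ,
                 occ_by_node = split(as.data.frame(node_occ), node_occ$node)),
            class = "minimizer_index")
}

#' Select weighted-minimizer seeds for a read
#'
#' Read minimizers are weighted by 1/(1+count)^e and taken in decreasing
#' weight until the selected weight reaches `score_fraction` of the total;
#' minimizers with more than `hard_hit_cap` occurrences are skipped. Each
#' emitted seed records the read offset, the graph position of the k-mer
#' start in read-forward direction, and the walk coordinate it came from.
#'
#' @param read DNA string.
#' @param index a `minimizer_index`.
#' @param params a [seeding_params()]; defaults to the index's parameters.
#' @return data frame of seeds: `read_offset` (0-based), `node`, `orient`,
#'   `offset`, `k`, `walk`, `wpos` (walk coordinate of the anchor start),
#'   `dir` (+1 when the read runs along the walk, -1 against it).
#' @export
select_seeds <- function(read, index, params = index$params) {
  k <- params$k
  empty <- data.frame(read_offset = integer(0), node = integer(0),
                      orient = integer(0), offset = integer(0), k = integer(0),
                      walk = integer(0), wpos = integer(0), dir = integer(0))
  if (nchar(read) < k) return(empty)
  mm <- minimizers_cpp(read, k, params$w)
  if (!length(mm$pos)) return(empty)
  rm_dt <- data.table::data.table(rpos = mm$pos - 1L, hash = mm$hash,
                                  sr = mm$strand)
  cnt <- index$counts[data.table::data.table(hash = rm_dt$hash), on = "hash"]
  rm_dt$count <- ifelse(is.na(cnt$count), 0L, cnt$count)
  rm_dt$weight <- 1 / (1 + rm_dt$count)^params$weight_downweight
  usable <- rm_dt$count >= 1L
  capped <- rm_dt$count > params$hard_hit_cap
  total_w <- sum(rm_dt$weight[usable & !capped])
  sel <- rm_dt[usable & !capped]
  sel <- sel[order(-sel$weight, sel$rpos)]
  if (nrow(sel)) {
    cum <- cumsum(sel$weight)
    keep_n <- which(cum >= params$score_fraction * total_w)[1]
    if (is.na(keep_n)) keep_n <- nrow(sel)
    sel <- sel[seq_len(keep_n)]
  }
  if (!nrow(sel)) return(empty)
  hits <- index$occ[data.table::data.table(hash = sel$hash), on = "hash",
                    allow.cartesian = TRUE, nomatch = NULL]
  sel_key <- sel[, c("hash", "rpos", "sr")]
  hits <- merge(hits, sel_key, by = "hash", allow.cartesian = TRUE)
  if (!nrow(hits)) return(empty)
  # project each hit to a read-forward anchor position (vectorized by walk)
  dirv <- hits$sw * hits$sr
  wl <- index$walks
  n_out <- nrow(hits)
  node <- integer(n_out); orient <- integer(n_out); offset <- integer(n_out)
  wpos <- integer(n_out)
  j_all <- ifelse(dirv > 0L, hits$ws + 1L, hits$ws + k)
  for (wk in unique(hits$walk)) {
    sel <- which(hits$walk == wk)
    co <- wl[[wk]]$coords
    j <- j_all[sel]
    node[sel] <- co$node[j]
    orient[sel] <- ifelse(dirv[sel] > 0L, co$orient[j], -co$orient[j])
    offset[sel] <- co$off[j]
    wpos[sel] <- ifelse(dirv[sel] > 0L, hits$ws[sel], hits$ws[sel] + k - 1L)
  }
  revsel <- which(dirv < 0L)
  if (length(revsel)) {
    occ_node <- index$node_occ$node
    occ_len <- index$node_occ$len
    node_lens <- occ_len[match(node[revsel], occ_node)]
    offset[revsel] <- node_lens - 1L - offset[revsel]
  }
  res <- data.frame(read_offset = hits$rpos, node = node, orient = orient,
                    offset = offset, k = k, walk = hits$walk, wpos = wpos,
                    dir = dirv)
  res <- res[!duplicated(res[, c("read_offset", "node", "orient", "offset")]), ]
  res <- res[order(res$read_offset, res$node, res$orient, res$offset), ]
  rownames(res) <- NULL
  res
}
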