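# Base-level extension of anchor chains into alignments.
#
# Between consecutive anchors the read gap is aligned with the wavefront
# kernel against local haplotype strings (subwalks of the embedded walks
# connecting the two anchor positions); a banded global graph aligner is
# the fallback when no haplotype connects them or the wavefront alignment
# fails or the problem exceeds the configured length ceiling. Tails beyond
# the first/last anchor are aligned with an X-drop extension along
# candidate graph walks; whatever cannot be extended is soft-clipped.

#' Alignment scoring scheme
#'
#' @param match match bonus (> 0).
#' @param mismatch mismatch penalty (>= 0).
#' @param gap_open,gap_extend affine gap penalties (>= 0).
#' @return An `aln_scoring` list.
#' @export
aln_scoring <- function(match = 1L, mismatch = 4L, gap_open = 6L,
                        gap_extend = 1L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "aln_scoring")
}

#' Gap-affine wavefront alignment of two strings
#'
#' Exact global gap-affine alignment (score-identical to full DP) computed
#' with a wavefront algorithm whose work scales with the alignment cost;
#' returns a failure value instead of an alignment when the cost exceeds
#' `max_cost`.
#'
#' @param query,target DNA strings.
#' @param scoring an [aln_scoring()] list.
#' @param max_cost maximum admissible alignment cost (penalty sum);
#'   `Inf` for unrestricted.
#' @return `list(ok, score, ops, lens)`; `ok = FALSE` marks failure (caller
#'   falls back to graph alignment).
#' @export
wfa_align <- function(query, target, scoring = aln_scoring(), max_cost = Inf) {
  r <- wfa_align_cpp(query, target, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend,
                     if (is.finite(max_cost)) max_cost else -1)
  list(ok = r$ok, score = r$score, ops = as.character(r$ops),
       lens = as.integer(r$lens))
}

# Score implied by a CIGAR (clips free; gaps affine).
cigar_score <- function(ops, lens, scoring) {
  s <- 0
  for (i in seq_along(ops)) {
    s <- s + switch(ops[i],
      "=" = scoring$match * lens[i],
      "X" = -scoring$mismatch * lens[i],
      "I" = -(scoring$gap_open + scoring$gap_extend * lens[i]),
      "D" = -(scoring$gap_open + scoring$gap_extend * lens[i]),
      "S" = 0, 0)
  }
  s
}

# run-length append of CIGAR pieces
cat_cigar <- function(ops1, lens1, ops2, lens2) {
  if (!length(ops2)) return(list(ops = ops1, lens = lens1))
  if (length(ops1) && ops1[length(ops1)] == ops2[1]) {
    lens1[length(lens1)] <- lens1[length(lens1)] + lens2[1]
    ops2 <- ops2[-1]; lens2 <- lens2[-1]
  }
  list(ops = c(ops1, ops2), lens = c(lens1, lens2))
}

# --- walk coordinate helpers -------------------------------------------

# occurrences of a graph position on the indexed walks:
# walk, wc (0-based walk coordinate of the base), dir (+1: the position's
# orientation runs along the walk; -1: against it)
pos_walk_occ <- function(hindex, pos) {
  no <- hindex$occ_by_node[[as.character(pos$node)]]
  if (is.null(no) || nrow(no) == 0L) {
    return(list(walk = integer(0), step = integer(0), wc = integer(0),
                dir = integer(0)))
  }
  dirv <- ifelse(no$worient == pos$orient, 1L, -1L)
  wc <- ifelse(dirv > 0L, no$start + pos$offset,
               no$start + (no$len - 1L - pos$offset))
  list(walk = no$walk, step = no$step, wc = as.integer(wc), dir = dirv)
}

# walk steps covering walk coordinates wc1..wc2 (inclusive, wc1 <= wc2)
walk_steps_covering <- function(hindex, walk, wc1, wc2) {
  w <- hindex$walks[[walk]]
  s1 <- findInterval(wc1, w$coords$starts)
  s2 <- findInterval(wc2, w$coords$starts)
  if (s2 < s1) return(NULL)
  steps_list(w$nodes[s1:s2], w$orients[s1:s2], rep(walk, s2 - s1 + 1L), s1:s2)
}

# lightweight step records: parallel vectors (node, orient, walk, step)
steps_list <- function(node, orient, walk, step) {
  list(node = node, orient = orient, walk = walk, step = step)
}

steps_n <- function(st) if (is.null(st)) 0L else length(st$node)

rev_steps <- function(st) {
  i <- rev(seq_along(st$node))
  steps_list(st$node[i], st$orient[i], st$walk[i], st$step[i])
}

# steps of a walk span in read direction; dir = -1 flips order/orientation
span_steps <- function(hindex, walk, lo, hi, dir) {
  st <- walk_steps_covering(hindex, walk, lo, hi)
  if (is.null(st)) return(NULL)
  if (dir < 0L) {
    st <- rev_steps(st)
    st$orient <- -st$orient
  }
  st
}

# spelled sequence of a walk span in read direction
span_string <- function(hindex, walk, lo, hi, dir) {
  if (hi < lo) return("")
  s <- substr(hindex$walks[[walk]]$seq, lo + 1L, hi + 1L)
  if (dir < 0L) rc_string_cpp(s) else s
}

#' Enumerate haplotype-consistent local walks between two positions
#'
#' Walks from `from` to `to` (exclusive of both endpoint bases) that are
#' subwalks of the embedded walks, with their spelled strings, deduplicated
#' by string, capped at `limit`.
#'
#' @param graph a `variation_graph`.
#' @param from,to `graph_pos` endpoints.
#' @param limit maximum number of walks returned.
#' @param hindex a `minimizer_index` over `graph` (carries walk
#'   coordinates); built on the fly if omitted.
#' @param max_span ignore occurrence pairs spanning more than this many
#'   bases on the walk.
#' @return List of `list(string, steps, walk, lo, hi, dir)`; empty when no
#'   embedded walk connects the positions.
#' @export
enumerate_local_haplotypes <- function(graph, from, to, limit = 16L,
                                       hindex = NULL, max_span = Inf) {
  if (is.null(hindex)) hindex <- walk_only_index(graph)
  of <- pos_walk_occ(hindex, from)
  ot <- pos_walk_occ(hindex, to)
  out <- list()
  seen <- character(0)
  if (length(of$walk) && length(ot$walk)) {
    # join occurrences on (walk, dir) without merge() overhead
    kf <- of$walk * 2L + (of$dir > 0L)
    kt <- ot$walk * 2L + (ot$dir > 0L)
    pair_i <- integer(0); pair_j <- integer(0)
    for (i in seq_along(kf)) {
      js <- which(kt == kf[i])
      if (length(js)) {
        pair_i <- c(pair_i, rep(i, length(js)))
        pair_j <- c(pair_j, js)
      }
    }
    if (!length(pair_i)) return(out)
    cand <- data.frame(walk = of$walk[pair_i], dir = of$dir[pair_i],
                       wc_f = of$wc[pair_i], wc_t = ot$wc[pair_j])
    cand$span <- ifelse(cand$dir > 0L, cand$wc_t - cand$wc_f,
                        cand$wc_f - cand$wc_t)
    cand <- cand[cand$span > 0L & cand$span <= max_span, , drop = FALSE]
    cand <- cand[order(cand$span, cand$walk), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      if (length(out) >= limit) break
      if (cand$dir[r] > 0L) {
        lo <- cand$wc_f[r] + 1L; hi <- cand$wc_t[r] - 1L
      } else {
        lo <- cand$wc_t[r] + 1L; hi <- cand$wc_f[r] - 1L
      }
      s <- if (hi < lo) "" else span_string(hindex, cand$walk[r], lo, hi, cand$dir[r])
      if (s %in% seen) next
      seen <- c(seen, s)
      steps <- if (hi < lo) NULL else
        span_steps(hindex, cand$walk[r], lo, hi, cand$dir[r])
      out[[length(out) + 1L]] <- list(string = s, steps = steps,
                                      walk = cand$walk[r], lo = lo, hi = hi,
                                      dir = cand$dir[r])
    }
  }
  out
}

# minimal walk-coordinate index when no minimizer index is at hand
walk_only_index <- function(graph) {
  winfo <- lapply(graph$walks, function(w) {
    c(w, list(seq = walk_sequence(graph, w), coords = walk_coords(graph, w)))
  })
  node_occ <- data.table::rbindlist(lapply(seq_along(graph$walks), function(wi) {
    co <- winfo[[wi]]$coords
    data.table::data.table(node = graph$walks[[wi]]$nodes,
                           worient = graph$walks[[wi]]$orients,
                           walk = wi, step = seq_along(graph$walks[[wi]]$nodes),
                           start = co$starts, len = co$lens)
  }))
  data.table::setkey(node_occ, node)
  list(walks = winfo, node_occ = node_occ,
       occ_by_node = split(as.data.frame(node_occ), node_occ$node))
}

# --- graph-walk enumeration (fallback paths) ---------------------------

# DFS enumeration of oriented walks from the base after `from` up to the
# base before `to`, capped by total spelled length and count. Strings are
# the spelled bases strictly between the endpoints; cycles unroll naturally
# under the length cap.
graph_walks_between <- function(graph, from, to, max_len, max_walks = 64L) {
  res <- list()
  node_len <- nchar(graph$seqs)
  e <- graph$edges
  neighbours <- function(node, orient) {
    ex <- exit_side(orient)
    sel1 <- e$node1 == node & e$side1 == ex
    sel2 <- e$node2 == node & e$side2 == ex
    nbr <- rbind(
      if (any(sel1)) data.frame(n = e$node2[sel1], s = e$side2[sel1]) else NULL,
      if (any(sel2)) data.frame(n = e$node1[sel2], s = e$side1[sel2]) else NULL)
    if (is.null(nbr) || !nrow(nbr)) return(NULL)
    nbr$o <- ifelse(nbr$s == "L", 1L, -1L)
    nbr[order(nbr$n, nbr$o), , drop = FALSE]
  }
  # same oriented node, target offset ahead: degenerate direct span
  if (from$node == to$node && from$orient == to$orient &&
      to$offset > from$offset) {
    s <- substr(oriented_seq(graph, from$node, from$orient),
                from$offset + 2L, to$offset)
    res[[1L]] <- list(string = s, steps = NULL)
  }
  dfs <- function(node, orient, spelled, steps, used_len) {
    if (length(res) >= max_walks || used_len > max_len) return()
    nbr <- neighbours(node, orient)
    if (is.null(nbr)) return()
    for (r in seq_len(nrow(nbr))) {
      n2 <- nbr$n[r]; o2 <- nbr$o[r]
      l2 <- node_len[[as.character(n2)]]
      new_steps <- list(node = c(steps$node, n2), orient = c(steps$orient, o2),
                        walk = c(steps$walk, NA_integer_),
                        step = c(steps$step, NA_integer_))
      if (n2 == to$node && o2 == to$orient) {
        pre <- substr(oriented_seq(graph, n2, o2), 1L, to$offset)
        res[[length(res) + 1L]] <<- list(
          string = paste0(spelled, pre),
          steps = new_steps)
        if (length(res) >= max_walks) return()
      }
      if (used_len + l2 <= max_len) {
        dfs(n2, o2, paste0(spelled, oriented_seq(graph, n2, o2)),
            new_steps, used_len + l2)
      }
    }
  }
  len_f <- node_len[[as.character(from$node)]]
  start_tail <- len_f - 1L - from$offset
  tail_str <- if (start_tail > 0L) {
    substr(oriented_seq(graph, from$node, from$orient), from$offset + 2L, len_f)
  } else ""
  dfs(from$node, from$orient, tail_str,
      list(node = integer(0), orient = integer(0), walk = integer(0),
           step = integer(0)), start_tail)
  seen <- character(0)
  out <- list()
  for (w in res) {
    if (w$string %in% seen) next
    seen <- c(seen, w$string)
    out[[length(out) + 1L]] <- w
  }
  out
}

oriented_seq <- function(graph, node, orient) {
  s <- graph$seqs[[as.character(node)]]
  if (orient > 0L) s else rc_string_cpp(s)
}

#' Banded global alignment of a query between two graph positions
#'
#' Aligns `query` to graph walks strictly between `from` and `to`: walks
#' whose spelled length lies within `band_width` of the query length are
#' enumerated from the graph (cycles unrolled up to the query length) and
#' scored with the exact gap-affine kernel; the best-scoring walk wins.
#' Returns a failure value when no walk fits in the band.
#'
#' @param query read substring (may be empty).
#' @param graph a `variation_graph`.
#' @param from,to `graph_pos` anchor endpoints (exclusive).
#' @param band_width band half-width on target length.
#' @param scoring an [aln_scoring()] list.
#' @return `list(ok, score, ops, lens, steps)`.
#' @export
banded_graph_align <- function(query, graph, from, to, band_width = 64L,
                               scoring = aln_scoring()) {
  # adjacent endpoints, empty query: empty alignment
  walks <- graph_walks_between(graph, from, to,
                               max_len = nchar(query) + band_width)
  best <- NULL
  for (w in walks) {
    if (abs(nchar(w$string) - nchar(query)) > band_width) next
    if (nchar(w$string) == 0L && nchar(query) == 0L) {
      r <- list(ok = TRUE, score = 0, ops = character(0), lens = integer(0))
    } else {
      r <- wfa_align(query, w$string, scoring)
    }
    if (r$ok && (is.null(best) || r$score > best$score)) {
      best <- list(ok = TRUE, score = r$score, ops = r$ops, lens = r$lens,
                   steps = trim_link_steps(w$steps, nchar(w$string), r))
    }
  }
  if (is.null(best)) {
    return(list(ok = FALSE, score = -Inf, ops = character(0),
                lens = integer(0), steps = NULL))
  }
  best
}

# the DFS steps include the `to` node as last step; alignment covers only
# bases before to$offset, so keep steps as-is (the caller merges by step id)
trim_link_steps <- function(steps, tlen, r) steps

#' X-drop tail alignment out from an anchor
#'
#' Extends the tail of a read outwards from an anchor along candidate graph
#' continuations (embedded haplotype continuations when available, graph
#' walks otherwise), pruning with an X-drop threshold; the unaligned
#' remainder is soft-clipped by the caller.
#'
#' @param query_tail read bases beyond the anchor, in extension direction.
#' @param graph a `variation_graph`.
#' @param anchor `graph_pos` of the last aligned base.
#' @param direction `"right"` extends after the anchor (in the anchor's
#'   orientation).
#' @param x_drop drop threshold.
#' @param scoring an [aln_scoring()] list.
#' @param hindex optional `minimizer_index` (for haplotype continuations).
#' @param band_width adaptive band half-width.
#' @return `list(score, query_used, target_used, ops, lens, steps)`.
#' @export
xdrop_tail_align <- function(query_tail, graph, anchor, direction = "right",
                             x_drop = 60L, scoring = aln_scoring(),
                             hindex = NULL, band_width = 64L) {
  if (nchar(query_tail) == 0L) {
    return(list(score = 0, query_used = 0L, target_used = 0L,
                ops = character(0), lens = integer(0), steps = NULL))
  }
  if (is.null(hindex)) hindex <- walk_only_index(graph)
  # candidate continuation strings beyond the anchor
  occ <- pos_walk_occ(hindex, anchor)
  cands <- list()
  seen <- character(0)
  tl <- nchar(query_tail)
  if (length(occ$walk)) {
    for (r in seq_along(occ$walk)) {
      w <- hindex$walks[[occ$walk[r]]]
      wlen <- nchar(w$seq)
      if (occ$dir[r] > 0L) {
        lo <- occ$wc[r] + 1L; hi <- min(wlen - 1L, occ$wc[r] + tl + band_width)
      } else {
        lo <- max(0L, occ$wc[r] - tl - band_width); hi <- occ$wc[r] - 1L
      }
      if (hi < lo) next
      s <- span_string(hindex, occ$walk[r], lo, hi, occ$dir[r])
      if (s %in% seen) next
      seen <- c(seen, s)
      cands[[length(cands) + 1L]] <- list(string = s, walk = occ$walk[r],
                                          lo = lo, hi = hi, dir = occ$dir[r])
    }
  }
  best <- list(score = 0, query_used = 0L, target_used = 0L,
               ops = character(0), lens = integer(0), steps = NULL,
               span = NULL)
  perfect <- scoring$match * tl
  for (cd in cands) {
    if (best$score >= perfect) break  # cannot improve on an all-match tail
    r <- xdrop_extend_cpp(query_tail, cd$string, scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend, x_drop, band_width)
    if (r$score > best$score) {
      if (r$target_used > 0L) {
        span <- if (cd$dir > 0L) {
          list(walk = cd$walk, lo = cd$lo, hi = cd$lo + r$target_used - 1L,
               dir = 1L)
        } else {
          list(walk = cd$walk, lo = cd$hi - r$target_used + 1L, hi = cd$hi,
               dir = -1L)
        }
        steps <- span_steps(hindex, span$walk, span$lo, span$hi, span$dir)
      } else { span <- NULL; steps <- NULL }
      best <- list(score = r$score, query_used = r$query_used,
                   target_used = r$target_used, ops = as.character(r$ops),
                   lens = as.integer(r$lens), steps = steps, span = span)
    }
  }
  best
}

# graph position of the base at walk coordinate wc, viewed in direction d
wc_to_pos <- function(hindex, walk, wc, d) {
  co <- hindex$walks[[walk]]$coords
  j <- wc + 1L
  nd <- co$node[j]; wo <- co$orient[j]; off <- co$off[j]
  st <- findInterval(wc, co$starts)
  ln <- co$lens[st]
  if (d > 0L) graph_pos(nd, wo, off) else graph_pos(nd, -wo, ln - 1L - off)
}

#' Extension parameters
#'
#' @param scoring an [aln_scoring()] list.
#' @param band_width band half-width for the banded graph aligner (doubled
#'   once on failure).
#' @param wfa_max length ceiling for wavefront alignment problems; longer
#'   links go straight to the banded graph aligner.
#' @param hap_limit maximum local haplotype walks enumerated per link.
#' @param x_drop X-drop threshold for tail alignment.
#' @return An `extension_params` list.
#' @export
extension_params <- function(scoring = aln_scoring(), band_width = 64L,
                             wfa_max = 65536L, hap_limit = 16L,
                             x_drop = 60L) {
  structure(list(scoring = scoring, band_width = as.integer(band_width),
                 wfa_max = as.integer(wfa_max), hap_limit = as.integer(hap_limit),
                 x_drop = as.integer(x_drop)),
            class = "extension_params")
}

# append steps to a path, merging boundary duplicates. Two adjacent step
# records with the same oriented node are the same node visit unless they
# are distinct steps of the same walk (a genuine loop revisit).
append_steps <- function(path, steps) {
  if (steps_n(steps) == 0L) return(path)
  if (steps_n(path) > 0L) {
    n <- steps_n(path)
    distinct_loop <- !is.na(path$walk[n]) && !is.na(steps$walk[1]) &&
      path$walk[n] == steps$walk[1] && path$step[n] != steps$step[1]
    same_visit <- path$node[n] == steps$node[1] &&
      path$orient[n] == steps$orient[1] && !distinct_loop
    if (same_visit) {
      steps <- steps_list(steps$node[-1], steps$orient[-1], steps$walk[-1],
                          steps$step[-1])
    }
  }
  if (is.null(path)) return(steps)
  steps_list(c(path$node, steps$node), c(path$orient, steps$orient),
             c(path$walk, steps$walk), c(path$step, steps$step))
}

#' Extend an anchor chain into a base-level alignment
#'
#' Anchors are merged and trimmed into exact-match runs, links between
#' runs are aligned against local haplotype strings (wavefront kernel) with
#' banded graph alignment as fallback, and tails are aligned with X-drop
#' extension. The stitched result is a walk through the graph with a
#' CIGAR-style operation list and a score.
#'
#' @param read the read sequence.
#' @param chain a chain from [chain_anchors()], with `seed_df` holding the
#'   seed rows in chain order.
#' @param graph a `variation_graph`.
#' @param params an [extension_params()] list.
#' @param hindex optional `minimizer_index` (walk coordinates); rebuilt from
#'   the graph if missing.
#' @return A `graph_alignment` list (path steps, CIGAR, score, query span),
#'   or `NULL` when a link cannot be stitched.
#' @export
extend_chain <- function(read, chain, graph, params = extension_params(),
                         hindex = NULL) {
  if (is.null(hindex)) hindex <- walk_only_index(graph)
  sd <- chain$seed_df
  if (is.null(sd) || nrow(sd) == 0L) return(NULL)
  scoring <- params$scoring

  # ---- merge anchors into exact runs ----------------------------------
  runs <- list()
  for (i in seq_len(nrow(sd))) {
    rs <- sd$read_offset[i]; k <- sd$k[i]; re <- rs + k - 1L
    wkk <- sd$walk[i]; wc <- sd$wpos[i]; d <- sd$dir[i]
    if (length(runs)) {
      pr <- runs[[length(runs)]]
      # repeat k-mers carry the walk coordinate of one stored copy; if the
      # gapless continuation of the previous run spells the same graph
      # position, re-anchor onto that copy
      if (wkk == pr$walk && d == pr$dir && wc != pr$wc_s + d * (rs - pr$rs)) {
        desired <- pr$wc_s + d * (rs - pr$rs)
        wlen <- nchar(hindex$walks[[wkk]]$seq)
        if (desired >= 0L && desired + k - 1L < wlen &&
            (d > 0L || desired - k + 1L >= 0L)) {
          p_old <- wc_to_pos(hindex, wkk, wc, d)
          p_new <- wc_to_pos(hindex, wkk, desired, d)
          if (p_old$node == p_new$node && p_old$orient == p_new$orient &&
              p_old$offset == p_new$offset) {
            wc <- desired
          }
        }
      }
      if (rs <= pr$re) {
        delta <- rs - pr$rs
        if (wkk == pr$walk && d == pr$dir && wc == pr$wc_s + d * delta) {
          if (re > pr$re) {
            pr$re <- re
            pr$wc_e <- pr$wc_s + d * (re - pr$rs)
            runs[[length(runs)]] <- pr
          }
          next
        }
        trim <- pr$re + 1L - rs
        rs <- rs + trim; wc <- wc + d * trim
        if (rs > re) next
      } else if (wkk == pr$walk && d == pr$dir) {
        if ((wc - pr$wc_e) * d <= 0L) next  # graph going backwards: drop
      }
    }
    wc_e <- wc + d * (re - rs)
    wlen <- nchar(hindex$walks[[wkk]]$seq)
    if (min(wc, wc_e) < 0L || max(wc, wc_e) >= wlen) next  # off the walk
    runs[[length(runs) + 1L]] <- list(rs = rs, re = re, walk = wkk,
                                      wc_s = wc, wc_e = wc_e, dir = d)
  }
  if (!length(runs)) return(NULL)

  # ---- per-link alignment ---------------------------------------------
  # A link can fail when a spurious repeat anchor slipped into the chain
  # (its graph position overlaps its neighbour inconsistently); drop the
  # shorter of the two offending runs and retry.
  pieces <- NULL
  for (attempt in seq_len(20L)) {
    pieces <- list()
    failed_at <- 0L
    for (t in seq_along(runs)) {
      r <- runs[[t]]
      span <- if (r$dir > 0L) c(r$wc_s, r$wc_e) else c(r$wc_e, r$wc_s)
      pieces[[length(pieces) + 1L]] <- list(
        ops = "=", lens = r$re - r$rs + 1L,
        steps = span_steps(hindex, r$walk, span[1], span[2], r$dir))
      if (t == length(runs)) break
      nx <- runs[[t + 1L]]
      q <- substr(read, r$re + 2L, nx$rs)  # read gap (may be empty)
      from <- wc_to_pos(hindex, r$walk, r$wc_e, r$dir)
      to <- wc_to_pos(hindex, nx$walk, nx$wc_s, nx$dir)
      link <- align_link(q, graph, from, to, params, hindex)
      if (is.null(link)) { failed_at <- t; break }
      pieces[[length(pieces) + 1L]] <- link
    }
    if (failed_at == 0L) break
    if (length(runs) <= 1L) return(NULL)
    len_a <- runs[[failed_at]]$re - runs[[failed_at]]$rs
    len_b <- runs[[failed_at + 1L]]$re - runs[[failed_at + 1L]]$rs
    drop <- if (len_a <= len_b) failed_at else failed_at + 1L
    runs[[drop]] <- NULL
    pieces <- NULL
  }
  if (is.null(pieces)) return(NULL)

  first <- runs[[1]]; last <- runs[[length(runs)]]

  # ---- tails -----------------------------------------------------------
  q_start <- first$rs; q_end <- last$re + 1L  # 0-based half-open on read
  left_piece <- NULL; right_piece <- NULL
  lead_clip <- first$rs; trail_clip <- nchar(read) - q_end
  if (first$rs > 0L) {
    p1 <- wc_to_pos(hindex, first$walk, first$wc_s, first$dir)
    lenp <- nchar(graph$seqs[[as.character(p1$node)]])
    anchor_flip <- graph_pos(p1$node, -p1$orient, lenp - 1L - p1$offset)
    tail_q <- rc_string_cpp(substr(read, 1L, first$rs))
    tl <- xdrop_tail_align(tail_q, graph, anchor_flip, "right",
                           params$x_drop, scoring, hindex, params$band_width)
    if (tl$query_used > 0L) {
      steps <- tl$steps
      if (!is.null(steps)) {
        steps <- rev_steps(steps)
        steps$orient <- -steps$orient
      }
      left_piece <- list(ops = rev(tl$ops), lens = rev(tl$lens), steps = steps,
                         span = tl$span)
      q_start <- first$rs - tl$query_used
      lead_clip <- q_start
    }
  }
  if (q_end < nchar(read)) {
    p2 <- wc_to_pos(hindex, last$walk, last$wc_e, last$dir)
    tail_q <- substr(read, q_end + 1L, nchar(read))
    tr <- xdrop_tail_align(tail_q, graph, p2, "right", params$x_drop,
                           scoring, hindex, params$band_width)
    if (tr$query_used > 0L) {
      right_piece <- list(ops = tr$ops, lens = tr$lens, steps = tr$steps,
                          span = tr$span)
      q_end <- q_end + tr$query_used
      trail_clip <- nchar(read) - q_end
    }
  }

  # ---- stitch ----------------------------------------------------------
  ops <- character(0); lens <- integer(0); path <- NULL
  add_piece <- function(pc) {
    if (is.null(pc)) return()
    cc <- cat_cigar(ops, lens, pc$ops, pc$lens)
    ops <<- cc$ops; lens <<- cc$lens
    path <<- append_steps(path, pc$steps)
  }
  add_piece(left_piece)
  for (pc in pieces) add_piece(pc)
  add_piece(right_piece)
  if (steps_n(path) == 0L) return(NULL)

  # path start/end offsets (on the oriented first/last path nodes)
  p_first <- if (!is.null(left_piece)) {
    sp <- left_piece$span
    flip_pos(graph, wc_to_pos(hindex, sp$walk,
                              if (sp$dir > 0L) sp$hi else sp$lo, sp$dir))
  } else wc_to_pos(hindex, first$walk, first$wc_s, first$dir)
  p_last <- if (!is.null(right_piece)) {
    sp <- right_piece$span
    wc_to_pos(hindex, sp$walk, if (sp$dir > 0L) sp$hi else sp$lo, sp$dir)
  } else wc_to_pos(hindex, last$walk, last$wc_e, last$dir)

  score <- cigar_score(ops, lens, scoring)
  if (lead_clip > 0L) { ops <- c("S", ops); lens <- c(lead_clip, lens) }
  if (trail_clip > 0L) { ops <- c(ops, "S"); lens <- c(lens, trail_clip) }

  structure(list(path = path, start_off = p_first$offset,
                 end_off = p_last$offset + 1L, ops = ops, lens = lens,
                 score = score, read_len = nchar(read),
                 q_start = q_start, q_end = q_end),
            class = "graph_alignment")
}

flip_pos <- function(graph, p) {
  len <- nchar(graph$seqs[[as.character(p$node)]])
  graph_pos(p$node, -p$orient, len - 1L - p$offset)
}

# align one link between anchor runs; NULL on hard failure
align_link <- function(q, graph, from, to, params, hindex) {
  scoring <- params$scoring
  cands <- enumerate_local_haplotypes(
    graph, from, to, limit = params$hap_limit, hindex = hindex,
    max_span = nchar(q) + 4L * params$band_width + 32L)
  best <- NULL
  for (cd in cands) {
    tlen <- nchar(cd$string)
    if (tlen == 0L && nchar(q) == 0L) {
      r <- list(ok = TRUE, score = 0, ops = character(0), lens = integer(0))
    } else if (tlen == nchar(q) && cd$string == q) {
      r <- list(ok = TRUE, score = scoring$match * tlen, ops = "=", lens = tlen)
    } else if (max(tlen, nchar(q)) <= params$wfa_max) {
      r <- wfa_align(q, cd$string, scoring)
    } else r <- list(ok = FALSE)
    if (r$ok && (is.null(best) || r$score > best$score)) {
      best <- list(ops = as.character(r$ops), lens = as.integer(r$lens),
                   steps = cd$steps, score = r$score)
    }
  }
  if (!is.null(best)) return(best)
  for (bw in c(params$band_width, 2L * params$band_width)) {
    r <- banded_graph_align(q, graph, from, to, bw, scoring)
    if (r$ok) {
      return(list(ops = r$ops, lens = r$lens, steps = r$steps, score = r$score))
    }
  }
  NULL
}
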