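# End-to-end single-read mapping pipeline: seeds -> zip code forest ->
# chains -> extension -> scored alignments with MAPQ, serialized as GAF.

#' Mapper parameters
#'
#' @param seeding a [seeding_params()] list.
#' @param chaining a [chaining_params()] list.
#' @param extension an [extension_params()] list.
#' @param max_alns maximum alignments reported per read.
#' @param min_anchors minimum seeds required to attempt mapping.
#' @param min_score_frac minimum alignment score as a fraction of read
#'   length x match bonus; lower-scoring reads are reported unmapped.
#' @return A `mapper_params` list.
#' @export
mapper_params <- function(seeding = seeding_params(),
                          chaining = chaining_params(),
                          extension = extension_params(),
                          max_alns = 4L, min_anchors = 2L,
                          min_score_frac = 0.25) {
  structure(list(seeding = seeding, chaining = chaining,
                 extension = extension, max_alns = as.integer(max_alns),
                 min_anchors = as.integer(min_anchors),
                 min_score_frac = min_score_frac),
            class = "mapper_params")
}

#' Build all mapping indexes for a graph
#'
#' Snarl tree, distance index (with cached chaining coordinates), and
#' minimizer index.
#'
#' @param graph a `variation_graph`.
#' @param params a [mapper_params()] list.
#' @return A `panmap_indexes` list.
#' @export
build_indexes <- function(graph, params = mapper_params()) {
  tree <- snarl_decompose(graph)
  dist <- build_distance_index(graph, tree)
  dist$coords <- index_coords(dist)
  minim <- build_minimizer_index(graph, params$seeding)
  structure(list(tree = tree, dist = dist, minim = minim),
            class = "panmap_indexes")
}

#' Mapping quality from primary and secondary scores
#'
#' `60 * (primary - secondary) / (primary - min_possible)`, rounded and
#' clamped to 0..60; a read with no secondary alignment gets 60.
#'
#' @param primary_score,secondary_score alignment scores
#'   (`secondary_score = NA` when there is no secondary).
#' @param min_possible,max_possible score bounds (only `min_possible`
#'   enters the formula; `max_possible` is accepted for symmetry).
#' @return Integer MAPQ in 0..60.
#' @export
compute_mapq <- function(primary_score, secondary_score = NA,
                         min_possible = 0, max_possible = NA) {
  if (is.na(secondary_score)) return(60L)
  if (primary_score < secondary_score) {
    pm_stop("contract_violation", "primary score below secondary")
  }
  denom <- primary_score - min_possible
  if (denom <= 0) return(0L)
  q <- round(60 * (primary_score - secondary_score) / denom)
  as.integer(max(0, min(60, q)))
}

#' Map a single read
#'
#' @param read DNA string.
#' @param graph a `variation_graph`.
#' @param indexes a [build_indexes()] bundle.
#' @param params a [mapper_params()] list.
#' @param name read name attached to the alignments.
#' @return List of `graph_alignment` objects (possibly empty = unmapped);
#'   the first is primary and carries the MAPQ.
#' @export
map_read <- function(read, graph, indexes, params = mapper_params(),
                     name = "read") {
  seeds <- select_seeds(read, indexes$minim, params$seeding)
  if (nrow(seeds) < params$min_anchors) return(list())
  ztree <- build_zip_tree(seeds, indexes$dist, labels = FALSE, items = FALSE)
  chains <- chain_anchors(seeds, ztree, params$chaining)
  if (!length(chains)) return(list())
  alns <- list()
  for (ch in chains) {
    ch$seed_df <- seeds[ch$anchors, , drop = FALSE]
    al <- extend_chain(read, ch, graph, params$extension, indexes$minim)
    if (!is.null(al)) {
      al$name <- name
      alns[[length(alns) + 1L]] <- al
    }
  }
  if (!length(alns)) return(list())
  sc <- vapply(alns, `[[`, numeric(1), "score")
  alns <- alns[order(-sc)]
  match_b <- params$extension$scoring$match
  if (alns[[1]]$score < params$min_score_frac * nchar(read) * match_b) {
    return(list())
  }
  # secondary = best other alignment at a distinct location
  primary <- alns[[1]]
  pnodes <- primary$path$node
  sec_score <- NA_real_
  keep <- list(primary)
  for (i in seq_along(alns)[-1]) {
    anodes <- alns[[i]]$path$node
    ov <- length(intersect(anodes, pnodes)) / max(1L, length(unique(anodes)))
    if (ov < 0.5) {
      if (is.na(sec_score)) sec_score <- alns[[i]]$score
      alns[[i]]$secondary <- TRUE
      keep[[length(keep) + 1L]] <- alns[[i]]
    }
  }
  keep[[1]]$mapq <- compute_mapq(primary$score, sec_score, min_possible = 0)
  keep[[1]]$secondary <- FALSE
  head(keep, params$max_alns)
}

#' Map many reads
#'
#' @param reads named character vector.
#' @param graph a `variation_graph`.
#' @param indexes a [build_indexes()] bundle.
#' @param params a [mapper_params()] list.
#' @param progress print progress every N reads (0 = quiet).
#' @return List of per-read alignment lists; unmapped reads are empty and
#'   counted in `attr(, "n_unmapped")`.
#' @export
map_reads <- function(reads, graph, indexes, params = mapper_params(),
                      progress = 0L) {
  out <- vector("list", length(reads))
  names(out) <- names(reads)
  for (i in seq_along(reads)) {
    out[[i]] <- map_read(reads[[i]], graph, indexes, params,
                         name = names(reads)[i])
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("mapped %d/%d reads", i, length(reads)))
    }
  }
  attr(out, "n_unmapped") <- sum(vapply(out, length, integer(1)) == 0L)
  out
}

# ---- GAF ---------------------------------------------------------------

gaf_path_string <- function(path) {
  paste0(ifelse(path$orient > 0L, ">", "<"), path$node, collapse = "")
}

#' Parse a GAF path string
#' @param s path column value like `">1>2<3"`.
#' @return data frame with `node`, `orient`.
#' @export
parse_gaf_path <- function(s) {
  toks <- regmatches(s, gregexpr("[<>][^<>]+", s))[[1]]
  data.frame(node = as.integer(substring(toks, 2L)),
             orient = ifelse(substr(toks, 1L, 1L) == ">", 1L, -1L))
}

# cs:Z difference string from CIGAR + sequences
cigar_to_cs <- function(ops, lens, qseq, tseq) {
  qi <- 1L; ti <- 1L
  out <- character(0)
  for (i in seq_along(ops)) {
    l <- lens[i]
    switch(ops[i],
      "=" = { out <- c(out, paste0(":", l)); qi <- qi + l; ti <- ti + l },
      "X" = {
        for (j in seq_len(l)) {
          out <- c(out, paste0("*", tolower(substr(tseq, ti, ti)),
                               tolower(substr(qseq, qi, qi))))
          qi <- qi + 1L; ti <- ti + 1L
        }
      },
      "I" = { out <- c(out, paste0("+", tolower(substr(qseq, qi, qi + l - 1L))))
              qi <- qi + l },
      "D" = { out <- c(out, paste0("-", tolower(substr(tseq, ti, ti + l - 1L))))
              ti <- ti + l },
      "S" = { qi <- qi + l })
  }
  paste0(out, collapse = "")
}

# spelled target sequence of an alignment path segment
path_target_seq <- function(graph, aln) {
  segs <- vapply(seq_along(aln$path$node), function(i) {
    oriented_seq(graph, aln$path$node[i], aln$path$orient[i])
  }, character(1))
  full <- paste0(segs, collapse = "")
  last_len <- nchar(segs[length(segs)])
  stop_at <- nchar(full) - (last_len - aln$end_off)
  substr(full, aln$start_off + 1L, stop_at)
}

#' Write alignments as GAF
#'
#' One record per alignment: query name/length/interval, strand, `>`/`<`
#' path, path length/interval, residue matches, block length, MAPQ, plus
#' `AS` (score), `tp` (P/S) and `cs` (difference string) tags. Coordinates
#' are 0-based half-open. Unmapped reads produce no record.
#'
#' @param alignments flat list of `graph_alignment` objects or the nested
#'   per-read list from [map_reads()].
#' @param path output file, or `NULL` to return the lines.
#' @param graph the `variation_graph` (for the cs tag); omit to skip cs.
#' @param reads named read sequences (for the cs tag).
#' @return Invisibly the GAF lines.
#' @export
write_gaf <- function(alignments, path = NULL, graph = NULL, reads = NULL) {
  if (length(alignments) && is.list(alignments[[1]]) &&
      !inherits(alignments[[1]], "graph_alignment")) {
    alignments <- unlist(alignments, recursive = FALSE)
  }
  lines <- character(0)
  for (al in alignments) {
    if (is.null(al)) next
    plen <- sum(nchar(graph$seqs[as.character(al$path$node)]))
    if (is.null(graph)) plen <- NA_integer_
    nmatch <- sum(al$lens[al$ops == "="])
    block <- sum(al$lens[al$ops %in% c("=", "X", "I", "D")])
    mapq <- al$mapq %||% 0L
    tags <- sprintf("AS:i:%d\ttp:A:%s", as.integer(round(al$score)),
                    if (isTRUE(al$secondary)) "S" else "P")
    if (!is.null(graph) && !is.null(reads) && al$name %in% names(reads)) {
      qseq <- substr(reads[[al$name]], al$q_start + 1L, al$q_end)
      tseq <- path_target_seq(graph, al)
      core <- al$ops != "S"
      tags <- paste0(tags, "\tcs:Z:",
                     cigar_to_cs(al$ops[core], al$lens[core], qseq, tseq))
    }
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s",
      al$name, al$read_len, al$q_start, al$q_end,
      gaf_path_string(al$path), plen, al$start_off,
      al$start_off + sum(al$lens[al$ops %in% c("=", "X", "D")]),
      nmatch, block, mapq, tags))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a GAF file
#'
#' @param path GAF file path or a character vector of GAF lines.
#' @return data frame with the standard columns and a `tags` column.
#' @export
read_gaf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (!length(lines)) {
    return(data.frame(name = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), path = character(0),
                      plen = integer(0), pstart = integer(0),
                      pend = integer(0), matches = integer(0),
                      block = integer(0), mapq = integer(0),
                      tags = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    name = vapply(f, `[[`, character(1), 1L),
    qlen = as.integer(vapply(f, `[[`, character(1), 2L)),
    qstart = as.integer(vapply(f, `[[`, character(1), 3L)),
    qend = as.integer(vapply(f, `[[`, character(1), 4L)),
    strand = vapply(f, `[[`, character(1), 5L),
    path = vapply(f, `[[`, character(1), 6L),
    plen = as.integer(vapply(f, `[[`, character(1), 7L)),
    pstart = as.integer(vapply(f, `[[`, character(1), 8L)),
    pend = as.integer(vapply(f, `[[`, character(1), 9L)),
    matches = as.integer(vapply(f, `[[`, character(1), 10L)),
    block = as.integer(vapply(f, `[[`, character(1), 11L)),
    mapq = as.integer(vapply(f, `[[`, character(1), 12L)),
    tags = vapply(f, function(x) {
      if (length(x) > 12L) paste(x[13:length(x)], collapse = "\t") else ""
    }, character(1)),
    stringsAsFactors = FALSE)
}
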