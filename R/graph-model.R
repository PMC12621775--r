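# Bidirected variation-graph data model and GFA I/O.
#
# A variation graph is a bidirected graph whose nodes carry DNA sequences and
# whose edges join node *sides* (left/right). Walks traverse nodes in an
# orientation: a forward visit spells the node sequence, a reverse visit its
# reverse complement. Named walks record the embedded haplotype (and
# reference) paths of the pangenome.

#' Construct a node side
#'
#' @param node positive integer node id.
#' @param side `"left"` or `"right"` (abbreviations `"L"`/`"R"` accepted).
#' @return A `node_side` object.
#' @export
node_side <- function(node, side) {
  side <- match.arg(toupper(substr(side, 1L, 1L)), c("L", "R"))
  structure(list(node = as.integer(node), side = side), class = "node_side")
}

#' @export
format.node_side <- function(x, ...) paste0(x$node, ".", x$side)
#' @export
print.node_side <- function(x, ...) cat(format(x), "\n")

#' Construct a graph position
#'
#' A position is a 0-based offset into the sequence of an oriented node.
#'
#' @param node positive integer node id.
#' @param orient `+1` (forward) or `-1` (reverse); `"+"`/`"-"` accepted.
#' @param offset 0-based offset into the oriented node sequence.
#' @return A `graph_pos` object.
#' @export
graph_pos <- function(node, orient, offset) {
  if (is.character(orient)) orient <- chr_orient(orient)
  structure(list(node = as.integer(node), orient = as.integer(orient),
                 offset = as.integer(offset)),
            class = "graph_pos")
}

#' @export
format.graph_pos <- function(x, ...) {
  paste0("(", x$node, ",", orient_chr(x$orient), ",", x$offset, ")")
}
#' @export
print.graph_pos <- function(x, ...) cat(format(x), "\n")

#' Construct a variation graph
#'
#' @param seqs named character vector of node sequences; names are positive
#'   integer node ids.
#' @param edges data frame with columns `node1`, `side1`, `node2`, `side2`
#'   (sides `"L"`/`"R"`); each row one biedged adjacency edge.
#' @param walks list of walks, each `list(name=, role=, nodes=, orients=)`
#'   with `role` one of `"reference"`, `"haplotype"`.
#' @param validate check structural invariants (default `TRUE`).
#' @return A `variation_graph` object.
#' @export
variation_graph <- function(seqs, edges = NULL, walks = list(), validate = TRUE) {
  nm <- names(seqs)
  seqs <- setNames(toupper(as.character(seqs)), nm)
  if (is.null(names(seqs))) stop("node sequences must be named by node id")
  ids <- as.integer(names(seqs))
  if (anyNA(ids) || any(ids <= 0L)) stop("node ids must be positive integers")
  names(seqs) <- as.character(ids)
  if (is.null(edges)) {
    edges <- data.frame(node1 = integer(0), side1 = character(0),
                        node2 = integer(0), side2 = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- canonical_edges(edges)
  g <- structure(list(seqs = seqs, edges = edges, walks = walks),
                 class = "variation_graph")
  if (validate) validate_graph(g)
  g
}

# Canonicalize edge table: (node1,side1) <= (node2,side2), dedupe.
canonical_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  edges$node1 <- as.integer(edges$node1); edges$node2 <- as.integer(edges$node2)
  swap <- edges$node1 > edges$node2 |
    (edges$node1 == edges$node2 & edges$side1 > edges$side2)
  tmp_n <- edges$node1[swap]; tmp_s <- edges$side1[swap]
  edges$node1[swap] <- edges$node2[swap]; edges$side1[swap] <- edges$side2[swap]
  edges$node2[swap] <- tmp_n; edges$side2[swap] <- tmp_s
  key <- paste(edges$node1, edges$side1, edges$node2, edges$side2)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

node_length <- function(graph, node) nchar(graph$seqs[as.character(node)])

# exit side of an oriented node / entry side
exit_side <- function(orient) ifelse(orient > 0L, "R", "L")
entry_side <- function(orient) ifelse(orient > 0L, "L", "R")

has_edge <- function(graph, n1, s1, n2, s2) {
  swap <- n1 > n2 | (n1 == n2 & s1 > s2)
  a_n <- ifelse(swap, n2, n1); a_s <- ifelse(swap, s2, s1)
  b_n <- ifelse(swap, n1, n2); b_s <- ifelse(swap, s1, s2)
  key <- paste(a_n, a_s, b_n, b_s)
  ekey <- paste(graph$edges$node1, graph$edges$side1,
                graph$edges$node2, graph$edges$side2)
  key %in% ekey
}

#' Validate a variation graph
#'
#' Checks node sequences, edge endpoints, and walk step consistency.
#' @param graph a `variation_graph`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_graph <- function(graph) {
  ids <- as.integer(names(graph$seqs))
  if (any(nchar(graph$seqs) == 0L)) {
    pm_stop("invalid_graph", "node sequences must be non-empty")
  }
  bad <- setdiff(unique(c(graph$edges$node1, graph$edges$node2)), ids)
  if (length(bad)) {
    pm_stop("invalid_graph", "edge references unknown node %s", bad[1])
  }
  for (w in graph$walks) validate_walk(graph, w)
  invisible(TRUE)
}

validate_walk <- function(graph, walk) {
  ids <- as.integer(names(graph$seqs))
  bad <- setdiff(walk$nodes, ids)
  if (length(bad)) {
    pm_stop("invalid_walk", "walk '%s' references unknown node %s",
            walk$name, bad[1])
  }
  k <- length(walk$nodes)
  if (k >= 2L) {
    n1 <- walk$nodes[-k]; o1 <- walk$orients[-k]
    n2 <- walk$nodes[-1]; o2 <- walk$orients[-1]
    ok <- has_edge(graph, n1, exit_side(o1), n2, entry_side(o2))
    if (!all(ok)) {
      pm_stop("broken_walk", "walk '%s': no edge joining steps %d and %d",
              walk$name, which(!ok)[1], which(!ok)[1] + 1L)
    }
  }
  invisible(TRUE)
}

#' Spell the sequence of a walk
#'
#' Concatenates oriented node sequences; reverse visits contribute the
#' reverse complement.
#'
#' @param graph a `variation_graph`.
#' @param walk a walk (element of `graph$walks` or a compatible list).
#' @return DNA string.
#' @export
walk_sequence <- function(graph, walk) {
  validate_walk(graph, walk)
  segs <- graph$seqs[as.character(walk$nodes)]
  rev_idx <- walk$orients < 0L
  if (any(rev_idx)) segs[rev_idx] <- revcomp(segs[rev_idx])
  paste0(segs, collapse = "")
}

#' Extract the base at a graph position
#'
#' @param graph a `variation_graph`.
#' @param pos a `graph_pos` (0-based offset on the oriented sequence).
#' @return Single character.
#' @export
extract_base <- function(graph, pos) {
  seq <- graph$seqs[[as.character(pos$node)]]
  if (is.null(seq) || is.na(seq)) pm_stop("bounds_error", "unknown node %d", pos$node)
  n <- nchar(seq)
  if (pos$offset < 0L || pos$offset >= n) {
    pm_stop("bounds_error", "offset %d out of range for node %d (length %d)",
            pos$offset, pos$node, n)
  }
  if (pos$orient > 0L) substr(seq, pos$offset + 1L, pos$offset + 1L)
  else substr(revcomp(seq), pos$offset + 1L, pos$offset + 1L)
}

#' Parse GFA v1
#'
#' Reads S lines (nodes), L lines (links; overlap must be `0M` or `*`), and
#' P/W lines (walks). L-line orientations are translated to side pairs:
#' `1 + 2 +` joins 1.right to 2.left; `1 + 2 -` joins 1.right to 2.right.
#' Walks whose name matches `reference_prefix` get role `"reference"`.
#'
#' @param text GFA text (single string or character vector of lines), or a
#'   file path.
#' @param reference_prefix regex; walk names matching it are reference paths.
#' @return A `variation_graph`.
#' @export
parse_gfa <- function(text, reference_prefix = "^(ref|GRCh|CHM)") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, `[[`, character(1), 1L)

  seqs <- character(0)
  for (i in which(types == "S")) {
    f <- fields[[i]]
    if (length(f) < 3L) pm_stop("gfa_parse_error", "line %d: malformed S line", i)
    seqs[f[2]] <- toupper(f[3])
  }
  ids <- names(seqs)

  e_n1 <- integer(0); e_s1 <- character(0); e_n2 <- integer(0); e_s2 <- character(0)
  for (i in which(types == "L")) {
    f <- fields[[i]]
    if (length(f) < 5L) pm_stop("gfa_parse_error", "line %d: malformed L line", i)
    if (length(f) >= 6L && !(f[6] %in% c("0M", "*"))) {
      pm_stop("gfa_unsupported_overlap",
              "line %d: unsupported overlap '%s' (only 0M/* handled)", i, f[6])
    }
    for (nd in c(f[2], f[4])) {
      if (!(nd %in% ids)) {
        pm_stop("gfa_parse_error", "line %d: L line references unknown node %s", i, nd)
      }
    }
    o1 <- chr_orient(f[3]); o2 <- chr_orient(f[5])
    e_n1 <- c(e_n1, as.integer(f[2])); e_s1 <- c(e_s1, exit_side(o1))
    e_n2 <- c(e_n2, as.integer(f[4])); e_s2 <- c(e_s2, entry_side(o2))
  }
  edges <- data.frame(node1 = e_n1, side1 = e_s1, node2 = e_n2, side2 = e_s2,
                      stringsAsFactors = FALSE)

  walks <- list()
  for (i in which(types == "P")) {
    f <- fields[[i]]
    if (length(f) < 3L) pm_stop("gfa_parse_error", "line %d: malformed P line", i)
    steps <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    nd <- sub("[+-]$", "", steps)
    missing_nd <- setdiff(nd, ids)
    if (length(missing_nd)) {
      pm_stop("gfa_parse_error", "line %d: P line references unknown node %s",
              i, missing_nd[1])
    }
    ori <- chr_orient(sub("^.*?([+-])$", "\\1", steps))
    role <- if (grepl(reference_prefix, f[2])) "reference" else "haplotype"
    walks[[length(walks) + 1L]] <-
      list(name = f[2], role = role, nodes = as.integer(nd), orients = ori)
  }
  for (i in which(types == "W")) {
    f <- fields[[i]]
    if (length(f) < 7L) pm_stop("gfa_parse_error", "line %d: malformed W line", i)
    toks <- regmatches(f[7], gregexpr("[<>][^<>]+", f[7]))[[1]]
    nd <- substring(toks, 2L)
    missing_nd <- setdiff(nd, ids)
    if (length(missing_nd)) {
      pm_stop("gfa_parse_error", "line %d: W line references unknown node %s",
              i, missing_nd[1])
    }
    ori <- ifelse(substr(toks, 1L, 1L) == ">", 1L, -1L)
    nm <- paste(f[2], f[3], f[4], sep = "#")
    role <- if (grepl(reference_prefix, nm)) "reference" else "haplotype"
    walks[[length(walks) + 1L]] <-
      list(name = nm, role = role, nodes = as.integer(nd), orients = ori)
  }
  variation_graph(seqs, edges, walks)
}

#' Write GFA v1
#'
#' Emits S, L (overlap 0M), and P lines. Inverse of [parse_gfa()] on node
#' sequences, edge sets, and walks.
#'
#' @param graph a `variation_graph`.
#' @param path output file path, or `NULL` to return the text.
#' @return The GFA text, invisibly when written to a file.
#' @export
write_gfa <- function(graph, path = NULL) {
  out <- c("H\tVN:Z:1.0")
  ids <- names(graph$seqs)[order(as.integer(names(graph$seqs)))]
  out <- c(out, sprintf("S\t%s\t%s", ids, graph$seqs[ids]))
  e <- graph$edges
  if (nrow(e)) {
    # edge (a,sa)-(b,sb): emit with 'a' leaving through sa
    o1 <- ifelse(e$side1 == "R", "+", "-")
    o2 <- ifelse(e$side2 == "L", "+", "-")
    out <- c(out, sprintf("L\t%d\t%s\t%d\t%s\t0M", e$node1, o1, e$node2, o2))
  }
  for (w in graph$walks) {
    steps <- paste0(w$nodes, orient_chr(w$orients), collapse = ",")
    out <- c(out, sprintf("P\t%s\t%s\t*", w$name, steps))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(txt)) }
  txt
}

#' Drop edges not supported by any walk
#'
#' Optional pruning mirroring the convention that embedded walks implicitly
#' define the usable edges of the graph.
#'
#' @param graph a `variation_graph`.
#' @return Graph with unsupported edges removed.
#' @export
prune_unsupported_edges <- function(graph) {
  used <- character(0)
  for (w in graph$walks) {
    k <- length(w$nodes)
    if (k < 2L) next
    n1 <- w$nodes[-k]; o1 <- w$orients[-k]
    n2 <- w$nodes[-1]; o2 <- w$orients[-1]
    s1 <- exit_side(o1); s2 <- entry_side(o2)
    swap <- n1 > n2 | (n1 == n2 & s1 > s2)
    key <- ifelse(swap, paste(n2, s2, n1, s1), paste(n1, s1, n2, s2))
    used <- c(used, key)
  }
  ekey <- paste(graph$edges$node1, graph$edges$side1,
                graph$edges$node2, graph$edges$side2)
  graph$edges <- graph$edges[ekey %in% used, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Canonical toy graphs
#'
#' Three small graphs reused throughout the package's tests and examples:
#' `"bubble"` (a SNP-like bubble with two alleles), `"inversion"` (a segment
#' traversable in either orientation), and `"loop"` (a node with a
#' back-edge, traversable repeatedly).
#'
#' @param which `"bubble"`, `"inversion"`, or `"loop"`.
#' @return A `variation_graph` with embedded haplotype walks.
#' @export
example_graph <- function(which = c("bubble", "inversion", "loop")) {
  which <- match.arg(which)
  gfa <- switch(which,
    bubble = paste(sep = "\n",
      "S\t1\tGATT", "S\t2\tA", "S\t3\tC", "S\t4\tACA",
      "L\t1\t+\t2\t+\t0M", "L\t1\t+\t3\t+\t0M",
      "L\t2\t+\t4\t+\t0M", "L\t3\t+\t4\t+\t0M",
      "P\thapA\t1+,2+,4+\t*", "P\thapB\t1+,3+,4+\t*"),
    inversion = paste(sep = "\n",
      "S\t1\tGAT", "S\t2\tTTG", "S\t3\tCA",
      "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
      "L\t1\t+\t2\t-\t0M", "L\t2\t-\t3\t+\t0M",
      "P\thapA\t1+,2+,3+\t*", "P\thapB\t1+,2-,3+\t*"),
    loop = paste(sep = "\n",
      "S\t1\tGAT", "S\t2\tCGA", "S\t3\tTT",
      "L\t1\t+\t2\t+\t0M", "L\t2\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
      "P\thapA\t1+,2+,3+\t*", "P\thapB\t1+,2+,2+,3+\t*")
  )
  parse_gfa(gfa)
}

#' Read sequencing reads from FASTA/FASTQ
#'
#' @param path file path (plain or gzipped FASTA/FASTQ).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
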