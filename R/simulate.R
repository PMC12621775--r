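# Synthetic pangenome and long-read simulation, and mapping evaluation.
#
# The generator applies variant events (SNPs, indels, inversions, tandem
# duplications) to a random backbone, materializes per-haplotype walks that
# pick an allele at each site, and derives the edge set from the walks, so
# every generated graph is walk-supported and decomposes cleanly.

#' Parameters for the pangenome simulator
#'
#' @param backbone_len backbone length in bp.
#' @param snp_rate per-base SNP site rate.
#' @param indel_rate per-base indel site rate.
#' @param indel_len_max maximum indel length (lengths uniform on 1..max).
#' @param n_inversions,inversion_len number and length of inversion events.
#' @param n_duplications,duplication_len number and length of tandem
#'   duplication events (represented as a back-edge; carriers traverse the
#'   segment twice).
#' @param n_haplotypes number of haplotype walks (a reference walk is always
#'   added as well).
#' @param seed RNG seed (integer).
#' @return A `graph_sim_params` list.
#' @export
graph_sim_params <- function(backbone_len = 100000L, snp_rate = 0.002,
                             indel_rate = 2e-4, indel_len_max = 20L,
                             n_inversions = 1L, inversion_len = 2000L,
                             n_duplications = 1L, duplication_len = 800L,
                             n_haplotypes = 20L, seed = 1L) {
  stopifnot(backbone_len > 0, snp_rate >= 0, snp_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_len_max >= 1,
            n_inversions >= 0, inversion_len >= 1,
            n_duplications >= 0, duplication_len >= 1, n_haplotypes >= 1)
  structure(as.list(environment()), class = "graph_sim_params")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pangenome variation graph
#'
#' @param params a [graph_sim_params()] list.
#' @return A `variation_graph` with `n_haplotypes` haplotype walks plus one
#'   reference walk.
#' @export
simulate_graph <- function(params = graph_sim_params()) {
  with_seed(params$seed, simulate_graph_impl(params))
}

simulate_graph_impl <- function(p) {
  L <- p$backbone_len
  backbone <- strsplit(random_dna(L), "")[[1]]

  # --- draw non-overlapping events -------------------------------------
  n_snp <- rbinom(1L, L, p$snp_rate)
  n_ind <- rbinom(1L, L, p$indel_rate)
  ev <- data.frame(pos = integer(0), len = integer(0), type = character(0),
                   stringsAsFactors = FALSE)
  margin <- max(5L, min(10L, L %/% 20L))
  add_events <- function(ev, n, type, len_fun) {
    for (i in seq_len(n)) {
      ln <- len_fun()
      placed <- FALSE
      for (try in 1:200) {
        pos <- margin + sample.int(L - ln - 2L * margin + 1L, 1L) - 1L
        if (!nrow(ev) ||
            all(pos + ln + 1L < ev$pos | pos > ev$pos + ev$len + 1L)) {
          ev <- rbind(ev, data.frame(pos = pos, len = ln, type = type,
                                     stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        pm_stop("generation_error",
                "cannot place %s event without overlap; reduce rates", type)
      }
    }
    ev
  }
  ev <- add_events(ev, p$n_inversions, "INV", function() p$inversion_len)
  ev <- add_events(ev, p$n_duplications, "DUP", function() p$duplication_len)
  ev <- add_events(ev, n_ind, "INDEL", function() sample(p$indel_len_max, 1L))
  ev <- add_events(ev, n_snp, "SNP", function() 1L)
  ev <- ev[order(ev$pos), , drop = FALSE]
  if (nrow(ev)) {
    ev$sub <- ifelse(ev$type == "INDEL",
                     sample(c("INS", "DEL"), nrow(ev), replace = TRUE), ev$type)
  } else ev$sub <- character(0)

  # --- materialize nodes and sites -------------------------------------
  seqs <- character(0)
  next_id <- 1L
  new_node <- function(seq) {
    id <- next_id
    seqs[as.character(id)] <<- seq
    next_id <<- next_id + 1L
    id
  }
  # item: list(kind = "plain"/"site", ...)
  items <- list()
  cur <- 1L
  for (r in seq_len(nrow(ev))) {
    pos <- ev$pos[r]; ln <- ev$len[r]; ty <- ev$sub[r]
    seg_end <- if (ty == "INS") pos else pos - 1L
    if (seg_end >= cur) {
      items[[length(items) + 1L]] <-
        list(kind = "plain",
             node = new_node(paste0(backbone[cur:seg_end], collapse = "")))
    }
    freq <- runif(1L, 0.15, 0.85)
    if (ty == "SNP") {
      ref_b <- backbone[pos]
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      items[[length(items) + 1L]] <-
        list(kind = "site", type = "SNP", freq = freq,
             ref_node = new_node(ref_b), alt_node = new_node(alt_b))
      cur <- pos + 1L
    } else if (ty == "DEL") {
      seg <- paste0(backbone[pos:(pos + ln - 1L)], collapse = "")
      items[[length(items) + 1L]] <-
        list(kind = "site", type = "DEL", freq = freq, node = new_node(seg))
      cur <- pos + ln
    } else if (ty == "INS") {
      items[[length(items) + 1L]] <-
        list(kind = "site", type = "INS", freq = freq,
             node = new_node(random_dna(ln)))
      cur <- pos + 1L
    } else if (ty == "INV") {
      seg <- paste0(backbone[pos:(pos + ln - 1L)], collapse = "")
      items[[length(items) + 1L]] <-
        list(kind = "site", type = "INV", freq = freq, node = new_node(seg))
      cur <- pos + ln
    } else {  # DUP
      seg <- paste0(backbone[pos:(pos + ln - 1L)], collapse = "")
      items[[length(items) + 1L]] <-
        list(kind = "site", type = "DUP", freq = freq, node = new_node(seg))
      cur <- pos + ln
    }
  }
  if (cur <= L) {
    items[[length(items) + 1L]] <-
      list(kind = "plain", node = new_node(paste0(backbone[cur:L], collapse = "")))
  }

  # --- haplotype walks ---------------------------------------------------
  H <- p$n_haplotypes
  walks <- vector("list", H + 1L)
  carrier <- lapply(items, function(it) {
    if (it$kind == "site") runif(H) < it$freq else NULL
  })
  for (h in seq_len(H + 1L)) {
    nodes <- integer(0); orients <- integer(0)
    for (t in seq_along(items)) {
      it <- items[[t]]
      if (it$kind == "plain") {
        nodes <- c(nodes, it$node); orients <- c(orients, 1L)
        next
      }
      carries <- h <= H && carrier[[t]][h]
      if (it$type == "SNP") {
        nodes <- c(nodes, if (carries) it$alt_node else it$ref_node)
        orients <- c(orients, 1L)
      } else if (it$type == "DEL") {
        if (!carries) { nodes <- c(nodes, it$node); orients <- c(orients, 1L) }
      } else if (it$type == "INS") {
        if (carries) { nodes <- c(nodes, it$node); orients <- c(orients, 1L) }
      } else if (it$type == "INV") {
        nodes <- c(nodes, it$node)
        orients <- c(orients, if (carries) -1L else 1L)
      } else {  # DUP
        nodes <- c(nodes, it$node); orients <- c(orients, 1L)
        if (carries) { nodes <- c(nodes, it$node); orients <- c(orients, 1L) }
      }
    }
    nm <- if (h <= H) sprintf("hap%02d", h) else "ref"
    walks[[h]] <- list(name = nm,
                       role = if (h <= H) "haplotype" else "reference",
                       nodes = nodes, orients = orients)
  }

  # --- edges derived from walks -----------------------------------------
  e_n1 <- integer(0); e_s1 <- character(0); e_n2 <- integer(0); e_s2 <- character(0)
  for (w in walks) {
    k <- length(w$nodes)
    if (k < 2L) next
    n1 <- w$nodes[-k]; o1 <- w$orients[-k]
    n2 <- w$nodes[-1]; o2 <- w$orients[-1]
    e_n1 <- c(e_n1, n1); e_s1 <- c(e_s1, exit_side(o1))
    e_n2 <- c(e_n2, n2); e_s2 <- c(e_s2, entry_side(o2))
  }
  edges <- data.frame(node1 = e_n1, side1 = e_s1, node2 = e_n2, side2 = e_s2,
                      stringsAsFactors = FALSE)
  variation_graph(seqs, edges, walks)
}

#' Parameters for the read simulator
#'
#' Two presets mirror common long-read error profiles: `"hifi"` (~0.5% total
#' error) and `"ont"` (~5% total error).
#'
#' @param n_reads number of reads.
#' @param len_min,len_max read length range (uniform).
#' @param sub_rate,ins_rate,del_rate per-base error rates.
#' @param preset optional `"hifi"` or `"ont"`; overrides the three rates.
#' @param seed RNG seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(n_reads = 100L, len_min = 1000L, len_max = 10000L,
                            sub_rate = 0.003, ins_rate = 0.001,
                            del_rate = 0.001, preset = NULL, seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("hifi", "ont"))
    if (preset == "hifi") { sub_rate <- 0.003; ins_rate <- 0.001; del_rate <- 0.001 }
    else { sub_rate <- 0.03; ins_rate <- 0.01; del_rate <- 0.01 }
  }
  stopifnot(n_reads >= 1, len_min >= 1, len_max >= len_min,
            sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1)
  structure(list(n_reads = as.integer(n_reads), len_min = as.integer(len_min),
                 len_max = as.integer(len_max), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate, seed = seed),
            class = "read_sim_params")
}

#' Simulate reads from the haplotype walks of a graph
#'
#' Reads are drawn uniformly over haplotypes, start positions and strands;
#' substitution/insertion/deletion errors are injected at the configured
#' rates. Truth records hold the source interval on the haplotype.
#'
#' @param graph a `variation_graph` with haplotype walks.
#' @param params a [read_sim_params()] list.
#' @return `list(reads = named character vector, truth = data.frame)` with
#'   truth columns name, hap, start, end (0-based half-open on the haplotype
#'   sequence), strand.
#' @export
simulate_reads <- function(graph, params = read_sim_params()) {
  haps <- Filter(function(w) w$role == "haplotype", graph$walks)
  if (!length(haps)) pm_stop("parameter_error", "graph has no haplotype walks")
  hap_seqs <- vapply(haps, function(w) walk_sequence(graph, w), character(1))
  names(hap_seqs) <- vapply(haps, `[[`, character(1), "name")
  with_seed(params$seed, {
    n <- params$n_reads
    reads <- character(n); nms <- sprintf("read%05d", seq_len(n))
    truth <- data.frame(name = nms, hap = character(n), start = integer(n),
                        end = integer(n), strand = character(n),
                        stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      ln <- params$len_min +
        sample.int(params$len_max - params$len_min + 1L, 1L) - 1L
      hi <- sample(length(hap_seqs), 1L)
      hl <- nchar(hap_seqs[hi])
      if (ln > hl) {
        warning(sprintf("read %d longer than haplotype; truncating", i))
        ln <- hl
      }
      st <- sample(hl - ln + 1L, 1L)  # 1-based
      frag <- substr(hap_seqs[hi], st, st + ln - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") frag <- revcomp(frag)
      ch <- strsplit(frag, "")[[1]]
      op <- sample(c("M", "S", "I", "D"), ln, replace = TRUE,
                   prob = c(1 - params$sub_rate - params$ins_rate - params$del_rate,
                            params$sub_rate, params$ins_rate, params$del_rate))
      keep <- op != "D"
      out <- ch
      sub_idx <- which(op == "S")
      if (length(sub_idx)) {
        out[sub_idx] <- vapply(ch[sub_idx], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      pieces <- out
      ins_idx <- which(op == "I")
      if (length(ins_idx)) {
        pieces[ins_idx] <- paste0(pieces[ins_idx],
                                  sample(bases, length(ins_idx), replace = TRUE))
      }
      reads[i] <- paste0(pieces[keep], collapse = "")
      truth$hap[i] <- names(hap_seqs)[hi]
      truth$start[i] <- st - 1L
      truth$end[i] <- st - 1L + ln
      truth$strand[i] <- strand
    }
    names(reads) <- nms
    list(reads = reads, truth = truth)
  })
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @param qual constant quality character.
#' @return Invisibly `path`.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n) {
    paste(rep(qual, n), collapse = "")
  }, character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(reads), q)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write truth records as TSV
#' @param truth truth data frame from [simulate_reads()].
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Occurrence offsets (0-based starts) of each oriented node on a haplotype
# walk sequence.
walk_node_offsets <- function(graph, walk) {
  lens <- nchar(graph$seqs[as.character(walk$nodes)])
  starts <- cumsum(c(0L, lens[-length(lens)]))
  data.frame(node = walk$nodes, orient = walk$orients, start = starts,
             len = as.integer(lens))
}

#' Evaluate mappings against simulation truth
#'
#' A read counts as correct when its reported graph interval, projected onto
#' the source haplotype, overlaps the truth interval by at least
#' `min_overlap` of the truth length. Results are stratified by MAPQ.
#'
#' @param gaf GAF records as parsed by [read_gaf()], or a path to a GAF file.
#' @param truth truth data frame from [simulate_reads()].
#' @param graph the `variation_graph` mapped against (needed to project graph
#'   intervals onto haplotype walks).
#' @param min_overlap required overlap fraction of the truth interval.
#' @return `list(per_read = data.frame, roc = data.frame, summary = list)`;
#'   `roc` has one row per MAPQ bin with cumulative correct/incorrect counts.
#' @export
evaluate_mappings <- function(gaf, truth, graph, min_overlap = 0.5) {
  if (is.character(gaf) && length(gaf) == 1L) gaf <- read_gaf(gaf)
  if (!all(gaf$name %in% truth$name)) {
    pm_stop("evaluation_error", "GAF contains read names absent from truth")
  }
  haps <- Filter(function(w) w$role == "haplotype", graph$walks)
  names(haps) <- vapply(haps, `[[`, character(1), "name")
  offs <- lapply(haps, function(w) walk_node_offsets(graph, w))

  per <- data.frame(name = truth$name, mapq = NA_integer_,
                    correct = FALSE, mapped = FALSE, stringsAsFactors = FALSE)
  rownames(per) <- truth$name
  prim <- gaf[!grepl("tp:A:S", gaf$tags %||% "", fixed = TRUE), , drop = FALSE]
  prim <- prim[!duplicated(prim$name), , drop = FALSE]
  for (r in seq_len(nrow(prim))) {
    nm <- prim$name[r]
    ti <- truth[truth$name == nm, ]
    per[nm, "mapped"] <- TRUE
    per[nm, "mapq"] <- prim$mapq[r]
    path_nodes <- parse_gaf_path(prim$path[r])$node
    off <- offs[[ti$hap]]
    hits <- off[off$node %in% path_nodes, , drop = FALSE]
    if (!nrow(hits)) next
    # candidate projected intervals from node occurrences; credit the read
    # if any projection overlaps the truth interval enough (duplicated nodes
    # project ambiguously)
    tlen <- ti$end - ti$start
    cand_s <- hits$start
    cand_e <- hits$start + hits$len
    ov <- pmin(cand_e, ti$end) - pmax(cand_s, ti$start)
    covered <- sum(pmax(ov, 0))  # crude union bound; refine below
    # exact union of overlaps
    sel <- ov > 0
    if (any(sel)) {
      iv <- cbind(pmax(cand_s[sel], ti$start), pmin(cand_e[sel], ti$end))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      tot <- 0; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
      if (nrow(iv) > 1) for (q in 2:nrow(iv)) {
        if (iv[q, 1] <= cur_e) cur_e <- max(cur_e, iv[q, 2])
        else { tot <- tot + cur_e - cur_s; cur_s <- iv[q, 1]; cur_e <- iv[q, 2] }
      }
      tot <- tot + cur_e - cur_s
      covered <- tot
    } else covered <- 0
    per[nm, "correct"] <- covered >= min_overlap * tlen
  }

  bins <- sort(unique(per$mapq[per$mapped]), decreasing = TRUE)
  roc <- data.frame(mapq = bins,
                    n = vapply(bins, function(q) sum(per$mapped & per$mapq == q), integer(1)),
                    correct = vapply(bins, function(q) sum(per$correct & per$mapq == q), integer(1)))
  roc$incorrect <- roc$n - roc$correct
  roc$cum_n <- cumsum(roc$n)
  roc$cum_incorrect <- cumsum(roc$incorrect)
  roc$incorrect_frac <- ifelse(roc$n > 0, roc$incorrect / roc$n, 0)
  summary <- list(
    n_reads = nrow(truth),
    n_mapped = sum(per$mapped),
    n_correct = sum(per$correct),
    frac_correct_mapq30 = {
      sel <- per$mapped & per$mapq >= 30
      if (any(sel)) sum(per$correct[sel]) / nrow(truth) else 0
    },
    mapq60_error = {
      sel <- per$mapped & per$mapq >= 60
      if (any(sel)) 1 - sum(per$correct[sel]) / sum(sel) else NA_real_
    })
  list(per_read = per, roc = roc, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ROC table as TSV
#' @param roc ROC data frame from [evaluate_mappings()].
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_roc <- function(roc, path) {
  write.table(roc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
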