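# Joint tumor/normal/reference colored de Bruijn graph assembly for one
# window: k selection, graph construction, cleaning, and haplotype path
# enumeration by capacity-constrained shortest-path extraction.

sg_error <- function(class, msg) {
  stop(structure(class = c(class, "somagraph_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Select the k-mer size for a window
#'
#' Returns the smallest odd k in `[k_min, k_max]` such that no k-mer occurs
#' twice on the forward strand of the reference window, so that the reference
#' spells a simple path through the graph.
#'
#' @param ref_window Reference sequence of the window.
#' @param k_min,k_max,step Candidate grid; `k_min` odd, `step` even.
#' @return Selected k.
#' @export
select_k <- function(ref_window, k_min = 11L, k_max = 101L, step = 2L) {
  stopifnot(k_min %% 2 == 1, step %% 2 == 0, step > 0)
  for (k in seq(k_min, min(k_max, nchar(ref_window)), by = step)) {
    if (!anyDuplicated(kmerize(ref_window, k))) return(as.integer(k))
  }
  sg_error("no_usable_k", "no k without repeated reference k-mers in window")
}

count_kmers <- function(seqs, k) {
  km <- kmerize(seqs, k)
  km <- km[!stringi::stri_detect_regex(km, "[^ACGT]")]
  if (length(km) == 0) return(integer(0))
  table(km)
}

#' Build the joint colored de Bruijn graph for a window
#'
#' Nodes are the union of k-mers from the reference window and from both
#' samples' reads (bases below `min_base_q` break a read into fragments);
#' per-color counts accumulate per occurrence. Edges carry traversal counts
#' (equivalently, (k+1)-mer counts). Read sequences are taken in reference
#' orientation (as stored in the BAM), so no strand folding is applied.
#'
#' @param tumor_reads,normal_reads Read frames from [load_reads()].
#' @param ref_window Reference window sequence.
#' @param k K-mer size from [select_k()].
#' @param min_base_q Minimum base quality for k-mer contribution.
#' @return Object of class `colored_dbg`.
#' @export
build_graph <- function(tumor_reads, normal_reads, ref_window, k,
                        min_base_q = 10L) {
  frag_t <- split_by_quality(tumor_reads$sequence, tumor_reads$qual,
                             min_base_q, k)
  frag_n <- split_by_quality(normal_reads$sequence, normal_reads$qual,
                             min_base_q, k)
  ref_nodes <- kmerize(ref_window, k)
  nt <- count_kmers(frag_t, k)
  nn <- count_kmers(frag_n, k)
  node_ids <- sort(unique(c(ref_nodes, names(nt), names(nn))))
  nodes <- data.frame(
    kmer = node_ids,
    tumor = as.integer(nt[node_ids]),
    normal = as.integer(nn[node_ids]),
    on_ref = node_ids %in% ref_nodes,
    stringsAsFactors = FALSE)
  nodes$tumor[is.na(nodes$tumor)] <- 0L
  nodes$normal[is.na(nodes$normal)] <- 0L
  et <- count_kmers(frag_t, k + 1L)
  en <- count_kmers(frag_n, k + 1L)
  ref_edges <- kmerize(ref_window, k + 1L)
  er <- table(ref_edges)
  edge_ids <- sort(unique(c(names(et), names(en), names(er))))
  ecnt <- function(tab) {
    x <- as.integer(tab[edge_ids])
    x[is.na(x)] <- 0L
    x
  }
  edges <- data.frame(
    from = substring(edge_ids, 1L, k),
    to = substring(edge_ids, 2L, k + 1L),
    tumor = ecnt(et), normal = ecnt(en), ref = ecnt(er),
    stringsAsFactors = FALSE)
  edges$on_ref <- edges$ref > 0L
  edges$count <- edges$tumor + edges$normal + edges$ref
  # edges require both endpoints to exist as nodes (always true by
  # construction, since every (k+1)-mer's two k-mers were also counted)
  g <- list(k = as.integer(k), nodes = nodes, edges = edges,
            source = ref_nodes[1], sink = ref_nodes[length(ref_nodes)],
            ref_path = ref_nodes, ref_window = ref_window)
  class(g) <- "colored_dbg"
  g
}

node_degrees <- function(g) {
  indeg <- table(g$edges$to)
  outdeg <- table(g$edges$from)
  list(indeg = stats::setNames(as.integer(indeg[g$nodes$kmer]), g$nodes$kmer),
       outdeg = stats::setNames(as.integer(outdeg[g$nodes$kmer]),
                                g$nodes$kmer))
}

drop_nodes <- function(g, kill) {
  if (length(kill) == 0) return(g)
  g$nodes <- g$nodes[!g$nodes$kmer %in% kill, , drop = FALSE]
  g$edges <- g$edges[!(g$edges$from %in% kill | g$edges$to %in% kill), ,
                     drop = FALSE]
  g
}

#' Clean a colored de Bruijn graph
#'
#' Iterates to a fixpoint: (1) remove non-reference nodes whose combined
#' tumor+normal count is below `min_node_cov`; (2) remove dead-end branches
#' ("tips") of at most `max_tip_len` nodes that do not terminate at the
#' source/sink. Reference-path nodes are never removed, so the cleaned graph
#' still spells the reference window.
#'
#' @param graph A `colored_dbg`.
#' @param min_node_cov Minimum read support to keep a non-reference node.
#' @param max_tip_len Maximum tip length in nodes (default `k`).
#' @return Cleaned `colored_dbg`.
#' @export
clean_graph <- function(graph, min_node_cov = 2L, max_tip_len = graph$k) {
  repeat {
    n_before <- nrow(graph$nodes)
    low <- graph$nodes$kmer[!graph$nodes$on_ref &
                              graph$nodes$tumor + graph$nodes$normal <
                                min_node_cov]
    graph <- drop_nodes(graph, low)
    graph <- trim_tips(graph, max_tip_len)
    if (nrow(graph$nodes) == n_before) break
  }
  graph
}

trim_tips <- function(g, max_tip_len) {
  repeat {
    deg <- node_degrees(g)
    indeg <- deg$indeg
    outdeg <- deg$outdeg
    indeg[is.na(indeg)] <- 0L
    outdeg[is.na(outdeg)] <- 0L
    removable <- character(0)
    for (dir in c("fwd", "rev")) {
      if (dir == "fwd") {
        tips <- g$nodes$kmer[!g$nodes$on_ref & indeg[g$nodes$kmer] == 0L]
        nxt <- function(x) g$edges$to[g$edges$from == x]
        deg_in <- function(x) indeg[[x]]
      } else {
        tips <- g$nodes$kmer[!g$nodes$on_ref & outdeg[g$nodes$kmer] == 0L]
        nxt <- function(x) g$edges$from[g$edges$to == x]
        deg_in <- function(x) outdeg[[x]]
      }
      for (t in tips) {
        chain <- t
        cur <- t
        ok <- TRUE
        repeat {
          nb <- nxt(cur)
          nb <- nb[!nb %in% chain]
          if (length(nb) == 0) break  # isolated dead end
          if (length(nb) > 1) { ok <- FALSE; break }
          if (g$nodes$on_ref[match(nb, g$nodes$kmer)] ||
              deg_in(nb) > 1L) break  # reached the trunk
          chain <- c(chain, nb)
          cur <- nb
          if (length(chain) > max_tip_len) { ok <- FALSE; break }
        }
        if (ok && length(chain) <= max_tip_len) {
          removable <- c(removable, chain)
        }
      }
    }
    removable <- unique(removable)
    if (length(removable) == 0) break
    g <- drop_nodes(g, removable)
  }
  g
}

#' Enumerate haplotype paths from a cleaned graph
#'
#' Iterative shortest-path extraction in the style of Edmonds-Karp BFS
#' augmentation: each round extracts the BFS-shortest source-to-sink path
#' that traverses at least one not-yet-used edge (ties broken by higher
#' minimum edge support, then lexicographically smaller k-mers) and marks its
#' edges used. A path's edge "capacity" (its read traversal count, reference
#' edges floored at 1) is consumed on first use; requiring fresh capacity in
#' every augmenting path guarantees distinct haplotypes and termination.
#' Stops when no source-to-sink path with unused capacity remains; raises a
#' `too_many_paths` condition if such a path still exists after `max_paths`
#' extractions.
#'
#' @param graph A cleaned `colored_dbg` with reachable sink.
#' @param max_paths Maximum number of path extractions.
#' @return List of `list(nodes, contig, min_edge_support)`, distinct contigs.
#' @export
enumerate_paths <- function(graph, max_paths = 16L) {
  nodes <- graph$nodes$kmer
  nid <- stats::setNames(seq_along(nodes), nodes)
  nn <- length(nodes)
  from <- unname(nid[graph$edges$from])
  to <- unname(nid[graph$edges$to])
  support <- graph$edges$count
  used <- rep(FALSE, length(from))
  src <- nid[[graph$source]]
  snk <- nid[[graph$sink]]
  k <- graph$k
  in_edges <- split(seq_along(to), to)
  out_edges <- split(seq_along(from), from)
  paths <- list()
  seen <- character(0)
  n_cyclic <- 0L
  for (iter in seq_len(max_paths + 1L)) {
    # BFS on the product graph (node, reached-via-unused-edge?); states
    # 1..nn = not yet via unused, nn+1..2nn = via >= 1 unused edge
    dist <- rep(NA_integer_, 2L * nn)
    dist[src] <- 0L
    frontier <- src
    target <- nn + snk
    while (length(frontier) > 0 && is.na(dist[target])) {
      nxt <- integer(0)
      for (s in frontier) {
        v <- if (s > nn) s - nn else s
        flagged <- s > nn
        es <- out_edges[[as.character(v)]]
        if (is.null(es)) next
        w <- to[es]
        ns <- ifelse(flagged | !used[es], w + nn, w)
        new <- is.na(dist[ns])
        dist[ns[new]] <- dist[s] + 1L
        nxt <- c(nxt, ns[new])
      }
      frontier <- unique(nxt)
    }
    if (is.na(dist[target])) break
    if (iter > max_paths) {
      sg_error("too_many_paths",
               "more haplotype paths than max_paths in window")
    }
    # widest (max-min original support) DP over the BFS shortest-path DAG
    wid <- rep(-Inf, 2L * nn)
    wid[src] <- Inf
    ord <- order(dist, na.last = NA)
    for (s in ord) {
      if (s == src) next
      v <- if (s > nn) s - nn else s
      flagged <- s > nn
      es <- in_edges[[as.character(v)]]
      if (is.null(es)) next
      # predecessor states consistent with this state's flag
      cand_states <- if (flagged) {
        # via unused edge from either state, or used edge from flagged state
        c(ifelse(used[es], NA_integer_, from[es]), from[es] + nn)
      } else {
        ifelse(used[es], from[es], NA_integer_)
      }
      cand_edges <- c(es, if (flagged) es)
      keep <- !is.na(cand_states) & !is.na(dist[cand_states]) &
        dist[cand_states] == dist[s] - 1L
      if (!any(keep)) next
      wid[s] <- max(pmin(wid[cand_states[keep]],
                         pmax(support[cand_edges[keep]], 1L)))
    }
    need <- wid[target]
    # backward reconstruction; lexicographically smallest predecessor k-mer
    path_edges <- integer(0)
    cur <- target
    while (cur != src) {
      v <- if (cur > nn) cur - nn else cur
      flagged <- cur > nn
      es <- in_edges[[as.character(v)]]
      cand_states <- if (flagged) {
        c(ifelse(used[es], NA_integer_, from[es]), from[es] + nn)
      } else {
        ifelse(used[es], from[es], NA_integer_)
      }
      cand_edges <- c(es, if (flagged) es)
      keep <- which(!is.na(cand_states) & !is.na(dist[cand_states]) &
                      dist[cand_states] == dist[cur] - 1L &
                      pmin(wid[cand_states],
                           pmax(support[cand_edges], 1L)) >= need)
      sel <- keep[order(nodes[from[cand_edges[keep]]])][1]
      path_edges <- c(cand_edges[sel], path_edges)
      cur <- cand_states[sel]
    }
    path <- c(from[path_edges[1]], to[path_edges])
    # a k-mer repeat can make the graph cyclic; the two-state BFS may then
    # traverse a node once per state. Such non-simple paths are not
    # haplotypes: consume their capacity and move on.
    if (anyDuplicated(path)) {
      used[path_edges] <- TRUE
      n_cyclic <- n_cyclic + 1L
      next
    }
    contig <- paste0(nodes[path[1]],
                     paste(substring(nodes[path[-1]], k, k), collapse = ""))
    if (!contig %in% seen) {
      seen <- c(seen, contig)
      paths[[length(paths) + 1L]] <- list(
        nodes = nodes[path], contig = contig,
        min_edge_support = min(support[path_edges]))
    }
    used[path_edges] <- TRUE
  }
  attr(paths, "n_cyclic") <- n_cyclic
  paths
}
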