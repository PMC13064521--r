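# GFA v1 export of the local POA variant graph.
#
# Dialect: every segment is a maximal unbranched node run, all orientations
# are "+", overlaps are "0M", and one P-line per traversal: the reference
# path is named "ref" and contig paths "hap1".."hapN". Spelling a path
# (concatenating its segments) reproduces the source sequence exactly.

#' Convert a POA MSA graph to a GFA graph
#'
#' Compresses maximal unbranched runs of POA nodes into segments; run breaks
#' are placed at branch points and at the first/last node of any traversal so
#' every path enters segments at their head.
#'
#' @param msa A `poa_msa`.
#' @return Object of class `gfa_graph`: `segments` (named character vector),
#'   `links` (data.frame from, from_orient, to, to_orient, overlap), `paths`
#'   (named list of segment-id vectors).
#' @export
msa_to_gfa <- function(msa) {
  g <- msa$graph
  n <- length(g$node_base)
  from <- g$edges[, 1]
  to <- g$edges[, 2]
  indeg <- tabulate(to, n)
  outdeg <- tabulate(from, n)
  # unique successor/predecessor per node (valid only where degree == 1)
  succ_map <- as.integer(stats::setNames(to, from)[as.character(seq_len(n))])
  pred_map <- as.integer(stats::setNames(from, to)[as.character(seq_len(n))])
  is_start <- indeg != 1L
  # nodes whose single predecessor branches also start a new run
  one_pred <- which(indeg == 1L)
  is_start[one_pred[outdeg[pred_map[one_pred]] != 1L]] <- TRUE
  # run breaks at the first node of any traversal and after its last node,
  # so every path enters and leaves segments at their boundaries
  for (p in g$row_paths) {
    if (length(p) > 0) {
      is_start[p[1]] <- TRUE
      last <- p[length(p)]
      if (outdeg[last] == 1L && !is.na(succ_map[last])) {
        is_start[succ_map[last]] <- TRUE
      }
    }
  }
  # build runs
  seg_of <- rep(NA_integer_, n)
  seg_nodes <- list()
  starts <- which(is_start)
  # deterministic segment order: by order of appearance along row paths
  appearance <- unique(unlist(g$row_paths, use.names = FALSE))
  starts <- starts[order(match(starts, appearance))]
  for (s in starts) {
    if (!is.na(seg_of[s])) next
    run <- s
    cur <- s
    repeat {
      if (outdeg[cur] != 1L) break
      nxt <- succ_map[cur]
      if (is.na(nxt) || is_start[nxt] || !is.na(seg_of[nxt])) break
      run <- c(run, nxt)
      cur <- nxt
    }
    id <- length(seg_nodes) + 1L
    seg_nodes[[id]] <- run
    seg_of[run] <- id
  }
  if (any(is.na(seg_of))) stop("GFA compression left orphan nodes")
  seg_names <- paste0("s", seq_along(seg_nodes))
  segments <- stats::setNames(vapply(seg_nodes, function(run) {
    paste(g$node_base[run], collapse = "")
  }, character(1)), seg_names)
  # links between segment boundaries
  link_rows <- unique(data.frame(
    from = seg_names[seg_of[from]], to = seg_names[seg_of[to]],
    stringsAsFactors = FALSE)[seg_of[from] != seg_of[to], , drop = FALSE])
  nl <- nrow(link_rows)
  links <- data.frame(from = link_rows$from,
                      from_orient = rep("+", nl),
                      to = link_rows$to, to_orient = rep("+", nl),
                      overlap = rep("0M", nl), stringsAsFactors = FALSE)
  links <- links[order(links$from, links$to), , drop = FALSE]
  rownames(links) <- NULL
  # paths: each row path as its sequence of segment heads
  paths <- lapply(g$row_paths, function(p) {
    segs <- seg_of[p]
    heads <- segs[c(TRUE, diff(segs) != 0)]
    # verify full traversal
    expect <- unlist(seg_nodes[heads], use.names = FALSE)
    if (!identical(expect, p)) stop("path does not traverse whole segments")
    seg_names[heads]
  })
  gfa <- list(segments = segments, links = links, paths = paths)
  class(gfa) <- "gfa_graph"
  gfa
}

#' Spell a GFA path
#'
#' Concatenates the path's segments (0M overlaps), reproducing the source
#' sequence of the traversal.
#' @param gfa A `gfa_graph`.
#' @param name Path name.
#' @return Character string.
#' @export
spell_gfa_path <- function(gfa, name) {
  segs <- gfa$paths[[name]]
  if (is.null(segs)) stop("no such path: ", name)
  missing <- setdiff(segs, names(gfa$segments))
  if (length(missing)) stop("path references missing segment: ", missing[1])
  paste(gfa$segments[segs], collapse = "")
}

#' Write a GFA v1 file
#'
#' @param gfa A `gfa_graph` (e.g. from [msa_to_gfa()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(gfa, path) {
  seg_ids <- names(gfa$segments)
  bad <- setdiff(unique(c(gfa$links$from, gfa$links$to,
                          unlist(gfa$paths, use.names = FALSE))), seg_ids)
  if (length(bad)) stop("link/path references missing segment: ", bad[1])
  lines <- c(
    "H\tVN:Z:1.0",
    sprintf("S\t%s\t%s", seg_ids, unname(gfa$segments)),
    if (nrow(gfa$links)) {
      sprintf("L\t%s\t%s\t%s\t%s\t%s", gfa$links$from, gfa$links$from_orient,
              gfa$links$to, gfa$links$to_orient, gfa$links$overlap)
    },
    vapply(names(gfa$paths), function(nm) {
      sprintf("P\t%s\t%s\t*", nm,
              paste0(gfa$paths[[nm]], "+", collapse = ","))
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFA v1 file written by [write_gfa()]
#'
#' @param path GFA path.
#' @return A `gfa_graph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(f, `[[`, character(1), 1)
  segs <- f[types == "S"]
  segments <- stats::setNames(vapply(segs, `[[`, character(1), 3),
                              vapply(segs, `[[`, character(1), 2))
  lnk <- f[types == "L"]
  links <- data.frame(
    from = vapply(lnk, `[[`, character(1), 2),
    from_orient = vapply(lnk, `[[`, character(1), 3),
    to = vapply(lnk, `[[`, character(1), 4),
    to_orient = vapply(lnk, `[[`, character(1), 5),
    overlap = vapply(lnk, `[[`, character(1), 6),
    stringsAsFactors = FALSE)
  pth <- f[types == "P"]
  paths <- stats::setNames(lapply(pth, function(x) {
    sub("\\+$", "", strsplit(x[[3]], ",", fixed = TRUE)[[1]])
  }), vapply(pth, `[[`, character(1), 2))
  bad <- setdiff(unique(c(links$from, links$to,
                          unlist(paths, use.names = FALSE))),
                 names(segments))
  if (length(bad)) stop("GFA references missing segment: ", bad[1])
  gfa <- list(segments = segments, links = links, paths = paths)
  class(gfa) <- "gfa_graph"
  gfa
}
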