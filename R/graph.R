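#' Explicit graph objects
#'
#' Ground-truth graphs (and decode targets) are kept as plain edge lists with
#' direction/weight flags. Canonical form: no self-loops, no duplicate edges,
#' undirected edges stored once with the lexicographically smaller label
#' first, edges sorted by (src, dst). Node labels are arbitrary strings; the
#' node set may include isolated nodes.
#'
#' @param edges a data.frame with character columns \code{src}, \code{dst}
#'   and, for weighted graphs, a numeric \code{weight} in [0, 1). May have
#'   zero rows.
#' @param nodes optional character vector of node labels; the final node set
#'   is the sorted union with all edge endpoints.
#' @param directed logical flag.
#' @param weighted logical flag; when TRUE every edge must carry a weight in
#'   [0, 1) (a weight of exactly 1 is rejected, not clamped).
#' @return an object of class \code{hd_graph}.
#' @export
hd_graph <- function(edges, nodes = NULL, directed = FALSE, weighted = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(src = character(), dst = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("src", "dst") %in% names(edges))) {
    stop("`edges` needs columns src and dst", call. = FALSE)
  }
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  if (any(edges$src == edges$dst)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (weighted) {
    if (!("weight" %in% names(edges))) {
      if (nrow(edges) > 0) {
        stop("weighted graph requires a weight on every edge", call. = FALSE)
      }
      edges$weight <- numeric()
    }
    if (nrow(edges) > 0 && any(is.na(edges$weight))) {
      stop("weighted graph requires a weight on every edge", call. = FALSE)
    }
    edges$weight <- as.numeric(edges$weight)
    if (nrow(edges) > 0 && any(edges$weight < 0 | edges$weight >= 1)) {
      stop("edge weights must lie in [0, 1)", call. = FALSE)
    }
    edges <- edges[, c("src", "dst", "weight")]
  } else {
    edges <- edges[, c("src", "dst")]
  }
  if (!directed && nrow(edges) > 0) {
    swap <- edges$src > edges$dst
    tmp <- edges$src[swap]
    edges$src[swap] <- edges$dst[swap]
    edges$dst[swap] <- tmp
  }
  if (nrow(edges) > 0) {
    key <- paste(edges$src, edges$dst, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$src, edges$dst)))
  structure(
    list(nodes = nodes, edges = edges,
         directed = isTRUE(directed), weighted = isTRUE(weighted)),
    class = "hd_graph"
  )
}

#' @export
print.hd_graph <- function(x, ...) {
  cat("<hd_graph> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (x$directed) ", directed" else ", undirected",
      if (x$weighted) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges of an \code{hd_graph}
#' @param g an \code{hd_graph}.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

# Logical adjacency matrix in codebook (sorted-label) order.
# adj[i, j] is TRUE when the edge i -> j exists (symmetric when undirected).
adjacency_matrix <- function(g) {
  V <- length(g$nodes)
  A <- matrix(FALSE, V, V, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    si <- match(g$edges$src, g$nodes)
    di <- match(g$edges$dst, g$nodes)
    A[cbind(si, di)] <- TRUE
    if (!g$directed) A[cbind(di, si)] <- TRUE
  }
  A
}

# All unordered node pairs (i < j) over V labels; used by generators and
# reconstruction. Returns a 2-column integer matrix.
pair_index <- function(V) {
  i <- rep.int(seq_len(V - 1L), times = (V - 1L):1L)
  j <- sequence((V - 1L):1L, from = 2L:V)
  cbind(i, j)
}

#' Generate a uniform random graph with a fixed edge count
#'
#' Samples exactly \code{E} distinct edges uniformly from all possible edges
#' on \code{V} labeled nodes -- equivalently, a complete graph with a
#' uniformly chosen set of edges deleted. Node labels are zero-padded
#' (\code{"n01"}, \code{"n02"}, ...) so sorted label order matches numeric
#' order. Weighted graphs draw i.i.d. uniform weights on [0, 1).
#'
#' @param V number of vertices.
#' @param E number of edges; at most \code{V(V-1)/2} (undirected) or
#'   \code{V(V-1)} (directed).
#' @param directed,weighted graph flags.
#' @param seed integer seed; generation is a pure function of the arguments.
#' @return an \code{hd_graph}.
#' @export
generate_random_graph <- function(V, E, directed = FALSE, weighted = FALSE,
                                  seed = 1L) {
  if (!is_count(V, min = 2)) stop("`V` must be an integer >= 2", call. = FALSE)
  maxE <- if (directed) V * (V - 1L) else V * (V - 1L) / 2
  if (!is_count(E, min = 0) || E > maxE) {
    stop("infeasible edge count E = ", E, " for V = ", V,
         " (max ", maxE, ")", call. = FALSE)
  }
  labels <- sprintf("n%0*d", nchar(as.character(V)), seq_len(V))
  if (directed) {
    up <- pair_index(V)
    all_pairs <- rbind(up, up[, 2:1, drop = FALSE])
  } else {
    all_pairs <- pair_index(V)
  }
  res <- local_seed(seed, {
    pick <- sample.int(nrow(all_pairs), E)
    w <- if (weighted) stats::runif(E) else NULL
    list(pick = pick, w = w)
  })
  sel <- all_pairs[res$pick, , drop = FALSE]
  edges <- data.frame(src = labels[sel[, 1L]], dst = labels[sel[, 2L]],
                      stringsAsFactors = FALSE)
  if (weighted) edges$weight <- res$w
  hd_graph(edges, nodes = labels, directed = directed, weighted = weighted)
}

# Plain BFS over an hd_graph; returns distances (Inf when unreachable) from
# `from` in node order. Used to certify generated chain graphs; tests use
# igraph as the independent oracle.
bfs_distances <- function(g, from) {
  V <- length(g$nodes)
  A <- adjacency_matrix(g)
  if (g$directed) A <- A | t(A)  # distance checks treat edges as traversable both ways
  dist <- rep(Inf, V)
  names(dist) <- g$nodes
  s <- match(from, g$nodes)
  if (is.na(s)) stop("unknown node label: ", from, call. = FALSE)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & is.infinite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Generate a chained-component graph with controlled node distances
#'
#' Builds \code{dnum} disjoint random components of \code{V_av} vertices and
#' \code{E_av} edges each, marks one uniformly chosen anchor node per
#' component, and joins *consecutive* anchors by an edge. Anchor k then sits
#' at graph distance k - 1 from anchor 1, giving node pairs with controlled
#' distances 1 ... dnum - 1. The construction is certified at generation time
#' with a breadth-first-search check.
#'
#' @param dnum number of components (>= 2).
#' @param V_av vertices per component.
#' @param E_av edges per component; must be feasible, i.e. at most
#'   \code{V_av (V_av - 1)/2}.
#' @param seed integer seed.
#' @return a list with the \code{graph} (an undirected \code{hd_graph}) and
#'   \code{anchors}, the ordered anchor labels.
#' @export
generate_chained_graph <- function(dnum, V_av, E_av, seed = 1L) {
  if (!is_count(dnum, min = 2)) stop("`dnum` must be >= 2", call. = FALSE)
  if (!is_count(V_av, min = 2) || !is_count(E_av, min = 1) ||
      E_av > V_av * (V_av - 1) / 2) {
    stop("infeasible chain config: E_av = ", E_av, " exceeds the ",
         V_av * (V_av - 1) / 2, " possible edges on V_av = ", V_av,
         " vertices", call. = FALSE)
  }
  parts <- vector("list", dnum)
  anchors <- character(dnum)
  for (k in seq_len(dnum)) {
    comp <- generate_random_graph(V_av, E_av, seed = seed + k)
    relab <- sprintf("c%02d_%s", k, comp$nodes)
    edges <- data.frame(
      src = sprintf("c%02d_%s", k, comp$edges$src),
      dst = sprintf("c%02d_%s", k, comp$edges$dst),
      stringsAsFactors = FALSE
    )
    anchors[k] <- local_seed(seed + 100000L + k, sample(relab, 1L))
    parts[[k]] <- list(edges = edges, nodes = relab)
  }
  edges <- do.call(rbind, lapply(parts, `[[`, "edges"))
  link <- data.frame(src = anchors[-dnum], dst = anchors[-1L],
                     stringsAsFactors = FALSE)
  g <- hd_graph(rbind(edges, link),
                nodes = unlist(lapply(parts, `[[`, "nodes")))
  dist <- bfs_distances(g, anchors[1L])
  if (!all(dist[anchors] == seq_len(dnum) - 1L)) {
    stop("internal error: chained anchors do not realize distances 0..dnum-1",
         call. = FALSE)
  }
  list(graph = g, anchors = anchors)
}

#' Read / write edge-list TSV files
#'
#' The on-disk format is a tab-separated file with columns \code{src},
#' \code{dst} and, for weighted graphs, \code{weight} (printed with 6
#' decimals). Lines starting with \code{#} are comments; the writer records
#' the graph flags and the full node set (including isolated nodes) in
#' comment lines so that a write/read round trip reproduces the canonical
#' graph exactly. A header row is optional on input.
#'
#' @param path file path.
#' @param directed,weighted flags used when the file carries no metadata
#'   comments.
#' @return \code{read_edge_list}: an \code{hd_graph}.
#' @export
read_edge_list <- function(path, directed = FALSE, weighted = NA) {
  lines <- readLines(path)
  meta_nodes <- NULL
  for (ln in grep("^#", lines, value = TRUE)) {
    if (grepl("^#\\s*directed:", ln)) {
      directed <- grepl("true", ln, ignore.case = TRUE)
    } else if (grepl("^#\\s*weighted:", ln)) {
      weighted <- grepl("true", ln, ignore.case = TRUE)
    } else if (grepl("^#\\s*nodes:", ln)) {
      meta_nodes <- strsplit(sub("^#\\s*nodes:\\s*", "", ln), ",", fixed = TRUE)[[1L]]
    }
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(rows) > 0 && identical(tolower(rows[[1L]][1:2]), c("src", "dst"))) {
    rows <- rows[-1L]
    lineno <- lineno[-1L]
  }
  nf <- vapply(rows, length, 1L)
  if (length(rows) == 0L) {
    has_w <- isTRUE(weighted)
    edges <- NULL
  } else {
    if (any(nf < 2L | nf > 3L)) {
      bad <- lineno[which(nf < 2L | nf > 3L)[1L]]
      stop("malformed edge-list row at line ", bad, call. = FALSE)
    }
    has_w <- if (is.na(weighted)) all(nf == 3L) else isTRUE(weighted)
    if (has_w && any(nf != 3L)) {
      stop("missing weight at line ", lineno[which(nf != 3L)[1L]], call. = FALSE)
    }
    src <- vapply(rows, `[[`, "", 1L)
    dst <- vapply(rows, `[[`, "", 2L)
    if (any(src == dst)) {
      stop("self-loop at line ", lineno[which(src == dst)[1L]], call. = FALSE)
    }
    edges <- data.frame(src = src, dst = dst, stringsAsFactors = FALSE)
    if (has_w) {
      w <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
      if (anyNA(w)) {
        stop("unparseable weight at line ", lineno[which(is.na(w))[1L]],
             call. = FALSE)
      }
      edges$weight <- w
    }
  }
  hd_graph(edges, nodes = meta_nodes, directed = directed, weighted = has_w)
}

#' @rdname read_edge_list
#' @param g an \code{hd_graph}.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "hd_graph"))
  hdr <- c("# hdgraph edge list",
           paste0("# directed: ", tolower(g$directed)),
           paste0("# weighted: ", tolower(g$weighted)),
           paste0("# nodes: ", paste(g$nodes, collapse = ",")),
           if (g$weighted) "src\tdst\tweight" else "src\tdst")
  body <- if (nrow(g$edges) == 0) character() else if (g$weighted) {
    sprintf("%s\t%s\t%.6f", g$edges$src, g$edges$dst, g$edges$weight)
  } else {
    sprintf("%s\t%s", g$edges$src, g$edges$dst)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
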