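#' Method-of-moments neighborhood difference estimator
#'
#' The difference of two exact node memories is a signed sum of the N
#' hypervectors of nodes that neighbor the node in exactly one of the two
#' graphs. Each component of the difference is then a sum of N independent
#' +/-1 terms, so its second moment equals N: the mean of the squared
#' difference over components is an unbiased estimator of the number of
#' neighborhood differences.
#'
#' @param Ma,Mb node-memory hypervectors of equal dimension (same node, same
#'   codebook, two graphs).
#' @return the estimated number of differing neighbors (a nonnegative real).
#' @export
estimate_node_difference <- function(Ma, Mb) {
  if (length(Ma) != length(Mb)) {
    stop("dimension mismatch in estimate_node_difference", call. = FALSE)
  }
  mean((as.double(Ma) - as.double(Mb))^2)
}

#' Estimate the number of edges stored in a graph memory
#'
#' Applies the same second-moment trick to the graph hypervector itself: an
#' unweighted graph memory is a sum of |E| independent bipolar edge
#' hypervectors, so the mean of its squared components estimates |E|
#' unbiasedly. Used internally to auto-set decision thresholds.
#'
#' @param G a \code{graph_memory} (plain unweighted kinds give an unbiased
#'   |E|; weighted memories also work since bound value vectors are bipolar)
#'   or a raw hypervector.
#' @return the edge-count estimate (a nonnegative real).
#' @export
estimate_edge_count <- function(G) {
  v <- if (inherits(G, "graph_memory")) G$vector else G
  mean(as.double(v)^2)
}

#' Match two graphs sharing a node identity
#'
#' Estimates the number of edges present in exactly one of two graphs whose
#' node-to-label mapping is fixed. Per node, the neighborhood difference is
#' estimated by \code{\link{estimate_node_difference}}; the total is the sum
#' over nodes for directed graphs, and half the sum for undirected graphs
#' (each differing undirected edge shows up at both endpoints).
#'
#' Two modes:
#' \itemize{
#'   \item \code{"exact-memories"} (default): \code{a}, \code{b} are node
#'     memory matrices from \code{\link{encode_node_memories}}; the estimator
#'     is unbiased.
#'   \item \code{"unbind-with-correction"}: \code{a}, \code{b} are
#'     \code{graph_memory} objects. Because both memories are encoded with
#'     the *same* codebook, unbinding noise from edges present in both graphs
#'     cancels exactly in the difference \code{H_a * (G - G')}: its power is
#'     the total number of differing edges, not the per-graph edge count. The
#'     total is therefore estimated directly as the second moment of the
#'     graph-vector difference (each differing edge contributes one bipolar
#'     term), and each per-node estimate is corrected by the expected
#'     non-incident share of that total before flooring at 0.
#' }
#'
#' @param a,b node-memory matrices (same column labels) or
#'   \code{graph_memory} objects encoded with the same codebook.
#' @param cb codebook; required in unbind mode.
#' @param mode see above.
#' @param directed logical; how to total per-node differences in exact mode
#'   (taken from the memories' kind in unbind mode).
#' @return an object of class \code{match_result}: list with
#'   \code{per_node_difference} (named, floored at 0),
#'   \code{total_difference} and \code{bias_corrected}.
#' @export
match_graphs <- function(a, b, cb = NULL,
                         mode = c("exact-memories", "unbind-with-correction"),
                         directed = FALSE) {
  mode <- match.arg(mode)
  if (mode == "exact-memories") {
    stopifnot(is.matrix(a), is.matrix(b))
    if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b))) {
      stop("node-memory matrices must share dimension and labels", call. = FALSE)
    }
    per_node <- colMeans((a - b)^2)
    corrected <- FALSE
  } else {
    stopifnot(inherits(a, "graph_memory"), inherits(b, "graph_memory"),
              inherits(cb, "hd_codebook"))
    if (!identical(a$codebook_seed, b$codebook_seed) || !identical(a$D, b$D)) {
      stop("memories were not encoded with the same codebook/D", call. = FALSE)
    }
    check_codebook_match(a, cb)
    directed <- grepl("(^|-)directed$", a$kind)
    labels <- cb$labels
    V <- length(labels)
    # |Delta| estimated from the memory difference itself: G - G' is the
    # bundle of one signed bipolar term per differing edge.
    delta_hat <- mean((a$vector - b$vector)^2)
    ends <- if (directed) 1 else 2
    bias <- delta_hat * max(0, 1 - ends / V)  # expected non-incident share
    per_node <- vapply(labels, function(lb) {
      estimate_node_difference(unbind_node(a, lb, cb), unbind_node(b, lb, cb)) - bias
    }, numeric(1))
    per_node <- pmax(per_node, 0)
    return(structure(
      list(per_node_difference = per_node, total_difference = delta_hat,
           bias_corrected = TRUE, mode = mode),
      class = "match_result"
    ))
  }
  per_node <- pmax(per_node, 0)
  total <- if (directed) sum(per_node) else sum(per_node) / 2
  structure(
    list(per_node_difference = per_node, total_difference = total,
         bias_corrected = corrected, mode = mode),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> total difference ", format(x$total_difference),
      " (", x$mode, if (x$bias_corrected) ", bias corrected", ")\n", sep = "")
  invisible(x)
}

#' Hypervector-native shortest path
#'
#' Breadth-first search run entirely with similarity tests on node memories.
#' Starting from node \code{from} (distance 0), each step bundles the node
#' memories of the current distance level into a single frontier memory and
#' admits every unvisited label whose decision score against that frontier
#' exceeds the threshold as the next level. Expansion stops when \code{to}
#' is discovered, no new nodes appear, or everything is visited. The path is
#' then read off backwards: at each level a predecessor whose own memory
#' contains the current node above threshold is chosen, uniformly at random
#' among ties (seeded).
#'
#' Node memories default to the ones *reconstructed* from the graph
#' hypervector (the holographic route); pass \code{memories} to use exact
#' ones.
#'
#' @param G a plain unweighted \code{graph_memory}, or NULL when
#'   \code{memories} is given.
#' @param from,to node labels.
#' @param cb the codebook.
#' @param model a \code{decision_model}; default derived from \code{G} (or
#'   from the memory matrix's mean degree).
#' @param seed integer seed for tie-breaking.
#' @param memories optional \code{D x V} node-memory matrix (columns in
#'   codebook order).
#' @return an object of class \code{path_result}: list with \code{found},
#'   \code{distance} (NA when not found), \code{path} (label vector, NA when
#'   not found) and \code{levels}, the discovered distance of every reached
#'   node.
#' @export
shortest_path <- function(G, from, to, cb, model = NULL, seed = 1L,
                          memories = NULL) {
  stopifnot(inherits(cb, "hd_codebook"))
  from <- as.character(from); to <- as.character(to)
  for (lb in c(from, to)) {
    if (!(lb %in% cb$labels)) stop("unknown node label: ", lb, call. = FALSE)
  }
  if (is.null(memories)) {
    stopifnot(inherits(G, "graph_memory"))
    if (is.null(model)) model <- default_model(G)
    rec <- reconstruct_node_memory(G, cb, model = model)
    memories <- cb$H %*% t(rec$adjacency * 1)
    colnames(memories) <- cb$labels
  } else {
    stopifnot(is.matrix(memories), ncol(memories) == length(cb$labels))
    if (is.null(model)) {
      d_hat <- max(1, mean(colMeans(memories^2)))
      model <- decision_model(d = d_hat, D = cb$D)
    }
  }
  V <- length(cb$labels)
  D <- cb$D
  levels <- stats::setNames(rep(NA_integer_, V), cb$labels)
  levels[from] <- 0L
  current <- from
  d <- 0L
  while (is.na(levels[to]) && length(current) > 0) {
    frontier <- rowSums(memories[, current, drop = FALSE])
    scores <- as.vector(crossprod(cb$H, frontier)) / D
    nxt <- cb$labels[scores > model$T & is.na(levels)]
    if (length(nxt) == 0) break
    d <- d + 1L
    levels[nxt] <- d
    current <- nxt
  }
  diag_levels <- levels[!is.na(levels)]
  if (is.na(levels[to])) {
    return(structure(list(found = FALSE, distance = NA_integer_,
                          path = NULL, levels = diag_levels),
                     class = "path_result"))
  }
  path <- to
  cur <- to
  k <- levels[to]
  picks <- local_seed(seed, {
    out <- character(0)
    while (k > 0L) {
      cand <- cb$labels[!is.na(levels) & levels == k - 1L]
      sc <- as.vector(crossprod(memories[, cand, drop = FALSE],
                                cb$H[, cur])) / D
      ok <- cand[sc > model$T]
      pick <- if (length(ok) > 0) ok[sample.int(length(ok), 1L)]
              else cand[which.max(sc)]  # forward pass admitted cur; fall back to best scorer
      out <- c(pick, out)
      cur <- pick
      k <- k - 1L
    }
    out
  })
  path <- c(picks, to)
  structure(
    list(found = TRUE, distance = as.integer(levels[to]),
         path = unname(path), levels = diag_levels),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  if (x$found) {
    cat("<path_result> distance ", x$distance, ": ",
        paste(x$path, collapse = " -> "), "\n", sep = "")
  } else {
    cat("<path_result> no path found (", length(x$levels),
        " nodes reached)\n", sep = "")
  }
  invisible(x)
}
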