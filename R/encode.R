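#' Encode node memories
#'
#' A node's memory is the exact integer bundle of its neighbors' hypervectors:
#' \code{M_i = sum_j H_j} over the neighbors j of i (out-neighbors only when
#' the graph is directed). In weighted graphs each neighbor is first bound to
#' the value hypervector of the edge weight: \code{M_i = sum_j V_w_ij * H_j}.
#' Isolated nodes get the zero vector.
#'
#' @param g an \code{hd_graph} whose node labels are all present in \code{cb}.
#' @param cb an \code{hd_codebook}.
#' @param enc an \code{hd_value_encoder}; required iff \code{g} is weighted.
#' @return a \code{D x V} integer matrix whose columns (named by label, in
#'   codebook order) are the node memories.
#' @export
encode_node_memories <- function(g, cb, enc = NULL) {
  stopifnot(inherits(g, "hd_graph"), inherits(cb, "hd_codebook"))
  check_labels(g, cb)
  if (g$weighted && is.null(enc)) {
    stop("weighted graph requires a value encoder", call. = FALSE)
  }
  V <- length(g$nodes)
  M <- matrix(0, nrow = cb$D, ncol = V, dimnames = list(NULL, g$nodes))
  if (nrow(g$edges) == 0) return(M)
  si <- match(g$edges$src, g$nodes)
  di <- match(g$edges$dst, g$nodes)
  H <- cb$H[, g$nodes, drop = FALSE]
  if (!g$weighted) {
    A <- adjacency_matrix(g)          # A[i, j]: edge i -> j
    M <- H %*% t(A)                   # column i = sum over out-neighbors j
    dimnames(M) <- list(NULL, g$nodes)
  } else {
    for (e in seq_len(nrow(g$edges))) {
      vw <- encode_value(g$edges$weight[e], enc)
      M[, si[e]] <- M[, si[e]] + vw * H[, di[e]]
      if (!g$directed) M[, di[e]] <- M[, di[e]] + vw * H[, si[e]]
    }
  }
  M
}

check_labels <- function(g, cb) {
  missing <- setdiff(g$nodes, cb$labels)
  if (length(missing) > 0) {
    stop("node labels missing from codebook: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

graph_kind <- function(g) {
  paste0(if (g$weighted) "weighted-" else "", if (g$directed) "directed" else "undirected")
}

new_graph_memory <- function(vector, D, kind, cb, enc = NULL, perm = perm_cyclic()) {
  structure(
    list(vector = vector, D = as.integer(D), kind = kind,
         codebook_seed = cb$seed, value_seed = if (is.null(enc)) NULL else enc$seed,
         node_labels = cb$labels, perm = perm),
    class = "graph_memory"
  )
}

#' @export
print.graph_memory <- function(x, ...) {
  cat("<graph_memory> D = ", x$D, ", kind = ", x$kind, ", ",
      length(x$node_labels), " labels, codebook seed = ", x$codebook_seed,
      "\n", sep = "")
  invisible(x)
}

#' Encode a whole graph into a single hypervector
#'
#' The graph memory superposes one bound pair per edge:
#' \itemize{
#'   \item undirected: \code{G = sum over edges (i,j) of H_i * H_j}, each
#'     unordered edge contributing exactly once. This edge-sum equals
#'     \code{(1/2) sum_i H_i * M_i} componentwise -- the conventional halved
#'     node-memory form -- but stays in exact integer arithmetic.
#'   \item directed: \code{G = sum_i H_i * rho(M_i)}, i.e. one
#'     \code{H_i * rho(H_j)} term per edge i -> j. The permutation rho makes
#'     the encoding non-commutative, so direction is preserved and no 1/2
#'     factor arises.
#'   \item weighted: the target hypervector is first bound to the value
#'     hypervector of the edge weight.
#' }
#'
#' @inheritParams encode_node_memories
#' @param perm permutation spec used for directed encodings (recorded in the
#'   memory's metadata).
#' @return an object of class \code{graph_memory} holding the integer vector
#'   and all metadata needed to decode (D, kind, codebook seed, value seed,
#'   label set, permutation spec).
#' @export
encode_graph <- function(g, cb, enc = NULL, perm = perm_cyclic()) {
  stopifnot(inherits(g, "hd_graph"), inherits(cb, "hd_codebook"))
  check_labels(g, cb)
  if (g$weighted && is.null(enc)) {
    stop("weighted graph requires a value encoder", call. = FALSE)
  }
  D <- cb$D
  Gv <- numeric(D)
  if (nrow(g$edges) > 0) {
    Hs <- cb$H[, g$edges$src, drop = FALSE]
    Hd <- cb$H[, g$edges$dst, drop = FALSE]
    if (g$weighted) {
      W <- vapply(g$edges$weight, encode_value, numeric(D), enc = enc)
      Hd <- Hd * W
    }
    if (g$directed) Hd <- Hd[perm_index(D, 1L, perm), , drop = FALSE]
    Gv <- rowSums(Hs * Hd)
  }
  new_graph_memory(Gv, D, graph_kind(g), cb, enc, perm)
}

#' Reconstruct a node memory by unbinding
#'
#' Binding the node's own hypervector with the graph memory cancels that
#' node's term and leaves its memory plus cross-term noise:
#' \code{H_i * G = M_i + noise}. For directed memories the inverse
#' permutation is applied afterwards. The estimate is exact when no other
#' edges exist; otherwise the noise has variance (E - d_i)/D per similarity.
#'
#' @param G a \code{graph_memory} (any unrefined kind).
#' @param label a node label in the codebook.
#' @param cb the \code{hd_codebook} the memory was encoded with.
#' @return the integer node-memory estimate (a hypervector).
#' @export
unbind_node <- function(G, label, cb) {
  stopifnot(inherits(G, "graph_memory"))
  check_codebook_match(G, cb)
  if (startsWith(G$kind, "refined")) {
    stop("unbinding refined memories is not supported; use query_edge",
         call. = FALSE)
  }
  h <- node_hv(cb, label)
  est <- h * G$vector
  if (grepl("directed$", G$kind) && !grepl("undirected$", G$kind)) {
    est <- est[perm_index(G$D, -1L, G$perm)]
  }
  est
}

check_codebook_match <- function(G, cb) {
  if (!identical(cb$seed, G$codebook_seed) || !identical(cb$D, G$D) ||
      !identical(cb$labels, G$node_labels)) {
    stop("codebook does not match the memory's encoding metadata",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Iterative memory refinement
#'
#' Strengthens overloaded node memories so that a single threshold separates
#' the decision scores of existing edges (signal) from non-edges (noise).
#' Each pass sweeps all ordered node pairs (i, j) in codebook order and
#' applies the correction rule: if i and j share an edge but
#' \code{R_ij = similarity(M_j, H_i) < T}, add \code{H_i} to \code{M_j}; if
#' they share no edge but \code{R_ij > T}, subtract \code{H_i}. Each such
#' update moves that score by exactly +/-1 (and every other score by O(1/sqrt(D))),
#' so a corrected pair is not re-broken within its own update. Passes repeat
#' until one makes zero updates (full separation certified) or
#' \code{max_passes} is reached.
#'
#' Only unweighted graphs are supported: the update rule adds whole node
#' hypervectors and has no stated weighted analogue.
#'
#' @param g the true \code{hd_graph} (unweighted).
#' @param cb the codebook.
#' @param mems optional starting \code{D x V} node-memory matrix (columns in
#'   codebook order). Defaults to the exact memories of \code{g}; pass
#'   unbound estimates (see \code{\link{unbind_node}}) to refine an
#'   overloaded holographic encoding.
#' @param T decision threshold in (0, 1); default is the equal-error
#'   threshold for the graph's average degree (0.5 fallback).
#' @param max_passes maximum sweeps (default 50).
#' @return a list with \code{mems} (refined memory matrix), \code{memory}
#'   (graph memory rebuilt as \code{sum_i H_i * M_i} without halving, kind
#'   prefixed \code{"refined-"}), and \code{report}: passes, updates per
#'   pass, convergence flag and the threshold used.
#' @export
refine <- function(g, cb, mems = NULL, T = NULL, max_passes = 50L) {
  stopifnot(inherits(g, "hd_graph"), inherits(cb, "hd_codebook"))
  if (g$weighted) {
    stop("refinement of weighted memories is unsupported", call. = FALSE)
  }
  check_labels(g, cb)
  if (!setequal(g$nodes, cb$labels)) {
    stop("refinement expects the codebook label set to equal the graph's",
         call. = FALSE)
  }
  if (is.null(mems)) mems <- encode_node_memories(g, cb)
  V <- length(cb$labels)
  stopifnot(is.matrix(mems), nrow(mems) == cb$D, ncol(mems) == V)
  if (is.null(T)) {
    d_hat <- max(1, (if (g$directed) 1 else 2) * nrow(g$edges) / V)
    T <- equal_error_threshold(signal_noise_model(d_hat, cb$D))
  }
  if (!is.numeric(T) || T <= 0 || T >= 1) {
    stop("`T` must lie in (0, 1)", call. = FALSE)
  }
  A <- adjacency_matrix(g)  # A[j, i]: H_i should be present in M_j (edge j -> i)
  H <- cb$H
  D <- cb$D
  updates_per_pass <- integer()
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    updates <- 0L
    for (i in seq_len(V)) {
      hi <- H[, i]
      R <- as.vector(crossprod(mems, hi)) / D
      # scores exactly at T (possible: scores are multiples of 1/D) count as
      # mispredictions, so the converged state is strictly separated
      add <- A[, i] & R <= T
      sub <- !A[, i] & R >= T
      add[i] <- sub[i] <- FALSE
      if (any(add)) mems[, add] <- mems[, add] + hi
      if (any(sub)) mems[, sub] <- mems[, sub] - hi
      updates <- updates + sum(add) + sum(sub)
    }
    updates_per_pass <- c(updates_per_pass, updates)
    if (updates == 0L) { converged <- TRUE; break }
  }
  Hm <- H[, colnames(mems), drop = FALSE]
  Gv <- if (g$directed) {
    rowSums(Hm * mems[perm_index(D, 1L), , drop = FALSE])
  } else {
    rowSums(Hm * mems)
  }
  mem <- new_graph_memory(Gv, D, paste0("refined-", graph_kind(g)), cb)
  list(
    mems = mems,
    memory = mem,
    report = list(passes = length(updates_per_pass),
                  updates_per_pass = updates_per_pass,
                  converged = converged,
                  final_threshold = T)
  )
}
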