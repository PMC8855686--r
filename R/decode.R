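#' Decision model for thresholded retrieval
#'
#' Retrieval tests compare a similarity score against a threshold
#' \code{T in (0, 1)}. Under the Gaussian capacity model, for a memory of
#' degree d at dimension D, scores of stored items follow N(1, (d-1)/D) and
#' scores of absent items follow N(0, d/D); \code{T} defaults to the
#' equal-error point between the two (see
#' \code{\link{equal_error_threshold}}).
#'
#' @param T decision threshold in (0, 1), or NULL to derive it from
#'   \code{d} and \code{D}.
#' @param d assumed or estimated average degree (>= 1).
#' @param D hypervector dimension.
#' @return an object of class \code{decision_model} with fields \code{T},
#'   \code{d}, \code{D}.
#' @export
decision_model <- function(T = NULL, d = NULL, D = NULL) {
  if (is.null(T)) {
    if (is.null(d) || is.null(D)) {
      stop("either `T` or both `d` and `D` must be given", call. = FALSE)
    }
    T <- equal_error_threshold(signal_noise_model(max(1, d), D))
  }
  if (!is.numeric(T) || length(T) != 1L || T <= 0 || T >= 1) {
    stop("`T` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(T = T, d = d, D = D), class = "decision_model")
}

# Default model for a graph memory: estimate |E| from the second moment of G
# itself, convert to an average degree, and take the equal-error threshold.
# Falls back to T = 0.5 when the memory looks empty.
default_model <- function(G) {
  E_hat <- estimate_edge_count(G)
  V <- length(G$node_labels)
  per_node <- if (grepl("(^|-)directed$", G$kind)) 1 else 2
  d_hat <- per_node * E_hat / V
  if (!is.finite(d_hat) || d_hat < 1) {
    return(decision_model(T = 0.5, d = 1, D = G$D))
  }
  decision_model(d = d_hat, D = G$D)
}

#' Decision score of a probe against a memory
#'
#' The retrieval statistic R: the similarity of a (node) memory with a probe
#' hypervector. For an exact memory of degree d, R decomposes additively into
#' a unit signal term (when the probe is stored) plus d - 1 independent
#' cross terms, each approximately N(0, 1/D).
#'
#' @param mem a memory hypervector (integer bundle).
#' @param h a probe hypervector.
#' @return the similarity (a real number).
#' @export
decision_score <- function(mem, h) hv_similarity(mem, h)

#' Query the existence of an edge in a graph memory
#'
#' Tests the stored-ness of the edge hypervector directly against the whole
#' graph memory: undirected memories use \code{similarity(G, H_i * H_j)},
#' directed ones \code{similarity(G, H_i * rho(H_j))}. Refined undirected
#' memories count every edge twice (they are rebuilt without the 1/2
#' factor), so their raw score is halved before thresholding.
#'
#' @param G a \code{graph_memory} (unweighted kind; for weighted memories use
#'   \code{\link{query_weight}}).
#' @param i,j distinct node labels.
#' @param cb the codebook.
#' @param model a \code{decision_model}; defaults to one derived from
#'   \code{G} itself.
#' @return a list with \code{exists} (logical), \code{score} and
#'   \code{threshold}.
#' @export
query_edge <- function(G, i, j, cb, model = NULL) {
  stopifnot(inherits(G, "graph_memory"))
  check_codebook_match(G, cb)
  if (grepl("weighted", G$kind)) {
    stop("use query_weight for weighted memories", call. = FALSE)
  }
  if (identical(as.character(i), as.character(j))) {
    stop("cannot query a self-loop (i == j)", call. = FALSE)
  }
  if (is.null(model)) model <- default_model(G)
  hi <- node_hv(cb, i)
  hj <- node_hv(cb, j)
  directed <- grepl("(^|-)directed$", G$kind)
  e <- if (directed) hi * hv_permute(hj, 1L, G$perm) else hi * hj
  score <- hv_similarity(G$vector, e)
  if (identical(G$kind, "refined-undirected")) score <- score / 2
  list(exists = score > model$T, score = score, threshold = model$T)
}

#' Query the weight of an edge in a weighted graph memory
#'
#' Unbinds node i's memory from \code{G}, binds it with \code{H_j} to expose
#' the value hypervector of the (i, j) edge, and scans the deterministic
#' weight family: the edge exists when the best family similarity clears the
#' threshold, and the weight estimate is refined with the value decoder
#' (resolution 1/D).
#'
#' @param G a weighted \code{graph_memory}.
#' @param i,j node labels (for directed memories, the edge i -> j).
#' @param cb the codebook.
#' @param enc the value encoder used at encoding time.
#' @param model a \code{decision_model}; default derived from \code{G}.
#' @param grid candidate weights scanned for existence (default steps of
#'   0.01 over [0, 0.99]).
#' @return a list with \code{exists}, \code{weight} (NA when absent) and
#'   \code{score}, the best family similarity.
#' @export
query_weight <- function(G, i, j, cb, enc, model = NULL,
                         grid = seq(0, 0.99, by = 0.01)) {
  stopifnot(inherits(G, "graph_memory"), inherits(enc, "hd_value_encoder"))
  check_codebook_match(G, cb)
  if (!grepl("weighted", G$kind)) {
    stop("query_weight requires a weighted memory", call. = FALSE)
  }
  if (!identical(enc$seed, G$value_seed)) {
    stop("value encoder does not match the memory's value seed", call. = FALSE)
  }
  if (is.null(model)) model <- default_model(G)
  cvec <- hv_bind(unbind_node(G, i, cb), node_hv(cb, j))
  fam <- vapply(grid, encode_value, numeric(enc$D), enc = enc)
  sims <- as.vector(crossprod(fam, cvec)) / enc$D
  best <- which.max(sims)
  exists <- sims[best] > model$T
  w <- if (exists) min(decode_value(cvec, enc), 1 - 1 / enc$D) else NA_real_
  list(exists = exists, weight = w, score = sims[best])
}

# Edge hypervector matrix: one column per candidate pair.
# pairs: 2-column index matrix into cb$labels; directed decides rho use.
edge_matrix <- function(cb, pairs, directed, perm) {
  Ha <- cb$H[, pairs[, 1L], drop = FALSE]
  Hb <- cb$H[, pairs[, 2L], drop = FALSE]
  if (directed) Hb <- Hb[perm_index(cb$D, 1L, perm), , drop = FALSE]
  Ha * Hb
}

candidate_pairs <- function(V, directed) {
  up <- pair_index(V)
  if (directed) rbind(up, up[, 2:1, drop = FALSE]) else up
}

#' Whole-graph reconstruction by iterative noise cancellation
#'
#' Decodes the full edge set from a single graph hypervector. Iteration 1
#' thresholds the direct similarity of every candidate edge hypervector with
#' \code{G}. Each later iteration re-tests pair (A, B) against the
#' noise-corrected residual \code{G - G_k + f_k(A,B) * (H_A * H_B)}, where
#' \code{G_k} encodes the currently believed edge indicator \code{f_k}: all
#' believed edges except (A, B) itself are cancelled before scoring. The
#' indicator for the next iteration is rebuilt from scratch from the frozen
#' current one (Jacobi-style), in lexicographic pair order. The process stops
#' when the indicator is identical on two consecutive iterations, or after
#' \code{max_iter} iterations (non-convergence is reported via the flag, not
#' an error).
#'
#' @param G an unweighted \code{graph_memory} (undirected or directed).
#' @param cb the codebook.
#' @param model a \code{decision_model}; default derived from \code{G}.
#' @param max_iter iteration cap (default 30).
#' @param reference optional true \code{hd_graph}; when given, per-iteration
#'   mismatched-edge counts are reported.
#' @return an object of class \code{reconstruction_result}: a list with
#'   \code{graph} (the decoded \code{hd_graph}), \code{iterations},
#'   \code{converged}, \code{mismatched_edges} (NA without a reference) and
#'   \code{history}, a data.frame of (iteration, flips, mismatches).
#' @export
reconstruct_graph <- function(G, cb, model = NULL, max_iter = 30L,
                              reference = NULL) {
  stopifnot(inherits(G, "graph_memory"))
  check_codebook_match(G, cb)
  if (grepl("weighted|refined", G$kind)) {
    stop("graph reconstruction supports plain unweighted memories only",
         call. = FALSE)
  }
  if (is.null(model)) model <- default_model(G)
  directed <- identical(G$kind, "directed")
  V <- length(cb$labels)
  pairs <- candidate_pairs(V, directed)
  Ep <- edge_matrix(cb, pairs, directed, G$perm)
  D <- G$D
  truth <- NULL
  if (!is.null(reference)) {
    A <- adjacency_matrix(reference)
    truth <- A[pairs]
  }
  base_scores <- as.vector(crossprod(Ep, G$vector)) / D
  f <- base_scores > model$T
  history <- data.frame(
    iteration = 1L, flips = sum(f),
    mismatches = if (is.null(truth)) NA_integer_ else sum(f != truth)
  )
  # f starts all-zero before the first estimate; an empty first estimate is
  # therefore already a fixed point.
  converged <- !any(f)
  iter <- 1L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    Gk <- if (any(f)) rowSums(Ep[, f, drop = FALSE]) else numeric(D)
    scores <- as.vector(crossprod(Ep, G$vector - Gk)) / D + f
    fnew <- scores > model$T
    flips <- sum(fnew != f)
    history <- rbind(history, data.frame(
      iteration = iter, flips = flips,
      mismatches = if (is.null(truth)) NA_integer_ else sum(fnew != truth)
    ))
    f <- fnew
    if (flips == 0L) { converged <- TRUE; break }
  }
  edges <- data.frame(src = cb$labels[pairs[f, 1L]],
                      dst = cb$labels[pairs[f, 2L]],
                      stringsAsFactors = FALSE)
  g <- hd_graph(edges, nodes = cb$labels, directed = directed)
  structure(
    list(graph = g, iterations = iter, converged = converged,
         mismatched_edges = utils::tail(history$mismatches, 1L),
         history = history),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat("<reconstruction_result> ", n_edges(x$graph), " decoded edges, ",
      x$iterations, " iterations, converged = ", x$converged,
      if (!is.na(x$mismatched_edges)) paste0(", mismatches = ", x$mismatched_edges),
      "\n", sep = "")
  invisible(x)
}

#' Node-memory reconstruction by iterative noise cancellation
#'
#' Recovers every node's neighbor set from the graph hypervector. The first
#' estimate of node i's memory is the one-shot unbinding \code{H_i * G};
#' thresholding its similarity with each candidate neighbor gives believed
#' neighbor sets. Each iteration then rebuilds the believed edge set, and
#' re-estimates node i's memory by binding \code{H_i} with \code{G} minus
#' the sum of believed edge hypervectors *not incident to i* (each believed
#' edge subtracted exactly once), then re-thresholds. Estimates are cleaned
#' up to exact integer bundles of believed neighbors rather than carrying
#' raw noisy vectors forward. Stops when the neighbor sets are stable or at
#' \code{max_iter}.
#'
#' @inheritParams reconstruct_graph
#' @return an object of class \code{node_reconstruction}: a list with
#'   \code{neighbors} (named list of neighbor label vectors),
#'   \code{adjacency} (logical believed adjacency, rows = nodes, columns =
#'   believed (out-)neighbors), \code{iterations} and \code{converged}.
#' @export
reconstruct_node_memory <- function(G, cb, model = NULL, max_iter = 30L) {
  stopifnot(inherits(G, "graph_memory"))
  check_codebook_match(G, cb)
  if (grepl("weighted|refined", G$kind)) {
    stop("node reconstruction supports plain unweighted memories only",
         call. = FALSE)
  }
  if (is.null(model)) model <- default_model(G)
  directed <- identical(G$kind, "directed")
  V <- length(cb$labels)
  D <- G$D
  H <- cb$H
  inv_idx <- perm_index(D, -1L, G$perm)

  # believed adjacency N[i, j]: j believed to be an (out-)neighbor of i
  score_all <- function(resid_fun) {
    N <- matrix(FALSE, V, V, dimnames = list(cb$labels, cb$labels))
    for (i in seq_len(V)) {
      est <- H[, i] * resid_fun(i)
      if (directed) est <- est[inv_idx]
      s <- as.vector(crossprod(H, est)) / D
      s[i] <- -Inf
      N[i, ] <- s > model$T
    }
    if (!directed) N <- N | t(N)
    N
  }

  N <- score_all(function(i) G$vector)
  converged <- FALSE
  iter <- 1L
  while (iter < max_iter) {
    iter <- iter + 1L
    # believed edge list from the current neighbor sets
    be <- if (directed) which(N, arr.ind = TRUE) else which(N & upper.tri(N), arr.ind = TRUE)
    if (nrow(be) > 0) {
      Ep <- edge_matrix(cb, be, directed, G$perm)
      Gk <- rowSums(Ep)
      resid0 <- G$vector - Gk
      Nnew <- score_all(function(i) {
        inc <- be[, 1L] == i | (!directed & be[, 2L] == i)
        if (any(inc)) resid0 + rowSums(Ep[, inc, drop = FALSE]) else resid0
      })
    } else {
      Nnew <- score_all(function(i) G$vector)
    }
    stable <- identical(Nnew, N)
    N <- Nnew
    if (stable) { converged <- TRUE; break }
  }
  neighbors <- lapply(seq_len(V), function(i) cb$labels[N[i, ]])
  names(neighbors) <- cb$labels
  structure(
    list(neighbors = neighbors, adjacency = N, iterations = iter,
         converged = converged),
    class = "node_reconstruction"
  )
}

#' @export
print.node_reconstruction <- function(x, ...) {
  cat("<node_reconstruction> ", length(x$neighbors), " nodes, ",
      x$iterations, " iterations, converged = ", x$converged, "\n", sep = "")
  invisible(x)
}
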