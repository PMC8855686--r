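# Shared fixtures, built in code.

triangle_graph <- function() {
  hd_graph(data.frame(src = c("A", "B", "A"), dst = c("B", "C", "C")))
}

# Exact node-memory matrix computed by the definitional sum, independent of
# encode_node_memories (oracle for the encoding tests).
oracle_node_memories <- function(g, cb, enc = NULL) {
  V <- length(g$nodes)
  M <- matrix(0, cb$D, V, dimnames = list(NULL, g$nodes))
  for (e in seq_len(nrow(g$edges))) {
    s <- g$edges$src[e]; d <- g$edges$dst[e]
    hs <- node_hv(cb, s); hd <- node_hv(cb, d)
    if (g$weighted) {
      vw <- encode_value(g$edges$weight[e], enc)
      M[, s] <- M[, s] + vw * hd
      if (!g$directed) M[, d] <- M[, d] + vw * hs
    } else {
      M[, s] <- M[, s] + hd
      if (!g$directed) M[, d] <- M[, d] + hs
    }
  }
  M
}

# Unbind all node memories from a graph memory (columns in codebook order).
unbind_all <- function(G, cb) {
  vapply(cb$labels, function(lb) unbind_node(G, lb, cb), numeric(cb$D))
}

# True adjacency in codebook order.
true_adjacency <- function(g) hdgraph:::adjacency_matrix(g)

expect_labeled_error <- function(expr, pattern) {
  expect_error(expr, pattern)
}
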