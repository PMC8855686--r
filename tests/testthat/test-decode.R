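test_that("decision scores follow the Eq-style signal/noise decomposition", {
  cb <- generate_codebook(c("A", "B"), 1000, seed = 1)
  expect_equal(decision_score(node_hv(cb, "B"), node_hv(cb, "B")), 1)
  # score of an exact memory equals the term-by-term similarity sum
  g <- generate_random_graph(10, 25, seed = 2)
  cbg <- generate_codebook(g$nodes, 1000, seed = 3)
  M <- encode_node_memories(g, cbg)
  A <- true_adjacency(g)
  for (i in g$nodes) {
    for (j in g$nodes) {
      manual <- 0
      for (k in g$nodes[A[i, ]]) {
        manual <- manual + hv_similarity(node_hv(cbg, k), node_hv(cbg, j))
      }
      expect_equal(decision_score(M[, i], node_hv(cbg, j)), manual)
    }
  }
})

test_that("non-neighbor scores stay inside the Gaussian noise band", {
  D <- 10000; d <- 20
  n <- 1000
  inside <- local({
    set.seed(101)
    ok <- logical(n)
    for (t in seq_len(n)) {
      X <- matrix(2L * (runif(D * (d + 1)) < 0.5) - 1L, nrow = D)
      mem <- rowSums(X[, seq_len(d)])
      ok[t] <- abs(sum(mem * X[, d + 1]) / D) <= 4 * sqrt(d / D)
    }
    ok
  })
  expect_gte(mean(inside), 0.99)
})

test_that("query_edge answers existence queries against the graph memory", {
  g <- hd_graph(data.frame(src = "A", dst = "B"), nodes = c("A", "B", "C"))
  cb <- generate_codebook(g$nodes, 10000, seed = 4)
  G <- encode_graph(g, cb)
  model <- decision_model(T = 0.5)
  q <- query_edge(G, "A", "B", cb, model)
  expect_true(q$exists)
  expect_equal(q$score, 1)
  q2 <- query_edge(G, "A", "C", cb, model)
  expect_false(q2$exists)
  expect_lte(abs(q2$score), 4 / sqrt(10000))
  # directed: only the encoded orientation queries true
  gd <- hd_graph(data.frame(src = "A", dst = "B"), nodes = c("A", "B", "C"),
                 directed = TRUE)
  Gd <- encode_graph(gd, cb)
  expect_true(query_edge(Gd, "A", "B", cb, model)$exists)
  expect_false(query_edge(Gd, "B", "A", cb, model)$exists)
  expect_error(query_edge(G, "A", "A", cb, model), "self-loop")
  expect_error(query_edge(G, "A", "Z", cb, model), "unknown node label")
})

test_that("query_weight recovers weights and rejects non-edges", {
  # single weighted edge: exact recovery (D divisible by 10)
  g <- hd_graph(data.frame(src = "A", dst = "B", weight = 0.7),
                nodes = c("A", "B", "C"), weighted = TRUE)
  cb <- generate_codebook(g$nodes, 1000, seed = 5)
  enc <- value_encoder(1000, seed = 6)
  G <- encode_graph(g, cb, enc)
  model <- decision_model(T = 0.5)
  qw <- query_weight(G, "A", "B", cb, enc, model)
  expect_true(qw$exists)
  expect_equal(qw$weight, 0.7)
  qn <- query_weight(G, "A", "C", cb, enc, model)
  expect_false(qn$exists)
  expect_true(is.na(qn$weight))
  expect_error(query_edge(G, "A", "B", cb, model), "query_weight")
  expect_error(query_weight(encode_graph(hd_graph(g$edges[, 1:2], g$nodes), cb),
                            "A", "B", cb, enc, model),
               "weighted memory")

  # 20-edge weighted graph at D = 10000: mean absolute error <= 0.05
  gw <- generate_random_graph(12, 20, weighted = TRUE, seed = 7)
  cbw <- generate_codebook(gw$nodes, 10000, seed = 8)
  encw <- value_encoder(10000, seed = 9)
  Gw <- encode_graph(gw, cbw, encw)
  err <- vapply(seq_len(20), function(e) {
    got <- query_weight(Gw, gw$edges$src[e], gw$edges$dst[e], cbw, encw, model)
    abs(got$weight - gw$edges$weight[e])
  }, numeric(1))
  expect_lte(mean(err), 0.05)
})

test_that("node-memory reconstruction recovers neighbor sets", {
  # single edge: exact after the first estimate
  g <- hd_graph(data.frame(src = "A", dst = "B"), nodes = c("A", "B", "C"))
  cb <- generate_codebook(g$nodes, 2000, seed = 10)
  G <- encode_graph(g, cb)
  rec <- reconstruct_node_memory(G, cb, decision_model(T = 0.5))
  expect_true(rec$converged)
  expect_identical(rec$neighbors$A, "B")
  expect_identical(rec$neighbors$C, character(0))

  # within capacity: 100 edges at D = 2000, full recovery
  g2 <- generate_random_graph(50, 100, seed = 11)
  cb2 <- generate_codebook(g2$nodes, 2000, seed = 12)
  rec2 <- reconstruct_node_memory(encode_graph(g2, cb2), cb2)
  expect_true(rec2$converged)
  expect_identical(unname(rec2$adjacency), unname(true_adjacency(g2)))

  # deliberately overloaded: failure is exposed via diagnostics, not hidden
  g3 <- generate_random_graph(30, 300, seed = 13)
  cb3 <- generate_codebook(g3$nodes, 500, seed = 14)
  rec3 <- reconstruct_node_memory(encode_graph(g3, cb3), cb3, max_iter = 10)
  expect_true(!rec3$converged ||
              !identical(unname(rec3$adjacency), unname(true_adjacency(g3))))
})

test_that("graph reconstruction: trivial cases", {
  cb <- generate_codebook(c("A", "B", "C"), 1000, seed = 15)
  # zero-vector memory decodes to the empty graph immediately
  G0 <- encode_graph(hd_graph(NULL, nodes = cb$labels), cb)
  r0 <- reconstruct_graph(G0, cb, decision_model(T = 0.5))
  expect_true(r0$converged)
  expect_equal(n_edges(r0$graph), 0)
  expect_equal(r0$iterations, 1)
  # triangle at D = 1000: exact in one iteration
  gt <- triangle_graph()
  Gt <- encode_graph(gt, cb)
  rt <- reconstruct_graph(Gt, cb, decision_model(T = 0.5), reference = gt)
  expect_true(rt$converged)
  expect_equal(rt$mismatched_edges, 0)
  expect_equal(rt$history$mismatches[1], 0)
  expect_identical(rt$graph$edges, gt$edges)
})

test_that("within-capacity graphs are recovered; mismatches shrink", {
  n_trials <- 40
  final_mismatch <- integer(n_trials)
  monotone <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    g <- generate_random_graph(30, 150, seed = 300 + t)
    cb <- generate_codebook(g$nodes, 4000, seed = 600 + t)
    rec <- reconstruct_graph(encode_graph(g, cb), cb, reference = g)
    final_mismatch[t] <- rec$mismatched_edges
    m <- rec$history$mismatches[-1]
    monotone[t] <- length(m) < 2 || all(diff(m) <= 0)
  }
  expect_gte(mean(final_mismatch == 0), 0.95)
  expect_gte(mean(monotone), 0.90)
})

test_that("directed graphs reconstruct with orientation intact", {
  g <- generate_random_graph(15, 40, directed = TRUE, seed = 16)
  cb <- generate_codebook(g$nodes, 4000, seed = 17)
  rec <- reconstruct_graph(encode_graph(g, cb), cb, reference = g)
  expect_equal(rec$mismatched_edges, 0)
  expect_identical(rec$graph$edges, g$edges)
})

test_that("reconstruction never invents labels or self-loops", {
  g <- generate_random_graph(20, 60, seed = 18)
  cb <- generate_codebook(g$nodes, 3000, seed = 19)
  rec <- reconstruct_graph(encode_graph(g, cb), cb)
  expect_true(all(c(rec$graph$edges$src, rec$graph$edges$dst) %in% cb$labels))
  expect_false(any(rec$graph$edges$src == rec$graph$edges$dst))
  nr <- reconstruct_node_memory(encode_graph(g, cb), cb)
  expect_false(any(diag(nr$adjacency)))
})
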