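test_that("node memories match their definitional sums exactly", {
  g <- triangle_graph()
  cb <- generate_codebook(g$nodes, 500, seed = 1)
  M <- encode_node_memories(g, cb)
  expect_equal(M[, "A"], node_hv(cb, "B") + node_hv(cb, "C"))
  # isolated node gets the zero vector
  gi <- hd_graph(data.frame(src = "A", dst = "B"), nodes = c("A", "B", "Z"))
  Mi <- encode_node_memories(gi, generate_codebook(gi$nodes, 200, seed = 2))
  expect_identical(unname(Mi[, "Z"]), rep(0, 200))
  # directed: out-neighbors only
  gd <- hd_graph(data.frame(src = "A", dst = "B"), directed = TRUE)
  cbd <- generate_codebook(gd$nodes, 300, seed = 3)
  Md <- encode_node_memories(gd, cbd)
  expect_equal(Md[, "A"], node_hv(cbd, "B") + 0)
  expect_identical(unname(Md[, "B"]), rep(0, 300))
  # random graphs, incl. weighted/directed, against an edge-loop oracle
  enc <- value_encoder(400, seed = 9)
  for (s in 1:5) {
    g <- generate_random_graph(10, 20, directed = s > 3, weighted = s %% 2 == 0,
                               seed = s)
    cb <- generate_codebook(g$nodes, 400, seed = s + 50)
    expect_equal(encode_node_memories(g, cb, enc),
                 oracle_node_memories(g, cb, enc))
  }
  expect_error(encode_node_memories(generate_random_graph(5, 4, weighted = TRUE, seed = 1),
                                    generate_codebook(sprintf("n%d", 1:5), 100, 1)),
               "value encoder")
})

test_that("graph memory: edge-sum form and the halving identity", {
  g <- triangle_graph()
  cb <- generate_codebook(g$nodes, 1000, seed = 4)
  G <- encode_graph(g, cb)
  hA <- node_hv(cb, "A"); hB <- node_hv(cb, "B"); hC <- node_hv(cb, "C")
  expect_equal(G$vector, as.numeric(hA * hB + hB * hC + hA * hC))
  # equals (1/2) sum_i H_i * M_i componentwise
  M <- encode_node_memories(g, cb)
  expect_equal(2 * G$vector, rowSums(cb$H * M))
  # empty edge set encodes to the zero vector
  g0 <- hd_graph(NULL, nodes = c("A", "B"))
  expect_identical(encode_graph(g0, generate_codebook(c("A", "B"), 100, 1))$vector,
                   rep(0, 100))
  # halving identity on random graphs, unweighted and weighted
  enc <- value_encoder(600, seed = 5)
  for (s in 1:6) {
    g <- generate_random_graph(12, 25, weighted = s > 3, seed = s)
    cb <- generate_codebook(g$nodes, 600, seed = s + 10)
    G <- encode_graph(g, cb, if (g$weighted) enc)
    M <- encode_node_memories(g, cb, if (g$weighted) enc)
    expect_equal(2 * G$vector, rowSums(cb$H[, g$nodes] * M))
  }
})

test_that("encoding is invariant to edge input order", {
  set.seed(12)
  edges <- generate_random_graph(10, 25, seed = 12)$edges
  shuf <- edges[sample(nrow(edges)), ]
  swap <- sample(nrow(shuf), 10)
  tmp <- shuf$src[swap]; shuf$src[swap] <- shuf$dst[swap]; shuf$dst[swap] <- tmp
  g1 <- hd_graph(edges); g2 <- hd_graph(shuf)
  cb <- generate_codebook(g1$nodes, 500, seed = 13)
  expect_identical(encode_graph(g1, cb)$vector, encode_graph(g2, cb)$vector)
})

test_that("directed encoding is non-commutative", {
  cb <- generate_codebook(c("A", "B"), 10000, seed = 14)
  hA <- node_hv(cb, "A"); hB <- node_hv(cb, "B")
  e_ab <- hA * hv_permute(hB)
  e_ba <- hB * hv_permute(hA)
  expect_lte(abs(hv_similarity(e_ab, e_ba)), 4 / sqrt(10000))
  # the two orientations encode distinguishably
  gd <- hd_graph(data.frame(src = "A", dst = "B"), directed = TRUE)
  G <- encode_graph(gd, cb)
  expect_equal(hv_similarity(G$vector, e_ab), 1)
})

test_that("unbinding recovers node memories up to cross-term noise", {
  # single edge: exact, zero cross terms
  g <- hd_graph(data.frame(src = "A", dst = "B"))
  cb <- generate_codebook(g$nodes, 2000, seed = 15)
  G <- encode_graph(g, cb)
  expect_equal(unbind_node(G, "A", cb), as.numeric(node_hv(cb, "B")))
  # directed single edge: inverse permutation recovers exactly
  gd <- hd_graph(data.frame(src = "A", dst = "B"), directed = TRUE)
  Gd <- encode_graph(gd, cb)
  expect_equal(unbind_node(Gd, "A", cb), as.numeric(node_hv(cb, "B")))
  # the non-source endpoint sees only cross-term noise, near-orthogonal to H_A
  expect_lte(abs(hv_similarity(unbind_node(Gd, "B", cb), node_hv(cb, "A"))),
             4 / sqrt(2000))
  # triangle at D = 10000: similarity with a true neighbor within the band
  gt <- triangle_graph()
  cbt <- generate_codebook(gt$nodes, 10000, seed = 16)
  Gt <- encode_graph(gt, cbt)
  s <- hv_similarity(unbind_node(Gt, "A", cbt), node_hv(cbt, "B"))
  expect_lte(abs(s - 1), 4 * sqrt(2 / 10000))
  expect_error(unbind_node(Gt, "Q", cbt), "unknown node label")
})

test_that("refinement: no-op when separated, convergence when overloaded", {
  # comfortably separated encoding: zero updates, memories unchanged
  g <- generate_random_graph(15, 30, seed = 17)
  cb <- generate_codebook(g$nodes, 4000, seed = 18)
  M0 <- encode_node_memories(g, cb)
  res <- refine(g, cb, T = 0.5)
  expect_identical(res$report$updates_per_pass, 0L)
  expect_true(res$report$converged)
  expect_equal(res$mems, M0)
  expect_identical(res$memory$kind, "refined-undirected")

  # overloaded: memories unbound from the graph hypervector at D = 2000
  g2 <- generate_random_graph(30, 150, seed = 19)
  cb2 <- generate_codebook(g2$nodes, 2000, seed = 20)
  G2 <- encode_graph(g2, cb2)
  mems <- unbind_all(G2, cb2)
  # before refinement the score distributions overlap at T = 0.5
  R0 <- crossprod(mems, cb2$H) / 2000  # R0[j, i] = score of H_i in M_j
  A <- true_adjacency(g2)
  offdiag <- !diag(TRUE, 30)
  expect_gt(sum(R0[A] < 0.5) + sum(R0[!A & offdiag] > 0.5), 0)
  res2 <- refine(g2, cb2, mems = mems, T = 0.5)
  expect_true(res2$report$converged)
  # after convergence every edge scores above T, every non-edge below
  R <- crossprod(res2$mems, cb2$H) / 2000
  expect_true(all(R[A] > 0.5))
  expect_true(all(R[!A & offdiag] < 0.5))
  expect_error(refine(generate_random_graph(6, 5, weighted = TRUE, seed = 1),
                      generate_codebook(sprintf("n%d", 1:6), 100, 1)),
               "unsupported")
})

test_that("a refinement update moves the corrected score by exactly 1", {
  cb <- generate_codebook(c("i", "j"), 3000, seed = 21)
  hi <- node_hv(cb, "i")
  M <- hv_bundle(lapply(1:5, function(s) node_hv(generate_codebook("z", 3000, seed = s), "z")))
  expect_equal(decision_score(M + hi, hi), decision_score(M, hi) + 1)
  expect_equal(decision_score(M - hi, hi), decision_score(M, hi) - 1)
})
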