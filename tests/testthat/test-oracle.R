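test_that("connected subgraph enumeration matches the subset-filter brute force", {
  g <- path_graph(c("A", "B", "C"))
  expect_equal(enumerate_connected_subgraphs(g, 2),
               list(c("A", "B"), c("B", "C")))
  tri <- cycle_graph(c("A", "B", "C"))
  expect_length(enumerate_connected_subgraphs(tri, 2), 3)
  set.seed(10)
  for (trial in 1:3) {
    g <- random_connected_graph(10, "erdos_renyi", runif(1, 0.25, 0.5))
    for (k in 1:10) {
      got <- enumerate_connected_subgraphs(g, k)
      want <- combn_connected_subgraphs(g, k)
      expect_length(got, length(want))
      expect_setequal(vapply(got, state_key, character(1)),
                      vapply(want, state_key, character(1)))
    }
  }
  expect_error(enumerate_connected_subgraphs(g, 3, budget = 2), "budget")
})

test_that("the exact fixed-order posterior matches hand and brute-force computations", {
  g <- path_graph(c("A", "B", "C"))
  p <- exact_posterior_fixed(g, c(A = 0.01, B = 0.25, C = 1), a = 0.5, k = 2)
  # scores: (AB) = (0.01*0.25)^(-1/2) = 20, (BC) = (0.25*1)^(-1/2) = 2
  expect_equal(as.numeric(p), c(20 / 22, 1, 2 / 22))

  # a = 1: weights cancel, probability = containment frequency
  set.seed(20)
  g2 <- random_connected_graph(9, "erdos_renyi", 0.35)
  w2 <- setNames(runif(9), g2$vertices)
  p_unif <- exact_posterior_fixed(g2, w2, a = 1, k = 3)
  subs <- combn_connected_subgraphs(g2, 3)
  freq <- setNames(numeric(9), g2$vertices)
  for (s in subs) freq[s] <- freq[s] + 1
  expect_equal(p_unif, freq / length(subs), ignore_attr = TRUE)

  # general a against the independent subset-filter oracle; marginals sum to k
  w3 <- generate_weights(g2, sample_uniform_module(g2, 3), 0.2)
  p3 <- exact_posterior_fixed(g2, w3, a = 0.2, k = 4)
  expect_equal(p3, combn_posterior_fixed(g2, w3, 0.2, 4), ignore_attr = TRUE)
  expect_equal(sum(p3), 4)
})

test_that("the exact variable-order posterior weighs subgraphs by the cancelled prior form", {
  # two vertices, both weights equal to tau: all three states equiprobable
  g <- load_graph(cbind("A", "B"))
  res <- exact_posterior_variable(g, c(A = 0.1, B = 0.1), a = 0.3, tau = 0.1,
                                  max_order = 2)
  expect_equal(unname(res$p), c(2 / 3, 2 / 3))
  expect_equal(unname(res$order_dist), c(2 / 3, 1 / 3))
  expect_equal(res$n_subgraphs, 3)

  # marginals sum to the expected order under the exact order distribution
  set.seed(25)
  g2 <- random_connected_graph(8, "erdos_renyi", 0.4)
  w2 <- generate_weights(g2, sample_uniform_module(g2, 3), 0.25)
  res2 <- exact_posterior_variable(g2, w2, 0.25, tau = 0.01, max_order = 8)
  expect_equal(sum(res2$p),
               sum(as.numeric(names(res2$order_dist)) * res2$order_dist))
})

test_that("the X3C reduction reproduces the printed construction and bound", {
  inst <- x3c_instance(c("x1", "x2", "x3"), list(c("x1", "x2", "x3")))
  red <- build_x3c_reduction(inst)
  expect_equal(red$graph$n, 5)
  expect_equal(red$eps, 1 / 24)
  expect_equal(red$bound, 3 / 2)
  # the exact-cover ranking v, c1, x1, x2, x3 hits the bound exactly
  expect_equal(ranking_objective(c("v", "c001", "x1", "x2", "x3"), red$p), 3 / 2)
  expect_equal(ranking_objective(brute_force_ocpr(red$graph, red$p), red$p), 3 / 2)

  inst_q2 <- x3c_instance(sprintf("x%d", 1:6),
                          list(c("x1", "x2", "x3"), c("x4", "x5", "x6")))
  expect_equal(build_x3c_reduction(inst_q2)$eps, 1 / 72)

  # duplicated triple: cover still exists, optimum still 3/2
  inst_dup <- x3c_instance(c("x1", "x2", "x3"),
                           list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  red_dup <- build_x3c_reduction(inst_dup)
  expect_equal(red_dup$graph$n, 6)
  expect_equal(ranking_objective(brute_force_ocpr(red_dup$graph, red_dup$p),
                                 red_dup$p), 3 / 2)

  # overlapping triples with no exact cover: the minimum exceeds 3/2
  inst_nc <- x3c_instance(sprintf("x%d", 1:6),
                          list(c("x1", "x2", "x3"), c("x1", "x4", "x5"),
                               c("x1", "x2", "x6")))
  red_nc <- build_x3c_reduction(inst_nc)
  expect_gt(ranking_objective(brute_force_ocpr(red_nc$graph, red_nc$p),
                              red_nc$p), 3 / 2)

  # an element covered by no set breaks the construction
  expect_error(build_x3c_reduction(
    x3c_instance(sprintf("x%d", 1:6), list(c("x1", "x2", "x3")))),
    "disconnected")
})

test_that("ranking_objective sums 1-based rank times probability", {
  expect_equal(ranking_objective(c("a", "b"), c(a = 0, b = 0)), 0)
  expect_equal(ranking_objective(c("a", "b"), c(a = 1, b = 1)), 3)
  expect_equal(ranking_objective(c("b", "a"), c(a = 1, b = 1)), 3)
})

test_that("brute-force OCPR is optimal and handles stars correctly", {
  # with the highest probability at the center, the optimum starts there;
  # (a high-probability leaf can legally start a CP ranking, since a
  # singleton prefix is connected, so center-first is not forced in general)
  gs <- star_graph("c", c("x", "y", "z"))
  p <- c(c = 0.9, x = 0.3, y = 0.2, z = 0.1)
  bf <- brute_force_ocpr(gs, p)
  expect_equal(bf$order, c("c", "x", "y", "z"))
  set.seed(28)
  for (trial in 1:5) {
    g <- random_connected_graph(7, "erdos_renyi", 0.4)
    pr <- setNames(runif(7), g$vertices)
    bf <- brute_force_ocpr(g, pr)
    expect_true(all(vapply(seq_len(7), function(k) {
      is_connected_induced(g, bf$order[1:k])
    }, logical(1))))
    expect_lte(ranking_objective(bf, pr),
               ranking_objective(ocpr_heuristic(g, pr), pr) + 1e-12)
    expect_lte(ranking_objective(bf, pr),
               ranking_objective(random_cp_ranking(g), pr) + 1e-12)
  }
  expect_error(brute_force_ocpr(random_connected_graph(12, "erdos_renyi", 0.3),
                                setNames(runif(12), NULL)), "n <= 10")
})
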