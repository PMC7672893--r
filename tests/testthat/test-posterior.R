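test_that("event probabilities reduce to vertex probabilities and match an enumeration oracle", {
  set.seed(6)
  g <- random_connected_graph(9, "erdos_renyi", 0.35)
  w <- generate_weights(g, sample_uniform_module(g, 3), 0.2)
  a <- 0.2; tau <- 0.05
  s <- run_mcmc(g, w, mode = "variable", tau = tau, a = a,
                n_iterations = 2e5, burn_in = 5000, seed = 17,
                retain_samples = TRUE)
  p <- estimate_vertex_probabilities(s)
  v1 <- g$vertices[1]; v2 <- g$vertices[5]
  expect_equal(event_probability(s, function(m) TRUE), 1)
  expect_equal(event_probability(s, function(m) v1 %in% m), p[[v1]])
  # oracle: exact posterior mass of the event over the enumerated state space
  states <- unlist(lapply(1:9, enumerate_connected_subgraphs, g = g),
                   recursive = FALSE)
  mass <- vapply(states, function(st) prod((w[st] / tau)^(a - 1)), numeric(1))
  mass <- mass / sum(mass)
  hit <- vapply(states, function(st) (v1 %in% st) || (v2 %in% st), logical(1))
  est <- event_probability(s, function(m) (v1 %in% m) || (v2 %in% m))
  expect_equal(est, sum(mass[hit]), tolerance = 0.02)
  # counts-only collections cannot answer event queries
  s2 <- run_mcmc(g, w, mode = "variable", tau = tau, a = a,
                 n_iterations = 100, burn_in = 10, seed = 1)
  expect_error(event_probability(s2, function(m) TRUE), "retain_samples")
})

test_that("set_fdr is the mean miss probability and is monotone in low-p additions", {
  p <- c(a = 1, b = 1, c = 0.9, d = 0.7, e = 0.1)
  expect_equal(set_fdr(p, c("a", "b")), 0)
  expect_equal(set_fdr(p, c("c", "d")), 0.2)
  expect_error(set_fdr(p, character(0)), "non-empty")
  # adding a vertex below the current mean p raises the FDR
  expect_gt(set_fdr(p, c("a", "b", "e")), set_fdr(p, c("a", "b")))
  # over all vertices of a fixed-order chain: 1 - k/n
  g <- path_graph(c("A", "B", "C", "D"))
  s <- run_mcmc(g, setNames(rep(.5, 4), g$vertices), mode = "fixed", k = 2,
                a = 0.5, n_iterations = 2000, burn_in = 100, seed = 3)
  pp <- estimate_vertex_probabilities(s)
  expect_equal(set_fdr(pp, g$vertices), 1 - 2 / 4)
})

test_that("expected AUC formula has the right extremes and swap sensitivity", {
  n <- 8; m <- 3
  ids <- letters[1:n]
  p_perfect <- setNames(c(rep(1, m), rep(0, n - m)), ids)
  expect_equal(expected_auc(ids, p_perfect, m), 1)
  p_worst <- setNames(c(rep(0, n - m), rep(1, m)), ids)
  expect_equal(expected_auc(ids, p_worst, m), 0)
  # swapping adjacent ranks i, i+1 changes the value by (p_{i+1}-p_i)/(m(n-m))
  set.seed(4)
  p <- setNames(runif(n), ids)
  i <- 4
  swapped <- ids; swapped[c(i, i + 1)] <- ids[c(i + 1, i)]
  expect_equal(expected_auc(swapped, p, m) - expected_auc(ids, p, m),
               (p[[ids[i + 1]]] - p[[ids[i]]]) / (m * (n - m)))
  expect_error(expected_auc(ids, p, n), "m")
})

test_that("the expected AUC equals the posterior-weighted mean of empirical AUCs", {
  set.seed(12)
  g <- random_connected_graph(10, "erdos_renyi", 0.35)
  w <- generate_weights(g, sample_uniform_module(g, 3), 0.2)
  a <- 0.25; k <- 3
  subs <- combn_connected_subgraphs(g, k)
  mass <- vapply(subs, function(s) prod(w[s]^(a - 1)), numeric(1))
  mass <- mass / sum(mass)
  p <- setNames(numeric(g$n), g$vertices)
  for (i in seq_along(subs)) p[subs[[i]]] <- p[subs[[i]]] + mass[i]
  ord <- rank_by_weight(w)$order
  oracle <- sum(mass * vapply(subs, function(s) counting_auc(ord, s), numeric(1)))
  expect_equal(expected_auc(ord, p, k), oracle, tolerance = 1e-10)
})

test_that("ranking by descending probability maximizes the expected AUC", {
  set.seed(19)
  n <- 6
  perms <- NULL
  rec <- function(pre, rest) {
    if (length(rest) == 0) perms[[length(perms) + 1]] <<- pre
    else for (i in seq_along(rest)) rec(c(pre, rest[i]), rest[-i])
  }
  perms <- list(); rec(character(0), letters[1:n])
  for (trial in 1:3) {
    p <- setNames(runif(n), letters[1:n])
    m <- sample(1:(n - 1), 1)
    best <- max(vapply(perms, expected_auc, numeric(1), p = p, m = m))
    expect_equal(expected_auc(rank_by_probability(p), p, m), best,
                 tolerance = 1e-12)
  }
})

test_that("unknown-order AUC reduces correctly and the exact method matches brute force", {
  set.seed(23)
  g <- random_connected_graph(12, "erdos_renyi", 0.3)
  w <- generate_weights(g, sample_uniform_module(g, 3), 0.2)
  # degenerate collection (fixed chain): all three methods equal the closed form
  s_fix <- run_mcmc(g, w, mode = "fixed", k = 3, a = 0.2,
                    n_iterations = 5000, burn_in = 500, seed = 2)
  p_fix <- estimate_vertex_probabilities(s_fix)
  ord <- rank_by_probability(p_fix)$order
  closed <- expected_auc(ord, p_fix, 3)
  for (meth in c("p_prime", "exact", "p_approx"))
    expect_equal(expected_auc_unknown_order(ord, s_fix, meth), closed)

  # mixed-order collection: exact method == sample-by-sample expectation
  s_var <- run_mcmc(g, w, mode = "variable", tau = 0.02, a = 0.2,
                    n_iterations = 3e4, burn_in = 1000, seed = 5,
                    retain_samples = TRUE)
  p_var <- estimate_vertex_probabilities(s_var)
  ord2 <- rank_by_probability(p_var)$order
  brute <- mean(vapply(s_var$retained, function(mod) counting_auc(ord2, mod),
                       numeric(1)))
  expect_equal(expected_auc_unknown_order(ord2, s_var, "exact"), brute,
               tolerance = 1e-10)
  # the closed-form p' variant shares the exact ranking-dependent term but
  # replaces the expectation of a ratio by a ratio of expectations in the
  # constant term; its deviation from the exact value is exactly that gap
  sizes <- as.numeric(names(s_var$size_counts))
  pm <- as.numeric(s_var$size_counts) / s_var$n_samples
  n <- length(s_var$vertices)
  const_gap <- sum(pm * sizes * (sizes + 1)) / (2 * sum(pm * sizes * (n - sizes))) -
    sum(pm * (sizes + 1) / (2 * (n - sizes)))
  expect_equal(expected_auc_unknown_order(ord2, s_var, "p_prime") - brute,
               const_gap, tolerance = 1e-10)

  # a single retained sample: AUC against that sample as ground truth
  s_one <- run_mcmc(g, w, mode = "variable", tau = 0.02, a = 0.2,
                    n_iterations = 200, strategy = "independent_runs",
                    n_runs = 1, seed = 9, retain_samples = TRUE)
  expect_equal(expected_auc_unknown_order(ord2, s_one, "exact"),
               counting_auc(ord2, s_one$retained[[1]]))
})
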