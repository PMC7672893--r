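test_that("init_state grows connected states of the right order", {
  g <- path_graph(c("A", "B", "C"))
  expect_equal(init_state(g, "fixed", k = 3, seed = 1), c("A", "B", "C"))
  expect_length(init_state(g, "variable", seed = 1), 1)
  set.seed(2)
  gr <- random_connected_graph(20, "erdos_renyi", 0.2)
  for (k in c(1, 5, 12)) {
    s <- init_state(gr, "fixed", k = k)
    expect_length(s, k)
    expect_true(is_connected_induced(gr, s))
  }
  # k = n is the single full-graph state; beyond n is impossible
  expect_equal(sort(init_state(gr, "fixed", k = 20)), sort(gr$vertices))
  expect_error(init_state(gr, "fixed", k = 21), "k")
})

test_that("fixed-order proposal and acceptance follow the printed formulas", {
  g <- path_graph(c("A", "B", "C", "D"))
  expect_equal(proposal_prob_fixed(g, c("B", "C")), 1 / 4)
  # disconnected proposal gets zero acceptance
  expect_equal(acceptance_prob_fixed(g, c(A = .5, B = .5, C = .5, D = .5), 0.5,
                                     c("B", "C"), "C", "D"), 0)
  # symmetric swap: same weight, same frontier size
  expect_equal(acceptance_prob_fixed(g, c(A = .5, B = .5, C = .5, D = .5), 0.5,
                                     c("B", "C"), "B", "D"), 1)
  # a = 1: only the frontier ratio survives
  w <- c(A = 0.9, B = 0.1, C = 0.2, D = 0.4)
  rho <- acceptance_prob_fixed(g, w, 1, c("B", "C"), "B", "D")
  expect_equal(rho, min(1, 2 / 2))
  # (0.01/0.1)^(-0.5) = sqrt(10) > 1 on equal frontiers
  g4 <- cycle_graph(c("A", "B", "C", "D"))
  w4 <- c(A = 0.1, B = 0.5, C = 0.01, D = 0.5)
  expect_equal(acceptance_prob_fixed(g4, w4, 0.5, c("A", "B"), "A", "C"), 1)
})

test_that("variable-order chain satisfies detailed balance on an enumerated state space", {
  set.seed(5)
  g <- load_graph(cbind(c("a", "a", "b", "c", "d"),
                        c("b", "c", "c", "d", "e")))
  w <- setNames(c(0.02, 0.3, 0.07, 0.6, 0.15), g$vertices)
  a <- 0.3; tau <- 0.05
  states <- unlist(lapply(1:5, enumerate_connected_subgraphs, g = g),
                   recursive = FALSE)
  pi_un <- vapply(states, function(s) prod((w[s] / tau)^(a - 1)), numeric(1))
  for (i in seq_along(states)) {
    s <- states[[i]]
    closed_s <- length(s) + length(neighborhood(g, s))
    for (u in neighborhood(g, s)) {
      sp <- sort(c(s, u))
      j <- which(vapply(states, function(x) identical(x, sp) ||
                          setequal(x, sp), logical(1)))
      closed_sp <- length(sp) + length(neighborhood(g, sp))
      flow_fwd <- pi_un[i] * (1 / closed_s) *
        acceptance_prob_variable(g, w, a, tau, s, sp)
      flow_bwd <- pi_un[j] * (1 / closed_sp) *
        acceptance_prob_variable(g, w, a, tau, sp, s)
      expect_equal(flow_fwd, flow_bwd, tolerance = 1e-12)
    }
  }
  # removing a cut vertex is always rejected
  expect_equal(acceptance_prob_variable(g, w, a, tau, c("a", "c", "d"), c("a", "d")), 0)
})

test_that("long-run occupancy matches the exact posterior and tightens with chain length", {
  set.seed(9)
  g <- random_connected_graph(10, "erdos_renyi", 0.35)
  mod <- sample_uniform_module(g, 3)
  w <- generate_weights(g, mod, 0.15)
  pex <- exact_posterior_fixed(g, w, 0.15, 3)
  tv <- vapply(c(1e4, 1e5), function(iters) {
    s <- run_mcmc(g, w, mode = "fixed", k = 3, a = 0.15,
                  n_iterations = iters, burn_in = 1000, seed = 21)
    0.5 * sum(abs(estimate_vertex_probabilities(s) - pex))
  }, numeric(1))
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.02)
})

test_that("fixed-order samples all have order k and induce connected subgraphs", {
  set.seed(3)
  g <- random_connected_graph(12, "erdos_renyi", 0.3)
  w <- generate_weights(g, sample_uniform_module(g, 4), 0.2)
  s <- run_mcmc(g, w, mode = "fixed", k = 4, a = 0.2, n_iterations = 3000,
                burn_in = 500, seed = 4, retain_samples = TRUE)
  expect_equal(names(s$size_counts), "4")
  expect_true(all(lengths(s$retained) == 4))
  for (smp in s$retained[seq(1, length(s$retained), by = 100)])
    expect_true(is_connected_induced(g, smp))
  # counting identity: sum of vertex probabilities = mean sampled order
  p <- estimate_vertex_probabilities(s)
  expect_equal(sum(p), mean_module_order(s))
})

test_that("identical seed and config reproduce the collection exactly", {
  set.seed(8)
  g <- random_connected_graph(15, "erdos_renyi", 0.25)
  w <- generate_weights(g, sample_uniform_module(g, 5), 0.2)
  run <- function() run_mcmc(g, w, mode = "variable", tau = 1e-3, a = 0.2,
                             n_iterations = 5000, burn_in = 100, seed = 77)
  s1 <- run(); s2 <- run()
  expect_identical(s1$vertex_counts, s2$vertex_counts)
  expect_identical(s1$size_counts, s2$size_counts)
  expect_identical(s1$trace, s2$trace)
})

test_that("trace bookkeeping records floor(n_iterations / trace_every) points", {
  g <- path_graph(c("A", "B", "C", "D"))
  w <- setNames(rep(0.5, 4), g$vertices)
  s <- run_mcmc(g, w, mode = "fixed", k = 2, a = 0.5, n_iterations = 1050,
                burn_in = 10, seed = 1, trace_every = 100)
  expect_equal(nrow(s$trace), 10)
})

test_that("independent runs behave like Bernoulli trials around the exact posterior", {
  set.seed(14)
  g <- random_connected_graph(8, "erdos_renyi", 0.4)
  w <- generate_weights(g, sample_uniform_module(g, 3), 0.2)
  pex <- exact_posterior_fixed(g, w, 0.2, 3)
  R <- 150
  s <- run_mcmc(g, w, mode = "fixed", k = 3, a = 0.2, n_iterations = 500,
                strategy = "independent_runs", n_runs = R, seed = 31)
  expect_equal(s$n_samples, R)
  phat <- estimate_vertex_probabilities(s)
  bound <- 4 * sqrt(pex * (1 - pex) / R)
  expect_gte(mean(abs(phat - pex) <= bound + 1e-9), 0.95)
})

test_that("unweighted vertices are rejected", {
  g <- path_graph(c("A", "B", "C"))
  expect_error(run_mcmc(g, c(A = 0.5, B = 0.5), mode = "fixed", k = 2, a = 0.5,
                        n_iterations = 10, burn_in = 1),
               "unweighted")
})
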