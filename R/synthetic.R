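# Simulation instances: random connected graphs, planted connected modules
# chosen uniformly at random (via the constant-weight chain), and vertex
# weights from the beta-uniform mixture — module vertices beta(a, 1),
# background vertices Uniform(0, 1).

#' Random connected graph
#'
#' `erdos_renyi`: G(n, p) with edge probability `param`, resampled until
#' connected (up to `max_attempts`). `scale_free`: Barabasi-Albert
#' preferential attachment with `param` edges per new vertex, connected by
#' construction.
#'
#' @param n vertex count, >= 2.
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param param edge probability (ER) or edges per new vertex (scale free).
#' @param seed optional RNG seed.
#' @param max_attempts resampling cap for the ER model.
#' @return a connected `interaction_graph` with zero-padded vertex ids
#'   `v001, v002, ...` (index order = lexicographic order).
#' @export
random_connected_graph <- function(n, model = c("erdos_renyi", "scale_free"),
                                   param, seed = NULL, max_attempts = 1000) {
  model <- match.arg(model)
  if (n < 2) stop("`n` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  width <- max(3, nchar(as.character(n)))
  ids <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  if (model == "erdos_renyi") {
    for (attempt in seq_len(max_attempts)) {
      ig <- igraph::sample_gnp(n, param)
      if (igraph::is_connected(ig) && igraph::ecount(ig) > 0) {
        el <- igraph::as_edgelist(ig, names = FALSE)
        return(load_graph(cbind(ids[el[, 1]], ids[el[, 2]])))
      }
    }
    stop(sprintf("no connected G(%d, %g) graph in %d attempts", n, param, max_attempts))
  }
  ig <- igraph::sample_pa(n, power = 1, m = param, directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  load_graph(cbind(ids[el[, 1]], ids[el[, 2]]))
}

#' Sample a module uniformly from connected subgraphs of a given order
#'
#' Runs the fixed-order chain with constant weights (the `a = 1` case, where
#' the acceptance ratio reduces to `min{1, |nei(S)|/|nei(S')|}`); its
#' stationary law is uniform over connected `m`-subgraphs. The default number
#' of iterations (`100 * m`, at least 1000) is a heuristic burn-in that works
#' well for the graph sizes used here.
#'
#' @param g a connected `interaction_graph`.
#' @param m module order, `1 <= m < n`.
#' @param iterations chain length before the state is taken.
#' @param seed optional RNG seed.
#' @return character vector of module vertex ids.
#' @export
sample_uniform_module <- function(g, m, iterations = max(1000, 100 * m),
                                  seed = NULL) {
  stopifnot_graph(g)
  if (m < 1 || m >= g$n) stop("`m` must satisfy 1 <= m < n")
  if (!is.null(seed)) set.seed(seed)
  w <- setNames(rep(1, g$n), g$vertices)
  res <- run_mcmc(g, w, mode = "fixed", k = m, a = 1,
                  n_iterations = iterations, burn_in = iterations - 1,
                  strategy = "independent_runs", n_runs = 1,
                  trace_every = 0, retain_samples = TRUE)
  sort(res$retained[[1]], method = "radix")
}

#' Generate BUM-distributed vertex weights for a planted module
#'
#' Module vertices receive `beta(a, 1)` draws (inverse CDF: `U^(1/a)`),
#' background vertices Uniform(0, 1); exact zeros are resampled.
#'
#' @param g an `interaction_graph`.
#' @param module character vector of planted module vertices.
#' @param a beta shape, `0 < a <= 1`.
#' @param seed optional RNG seed.
#' @return named weight vector over all vertices, values in (0, 1].
#' @export
generate_weights <- function(g, module, a, seed = NULL) {
  stopifnot_graph(g)
  if (a <= 0 || a > 1) stop("`a` must be in (0, 1]")
  vertex_index(g, module)  # validates membership
  if (!is.null(seed)) set.seed(seed)
  draw <- function(k, transform) {
    x <- transform(runif(k))
    while (any(x == 0)) x[x == 0] <- transform(runif(sum(x == 0)))
    x
  }
  w <- setNames(numeric(g$n), g$vertices)
  bg <- setdiff(g$vertices, module)
  w[module] <- draw(length(module), function(u) u^(1 / a))
  w[bg] <- draw(length(bg), identity)
  w
}

#' Generate a complete synthetic benchmark instance
#'
#' Composes the graph, module and weight generators following the simulation
#' protocol: the module order is drawn uniformly from 5–25% of the graph
#' order and the beta shape from \[0.01, 0.5\] unless fixed explicitly.
#'
#' @param n graph order.
#' @param model graph model (see [random_connected_graph()]).
#' @param param graph model parameter; defaults to 2 attachment edges
#'   (scale free) or `2 * log(n) / n` (Erdos-Renyi).
#' @param m_frac_range range of the module-order fraction.
#' @param a_range range of the beta shape.
#' @param m,a fixed module order / shape overriding the ranges.
#' @param target_edges optional edge-count target: the graph is resampled
#'   until its edge count is within 10% of this value.
#' @param seed RNG seed (the whole instance is reproducible from it).
#' @return object of class `synthetic_instance`: list with `graph`, `module`,
#'   `weights`, `gen_params`.
#' @export
generate_instance <- function(n, model = c("scale_free", "erdos_renyi"),
                              param = NULL, m_frac_range = c(0.05, 0.25),
                              a_range = c(0.01, 0.5), m = NULL, a = NULL,
                              target_edges = NULL, seed = NULL) {
  model <- match.arg(model)
  if (is.null(param))
    param <- if (model == "scale_free") 2 else min(1, 2 * log(n) / n)
  if (!is.null(seed)) set.seed(seed)
  g <- random_connected_graph(n, model, param)
  if (!is.null(target_edges)) {
    attempts <- 1
    while (abs(g$n_edges - target_edges) > 0.1 * target_edges) {
      if ((attempts <- attempts + 1) > 1000)
        stop("could not hit the target edge count within 10% in 1000 attempts")
      g <- random_connected_graph(n, model, param)
    }
  }
  if (is.null(m)) {
    lo <- max(1, ceiling(m_frac_range[1] * n))
    hi <- min(n - 1, floor(m_frac_range[2] * n))
    m <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1, 1) - 1
  }
  if (is.null(a)) a <- runif(1, a_range[1], a_range[2])
  module <- sample_uniform_module(g, m)
  weights <- generate_weights(g, module, a)
  structure(list(
    graph = g, module = module, weights = weights,
    gen_params = list(n = n, model = model, param = param, m = m, a = a,
                      target_edges = target_edges, seed = seed)),
    class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "synthetic_instance: %d vertices, %d edges (%s), planted module of %d, a = %.3f\n",
    x$graph$n, x$graph$n_edges, x$gen_params$model, length(x$module), x$gen_params$a))
  invisible(x)
}
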