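# Metropolis-Hastings sampling of connected subgraphs from the module
# posterior. Two chains are available:
#  * fixed order: states are connected k-subgraphs; a move swaps one member
#    for one frontier vertex, with proposal Q(S'|S) = 1/(|nei(S)| * |S|) and
#    acceptance min{1, (w+/w-)^(a-1) * |nei(S)|/|nei(S')|};
#  * variable order: states are non-empty connected subgraphs; a move adds or
#    removes a single vertex chosen uniformly from nei(S) u V(S), with each
#    vertex carrying a prior penalty a * tau^(a-1), giving stationary law
#    pi(S) proportional to prod_{v in S} (w_v / tau)^(a-1).
# Disconnecting moves are proposed and rejected (zero posterior), which keeps
# the printed proposal probabilities exact.

#' Random initial chain state
#'
#' Fixed order: starts at a uniformly chosen vertex and repeatedly adds a
#' uniformly chosen frontier vertex until the state has `k` members (a random
#' connected growth — not uniform over connected k-subgraphs, which is
#' irrelevant after burn-in by ergodicity). Variable order: a single uniformly
#' chosen vertex.
#'
#' @param g an `interaction_graph`.
#' @param mode `"fixed"` or `"variable"`.
#' @param k module order (fixed mode), `1 <= k < n`.
#' @param seed optional RNG seed.
#' @return character vector of member vertex ids.
#' @export
init_state <- function(g, mode = c("variable", "fixed"), k = NULL, seed = NULL) {
  stopifnot_graph(g)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "variable") k <- 1L
  # k = n is a legal (single) state here; the chain itself requires k < n
  if (is.null(k) || k < 1 || k > g$n) stop("`k` must satisfy 1 <= k <= n")
  members <- sample.int(g$n, 1)
  while (length(members) < k) {
    frontier <- setdiff(unique(unlist(g$adj[members], use.names = FALSE)), members)
    members <- c(members, frontier[sample.int(length(frontier), 1)])
  }
  sort(g$vertices[members], method = "radix")
}

#' Proposal probability of the fixed-order chain
#'
#' `Q(S' | S) = 1 / (|nei(S)| * |S|)`: the swap proposal draws the leaving
#' vertex uniformly from `S` and the entering vertex uniformly from the
#' frontier of `S` computed before the removal.
#'
#' @param g an `interaction_graph`.
#' @param members current state (character vertex ids).
#' @return the proposal probability (identical for every proposed `S'`).
#' @export
proposal_prob_fixed <- function(g, members) {
  1 / (length(neighborhood(g, members)) * length(members))
}

#' Acceptance probability of the fixed-order chain
#'
#' Zero when the proposed state is disconnected, otherwise
#' `min{1, (w(v+)/w(v-))^(a-1) * |nei(S)| / |nei(S')|}` (computed in log
#' space).
#'
#' @param g an `interaction_graph`.
#' @param w named vector of vertex weights (p-values).
#' @param a beta shape parameter.
#' @param members current state `S`.
#' @param v_minus member leaving `S`.
#' @param v_plus frontier vertex entering.
#' @return the acceptance probability.
#' @export
acceptance_prob_fixed <- function(g, w, a, members, v_minus, v_plus) {
  s_prime <- c(setdiff(members, v_minus), v_plus)
  if (!is_connected_induced(g, s_prime)) return(0)
  log_rho <- (a - 1) * (log(w[[v_plus]]) - log(w[[v_minus]])) +
    log(length(neighborhood(g, members))) -
    log(length(neighborhood(g, s_prime)))
  min(1, exp(log_rho))
}

#' Acceptance probability of the variable-order chain
#'
#' For an addition `S' = S u {v+}`:
#' `min{1, (w(v+)/tau)^(a-1) * |nei(S) u V(S)| / |nei(S') u V(S')|}`;
#' for a removal `S' = S \ {v-}` the weight factor is `(tau/w(v-))^(a-1)`,
#' and the result is 0 when the removal disconnects the state.
#'
#' @param g an `interaction_graph`.
#' @param w named vector of vertex weights.
#' @param a beta shape parameter.
#' @param tau confidence threshold in (0, 1).
#' @param members current state `S`.
#' @param s_prime proposed state, differing from `S` by exactly one vertex.
#' @return the acceptance probability.
#' @export
acceptance_prob_variable <- function(g, w, a, tau, members, s_prime) {
  closed_old <- length(members) + length(neighborhood(g, members))
  if (length(s_prime) == length(members) + 1) {
    v_plus <- setdiff(s_prime, members)
    if (length(v_plus) != 1 || !(v_plus %in% neighborhood(g, members)))
      stop("`s_prime` must add a single frontier vertex")
    log_fac <- (a - 1) * (log(w[[v_plus]]) - log(tau))
  } else if (length(s_prime) == length(members) - 1) {
    v_minus <- setdiff(members, s_prime)
    if (length(v_minus) != 1) stop("`s_prime` must remove a single member")
    if (length(s_prime) == 0) stop("the chain never occupies the empty state")
    if (!is_connected_induced(g, s_prime)) return(0)
    log_fac <- (a - 1) * (log(tau) - log(w[[v_minus]]))
  } else {
    stop("`s_prime` must differ from `members` by exactly one vertex")
  }
  closed_new <- length(s_prime) + length(neighborhood(g, s_prime))
  min(1, exp(log_fac + log(closed_old) - log(closed_new)))
}

check_weights <- function(g, w) {
  if (is.null(names(w))) stop("`weights` must be a named vector (vertex id -> p-value)")
  missing <- setdiff(g$vertices, names(w))
  if (length(missing) > 0)
    stop("unweighted vertices: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  w <- w[g$vertices]
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weights must be p-values in [0, 1]")
  pmax(w, W_CLAMP)
}

#' Run the Metropolis-Hastings module sampler
#'
#' Samples connected subgraphs from the module posterior and tallies
#' per-vertex and per-order occurrence counts. With
#' `strategy = "one_long_run"` every visited state after `burn_in` iterations
#' contributes one sample (rejected moves re-count the current state, which is
#' what makes the occupancy estimate the stationary law). With
#' `strategy = "independent_runs"`, `n_runs` chains of `n_iterations` each are
#' run and only each final state is kept, giving independent samples.
#'
#' @param g an `interaction_graph`.
#' @param weights named vector of vertex p-values covering all vertices.
#' @param mode `"variable"` (arbitrary module order, default) or `"fixed"`.
#' @param k module order for the fixed chain; defaults to
#'   [estimate_module_order()] from a BUM fit of `weights`.
#' @param tau confidence threshold of the variable chain (per-vertex prior
#'   penalty `a * tau^(a-1)`); default `1e-7`.
#' @param a beta shape; fitted from `weights` when omitted.
#' @param n_iterations chain length (per run), default `1e5`.
#' @param burn_in iterations discarded before sampling (long-run strategy),
#'   default `25000`.
#' @param strategy `"one_long_run"` or `"independent_runs"`.
#' @param n_runs number of chains for the independent strategy.
#' @param seed RNG seed (set it for reproducible runs).
#' @param trace_every record the subgraph log-likelihood every this many
#'   iterations (0 disables the trace).
#' @param retain_samples keep every sampled vertex set (needed by
#'   [event_probability()]; memory-heavy for long runs).
#' @param init optional initial state (character vertex ids); defaults to
#'   [init_state()].
#' @return object of class `mcmc_samples`; see
#'   [estimate_vertex_probabilities()].
#' @export
run_mcmc <- function(g, weights, mode = c("variable", "fixed"), k = NULL,
                     tau = 1e-7, a = NULL, n_iterations = 1e5,
                     burn_in = 25000, strategy = c("one_long_run", "independent_runs"),
                     n_runs = 1000, seed = NULL, trace_every = 100,
                     retain_samples = FALSE, init = NULL) {
  stopifnot_graph(g)
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  w <- check_weights(g, weights)
  if (is.null(a) || (mode == "fixed" && is.null(k))) {
    fit <- fit_bum(w)
    if (is.null(a)) a <- fit$a
    if (mode == "fixed" && is.null(k)) k <- estimate_module_order(fit, g$n)
  }
  if (a <= 0 || a > 1) stop("`a` must be in (0, 1]")
  if (mode == "fixed" && (k < 1 || k >= g$n)) stop("`k` must satisfy 1 <= k < n")
  if (mode == "variable" && (tau <= 0 || tau >= 1)) stop("`tau` must be in (0, 1)")
  if (strategy == "one_long_run" && burn_in >= n_iterations)
    stop("`burn_in` must be smaller than `n_iterations`")
  if (!is.null(seed)) set.seed(seed)

  csr <- graph_csr(g)
  logw <- log(w)
  run_one <- function(record, init_members) {
    .run_chain_cpp(csr$offsets, csr$targets, logw, a,
                   if (mode == "fixed") 0L else 1L, log(tau),
                   vertex_index(g, init_members) - 1L,
                   n_iterations, burn_in, record, as.integer(trace_every),
                   retain_samples)
  }

  if (strategy == "one_long_run") {
    if (is.null(init)) init <- init_state(g, mode, k)
    res <- run_one(1L, init)
    traces <- if (length(res$trace_iter))
      data.frame(run = 1L, iteration = res$trace_iter, loglik = res$trace_loglik)
    else NULL
    results <- list(res)
  } else {
    results <- vector("list", n_runs)
    traces <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      init_r <- if (is.null(init)) init_state(g, mode, k) else init
      res <- run_one(2L, init_r)
      results[[r]] <- res
      if (length(res$trace_iter))
        traces[[r]] <- data.frame(run = r, iteration = res$trace_iter,
                                  loglik = res$trace_loglik)
    }
    traces <- if (any(!vapply(traces, is.null, logical(1))))
      do.call(rbind, traces) else NULL
  }

  # merge per-run tallies
  vertex_counts <- setNames(numeric(g$n), g$vertices)
  size_tallies <- list()
  vsc <- list()   # size -> per-vertex counts
  n_samples <- 0
  retained <- if (retain_samples) list() else NULL
  for (res in results) {
    n_samples <- n_samples + res$n_samples
    vertex_counts <- vertex_counts + res$vertex_counts
    for (j in seq_along(res$sizes)) {
      key <- as.character(res$sizes[j])
      size_tallies[[key]] <- (size_tallies[[key]] %||% 0) + res$size_counts[j]
      vsc[[key]] <- (vsc[[key]] %||% numeric(g$n)) + res$vertex_size_counts[, j]
    }
    if (retain_samples) {
      retained <- c(retained, lapply(res$retained, function(s) g$vertices[s + 1L]))
    }
  }
  sizes <- sort(as.integer(names(size_tallies)))
  size_counts <- setNames(vapply(as.character(sizes), function(k) size_tallies[[k]],
                                 numeric(1)), sizes)
  vertex_size_counts <- do.call(cbind, lapply(as.character(sizes), function(k) vsc[[k]]))
  dimnames(vertex_size_counts) <- list(g$vertices, sizes)

  structure(list(
    n_samples = n_samples,
    vertices = g$vertices,
    vertex_counts = vertex_counts,
    size_counts = size_counts,
    vertex_size_counts = vertex_size_counts,
    retained = retained,
    trace = traces,
    config = list(mode = mode, k = k, tau = tau, a = a,
                  n_iterations = n_iterations, burn_in = burn_in,
                  strategy = strategy,
                  n_runs = if (strategy == "independent_runs") n_runs else 1L,
                  seed = seed)),
    class = "mcmc_samples")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.mcmc_samples <- function(x, ...) {
  cat(sprintf("mcmc_samples: %s samples (%s chain, %s)\n",
              format(x$n_samples, big.mark = ","), x$config$mode, x$config$strategy))
  cat(sprintf("  module orders observed: %s\n",
              paste(names(x$size_counts), collapse = ", ")))
  invisible(x)
}

#' Per-vertex module membership probabilities
#'
#' The Monte-Carlo estimator `P(v in M | W = w) ~ |{S in samples : v in S}| /
#' |samples|`; vertices never sampled get probability 0.
#'
#' @param samples an `mcmc_samples` object.
#' @return named numeric vector of probabilities over all graph vertices.
#' @export
estimate_vertex_probabilities <- function(samples) {
  if (!inherits(samples, "mcmc_samples")) stop("expected an `mcmc_samples` object")
  if (samples$n_samples < 1) stop("empty sample collection")
  samples$vertex_counts / samples$n_samples
}

#' Expected module order of a sample collection
#'
#' @param samples an `mcmc_samples` object.
#' @return the mean sampled module order.
#' @export
mean_module_order <- function(samples) {
  sizes <- as.numeric(names(samples$size_counts))
  sum(sizes * samples$size_counts) / samples$n_samples
}
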