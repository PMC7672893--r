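# Exact small-instance computations used as ground truth: enumeration of
# connected induced subgraphs, exact module posteriors (fixed and variable
# order), the X3C -> OCPR reduction construction, and a brute-force OCPR
# solver (dynamic programming over connected vertex subsets).

DEFAULT_ENUM_BUDGET <- 5e7

#' Enumerate connected induced subgraphs of a given order
#'
#' Yields every connected induced subgraph of order exactly `k` exactly once
#' (recursive prefix extension with exclusion sets; deterministic order).
#'
#' @param g an `interaction_graph`.
#' @param k subgraph order, `1 <= k <= n`.
#' @param budget abort when more than this many subgraphs are produced.
#' @return list of character vectors of vertex ids.
#' @export
enumerate_connected_subgraphs <- function(g, k, budget = DEFAULT_ENUM_BUDGET) {
  stopifnot_graph(g)
  if (k < 1 || k > g$n) stop("`k` must satisfy 1 <= k <= n")
  csr <- graph_csr(g)
  raw <- .enum_collect_cpp(csr$offsets, csr$targets, as.integer(k), budget)
  lapply(raw, function(s) g$vertices[s + 1L])
}

#' Exact vertex posterior for a fixed module order
#'
#' Under a uniform prior over connected `k`-subgraphs, the posterior of a
#' module `S` is proportional to `prod_{v in S} w_v^(a-1)` (the `a^k` factor
#' cancels). Vertex probabilities are the per-vertex marginals over the full
#' enumeration, accumulated in shifted exponential space for stability.
#'
#' @param g an `interaction_graph`.
#' @param w named vertex weights (p-values).
#' @param a beta shape parameter.
#' @param k module order.
#' @param budget enumeration safety budget (number of subgraphs).
#' @return named numeric vector of exact membership probabilities; the
#'   attribute `n_subgraphs` carries the enumeration count.
#' @export
exact_posterior_fixed <- function(g, w, a, k, budget = DEFAULT_ENUM_BUDGET) {
  stopifnot_graph(g)
  w <- check_weights(g, w)
  csr <- graph_csr(g)
  svec <- (a - 1) * log(as.numeric(w[g$vertices]))
  pass1 <- .enum_count_cpp(csr$offsets, csr$targets, svec, as.integer(k),
                           as.integer(k), budget)
  pass2 <- .enum_posterior_cpp(csr$offsets, csr$targets, svec, as.integer(k),
                               as.integer(k), budget, pass1$smax)
  p <- setNames(pass2$vertex_sums / pass2$total, g$vertices)
  attr(p, "n_subgraphs") <- pass2$count
  p
}

#' Exact vertex posterior for variable module order
#'
#' Enumerates all non-empty connected subgraphs of order up to `max_order`;
#' each is scored `prod_{v in S} (w_v / tau)^(a-1)` (the per-vertex prior
#' penalty in cancelled form). Returns the vertex marginals and the exact
#' module-order distribution.
#'
#' @param g an `interaction_graph`.
#' @param w named vertex weights.
#' @param a beta shape parameter.
#' @param tau confidence threshold in (0, 1).
#' @param max_order largest module order enumerated.
#' @param budget enumeration safety budget.
#' @return list with `p` (named probabilities), `order_dist` (named
#'   `P(|M| = m)` for m = 1..max_order) and `n_subgraphs`.
#' @export
exact_posterior_variable <- function(g, w, a, tau, max_order,
                                     budget = DEFAULT_ENUM_BUDGET) {
  stopifnot_graph(g)
  if (max_order < 1 || max_order > g$n) stop("`max_order` must be in 1..n")
  w <- check_weights(g, w)
  csr <- graph_csr(g)
  svec <- (a - 1) * (log(as.numeric(w[g$vertices])) - log(tau))
  pass1 <- .enum_count_cpp(csr$offsets, csr$targets, svec, 1L,
                           as.integer(max_order), budget)
  pass2 <- .enum_posterior_cpp(csr$offsets, csr$targets, svec, 1L,
                               as.integer(max_order), budget, pass1$smax)
  p <- setNames(pass2$vertex_sums / pass2$total, g$vertices)
  order_dist <- pass2$order_sums[-1] / pass2$total   # drop order-0 slot
  names(order_dist) <- seq_len(max_order)
  list(p = p, order_dist = order_dist, n_subgraphs = pass2$count)
}

#' Construct an X3C instance
#'
#' Exact Cover by 3-Sets: a ground set `X` of `3q` elements and a collection
#' of 3-element subsets; the question is whether some subcollection covers
#' every element exactly once.
#'
#' @param x character vector of `3q` distinct element ids.
#' @param sets list of character vectors, each a 3-element subset of `x`.
#' @return object of class `x3c_instance` with fields `x`, `sets`, `q`.
#' @export
x3c_instance <- function(x, sets) {
  x <- as.character(x)
  if (length(x) %% 3 != 0 || length(x) == 0 || anyDuplicated(x))
    stop("|X| must be a positive multiple of 3 with distinct elements")
  for (s in sets) {
    s <- as.character(s)
    if (length(s) != 3 || anyDuplicated(s) || !all(s %in% x))
      stop("every set must be a 3-element subset of X")
  }
  structure(list(x = x, sets = lapply(sets, as.character), q = length(x) %/% 3),
            class = "x3c_instance")
}

#' Build the X3C-to-OCPR reduction
#'
#' Constructs the graph with a hub vertex `v`, one vertex per 3-set `c_i`
#' (adjacent to the hub) and one vertex per element `x_j` (adjacent to every
#' set containing it), with probabilities `p_v = 1`, `p_c = 0`,
#' `p_x = eps = 1/(12 q (q+1))`. The instance has an exact cover iff some
#' connectivity-preserving ranking achieves objective
#' `sum_i i p_i = 3/2` (the returned bound).
#'
#' @param inst an `x3c_instance`.
#' @return list with `graph`, `p` (named probabilities), `eps`, `bound`.
#' @export
build_x3c_reduction <- function(inst) {
  if (!inherits(inst, "x3c_instance")) stop("expected an `x3c_instance`")
  q <- inst$q
  if (length(inst$sets) == 0) stop("the reduction needs at least one set")
  covered <- unique(unlist(inst$sets))
  if (!setequal(covered, inst$x))
    stop("every element of X must appear in at least one set (otherwise the reduction graph is disconnected)")
  hub <- "v"
  cset <- sprintf("c%03d", seq_along(inst$sets))
  edges <- rbind(
    cbind(hub, cset),
    do.call(rbind, lapply(seq_along(inst$sets), function(i) {
      cbind(cset[i], inst$sets[[i]])
    })))
  g <- load_graph(edges)
  eps <- 1 / (12 * q * (q + 1))
  p <- setNames(numeric(g$n), g$vertices)
  p[hub] <- 1
  p[inst$x] <- eps
  list(graph = g, p = p, eps = eps, bound = 3 / 2)
}

#' Ranking objective of the decisional OCPR problem
#'
#' `sum_i i * p_i` over 1-based rank positions; minimizing it is equivalent
#' to maximizing the expected AUC ROC.
#'
#' @param ranking a permutation of vertices.
#' @param p named probabilities.
#' @return the objective value.
#' @export
ranking_objective <- function(ranking, p) {
  ord <- ranking_order(ranking)
  if (anyDuplicated(ord) || anyNA(match(ord, names(p))))
    stop("`ranking` must be a permutation of vertices named in `p`")
  sum(seq_along(ord) * p[ord])
}

#' Brute-force optimal connectivity-preserving ranking
#'
#' Exact solver for small instances: dynamic programming over all connected
#' vertex subsets (each subset is a possible ranking prefix), minimizing
#' `sum_i i p_i`. Among optimal rankings the lexicographically smallest order
#' sequence is returned. Limited to `n <= 10`.
#'
#' @param g a connected `interaction_graph` with `n <= 10`.
#' @param p named membership probabilities.
#' @return an optimal connectivity-preserving `vertex_ranking`.
#' @export
brute_force_ocpr <- function(g, p) {
  stopifnot_graph(g)
  n <- g$n
  if (n > 10) stop("brute-force OCPR is limited to n <= 10")
  pv <- as.numeric(p[g$vertices])
  if (anyNA(pv)) stop("probabilities missing for some vertices")
  full <- bitwShiftL(1L, n) - 1L
  # F[mask]: minimal remaining cost given the prefix set `mask` already placed
  F <- rep(NA_real_, full + 1L)
  F[full + 1L] <- 0
  # frontier extension: vertex v can follow prefix `mask` iff mask == 0 or v
  # is adjacent to mask
  adj_mask <- integer(n)
  for (v in seq_len(n)) {
    m <- 0L
    for (u in g$adj[[v]]) m <- bitwOr(m, bitwShiftL(1L, u - 1L))
    adj_mask[v] <- m
  }
  solve_from <- function(mask) {
    if (!is.na(F[mask + 1L])) return(F[mask + 1L])
    pos <- sum(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)) + 1L
    best <- Inf
    for (v in seq_len(n)) {
      bit <- bitwShiftL(1L, v - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      if (mask != 0L && bitwAnd(adj_mask[v], mask) == 0L) next
      val <- pos * pv[v] + solve_from(bitwOr(mask, bit))
      if (val < best) best <- val
    }
    F[mask + 1L] <<- best
    best
  }
  total <- solve_from(0L)
  # reconstruct lexicographically smallest optimal order, front to back
  ord <- character(0)
  mask <- 0L
  pos <- 1L
  while (mask != full) {
    for (v in seq_len(n)) {
      bit <- bitwShiftL(1L, v - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      if (mask != 0L && bitwAnd(adj_mask[v], mask) == 0L) next
      val <- pos * pv[v] + solve_from(bitwOr(mask, bit))
      if (isTRUE(all.equal(val, solve_from(mask), tolerance = 1e-12)) ||
          val <= solve_from(mask) + 1e-12) {
        ord <- c(ord, g$vertices[v])
        mask <- bitwOr(mask, bit)
        pos <- pos + 1L
        break
      }
    }
  }
  new_vertex_ranking(ord, p = setNames(pv, g$vertices),
                     connectivity_preserving = TRUE)
}

#' Random connectivity-preserving ranking
#'
#' Uniform random prefix extension: start at a uniformly chosen vertex and
#' repeatedly append a uniformly chosen frontier vertex. Used as a null
#' reference when assessing the peeling heuristic.
#'
#' @param g a connected `interaction_graph`.
#' @param p optional probabilities to attach.
#' @return a connectivity-preserving `vertex_ranking`.
#' @export
random_cp_ranking <- function(g, p = NULL) {
  stopifnot_graph(g)
  members <- sample.int(g$n, 1)
  while (length(members) < g$n) {
    frontier <- setdiff(unique(unlist(g$adj[members], use.names = FALSE)), members)
    members <- c(members, frontier[sample.int(length(frontier), 1)])
  }
  new_vertex_ranking(g$vertices[members], p = p, connectivity_preserving = TRUE)
}
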