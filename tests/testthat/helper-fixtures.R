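# Small graphs and independent brute-force oracles used across the tests.

path_graph <- function(ids) {
  load_graph(cbind(ids[-length(ids)], ids[-1]))
}

cycle_graph <- function(ids) {
  load_graph(cbind(ids, c(ids[-1], ids[1])))
}

star_graph <- function(center, leaves) {
  load_graph(cbind(rep(center, length(leaves)), leaves))
}

as_igraph <- function(g) {
  igraph::graph_from_edgelist(graph_edges(g), directed = FALSE)
}

# all connected induced subgraphs of order k by brute-force subset filtering
# (independent of the package's recursive enumerator)
combn_connected_subgraphs <- function(g, k) {
  sets <- utils::combn(g$vertices, k, simplify = FALSE)
  ig <- as_igraph(g)
  Filter(function(s) {
    igraph::is_connected(igraph::induced_subgraph(ig, s))
  }, sets)
}

# exact fixed-order posterior by direct summation over the subset filter
combn_posterior_fixed <- function(g, w, a, k) {
  subs <- combn_connected_subgraphs(g, k)
  scores <- vapply(subs, function(s) prod(w[s]^(a - 1)), numeric(1))
  total <- sum(scores)
  p <- setNames(numeric(g$n), g$vertices)
  for (i in seq_along(subs)) p[subs[[i]]] <- p[subs[[i]]] + scores[i]
  p / total
}

# AUC as the probability that a uniformly chosen module vertex is ranked
# above a uniformly chosen background vertex (counting definition,
# independent of the closed-form used by the package)
counting_auc <- function(ord, module) {
  is_mod <- ord %in% module
  m <- sum(is_mod)
  n <- length(ord)
  hits <- 0
  for (i in which(!is_mod)) hits <- hits + sum(is_mod[seq_len(i - 1)])
  hits / (m * (n - m))
}

# deterministic BUM sample at given parameters
rbum <- function(n, lam, a) {
  sig <- runif(n) > lam
  ifelse(sig, runif(n)^(1 / a), runif(n))
}

state_key <- function(members) paste(sort(members), collapse = "|")
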