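# Vertex rankings. A connectivity-preserving (CP) ranking is one in which
# every prefix induces a connected subgraph, so that FDR-thresholded modules
# are nested: M(q1) is a subgraph of M(q2) whenever q1 < q2. Finding the CP
# ranking with maximal expected AUC (the OCPR problem) is NP-hard; the peeling
# heuristic below solves it well in practice in O(n^3).

new_vertex_ranking <- function(order, p = NULL, connectivity_preserving = FALSE) {
  prefix_fdr <- if (!is.null(p)) cumsum(1 - p[order]) / seq_along(order) else NULL
  structure(list(order = order, p = p, prefix_fdr = prefix_fdr,
                 connectivity_preserving = connectivity_preserving),
            class = "vertex_ranking")
}

#' @export
print.vertex_ranking <- function(x, ...) {
  cat(sprintf("vertex_ranking on %d vertices%s\n", length(x$order),
              if (x$connectivity_preserving) " (connectivity preserving)" else ""))
  show <- head(x$order, 10)
  cat("  top: ", paste(show, collapse = ", "),
      if (length(x$order) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.vertex_ranking <- function(x, ...) x$order

#' Rank vertices by descending membership probability
#'
#' The ranking that maximizes the expected AUC ROC for any module order.
#' Ties are broken by ascending input weight (when supplied), then by
#' lexicographic vertex id.
#'
#' @param p named membership probabilities for all vertices.
#' @param w optional named input weights used as first tie-breaker.
#' @return a `vertex_ranking` (not connectivity preserving).
#' @export
rank_by_probability <- function(p, w = NULL) {
  ids <- names(p)
  if (is.null(ids)) stop("`p` must be named by vertex id")
  lex <- order(ids, method = "radix")
  p_l <- p[lex]; ids_l <- ids[lex]
  if (!is.null(w)) {
    ord <- order(-p_l, w[ids_l], method = "radix")
  } else {
    ord <- order(-p_l, method = "radix")
  }
  new_vertex_ranking(ids_l[ord], p = p, connectivity_preserving = FALSE)
}

#' Rank vertices by ascending input weight
#'
#' The baseline ranking by individual significance (smallest p-value first);
#' ties are lexicographic.
#'
#' @param w named vertex weights (p-values).
#' @param p optional membership probabilities used to annotate prefix FDRs.
#' @return a `vertex_ranking`.
#' @export
rank_by_weight <- function(w, p = NULL) {
  ids <- names(w)
  if (is.null(ids)) stop("`w` must be named by vertex id")
  lex <- order(ids, method = "radix")
  ord <- order(w[lex], method = "radix")
  new_vertex_ranking(ids[lex][ord], p = p, connectivity_preserving = FALSE)
}

#' Connectivity-preserving ranking by iterative peeling
#'
#' Heuristic for the NP-hard optimal connectivity-preserving ranking (OCPR)
#' problem. Starting from the full graph, each step removes the vertex whose
#' removal block `H` (the vertex together with everything cut off from the
#' largest remaining component) has maximal average FDR `mean(1 - p)`; the
#' block takes the lowest remaining rank positions. Ties are broken towards
#' smaller blocks, then lexicographically. Within a block, vertices are
#' ordered greedily (highest probability first among vertices adjacent to the
#' surviving component and already-placed block members) so that every global
#' prefix induces a connected subgraph; this within-block order is validated
#' before returning.
#'
#' @param g a connected `interaction_graph`.
#' @param p named membership probabilities for all vertices.
#' @return a connectivity-preserving `vertex_ranking`.
#' @export
ocpr_heuristic <- function(g, p) {
  stopifnot_graph(g)
  if (anyNA(match(g$vertices, names(p)))) stop("probabilities missing for some vertices")
  csr <- graph_csr(g)
  idx <- .ocpr_peel_cpp(csr$offsets, csr$targets, as.numeric(p[g$vertices])) + 1L
  ord <- g$vertices[idx]
  r <- new_vertex_ranking(ord, p = p[g$vertices], connectivity_preserving = TRUE)
  # contract check: every prefix connected (cheap incremental validation)
  if (!all(prefix_connectivity(g, ord)))
    stop("internal error: peeling produced a non-connectivity-preserving ranking")
  r
}

# logical vector: is each prefix of `ord` connected? (incremental union-find)
prefix_connectivity <- function(g, ord) {
  idx <- vertex_index(g, ord)
  parent <- seq_len(g$n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_prefix <- logical(g$n)
  n_comp <- 0L
  out <- logical(length(ord))
  for (i in seq_along(idx)) {
    v <- idx[i]
    in_prefix[v] <- TRUE
    n_comp <- n_comp + 1L
    for (u in g$adj[[v]]) {
      if (in_prefix[u]) {
        ru <- find(u); rv <- find(v)
        if (ru != rv) {
          parent[ru] <- rv
          n_comp <- n_comp - 1L
        }
      }
    }
    out[i] <- n_comp == 1L
  }
  out
}

#' Extract the module at a given FDR level
#'
#' The longest prefix of a connectivity-preserving ranking whose average FDR
#' `mean(1 - p)` does not exceed `q`. Modules are nested across FDR levels by
#' construction.
#'
#' @param ranking a connectivity-preserving `vertex_ranking` with
#'   probabilities attached (or supply `p`).
#' @param q FDR level in \[0, 1\].
#' @param p optional named probabilities overriding the ones stored in
#'   `ranking`.
#' @return character vector of module vertex ids (possibly empty).
#' @export
module_at_fdr <- function(ranking, q, p = NULL) {
  if (!inherits(ranking, "vertex_ranking")) stop("expected a `vertex_ranking`")
  if (!isTRUE(ranking$connectivity_preserving))
    stop("`ranking` must be connectivity preserving for module extraction")
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]")
  p <- p %||% ranking$p
  if (is.null(p)) stop("no probabilities available")
  prefix_fdr <- cumsum(1 - p[ranking$order]) / seq_along(ranking$order)
  keep <- which(prefix_fdr <= q + 1e-12)
  if (length(keep) == 0) return(character(0))
  ranking$order[seq_len(max(keep))]
}
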