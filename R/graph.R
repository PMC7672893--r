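# Interaction graph: undirected, simple, connected. Vertices are opaque string
# ids; internally they are sorted byte-lexicographically so that index order is
# the deterministic tie-breaking order used everywhere in the package.

#' Construct an interaction graph from an edge list
#'
#' Builds the undirected simple graph induced by `edges`, dropping self-loops
#' and duplicate edges, and reduces it to its largest connected component
#' (ties between equally large components are broken in favour of the
#' component containing the lexicographically smallest vertex id). A warning
#' reports how many vertices were discarded.
#'
#' @param edges two-column character matrix or data frame; one edge per row.
#' @return An object of class `interaction_graph` with elements
#'   `vertices` (sorted character vector), `adj` (list of integer neighbour
#'   indices), `n` (vertex count) and `n_edges`.
#' @examples
#' g <- load_graph(cbind(c("A", "B"), c("B", "C")))
#' g$n
#' @export
load_graph <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges)) || ncol(edges) < 2 || nrow(edges) == 0)
    stop("`edges` must be a non-empty two-column edge list")
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("edge list contains no non-loop edges")
  # canonical undirected representation for dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste0(lo, "\r", hi))
  lo <- lo[!dup]; hi <- hi[!dup]

  verts <- sort(unique(c(lo, hi)), method = "radix")
  ig <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  comp <- igraph::components(ig)
  if (comp$no > 1) {
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # component containing the lexicographically smallest id among tied ones
      nm <- igraph::V(ig)$name
      smallest <- vapply(best, function(ci) {
        min(sort(nm[comp$membership == ci], method = "radix"))
      }, character(1))
      best <- best[order(smallest, method = "radix")[1]]
    }
    keep_names <- igraph::V(ig)$name[comp$membership == best]
    n_drop <- length(verts) - length(keep_names)
    warning(sprintf(
      "input graph is disconnected: keeping largest component (%d vertices), discarding %d",
      length(keep_names), n_drop))
    sel <- lo %in% keep_names & hi %in% keep_names
    lo <- lo[sel]; hi <- hi[sel]
    verts <- sort(keep_names, method = "radix")
  }
  ii <- match(lo, verts); jj <- match(hi, verts)
  adj <- vector("list", length(verts))
  for (v in seq_along(verts)) adj[[v]] <- integer(0)
  nbrs <- split(c(jj, ii), c(ii, jj))
  for (nm in names(nbrs)) adj[[as.integer(nm)]] <- sort(unique(nbrs[[nm]]))
  structure(
    list(vertices = verts, adj = adj, n = length(verts), n_edges = length(lo)),
    class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d vertices, %d edges\n", x$n, x$n_edges))
  invisible(x)
}

is_interaction_graph <- function(g) inherits(g, "interaction_graph")

stopifnot_graph <- function(g) {
  if (!is_interaction_graph(g)) stop("expected an `interaction_graph` object")
}

# vertex names -> internal indices, with validation
vertex_index <- function(g, v) {
  idx <- match(v, g$vertices)
  if (anyNA(idx)) stop("unknown vertex id(s): ", paste(v[is.na(idx)], collapse = ", "))
  idx
}

#' Edge list of an interaction graph
#'
#' @param g an `interaction_graph`.
#' @return two-column character matrix, one undirected edge per row
#'   (`from` lexicographically smaller than `to`).
#' @export
graph_edges <- function(g) {
  stopifnot_graph(g)
  from <- integer(0); to <- integer(0)
  for (v in seq_len(g$n)) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]
    from <- c(from, rep.int(v, length(nb)))
    to <- c(to, nb)
  }
  cbind(from = g$vertices[from], to = g$vertices[to])
}

#' Neighborhood of a vertex subset
#'
#' The set of vertices at distance exactly 1 from `members`: vertices outside
#' the set with at least one neighbour inside it (the frontier `nei(S)`).
#'
#' @param g an `interaction_graph`.
#' @param members character vector of vertex ids (a subset of `g$vertices`).
#' @return sorted character vector of frontier vertex ids.
#' @export
neighborhood <- function(g, members) {
  stopifnot_graph(g)
  idx <- vertex_index(g, members)
  out <- unique(unlist(g$adj[idx], use.names = FALSE))
  out <- setdiff(out, idx)
  sort(g$vertices[out], method = "radix")
}

#' Is an induced subgraph connected?
#'
#' @param g an `interaction_graph`.
#' @param members non-empty character vector of vertex ids.
#' @return `TRUE` iff the subgraph induced on `members` has exactly one
#'   connected component.
#' @export
is_connected_induced <- function(g, members) {
  stopifnot_graph(g)
  if (length(members) == 0) stop("`members` must be non-empty")
  idx <- vertex_index(g, members)
  in_s <- logical(g$n)
  in_s[idx] <- TRUE
  seen <- logical(g$n)
  queue <- idx[1]
  seen[queue] <- TRUE
  cnt <- 1L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (u in g$adj[[v]]) {
      if (in_s[u] && !seen[u]) {
        seen[u] <- TRUE
        cnt <- cnt + 1L
        queue <- c(queue, u)
      }
    }
  }
  cnt == length(idx)
}

# connected components of the subgraph induced on `idx` (integer indices);
# returns list of integer vectors, deterministic order
induced_components <- function(g, idx) {
  in_s <- logical(g$n)
  in_s[idx] <- TRUE
  seen <- logical(g$n)
  comps <- list()
  for (start in sort(idx)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (u in g$adj[[v]]) {
        if (in_s[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Split a connected (sub)graph by removing one vertex
#'
#' Removes `v` from the subgraph induced on `members` (the whole graph by
#' default) and returns the vertex set of the largest remaining connected
#' component (`G_next`) together with its complement `H` (which always
#' contains `v`). Ties between equally large components are broken in favour
#' of the component containing the lexicographically smallest vertex id.
#'
#' @param g an `interaction_graph`.
#' @param v a single vertex id in `members`.
#' @param members vertex ids forming a connected induced subgraph; defaults to
#'   all vertices.
#' @return list with character vectors `G_next` and `H`.
#' @export
split_by_removal <- function(g, v, members = NULL) {
  stopifnot_graph(g)
  if (is.null(members)) members <- g$vertices
  midx <- vertex_index(g, members)
  vidx <- vertex_index(g, v)
  if (length(vidx) != 1 || !(vidx %in% midx)) stop("`v` must be a single vertex in `members`")
  rest <- setdiff(midx, vidx)
  if (length(rest) == 0) {
    return(list(G_next = character(0), H = g$vertices[vidx]))
  }
  comps <- induced_components(g, rest)
  sizes <- vapply(comps, length, integer(1))
  # components are discovered from the smallest index, so among equal sizes
  # the first found contains the lexicographically smallest id
  best <- which(sizes == max(sizes))[1]
  g_next <- comps[[best]]
  h <- setdiff(midx, g_next)
  list(G_next = g$vertices[sort(g_next)], H = g$vertices[sort(h)])
}

# flat CSR adjacency for the C++ kernels (0-based)
graph_csr <- function(g) {
  deg <- lengths(g$adj)
  offsets <- c(0L, cumsum(deg))
  list(offsets = as.integer(offsets),
       targets = as.integer(unlist(g$adj, use.names = FALSE) - 1L))
}
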