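# Tabular readers/writers and the end-to-end pipeline. Tables are TSV;
# headers on edge-list and weight files are auto-detected.

# is the first line of a 2-column TSV a header?  For weight tables: yes when
# the second field is not numeric.  For edge lists: yes when neither endpoint
# of line 1 reappears in the remaining lines.
detect_header_weights <- function(first_row) {
  suppressWarnings(is.na(as.numeric(first_row[[2]])))
}

#' Read a vertex weight table
#'
#' Two tab-separated columns: vertex id and p-value in (0, 1]. A header line
#' is auto-detected (non-numeric second field). Duplicate ids and out-of-range
#' p-values are errors reported with their line numbers.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of p-values.
#' @export
read_weights_table <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("weight table must have two tab-separated columns")
  offset <- 0L
  if (nrow(raw) > 0 && detect_header_weights(raw[1, ])) {
    raw <- raw[-1, , drop = FALSE]
    offset <- 1L
  }
  if (nrow(raw) == 0) stop("weight table is empty")
  ids <- raw[[1]]
  vals <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(vals) | vals <= 0 | vals > 1)
  if (length(bad) > 0)
    stop(sprintf("invalid p-value at line %d: '%s'", bad[1] + offset, raw[[2]][bad[1]]))
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop(sprintf("duplicate vertex id '%s' at line %d", ids[dup[1]], dup[1] + offset))
  setNames(vals, ids)
}

#' Read an interaction graph from an edge-list TSV
#'
#' Two tab-separated columns, one edge per line. Line 1 is treated as data
#' when either of its fields reappears as an endpoint later in the file,
#' and as a header otherwise.
#'
#' @param path path to the TSV file.
#' @return an `interaction_graph` (see [load_graph()] for the reduction to
#'   the largest connected component).
#' @export
read_graph_tsv <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("edge list must have two tab-separated columns")
  if (nrow(raw) > 1) {
    rest <- c(raw[[1]][-1], raw[[2]][-1])
    if (!any(unlist(raw[1, 1:2]) %in% rest)) raw <- raw[-1, , drop = FALSE]
  }
  load_graph(as.matrix(raw[, 1:2]))
}

#' Read an interaction graph from a GraphML file
#'
#' @param path path to the GraphML file.
#' @return an `interaction_graph`.
#' @export
read_graph_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nm <- igraph::V(ig)$name
  if (is.null(nm)) nm <- sprintf("n%d", seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = FALSE)
  load_graph(cbind(nm[el[, 1]], nm[el[, 2]]))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write vertex probabilities as TSV
#'
#' @param p named probabilities.
#' @param path output path.
#' @export
write_probabilities_tsv <- function(p, path) {
  write_tsv(data.frame(vertex = names(p), probability = sprintf("%.6f", p)), path)
}

#' Write a ranking as TSV
#'
#' Columns: rank, vertex, probability, prefix FDR.
#'
#' @param ranking a `vertex_ranking` with probabilities attached.
#' @param path output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  ord <- ranking$order
  df <- data.frame(rank = seq_along(ord), vertex = ord)
  if (!is.null(ranking$p)) {
    df$probability <- sprintf("%.6f", ranking$p[ord])
    df$prefix_fdr <- sprintf("%.6f", cumsum(1 - ranking$p[ord]) / seq_along(ord))
  }
  write_tsv(df, path)
}

# restrict graph and weights to their common vertex set (largest component),
# logging discarded counts
align_graph_weights <- function(g, w) {
  common <- intersect(g$vertices, names(w))
  drop_g <- g$n - length(common)
  drop_w <- length(w) - length(common)
  if (drop_w > 0)
    message(sprintf("dropping %d weight entr%s not present in the graph",
                    drop_w, if (drop_w == 1) "y" else "ies"))
  if (drop_g > 0) {
    message(sprintf("dropping %d unweighted graph vert%s",
                    drop_g, if (drop_g == 1) "ex" else "ices"))
    el <- graph_edges(g)
    keep <- el[, 1] %in% common & el[, 2] %in% common
    g <- load_graph(el[keep, , drop = FALSE])
  }
  list(graph = g, weights = w[g$vertices])
}

#' Run the full analysis pipeline
#'
#' Chains BUM fitting, MCMC sampling (variable order by default), probability
#' estimation, connectivity-preserving ranking and module extraction at each
#' requested FDR level; writes all outputs (probabilities, ranking, per-q
#' module edge lists and vertex tables, likelihood trace and a provenance
#' record) to `out_dir`.
#'
#' @param graph an `interaction_graph` or a path to an edge-list TSV /
#'   GraphML file.
#' @param weights a named p-value vector or a path to a weight TSV.
#' @param out_dir output directory (created if missing).
#' @param fdr_levels FDR levels at which modules are extracted.
#' @param mode,tau,a,k,n_iterations,burn_in,strategy,n_runs passed to
#'   [run_mcmc()].
#' @param seed RNG seed (required: runs must be reproducible).
#' @return (invisibly) list with the fitted BUM parameters, probabilities,
#'   ranking, modules and output paths.
#' @export
run_pipeline <- function(graph, weights, out_dir,
                         fdr_levels = c(0.05, 0.15, 0.25),
                         mode = "variable", tau = 1e-7, a = NULL, k = NULL,
                         n_iterations = 1e5, burn_in = 25000,
                         strategy = "one_long_run", n_runs = 1000, seed) {
  if (missing(seed)) stop("`seed` is required: pipeline runs must be reproducible")
  if (is.character(graph)) {
    graph <- if (grepl("\\.graphml$", graph, ignore.case = TRUE))
      read_graph_graphml(graph) else read_graph_tsv(graph)
  }
  if (is.character(weights)) weights <- read_weights_table(weights)
  al <- align_graph_weights(graph, weights)
  g <- al$graph; w <- al$weights
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- fit_bum(w)
  if (is.null(a)) a <- fit$a
  samples <- run_mcmc(g, w, mode = mode, k = k, tau = tau, a = a,
                      n_iterations = n_iterations, burn_in = burn_in,
                      strategy = strategy, n_runs = n_runs, seed = seed)
  p <- estimate_vertex_probabilities(samples)
  ranking <- ocpr_heuristic(g, p)

  paths <- list(
    probabilities = file.path(out_dir, "probabilities.tsv"),
    ranking = file.path(out_dir, "ranking.tsv"),
    trace = file.path(out_dir, "trace.tsv"),
    provenance = file.path(out_dir, "provenance.json"))
  write_probabilities_tsv(p, paths$probabilities)
  write_ranking_tsv(ranking, paths$ranking)
  if (!is.null(samples$trace)) write_tsv(samples$trace, paths$trace)

  modules <- list()
  for (q in fdr_levels) {
    mod <- module_at_fdr(ranking, q)
    tag <- sub("\\.", "_", sprintf("%g", q))
    vp <- file.path(out_dir, sprintf("module_fdr_%s.vertices.tsv", tag))
    ep <- file.path(out_dir, sprintf("module_fdr_%s.edges.tsv", tag))
    write_tsv(data.frame(vertex = mod,
                         probability = sprintf("%.6f", p[mod])), vp)
    el <- graph_edges(g)
    keep <- el[, 1] %in% mod & el[, 2] %in% mod
    write_tsv(as.data.frame(el[keep, , drop = FALSE]), ep)
    modules[[sprintf("%g", q)]] <- mod
    paths[[sprintf("module_%g", q)]] <- vp
  }
  jsonlite::write_json(
    list(package = "mcmcModules",
         version = as.character(utils::packageVersion("mcmcModules")),
         seed = seed, mode = mode, tau = tau, a = a, k = k,
         n_iterations = n_iterations, burn_in = burn_in, strategy = strategy,
         fdr_levels = fdr_levels, bum = list(lam = fit$lam, a = fit$a),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(list(bum = fit, samples = samples, probabilities = p,
                 ranking = ranking, modules = modules, paths = paths))
}
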