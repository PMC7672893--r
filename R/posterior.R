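# Derived quantities over the sample collection: probabilities of arbitrary
# module events, FDR of vertex sets, and expected AUC ROC of vertex rankings
# (for known and unknown module order).

#' Probability of an arbitrary module event
#'
#' Estimates `P(A(M) | W = w)` for any boolean-valued predicate of the module
#' vertex set as the fraction of retained samples satisfying it. Each
#' `A(S)` is a Bernoulli trial, so with independent samples the estimator has
#' mean square error of order `p(1-p)/|samples|`.
#'
#' @param samples an `mcmc_samples` object created with
#'   `retain_samples = TRUE`.
#' @param predicate function taking a character vector of module vertex ids
#'   and returning a single logical.
#' @return the estimated event probability.
#' @export
event_probability <- function(samples, predicate) {
  if (!inherits(samples, "mcmc_samples")) stop("expected an `mcmc_samples` object")
  if (is.null(samples$retained))
    stop("samples were collected counts-only; rerun with `retain_samples = TRUE`")
  hits <- vapply(samples$retained, function(s) isTRUE(predicate(s)), logical(1))
  mean(hits)
}

#' False discovery rate of a vertex set
#'
#' The expected fraction of false inclusions in `V`:
#' `(1/|V|) * sum_{v in V} P(v not in M | W = w)`, i.e. the mean of
#' `1 - p_v` over the set.
#'
#' @param p named vector of membership probabilities.
#' @param v non-empty character vector of vertex ids.
#' @return the FDR value in \[0, 1\].
#' @export
set_fdr <- function(p, v) {
  if (length(v) == 0) stop("`v` must be non-empty")
  if (anyNA(match(v, names(p)))) stop("probabilities missing for some vertices in `v`")
  mean(1 - p[v])
}

ranking_order <- function(ranking) {
  if (inherits(ranking, "vertex_ranking")) ranking$order else as.character(ranking)
}

#' Expected AUC ROC of a ranking for a known module order
#'
#' For a ranking `v_1, ..., v_n` (most confident first) and membership
#' probabilities `p_i`, the expected area under the ROC curve against the
#' random module `M` of order `m` is
#' `1 - (sum_i i * p_i - m(m+1)/2) / (m (n - m))`.
#' The value is not clipped: results outside \[0, 1\] beyond floating error
#' indicate probabilities inconsistent with `m`.
#'
#' @param ranking a permutation of all vertices (character vector or
#'   `vertex_ranking`).
#' @param p named membership probabilities.
#' @param m module order, `1 <= m < n`.
#' @return the expected AUC ROC.
#' @export
expected_auc <- function(ranking, p, m) {
  ord <- ranking_order(ranking)
  n <- length(ord)
  if (anyDuplicated(ord) || anyNA(match(ord, names(p))) || length(p) != n)
    stop("`ranking` must be a permutation of the vertices named in `p`")
  if (m < 1 || m >= n) stop("`m` must satisfy 1 <= m < n")
  s <- sum(seq_len(n) * p[ord])
  1 - (s - m * (m + 1) / 2) / (m * (n - m))
}

#' Empirical AUC ROC of a ranking against a known module
#'
#' The known module plays the role of ground truth: membership probabilities
#' are its indicator, so the expected AUC formula reduces to the usual
#' rank-based AUC.
#'
#' @param ranking a permutation of all vertices.
#' @param module character vector of true module vertices.
#' @return the AUC ROC in \[0, 1\].
#' @export
empirical_auc <- function(ranking, module) {
  ord <- ranking_order(ranking)
  p <- setNames(as.numeric(ord %in% module), ord)
  expected_auc(ord, p, length(module))
}

#' Expected AUC ROC when the module order is unknown
#'
#' Uses the per-order tallies of the sample collection. Three methods:
#' \describe{
#'   \item{`"p_prime"`}{(default) the closed-form expression with modified
#'     probabilities `p'_i = E(|M| |G\\M|) * sum_m P(|M|=m) p_i^(m) / (m(n-m))`
#'     and value `1 - (sum_i i p'_i - E(|M|(|M|+1))/2) / E(|M| |G\\M|)`. Its
#'     ranking-dependent term is exact; the constant term replaces a ratio
#'     expectation by a ratio of expectations, so the value can deviate
#'     slightly from the exact expectation when the order distribution is
#'     spread out (see the methods vignette).}
#'   \item{`"exact"`}{the exact mixture `sum_m P(|M|=m) * AUC_m` computed
#'     order by order from the conditional probabilities `p_i^(m)`.}
#'   \item{`"p_approx"`}{the same closed form with the marginal `p_i` in place
#'     of `p'_i` (a cheaper approximation).}
#' }
#' With all samples of a single order every method reduces to
#' [expected_auc()].
#'
#' @param ranking a permutation of all vertices.
#' @param samples an `mcmc_samples` object.
#' @param method see Details.
#' @return the expected AUC ROC.
#' @export
expected_auc_unknown_order <- function(ranking, samples,
                                       method = c("p_prime", "exact", "p_approx")) {
  method <- match.arg(method)
  if (!inherits(samples, "mcmc_samples")) stop("expected an `mcmc_samples` object")
  ord <- ranking_order(ranking)
  n <- length(samples$vertices)
  if (length(ord) != n || anyDuplicated(ord)) stop("`ranking` must be a permutation of all vertices")
  sizes <- as.numeric(colnames(samples$vertex_size_counts))
  if (any(sizes >= n)) stop("a sampled module of order n makes n - m = 0; AUC undefined")
  if (any(sizes < 1)) stop("sampled module orders must be >= 1")
  pm <- samples$size_counts / samples$n_samples               # P(|M| = m)
  p_cond <- sweep(samples$vertex_size_counts, 2, samples$size_counts, "/")
  ranks <- setNames(seq_len(n), ord)
  i_of <- ranks[samples$vertices]                             # rank of each vertex

  if (method == "exact") {
    aucs <- vapply(seq_along(sizes), function(j) {
      expected_auc(ord, setNames(p_cond[, j], samples$vertices), sizes[j])
    }, numeric(1))
    return(sum(pm * aucs))
  }
  e_mnm <- sum(pm * sizes * (n - sizes))                      # E(|M| |G\M|)
  e_mm1 <- sum(pm * sizes * (sizes + 1))                      # E(|M|(|M|+1))
  if (method == "p_prime") {
    inner <- p_cond %*% (pm / (sizes * (n - sizes)))
    p_use <- e_mnm * drop(inner)
  } else {
    p_use <- drop(samples$vertex_counts / samples$n_samples)
  }
  names(p_use) <- samples$vertices
  s <- sum(i_of * p_use[samples$vertices])
  1 - (s - e_mm1 / 2) / e_mnm
}

#' Conditional membership probabilities by module order
#'
#' @param samples an `mcmc_samples` object.
#' @return matrix `p_i^(m)` (vertices x observed orders m); orders never
#'   sampled are absent.
#' @export
conditional_probabilities <- function(samples) {
  if (!inherits(samples, "mcmc_samples")) stop("expected an `mcmc_samples` object")
  sweep(samples$vertex_size_counts, 2, samples$size_counts, "/")
}
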