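# Beta-uniform mixture (BUM) model of the vertex p-value distribution:
# density lambda + (1 - lambda) * a * x^(a - 1), with mixture weight lambda of
# the uniform (noise) component and beta shape a in (0, 1) so that small
# p-values are enriched in the signal component.

BUM_EPS <- 1e-6     # box bound for the MLE
W_CLAMP <- 1e-16    # p-values of exactly 0 are clamped here (x^(a-1) diverges)

#' Beta-uniform mixture density
#'
#' @param x p-values in (0, 1]; values <= 0 are an error.
#' @param lam mixture weight of the uniform component, in (0, 1).
#' @param a beta shape parameter, in (0, 1).
#' @return density values `lam + (1 - lam) * a * x^(a - 1)`.
#' @export
bum_density <- function(x, lam, a) {
  if (any(x <= 0)) stop("p-values must be strictly positive")
  if (any(x > 1)) stop("p-values must be <= 1")
  lam + (1 - lam) * a * x^(a - 1)
}

bum_negloglik <- function(par, logw) {
  lam <- par[1]; a <- par[2]
  # log(lam + (1-lam) * a * exp((a-1) * logw)), stably
  t <- log1p(exp(log((1 - lam) * a) + (a - 1) * logw - log(lam))) + log(lam)
  -sum(t)
}

bum_negloglik_grad <- function(par, logw) {
  lam <- par[1]; a <- par[2]
  xa1 <- exp((a - 1) * logw)      # w^(a-1)
  f <- lam + (1 - lam) * a * xa1
  dlam <- (1 - a * xa1) / f
  da <- (1 - lam) * xa1 * (1 + a * logw) / f
  -c(sum(dlam), sum(da))
}

#' Fit the beta-uniform mixture by maximum likelihood
#'
#' Maximises the BUM log-likelihood over (lambda, a) on the box
#' `[1e-6, 1 - 1e-6]^2` with `L-BFGS-B` from a 3 x 3 grid of starting points
#' (the likelihood can have a boundary ridge, so a single start is not
#' reliable). Weights below 1e-16 are clamped up before fitting.
#'
#' @param w numeric vector (optionally named by vertex) of p-values in (0, 1];
#'   at least 10 values.
#' @return object of class `bum_fit`: list with `lam`, `a`, `loglik`, `n`.
#' @examples
#' set.seed(1)
#' fit <- fit_bum(runif(200))
#' fit$lam   # close to 1: no signal component
#' @export
fit_bum <- function(w) {
  w <- as.numeric(w)
  if (length(w) < 10) stop("need at least 10 p-values to fit the BUM model")
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("p-values must be finite and in [0, 1]")
  w <- pmax(w, W_CLAMP)
  logw <- log(w)
  starts <- expand.grid(lam = c(0.25, 0.5, 0.75), a = c(0.25, 0.5, 0.75))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$lam[s], starts$a[s]), bum_negloglik, bum_negloglik_grad,
            logw = logw, method = "L-BFGS-B",
            lower = c(BUM_EPS, BUM_EPS), upper = c(1 - BUM_EPS, 1 - BUM_EPS)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BUM maximum-likelihood fit failed from all starting points")
  structure(list(lam = best$par[1], a = best$par[2],
                 loglik = -best$value, n = length(w)),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("BUM fit: lambda = %.4f, a = %.4f  (n = %d, loglik = %.2f)\n",
              x$lam, x$a, x$n, x$loglik))
  invisible(x)
}

#' BUM log-likelihood of a p-value sample at given parameters
#'
#' @param w p-values in (0, 1] (clamped as in [fit_bum()]).
#' @param lam,a BUM parameters.
#' @return the log-likelihood.
#' @export
bum_loglik <- function(w, lam, a) {
  -bum_negloglik(c(lam, a), log(pmax(as.numeric(w), W_CLAMP)))
}

#' Estimate the module order from BUM parameters
#'
#' The expected module order is `(1 - lambda) * n`, rounded (half to even),
#' floored at 1 and capped at `n - 1`.
#'
#' @param params a `bum_fit` object or a numeric `lam`.
#' @param n graph order (vertex count), >= 2.
#' @return integer module order `k` with `1 <= k < n`.
#' @examples
#' estimate_module_order(list(lam = 0.9), 100)  # 10
#' @export
estimate_module_order <- function(params, n) {
  lam <- if (is.list(params)) params$lam else params
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2")
  k <- round((1 - lam) * n)
  as.integer(min(max(1, k), n - 1))
}
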