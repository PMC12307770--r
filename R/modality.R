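#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a `K`-component 1-D Gaussian mixture by
#' expectation-maximisation with random restarts. Each restart initialises
#' the component means at (jittered) spread quantiles of the data, weights
#' equal, and every component variance at the pooled sample variance; EM
#' iterates until the log-likelihood gain drops below `tol` or `max_iter` is
#' reached, and the best restart by log-likelihood is kept. Component
#' variances are floored at `1e-6` times the sample variance so repeated
#' values cannot produce a degenerate spike. Components are reported sorted
#' by mean.
#'
#' The information criterion is reported in the higher-is-better
#' orientation, `BIC = 2 loglik - p ln(n)`, with `p = 3K - 1` free
#' parameters for free-variance components (`p = 2K` when
#' `equal_var = TRUE`).
#'
#' @param x Numeric vector of observations (`n >= 3K`, finite).
#' @param K Number of components.
#' @param n_starts Random restarts (default 10).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param seed Seed for the restart stream.
#' @param equal_var Constrain all component variances to be equal.
#' @return Object of class `mixture_fit`: `K`, `weights`, `means`,
#'   `variances`, `loglik`, `bic`, `converged`, `n_iter`, `loglik_trace`
#'   (of the best restart), `n`, `equal_var`.
#' @export
fit_gmm_1d <- function(x, K, n_starts = 10L, tol = 1e-8, max_iter = 500L,
                       seed = NULL, equal_var = FALSE) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3L * K) {
    stop("need at least 3 observations per component (n >= 3K)", call. = FALSE)
  }
  v0 <- stats::var(x)
  var_floor <- max(1e-6 * v0, 1e-12)
  fits <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    probs <- (seq_len(K) - 0.5) / K
    if (s > 1L) probs <- pmin(1, pmax(0, probs + stats::runif(K, -0.5 / K, 0.5 / K)))
    mu0 <- as.numeric(stats::quantile(x, sort(probs), type = 7))
    mu0 <- mu0 + stats::rnorm(K, 0, sqrt(var_floor))  # break exact ties
    .em_gmm_1d_cpp(x, mu0, var0 = max(v0, var_floor), tol = tol,
                   max_iter = as.integer(max_iter), var_floor = var_floor,
                   equal_var = equal_var)
  }))
  ll <- vapply(fits, function(f) f$loglik, numeric(1L))
  best <- fits[[which.max(ll)]]
  if (!best$converged) {
    warning("EM did not converge within max_iter in the best restart",
            call. = FALSE)
  }
  ord <- order(best$means)
  p <- if (equal_var) 2L * K else 3L * K - 1L
  structure(list(K = K,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 variances = best$variances[ord],
                 loglik = best$loglik,
                 bic = 2 * best$loglik - p * log(n),
                 converged = best$converged,
                 n_iter = best$n_iter,
                 loglik_trace = best$loglik_trace,
                 n = n, equal_var = equal_var),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> K = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$K, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  comp <- data.frame(weight = round(x$weights, 4L),
                     mean = round(x$means, 4L),
                     sd = round(sqrt(x$variances), 4L))
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Decide distribution modality by BIC over mixture fits
#'
#' Fits Gaussian mixtures with `K = 1..K_max` components ([fit_gmm_1d()])
#' and picks the component count with the highest BIC (higher-is-better
#' orientation), following the mixture-model convention that the best BIC
#' indicates the most likely number of underlying Gaussian modes. BIC values
#' are additionally min-max scaled to `[0, 1]` over the K grid for
#' cross-group display.
#'
#' @param x Numeric samples (`n >= 3 * K_max` recommended; K values that
#'   cannot be fitted are excluded with a warning).
#' @param K_max Largest component count tried (default 3).
#' @param ... Passed to [fit_gmm_1d()] (`n_starts`, `tol`, `max_iter`,
#'   `seed`, `equal_var`).
#' @return Object of class `modality_decision`: `best_K`, `bic_by_K`
#'   (named numeric), `scaled_bic_by_K`, `fits` (list of `mixture_fit`).
#' @examples
#' x <- simulate_population_values(weights = 1, means = 0, sds = 1,
#'                                 n = 120, seed = 5)
#' select_modality(x, seed = 5)$best_K
#' @export
select_modality <- function(x, K_max = 3L, ...) {
  fits <- list()
  for (K in seq_len(K_max)) {
    f <- tryCatch(fit_gmm_1d(x, K, ...), error = function(e) e)
    if (inherits(f, "error")) {
      warning("K = ", K, " could not be fitted (", conditionMessage(f),
              "); excluded", call. = FALSE)
    } else {
      fits[[as.character(K)]] <- f
    }
  }
  if (length(fits) == 0L) stop("no mixture size could be fitted", call. = FALSE)
  bic <- vapply(fits, function(f) f$bic, numeric(1L))
  scaled <- scale_minmax(bic)   # best K attains 1, worst 0 over the grid
  best_K <- as.integer(names(bic)[which.max(bic)])
  structure(list(best_K = best_K, bic_by_K = bic, scaled_bic_by_K = scaled,
                 fits = fits),
            class = "modality_decision")
}

#' @export
print.modality_decision <- function(x, ...) {
  cat("<modality_decision> best K =", x$best_K, "\n")
  tab <- data.frame(K = names(x$bic_by_K),
                    BIC = round(x$bic_by_K, 3L),
                    scaled = round(x$scaled_bic_by_K, 3L))
  print(tab, row.names = FALSE)
  invisible(x)
}
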