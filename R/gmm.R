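# Constrained-covariance Gaussian mixtures fitted by EM.
#
# Component covariances follow the volume/shape/orientation decomposition
# Sigma_k = lambda_k * A_k with diagonal A_k of unit determinant (the
# orientation is the identity for all families here): EII, VII, EEI, VEI,
# EVI, VVI. With many more genes than cells only these axis-aligned
# families are estimable, and VEI (varying volume, equal shape) is the
# default: a cluster whose expression profile is a scalar multiple of
# another's differs exactly by its volume.

sc_families <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI")

#' Free-parameter count of a constrained Gaussian mixture
#'
#' Mixing weights contribute K - 1, means K * p, and the covariance
#' contributes, by family: EII 1; VII K; EEI p; VEI K + (p - 1);
#' EVI 1 + K * (p - 1); VVI K * p.
#'
#' @param family One of `"EII", "VII", "EEI", "VEI", "EVI", "VVI"`.
#' @param K Number of components (>= 1).
#' @param p Dimension (>= 1).
#' @return Integer free-parameter count.
#' @export
count_free_parameters <- function(family, K, p) {
  stopifnot(K >= 1, p >= 1)
  cov_params <- switch(family,
                       EII = 1,
                       VII = K,
                       EEI = p,
                       VEI = K + (p - 1),
                       EVI = 1 + K * (p - 1),
                       VVI = K * p,
                       stop("unknown covariance family: ", family,
                            call. = FALSE))
  as.integer((K - 1) + K * p + cov_params)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `2 * loglik - n_params * log(n)`; larger is better.
#'
#' @param loglik Maximised log-likelihood, or an `sc_gmm` object.
#' @param n_params Free-parameter count (ignored when `loglik` is a model).
#' @param n Number of observations (> 1).
#' @return The BIC score.
#' @export
gmm_bic <- function(loglik, n_params = NULL, n) {
  if (inherits(loglik, "sc_gmm")) {
    n_params <- loglik$n_params
    loglik <- loglik$loglik
  }
  if (n <= 1) stop("BIC requires n > 1", call. = FALSE)
  2 * loglik - n_params * log(n)
}

# log-density of every observation under every component (n x K), for
# diagonal covariances. mu: K x p, sigma: p x K per-dimension variances.
diag_log_dens <- function(x, mu, sigma) {
  n <- nrow(x); p <- ncol(x); K <- nrow(mu)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    xc <- sweep(x, 2, mu[k, ], "-")
    q <- as.vector(xc^2 %*% (1 / sigma[, k]))
    out[, k] <- -0.5 * (p * log(2 * pi) + sum(log(sigma[, k])) + q)
  }
  out
}

row_log_sum_exp <- function(la) {
  mx <- la[, 1]
  if (ncol(la) > 1L) for (k in 2:ncol(la)) mx <- pmax(mx, la[, k])
  mx + log(rowSums(exp(la - mx)))
}

# M-step covariance update. w: p x K within-component scatter (diagonal),
# nk: component weights summed. Returns p x K per-dimension variances.
# The scatter is floored at vfloor * nk (the scatter a variance-floored
# dimension would have) so the shape iterations of VEI/EVI stay finite
# when a component sees a zero-variance direction.
mstep_sigma <- function(family, w, nk, n, p, vfloor) {
  K <- length(nk)
  w <- pmax(w, rep(vfloor * nk, each = p))
  eps <- .Machine$double.xmin
  switch(family,
         EII = {
           s2 <- sum(w) / (n * p)
           matrix(s2, p, K)
         },
         VII = {
           lam <- colSums(w) / (nk * p)
           matrix(lam, p, K, byrow = TRUE)
         },
         EEI = {
           b <- rowSums(w) / n
           matrix(b, p, K)
         },
         VEI = {
           b <- pmax(rowSums(w), eps)
           A <- b / exp(mean(log(b)))
           lam <- rep(1, K)
           for (it in seq_len(50)) {
             lam_new <- colSums(w / A) / (nk * p)
             B <- pmax(rowSums(sweep(w, 2, lam_new, "/")), eps)
             A_new <- B / exp(mean(log(B)))
             delta <- max(abs(lam_new - lam) / (abs(lam_new) + eps),
                          abs(A_new - A) / (A_new + eps))
             lam <- lam_new; A <- A_new
             if (delta < 1e-8) break
           }
           outer(A, lam)
         },
         EVI = {
           wk <- pmax(w, eps)
           gm <- exp(colMeans(log(wk)))
           A <- sweep(wk, 2, gm, "/")
           lam <- sum(gm) / n
           lam * A
         },
         VVI = {
           sweep(w, 2, nk, "/")
         },
         stop("unknown covariance family: ", family, call. = FALSE))
}

kmeanspp_labels <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  if (K > 1L) {
    for (k in 2:K) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) <= 0) {
        centers[k] <- sample.int(n, 1L)
      } else {
        centers[k] <- sample.int(n, 1L, prob = prob)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[k], ], "-")^2))
    }
  }
  cent <- x[centers, , drop = FALSE]
  dall <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dall[, k] <- rowSums(sweep(x, 2, cent[k, ], "-")^2)
  }
  max.col(-dall, ties.method = "first")
}

em_one_run <- function(x, K, family, max_iter, tol, vfloor,
                       labels = NULL) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(labels)) labels <- kmeanspp_labels(x, K)
  if (length(unique(labels)) < K) return(NULL)
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), labels)] <- 1
  ll_old <- -Inf
  trace <- numeric(0)
  pi_k <- NULL; mu <- NULL; sigma <- NULL; ll <- NA_real_
  for (iter in seq_len(max_iter)) {
    nk <- colSums(R)
    # a component needs at least two expected members: a single cell
    # cannot carry a covariance estimate, and a floored singleton would
    # have a spuriously unbounded likelihood
    if (any(nk < 2)) return(NULL)
    pi_k <- nk / n
    mu <- sweep(crossprod(R, x), 1, nk, "/")  # K x p
    w <- matrix(0, p, K)
    for (k in seq_len(K)) {
      xc <- sweep(x, 2, mu[k, ], "-")
      w[, k] <- as.vector(crossprod(xc^2, R[, k]))
    }
    sigma <- pmax(mstep_sigma(family, w, nk, n, p, vfloor), vfloor)
    la <- sweep(diag_log_dens(x, mu, sigma), 2, log(pi_k), "+")
    lse <- row_log_sum_exp(la)
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)  # numerically degenerate start
    R <- exp(la - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + .Machine$double.eps)) {
      break
    }
    ll_old <- ll
  }
  list(pi = pi_k, mean = mu, sigma = sigma, loglik = ll,
       loglik_trace = trace, responsibilities = R, iterations = iter,
       converged = iter < max_iter)
}

#' Fit a constrained-covariance Gaussian mixture by EM
#'
#' Runs expectation-maximization from `n_init` starts — the first a
#' deterministic Ward-linkage agglomerative cut (which reliably seeds
#' small, well-separated components), the rest k-means++ draws — and
#' keeps the run with the highest log-likelihood. Responsibilities are
#' computed with log-sum-exp stabilisation, and every per-dimension variance
#' is floored at `var_floor_factor` times the mean per-dimension variance of
#' the data, so planted zero-variance directions cannot blow the likelihood
#' up. A run in which any component's expected membership falls below two
#' cells is abandoned (and retried from the next start): one cell cannot
#' carry a covariance estimate.
#'
#' @param x Numeric data matrix, observations in rows (cells) and features
#'   in columns (genes).
#' @param K Number of mixture components.
#' @param family Covariance family code (see [count_free_parameters()]).
#' @param n_init Number of restarts.
#' @param seed Optional integer seed for the initialisations.
#' @param max_iter Maximum EM iterations per run.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor_factor Variance floor, as a fraction of the pooled
#'   per-dimension variance.
#' @return An object of class `sc_gmm`: parameters (`pi`, `mean` K x p,
#'   `sigma` p x K per-dimension variances, `volume`, `shape`), `loglik`,
#'   `loglik_trace`, `n_params`, `bic`, `responsibilities` and fit metadata.
#' @export
fit_gmm <- function(x, K, family = "VEI", n_init = 5L, seed = NULL,
                    max_iter = 500L, tol = 1e-8, var_floor_factor = 1e-6) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.matrix(x))
  if (!all(is.finite(x))) {
    stop("non-finite values in the data matrix", call. = FALSE)
  }
  family <- match.arg(family, sc_families)
  n <- nrow(x); p <- ncol(x)
  if (K < 1) stop("K must be at least 1", call. = FALSE)
  if (K >= n) stop("K (", K, ") must be smaller than the number of ",
                   "observations (", n, ")", call. = FALSE)
  pooled <- mean(row_vars(t(x)))
  vfloor <- max(var_floor_factor * pooled, .Machine$double.xmin)

  # the first start is deterministic: a Ward-linkage agglomerative cut,
  # which reliably seeds small, well-separated components; the remaining
  # starts are k-means++ draws
  ward_labels <- if (K > 1L) {
    tryCatch(stats::cutree(stats::hclust(stats::dist(x),
                                         method = "ward.D2"), k = K),
             error = function(e) NULL)
  } else {
    rep(1L, n)
  }
  runner <- function() {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- if (r == 1L) ward_labels else NULL
      # a degenerate restart must not take down the healthy ones
      fit <- tryCatch(
        em_one_run(x, K, family, max_iter, tol, vfloor, labels = init),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    best
  }
  best <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  if (is.null(best)) {
    stop("all ", n_init, " EM restarts collapsed a component below one ",
         "expected member (K = ", K, ", family = ", family, ")",
         call. = FALSE)
  }
  volume <- exp(colMeans(log(best$sigma)))
  shape <- sweep(best$sigma, 2, volume, "/")
  n_params <- count_free_parameters(family, K, p)
  rownames(best$responsibilities) <- rownames(x)
  structure(list(family = family, K = K, n = n, p = p,
                 pi = best$pi,
                 mean = best$mean,
                 sigma = best$sigma,
                 volume = volume,
                 shape = shape,
                 loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 n_params = n_params,
                 bic = gmm_bic(best$loglik, n_params, n),
                 responsibilities = best$responsibilities,
                 iterations = best$iterations,
                 converged = best$converged,
                 var_floor = vfloor),
            class = "sc_gmm")
}

#' @export
print.sc_gmm <- function(x, ...) {
  cat("Gaussian mixture (", x$family, "), K = ", x$K, ", p = ", x$p,
      ", n = ", x$n, "\n", sep = "")
  cat("  loglik: ", format(x$loglik), "; params: ", x$n_params,
      "; BIC: ", format(x$bic), "\n", sep = "")
  cat("  weights: ", paste(format(x$pi, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
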