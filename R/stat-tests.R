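# Two-sample checks: Mann-Whitney U (exact null from the rank-sum
# distribution when feasible, otherwise tie-corrected normal approximation
# with continuity correction), two-sample Kolmogorov-Smirnov with the
# asymptotic Kolmogorov distribution, the pooled signature comparison, and
# the sampling-based mixture goodness-of-fit check.

#' Mann-Whitney U test
#'
#' The statistic is the U of the first sample, computed from midranks.
#' When the samples are untied and `n * m` does not exceed
#' `exact_max_product`, the two-sided p-value is taken from the exact null
#' distribution of U; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max_product Largest `n * m` for which the exact null
#'   distribution is used (default 400).
#' @return An object of class `sc_test` with `statistic` (U), `p_value`,
#'   `method` (`"exact"` or `"normal_approx_tie_corrected"`) and sample
#'   sizes.
#' @export
mann_whitney_u <- function(x, y, exact_max_product = 400) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  tab <- table(c(x, y))
  has_ties <- any(tab > 1)
  if (!has_ties && n * m <= exact_max_product) {
    method <- "exact"
    p <- 2 * min(stats::pwilcox(U, n, m),
                 stats::pwilcox(U - 1, n, m, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    method <- "normal_approx_tie_corrected"
    mu <- n * m / 2
    tie_term <- sum(tab^3 - tab)
    sig2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(test = "mann_whitney_u", statistic = U, p_value = p,
                 method = method, n = n, m = m),
            class = "sc_test")
}

# Asymptotic Kolmogorov survival function Q(lambda).
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the two-sided
#' p-value uses the asymptotic Kolmogorov distribution at effective sample
#' size `n * m / (n + m)`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return An object of class `sc_test` with `statistic` (D), `p_value` and
#'   `method = "asymptotic"`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  n <- length(x); m <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- n * m / (n + m)
  p <- if (D == 0) 1 else kolmogorov_sf(sqrt(ne) * D)
  structure(list(test = "ks_two_sample", statistic = D, p_value = p,
                 method = "asymptotic", n = n, m = m),
            class = "sc_test")
}

#' @export
print.sc_test <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), " (", x$method, "; n = ", x$n,
      ", m = ", x$m, ")\n", sep = "")
  invisible(x)
}

#' Pooled two-sample test of a gene signature
#'
#' Pools every (gene, cell) RPKM value of the signature inside the focal
#' cluster into one sample and every value of the same genes in all other
#' clusters into the other, then runs both the Mann-Whitney U test and the
#' two-sample KS test.
#'
#' @param rpkm Gene-by-cell expression matrix.
#' @param genes Signature gene ids (all must be present in the matrix).
#' @param focal Focal cluster id.
#' @param labels Cluster label per cell.
#' @return A list of class `sc_pooled_test` with `u` and `ks` (`sc_test`
#'   objects) plus convenience fields `u_statistic`, `ks_statistic`,
#'   `p_value_u`, `p_value_ks`.
#' @export
pooled_signature_test <- function(rpkm, genes, focal, labels) {
  stopifnot(is.matrix(rpkm))
  if (!length(genes)) stop("empty signature", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(rpkm))
  if (length(missing_genes)) {
    stop("signature genes missing from the matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(rpkm)) {
    stop("'labels' must have one entry per cell", call. = FALSE)
  }
  in_focal <- labels == focal
  if (!any(in_focal)) {
    stop("focal cluster '", focal, "' is empty", call. = FALSE)
  }
  x <- as.vector(rpkm[genes, in_focal, drop = FALSE])
  y <- as.vector(rpkm[genes, !in_focal, drop = FALSE])
  u <- mann_whitney_u(x, y)
  ks <- ks_two_sample(x, y)
  structure(list(u = u, ks = ks,
                 u_statistic = u$statistic, ks_statistic = ks$statistic,
                 p_value_u = u$p_value, p_value_ks = ks$p_value,
                 focal = focal, n_genes = length(genes),
                 n_focal_values = length(x), n_other_values = length(y)),
            class = "sc_pooled_test")
}

#' @export
print.sc_pooled_test <- function(x, ...) {
  cat("Pooled signature test: cluster ", x$focal, ", ", x$n_genes,
      " genes\n", sep = "")
  cat("  U = ", format(x$u_statistic), ", p = ", format(x$p_value_u),
      " (", x$u$method, ")\n", sep = "")
  cat("  D = ", format(x$ks_statistic), ", p = ", format(x$p_value_ks),
      " (", x$ks$method, ")\n", sep = "")
  invisible(x)
}

#' Fit a one-dimensional expression mixture for a single cell
#'
#' Fits univariate Gaussian mixtures to one cell's expression values across
#' its gene panel and selects the component count by BIC; a convenience
#' front end to [select_model()] for the goodness-of-fit check.
#'
#' @param values The cell's expression values (one per panel gene).
#' @param K_range Component counts to try.
#' @param seed,n_init Passed to [select_model()].
#' @return The chosen `sc_gmm` model.
#' @export
fit_expression_mixture <- function(values, K_range = 1:4, seed = NULL,
                                   n_init = 5L) {
  sel <- select_model(matrix(values, ncol = 1), K_range = K_range,
                      families = "VII", seed = seed, n_init = n_init)
  sel$model
}

#' Sampling-based mixture goodness-of-fit check
#'
#' Draws `n_samples` values from a fitted univariate mixture and compares
#' them with the observed cell values by the Mann-Whitney U test. A
#' non-significant p-value supports the adequacy of the mixture as a model
#' of the cell's expression distribution.
#'
#' @param cell_values Observed expression values of one cell over its gene
#'   panel.
#' @param model A fitted `sc_gmm` with `p == 1` (see
#'   [fit_expression_mixture()]).
#' @param n_samples Number of draws from the fitted mixture (default
#'   10,000).
#' @param seed Optional seed for the draws.
#' @return The `sc_test` from [mann_whitney_u()] with the draws attached as
#'   attribute `"draws"`.
#' @export
mixture_gof_check <- function(cell_values, model, n_samples = 10000L,
                              seed = NULL) {
  if (!inherits(model, "sc_gmm") || is.null(model$loglik)) {
    stop("'model' must be a fitted sc_gmm", call. = FALSE)
  }
  if (model$p != 1) {
    stop("the goodness-of-fit check expects a univariate mixture",
         call. = FALSE)
  }
  draw <- function() {
    comp <- sample.int(model$K, n_samples, replace = TRUE, prob = model$pi)
    stats::rnorm(n_samples, model$mean[comp, 1],
                 sqrt(model$sigma[1, comp]))
  }
  draws <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  res <- mann_whitney_u(draws, cell_values)
  attr(res, "draws") <- draws
  res
}
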