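# Stage 2: BIC model selection across component counts and covariance
# families, hard assignment, and clustering agreement measures.

#' Fit mixtures over a grid and select a model by BIC
#'
#' Fits every (family, K) combination with [fit_gmm()] and picks a model:
#' rule `"max_bic"` takes the global BIC maximum (ties broken toward smaller
#' K, then by the order families were given); rule `"elbow"` reads the
#' per-K BIC profile (maximised over families) as a scree plot and picks the
#' smallest K whose gain over K - 1 falls below 1% of the profile's total
#' range.
#'
#' @param x Data matrix, cells in rows, panel genes in columns.
#' @param K_range Component counts to try.
#' @param families Covariance families to try (default VEI, the only member
#'   of the varying-volume, equal-shape class that is estimable when genes
#'   far outnumber cells).
#' @param rule `"max_bic"` or `"elbow"`.
#' @param n_init,seed,max_iter,tol Passed to [fit_gmm()].
#' @param elbow_gain Relative gain threshold for the elbow rule.
#' @return An object of class `sc_cluster`: `labels` (hard assignments),
#'   `responsibilities`, `model` (the chosen `sc_gmm`), `bic_table`
#'   (one row per fit, including failures), `rule` and `K`.
#' @export
select_model <- function(x, K_range = 1:9, families = "VEI",
                         rule = c("max_bic", "elbow"), n_init = 5L,
                         seed = NULL, max_iter = 500L, tol = 1e-8,
                         elbow_gain = 0.01) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x))
  if (max(K_range) >= nrow(x)) {
    stop("K_max must be smaller than the number of cells", call. = FALSE)
  }
  families <- match.arg(families, sc_families, several.ok = TRUE)
  grid <- expand.grid(K = sort(unique(as.integer(K_range))),
                      family = families, stringsAsFactors = FALSE)
  seeds <- if (is.null(seed)) {
    rep(list(NULL), nrow(grid))
  } else {
    with_local_seed(seed, as.list(sample.int(.Machine$integer.max,
                                             nrow(grid))))
  }
  fits <- vector("list", nrow(grid))
  errs <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[i] <- list(tryCatch(
      fit_gmm(x, K = grid$K[i], family = grid$family[i], n_init = n_init,
              seed = seeds[[i]], max_iter = max_iter, tol = tol),
      error = function(e) {
        errs[i] <<- conditionMessage(e)
        NULL
      }))
  }
  ok <- !vapply(fits, is.null, logical(1))
  bic_table <- data.frame(
    family = grid$family,
    K = grid$K,
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik,
                    numeric(1)),
    n_params = vapply(fits, function(f) if (is.null(f)) NA_integer_ else
      f$n_params, integer(1)),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                 numeric(1)),
    converged = vapply(fits, function(f) if (is.null(f)) NA else f$converged,
                       logical(1)),
    error = errs,
    stringsAsFactors = FALSE)
  if (!any(ok)) {
    stop("all mixture fits failed:\n",
         paste(sprintf("  %s K=%d: %s", grid$family, grid$K, errs),
               collapse = "\n"), call. = FALSE)
  }

  if (rule == "max_bic") {
    idx <- which(ok)
    ord <- idx[order(-bic_table$bic[idx], bic_table$K[idx],
                     match(bic_table$family[idx], families))]
    chosen <- ord[1]
  } else {
    prof <- stats::aggregate(bic ~ K, data = bic_table[ok, , drop = FALSE],
                             FUN = max)
    prof <- prof[order(prof$K), ]
    rng <- diff(range(prof$bic))
    K_sel <- prof$K[nrow(prof)]
    if (nrow(prof) > 1 && rng > 0) {
      gains <- diff(prof$bic)
      hit <- which(gains < elbow_gain * rng)
      if (length(hit)) K_sel <- prof$K[hit[1] + 1]
    } else if (rng == 0) {
      K_sel <- prof$K[1]
    }
    cand <- which(ok & bic_table$K == K_sel)
    chosen <- cand[order(-bic_table$bic[cand],
                         match(bic_table$family[cand], families))][1]
  }
  model <- fits[[chosen]]
  labels <- map_assign(model$responsibilities)
  names(labels) <- rownames(x)
  structure(list(labels = labels,
                 responsibilities = model$responsibilities,
                 model = model,
                 bic_table = bic_table,
                 rule = rule,
                 K = model$K),
            class = "sc_cluster")
}

#' @export
print.sc_cluster <- function(x, ...) {
  cat("Model-based clustering: family ", x$model$family, ", K = ", x$K,
      " (rule ", x$rule, ")\n", sep = "")
  cat("  cluster sizes: ",
      paste(sort(table(x$labels), decreasing = TRUE), collapse = ", "),
      "\n", sep = "")
  cat("  BIC: ", format(x$model$bic), "\n", sep = "")
  invisible(x)
}

#' Maximum-a-posteriori assignment
#'
#' @param responsibilities Matrix of posterior responsibilities, one row per
#'   observation, rows summing to one. Ties break toward the lowest
#'   component index.
#' @return Integer component labels.
#' @export
map_assign <- function(responsibilities) {
  if (is.null(dim(responsibilities)) || nrow(responsibilities) == 0) {
    stop("empty responsibility matrix", call. = FALSE)
  }
  max.col(responsibilities, ties.method = "first")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model;
#' 1 for identical partitions (up to label renaming).
#'
#' @param labels_a,labels_b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n == 0) stop("empty label vectors", call. = FALSE)
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

#' Corroborate a mixture clustering with hierarchical clustering
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' same panel matrix, cut at K clusters, compared with the mixture labels
#' via the adjusted Rand index.
#'
#' @param x Data matrix, cells in rows, panel genes in columns.
#' @param K Number of clusters to cut at (>= 2; K equal to the number of
#'   cells yields singletons).
#' @param gmm_labels Mixture-model hard labels for the same cells.
#' @param linkage Linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return A list with `ari`, the dendrogram cut `labels` and the `hclust`
#'   object.
#' @export
hierarchical_corroboration <- function(x, K, gmm_labels,
                                       linkage = "ward.D2") {
  stopifnot(is.matrix(x))
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (K > nrow(x)) {
    stop("K cannot exceed the number of cells", call. = FALSE)
  }
  if (length(gmm_labels) != nrow(x)) {
    stop("'gmm_labels' must have one entry per cell", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(x), method = linkage)
  labels <- stats::cutree(hc, k = K)
  list(ari = adjusted_rand_index(labels, gmm_labels),
       labels = labels,
       hclust = hc)
}
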