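# sample data: K well-separated diagonal-Gaussian blobs
blob_data <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      matrix(rnorm(n_per * ncol(centers), mean = rep(centers[k, ],
                                                     each = n_per),
                   sd = sd), nrow = n_per)
    }))
  })
}

test_that("free-parameter counts match an independent slot enumeration", {
  # hand counts
  expect_identical(count_free_parameters("VVI", 2, 3), 13L)
  expect_identical(count_free_parameters("EII", 1, 1), 2L)
  expect_identical(count_free_parameters("VEI", 3, 4), 20L)
  # oracle: weights (K-1) + means (K p) + volumes (1 or K) + shape
  # matrices (0, 1 or K of them, each p-1 free under the det-1 constraint)
  for (fam in c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
    nv <- if (substr(fam, 1, 1) == "V") quote(K) else quote(1)
    ns <- switch(substr(fam, 2, 2), I = quote(0), E = quote(1), V = quote(K))
    for (K in 1:4) {
      for (p in 1:5) {
        oracle <- (K - 1) + K * p + eval(nv) + eval(ns) * (p - 1)
        expect_identical(count_free_parameters(fam, K, p),
                         as.integer(oracle))
      }
    }
  }
  expect_error(count_free_parameters("XYZ", 2, 2), "unknown")
})

test_that("BIC follows its closed form", {
  expect_equal(gmm_bic(-100, 13, 50), -200 - 13 * log(50))
  expect_equal(gmm_bic(-100, 0, 50), -200)
  # doubling the parameter count at equal loglik costs m * log(n)
  expect_equal(gmm_bic(-100, 13, 50) - gmm_bic(-100, 26, 50), 13 * log(50))
  expect_error(gmm_bic(-100, 13, 1), "n > 1")
})

test_that("a single component reduces to the independent-Gaussian MLE", {
  x <- toy_matrix(6, 40, seed = 3, rfun = rnorm)
  x <- t(x)  # 40 cells x 6 dims
  fit <- fit_gmm(x, K = 1, family = "VVI", seed = 1)
  expect_equal(unname(fit$mean[1, ]), unname(colMeans(x)))
  ml_var <- apply(x, 2, function(col) mean((col - mean(col))^2))
  expect_equal(unname(fit$sigma[, 1]), unname(ml_var), tolerance = 1e-8)
  closed <- sum(vapply(seq_len(ncol(x)), function(j)
    sum(dnorm(x[, j], colMeans(x)[j], sqrt(ml_var[j]), log = TRUE)),
    numeric(1)))
  expect_equal(fit$loglik, closed, tolerance = 1e-8)
})

test_that("for K = 1 every family collapses to the same model", {
  x <- blob_data(30, matrix(c(0, 0, 0), 1), seed = 5)
  lls <- vapply(c("EII", "VII", "EEI", "VEI", "EVI", "VVI"),
                function(fam) fit_gmm(x, 1, fam, seed = 1)$loglik,
                numeric(1))
  # EII/VII pool variances across dims; EEI/VEI/EVI/VVI estimate per dim
  expect_equal(unname(lls["EEI"]), unname(lls["VEI"]), tolerance = 1e-8)
  expect_equal(unname(lls["EEI"]), unname(lls["VVI"]), tolerance = 1e-8)
  expect_equal(unname(lls["EII"]), unname(lls["VII"]), tolerance = 1e-8)
})

test_that("EM separates two 1-D components across seeds", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(c(rnorm(150, 0), rnorm(150, 10)),
                                       ncol = 1))
    fit <- fit_gmm(x, K = 2, family = "VII", seed = seed)
    mu <- sort(fit$mean[, 1])
    expect_lt(abs(mu[1] - 0), 0.2)
    expect_lt(abs(mu[2] - 10), 0.2)
  }
})

test_that("the EM log-likelihood trace is monotone for every family", {
  x <- blob_data(25, rbind(c(0, 0, 0, 0), c(4, 4, 0, 0), c(0, 4, 4, 0)),
                 seed = 7)
  for (fam in c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
    fit <- fit_gmm(x, K = 3, family = fam, seed = 2)
    expect_true(all(diff(fit$loglik_trace) > -1e-6 *
                      abs(fit$loglik_trace[-1])),
                info = fam)
  }
})

test_that("responsibilities are normalised and consistent with labels", {
  x <- blob_data(30, rbind(c(0, 0), c(6, 6)), seed = 9)
  fit <- fit_gmm(x, K = 2, family = "VEI", seed = 3)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-8))
  expect_identical(map_assign(fit$responsibilities),
                   unname(apply(fit$responsibilities, 1, which.max)))
})

test_that("the mixture density agrees with a brute-force evaluation", {
  x <- blob_data(20, rbind(c(0, 0), c(5, 1)), seed = 11)
  fit <- fit_gmm(x, K = 2, family = "VVI", seed = 4)
  dens <- vapply(seq_len(nrow(x)), function(i) {
    sum(vapply(seq_len(2), function(k) {
      fit$pi[k] * prod(dnorm(x[i, ], fit$mean[k, ], sqrt(fit$sigma[, k])))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(fit$loglik, sum(log(dens)), tolerance = 1e-8)
})

test_that("EM attains the reference implementation's likelihood", {
  skip_if_not_installed("mclust")
  # Mclust resolves mclustBIC in the calling frame when not attached
  mclustBIC <- mclust::mclustBIC
  x <- blob_data(40, rbind(c(0, 0, 0), c(5, 5, 0)), seed = 13)
  fit <- fit_gmm(x, K = 2, family = "VVI", seed = 5)
  ref <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  # same data, same model class: the two optimisers should find the same
  # optimum (mclust's loglik is the benchmark)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  x <- blob_data(10, matrix(0, 1, 2), seed = 1)
  expect_error(fit_gmm(x, K = 0), "at least 1")
  expect_error(fit_gmm(x, K = 10), "smaller than")
  x[1, 1] <- NA
  expect_error(fit_gmm(x, K = 1), "non-finite")
})

test_that("the variance floor keeps zero-variance directions finite", {
  # second dimension constant inside one component
  x <- blob_data(25, rbind(c(0, 0), c(8, 0)), seed = 15)
  x[1:25, 2] <- 0
  fit <- fit_gmm(x, K = 2, family = "VVI", seed = 6)
  expect_true(all(is.finite(fit$loglik)))
  expect_true(all(fit$sigma >= fit$var_floor))
})
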