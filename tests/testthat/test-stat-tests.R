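test_that("Mann-Whitney U handles identical samples symmetrically", {
  x <- c(1.5, 2.5, 3.5, 4.5)
  res <- mann_whitney_u(x, x)
  expect_equal(res$statistic, length(x)^2 / 2)
  expect_equal(res$p_value, 1)
})

test_that("Mann-Whitney exact p matches a small worked example", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_identical(res$method, "exact")
  # 2 of the 20 equally likely rank splits are this extreme (U = 0 or 9)
  expect_equal(res$p_value, 0.1)
})

test_that("exact p equals full enumeration for all n, m <= 5", {
  enum_p <- function(x, y) {
    n <- length(x); m <- length(y)
    pooled <- c(x, y)
    u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    splits <- utils::combn(n + m, n)
    us <- apply(splits, 2, function(idx) {
      sum(rank(pooled)[idx]) - n * (n + 1) / 2
    })
    mu <- n * m / 2
    # two-sided: arrangements at least as far from the null mean
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(51)
  for (n in 2:5) {
    for (m in 2:5) {
      x <- round(runif(n, 0, 100), 3)
      y <- round(runif(m, 0, 100), 3)
      res <- mann_whitney_u(x, y)
      expect_identical(res$method, "exact")
      expect_equal(res$p_value, min(1, enum_p(x, y)), tolerance = 1e-12,
                   info = paste(n, m))
    }
  }
})

test_that("tie-corrected normal approximation matches the reference", {
  set.seed(52)
  x <- sample(1:10, 30, TRUE)
  y <- sample(3:12, 25, TRUE)
  res <- mann_whitney_u(x, y)
  expect_identical(res$method, "normal_approx_tie_corrected")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # gross shifts are detected
  big <- mann_whitney_u(rnorm(300), rnorm(300, 5))
  expect_lt(big$p_value, 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("KS statistic equals a brute-force ECDF scan", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  brute_D <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)),
               numeric(1)))
  }
  set.seed(53)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(15, 0.5)
    expect_equal(ks_two_sample(x, y)$statistic, brute_D(x, y))
  }
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(54)
  x <- rlnorm(25)
  y <- rlnorm(30, 0.4)
  d0 <- ks_two_sample(x, y)$statistic
  expect_equal(ks_two_sample(log(x), log(y))$statistic, d0)
  expect_equal(ks_two_sample(sqrt(x), sqrt(y))$statistic, d0)
})

test_that("KS asymptotic p matches the reference implementation", {
  set.seed(55)
  x <- rnorm(40)
  y <- rnorm(35, 0.6)
  res <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the pooled signature test flags planted suppression", {
  d <- generate_dataset(test_metformin())
  keep <- !d$is_low_depth
  m <- d$rpkm[, keep]
  lab <- paste0("M", d$true_labels[keep])
  res <- pooled_signature_test(m, d$suppressed_genes[[2]], "M2", lab)
  expect_lt(res$p_value_u, 0.01)
  expect_lt(res$p_value_ks, 0.01)
  expect_identical(res$n_focal_values, 230L * 6L)
  expect_error(pooled_signature_test(m, c("nope1", "nope2"), "M2", lab),
               "nope1")
  expect_error(pooled_signature_test(m, d$suppressed_genes[[2]], "M9", lab),
               "empty")
})

test_that("the smallest legal pooled input is well defined", {
  m <- matrix(c(5, 7), 1, 2, dimnames = list("g1", c("c1", "c2")))
  res <- pooled_signature_test(m, "g1", "A", c("A", "B"))
  expect_true(res$u_statistic %in% c(0, 1))
  expect_true(res$p_value_u >= 0 && res$p_value_u <= 1)
})

test_that("the goodness-of-fit check separates fit from misfit", {
  set.seed(56)
  vals <- c(rnorm(150, 0, 1), rnorm(150, 6, 1))
  model <- fit_expression_mixture(vals, K_range = 1:3, seed = 57)
  ok <- mixture_gof_check(vals, model, n_samples = 5000, seed = 58)
  expect_gt(ok$p_value, 0.05)
  # shift the model far from the data: gross misfit must be flagged
  bad <- model
  bad$mean <- bad$mean + 10
  misfit <- mixture_gof_check(vals, bad, n_samples = 5000, seed = 58)
  expect_lt(misfit$p_value, 0.01)
  expect_error(mixture_gof_check(vals, list()), "fitted")
})
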