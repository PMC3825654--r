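test_that("logistic LRT matches a grid-search maximum-likelihood oracle", {
  # the spec case: a weak shift between two small groups
  x <- c(0.2, 0.8, 0.3, 0.9)
  y <- c(0, 0, 1, 1)
  fit <- fit_cpg_logistic(x, y)
  expect_equal(fit$lrt_stat, oracle_logistic_lrt(x, y), tolerance = 1e-6)
  expect_false(fit$separated)

  # parameterised sweep over random small data sets
  set.seed(301)
  for (i in 1:12) {
    n <- sample(8:16, 1)
    y <- rep(c(0, 1), length.out = n)
    x <- runif(n) + 0.25 * y
    x <- pmin(pmax(x / max(x + 0.1), 0.01), 0.99)
    fit <- fit_cpg_logistic(x, y)
    if (fit$separated) next
    expect_equal(fit$lrt_stat, oracle_logistic_lrt(x, y), tolerance = 1e-6)
    expect_equal(fit$p, pchisq(fit$lrt_stat, 1, lower.tail = FALSE))
  }
})

test_that("degenerate and separated CpGs are handled", {
  # no information: identical constant in both groups
  fit <- fit_cpg_logistic(rep(0.5, 6), c(0, 0, 0, 1, 1, 1))
  expect_identical(fit[c("lrt_stat", "p", "delta", "z")],
                   list(lrt_stat = 0, p = 1, delta = 0, z = 0))

  # complete separation: flagged, statistic finite at the cap
  fit2 <- fit_cpg_logistic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_true(fit2$separated)
  expect_true(is.finite(fit2$lrt_stat) && is.finite(fit2$z))
  expect_gt(fit2$lrt_stat, 0)

  expect_error(fit_cpg_logistic(c(0.1, 0.2, 0.3), c(1, 1, 1)), "constant")
  expect_error(fit_cpg_logistic(c(0.1, NA, 0.3, 0.4), c(0, 0, 1, 1)),
               "2 samples per class")
})

test_that("sign and ranking conventions of the z statistic hold", {
  set.seed(302)
  for (i in 1:20) {
    p <- runif(1, 1e-6, 1)
    d <- runif(1, -0.5, 0.5)
    z <- signed_zstat(p, d)
    if (d != 0) expect_identical(sign(z), sign(d))
  }
  expect_error(signed_zstat(0, 1), "0, 1")
  # smaller p gives larger |z|
  expect_gt(abs(signed_zstat(1e-8, 1)), abs(signed_zstat(1e-4, 1)))
})

test_that("Storey q-values reduce to Benjamini-Hochberg at pi0 = 1", {
  expect_equal(storey_qvalues(1, pi0 = 1), 1)
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  set.seed(303)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))
    p[sample(length(p), 2)] <- p[1]  # ties
    expect_identical(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"))
  }
})

test_that("pi0 estimation is near 1 for uniform p and q-values are stable", {
  set.seed(304)
  # median over replicate draws isolates estimator bias from the sampling
  # noise of any single uniform sample
  ests <- replicate(5, storey_pi0(runif(10000)))
  expect_lt(abs(median(ests) - 1), 0.05)

  p <- runif(10000)
  q <- storey_qvalues(p)
  # invariance under permutation of input order
  perm <- sample(length(p))
  expect_equal(storey_qvalues(p[perm]), q[perm])
  # q monotone non-decreasing when ordered by p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q > 0 & q <= 1))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 1.5)), "0, 1")
})

test_that("DMC calling partitions significant CpGs by direction", {
  st <- data.frame(cpg_id = c("a", "b", "c"), delta = c(0.3, -0.3, 0.2),
                   p = c(0.001, 0.2, 0.01), q = c(0.05, 0.2, 0.09))
  calls <- call_dmcs(st, q_threshold = 0.1)
  expect_identical(calls$hyper$cpg_id, c("a", "c"))
  expect_identical(nrow(calls$hypo), 0L)
  expect_length(intersect(calls$hyper$cpg_id, calls$hypo$cpg_id), 0)

  calls2 <- call_dmcs(transform(st, q = 0.5))
  expect_identical(nrow(calls2$hyper) + nrow(calls2$hypo), 0L)
})

test_that("dmc_stats runs over a matrix with missing values and attaches q", {
  set.seed(305)
  beta <- matrix(runif(30 * 20, 0.2, 0.8), nrow = 30,
                 dimnames = list(sprintf("cg%02d", 1:30),
                                 sprintf("S%02d", 1:20)))
  beta[1, 1:3] <- NA
  samples <- data.frame(sample_id = colnames(beta),
                        phenotype = rep(c(0L, 1L), each = 10))
  st <- dmc_stats(beta, samples)
  expect_identical(nrow(st), 30L)
  expect_true(all(st$p > 0 & st$p <= 1, na.rm = TRUE))
  expect_true(all(st$q > 0 & st$q <= 1, na.rm = TRUE))
  nz <- !is.na(st$z) & st$delta != 0
  expect_identical(sign(st$z[nz]), sign(st$delta[nz]))
})

test_that("PCA summary matches a dense eigendecomposition", {
  # rank-1 matrix: a single component carries all variance
  u <- runif(12); v <- runif(5)
  m1 <- (u %o% v) / max(u %o% v)
  dimnames(m1) <- list(paste0("cg", 1:12), paste0("S", 1:5))
  expect_equal(pca_summary(m1, 1)$var_explained, 1.0)

  set.seed(306)
  m <- matrix(runif(50 * 20), nrow = 50,
              dimnames = list(paste0("cg", 1:50), paste0("S", 1:20)))
  ps <- pca_summary(m, 3)
  xc <- m - rowMeans(m)
  ev <- eigen(crossprod(xc), symmetric = TRUE)$values
  expect_equal(ps$var_explained, (ev / sum(ev))[1:3], tolerance = 1e-8)
  expect_identical(rownames(ps$sample_weights), colnames(m))
  expect_error(pca_summary(m, 21), "fewer samples")
})
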