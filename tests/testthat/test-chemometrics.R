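test_that("PCA matches the eigendecomposition oracle and degenerate cases", {
  set.seed(11)
  x <- matrix(rnorm(50), 10, 5)
  m <- fit_pca(x, scale_mode = "none")
  # scores covariance diagonal equals the covariance eigenvalues
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(unname(apply(m$scores, 2, var)), ev, tolerance = 1e-10)
  # full reconstruction
  xc <- sweep(x, 2, colMeans(x), "-")
  expect_equal(unname(m$scores %*% t(m$loadings)), unname(xc), tolerance = 1e-8)
  # loadings orthonormal, explained variance non-increasing
  expect_equal(unname(crossprod(m$loadings)), diag(5), tolerance = 1e-10)
  expect_true(all(diff(m$explained_variance) <= 1e-10))
  # rank-1 input: all variance on PC1
  r1 <- outer(rnorm(8), rnorm(4))
  mr <- fit_pca(r1, scale_mode = "none")
  expect_equal(mr$explained_variance[1], 100, tolerance = 1e-8)
  # duplicated samples give duplicated score rows
  xd <- rbind(x, x[1, ])
  md <- fit_pca(xd, scale_mode = "none")
  expect_equal(md$scores[11, ], md$scores[1, ], tolerance = 1e-8)
  # constant column under UV scaling is a named error
  xb <- cbind(x, flat = 1)
  expect_error(fit_pca(xb), "flat")
})

test_that("interclass inertia statistic is a ratio in [0,1] with valid p-values", {
  set.seed(3)
  x <- matrix(rnorm(80), 16, 5)
  lab <- rep(c("T0", "T1"), each = 8)
  r <- interclass_pca_test(x, lab, n_perm = 99, seed = 1)
  expect_gte(r$statistic, 0); expect_lte(r$statistic, 1)
  expect_true(all(r$perm_stats >= 0 & r$perm_stats <= 1))
  expect_gte(r$p_value, 1 / 100); expect_lte(r$p_value, 1)
  # maximal separation: duplicated sample set shifted by a large delta
  x2 <- rbind(x[1:8, ], x[1:8, ] + 50)
  r2 <- interclass_pca_test(x2, lab, n_perm = 999, seed = 1)
  expect_equal(r2$p_value, 0.001)
  expect_error(interclass_pca_test(x, rep("T0", 16)), "two classes")
})

test_that("interclass test is calibrated under label-independent data", {
  set.seed(99)
  rej <- replicate(200, {
    x <- matrix(rnorm(12 * 5), 12, 5)
    interclass_pca_test(x, rep(c("a", "b"), each = 6), n_perm = 99)$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("OPLS recovers a noiseless rank-1 class signal exactly", {
  set.seed(5)
  y <- rep(c(-1, 1), each = 10)
  v <- rnorm(8)
  x <- outer(y, v)
  m <- fit_opls(x, y, n_ortho = 0, scale_mode = "none", seed = 1)
  expect_equal(m$R2, 1, tolerance = 1e-10)
  expect_lt(m$cv$RMSEP, 1e-6)
  expect_equal(m$cv$Q2, 1, tolerance = 1e-6)
})

test_that("orthogonal scores are uncorrelated with y and OSC removes a planted confound", {
  set.seed(8)
  y <- rep(c(-1, 1), each = 12)
  v <- rnorm(10); v <- v / sqrt(sum(v^2))
  u <- orthogonalize(rnorm(24), y) * 8      # strong, y-orthogonal confound
  w <- rnorm(10) + 0.6 * v                  # overlaps the signal loadings
  x0 <- outer(y, v)
  x1 <- x0 + outer(c(u), w)
  m0 <- fit_opls(x0, y, n_ortho = 0, scale_mode = "none", center = FALSE, cv = FALSE)
  m1 <- fit_opls(x1, y, n_ortho = 1, scale_mode = "none", center = FALSE, cv = FALSE)
  expect_lt(max(abs(cor(m1$t_ortho, y))), 1e-8)
  expect_equal(m1$p, m0$p, tolerance = 1e-6)
  expect_equal(m1$w, m0$w, tolerance = 1e-6)
  # removing the confound can only help the predictive fit
  mraw <- fit_opls(x1, y, n_ortho = 0, scale_mode = "none", center = FALSE, cv = FALSE)
  expect_gte(m1$R2 + 1e-12, mraw$R2)
  expect_error(fit_opls(x0, y, n_ortho = 5, scale_mode = "none"), "rank")
})

test_that("cross-validation is honest: null Q2 is non-positive on average", {
  q2 <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(20 * 10), 20, 10)
    cross_validate(x, rep(c(-1, 1), each = 10), k = 5, seed = s)$Q2
  }, numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("Q2 computed from stored predictions reproduces the reported Q2", {
  set.seed(21)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(c(-1, 1), each = 10)
  cv <- cross_validate(x, y, k = 10, seed = 2)
  press <- sum((y - cv$predictions)^2)
  expect_equal(cv$Q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(cv$RMSEP, sqrt(press / length(y)), tolerance = 1e-12)
})

test_that("permutation validation detects a strong planted effect and stays calibrated", {
  set.seed(31)
  n <- 20
  y <- rep(c(-1, 1), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 1:3] <- x[, 1:3] + 1.5 * y            # standardized delta = 3 between classes
  pv <- permutation_validate(x, y, n = 999, seed = 4, k = 5)
  expect_lte(pv$p_value, 0.001)
  expect_equal(nrow(pv$permuted), 999)
  expect_gte(pv$p_value, 1 / 1000)
  # null p-values roughly uniform
  set.seed(32)
  ps <- replicate(60, {
    xn <- matrix(rnorm(16 * 6), 16, 6)
    permutation_validate(xn, rep(c(-1, 1), each = 8), n = 39, k = 4)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("jack-knife selection recovers planted discriminant variables", {
  hits <- t(vapply(1:20, function(s) {
    set.seed(s)
    n <- 20
    y <- rep(c(-1, 1), each = n / 2)
    x <- matrix(rnorm(n * 40), n, 40)
    x[, 1:5] <- x[, 1:5] + 1.25 * y          # 5 planted of 40
    m <- fit_opls(x, y, seed = s)
    sel <- select_discriminant_variables(m)
    c(tp = sum(sel$selected[1:5]), fp = sum(sel$selected[-(1:5)]))
  }, numeric(2)))
  expect_gte(median(hits[, "tp"]), 5)
  expect_lte(median(hits[, "fp"]), 1)
})

test_that("a variable with no class signal is essentially never selected", {
  rate <- vapply(1:40, function(s) {
    set.seed(s)
    y <- rep(c(-1, 1), each = 8)
    x <- matrix(rnorm(16 * 10), 16, 10)
    x[, 1:3] <- x[, 1:3] + y                 # real signal elsewhere
    x[, 10] <- rep(rnorm(8), 2)              # identical values in both classes
    m <- fit_opls(x, y, k = 8, seed = s)
    select_discriminant_variables(m)$selected[10]
  }, logical(1))
  expect_lte(mean(rate), 0.1)
})

test_that("selection is invariant to variable ordering", {
  set.seed(77)
  y <- rep(c(-1, 1), each = 10)
  x <- matrix(rnorm(20 * 12), 20, 12)
  colnames(x) <- paste0("v", 1:12)
  x[, 1:3] <- x[, 1:3] + 1.2 * y
  perm <- sample(12)
  s1 <- select_discriminant_variables(fit_opls(x, y, seed = 9))
  s2 <- select_discriminant_variables(fit_opls(x[, perm], y, seed = 9))
  expect_setequal(s1$variable[s1$selected], s2$variable[s2$selected])
})

test_that("per-peak ANOVA agrees with aov/t-test and Bonferroni caps at 1", {
  set.seed(13)
  x <- matrix(rnorm(24 * 6), 24, 6)
  lab <- rep(c("T0", "T1"), each = 12)
  res <- anova_bonferroni(x, lab)
  # two-group F equals squared equal-variance t
  tt <- apply(x, 2, function(col)
    t.test(col[lab == "T0"], col[lab == "T1"], var.equal = TRUE)$statistic)
  expect_equal(res$F, unname(tt^2), tolerance = 1e-10)
  # and the aov route
  f1 <- summary(aov(x[, 1] ~ lab))[[1]]$`F value`[1]
  expect_equal(res$F[1], f1, tolerance = 1e-10)
  expect_equal(res$p_corrected, pmin(1, res$p * 6))
  # m = 1: corrected equals raw
  r1 <- anova_bonferroni(x[, 1, drop = FALSE], lab)
  expect_equal(r1$p_corrected, r1$p)
  # degenerate zero within-group variance
  xd <- cbind(x, deg = rep(c(0, 1), each = 12))
  rd <- anova_bonferroni(xd, lab)
  expect_true(rd$degenerate[7])
  expect_equal(rd$p[7], 0)
  # three groups are supported
  lab3 <- rep(c("a", "b", "c"), each = 8)
  r3 <- anova_bonferroni(x, lab3)
  f3 <- summary(aov(x[, 2] ~ lab3))[[1]]$`F value`[1]
  expect_equal(r3$F[2], f3, tolerance = 1e-10)
})
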