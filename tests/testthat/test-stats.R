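test_that("one-way ANOVA recovers the classical decomposition and edge cases", {
  # equal group means with spread: F ~ 0
  vals <- rep(c(-1, 0, 1), 4)
  grp <- rep(c("a", "b", "c", "d"), each = 3)
  res <- anova_oneway(vals, grp)
  expect_lt(res$F, 1e-12)
  expect_gt(res$p, 0.999)

  # all observations identical
  res0 <- anova_oneway(rep(2, 10), rep(c("a", "b"), 5))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(5)
  x <- c(rnorm(9, 0), rnorm(14, 0.8))
  g <- rep(c("a", "b"), c(9, 14))
  tt <- t.test(x ~ g, var.equal = TRUE)
  res2 <- anova_oneway(x, g)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA degrees of freedom and Tukey table size follow the design", {
  ns <- c(12, 20, 20, 11, 9, 17, 20, 12, 20, 20, 4, 20)
  set.seed(2)
  vals <- rnorm(sum(ns))
  grp <- rep(paste0("s", seq_along(ns)), ns)
  res <- anova_oneway(vals, grp)
  expect_equal(res$df1, 11L)
  expect_equal(res$df2, 173L)
  expect_equal(nrow(res$tukey), 12 * 11 / 2)
  # Tukey-Kramer adjusted p agrees with the base TukeyHSD implementation
  th <- TukeyHSD(aov(vals ~ factor(grp)))[[1]]
  key <- paste(res$tukey$group_j, res$tukey$group_i, sep = "-")
  expect_equal(res$tukey$adjusted_p, unname(th[key, "p adj"]), tolerance = 1e-8)
})

test_that("Kaiser selection retains correlation-matrix components above eigenvalue 1", {
  set.seed(8)
  X <- matrix(rnorm(50 * 8), 50, 8)
  sel <- pca_select(X)
  expect_equal(sum(sel$eigenvalues), 8, tolerance = 1e-6)   # trace conservation
  expect_true(all(diff(sel$eigenvalues) <= 1e-12))
  expect_lt(max(abs(colMeans(sel$scores))), 1e-9)
  expect_equal(sel$retained_count, sum(sel$eigenvalues > 1))

  # duplicated column + independent column: eigenvalues ~ (2, 1, 0), one kept
  x <- rnorm(200); y <- rnorm(200)
  sel3 <- pca_select(cbind(x, x, y))
  expect_equal(sel3$eigenvalues, c(2, 1, 0), tolerance = 0.1)
  expect_equal(sel3$retained_count, 1L)

  expect_warning(pca_select(cbind(x, 0)), "zero-variance")
  expect_error(pca_select(matrix(1, 1, 3)),
               class = "statomorph_insufficient_data_error")
})

test_that("Wilks' lambda is 1 for coincident group means and drops when they separate", {
  set.seed(13)
  k <- 3; n <- 12; p <- 4
  blocks <- lapply(1:k, function(i) {
    D <- matrix(rnorm(n * p), n, p)
    sweep(D, 2, colMeans(D))          # group mean exactly zero
  })
  X <- do.call(rbind, blocks)
  g <- rep(letters[1:k], each = n)
  m0 <- cda_fit(X, g)
  expect_equal(m0$wilks_lambda, 1, tolerance = 1e-10)

  X2 <- X; X2[g == "a", 1] <- X2[g == "a", 1] + 2
  m1 <- cda_fit(X2, g)
  expect_lt(m1$wilks_lambda, m0$wilks_lambda - 0.1)
  expect_equal(m1$df1, p * (k - 1))
})

test_that("classification is by nearest centroid in canonical space", {
  set.seed(21)
  # 10-sigma separated clusters classify perfectly
  X <- rbind(matrix(rnorm(40 * 2), 40, 2),
             sweep(matrix(rnorm(40 * 2), 40, 2), 2, c(10, 0), "+"),
             sweep(matrix(rnorm(40 * 2), 40, 2), 2, c(0, 10), "+"))
  g <- rep(c("a", "b", "c"), each = 40)
  m <- cda_fit(X, g)
  cl <- cda_classify(m, X, labels = g)
  expect_equal(cl$confusion$overall_percent_correct, 100)
  expect_equal(sum(diag(cl$confusion$counts)), 120)

  # one observation per group: every point is its own centroid
  X1 <- rbind(c(0, 0), c(4, 0), c(0, 4))
  g1 <- c("a", "b", "c")
  m1 <- suppressWarnings(cda_fit(X1, g1))
  expect_equal(as.character(cda_classify(m1, X1)$predicted), g1)

  expect_error(cda_classify(m, X[, 1, drop = FALSE]),
               class = "statomorph_parameter_error")
})

test_that("equal and proportional priors differ exactly by the log-prior offset", {
  # 1-D two-group problem with unequal n: the decision boundary shifts
  # toward the smaller group under proportional priors
  xa <- rep(c(-1, 1), 5)           # group a: mean 0, n = 10
  xb <- rep(c(5, 7), 20)           # group b: mean 6, n = 40
  X <- matrix(c(xa, xb), ncol = 1)
  g <- rep(c("a", "b"), c(10, 40))
  m_eq <- cda_fit(X, g, priors = "equal")
  m_pr <- cda_fit(X, g, priors = "proportional")
  # canonical-space half-gap and the prior-induced boundary shift
  a <- m_eq$canonical_coefficients[1, 1]
  shift <- log(0.8 / 0.2) / (abs(a)^2 * 6)      # in data units
  border <- 3                                    # midpoint of 0 and 6
  probe <- matrix(border - shift / 2, ncol = 1)  # inside the flip zone
  expect_equal(as.character(cda_classify(m_eq, probe)$predicted), "a")
  expect_equal(as.character(cda_classify(m_pr, probe)$predicted), "b")
  probe2 <- matrix(border - 2 * shift, ncol = 1) # beyond it: both agree
  expect_equal(as.character(cda_classify(m_pr, probe2)$predicted), "a")
})

test_that("CDA classification is invariant under invertible affine maps", {
  set.seed(77)
  X <- rbind(matrix(rnorm(30 * 4), 30, 4),
             sweep(matrix(rnorm(30 * 4), 30, 4), 2, c(2, -1, 0.5, 0), "+"),
             sweep(matrix(rnorm(30 * 4), 30, 4), 2, c(-1, 2, 0, 1), "+"))
  g <- rep(c("a", "b", "c"), each = 30)
  M <- qr.Q(qr(matrix(rnorm(16), 4, 4))) %*% diag(c(3, 0.2, 1.5, 0.7))
  Y <- sweep(X %*% M, 2, c(5, -3, 2, 100), "+")
  c1 <- cda_classify(cda_fit(X, g), X, labels = g)$confusion
  c2 <- cda_classify(cda_fit(Y, g), Y, labels = g)$confusion
  expect_identical(c1$counts, c2$counts)
  j1 <- jackknife_classify(X, g)
  j2 <- jackknife_classify(Y, g)
  expect_identical(j1$counts, j2$counts)
})

test_that("the jackknife refits once per observation and is honest", {
  set.seed(42)
  # clearly separated: leave-one-out still perfect
  X <- rbind(matrix(rnorm(20 * 2), 20, 2),
             sweep(matrix(rnorm(20 * 2), 20, 2), 2, c(10, 10), "+"))
  g <- rep(c("a", "b"), each = 20)
  jk <- jackknife_classify(X, g)
  expect_equal(jk$overall_percent_correct, 100)
  expect_equal(attr(jk, "n_refits"), 40L)
  expect_equal(rowSums(jk$counts), c(a = 20, b = 20))

  # overlapping groups: jackknife does not beat resubstitution here
  X2 <- rbind(matrix(rnorm(25 * 3), 25, 3),
              sweep(matrix(rnorm(25 * 3), 25, 3), 2, c(1, 0, 0), "+"))
  g2 <- rep(c("a", "b"), each = 25)
  m2 <- cda_fit(X2, g2)
  resub <- cda_classify(m2, X2, labels = g2)$confusion
  jk2 <- jackknife_classify(X2, g2)
  expect_lte(jk2$overall_percent_correct, resub$overall_percent_correct)

  expect_warning(
    jackknife_classify(rbind(X2, c(9, 9, 9)), c(g2, "c")),
    "size 1")
})

test_that("combining faces does not reduce resubstitution accuracy", {
  samples <- synth_nef_samples(k = 4, n = 8, sd_noise = 0.006,
                               sd_species = 0.006, seed = 19)
  # small-n fixtures leave the pooled covariance near-singular; the ridge
  # fallback warns while degrading gracefully
  all3 <- suppressWarnings(run_face_combination_cda(samples, level = "species"))
  accs <- vapply(c("proximal", "oral", "lateral"), function(f) {
    suppressWarnings(run_face_combination_cda(
      samples, face_set = f,
      level = "species"))$resubstitution$overall_percent_correct
  }, numeric(1))
  expect_true(all(all3$resubstitution$overall_percent_correct >= accs))

  # family level: table has one row per family
  fam <- suppressWarnings(run_face_combination_cda(samples, level = "family"))
  expect_equal(nrow(fam$jackknife$counts), length(unique(
    vapply(samples, function(s) s$meta$family, ""))))

  # without PCA reduction df1 = p (k - 1)
  raw <- suppressWarnings(run_face_combination_cda(samples, level = "species",
                                                   use_pca_reduction = FALSE))
  expect_equal(raw$model$df1, 228L * 3L)
  expect_null(raw$pca)
})

test_that("shape-size regression behaves under the null and rejects tiny groups", {
  set.seed(30)
  len <- rnorm(60, 200, 15)
  sp <- rep(c("u", "v", "w"), each = 20)
  nef <- 0.02 + rnorm(60, 0, 0.001)    # size-independent shape
  res <- allometry_regression(nef, len, sp)
  expect_equal(nrow(res), 3)
  expect_true(all(res$r_squared >= 0 & res$r_squared <= 1))
  # |slope| < 2 SE, recovered through the slope t statistic
  tstat <- qt(res$p_value / 2, df = res$n - 2, lower.tail = FALSE)
  expect_true(all(tstat < 2))

  expect_error(allometry_regression(nef[1:2], len[1:2], c("z", "z")),
               class = "statomorph_parameter_error")
  expect_error(allometry_regression(nef[1:5], rep(100, 5), rep("z", 5)),
               class = "statomorph_degenerate_error")
})
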