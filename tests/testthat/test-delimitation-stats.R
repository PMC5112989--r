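# Temperature GLMs, partial-residual classification, PCA and the rank test.

test_that("ANCOVA interaction test behaves under null and alternative", {
  # identical data in both groups: interaction estimate is zero
  set.seed(1)
  tmp <- runif(20, 17, 33)
  v <- 1 + 0.1 * tmp + rnorm(20, 0, 0.1)
  fit0 <- lm(c(v, v) ~ rep(tmp, 2) * factor(rep(c("a", "b"), each = 20)))
  expect_lt(abs(coef(fit0)[4]), 1e-10)
  # type-I error near nominal under equal slopes
  set.seed(2)
  rej <- mean(replicate(200, {
    d <- data.frame(t = runif(60, 17, 33),
                    otu = rep(c("a", "b"), each = 30))
    d$v <- 2 + 0.05 * d$t + rnorm(60)
    ancova_interaction(d$v, d$t, d$otu)$p_value < 0.05
  }))
  expect_gt(rej, 0.005); expect_lt(rej, 0.12)
  # gross slope difference is detected
  set.seed(3)
  d <- data.frame(t = runif(200, 17, 33), otu = rep(c("a", "b"), 100))
  d$v <- 2 + ifelse(d$otu == "a", 0.05, 1.05) * d$t + rnorm(200, 0, 0.05)
  expect_lt(ancova_interaction(d$v, d$t, d$otu)$p_value, 0.001)
  expect_error(ancova_interaction(1:5, 1:5, rep("a", 5)), "two OTU")
})

test_that("temperature GLM recovers generating coefficients", {
  # zero-noise limit: exact recovery
  d <- simulate_glm_data(0.3, -0.002, 0.4, "gaussian_identity", 50,
                         sd = 0, seed = 1)
  f <- suppressWarnings(  # a perfect fit is the point here
    fit_temperature_glm(d$value, d$temperature, d$otu,
                        "gaussian_identity", reference = "ref"))
  expect_equal(c(f$a, f$b, f$c), c(0.3, -0.002, 0.4), tolerance = 1e-8)
  # Poisson simulation from the published chirp-count model, n = 200
  d2 <- simulate_glm_data(-0.662, 0.036, 1.622, "poisson_log", 200,
                          seed = 2)
  f2 <- fit_temperature_glm(d2$value, d2$temperature, d2$otu,
                            "poisson_log", reference = "ref")
  expect_lt(abs(f2$c - 1.622), 3 * f2$se_c)
  expect_equal(f2$family, "poisson_log")
  # binomial with per-individual denominators
  d3 <- simulate_glm_data(-1.49, -0.03, 2.011, "binomial_logit", 200,
                          sizes = 20L, seed = 3)
  f3 <- fit_temperature_glm(d3$value, d3$temperature, d3$otu,
                            "binomial_logit", sizes = d3$size,
                            reference = "ref")
  expect_lt(abs(f3$c - 2.011), 3 * f3$se_c)
  # constant temperature: slope inestimable
  expect_error(fit_temperature_glm(rnorm(10), rep(25, 10),
                                   rep(c("a", "b"), 5),
                                   "gaussian_identity"), "inestimable")
})

test_that("partial-residual classification separates and overlaps", {
  # two disjoint clusters -> no overlap labels among the reference pair
  d <- simulate_glm_data(0.3, -0.002, 5, "gaussian_identity", 60,
                         sd = 0.05, seed = 4)
  f <- fit_temperature_glm(d$value, d$temperature, d$otu,
                           "gaussian_identity", reference = "ref")
  cl <- classify_by_partial_residuals(f, d$value, d$temperature, d$otu)
  expect_true(all(cl$label != "overlap"))
  expect_true(all(cl$label[d$otu == "ref"] == "reference"))
  # identical distributions -> overlap everywhere
  set.seed(5)
  v <- rnorm(40); v <- c(v, v)
  tmp <- rep(runif(40, 17, 33), 2)
  lab <- rep(c("a", "b"), each = 40)
  fi <- fit_temperature_glm(v, tmp, lab, "gaussian_identity",
                            reference = "a")
  cli <- classify_by_partial_residuals(fi, v, tmp, lab)
  expect_true(all(cli$label == "overlap"))
  # location invariance: adding a constant changes no label
  cl2 <- classify_by_partial_residuals(f, d$value + 13.7, d$temperature,
                                       d$otu)
  expect_equal(cl2$label, cl$label)
  # an individual of a third OTU inside the reference interval only
  iv <- attr(cl, "intervals")
  probe <- mean(iv$reference)
  cl3 <- classify_by_partial_residuals(
    f, c(d$value, probe + f$b * 25), c(d$temperature, 25),
    c(d$otu, "lito"))
  expect_equal(cl3$label[nrow(cl3)], "reference")
})

test_that("correlation PCA matches a brute-force eigendecomposition", {
  set.seed(6)
  X <- matrix(rnorm(90), 30, 3,
              dimnames = list(NULL, c("ep", "ied", "ein")))
  pc <- pca_correlation(X)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(pc$explained, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  expect_true(all(apply(pc$loadings, 2, function(l) l[which.max(abs(l))]) > 0))
  # affine rescaling of features leaves scores unchanged
  Y <- sweep(sweep(X, 2, c(2, -3, 0.5), "*"), 2, c(1, 10, -4), "+")
  pc2 <- pca_correlation(Y)
  expect_equal(abs(pc2$scores), abs(pc$scores), tolerance = 1e-9)
  # rank-1 data: PC1 explains everything
  Z <- cbind(X[, 1], 2 * X[, 1], -X[, 1])
  expect_equal(pca_correlation(Z)$explained[1], 1, tolerance = 1e-12)
  expect_error(pca_correlation(cbind(X[, 1:2], 0)), "zero-variance")
})

test_that("preset cohorts separate in the three-character PCA", {
  p <- taxon_presets()
  a <- simulate_trait_records(p$petr, 25, seed = 7)
  b <- simulate_trait_records(p$brev, 25, seed = 8)
  X <- rbind(a, b)[, c("ep_l_1", "ied_s_l_min", "e_in_number")]
  pc <- pca_correlation(X)
  s1 <- pc$scores[1:25, 1]; s2 <- pc$scores[26:50, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("rank-sum statistic follows the pair-count convention", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$W, 0)
  x <- c(1, 2, 3)
  expect_equal(wilcoxon_rank_sum(x, x)$W, length(x)^2 / 2)
  # complementarity for arbitrary inputs, with and without ties
  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:10, sample(2:25, 1), replace = TRUE)
    y <- sample(1:10, sample(2:25, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$W + wilcoxon_rank_sum(y, x)$W,
                 length(x) * length(y))
  }
  # exact p agrees with the reference implementation when tie-free
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample normal approximation stays close to the reference
  set.seed(11)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})
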