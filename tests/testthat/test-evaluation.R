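test_that("OLS R2 matches the normal-equations oracle", {
  # 6-point fixture, solved independently via the normal equations
  x <- c(0.2, -1.1, 0.5, 1.7, -0.3, 0.9)
  z <- c(1.0, 0.4, -0.6, 1.2, 0.1, -0.9)
  y <- c(0.5, -0.8, 0.3, 2.0, -0.2, 0.7)
  X <- cbind(1, x, z)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  r2Oracle <- 1 - sum((y - X %*% bh)^2) / sum((y - mean(y))^2)
  res <- r2Quantitative(x, y, data.frame(z = z))
  expect_equal(res$estimate[res$metric == "r2_full"], r2Oracle)

  # phenotype identical to the score: R2 = 1
  perfect <- suppressWarnings(r2Quantitative(y, y))
  expect_equal(perfect$estimate[perfect$metric == "r2_full"], 1)

  # independent score at large n: incremental R2 near zero
  set.seed(60)
  n <- 5000
  res0 <- r2Quantitative(rnorm(n), rnorm(n))
  expect_lt(res0$estimate[res0$metric == "r2_incremental"], 0.01)

  # collinear covariates are reported, rank-deficiency is fatal
  expect_error(r2Quantitative(x, y, data.frame(z = z, z2 = 2 * z)),
               class = "prsDataError", regexp = "z2")
})

test_that("AUC equals exhaustive pair counting", {
  # fixed toy: 4 cases vs 4 controls, no ties
  s <- c(3, 2, 1, 0, 2.5, 0.5, -1, -2)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(aucScore(s, y)$estimate, bruteAUC(s, y))
  expect_equal(aucScore(s, y)$estimate, 0.75)

  # ties contribute one half
  st <- c(3, 2, 1, 0, 2.5, 1, -1, -2)
  expect_equal(aucScore(st, y)$estimate, bruteAUC(st, y))
  expect_equal(aucScore(st, y)$estimate, 11.5 / 16)

  # perfect separation
  expect_equal(aucScore(c(5, 4, 1, 0), c(1, 1, 0, 0))$estimate, 1)
  expect_error(aucScore(1:4, c(1, 1, 1, 1)), class = "prsDataError")

  # property: random instances up to 1000 subjects, incl. ties
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    sc <- sample(seq(-2, 2, 0.5), n, replace = TRUE)
    yy <- rbinom(n, 1, 0.4)
    if (sum(yy) %in% c(0, n)) next
    expect_equal(aucScore(sc, yy)$estimate, bruteAUC(sc, yy))
    # complement symmetry
    expect_equal(aucScore(sc, yy)$estimate + aucScore(sc, 1 - yy)$estimate, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- rnorm(300)
  y <- rbinom(300, 1, plogis(s))
  expect_equal(aucScore(s, y)$estimate,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("Nagelkerke R2 matches the likelihood-grid oracle on an 8-obs toy", {
  s <- c(-1.5, -0.7, -0.2, 0.1, 0.3, 0.8, 1.2, 2.0)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- nagelkerkeR2(s, y)
  expect_equal(fit$estimate, gridNagelkerke(s, y), tolerance = 1e-4)
  expect_gte(fit$estimate, 0)
  expect_lte(fit$estimate, 1)

  # symmetric design: score coefficient 0 at the optimum, R2 = 0
  null <- nagelkerkeR2(c(1, 1, 2, 2), c(0, 1, 0, 1))
  expect_lt(null$estimate, 1e-10)

  # invariant to affine score rescaling and covariate column order
  set.seed(63)
  n <- 200
  sc <- rnorm(n); yy <- rbinom(n, 1, plogis(sc))
  cv <- data.frame(u = rnorm(n), v = rnorm(n))
  a <- nagelkerkeR2(sc, yy, cv)
  b <- nagelkerkeR2(2 * sc + 5, yy, cv[, c("v", "u")])
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
})

test_that("top-decile odds ratio reproduces the contingency oracle", {
  # 100 subjects; top decile: 9 cases + 1 control; bottom: 10 cases + 80
  # controls -> OR = (9*80)/(1*10) = 72
  scores <- c(seq(10, 10.9, 0.1), seq(0, 8.9, 0.1))
  labels <- c(rep(1, 9), 0, rep(1, 10), rep(0, 80))
  res <- topDecileOR(scores, labels)
  expect_equal(res$estimate, 72)
  expect_false(res$corrected)

  # invariant to strictly monotone transformation of the scores
  res2 <- topDecileOR(exp(scores / 4), labels)
  expect_equal(res2$estimate, 72)

  # zero cell triggers the 0.5 correction with a warning
  s0 <- c(seq(10, 10.9, 0.1), seq(0, 8.9, 0.1))
  y0 <- c(rep(1, 10), rep(0, 90))
  expect_warning(r0 <- topDecileOR(s0, y0), "0.5")
  expect_true(r0$corrected)
  expect_equal(r0$estimate, (10.5 * 90.5) / (0.5 * 0.5))

  # independent labels: OR near 1 at large n
  set.seed(64)
  rr <- topDecileOR(rnorm(20000), rbinom(20000, 1, 0.3))
  expect_gt(rr$estimate, 0.7)
  expect_lt(rr$estimate, 1.4)
  expect_error(topDecileOR(1:5, c(1, 0, 1, 0, 1)), class = "prsDataError")
})

test_that("concordance protocol: squared errors, median, paired t-test", {
  w <- data.frame(snp = paste0("s", 1:5),
                  beta = c(0.1, -0.2, 0.05, 0, 0.3))
  # identical inputs
  same <- concordanceWeights(w, w)
  expect_equal(same$median_sq_error, 0)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # constant offset: every squared error is c^2
  off <- transform(w, beta = beta + 0.01)
  res <- concordanceWeights(w, off)
  expect_equal(unname(res$squared_errors), rep(1e-4, 5))

  # hand-computed 5-SNP oracle
  w2 <- data.frame(snp = paste0("s", 1:5),
                   beta = c(0.12, -0.18, 0.01, -0.03, 0.33))
  d <- w$beta - w2$beta
  res2 <- concordanceWeights(w, w2)
  expect_equal(res2$median_sq_error, median(d^2))
  expect_equal(res2$t_statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(res2$p_value, 2 * pt(-abs(res2$t_statistic), 4))

  # SNP set mismatch lists the symmetric difference
  expect_error(concordanceWeights(w, transform(w, snp = paste0("x", 1:5))),
               class = "prsDataError", regexp = "x1")
})

test_that("replicate summaries report mean and k-1 SD", {
  r <- function(v) data.frame(metric = "auc", estimate = v)
  two <- replicateSummary(list(r(1), r(3)))
  expect_equal(two$mean, 2)
  expect_equal(two$sd, sqrt(2))
  same <- replicateSummary(list(r(0.5), r(0.5), r(0.5)))
  expect_equal(same$sd, 0)
  expect_warning(one <- replicateSummary(list(r(1))), "single")
  expect_true(is.na(one$sd))
})
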