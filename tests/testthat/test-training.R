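test_that("huber loss matches its closed form on both branches", {
  expect_equal(huber_loss(c(1, 2, 3), c(1, 2, 3), 0.1), 0)
  expect_equal(huber_loss(0.05, 0, 0.1), 0.00125)      # quadratic branch
  expect_equal(huber_loss(1, 0, 0.1), 0.095)           # linear branch
  expect_error(huber_loss(numeric(0), numeric(0), 0.1),
               class = "lazynet_validation_error")
  expect_error(huber_loss(1, 0, delta = 0), class = "lazynet_validation_error")
})

test_that("huber loss approaches its two analytic limits", {
  set.seed(5)
  e <- rnorm(200, 0, 1)
  # delta -> Inf: 0.5 * MSE
  expect_equal(huber_loss(e, rep(0, 200), delta = 1e6), 0.5 * mean(e^2))
  # small delta: delta * (MAE - 0.5 delta)
  d <- 1e-4
  expect_equal(huber_loss(e, rep(0, 200), delta = d),
               d * (mean(abs(e)) - 0.5 * d), tolerance = 1e-6)
})

test_that("regression metrics match direct textbook formulas", {
  p <- matrix(1:6, 2); y <- p
  m <- evaluate_regression(p, y)
  expect_equal(unlist(m[c("rmse", "mae", "pearson_r")]),
               c(rmse = 0, mae = 0, pearson_r = 1))
  m2 <- evaluate_regression(p + 1, p)
  expect_equal(unlist(m2[c("rmse", "mae", "pearson_r")]),
               c(rmse = 1, mae = 1, pearson_r = 1))
  set.seed(8)
  pr <- matrix(rnorm(100), 10); ty <- matrix(rnorm(100), 10)
  m3 <- evaluate_regression(pr, ty)
  e <- as.numeric(pr) - as.numeric(ty)
  expect_equal(m3$rmse, sqrt(sum(e^2) / 100), tolerance = 1e-12)
  expect_equal(m3$mae, sum(abs(e)) / 100, tolerance = 1e-12)
  r_direct <- sum((pr - mean(pr)) * (ty - mean(ty))) /
    sqrt(sum((pr - mean(pr))^2) * sum((ty - mean(ty))^2))
  expect_equal(m3$pearson_r, r_direct, tolerance = 1e-12)
  expect_true(is.na(evaluate_regression(pr, ty * 0)$pearson_r))
})

test_that("ROC-AUC equals exhaustive pair counting", {
  # 4-point instance: positives (0.35, 0.8) vs negatives (0.1, 0.4)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # exhaustive oracle on random instances with ties
  set.seed(11)
  for (i in 1:5) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, y), mean(pairs))
  }
})

test_that("ROC-AUC agrees with an independent implementation", {
  set.seed(12)
  s <- rnorm(300); y <- rbinom(300, 1, 0.3)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("ranking metrics are invariant to monotone transforms and calibrated on noise", {
  set.seed(13)
  s <- rnorm(500); y <- rbinom(500, 1, 0.5)
  a1 <- evaluate_ranking(matrix(s), matrix(y))
  a2 <- evaluate_ranking(matrix(exp(3 * s)), matrix(y))
  expect_equal(a1, a2, tolerance = 1e-12)
  # predictions independent of labels: ROC-AUC ~ 0.5
  set.seed(14)
  s <- rnorm(1e4); y <- rbinom(1e4, 1, 0.3)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.02)
  # perfect ranking
  pr <- evaluate_ranking(matrix(c(0.9, 0.8, 0.1, 0.2)),
                         matrix(c(1, 1, 0, 0)))
  expect_equal(pr$roc_auc, 1)
  expect_equal(pr$pr_auc, 1)
  expect_true(is.na(roc_auc(s, rep(1, 1e4))))
})

test_that("F1 at the frozen per-gene quantile threshold matches hand confusion matrices", {
  tr <- rbind(g1 = c(0, 0, 1, 2), g2 = c(0, 1, 1, 3), g3 = c(5, 5, 5, 5))
  pred <- rbind(g1 = c(0.1, 1.5), g2 = c(2, 0.2), g3 = c(5, 5))
  targ <- rbind(g1 = c(0, 2), g2 = c(3, 0), g3 = c(5, 5))
  # pred == target is perfect whenever each gene has a positive at its
  # threshold (g3's all-negative binarization contributes 0 by convention)
  tr2 <- tr; tr2["g3", ] <- c(4, 5, 5, 6)
  targ2 <- targ; targ2["g3", ] <- c(5, 6)
  f <- f1_at_quantile_threshold(tr2, targ2, targ2, quantile = 0.5)
  expect_equal(f$f1_micro, 1)
  expect_equal(f$f1_macro, 1)
  # hand-set quantile 0.5: thresholds are per-gene medians of tr
  f2 <- f1_at_quantile_threshold(tr, pred, targ, quantile = 0.5)
  thr <- apply(tr, 1, median)
  TPs <- FPs <- FNs <- f1s <- numeric(3)
  for (i in 1:3) {
    ph <- pred[i, ] > thr[i]; yh <- targ[i, ] > thr[i]
    TPs[i] <- sum(ph & yh); FPs[i] <- sum(ph & !yh); FNs[i] <- sum(!ph & yh)
    f1s[i] <- if (2 * TPs[i] + FPs[i] + FNs[i] == 0) 0 else
      2 * TPs[i] / (2 * TPs[i] + FPs[i] + FNs[i])
  }
  expect_equal(f2$f1_macro, mean(f1s))
  expect_equal(f2$f1_micro,
               2 * sum(TPs) / (2 * sum(TPs) + sum(FPs) + sum(FNs)))
  # all-negative binarization contributes zero (g3 is constant at threshold)
  expect_equal(f1s[3], 0)
})

test_that("fitting null dynamics yields a near-zero rate law", {
  set.seed(31)
  X <- matrix(exp(rnorm(6 * 120, 0, 0.3)), 6)
  rownames(X) <- sprintf("g%d", 1:6)
  pr <- snapshot_pairs(X, X, data.frame(target_gene = rep(letters[1:6], 20),
                                        guide_id = "g"))
  fit <- lazynet(pr, width = 16, replicas = 1, epochs = 800, seed = 2)
  expect_lt(evaluate_regression(predict(fit, pr), pr$post)$mae, 1e-3)
})

test_that("fitting is bitwise deterministic for a fixed seed", {
  sys <- sample_monomial_system(5, 6, seed = 1)
  pr <- simulate_snapshot_pairs(sys, 60, seed = 2)
  f1 <- lazynet(pr, width = 8, replicas = 2, epochs = 120, seed = 9)
  f2 <- lazynet(pr, width = 8, replicas = 2, epochs = 120, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("a sparse monomial system is fit to small held-out error", {
  sys <- sample_monomial_system(5, 6, seed = 20)
  # noise chosen below the error bound so the bound tests the fit, not the
  # irreducible readout noise
  train <- simulate_snapshot_pairs(sys, 200, noise_sd = 0.02, seed = 21)
  test <- simulate_snapshot_pairs(sys, 100, noise_sd = 0.02, seed = 22)
  fit <- lazynet(train, width = 32, replicas = 1, epochs = 1200, seed = 3)
  rmse <- evaluate_regression(predict(fit, test), test$post)$rmse
  expect_lt(rmse, 0.1 * sd(test$post))
})

test_that("trained elasticities rank true interactions highly", {
  sys <- sample_monomial_system(20, 30, seed = 11)
  pr <- simulate_snapshot_pairs(sys, 500, seed = 12)
  fit <- lazynet(pr, width = 64, replicas = 3, epochs = 1500, seed = 5)
  E <- compute_elasticity(fit, rowMeans(pr$time0))
  sup <- attr(sys, "support")
  off <- row(sup) != col(sup)
  expect_gte(roc_auc(E$A[off], sup[off] != 0), 0.9)
})
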