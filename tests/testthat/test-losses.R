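# loss closed forms, brute-force cross-checks, and identities

test_that("jaccard loss matches a direct summation oracle on 4x4 patches", {
  set.seed(7)
  for (i in 1:5) {
    pred <- matrix(runif(16), 4, 4)
    truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
    s <- 1
    inter <- sum(pred * truth)
    union <- sum(pred) + sum(truth) - inter
    expect_equal(jaccard_loss(pred, truth, smooth = s),
                 1 - (inter + s) / (union + s))
  }
  # perfect binary prediction: ~0; disjoint: ~1
  t1 <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_lt(jaccard_loss(t1, t1), 0.05)
  expect_gt(jaccard_loss(1 - t1, t1), 0.95)
  # uniform 0.5 prediction, half foreground, closed form on 4x4
  pred <- matrix(0.5, 4, 4)
  truth <- matrix(c(rep(1, 8), rep(0, 8)), 4, 4)
  expect_equal(jaccard_loss(pred, truth, smooth = 1),
               1 - (4 + 1) / (8 + 8 - 4 + 1))
})

test_that("focal loss closed forms and the cross-entropy limit hold", {
  # single pixel, truth 1, pred 0.5, gamma 2, alpha 0.25
  expect_equal(focal_loss(matrix(0.5), matrix(1), gamma = 2, alpha = 0.25),
               0.25 * 0.25 * (-log(0.5)))
  # gamma=0, alpha=1 reduces to mean binary cross-entropy
  set.seed(8)
  for (i in 1:5) {
    pred <- matrix(runif(16, 0.05, 0.95), 4, 4)
    truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
    bce <- -mean(truth * log(pred) + (1 - truth) * log(1 - pred))
    expect_equal(focal_loss(pred, truth, gamma = 0, alpha = 1), bce,
                 tolerance = 1e-10)
  }
  # approaches zero as prediction approaches truth
  truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
  near <- abs(truth - 1e-6)
  expect_lt(focal_loss(near, truth), 1e-4)
})

test_that("combined loss is exactly the weighted sum of its components", {
  set.seed(9)
  pred <- matrix(runif(36), 6, 6)
  truth <- matrix(rbinom(36, 1, 0.3), 6, 6)
  cfg1 <- train_config(loss_weights = c(1, 0))
  cfg2 <- train_config(loss_weights = c(0, 1))
  cfg3 <- train_config(loss_weights = c(1, 1))
  expect_equal(combined_loss(pred, truth, cfg1),
               jaccard_loss(pred, truth, smooth = cfg1$jaccard_smooth))
  expect_equal(combined_loss(pred, truth, cfg2),
               focal_loss(pred, truth, gamma = cfg2$focal_gamma,
                          alpha = cfg2$focal_alpha))
  expect_equal(combined_loss(pred, truth, cfg3),
               combined_loss(pred, truth, cfg1) +
                 combined_loss(pred, truth, cfg2))
  cfgw <- train_config(loss_weights = c(0.3, 1.7))
  expect_equal(combined_loss(pred, truth, cfgw),
               0.3 * jaccard_loss(pred, truth) +
                 1.7 * focal_loss(pred, truth))
})

test_that("losses are non-negative and reject mismatched shapes", {
  pred <- matrix(runif(16), 4, 4)
  truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_gte(jaccard_loss(pred, truth), 0)
  expect_gte(focal_loss(pred, truth), 0)
  expect_error(jaccard_loss(pred, truth[1:2, ]), "shapes differ")
  expect_error(focal_loss(pred[, 1:2], truth), "shapes differ")
})

test_that("the native training loss/gradient agrees with the R reference", {
  set.seed(10)
  n <- 3
  up <- array(rnorm(8 * 8 * 1 * n), c(8, 8, 1, n))
  truth <- array(as.double(rbinom(8 * 8 * n, 1, 0.4)), c(8, 8, 1, n))
  cfg <- train_config(loss_weights = c(1, 1))
  sl <- ophiocount:::cpp_sigmoid_loss(up, truth, 64L, n, 1, 1,
                                      cfg$jaccard_smooth,
                                      cfg$focal_gamma, cfg$focal_alpha)
  prob <- 1 / (1 + exp(-up))
  ref <- ophiocount:::combined_loss_grad(prob, truth, cfg)
  expect_equal(sl$loss, ref$loss, tolerance = 1e-12)
  expect_equal(as.vector(sl$grad_logit),
               as.vector(ref$grad * prob * (1 - prob)), tolerance = 1e-12)
})
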