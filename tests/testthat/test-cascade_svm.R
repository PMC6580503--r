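## a fast, low-dimensional feature set with tunable signal
toy_pool <- function(n_pos, n_neg, effect = 1.5, p = 6, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  X <- matrix(rnorm((n_pos + n_neg) * p), ncol = p)
  X[labels == 1, 1:2] <- X[labels == 1, 1:2] + effect
  colnames(X) <- paste0("f", seq_len(p))
  list(features = tibble::as_tibble(X), labels = labels)
}

test_that("the layer threshold implements the descending ceil(q*M) rank rule", {
  expect_equal(layer_threshold(c(5, 4, 3, 2, 1), q = 0.95), 1)
  ## M = 100 distinct scores: threshold is the 95th largest and exactly 95
  ## positives reach it
  set.seed(20)
  sc <- sample(seq(0.01, 1, by = 0.01))
  t95 <- layer_threshold(sc, q = 0.95)
  expect_equal(t95, sort(sc, decreasing = TRUE)[95])
  expect_equal(sum(sc >= t95), 95)
  ## ties saturate: all-equal scores let every positive pass
  expect_equal(layer_threshold(rep(3.3, 10)), 3.3)
  expect_error(layer_threshold(numeric(0)), "empty")
})

test_that("raising q never decreases per-layer positive retention", {
  set.seed(21)
  sc <- rnorm(57)
  retention <- vapply(c(0.90, 0.95, 0.99), function(q) {
    sum(sc >= layer_threshold(sc, q))
  }, numeric(1))
  expect_true(all(diff(retention) >= 0))
})

test_that("cascade training keeps the documented TND accounting", {
  pool <- toy_pool(40, 400, effect = 1.2, seed = 22)
  model <- suppressWarnings(
    train_cascade(pool$features, pool$labels, seed = 22))
  log <- tidy(model)
  expect_gte(nrow(log), 1)
  ## strictly non-increasing TND, and the balance equation per layer
  expect_equal(log$tnd_after, log$tnd_before - log$n_removed)
  expect_true(all(diff(log$tnd_before) < 0 | nrow(log) == 1))
  expect_equal(log$tnd_before[-1], log$tnd_after[-nrow(log)])
  ## every round except the last removes at least stop_frac * TND0
  if (nrow(log) > 1) {
    expect_true(all(log$n_removed[-nrow(log)] >= 0.05 * 400))
  }
  ## with continuous scores, exactly M - ceil(q*M) positives fall below T_i
  expect_equal(log$n_pos_below, rep(40 - ceiling(0.95 * 40), nrow(log)))
})

test_that("an easy, separable pool collapses the cascade quickly", {
  pool <- toy_pool(30, 300, effect = 6, seed = 23)
  model <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 23))
  log <- tidy(model)
  expect_lte(nrow(log), 2)
  expect_gte(log$n_removed[1] / 300, 0.9)
})

test_that("with an exchangeable scorer, pure noise removes about 1 - q and stops", {
  ## injected scorer independent of the training data: a fixed linear
  ## projection, so positive and negative scores are exchangeable
  fixed_projection <- function(X, y) list(score = function(Xn) rowSums(Xn))
  fracs <- vapply(1:8, function(s) {
    pool <- toy_pool(50, 1000, effect = 0, seed = s)
    model <- suppressWarnings(train_cascade(pool$features, pool$labels,
                                            seed = s,
                                            layer_trainer = fixed_projection))
    log <- tidy(model)
    expect_lte(nrow(log), 3)
    log$n_removed[1] / 1000
  }, numeric(1))
  ## the threshold is the 3rd-smallest of 50 exchangeable positive scores,
  ## so the expected removal fraction is 3/51; the order statistic itself
  ## has SD ~ 0.032, hence the averaged Monte-Carlo tolerance
  expect_lt(abs(mean(fracs) - 3 / 51), 4 * 0.033 / sqrt(8))
})

test_that("an overfit-prone scorer on pure noise still stops and keeps the accounting", {
  pool <- toy_pool(50, 500, effect = 0, seed = 24)
  model <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 24))
  log <- tidy(model)
  expect_true(all(diff(log$tnd_before) < 0))
  expect_lt(log$n_removed[nrow(log)], 0.05 * 500)
  expect_true(all(log$n_removed[-nrow(log)] >= 0.05 * 500))
})

test_that("prediction is the short-circuiting conjunction over layers", {
  pool <- toy_pool(40, 400, effect = 1.5, seed = 25)
  model <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 25))
  pred <- predict(model, pool$features)
  expect_equal(nrow(pred), 440)
  ## positives either pass all layers (NA exit) or record their exit layer
  expect_true(all(is.na(pred$exit_layer[pred$pred == 1])))
  expect_true(all(pred$exit_layer[pred$pred == 0] >= 1))
  ## manual replay of layer 1: samples below T1 must exit at layer 1
  sc1 <- cascade_layer_scores(model, pool$features, layer = 1)
  expect_equal(!is.na(pred$exit_layer) & pred$exit_layer == 1,
               sc1 < model$layers[[1]]$threshold, ignore_attr = TRUE)
  ## a one-layer model predicts exactly (score >= T1)
  one <- model
  one$layers <- one$layers[1]
  pred1 <- predict(one, pool$features)
  expect_equal(pred1$pred, as.integer(sc1 >= model$layers[[1]]$threshold))
})

test_that("training positives are retained at about q^n through their cascade", {
  pool <- toy_pool(60, 600, effect = 1.2, seed = 26)
  model <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 26))
  n_layers <- length(model$layers)
  pred <- predict(model, pool$features[pool$labels == 1, ])
  retention <- mean(pred$pred)
  expect_gte(retention, 0.95^n_layers - 1e-9)
})

test_that("cascade training is deterministic for a fixed seed", {
  pool <- toy_pool(30, 300, effect = 1, seed = 27)
  m1 <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 5))
  m2 <- suppressWarnings(train_cascade(pool$features, pool$labels, seed = 5))
  expect_equal(tidy(m1), tidy(m2))
  expect_equal(predict(m1, pool$features), predict(m2, pool$features))
  ## and serializes byte-identically
  f1 <- tempfile(); f2 <- tempfile()
  write_cascade(m1, f1); write_cascade(m2, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  m3 <- read_cascade(f1)
  expect_equal(predict(m3, pool$features), predict(m1, pool$features))
})

test_that("degenerate pools are rejected with clear errors", {
  pool <- toy_pool(5, 20, seed = 28)
  expect_error(train_cascade(pool$features, rep(1L, 25)), "negatives")
  expect_error(train_cascade(pool$features[1:3, ], c(1L, 0L, 0L)),
               "2 positive")
  expect_error(predict(suppressWarnings(
    train_cascade(pool$features, pool$labels)),
    pool$features[, 1:3]), "lacks feature")
})

test_that("the baselines expose calibrated decision scores", {
  pool <- toy_pool(50, 500, effect = 2, seed = 29)
  bal <- train_single_balanced(pool$features, pool$labels, seed = 1)
  all_fit <- train_single_all(pool$features, pool$labels)
  pb <- predict_scores(bal, pool$features)
  pa <- predict_scores(all_fit, pool$features)
  expect_equal(nrow(pb), 440 + 110)
  ## higher scores for positives on average (sign convention)
  expect_gt(mean(pb$score[pool$labels == 1]), mean(pb$score[pool$labels == 0]))
  expect_gt(mean(pa$score[pool$labels == 1]), mean(pa$score[pool$labels == 0]))
  expect_equal(pb$pred, as.integer(pb$score >= 0))
})

test_that("balanced layer training enforces equal class sizes", {
  pool <- toy_pool(10, 10, seed = 30)
  layer <- train_balanced_layer(pool$features[pool$labels == 1, ],
                                pool$features[pool$labels == 0, ])
  expect_s3_class(layer, "svm_scorer")
  expect_error(train_balanced_layer(pool$features[1:3, ], pool$features[1:5, ]))
})
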