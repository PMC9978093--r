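test_that("baseline featurization z-scores with training statistics only", {
  set.seed(1)
  f <- data.frame(fix_total = rnorm(50, 500, 40), n_saccades = rpois(50, 8),
                  scan_path_length = runif(50, 0.01, 0.2), kept = TRUE)
  sc <- fit_feature_scaler(f)
  z <- featurize_baseline(f, sc)
  expect_equal(dim(z), c(3, 50))
  expect_equal(rowMeans(z), c(fix_total = 0, n_saccades = 0,
                              scan_path_length = 0), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), c(fix_total = 1, n_saccades = 1,
                                  scan_path_length = 1), tolerance = 1e-12)
  # a trial equal to the training mean maps to the origin
  mean_trial <- data.frame(fix_total = sc$mean[1], n_saccades = sc$mean[2],
                           scan_path_length = sc$mean[3])
  expect_equal(as.numeric(featurize_baseline(mean_trial, sc)), c(0, 0, 0))
  # constant training feature maps to 0, guarded divide
  f$n_saccades <- 5
  sc2 <- fit_feature_scaler(f)
  z2 <- featurize_baseline(f, sc2)
  expect_true(all(z2["n_saccades", ] == 0))
  # unfiltered trials are rejected
  f$kept[1] <- FALSE
  expect_error(featurize_baseline(f, sc2), "filtered")
})

test_that("architectures match the declared structures", {
  mlp <- arch_config("baseline")
  expect_equal(mlp$widths, c(3L, 5L, 5L, 5L, 2L))
  cnn <- arch_config("cnn")
  expect_equal(c(cnn$F1, cnn$F2, cnn$K), c(8L, 16L, 3L))
  # parameter count is small (order 1e4), suited to ~630-trial training sets
  set.seed(1)
  n_par <- sum(lengths(gazedx:::.init_params(cnn)))
  expect_lt(n_par, 5e4)
  expect_gt(n_par, 1e3)
})

test_that("CNN gradients match finite differences", {
  set.seed(5)
  arch <- arch_config("cnn", input_side = 10)
  X <- matrix(rnorm(2 * 100 * 6), 200, 6)
  y <- c(0, 1, 0, 1, 1, 0)
  params <- gazedx:::.init_params(arch)
  cache <- gazedx:::.fw_cnn(params, X, arch)
  ce <- gazedx:::.softmax_ce(cache$logits, y, c(1.2, 0.8))
  grads <- gazedx:::.bw_cnn(params, cache, ce$dZ, arch)
  lossfn <- function(p) {
    gazedx:::.softmax_ce(gazedx:::.fw_cnn(p, X, arch)$logits, y, c(1.2, 0.8))$loss
  }
  for (k in names(params)) {
    for (rep in 1:3) {
      i <- sample(length(params[[k]]), 1)
      p2 <- params
      p2[[k]][i] <- p2[[k]][i] + 1e-6
      num <- (lossfn(p2) - ce$loss) / 1e-6
      expect_equal(grads[[k]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("training learns separable data, stops early and is reproducible", {
  set.seed(2)
  n_pid <- 12
  pid <- rep(sprintf("P%02d", 1:n_pid), each = 10)
  y <- rep(rep(c(0L, 1L), each = n_pid / 2), each = 10)
  x <- rbind(matrix(rnorm(length(y) * 2, sd = 0.3), 2),
             ifelse(y == 1, 2, -2) + rnorm(length(y), sd = 0.3))
  cfg <- train_config(max_epochs = 120, early_stop_patience = 10,
                      lr_grid = 1e-2, seed = 7)
  m <- train_trial_model(x, y, pid, arch_config("baseline"), cfg)
  expect_lte(nrow(m$log), 120)
  expect_gt(mean(predict_trials(m, x) == y), 0.95)
  # early stopping restores the best validation epoch
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  # bit-reproducible under the seed
  m2 <- train_trial_model(x, y, pid, arch_config("baseline"), cfg)
  expect_identical(m$params, m2$params)
  # single-class training data errors
  expect_error(train_trial_model(x[, y == 1], y[y == 1], pid[y == 1],
                                 arch_config("baseline"), cfg), "single class")
})

test_that("label-shuffled training stays near chance", {
  set.seed(3)
  n_pid <- 12
  pid <- rep(sprintf("P%02d", 1:n_pid), each = 10)
  y <- rep(rep(c(0L, 1L), each = n_pid / 2), each = 10)
  x <- rbind(matrix(rnorm(length(y) * 2, sd = 0.3), 2),
             ifelse(y == 1, 2, -2) + rnorm(length(y), sd = 0.3))
  y_shuf <- sample(y)  # break the participant-feature link
  cfg <- train_config(max_epochs = 60, early_stop_patience = 10,
                      lr_grid = 1e-2, seed = 7)
  m <- train_trial_model(x, y_shuf, pid, arch_config("baseline"), cfg)
  acc <- mean(predict_trials(m, x) == y_shuf)
  expect_lt(acc, 0.70)  # inside binomial noise of the 50% base rate at n=120
})

test_that("learning-rate selection returns the exhaustively best rate, ties to smallest", {
  set.seed(4)
  n_pid <- 8
  pid <- rep(sprintf("P%02d", 1:n_pid), each = 8)
  y <- rep(rep(c(0L, 1L), each = n_pid / 2), each = 8)
  x <- rbind(ifelse(y == 1, 1.5, -1.5) + rnorm(length(y), sd = 0.2),
             matrix(rnorm(length(y) * 2, sd = 0.3), 2))
  cfg <- train_config(max_epochs = 40, early_stop_patience = 8,
                      lr_grid = c(1e-2, 1e-3), seed = 5)
  lr <- select_learning_rate(x, y, pid, arch_config("baseline"), cfg)
  scores <- attr(lr, "scores")
  expect_equal(as.numeric(lr), cfg$lr_grid[which.max(scores)])
  # strongly separable data: every candidate reaches the maximum, so the
  # tie rule must return the smallest rate
  if (max(scores) == min(scores)) expect_equal(as.numeric(lr), min(cfg$lr_grid))
  # grid of one short-circuits
  cfg1 <- train_config(lr_grid = 5e-3)
  expect_equal(select_learning_rate(x, y, pid, arch_config("baseline"), cfg1), 5e-3)
})

test_that("trial prediction is a deterministic argmax over the two logits", {
  arch <- arch_config("baseline")
  params <- list(W1 = matrix(0, 5, 3), b1 = numeric(5),
                 W2 = matrix(0, 5, 5), b2 = numeric(5),
                 W3 = matrix(0, 5, 5), b3 = numeric(5),
                 W4 = matrix(0, 2, 5), b4 = c(0.9, 0.1))
  m <- structure(list(params = params, arch = arch), class = "trial_model")
  x <- matrix(rnorm(9), 3, 3)
  expect_equal(predict_trials(m, x), c(0L, 0L, 0L))  # logits (0.9, 0.1) -> 0
  params$b4 <- c(0.1, 0.9)
  m$params <- params
  expect_equal(predict_trials(m, x), c(1L, 1L, 1L))
  expect_error(predict_trials(m, matrix(0, 5, 2)), "mismatch")
})
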