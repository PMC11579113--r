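# Network construction, parameter accounting, training/early stopping and
# prediction determinism.

test_that("forward pass yields a single finite scalar per sample", {
  m <- build_model(model_config(input_size = 32,
                                conv_filters = c(2, 2, 2, 2),
                                dense_width = 4, seed = 2))
  y <- predict_ba(m, array(rnorm(32^3), c(32, 32, 32)))
  expect_length(y, 1)
  expect_true(is.finite(y))
  yz <- predict_ba(m, array(0, c(32, 32, 32)))
  expect_true(is.finite(yz))
})

test_that("initialization is deterministic under the config seed", {
  cfg <- toy_model_config(seed = 11)
  expect_identical(build_model(cfg)$layers, build_model(cfg)$layers)
  cfg2 <- toy_model_config(seed = 12)
  expect_false(identical(build_model(cfg)$layers, build_model(cfg2)$layers))
})

test_that("parameter count matches an independent layer-by-layer tally", {
  # input 16, kernel 3, filters (2,3,4,5), dense width 7:
  #  conv1 3^3*1*2+2 = 56   bn1 2*2 = 4
  #  conv2 3^3*2*3+3 = 165  bn2 6
  #  conv3 3^3*3*4+4 = 328  bn3 8
  #  conv4 3^3*4*5+5 = 545  bn4 10
  #  16 -> 8 -> 4 -> 2 -> 1 voxel, so flatten = 1*5 = 5
  #  dense1 5*7+7 = 42      dense2 7*1+1 = 8
  m <- build_model(model_config(input_size = 16, conv_filters = c(2, 3, 4, 5),
                                conv_kernel = 3, dense_width = 7, seed = 1))
  expect_identical(n_parameters(m), 56 + 4 + 165 + 6 + 328 + 8 + 545 + 10 +
                     42 + 8)
})

test_that("pooling collapse is rejected naming the offending block", {
  expect_error(model_config(input_size = 24), "block 4")
})

test_that("a cohort with a learnable intensity signal trains below the constant predictor", {
  co <- intensity_coded_cohort(36, seed = 21)
  parts <- split_cohort(co, c(train = 0.75, val = 0.25), seed = 1)
  cfg <- toy_model_config(seed = 3, conv_filters = c(2, 3, 4, 4),
                          dense_width = 6, learning_rate = 5e-3,
                          max_epochs = 12, batch_size = 6)
  m <- train_model(build_model(cfg), parts$train, parts$val, variant = "ND")
  ages_tr <- vapply(parts$train, function(s) s$age, numeric(1))
  ages_va <- vapply(parts$val, function(s) s$age, numeric(1))
  const_mae <- mean(abs(ages_va - median(ages_tr)))
  expect_lt(evaluate_mae(m, parts$val), const_mae)
  expect_identical(m$variant, "ND")
  # best epoch always carries the minimum validation loss in history
  expect_equal(m$history$val_mae[m$best_epoch], min(m$history$val_mae))
  expect_true(all(is.finite(m$history$val_mae)))
})

test_that("early stopping waits exactly `patience` epochs without improvement", {
  co <- intensity_coded_cohort(12, seed = 31)
  parts <- split_cohort(co, c(train = 0.75, val = 0.25), seed = 2)
  # zero learning rate and a zeroed dense head: the validation loss is
  # exactly flat, so epoch 1 sets the best and nothing ever improves
  zero_head <- function(m) {
    m$layers <- lapply(m$layers, function(ly) {
      if (ly$type == "dense") { ly$w[] <- 0; ly$b[] <- 0 }
      ly
    })
    m
  }
  cfg <- toy_model_config(seed = 4, conv_filters = c(2, 2, 2, 2),
                          dense_width = 4, learning_rate = 0,
                          max_epochs = 50, batch_size = 4, patience = 1)
  m <- train_model(zero_head(build_model(cfg)), parts$train, parts$val)
  expect_identical(nrow(m$history), 2L)   # stops at epoch 2
  expect_identical(m$best_epoch, 1L)
  cfg3 <- toy_model_config(seed = 4, conv_filters = c(2, 2, 2, 2),
                           dense_width = 4, learning_rate = 0,
                           max_epochs = 50, batch_size = 4, patience = 3)
  m3 <- train_model(zero_head(build_model(cfg3)), parts$train, parts$val)
  expect_identical(nrow(m3$history), 4L)  # 1 + patience epochs
})

test_that("training rejects overlapping or empty cohorts", {
  co <- intensity_coded_cohort(8, seed = 41)
  cfg <- toy_model_config(seed = 1, conv_filters = c(2, 2, 2, 2),
                          dense_width = 4, max_epochs = 1)
  m <- build_model(cfg)
  expect_error(train_model(m, co, list()), "non-empty")
  expect_error(train_model(m, co, co[3]), "overlap")
})

test_that("prediction is deterministic in evaluation mode and validates shape", {
  m <- live_toy_model(seed = 6)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(predict_ba(m, x), predict_ba(m, x))
  expect_error(predict_ba(m, array(0, c(4, 4, 4))), "does not match")
})

test_that("evaluate_mae is the arithmetic mean of absolute errors", {
  # a model that always predicts its age_center lets errors be hand-set
  m <- live_toy_model(seed = 7)
  m$layers <- lapply(m$layers, function(ly) {
    if (ly$type == "dense") { ly$w[] <- 0; ly$b[] <- 0 }
    ly
  })
  m$age_center <- 50; m$age_scale <- 1
  subj <- lapply(c(51, 52, 56), function(a) {
    make_subject(paste0("s", a), a, array(rnorm(8^3), c(8, 8, 8)))
  })
  expect_equal(evaluate_mae(m, subj), 3)          # errors {1, 2, 6}
  expect_equal(evaluate_mae(m, subj[2]), 2)       # single subject
  expect_equal(evaluate_mae(m, list(make_subject("x", 50, subj[[1]]$volume$data))),
               0)                                 # perfect prediction
  expect_error(evaluate_mae(m, list()), "non-empty")
})

test_that("input gradients match central finite differences", {
  m <- live_toy_model(seed = 8)
  set.seed(1)
  x <- array(rnorm(8^3), c(8, 8, 8))
  g <- input_gradient(m, x)
  idx <- sample(length(x), 12)
  fd <- fd_gradient(m, x, idx)
  rel <- abs(fd - g[idx]) / pmax(abs(fd) + abs(g[idx]), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("checkpoints round-trip with config and history", {
  m <- live_toy_model(seed = 9)
  f <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(m, f)
  r <- load_checkpoint(f)
  expect_identical(r$layers, m$layers)
  expect_identical(r$config, m$config)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(predict_ba(r, x), predict_ba(m, x))
})
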