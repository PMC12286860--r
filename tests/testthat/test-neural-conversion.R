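# Converters: content loss, unit sampling, MLP training, and baselines.

test_that("content loss follows the weighted squared-error formula", {
  spec1 <- list(x = layer_spec("x", "fully_connected", 1, 1, 2))
  truth <- feature_stack(list(x = matrix(c(3, 4), 1, 2)), spec1)
  zero <- feature_stack(list(x = matrix(0, 1, 2)), spec1)
  expect_equal(content_loss(zero, truth)$total, 1)    # 25 / ||(3,4)||^2
  expect_equal(content_loss(truth, truth)$total, 0)

  # random two-layer, three-sample stack vs an explicit nested-loop oracle
  set.seed(31)
  specs <- list(a = layer_spec("a", "fully_connected", 1, 1, 4),
                b = layer_spec("b", "fully_connected", 1, 1, 3))
  V <- list(a = matrix(rnorm(12), 3, 4), b = matrix(rnorm(9), 3, 3))
  D <- list(a = matrix(rnorm(12), 3, 4), b = matrix(rnorm(9), 3, 3))
  got <- content_loss(feature_stack(D, specs), feature_stack(V, specs))
  oracle <- 0
  for (nm in c("a", "b")) {
    for (i in 1:3) {
      eta <- 1 / sum(V[[nm]][i, ]^2)
      oracle <- oracle + eta * sum((V[[nm]][i, ] - D[[nm]][i, ])^2)
    }
  }
  expect_equal(got$total, oracle, tolerance = 1e-12)

  # empty unit subset contributes zero
  got0 <- content_loss(feature_stack(D, specs), feature_stack(V, specs),
                       units = list(a = integer(0), b = 1:3))
  expect_equal(unname(got0$per_layer["a"]), 0)
})

test_that("unit sampling takes one channel per conv layer, all dense units", {
  specs <- list(c1 = layer_spec("c1", "convolutional", 4, 4, 3),
                c2 = layer_spec("c2", "convolutional", 2, 2, 1),
                fc = layer_spec("fc", "fully_connected", 1, 1, 64))
  set.seed(77)
  counts <- integer(3)
  for (k in 1:3000) {
    u <- sample_units_for_iteration(specs)
    expect_length(u$c1, 16)
    ch <- (u$c1[1] - 1) %/% 16 + 1
    counts[ch] <- counts[ch] + 1L
    expect_identical(u$c2, 1:4)     # single channel: chosen every time
    expect_identical(u$fc, 1:64)    # dense: all units
  }
  expect_true(all(abs(counts / 3000 - 1 / 3) < 0.03))
})

test_that("brain-loss ridge converter matches its closed form", {
  # identity recovery at lambda = 0
  set.seed(41)
  X <- matrix(rnorm(30), 6, 5)
  cv <- train_brain_loss_converter(X, X, ridge_penalty = 0)
  expect_equal(cv$M, diag(5), tolerance = 1e-8)
  expect_equal(cv$c, rep(0, 5), tolerance = 1e-8)
  expect_equal(convert_activity(cv, X), X, tolerance = 1e-8)

  # huge penalty: weights vanish, bias = target column means
  Y <- matrix(rnorm(12), 6, 2)
  cvL <- train_brain_loss_converter(X, Y, ridge_penalty = 1e12)
  expect_lt(sqrt(sum(cvL$M^2)), 1e-6)
  expect_equal(cvL$c, colMeans(Y), tolerance = 1e-6)

  # normal-equation oracle on centered data
  lam <- 1
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  B <- solve(crossprod(Xc) + lam * diag(5), crossprod(Xc, Yc))
  cv1 <- train_brain_loss_converter(X, Y, ridge_penalty = lam)
  expect_equal(cv1$M, t(B), tolerance = 1e-10)
  expect_equal(cv1$c, colMeans(Y) - as.vector(t(B) %*% colMeans(X)),
               tolerance = 1e-10)
  expect_error(train_brain_loss_converter(X, Y[1:3, ]), "sample counts")
})

test_that("GCV penalty selection picks a finite grid value", {
  set.seed(42)
  X <- matrix(rnorm(200), 40, 5)
  Y <- X %*% matrix(rnorm(15), 5, 3) + matrix(rnorm(120, sd = 0.5), 40, 3)
  cv <- train_brain_loss_converter(X, Y)
  expect_true(cv$ridge_penalty %in% 10^seq(-2, 4, by = 0.5))
})

test_that("Procrustes converter recovers planted orthogonal maps", {
  set.seed(43)
  X <- matrix(rnorm(200), 40, 5)
  R0 <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  Y <- X %*% R0
  cv <- train_procrustes_converter(X, Y)
  expect_equal(cv$R, R0, tolerance = 1e-6)
  expect_equal(cv$scale, 1, tolerance = 1e-6)
  expect_lt(max(abs(crossprod(cv$R) - diag(5))), 1e-8)
  expect_equal(convert_activity(cv, X), Y, tolerance = 1e-6)

  # identity when target == source
  cvi <- train_procrustes_converter(X, X)
  expect_equal(cvi$R, diag(5), tolerance = 1e-8)

  # reflections allowed: residual never worse than rotation-only
  R1 <- R0
  R1[, 1] <- -R1[, 1]                         # det flips sign
  Yr <- X %*% R1
  cvr <- train_procrustes_converter(X, Yr, scaling = FALSE)
  res_free <- sum((convert_activity(cvr, X) - Yr)^2)
  sv <- svd(crossprod(scale(X, scale = FALSE), scale(Yr, scale = FALSE)))
  d <- diag(ncol(X)); d[5, 5] <- sign(det(sv$u %*% t(sv$v)))
  R_rot <- sv$u %*% d %*% t(sv$v)             # det = +1 constrained
  res_rot <- sum((sweep(scale(X, scale = FALSE) %*% R_rot, 2,
                        colMeans(Yr), "+") - Yr)^2)
  expect_lte(res_free, res_rot + 1e-8)

  expect_error(train_procrustes_converter(X, cbind(Y, Y[, 1])),
               "matching voxel counts")
  padded <- train_procrustes_converter(X[, 1:4], Y, pad = TRUE)
  expect_equal(ncol(convert_activity(padded, X[, 1:4])), 5)
})

test_that("linear MLP conversion collapses to a single affine map", {
  set.seed(44)
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cv <- train_content_converter(ds, world_train_features(), dec,
                                content_config(iterations = 3, seed = 2),
                                kind = "content_mlp_linear")
  # compose the affine stack explicitly
  W <- diag(cv$m)
  b <- rep(0, cv$m)
  for (op in cv$ops) {
    b <- as.vector(t(op$params$W) %*% b) + op$params$b
    W <- W %*% op$params$W
  }
  X <- response_matrix(noiseless_sessions()$test, average = TRUE)
  expect_equal(convert_activity(cv, X),
               X %*% W + rep(b, each = nrow(X)), tolerance = 1e-10)
  # affine consistency under scaling
  a <- 2.5
  expect_equal(convert_activity(cv, a * X),
               a * (X %*% W) + rep(b, each = nrow(X)), tolerance = 1e-8)
})

test_that("conversion has no cross-sample coupling and checks dimensions", {
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cv <- train_content_converter(ds, world_train_features(), dec,
                                content_config(iterations = 3, seed = 2))
  X <- response_matrix(noiseless_sessions()$test, average = TRUE)[1:10, ]
  whole <- convert_activity(cv, X)
  alone <- convert_activity(cv, X[4, , drop = FALSE])
  expect_equal(whole[4, ], alone[1, ], tolerance = 1e-12)
  expect_error(convert_activity(cv, X[, 1:7]), "voxel dimension")
})

test_that("content training is seed-deterministic with decreasing loss", {
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cfg <- content_config(iterations = 120, learning_rate = 1e-2, seed = 9)
  cv1 <- train_content_converter(ds, world_train_features(), dec, cfg)
  cv2 <- train_content_converter(ds, world_train_features(), dec, cfg)
  expect_identical(cv1$ops, cv2$ops)
  expect_identical(cv1$trajectory, cv2$trajectory)

  # smoothed (window-50) trajectory is non-increasing up to small jitter
  sm <- stats::filter(cv1$trajectory, rep(1 / 50, 50), sides = 1)
  sm <- sm[!is.na(sm)]
  tol <- 0.01 * (max(sm) - min(sm))
  expect_true(all(diff(sm) <= tol))
  expect_lt(sm[length(sm)], sm[1])
})

test_that("content converter ignores target brain data by construction", {
  # the API takes no target responses: the only target input is the frozen
  # decoder, so retraining after changing the target's raw data (but not
  # the decoder) must give the identical converter
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cfg <- content_config(iterations = 10, seed = 4)
  cv1 <- train_content_converter(ds, world_train_features(), dec, cfg)
  expect_false("responses" %in% names(formals(train_content_converter)))
  cv2 <- train_content_converter(ds, world_train_features(), dec, cfg)
  expect_identical(cv1$ops, cv2$ops)
})

test_that("linear content converter drives training loss toward zero", {
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cv <- train_content_converter(
    ds, world_train_features(), dec,
    content_config(iterations = 800, learning_rate = 1e-2, seed = 3),
    kind = "content_mlp_linear")
  expect_lt(mean(utils::tail(cv$trajectory, 20)),
            0.01 * cv$trajectory[1])
})

test_that("residual MLP trains and converts", {
  ds <- noiseless_sessions()$train
  dec <- noiseless_decoder()
  cv <- train_content_converter(ds, world_train_features(), dec,
                                content_config(iterations = 30, seed = 6),
                                kind = "content_mlp_residual")
  out <- convert_activity(cv,
                          response_matrix(noiseless_sessions()$test,
                                          average = TRUE))
  expect_true(all(is.finite(out)))
  expect_lt(utils::tail(cv$trajectory, 1), cv$trajectory[1])
})
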