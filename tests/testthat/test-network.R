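# Reduced-channel configurations keep these tests CPU-friendly; the decoder
# channel contract (4/4/21) is independent of channel widths.

test_that("forward pass emits 4/4/21-channel logits and is deterministic", {
  cf <- model_config_tiny(window = 8L)
  m <- build_model(cf, seed = 1L)
  set.seed(2)
  x <- array(runif(8^3), rep(8L, 3L))
  af <- array(rbinom(24 * 8^3, 1L, 0.05), c(24L, 8L, 8L, 8L))
  fw <- forward_window(m, x, af)
  expect_equal(dim(fw$backbone), c(4L, 8L, 8L, 8L))
  expect_equal(dim(fw$calpha), c(4L, 8L, 8L, 8L))
  expect_equal(dim(fw$amino), c(21L, 8L, 8L, 8L))
  # eval-mode determinism
  fw2 <- forward_window(m, x, af)
  expect_identical(fw, fw2)
  # density-only fallback runs the same pipeline with zero AF3 channels
  fw0 <- forward_window(m, x, NULL)
  expect_true(all(is.finite(fw0$amino)))
  zeros <- forward_window(m, x, array(0, c(24L, 8L, 8L, 8L)))
  expect_equal(fw0, zeros)
  # parameter count is deterministic for a fixed config
  expect_equal(n_parameters(build_model(cf, seed = 99L)), n_parameters(m))
  expect_error(forward_window(m, array(0, c(4L, 4L, 4L)), af), "mismatch")
})

test_that("optional encoder downsampling keeps output shapes via the FPN", {
  cf <- model_config_tiny(window = 8L)
  cf$downsample_encoders <- TRUE
  m <- build_model(cf, seed = 4L)
  fw <- forward_window(m, array(runif(8^3), rep(8L, 3L)))
  expect_equal(dim(fw$amino), c(21L, 8L, 8L, 8L))
})

test_that("weighted cross-entropy matches hand computation", {
  # 1 voxel, 4 classes, all-zero logits, true class 3 (0-based), w = 1
  expect_equal(weighted_cross_entropy(matrix(0, 4L, 1L), 3L), log(4),
               tolerance = 1e-12)
  # logits strongly favoring the true class -> loss ~ 0
  l <- matrix(c(0, 0, 0, 50), 4L, 1L)
  expect_lt(weighted_cross_entropy(l, 3L), 1e-12)
  # linearity in the true-class weight
  w1 <- c(1, 1, 1, 1); w2 <- c(1, 1, 1, 2)
  expect_equal(weighted_cross_entropy(matrix(0, 4L, 1L), 3L, w2),
               2 * weighted_cross_entropy(matrix(0, 4L, 1L), 3L, w1))
  # multi-voxel mean, mixed weights: direct formula
  set.seed(8)
  lg <- matrix(rnorm(12), 3L, 4L)
  lab <- c(0L, 2L, 1L, 2L)
  w <- c(0.2, 1, 5)
  p <- apply(lg, 2L, function(col) exp(col) / sum(exp(col)))
  manual <- mean(-w[lab + 1L] * log(p[cbind(lab + 1L, 1:4)]))
  expect_equal(weighted_cross_entropy(lg, lab, w), manual, tolerance = 1e-12)
  expect_error(weighted_cross_entropy(matrix(0, 4L, 1L), 4L), "range")
})

test_that("total_loss weights tasks and validates lambda", {
  expect_equal(total_loss(1, 1, 1, c(0.6, 0.3, 0.1)), 1.0)
  expect_equal(total_loss(2, 0, 0, c(0.25, 0.4, 0.35)), 0.5)
  expect_equal(total_loss(3, 7, 9, c(0, 1, 0)), 7)
  expect_error(total_loss(1, 1, 1, c(0.5, 0.3, 0.1)), "sum")
  # invariance under joint permutation of (lambda, loss) pairs
  lam <- c(0.6, 0.3, 0.1); ls <- c(1.3, 0.4, 2.2)
  perm <- c(3L, 1L, 2L)
  expect_equal(total_loss(ls[1], ls[2], ls[3], lam),
               total_loss(ls[perm[1]], ls[perm[2]], ls[perm[3]], lam[perm]))
})

test_that("lambda schedule hits its printed endpoints and ramps linearly", {
  expect_equal(lambda_schedule(0), c(0.6, 0.3, 0.1))
  expect_equal(lambda_schedule(10), c(0.6, 0.3, 0.1))
  expect_equal(lambda_schedule(25), c(0.25, 0.4, 0.35))
  expect_equal(lambda_schedule(40), c(0.25, 0.4, 0.35))
  expect_equal(lambda_schedule(22.5),
               (c(0.6, 0.3, 0.1) + c(0.25, 0.4, 0.35)) / 2)
  for (e in c(0, 21, 22.7, 25, 31))
    expect_equal(sum(lambda_schedule(e)), 1, tolerance = 1e-12)
})

test_that("augmentation is seed-reproducible and transforms jointly", {
  fx <- toy_fixture()
  win <- 16L
  sl <- function(a) a[1:win, 1:win, 1:win]
  density <- sl(fx$map$data)
  af3 <- array(0, c(24L, win, win, win))
  af3[1, , , ] <- sl(fx$masks$calpha) == 3L
  masks <- list(backbone = sl(fx$masks$backbone),
                calpha = sl(fx$masks$calpha), amino = sl(fx$masks$amino))
  a1 <- augment_batch(density, af3, masks, rng_seed = 5L)
  a2 <- augment_batch(density, af3, masks, rng_seed = 5L)
  expect_identical(a1, a2)
  # masks stay integer-valued
  expect_true(is.integer(a1$masks$calpha))
  # joint spatial transform: the AF3 channel that mirrored the CA mask
  # still equals it after augmentation
  expect_equal(array(a1$af3[1, , , ], rep(win, 3L)),
               (a1$masks$calpha == 3L) + 0)
})

test_that("four quarter-turns compose to the identity", {
  a <- array(runif(4^3), rep(4L, 3L))
  out <- a
  for (r in 1:4)
    out <- cryotrace:::spatial_transform(out, rots = c(0L, 0L, 1L),
                                         flips = rep(FALSE, 3L),
                                         shift = c(0L, 0L, 0L))
  expect_equal(out, a)
  # translation moves labeled voxels by the stated offset
  m <- array(0L, rep(6L, 3L)); m[2, 3, 4] <- 3L
  t1 <- cryotrace:::spatial_transform(m, rep(0L, 3L), rep(FALSE, 3L),
                                      shift = c(1L, 2L, -1L))
  expect_equal(which(t1 == 3L, arr.ind = TRUE)[1, ], c(3L, 5L, 3L),
               ignore_attr = TRUE)
})

test_that("analytic gradients agree with numerical differentiation", {
  cf <- model_config_tiny(window = 4L)
  m <- build_model(cf, seed = 3L)
  m$config$dropout <- 0
  set.seed(21)
  x <- array(runif(64), rep(4L, 3L))
  af <- array(rbinom(24 * 64, 1L, 0.1), c(24L, 4L, 4L, 4L))
  masks <- list(backbone = array(sample(0:3, 64, TRUE), rep(4L, 3L)),
                calpha = array(sample(0:3, 64, TRUE), rep(4L, 3L)),
                amino = array(sample(0:20, 64, TRUE), rep(4L, 3L)))
  cw <- list(backbone = rep(1, 4), calpha = rep(1, 4), amino = rep(1, 21))
  lam <- c(0.6, 0.3, 0.1)
  lossfun <- function(model) {
    fw <- cryotrace:::model_forward(model, x, af, training = FALSE)
    total_loss(
      weighted_cross_entropy(fw$backbone$val, as.integer(masks$backbone),
                             cw$backbone),
      weighted_cross_entropy(fw$calpha$val, as.integer(masks$calpha),
                             cw$calpha),
      weighted_cross_entropy(fw$amino$val, as.integer(masks$amino),
                             cw$amino), lam)
  }
  fw <- cryotrace:::model_forward(m, x, af, training = TRUE)
  loss <- cryotrace:::window_loss(fw, masks, lam, cw)
  cryotrace:::backward(fw$tape, loss)
  expect_equal(as.numeric(loss$val), lossfun(m), tolerance = 1e-10)
  refs <- cryotrace:::param_refs(m$params)
  set.seed(31)
  rel <- vapply(1:15, function(trial) {
    rf <- refs[[sample(length(refs), 1L)]]
    nd <- cryotrace:::get_by_path(fw$leaves, rf)
    W <- cryotrace:::get_by_path(m$params, rf)
    ij <- sample(length(W), 1L)
    eps <- 1e-5
    Wp <- W; Wp[ij] <- Wp[ij] + eps
    m$params <- cryotrace:::set_by_path(m$params, rf, Wp)
    lp <- lossfun(m)
    Wm <- W; Wm[ij] <- Wm[ij] - eps
    m$params <- cryotrace:::set_by_path(m$params, rf, Wm)
    lm <- lossfun(m)
    m$params <- cryotrace:::set_by_path(m$params, rf, W)
    num <- (lp - lm) / (2 * eps)
    ana <- if (is.null(nd$grad)) 0 else nd$grad[ij]
    abs(num - ana) / max(1e-8, abs(num) + abs(ana))
  }, numeric(1))
  # ReLU kinks can spoil single finite differences; the bulk must agree
  expect_lt(median(rel), 1e-5)
  expect_gte(mean(rel < 1e-3), 0.8)
})

test_that("a tiny model takes optimization steps that reduce the loss", {
  set.seed(12)
  win <- 8L
  masks <- list(
    backbone = array(sample(0:3, win^3, TRUE, prob = c(.85, .1, .03, .02)),
                     rep(win, 3L)),
    calpha = array(sample(0:3, win^3, TRUE, prob = c(.85, .1, .03, .02)),
                   rep(win, 3L)),
    amino = array(sample(0:20, win^3, TRUE, prob = c(.9, rep(.005, 20))),
                  rep(win, 3L)))
  ds <- list(list(density = array(runif(win^3), rep(win, 3L)),
                  af3 = NULL, masks = masks))
  m <- build_model(model_config_tiny(win), seed = 5L)
  res <- train_model(m, ds, epochs = 4L, lr = 5e-3, seed = 3L)
  h <- res$history
  expect_equal(nrow(h), 4L)
  expect_lt(h$val_loss[4], h$val_loss[1])
  expect_equal(h$lambda_b[1], 0.6)
  # resumed run with the same seeds reproduces the logged losses
  m2 <- build_model(model_config_tiny(win), seed = 5L)
  res2 <- train_model(m2, ds, epochs = 4L, lr = 5e-3, seed = 3L)
  expect_equal(res2$history$train_loss, h$train_loss, tolerance = 1e-12)
  expect_error(train_model(m, list(), epochs = 1L), "empty")
})

test_that("predict_map stitches window predictions into probability volumes", {
  set.seed(9)
  # one-window map (core 8 + pad 2 -> window 12) with a reduced model
  cf <- model_config_tiny(window = 12L)
  m <- build_model(cf, seed = 6L)
  map <- density_map(array(runif(8^3), rep(8L, 3L)))
  pred <- predict_map(m, map, core = 8L, pad = 2L)
  expect_equal(dim(pred$calpha_p), dim(map$data))
  expect_equal(dim(pred$amino_p), c(20L, dim(map$data)))
  expect_true(all(pred$calpha_p >= 0 & pred$calpha_p <= 1))
  expect_true(all(pred$backbone_p >= 0 & pred$backbone_p <= 1))
  sums <- apply(pred$amino_p, 2:4, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # AF3 shape mismatch is rejected
  expect_error(predict_map(m, map, af3 = array(0, c(24L, 4L, 4L, 4L)),
                           core = 8L, pad = 2L), "shape")
})

test_that("oracle logit injection recovers the labels through softmax", {
  # build sharp logits directly from a mask and check the class-3
  # probability extraction used by predict_map
  d <- c(5L, 5L, 5L)
  mask <- array(sample(0:3, prod(d), TRUE), d)
  logits <- array(0, c(4L, d))
  for (cls in 0:3) {
    sel <- which(mask == cls)
    idx <- arrayInd(sel, d)
    logits[cbind(cls + 1L, idx)] <- 30
  }
  p3 <- array(cryotrace:::softmax_class(logits, 4L), d)
  expect_true(all(p3[mask == 3L] > 0.999))
  expect_true(all(p3[mask != 3L] < 0.001))
})
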