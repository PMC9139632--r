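test_that("undersampling balances the clinical-scale class counts", {
  # class-count stub at the reference scale: 428,159 healthy / 23,866 tumor
  stub <- data.frame(tumor = rep(c(FALSE, TRUE), c(428159L, 23866L)))
  pool <- balance_pool(stub, per_class_target = 30000L, seed = 7)
  expect_equal(nrow(pool$healthy), 30000L)
  expect_equal(nrow(pool$tumor), 30000L)
  expect_true(all(pool$tumor$tumor))
  expect_false(any(pool$healthy$tumor))

  # deterministic per seed
  pool2 <- balance_pool(stub, per_class_target = 30000L, seed = 7)
  expect_identical(pool, pool2)
  pool3 <- balance_pool(stub, per_class_target = 30000L, seed = 8)
  expect_false(identical(rownames(pool$healthy), rownames(pool3$healthy)))
})

test_that("an already-balanced pool is returned unchanged up to ordering", {
  stub <- data.frame(id = 1:40, tumor = rep(c(FALSE, TRUE), each = 20))
  pool <- balance_pool(stub, per_class_target = 20L, seed = 1)
  expect_setequal(pool$healthy$id, 1:20)
  expect_setequal(pool$tumor$id, 21:40)
})

test_that("degenerate pools are rejected", {
  expect_error(balance_pool(data.frame(tumor = rep(FALSE, 10))),
               "no tumor")
  expect_error(balance_pool(data.frame(tumor = rep(TRUE, 10))),
               "no healthy")
})

test_that("balancing preserves the class definitions on real stacks", {
  ph <- tiny_phantom(seed = 13)
  img <- scale_intensity(ph$image)
  idx <- index_patches(img, ph$gt, plan_grid(64, 64, 16, 8))
  pool <- materialize_pool(balance_pool(idx, per_class_target = 12, seed = 3))
  expect_length(pool$tumor, 12)
  expect_length(pool$healthy, 12)
  for (p in pool$tumor) expect_gt(sum(p$label_crop), 0)
  for (p in pool$healthy) expect_equal(sum(p$label_crop), 0)
})

test_that("augmentation preserves the label class and composes to identity", {
  ph <- tiny_phantom(seed = 17)
  img <- scale_intensity(ph$image)
  idx <- index_patches(img, ph$gt, plan_grid(64, 64, 16, 8))
  pool <- materialize_pool(balance_pool(idx, per_class_target = 4, seed = 3))
  p <- pool$tumor[[1]]

  # probability 0 disables everything
  expect_identical(augment(p, prob = 0), p)

  # with prob 1 and rotation 0, the spatial transform is hflip . vflip;
  # applying it twice restores the label exactly, and blur/gamma leave the
  # label untouched, so foreground count is invariant throughout
  n0 <- sum(p$label_crop)
  a1 <- augment(p, prob = 1, rotation_deg = 0)
  expect_equal(sum(a1$label_crop), n0)
  a2 <- augment(a1, prob = 1, rotation_deg = 0)
  expect_identical(a2$label_crop, p$label_crop)

  # full augmentation never flips the class
  set.seed(99)
  for (k in 1:10) {
    aug <- augment(p, prob = 0.8)
    expect_gt(sum(aug$label_crop), 0)
    h <- augment(pool$healthy[[1]], prob = 0.8)
    expect_equal(sum(h$label_crop), 0)
  }
})

test_that("network output matches the input patch geometry", {
  spec <- unet_spec(in_channels = 5, depth = 4, base_filters = 4,
                    patch_size = 128)
  m <- build_unet(spec, seed = 2)
  x <- array(runif(128 * 128 * 5), c(128, 128, 5, 1))
  p <- unet_predict(m, x)
  expect_identical(dim(p), c(128L, 128L, 1L))
  expect_true(all(p >= 0 & p <= 1))

  # depth 4 on a 128 patch: bottleneck spatial size 8 x 8
  ns <- asNamespace("bmseg")
  fw <- ns$unet_forward(m, x, training = FALSE)
  expect_identical(dim(fw$cache$bott_c1$x)[1:2], c(8L, 8L))

  expect_error(unet_spec(5, 4, 8, 100), "divisible")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("bmseg")
  m <- build_unet(unet_spec(2, depth = 1, base_filters = 2, patch_size = 8),
                  seed = 4)
  set.seed(6)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  t <- array(as.numeric(runif(8 * 8 * 3) < 0.3), c(8, 8, 1, 3))
  lossfn <- function(model) {
    fw <- ns$unet_forward(model, x, training = TRUE)
    ns$unet_loss(fw$prob, t, "dice_bce")$loss
  }
  fw <- ns$unet_forward(m, x, training = TRUE)
  gr <- ns$unet_backward(m, fw$cache,
                         ns$unet_loss(fw$prob, t, "dice_bce")$glogit)
  for (nm in names(gr)) {
    g <- gr[[nm]]
    for (k in sample(length(g), min(3, length(g)))) {
      eps <- 1e-5
      mp <- m; mp$params[[nm]][k] <- mp$params[[nm]][k] + eps
      mm <- m; mm$params[[nm]][k] <- mm$params[[nm]][k] - eps
      gn <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_lt(abs(gn - g[k]) / max(1e-6, abs(gn) + abs(g[k])), 1e-4,
                label = paste("relative gradient error for", nm))
    }
  }
})

test_that("plateau schedule halves the LR every patience+1 stagnant epochs", {
  # monitored metric never improves after epoch 1
  lr <- lr_schedule(rep(1, 10), initial_lr = 1e-4, factor = 0.5,
                    patience = 2)
  expect_equal(lr, c(rep(1e-4, 4), rep(5e-5, 3), rep(2.5e-5, 3)))
  # strictly improving metric: LR never moves
  expect_equal(lr_schedule(seq(1, 0.1, length.out = 8)), rep(1e-4, 8))
})

test_that("the network can overfit a 10-patch pool (capacity sanity check)", {
  ns <- asNamespace("bmseg")
  ph <- tiny_phantom(seed = 7)
  img <- scale_intensity(ph$image)
  idx <- index_patches(img, ph$gt, plan_grid(64, 64, 32, 16))
  pool <- materialize_pool(balance_pool(idx, per_class_target = 5, seed = 1))
  m <- build_unet(unet_spec(5, depth = 2, base_filters = 4, patch_size = 32),
                  seed = 5)
  cfg <- train_config(initial_lr = 1e-2, max_epochs = 50, batch_size = 2,
                      augment_prob = 0, seed = 9)
  fit <- train_model(m, pool, cfg)
  b <- ns$stacks_to_batch(pool$tumor)
  d <- ns$soft_dice(unet_predict(fit$model, b$x), b$y[, , 1, ])
  expect_gt(d, 0.8)
  expect_lt(fit$history$train_loss[50], fit$history$train_loss[1] / 3)
})

test_that("training is bitwise reproducible given the seed", {
  ph <- tiny_phantom(seed = 23)
  img <- scale_intensity(ph$image)
  idx <- index_patches(img, ph$gt, plan_grid(64, 64, 16, 8))
  pool <- materialize_pool(balance_pool(idx, per_class_target = 6, seed = 2))
  run <- function() {
    m <- build_unet(unet_spec(5, depth = 2, base_filters = 2,
                              patch_size = 16), seed = 11)
    train_model(m, pool, train_config(max_epochs = 3, lr_patience = 1,
                                      batch_size = 4, seed = 31))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- build_unet(unet_spec(5, 2, 2, 16), seed = 1)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf, config = train_config())
  m2 <- load_model(tf)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(side$spec$patch_size, 16)
  expect_equal(side$config$initial_lr, 1e-4)
})
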