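test_that("trainable-parameter counts reproduce the reference totals", {
  counts <- c(unet = 32521250, resunet = 33435410,
              deeplabv3 = 39633986, unetpp = 48985890)
  for (arch in names(counts)) {
    m <- build_model(arch, seed = 1)
    expect_equal(count_trainable_params(m), unname(counts[arch]),
                 label = paste(arch, "params"))
    rm(m); gc(FALSE)
  }
})

test_that("counts are seed-independent and reflect the head size", {
  expect_equal(count_trainable_params(build_model("unet", seed = 1)),
               count_trainable_params(build_model("unet", seed = 99)))
  # a single-logit sigmoid head drops exactly one 3x3x16 filter plus bias
  expect_equal(count_trainable_params(build_model("unet", out_channels = 1L)),
               32521250 - (16 * 9 + 1))
})

test_that("initialization is deterministic under seed", {
  m1 <- build_model("resunet", seed = 5)
  m2 <- build_model("resunet", seed = 5)
  m3 <- build_model("resunet", seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params[["stem.conv.W"]], m3$params[["stem.conv.W"]]))
})

test_that("networks map (H, W) images to same-size probability maps", {
  m <- build_model("resunet", seed = 1)
  img <- matrix(runif(64 * 64), 64, 64)
  p <- predict_prob(m, img)
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_prob(m, matrix(0, 50, 64)), "divisible by 32")
})

test_that("binarization threshold uses the >= convention", {
  model <- tiny_model()
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict_prob(model, img)
  m1 <- predict_mask(model, img, threshold = min(p))
  expect_true(all(m1 == 1))  # every pixel >= min
  m0 <- predict_mask(model, img, threshold = max(p) + 1e-12)
  expect_true(all(m0 == 0))
  expect_error(predict_mask(model, img, threshold = 0), "0, 1")
})

test_that("augmentation yields exactly 4n pairs with faithful transforms", {
  set.seed(2)
  imgs <- replicate(3, matrix(runif(24 * 24), 24, 24), simplify = FALSE)
  msks <- replicate(3, {
    m <- matrix(0, 24, 24); m[5:14, 8:15] <- 1; m
  }, simplify = FALSE)
  aug <- augment_training_set(imgs, msks)
  expect_length(aug$images, 12)
  expect_length(aug$masks, 12)
  expect_equal(as.vector(table(aug$origin$transform)), rep(3, 4))

  # flips preserve pixel counts exactly and are involutions
  expect_equal(sum(aug$masks[[3]]), sum(msks[[1]]))
  expect_equal(sum(aug$masks[[4]]), sum(msks[[1]]))
  expect_identical(sacmetry:::flip_h(sacmetry:::flip_h(imgs[[1]])), imgs[[1]])
  expect_identical(sacmetry:::flip_v(sacmetry:::flip_v(imgs[[1]])), imgs[[1]])
  # nearest-neighbor rotation keeps the mask binary and roughly area-preserving
  rot <- aug$masks[[2]]
  expect_setequal(unique(as.vector(rot)), c(0L, 1L))
  expect_equal(sum(rot), sum(msks[[1]]), tolerance = 0.1)
  expect_error(augment_training_set(imgs, msks[1:2]), "equal length")
})

test_that("fold assignment is a stratified partition", {
  fs <- make_folds(500, k = 5, seed = 1)
  sizes <- table(fs$assignments$fold)
  expect_equal(as.vector(sizes), rep(100, 5))
  for (i in 1:5) {
    it <- fold_iteration(fs, i)
    expect_length(it$train, 400)
    expect_length(it$test, 100)
    expect_length(intersect(it$train, it$test), 0)
  }
  # held-out folds cover every item exactly once
  all_test <- unlist(lapply(1:5, function(i) fold_iteration(fs, i)$test))
  expect_setequal(all_test, 1:500)
  expect_equal(anyDuplicated(all_test), 0)

  # perfect stratification of a balanced two-class set
  fs2 <- make_folds(10, k = 5, labels = rep(c("normal", "abnormal"), each = 5),
                    seed = 2)
  tab <- table(fs2$assignments$fold, fs2$assignments$label)
  expect_true(all(tab == 1))

  # class fractions stay within one item of the global fraction
  labs <- rep(c("a", "b"), c(274, 226))
  fs3 <- make_folds(500, k = 5, labels = labs, seed = 3)
  tab3 <- table(fs3$assignments$fold, fs3$assignments$label)
  expect_lte(max(tab3[, "a"]) - min(tab3[, "a"]), 1)
  expect_lte(max(tab3[, "b"]) - min(tab3[, "b"]), 1)

  expect_error(make_folds(3, k = 5), "at least k")
})

test_that("fold assignment is reproducible under seed", {
  expect_identical(make_folds(100, seed = 7)$assignments,
                   make_folds(100, seed = 7)$assignments)
  expect_false(identical(make_folds(100, seed = 7)$assignments$fold,
                         make_folds(100, seed = 8)$assignments$fold))
})

test_that("short training on separable data reduces the loss", {
  dat <- smoke_training_set(4, size = 64L, seed = 31)
  m <- build_model("resunet", seed = 1)
  tr <- train(m, dat$images, dat$masks,
              train_config(loss = "dl", max_epochs = 2, batch_size = 2, seed = 1))
  expect_equal(nrow(tr$history), 2)
  expect_lt(tr$history$train_loss[2], tr$history$train_loss[1])
})

test_that("training is deterministic and respects the epoch cap", {
  dat <- smoke_training_set(2, size = 64L, seed = 32)
  m <- build_model("resunet", seed = 2)
  t1 <- train(m, dat$images, dat$masks,
              train_config(loss = "dl", max_epochs = 1, seed = 3))
  t2 <- train(m, dat$images, dat$masks,
              train_config(loss = "dl", max_epochs = 1, seed = 3))
  expect_equal(nrow(t1$history), 1)
  expect_identical(t1$history$train_loss, t2$history$train_loss)
  expect_error(train(m, list(), list(), train_config()), "empty")
})
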