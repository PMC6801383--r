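# A tiny synthetic image set with a purely local color cue: images of one
# class contain a small green patch at a random location. Built directly as
# pixel arrays so classifier tests do not depend on the renderer.
make_patch_images <- function(n, size = 16L, seed = 1L) {
  set.seed(seed)
  tmp <- withr::local_tempdir(.local_envir = parent.frame())
  x <- matrix(stats::runif(n * size * size * 3, 0.8, 1.0), n)
  label <- rep(c("active", "inactive"), length.out = n)
  d <- size * size
  for (k in which(label == "active")) {
    ci <- sample(2:(size - 1), 1); cj <- sample(2:(size - 1), 1)
    for (di in -1:1) for (dj in -1:1) {
      px <- (cj + dj - 1) * size + (ci + di)
      x[k, px] <- 0.1          # red channel low
      x[k, d + px] <- 0.9      # green high
      x[k, 2 * d + px] <- 0.1  # blue low
    }
  }
  list(x = x, mol_id = sprintf("im%03d", seq_len(n)),
       rotation = data.frame(rx = 0, ry = 0, rz = 0)[rep(1, n), ],
       label = label)
}

test_that("the reference network learns a separable local-color image set", {
  tr <- make_patch_images(60, seed = 11)
  va <- make_patch_images(30, seed = 12)
  cfg <- training_config(lr = 0.05, bs = 16, epochs = 30, seed = 5,
                         input_size = 16)
  m <- train_image_classifier(tr, va, cfg)
  expect_equal(nrow(m$history), 30L)
  expect_true(all(c("loss_tra", "loss_val", "acc_val") %in%
                    names(m$history)))
  expect_gt(utils::tail(m$history$acc_val, 1), 0.9)
  # prediction contract
  p <- predict_images(m, va)
  expect_equal(nrow(p), 30L)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  # duplicate images get identical probabilities (pure function)
  va2 <- va
  va2$x <- va$x[c(1, 1, 2), , drop = FALSE]
  va2$mol_id <- va$mol_id[c(1, 1, 2)]
  va2$rotation <- va$rotation[c(1, 1, 2), ]
  p2 <- predict_images(m, va2)
  expect_equal(p2$probability[1], p2$probability[2])
})

test_that("training is deterministic under a fixed seed", {
  tr <- make_patch_images(20, seed = 21)
  va <- make_patch_images(10, seed = 22)
  cfg <- training_config(lr = 0.05, bs = 8, epochs = 3, seed = 9,
                         input_size = 16)
  m1 <- train_image_classifier(tr, va, cfg)
  m2 <- train_image_classifier(tr, va, cfg)
  expect_identical(m1$net$W1, m2$net$W1)
  expect_identical(m1$history, m2$history)
})

test_that("classifier contract rejects bad inputs", {
  tr <- make_patch_images(10, seed = 31)
  va <- make_patch_images(6, seed = 32)
  # single-class training set
  tr1 <- tr; tr1$label <- rep("active", 10)
  expect_error(train_image_classifier(tr1, va,
                 training_config(input_size = 16)), "single class")
  # epochs = 0: untrained model, empty history
  m0 <- train_image_classifier(tr, va,
          training_config(epochs = 0, input_size = 16))
  expect_equal(nrow(m0$history), 0L)
  # image size mismatch at prediction
  big <- make_patch_images(4, size = 32L, seed = 33)
  expect_error(predict_images(m0, big), "size mismatch")
  # empty image list -> empty table
  empty <- list(x = matrix(numeric(0), 0, 16 * 16 * 3),
                mol_id = character(0),
                rotation = data.frame(), label = character(0))
  expect_equal(nrow(predict_images(m0, empty)), 0L)
})

test_that("the external-architecture hook is honoured", {
  tr <- make_patch_images(10, seed = 41)
  va <- make_patch_images(6, seed = 42)
  cfg <- training_config(arch = "external", input_size = 16,
    train_fn = function(train, val, config) list(mean = mean(train$x)),
    predict_fn = function(model, images) rep(0.5, nrow(images$x)))
  m <- train_image_classifier(tr, va, cfg)
  expect_equal(m$arch, "external")
  p <- predict_images(m, va)
  expect_true(all(p$probability == 0.5))
})

test_that("descriptor tables are deterministic, wide and imputed", {
  smiles <- c("CCO", "c1ccccc1", "CC(=O)O", "CCN", "Clc1ccccc1", "CCCC")
  d1 <- compute_descriptors(smiles)
  d2 <- compute_descriptors(smiles)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 6L)
  expect_gt(ncol(d1), 500)        # physchem block + fingerprint bits
  expect_true(all(is.finite(d1)))
  # same molecule twice -> identical rows
  dd <- compute_descriptors(c("CCO", "CCO"), c("a", "b"))
  expect_equal(unname(dd["a", ]), unname(dd["b", ]))
  # failures reported, rows dropped
  dbad <- compute_descriptors(c("CCO", "xx(("), c("ok", "bad"))
  expect_equal(rownames(dbad), "ok")
  expect_equal(attr(dbad, "dropped"), "bad")
  # empty input
  d0 <- compute_descriptors(character(0))
  expect_equal(nrow(d0), 0L)
})

test_that("tree baselines separate a separable table and accept the grid", {
  set.seed(61)
  n <- 60
  x <- matrix(stats::rnorm(n * 20), n, 20)
  y <- ifelse(x[, 1] + x[, 2] > 0, "active", "inactive")
  x[, 1] <- x[, 1] + 2 * (y == "active")   # make it clearly separable
  colnames(x) <- paste0("f", 1:20)
  for (cfg in list(baseline_config("rf", 20, 200, 10, seed = 5),
                   baseline_config("xgb", 3, 200, 10, seed = 5))) {
    res <- train_tree_baseline(x, y, cfg, n_repeats = 3)
    expect_length(res$aucs, 3L)
    expect_gt(res$mean, 0.9)
    expect_true(is.finite(res$sd))
  }
  # every grid row of the published baseline table is accepted
  grid <- rbind(
    c(3, 100, 29), c(3, 500, 29), c(3, 1000, 29), c(30, 1000, 29),
    c(2, 10, 29), c(20, 1000, 120), c(200, 1000, 29), c(20, 1000, 250))
  for (r in seq_len(nrow(grid)))
    expect_s3_class(baseline_config("xgb", grid[r, 1], grid[r, 2],
                                    grid[r, 3]), "baseline_config")
  # permuted labels land near chance
  yp <- permute_labels(y, seed = 8)
  resp <- train_tree_baseline(x, yp, baseline_config("rf", 20, 200, 10,
                                                     seed = 5),
                              n_repeats = 3)
  expect_gt(resp$mean, 0.25)
  expect_lt(resp$mean, 0.75)
})

test_that("baseline rejects degenerate inputs and redraws bad splits", {
  x <- matrix(stats::rnorm(40), 10, 4)
  expect_error(train_tree_baseline(x, rep("active", 10),
                                   baseline_config("rf")), "single class")
  expect_error(train_tree_baseline(x[1:3, ], c("active", "inactive",
                                               "active"),
                                   baseline_config("rf")), "at least 4")
  # imbalanced labels force occasional single-class halves; the redraw
  # mechanism must still deliver all repeats
  y <- c("active", "active", rep("inactive", 8))
  res <- train_tree_baseline(x, y, baseline_config("rf", 5, 50, 2,
                                                   seed = 1),
                             n_repeats = 3)
  expect_length(res$aucs, 3L)
  # a lone active can never appear in both halves: clean error, no hang
  expect_error(train_tree_baseline(x, c("active", rep("inactive", 9)),
                                   baseline_config("rf", 5, 50, 2),
                                   n_repeats = 2),
               "two-class")
})
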