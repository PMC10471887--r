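test_that("stratified folds partition scenes with balanced class counts", {
  man <- tiny_manifest(142, 738, n_partial = 690)
  cfg <- train_config(n_folds = 5, seed = 9)
  folds <- make_folds(man, cfg)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, man$samples$scene_id)
  expect_equal(length(all_test), 880)        # pairwise disjoint partition
  lab <- setNames(man$samples$label, man$samples$scene_id)
  ben <- vapply(folds, function(f) sum(lab[f$test] == "benign"), 0L)
  mal <- vapply(folds, function(f) sum(lab[f$test] == "malignant"), 0L)
  expect_equal(sum(ben), 142)
  expect_equal(sum(mal), 738)
  expect_true(all(ben %in% c(28L, 29L)))     # within one of 142/5
  expect_true(all(mal %in% c(147L, 148L)))
  for (f in folds) expect_length(intersect(f$train, f$test), 0)
})

test_that("two samples per class over two folds split one apiece", {
  man <- tiny_manifest(2, 2)
  folds <- make_folds(man, train_config(n_folds = 2, seed = 1))
  lab <- setNames(man$samples$label, man$samples$scene_id)
  for (f in folds) {
    expect_equal(sum(lab[f$test] == "benign"), 1)
    expect_equal(sum(lab[f$test] == "malignant"), 1)
  }
})

test_that("undersized classes and empty manifests are rejected", {
  expect_error(make_folds(tiny_manifest(2, 8),
                          train_config(n_folds = 4, seed = 1)),
               class = "fusenet_class_too_small")
  expect_error(make_folds(build_manifest(synth_config(0, 0, 0)),
                          train_config()),
               class = "fusenet_data_error")
})

test_that("patient grouping never splits a patient across folds", {
  man <- build_manifest(synth_config(
    n_no_cancer = 12, n_partial = 18, n_full = 6,
    image_height = 32, image_width = 32,
    n_patients = c(no_cancer = 4, partial_cancer = 6, full_cancer = 2),
    seed = 3))
  folds <- make_folds(man, train_config(n_folds = 2, seed = 3,
                                        grouping = "patient"))
  pat <- setNames(man$samples$patient_id, man$samples$scene_id)
  for (f in folds) {
    expect_length(intersect(unique(pat[f$test]), unique(pat[f$train])), 0)
  }
})

test_that("fold assignment is deterministic in the seed", {
  man <- tiny_manifest(20, 30)
  f1 <- make_folds(man, train_config(n_folds = 5, seed = 42))
  f2 <- make_folds(man, train_config(n_folds = 5, seed = 42))
  f3 <- make_folds(man, train_config(n_folds = 5, seed = 43))
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("a zero learning rate freezes the weights bit for bit", {
  g <- build_dcfcnn(arch_config())
  m <- init_model(g, seed = 8)
  set.seed(12)
  x <- array(rnorm(3 * 32 * 32 * 6), c(3, 32, 32, 6))
  y <- rep(c(1L, 2L), 3)
  # one batch per epoch: with minibatches, frozen weights can still yield
  # varying epoch accuracies through batch-normalization batch statistics
  res <- train_model(m, x, y, train_config(learning_rate = 0, epochs = 3,
                                           batch_size = 6, seed = 2))
  expect_identical(res$final_model$params, m$params)
  # constant accuracy history; earliest epoch wins the tie-break
  expect_equal(length(unique(res$history$accuracy)), 1)
  expect_equal(res$best_epoch, 1)
})

test_that("training is deterministic and its loss decreases on easy data", {
  cfg <- synth_config(n_no_cancer = 6, n_partial = 6, n_full = 0,
                      image_height = 32, image_width = 32,
                      separability = 1, seed = 77)
  man <- build_manifest(cfg)
  pre <- preprocess_config(short_edge = 32, crop_size = 32)
  imgs <- lapply(man$samples$scene_id,
                 function(id) preprocess(load_scene(man, id)$pixels, pre))
  x <- as_batch(imgs)
  y <- ifelse(man$samples$label == "malignant", 2L, 1L)
  tcfg <- train_config(epochs = 4, batch_size = 6, seed = 5)
  r1 <- train_model(init_model(build_dcfcnn(arch_config()), seed = 4),
                    x, y, tcfg)
  r2 <- train_model(init_model(build_dcfcnn(arch_config()), seed = 4),
                    x, y, tcfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  expect_lt(r1$history$loss[4], r1$history$loss[1])
})
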