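test_that("label merge maps cancer-bearing categories to malignant", {
  expect_identical(merge_labels("no_cancer"), "benign")
  expect_identical(merge_labels(c("partial_cancer", "full_cancer")),
                   c("malignant", "malignant"))
  expect_error(merge_labels("necrosis"), class = "fusenet_invalid_category")
})

test_that("scene generation is byte-deterministic under a fixed seed", {
  cfg <- synth_config(image_height = 48, image_width = 64)
  a <- generate_scene("no_cancer", cfg, seed = 7)
  b <- generate_scene("no_cancer", cfg, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(dim(a$pixels), c(48L, 64L, 3L))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  d <- generate_scene("no_cancer", cfg, seed = 8)
  expect_false(identical(a$pixels, d$pixels))
  expect_error(generate_scene("bad", cfg), class = "fusenet_invalid_category")
})

test_that("manifests honour composition, label counts and patient disjointness", {
  m <- tiny_manifest(3, 3, n_partial = 2)  # counts (no, partial, full) = (3, 2, 1)
  expect_equal(nrow(m$samples), 6)
  expect_equal(sum(m$samples$label == "malignant"), 3)
  expect_equal(sum(m$samples$label == "benign"), 3)
  expect_false(any(duplicated(m$samples$scene_id)))
  expect_true(all(nzchar(m$samples$patient_id)))
  # no patient straddles two categories
  tab <- table(m$samples$patient_id, m$samples$category)
  expect_true(all(rowSums(tab > 0) == 1))

  empty <- build_manifest(synth_config(0, 0, 0))
  expect_equal(nrow(empty$samples), 0)
  expect_true(all(empty$counts == 0))
})

test_that("manifest regeneration with one seed is fully reproducible", {
  m1 <- tiny_manifest(4, 5, seed = 11)
  m2 <- tiny_manifest(4, 5, seed = 11)
  expect_identical(m1$samples, m2$samples)
  s1 <- load_scene(m1, m1$samples$scene_id[2])
  s2 <- load_scene(m2, m2$samples$scene_id[2])
  expect_identical(s1$pixels, s2$pixels)
})

test_that("dataset written to disk reloads with identical pixels and bytes", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_no_cancer = 2, n_partial = 2, n_full = 1,
                      image_height = 32, image_width = 32, seed = 5)
  man <- simulate_dataset(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  reread <- read_manifest(file.path(dir, "manifest.csv"), cfg)
  expect_equal(nrow(reread$samples), 5)
  id <- man$samples$scene_id[1]
  from_png <- load_scene(man, id)$pixels
  regenerated <- generate_scene(man$samples$category[1], cfg,
                                seed = man$samples$seed[1])$pixels
  expect_identical(from_png, regenerated)
  # regeneration produces byte-identical files
  dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir2)
  f <- paste0(id, ".png")
  expect_identical(readBin(file.path(dir, "images", f), "raw", 1e6),
                   readBin(file.path(dir2, "images", f), "raw", 1e6))
})

test_that("full-cancer and no-cancer scenes separate by over 3 sd in green", {
  cfg <- synth_config(image_height = 48, image_width = 48, separability = 1.0)
  green_mean <- function(cat, i) {
    mean(generate_scene(cat, cfg, seed = 1000 + i)$pixels[, , 2])
  }
  g_full <- vapply(1:50, function(i) green_mean("full_cancer", i), 0)
  g_none <- vapply(1:50, function(i) green_mean("no_cancer", i + 50), 0)
  gap <- abs(mean(g_full) - mean(g_none))
  expect_gt(gap, 3 * max(sd(g_full), sd(g_none)))
})

test_that("at separability zero the class-conditional intensities coincide", {
  cfg <- synth_config(image_height = 48, image_width = 48, separability = 0)
  gm <- function(cat, i) mean(generate_scene(cat, cfg, seed = 2000 + i)$pixels)
  a <- vapply(1:30, function(i) gm("partial_cancer", i), 0)
  b <- vapply(1:30, function(i) gm("no_cancer", i + 30), 0)
  se <- sqrt(var(a) / 30 + var(b) / 30)
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("a one-feature threshold classifier tracks the separability dial", {
  run_auc <- function(sep) {
    cfg <- synth_config(image_height = 48, image_width = 48,
                        separability = sep)
    score <- c(vapply(1:100, function(i)
      -mean(generate_scene("partial_cancer", cfg, seed = 3000 + i)$pixels[, , 2]), 0),
      vapply(1:100, function(i)
        -mean(generate_scene("no_cancer", cfg, seed = 4000 + i)$pixels[, , 2]), 0))
    score <- (score - min(score)) / diff(range(score))
    truth <- rep(c("malignant", "benign"), each = 100)
    auc_roc(score, truth)
  }
  expect_gte(run_auc(1.0), 0.95)
  a0 <- run_auc(0.0)
  expect_gte(a0, 0.4)
  expect_lte(a0, 0.6)
})
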