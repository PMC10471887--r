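test_that("builder parameter counts match the independent closed-form oracle", {
  graphs <- list(
    res_plain = build_residual_structure(32, 32, FALSE),
    res_down = build_residual_structure(3, 32, TRUE),
    rs2 = build_rs_layer(2, 32, 64),
    rs5 = build_rs_layer(5, 256, 512),
    msf = build_msf(),
    mlf_same = build_mlf(64, 64),
    mlf_double = build_mlf(64, 128, feature_reuse = FALSE)
  )
  for (cfg in ablation_variants()) {
    graphs[[length(graphs) + 1]] <- build_dcfcnn(cfg)
  }
  for (n in c(1, 2, 4)) {
    graphs[[length(graphs) + 1]] <- build_dcfcnn(arch_config(n_mlf = n))
  }
  for (g in graphs) {
    expect_equal(count_trainable_params(g), oracle_param_count(g))
  }
})

test_that("unit-level parameter counts match hand-derived values", {
  # plain residual structure, 32 channels, convs bias-free + BN:
  # 2*(3*3*32*32) + 2*(2*32)
  expect_equal(count_trainable_params(build_residual_structure(32, 32)), 18560)
  # multiscale stem: 4 biased convs to 64 channels + 4 BN units
  expect_equal(count_trainable_params(build_msf()),
               (1 + 9 + 25 + 49) * 3 * 64 + 4 * 64 + 4 * 2 * 64)
  # the classification head's fully connected layer: 1024*2 + 2
  g <- build_dcfcnn(arch_config())
  fc <- g$nodes[["fc"]]
  expect_equal(fc$in_ch * fc$out_ch + fc$out_ch, 2050)
  # feature reuse rewires without adding parameters
  expect_equal(count_trainable_params(build_mlf(64, 128, TRUE)),
               count_trainable_params(build_mlf(64, 128, FALSE)))
  expect_equal(count_trainable_params(build_dcfcnn(arch_config())),
               count_trainable_params(
                 build_dcfcnn(arch_config(feature_reuse = FALSE))))
})

test_that("residual structures obey the declared shape contracts", {
  tr <- shape_trace(build_residual_structure(3, 32, TRUE), c(448, 448, 3))
  expect_equal(tr$output, "224x224x32")
  tr2 <- shape_trace(build_residual_structure(32, 32), c(224, 224, 32))
  expect_equal(tr2$input, tr2$output)
  expect_error(build_residual_structure(32, 64, FALSE),
               class = "fusenet_invalid_channels")
  # RS_5 stacks three structures (three shortcut additions)
  g5 <- build_rs_layer(5, 256, 512)
  expect_equal(sum(vapply(g5$nodes, function(n) n$op == "add", TRUE)), 3)
  g2 <- build_rs_layer(2, 32, 64)
  expect_equal(sum(vapply(g2$nodes, function(n) n$op == "add", TRUE)), 2)
  expect_equal(shape_trace(g2, c(224, 224, 32))$output, "112x112x64")
  # ablation stride keeps the first stage at full resolution
  g1 <- build_rs_layer(1, 3, 32, first_stride = 1)
  expect_equal(shape_trace(g1, c(448, 448, 3))$output, "448x448x32")
})

test_that("stem and multilevel blocks reproduce their table shapes", {
  expect_equal(shape_trace(build_msf(), c(448, 448, 3))$output, "224x224x64")
  expect_equal(shape_trace(build_msf(), c(336, 336, 3))$output, "168x168x64")
  expect_equal(shape_trace(build_mlf(64, 64), c(224, 224, 64))$output,
               "112x112x64")
  expect_equal(shape_trace(build_mlf(64, 128), c(112, 112, 64))$output,
               "56x56x128")
  expect_equal(shape_trace(build_mlf(64, 128, FALSE), c(112, 112, 64))$output,
               shape_trace(build_mlf(64, 128, TRUE), c(112, 112, 64))$output)
  expect_error(build_mlf(64, 96), class = "fusenet_invalid_channels")
})

test_that("channel-branch fusion is feasible at every depth", {
  for (n in 1:4) {
    g <- build_dcfcnn(arch_config(n_mlf = n))
    tr <- shape_trace(g, c(448, 448, 3))     # raises on any fusion mismatch
    expect_equal(tr$output[tr$module == "Fully connect"], "1x2")
    mlf_out <- tr$output[tr$module == sprintf("MLF_%d", n)]
    rs_out <- tr$output[tr$module == sprintf("RS_%d", n + 1)]
    expect_equal(mlf_out, rs_out)
  }
})

test_that("misconfigured branch shapes are rejected with both shapes named", {
  bad <- arch_config(use_msf = FALSE, rs1_first_stride = 2)
  err <- expect_error(shape_trace(build_dcfcnn(bad), c(448, 448, 3)),
                      class = "fusenet_shape_mismatch")
  expect_match(conditionMessage(err), "\\d+x\\d+x\\d+.*\\d+x\\d+x\\d+")
})

test_that("ablation variants drop parameters but keep the head output", {
  full <- count_trainable_params(build_dcfcnn(arch_config()))
  spatial <- count_trainable_params(
    build_dcfcnn(arch_config(use_channel_branch = FALSE)))
  no_msf <- count_trainable_params(build_dcfcnn(arch_config(use_msf = FALSE)))
  expect_lt(spatial, full)
  expect_lt(no_msf, full)
  for (cfg in ablation_variants()) {
    tr <- shape_trace(build_dcfcnn(cfg), c(64, 64, 3))
    expect_equal(tr$output[tr$module == "Fully connect"], "1x2")
  }
})

test_that("forward passes at initialization are finite for every variant", {
  set.seed(99)
  x <- array(rnorm(3 * 32 * 32 * 4), c(3, 32, 32, 4))
  for (cfg in ablation_variants()) {
    m <- init_model(build_dcfcnn(cfg), seed = 21)
    out_tr <- fusenet:::nn_forward(m, x, train = TRUE)$out
    out_ev <- fusenet:::nn_forward(m, x, train = FALSE)$out
    expect_true(all(is.finite(out_tr)))
    expect_true(all(is.finite(out_ev)))
    expect_identical(dim(out_tr), c(2L, 4L))
  }
})

test_that("doubling the input side doubles every spatial extent in the trace", {
  g <- build_dcfcnn(arch_config())
  t1 <- shape_trace(g, c(448, 448, 3))
  t2 <- shape_trace(g, c(896, 896, 3))
  parse_dims <- function(s) as.integer(strsplit(s, "x")[[1]])
  for (i in seq_len(nrow(t1))) {
    a <- parse_dims(t1$output[i]); b <- parse_dims(t2$output[i])
    if (length(a) == 3) {
      expect_identical(b, c(2L * a[1], 2L * a[2], a[3]))
    } else {
      expect_identical(a, b)  # flattened head shapes are size-independent
    }
  }
})
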