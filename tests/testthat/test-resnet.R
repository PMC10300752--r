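toy_cfg <- function(...) {
  resnet_config("stage1_k5", blocks_per_stage = 1, ...)
}

test_that("stage output lengths follow the architecture table", {
  sh <- resnet_shapes(resnet_config("stage1_k5"))
  expect_identical(sh[["stage0"]], 64L)
  expect_identical(sh[["stage1"]], 32L)
  expect_identical(sh[["stage2"]], 32L)
  expect_identical(sh[["stage3"]], 16L)
  expect_identical(sh[["stage4"]], 8L)
  expect_identical(sh[["features"]], 256L)
  sh3 <- resnet_shapes(resnet_config("stage1_k3"))
  expect_identical(unname(sh3), unname(sh))
  shds <- resnet_shapes(resnet_config("ds"))
  expect_identical(shds[["stage0"]], 32L)
  expect_identical(shds[["stage4"]], 8L)
  expect_identical(shds[["features"]], 256L)
})

test_that("runtime forward-pass lengths match the declared shapes", {
  model <- build_resnet(resnet_config("stage1_k5"), seed = 1)
  x <- array(rnorm(2 * 1 * 64), c(2, 1, 64))
  fwd <- nirsnet:::forward_net(model, nirsnet:::windows_to_matrix(x), 2)
  expect_identical(fwd$stage_lengths[["stage1"]], 32L)
  expect_identical(fwd$stage_lengths[["stage2"]], 32L)
  expect_identical(fwd$stage_lengths[["stage3"]], 16L)
  expect_identical(fwd$stage_lengths[["stage4"]], 8L)
  expect_identical(fwd$pooled_dim, 256L)
})

test_that("weighted layer counts match the conv + fc convention", {
  expect_identical(count_weighted_layers(resnet_config("stage1_k5")), 113L)
  expect_identical(count_weighted_layers(resnet_config("stage1_k3")), 113L)
  expect_identical(count_weighted_layers(resnet_config("ds")), 110L)
  expect_identical(count_weighted_layers(toy_cfg()), 14L)
})

test_that("parameter totals agree with the independent closed-form ledger", {
  for (variant in c("stage1_k5", "stage1_k3", "ds")) {
    led <- ledger_counts(variant)
    expect_identical(count_parameters(resnet_config(variant)),
                     led$params, info = variant)
  }
  led_toy <- ledger_counts("stage1_k5", blocks = 1L)
  expect_identical(count_parameters(toy_cfg()), led_toy$params)
})

test_that("individual layer contributions are as expected", {
  acc <- layer_account(resnet_config("stage1_k5"))
  rows <- acc$layers
  # classifier: 256 x 3 weights + 3 biases
  expect_identical(rows$params[rows$layer == "fc"], 771L)
  # stem: kernel 5, 1 -> 16 channels, no bias
  expect_identical(rows$params[rows$stage == "stage0"], 80L)
  # classifier FLOPs 2 x 256 x 3; stem FLOPs 2 x 5 x 1 x 16 x 64
  expect_identical(rows$flops[rows$layer == "fc"], 1536)
  expect_identical(rows$flops[rows$stage == "stage0"], 10240)
})

test_that("FLOP totals agree with the ledger and the shortcut convention", {
  for (variant in c("stage1_k5", "ds")) {
    led <- ledger_counts(variant)
    expect_identical(count_flops(resnet_config(variant)), led$flops,
                     info = variant)
  }
  cfg <- resnet_config("stage1_k5")
  # including projections adds their 2*Cin*Cout*Lout terms
  extra <- 2 * (16 * 16 * 32 + 16 * 64 * 32 + 64 * 128 * 16 + 128 * 256 * 8)
  expect_identical(count_flops(cfg, include_shortcuts = TRUE),
                   count_flops(cfg) + extra)
})

test_that("headline totals round to the published 0.7 M / 15 M figures", {
  cfg <- resnet_config("stage1_k5")
  expect_equal(round(count_parameters(cfg) / 1e6, 1), 0.7)
  expect_equal(round(count_flops(cfg) / 1e6), 15)
  dscfg <- resnet_config("ds")
  expect_equal(round(count_parameters(dscfg) / 1e6, 1), 0.7)
  expect_equal(round(count_flops(dscfg) / 1e6), 15)
})

test_that("an identity-shortcut unit with zeroed final conv is the identity", {
  cfg <- resnet_config("stage1_k5", input_length = 16,
                       blocks_per_stage = 2, base_width = 4)
  model <- build_resnet(cfg, seed = 7)
  # unit 4 is the second Stage-2 unit: identity shortcut
  unit <- model$units[[4]]
  expect_null(unit$proj)
  unit$convs[[3]]$W[] <- 0
  A <- matrix(rnorm(16 * 8 * 4), 16, 32)
  out <- nirsnet:::.unit_forward(unit, A, 8, 4, FALSE, FALSE)$out
  expect_identical(out, A)
})

test_that("ties in the logits resolve to the lowest class index", {
  cfg <- toy_cfg(input_length = 16, base_width = 4)
  model <- build_resnet(cfg, seed = 3)
  model$fc$W[] <- 0
  model$fc$b[] <- 0
  x <- array(rnorm(5 * 1 * 16), c(5, 1, 16))
  Z <- resnet_logits(model, x)
  expect_identical(dim(Z), c(5L, 3L))
  expect_true(all(Z == Z[, 1]))
  expect_identical(predict_class_index(Z), rep(1L, 5))
})

test_that("logits are finite, batch-shaped and deterministic in inference", {
  cfg <- toy_cfg(input_length = 16, base_width = 4)
  model <- build_resnet(cfg, seed = 3)
  x <- array(rnorm(7 * 1 * 16), c(7, 1, 16))
  Z1 <- resnet_logits(model, x)
  Z2 <- resnet_logits(model, x)
  expect_identical(Z1, Z2)
  expect_true(all(is.finite(Z1)))
  expect_identical(dim(Z1), c(7L, 3L))
  # chunked evaluation agrees with one batch
  expect_equal(resnet_logits(model, x, batch_size = 3), Z1,
               tolerance = 1e-12)
})

test_that("seeded builds are reproducible", {
  cfg <- toy_cfg()
  a <- build_resnet(cfg, seed = 21)
  b <- build_resnet(cfg, seed = 21)
  expect_identical(a$units[[2]]$convs[[2]]$W, b$units[[2]]$convs[[2]]$W)
  expect_identical(a$fc$W, b$fc$W)
  d <- build_resnet(cfg, seed = 22)
  expect_false(identical(a$fc$W, d$fc$W))
})

test_that("shape mismatches and invalid configs are rejected", {
  cfg <- toy_cfg()
  model <- build_resnet(cfg, seed = 1)
  expect_error(resnet_logits(model, array(0, c(2, 2, 64))), "channel")
  expect_error(resnet_logits(model, array(0, c(2, 1, 32))), "length")
  expect_error(resnet_config("stage1_k5", input_length = 60), "divisible")
  expect_error(resnet_config("stage1_k5", blocks_per_stage = 0),
               "blocks_per_stage")
})

test_that("downsampling halves windows by subsampling or pair means", {
  x <- array(seq_len(2 * 1 * 8), c(2, 1, 8))
  sub <- downsample_windows(x)
  expect_identical(dim(sub), c(2L, 1L, 4L))
  expect_identical(sub[1, 1, ], x[1, 1, c(1, 3, 5, 7)])
  avg <- downsample_windows(x, "average")
  expect_identical(avg[1, 1, ], (x[1, 1, c(1, 3, 5, 7)] +
                                   x[1, 1, c(2, 4, 6, 8)]) / 2)
})
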