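test_that("fused dimension follows the block-width arithmetic", {
  expect_equal(fused_dimension(fusion_spec("vgg16", 1:5, "fusion1")), 1472L)
  expect_equal(fused_dimension(fusion_spec("vgg16", 4:5, "fusion1")), 1024L)
  expect_equal(fused_dimension(fusion_spec("vgg19", 1:5, "fusion1")), 1472L)
  expect_equal(fused_dimension(
    fusion_spec("vgg16", 1:5, "fusion2", bottleneck_channels = 64)), 320L)
  expect_equal(fused_dimension(tiny_model()$spec), 8 + 16 + 32 + 32 + 32)
})

test_that("spec validation rejects bad architectures", {
  expect_error(fusion_spec("tiny_test", integer(0)), "branches")
  expect_error(fusion_spec("tiny_test", c(0, 6)), "branches")
  expect_error(fusion_spec("resnet"), "arg")
  expect_error(fusion_spec("tiny_test", 1:5, "fusion2",
                           bottleneck_channels = 0), "bottleneck")
})

test_that("fusion2 fuses strictly fewer dimensions than fusion1 on VGG", {
  # the cross-channel bottleneck's dimensionality-reduction property: with
  # bottleneck below the narrowest VGG block width, every branch subset
  # shrinks
  for (bits in 1:31) {
    branches <- which(bitwAnd(bits, 2^(0:4)) > 0)
    d1 <- fused_dimension(fusion_spec("vgg16", branches, "fusion1"))
    d2 <- fused_dimension(fusion_spec("vgg16", branches, "fusion2",
                                      bottleneck_channels = 63))
    expect_lt(d2, d1)
  }
})

test_that("branch maps follow the 72 -> 36/18/9/4/2 spatial progression", {
  model <- tiny_model()
  x <- mammofuse:::as_patch_array(array(rnorm(72 * 72 * 2), c(72, 72, 2)), 72)
  maps <- mammofuse:::backbone_branch_maps(model, x)
  sides <- vapply(1:5, function(b) dim(maps[[as.character(b)]])[1], 0)
  expect_equal(sides, c(36, 18, 9, 4, 2))
  widths <- vapply(1:5, function(b) dim(maps[[as.character(b)]])[3], 0)
  expect_equal(widths, c(8, 16, 32, 32, 32))
})

test_that("parameter partition matches the frozen-backbone contract", {
  m1 <- tiny_model("fusion1")
  tn1 <- trainable_parameter_names(m1)
  expect_false(any(grepl("backbone", tn1)))
  expect_setequal(tn1, c("head.bn.gamma", "head.bn.beta", "head.fc1.W",
                         "head.fc1.b", "head.fc2.W", "head.fc2.b",
                         "head.out.W", "head.out.b"))
  m2 <- tiny_model("fusion2")
  tn2 <- trainable_parameter_names(m2)
  expect_equal(sum(grepl("conv1x1\\.W$", tn2)), 5L)
  expect_equal(sum(grepl("bn\\.gamma$", tn2)), 6L)  # 5 branches + head
  fr <- frozen_parameter_names(m2)
  expect_equal(sum(grepl("^backbone\\.block[1-5]\\.conv1\\.W$", fr)), 5L)
  # frozen and trainable partition the parameter space
  expect_length(intersect(tn2, fr), 0L)
})

test_that("patch probabilities are softmax rows, deterministic, shape checked", {
  model <- tiny_model("fusion2", seed = 3)
  set.seed(1)
  batch <- array(rnorm(72 * 72 * 4, sd = 20), c(72, 72, 4))
  p1 <- predict_patch_probs(model, batch)
  expect_equal(dim(p1), c(4L, 2L))
  expect_true(all(p1 >= 0))
  expect_equal(unname(rowSums(p1)), rep(1, 4), tolerance = 1e-5)
  expect_identical(p1, predict_patch_probs(model, batch))
  expect_equal(nrow(predict_patch_probs(model,
                                        array(0, c(72, 72, 0)))), 0L)
  expect_error(predict_patch_probs(model, array(0, c(64, 64, 2))),
               "spatial")
})

test_that("pretrained weights are a declared unavailable dependency", {
  spec <- fusion_spec("vgg16", 1:5, "fusion1", pretrained = TRUE)
  expect_error(build_model(spec), "pretrained")
})

test_that("model initialisation is seed deterministic", {
  a <- tiny_model("fusion2", seed = 42)
  b <- tiny_model("fusion2", seed = 42)
  expect_identical(a, b)
  c <- tiny_model("fusion2", seed = 43)
  expect_false(identical(a$params, c$params))
})
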