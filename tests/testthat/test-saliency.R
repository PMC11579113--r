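# Attribution methods: linear-model reductions, guided-ReLU gating, GradCAM
# hand cases, IG quadrature and completeness, GSHAP limits, normalization.

lin_w <- array(rnorm(4^3), c(4, 4, 4))
lin <- make_linear_model(lin_w)
lin_x <- array(rnorm(4^3), c(4, 4, 4))

test_that("linear model: G is the weight map, IXG and IG(0) the weighted input", {
  g <- gradient_saliency(lin, lin_x)
  expect_equal(array(g$data, dim(lin_w)), lin_w)
  ixg <- input_x_gradient(lin, lin_x)
  expect_equal(ixg$data, lin_w * lin_x)
  ig <- integrated_gradients(lin, lin_x, config = saliency_config(ig_points = 5))
  expect_equal(ig$data, lin_w * lin_x, tolerance = 1e-12)
  expect_equal(input_x_gradient(lin, array(0, c(4, 4, 4)))$data,
               array(0, c(4, 4, 4)))
})

test_that("masked gradient is gradient times mask, exactly zero outside", {
  m <- live_toy_model(seed = 13)
  x <- array(abs(rnorm(8^3)), c(8, 8, 8))
  g <- gradient_saliency(m, x)
  mask <- array(FALSE, c(8, 8, 8)); mask[1:200] <- TRUE
  mg <- masked_gradient(m, x, mask)
  expect_equal(mg$data[mask], g$data[mask])
  expect_true(all(mg$data[!mask] == 0))
  expect_equal(masked_gradient(m, x, array(TRUE, c(8, 8, 8)))$data, g$data)
  expect_true(all(masked_gradient(m, x, array(FALSE, c(8, 8, 8)))$data == 0))
  ixg <- input_x_gradient(m, x)
  expect_equal(ixg$data, g$data * x)
})

test_that("guided backprop equals the gradient when every backward signal is positive", {
  # all-positive scalar chain: no ReLU gates close, no negative signals
  m <- scalar_chain_model(conv_w = c(1.5, 0.5, 2, 1), conv_b = c(0, 0, 0, 0))
  x <- array(2, c(1, 1, 1))
  g <- gradient_saliency(m, x)
  gb <- guided_backprop(m, x)
  expect_equal(gb$data, g$data)
  expect_equal(as.vector(g$data), 1.5 * 0.5 * 2 * 1)
})

test_that("guided backprop zeroes a hand-built negative backward path that G keeps", {
  # f(x) = 10 - x for x in (0, 10): gradient -1, but the -1 signal entering
  # the first ReLU is negative, so guided backprop attributes 0
  m <- scalar_chain_model(conv_w = c(1, -1, 1, 1), conv_b = c(0, 10, 0, 0))
  x <- array(2, c(1, 1, 1))
  expect_equal(as.vector(predict_scalar(m, x)), 8)
  expect_equal(as.vector(gradient_saliency(m, x)$data), -1)
  expect_equal(as.vector(guided_backprop(m, x)$data), 0)
})

test_that("gradcam matches the hand computation on a single-channel layer", {
  # scalar chain: final-block activation a = 8, d(output)/d(a) = 1,
  # channel weight = spatial mean = 1, coarse map = relu(1 * 8) = 8
  m <- scalar_chain_model(conv_w = c(1, -1, 1, 1), conv_b = c(0, 10, 0, 0))
  x <- array(2, c(1, 1, 1))
  gc <- gradcam(m, x)
  expect_equal(as.vector(gc$data), 8)
  # negated output layer: d(output)/d(a) = -1 -> coarse map relu(-8) = 0
  m2 <- scalar_chain_model(conv_w = c(1, -1, 1, 1), conv_b = c(0, 10, 0, 0))
  last_dense <- max(which(vapply(m2$layers, function(l) l$type == "dense",
                                 logical(1))))
  m2$layers[[last_dense]]$w <- -m2$layers[[last_dense]]$w
  expect_equal(as.vector(gradcam(m2, x)$data), 0)
})

test_that("gradcam output has the input's shape and GGC is its product with GB", {
  m <- live_toy_model(seed = 14)
  x <- array(abs(rnorm(8^3)), c(8, 8, 8))
  gc <- gradcam(m, x)
  expect_identical(dim(gc$data), c(8L, 8L, 8L))
  expect_true(all(gc$data >= 0))
  ggc <- guided_gradcam(m, x)
  gb <- guided_backprop(m, x)
  expect_equal(ggc$data, gb$data * gc$data)
})

test_that("integrated gradients vanish at the baseline and satisfy completeness", {
  m <- live_toy_model(seed = 15)
  b <- array(rnorm(8^3), c(8, 8, 8))
  ig0 <- integrated_gradients(m, b, baseline = b)
  expect_true(all(abs(ig0$data) < 1e-12))

  for (s in 16:18) {
    mm <- live_toy_model(seed = s)
    set.seed(s)
    x <- array(rnorm(8^3), c(8, 8, 8))
    ig <- integrated_gradients(mm, x)
    gap <- predict_scalar(mm, x) - predict_scalar(mm, array(0, c(8, 8, 8)))
    expect_equal(sum(ig$data), gap, tolerance = 1e-3 * max(abs(gap), 1e-6))
  }
  expect_error(saliency_config(ig_points = 0), "ig_points")
})

test_that("gradient SHAP is seed-reproducible and converges to IXG for linear models", {
  cfg <- saliency_config(gshap_samples = 5, gshap_sigma = 0.05, seed = 42)
  m <- live_toy_model(seed = 19)
  x <- array(abs(rnorm(8^3)) + 0.5, c(8, 8, 8))
  a <- gradient_shap(m, x, config = cfg)
  b <- gradient_shap(m, x, config = cfg)
  expect_identical(a$data, b$data)
  cfg2 <- saliency_config(gshap_samples = 5, gshap_sigma = 0.05, seed = 43)
  expect_false(identical(a$data, gradient_shap(m, x, config = cfg2)$data))

  # linear model, single zero baseline, vanishing noise -> IXG
  cfg3 <- saliency_config(gshap_samples = 8, gshap_sigma = 1e-9, seed = 1)
  gs <- gradient_shap(lin, lin_x, config = cfg3)
  expect_equal(gs$data, lin_w * lin_x, tolerance = 1e-6)

  # input equal to the only baseline, vanishing noise -> zero attribution
  gs0 <- gradient_shap(lin, lin_x, baselines = list(lin_x), config = cfg3)
  expect_lt(max(abs(gs0$data)), 1e-6)
})

test_that("density normalization uses absolute values and rejects zero maps", {
  raw <- structure(list(data = array(c(1, -1, 2, 0, 0, 0, 0, 0), c(2, 2, 2)),
                        method = "G"), class = "vb_attribution")
  d <- normalize_to_density(raw)
  expect_equal(as.vector(d$density)[1:3], c(0.25, 0.25, 0.5))
  expect_equal(sum(d$density), 1)

  single <- structure(list(data = array(c(0, 0, -3, 0, 0, 0, 0, 0), c(2, 2, 2)),
                           method = "G"), class = "vb_attribution")
  expect_equal(max(normalize_to_density(single)$density), 1)

  const <- structure(list(data = array(2, c(2, 2, 2)), method = "G"),
                     class = "vb_attribution")
  expect_true(all(normalize_to_density(const)$density == 1 / 8))
  zero <- structure(list(data = array(0, c(2, 2, 2)), method = "G"),
                    class = "vb_attribution")
  expect_error(normalize_to_density(zero), "identically zero")
})

test_that("cohort averaging renormalizes the voxelwise mean", {
  d1 <- array(0, c(2, 2, 2)); d1[1] <- 1
  d2 <- array(0, c(2, 2, 2)); d2[8] <- 1
  s1 <- structure(list(density = d1, method = "G"), class = "vb_saliency")
  s2 <- structure(list(density = d2, method = "G"), class = "vb_saliency")
  expect_equal(cohort_average_map(list(s1))$density, d1)
  expect_equal(cohort_average_map(list(s1, s1))$density, d1)
  avg <- cohort_average_map(list(s1, s2))$density
  expect_equal(avg[1], 0.5)
  expect_equal(avg[8], 0.5)
})

test_that("every method returns the input shape and a normalizable map on a live model", {
  m <- live_toy_model(seed = 20)
  s <- generate_phantom(70, phantom_params(grid_size = 16,
                                           ventricle_base_radius = 1,
                                           ventricle_age_slope = 0.02),
                        seed = 5)
  x <- downsample(s$volume, 2)$data
  mask <- downsample(s$labels, 2)$data != 0
  cfg <- saliency_config(ig_points = 8, gshap_samples = 2, seed = 3)
  for (meth in c("G", "IXG", "MG", "GB", "GGC", "IG", "GSHAP")) {
    att <- compute_attribution(meth, m, x, mask = mask,
                               baselines = list(x * 0.9), config = cfg)
    expect_identical(dim(att$data), dim(x))
    if (sum(abs(att$data)) > 0) {
      expect_equal(sum(normalize_to_density(att)$density), 1, tolerance = 1e-9)
    }
  }
})

test_that("upsampling preserves constants and interpolates linearly between planes", {
  u <- upsample_trilinear(array(3, c(2, 2, 2)), c(8, 8, 8))
  expect_true(all(abs(u - 3) < 1e-12))
  ramp <- array(rep(c(0, 1), each = 1), c(2, 1, 1))
  up <- upsample_trilinear(ramp, c(4, 1, 1))
  expect_equal(as.vector(up), c(0, 0.25, 0.75, 1))
})
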