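test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom_pair(phantom_spec(seed = 42))
  b <- generate_phantom_pair(phantom_spec(seed = 42))
  expect_identical(a$reference$data, b$reference$data)
  expect_identical(a$floating$data, b$floating$data)
  expect_identical(a$truth_field$vectors, b$truth_field$vectors)
  c <- generate_phantom_pair(phantom_spec(seed = 43))
  expect_false(identical(a$floating$data, c$floating$data))
})

test_that("the truth field respects the amplitude bound", {
  for (amp in c(0.5, 2, 5)) {
    pair <- generate_phantom_pair(phantom_spec(seed = 7,
                                               deform_amplitude = amp))
    mag <- sqrt(rowSums(gmidemons:::.field_matrix(pair$truth_field)^2))
    expect_lte(max(mag), amp + 1e-9)
    expect_gt(max(mag), 0.9 * amp)  # rescaled to attain the bound
  }
})

test_that("the degenerate spec reduces to a pure intensity remap", {
  spec <- phantom_spec(seed = 1, deform_amplitude = 0, rigid_rotation = 0,
                       rigid_translation = c(0, 0), noise_sigma = 0,
                       lesion = FALSE)
  pair <- generate_phantom_pair(spec)
  expect_true(all(pair$truth_field$vectors == 0))
  remap <- function(x) 1 - abs(2 * x - 1)
  expect_equal(pair$floating$data, remap(pair$reference$data),
               tolerance = 1e-12)
})

test_that("the non-monotone remap breaks intensity ordering but not MI", {
  pair <- generate_phantom_pair(phantom_spec(seed = 3, deform_amplitude = 0,
                                             rigid_rotation = 0,
                                             rigid_translation = c(0, 0),
                                             noise_sigma = 0, lesion = FALSE))
  r <- as.vector(pair$reference$data)
  f <- as.vector(pair$floating$data)
  # the tent remap folds the upper intensities: the bright ring (r ~ 0.8)
  # maps below the mid-intensity organ (r ~ 0.55)
  organ <- abs(r - 0.55) < 0.05
  ring <- abs(r - 0.80) < 0.05
  expect_gt(mean(f[organ]), mean(f[ring]))
  jd <- estimate_joint_density(pair$reference, pair$floating, 0.05, 64)
  expect_gt(mutual_information(jd), 0.3)  # but strongly dependent
})

test_that("aligning with the truth raises MI above the misaligned state", {
  pair <- generate_phantom_pair(phantom_spec(seed = 5))
  aligned <- warp_image(apply_rigid(pair$floating, pair$truth_rigid),
                        pair$truth_field)
  mi_mis <- mutual_information(
    estimate_joint_density(pair$reference, pair$floating, 0.05, 64))
  mi_ali <- mutual_information(
    estimate_joint_density(pair$reference, aligned, 0.05, 64))
  expect_gt(mi_ali, mi_mis)
  expect_gt(mi_ali, 0)
})

test_that("endpoint error matches the double-loop oracle and edge cases", {
  set.seed(8)
  shape <- c(6, 5)
  a <- random_smooth_field(shape, rms = 1)
  b <- random_smooth_field(shape, rms = 1)
  ee <- endpoint_error(a, b)
  # brute-force oracle
  errs <- c()
  for (i in 1:6) for (j in 1:5) {
    errs <- c(errs, sqrt(sum((a$vectors[i, j, ] - b$vectors[i, j, ])^2)))
  }
  expect_equal(ee$mean, mean(errs))
  expect_equal(ee$max, max(errs))
  expect_equal(ee$n, 30)
  # identical fields: all zero
  z <- endpoint_error(a, a)
  expect_equal(z$mean, 0)
  expect_equal(z$max, 0)
  # uniform offset of (1, 0): mean error exactly 1
  shifted <- displacement_field(
    a$vectors + array(rep(c(1, 0), each = 30), dim = c(shape, 2)))
  expect_equal(endpoint_error(shifted, a)$mean, 1)
  # mask restriction and shape mismatch
  mask <- array(FALSE, dim = shape); mask[2, 2] <- TRUE
  expect_equal(endpoint_error(shifted, a, mask)$n, 1)
  expect_error(endpoint_error(a, zero_field(c(4, 4))), "grid")
})

test_that("3D phantoms generate with consistent geometry", {
  spec <- phantom_spec(shape = c(24, 24, 16), deform_amplitude = 2,
                       rigid_rotation = 0, rigid_translation = c(2, -1, 1),
                       seed = 9)
  pair <- generate_phantom_pair(spec)
  expect_equal(dim(pair$reference$data), c(24, 24, 16))
  expect_equal(dim(pair$truth_field$vectors), c(24, 24, 16, 3))
  expect_true(any(pair$body_mask))
})
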