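test_that("pyramids have the expected shapes and reduce degenerate depths", {
  img <- scalar_image(matrix(runif(64 * 64), 64, 64))
  pyr <- build_pyramid(img, n_levels = 3, factor = 2)
  expect_equal(lapply(pyr$levels, function(l) dim(l$data)),
               list(c(16L, 16L), c(32L, 32L), c(64L, 64L)))
  expect_equal(pyr$levels[[2]]$spacing, c(2, 2))
  # n_levels = 1: original image only
  pyr1 <- build_pyramid(img, n_levels = 1)
  expect_identical(pyr1$levels[[1]]$data, img$data)
  # constant images stay constant at every level
  pyrc <- build_pyramid(scalar_image(matrix(0.4, 32, 32)), 2)
  for (l in pyrc$levels) expect_equal(unique(as.vector(l$data)), 0.4)
  # depth auto-reduction keeps >= 8 voxels per axis
  expect_warning(pyr_s <- build_pyramid(scalar_image(matrix(runif(256), 16, 16)),
                                        n_levels = 4),
                 "reduced")
  expect_equal(pyr_s$n_levels, 2L)
})

test_that("field upsampling rescales components and preserves constants", {
  z <- upsample_field(zero_field(c(8, 8)), c(16, 16), 2)
  expect_true(all(z$vectors == 0))
  expect_equal(field_shape(z), c(16L, 16L))
  # uniform v = (1, 0) doubles to (2, 0)
  fv <- array(0, dim = c(8, 8, 2)); fv[, , 1] <- 1
  up <- upsample_field(displacement_field(fv), c(16, 16), 2)
  expect_equal(unique(as.vector(up$vectors[, , 1])), 2)
  expect_equal(unique(as.vector(up$vectors[, , 2])), 0)
  expect_error(upsample_field(displacement_field(fv), c(20, 16), 2),
               "refinement")
})

test_that("with alpha = 0 the MI-augmented iteration is bit-identical to classic", {
  set.seed(14)
  for (rep in 1:3) {
    r <- smooth_textured_image(c(16, 16))
    f <- smooth_textured_image(c(16, 16))
    v <- random_smooth_field(c(16, 16), rms = 0.8)
    cfg <- registration_config(alpha = 0, sigma = runif(1, 0, 1.5))
    a <- gmi_demons_iteration(v, r, f, cfg)
    b <- demons_iteration(v, r, f, cfg)
    expect_identical(a$vectors, b$vectors)
  }
})

test_that("with alpha > 0 the MI force changes the update", {
  set.seed(15)
  r <- smooth_textured_image(c(16, 16))
  f <- smooth_textured_image(c(16, 16))
  v <- random_smooth_field(c(16, 16), rms = 0.5)
  a <- gmi_demons_iteration(v, r, f, registration_config(alpha = 0.3))
  b <- demons_iteration(v, r, f, registration_config(alpha = 0.3))
  expect_false(identical(a$vectors, b$vectors))
  expect_true(is.finite(attr(a, "mi_value")))
})

test_that("registering an image with itself yields a near-zero field", {
  img <- generate_phantom_pair(phantom_spec(seed = 16))$reference
  res <- register(img, img, registration_config(max_iters_per_level = 20))
  expect_lt(max(abs(res$global_transform$translation)), 0.2)
  mag <- sqrt(rowSums(gmidemons:::.field_matrix(res$field)^2))
  expect_lt(max(mag), 0.1)
})

test_that("single-level alpha = 0 register reproduces a plain demons loop", {
  set.seed(17)
  r <- smooth_textured_image(c(24, 24))
  fv <- array(0, dim = c(24, 24, 2)); fv[, , 1] <- 0.8
  f <- warp_image(r, displacement_field(fv))
  cfg <- registration_config(alpha = 0, k = 1, n_levels = 1, sigma = 1,
                             max_iters_per_level = 10, mi_stop_threshold = 0,
                             refine_sigma = NULL, refine_delta = NULL)
  res <- register(r, f, cfg, skip_global = TRUE)
  # hand-rolled loop with the same stopping and monotone-acceptance rules
  v0 <- v <- zero_field(c(24, 24))
  trace <- numeric(0)
  rn <- normalize_image(r); fn <- normalize_image(f)
  for (n in 1:10) {
    w <- warp_image(fn, v)
    trace <- c(trace, mutual_information(
      estimate_joint_density(rn, w, cfg$parzen_delta, cfg$lattice_size)))
    if (n >= 2 && trace[n] - trace[n - 1] < cfg$mi_stop_threshold) break
    v <- demons_iteration(v, rn, fn, cfg)
  }
  if (length(trace) >= 2 && trace[length(trace)] < trace[1]) {
    v <- v0
    trace <- trace[1]
  }
  expect_identical(res$field$vectors, v$vectors)
  expect_equal(res$mi_trace[[1]], trace)
})

test_that("MI traces improve over each level and the driver is deterministic", {
  pair <- generate_phantom_pair(phantom_spec(seed = 19, deform_amplitude = 3))
  cfg <- registration_config(k = 0.1, alpha = 0.3, sigma = 2, n_levels = 2,
                             max_iters_per_level = 30)
  res1 <- register(pair$reference, pair$floating, cfg)
  for (tr in res1$mi_trace) {
    expect_gte(tr[length(tr)], tr[1] - 1e-6)
  }
  res2 <- register(pair$reference, pair$floating, cfg)
  expect_identical(res1$field$vectors, res2$field$vectors)
  expect_identical(res1$global_transform$translation,
                   res2$global_transform$translation)
  expect_identical(res1$mi_trace, res2$mi_trace)
})

test_that("two levels do not end with worse MI than the coarse level alone", {
  pair <- generate_phantom_pair(phantom_spec(seed = 23, deform_amplitude = 3,
                                             rigid_rotation = 0,
                                             rigid_translation = c(0, 0)))
  r <- normalize_image(pair$reference)
  f <- normalize_image(pair$floating)
  base <- registration_config(k = 0.1, alpha = 0.3, sigma = 2,
                              max_iters_per_level = 25)
  mi_final <- function(res) {
    w <- warp_image(f, res$field)
    mutual_information(estimate_joint_density(r, w, base$parzen_delta,
                                              base$lattice_size))
  }
  cfg2 <- base; cfg2$n_levels <- 2L
  res2 <- register(r, f, cfg2, skip_global = TRUE)
  # coarse-only run, upsampled to full resolution for a like-for-like MI
  cfg1 <- base; cfg1$n_levels <- 1L
  r_c <- build_pyramid(r, 2)$levels[[1]]
  f_c <- build_pyramid(f, 2)$levels[[1]]
  res1 <- register(r_c, f_c, cfg1, skip_global = TRUE)
  up <- upsample_field(res1$field, c(64, 64), 2)
  expect_gte(mi_final(res2), mi_final(list(field = up)) - 1e-6)
})

test_that("composing rigid and deformable stages gives the total mapping", {
  tf <- rigid_transform(0.1, c(2, -1), center = c(8.5, 8.5))
  fld <- zero_field(c(16, 16))
  tot <- compose_rigid_field(fld, tf)
  grid <- gmidemons:::.grid_coords(c(16, 16))
  expected <- gmidemons:::.rigid_coords(tf, grid, c(8.5, 8.5)) - grid
  expect_equal(gmidemons:::.field_matrix(tot), expected)
})
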