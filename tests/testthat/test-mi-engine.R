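test_that("joint densities integrate to 1 with consistent marginals", {
  set.seed(2)
  for (rep in 1:5) {
    r <- smooth_textured_image(c(12, 12), lo = 0.05, hi = 0.95)
    f <- smooth_textured_image(c(12, 12), lo = 0.05, hi = 0.95)
    jd <- estimate_joint_density(r, f, delta = 0.05, lattice_size = 64)
    W <- outer(jd$quad_w, jd$quad_w)
    expect_equal(sum(W * jd$grid), 1, tolerance = 1e-6)
    expect_equal(as.vector(jd$grid %*% jd$quad_w), jd$marginal_r,
                 tolerance = 1e-12)
    expect_equal(sum(jd$quad_w * jd$marginal_r), 1, tolerance = 1e-6)
    expect_equal(sum(jd$quad_w * jd$marginal_f), 1, tolerance = 1e-6)
    expect_true(all(jd$grid >= 0))
  }
})

test_that("density preconditions are enforced", {
  r <- scalar_image(matrix(0.5, 4, 4))
  expect_error(estimate_joint_density(r, scalar_image(matrix(1.5, 4, 4))),
               "normalized")
  expect_error(estimate_joint_density(r, r, delta = 0), "delta")
  expect_error(estimate_joint_density(r, r, lattice_size = 4), "lattice_size")
})

test_that("constant images concentrate the density at their intensity pair", {
  r <- scalar_image(matrix(0.5, 6, 6))
  jd <- estimate_joint_density(r, r, delta = 0.05, lattice_size = 65)
  peak <- which(jd$grid == max(jd$grid), arr.ind = TRUE)
  expect_equal(jd$lattice[peak[1, 1]], 0.5, tolerance = 0.01)
  expect_equal(jd$lattice[peak[1, 2]], 0.5, tolerance = 0.01)
})

test_that("the two-pixel dependent pair gives two equal modes and MI near log 2", {
  # r = (0, 1), f = (0, 1): modes at (0,0) and (1,1), mass ~0.5 each; the
  # closed form for the ideal two-symbol joint distribution is MI = log 2
  r <- scalar_image(matrix(c(0, 1), 2, 2))
  jd <- estimate_joint_density(r, r, delta = 0.02, lattice_size = 128)
  L <- length(jd$lattice)
  half <- seq_len(L / 2)
  W <- outer(jd$quad_w, jd$quad_w)
  mass00 <- sum((W * jd$grid)[half, half])
  mass11 <- sum((W * jd$grid)[-half, -half])
  expect_equal(mass00, 0.5, tolerance = 0.01)
  expect_equal(mass11, 0.5, tolerance = 0.01)
  expect_equal(mutual_information(jd), log(2), tolerance = 0.02)
})

test_that("independent constructions give zero MI", {
  # p(i,j) = pR(i) pF(j) exactly: build a product density by hand
  r <- scalar_image(matrix(rep(c(0.3, 0.7), each = 8), 4, 4))
  f <- scalar_image(matrix(rep(c(0.2, 0.8), times = 8), 4, 4))
  # every (r, f) combination appears equally often -> independence
  jd <- estimate_joint_density(r, f, delta = 0.03, lattice_size = 64)
  expect_equal(mutual_information(jd), 0, tolerance = 1e-6)
})

test_that("MI is symmetric and ranks alignment above shuffling", {
  set.seed(4)
  r <- smooth_textured_image(c(16, 16))
  f <- smooth_textured_image(c(16, 16))
  jd_rf <- estimate_joint_density(r, f, 0.05, 64)
  jd_fr <- estimate_joint_density(f, r, 0.05, 64)
  expect_equal(mutual_information(jd_rf), mutual_information(jd_fr),
               tolerance = 1e-9)
  shuffled <- scalar_image(array(sample(as.vector(r$data)), dim = c(16, 16)))
  mi_self <- mutual_information(estimate_joint_density(r, r, 0.05, 64))
  mi_shuf <- mutual_information(estimate_joint_density(r, shuffled, 0.05, 64))
  expect_gt(mi_self, mi_shuf)
})

test_that("a spatially constant floating image yields a zero MI force", {
  set.seed(6)
  r <- smooth_textured_image(c(12, 12))
  f <- scalar_image(matrix(0.5, 12, 12))
  g <- mi_gradient_field(r, f, zero_field(c(12, 12)), 0.05, 64)
  expect_true(all(g$vectors == 0))
})

test_that("the analytic MI gradient matches finite differences of MI", {
  # norm-relative agreement of analytic directional derivatives with central
  # finite differences under single-voxel perturbations; probes avoid
  # interpolation-cell boundaries where the discrete objective is kinked
  set.seed(12)
  for (rep in 1:2) {
    shape <- c(16, 16)
    r <- smooth_textured_image(shape)
    f <- smooth_textured_image(shape)
    fld <- random_smooth_field(shape)
    fv <- fld$vectors
    g <- mi_gradient_field(r, f, fld, delta = 0.05, lattice_size = 128)
    an <- fd <- numeric(0)
    tries <- 0
    while (length(fd) < 10 && tries < 500) {
      tries <- tries + 1
      px <- sample(3:14, 1); py <- sample(3:14, 1); ax <- sample(1:2, 1)
      frac <- (c(px, py) + fv[px, py, ]) %% 1
      if (any(frac < 0.15 | frac > 0.85)) next
      mi_at <- function(s) {
        f2 <- fv; f2[px, py, ax] <- f2[px, py, ax] + s
        w <- warp_image(f, displacement_field(f2))
        mutual_information(estimate_joint_density(r, w, 0.05, 128))
      }
      fd <- c(fd, (mi_at(0.02) - mi_at(-0.02)) / 0.04)
      an <- c(an, g$vectors[px, py, ax])
    }
    expect_gte(length(fd), 10)
    expect_lt(sqrt(sum((an - fd)^2)) / sqrt(sum(fd^2)), 1e-2)
  }
})

test_that("a small MI-ascent step does not decrease MI", {
  set.seed(21)
  pair <- generate_phantom_pair(phantom_spec(
    seed = 21, deform_amplitude = 2, rigid_rotation = 0,
    rigid_translation = c(0, 0)))
  r <- pair$reference; f <- pair$floating
  fld <- zero_field(c(64, 64))
  g <- mi_gradient_field(r, f, fld, 0.05, 64)
  mi0 <- g$mi_value
  step <- displacement_field(fld$vectors + 1e3 * g$vectors)
  w <- warp_image(f, step)
  mi1 <- mutual_information(estimate_joint_density(r, w, 0.05, 64))
  expect_gte(mi1, mi0)
})

test_that("MI peaks at the true alignment against jittered fields", {
  set.seed(33)
  pair <- generate_phantom_pair(phantom_spec(
    seed = 33, rigid_rotation = 0, rigid_translation = c(0, 0)))
  r <- pair$reference; f <- pair$floating
  w_true <- warp_image(f, pair$truth_field)
  mi_true <- mutual_information(estimate_joint_density(r, w_true, 0.05, 64))
  for (rep in 1:3) {
    jitter <- random_smooth_field(c(64, 64), rms = 1.5, smooth = 3)
    fld <- displacement_field(pair$truth_field$vectors + jitter$vectors)
    w <- warp_image(f, fld)
    mi_j <- mutual_information(estimate_joint_density(r, w, 0.05, 64))
    expect_gt(mi_true, mi_j)
  }
})
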