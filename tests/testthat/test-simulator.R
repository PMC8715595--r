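test_that("affine sampling respects its ranges and the RNG contract", {
  degenerate <- affine_ranges(rotation = c(0, 0), scale = c(1, 1),
                              shear = c(0, 0), translation = c(0, 0))
  p <- sample_affine(degenerate, hr_rng(1))
  expect_equal(p$rotation, c(0, 0, 0))
  expect_equal(p$scale, c(1, 1, 1))

  rng <- hr_rng(42)
  draws <- replicate(1000, sample_affine(affine_ranges(), rng)$rotation[1])
  expect_lt(abs(mean(draws)), 1)      # Monte-Carlo mean of U(-10, 10)

  r1 <- hr_rng(5); r2 <- hr_rng(5)
  a <- sample_affine(affine_ranges(), r1)
  b <- sample_affine(affine_ranges(), r1)
  expect_false(identical(a$rotation, b$rotation))
  expect_identical(a$rotation, sample_affine(affine_ranges(), r2)$rotation)

  expect_error(affine_ranges(rotation = c(10, -10)), "inverted")
})

test_that("affine fields match the closed forms and the matrix oracle", {
  z <- affine_to_field(affine_params(), c(6, 6, 4), c(1, 1, 2))
  expect_true(all(z$vectors == 0))

  tr <- affine_to_field(affine_params(translation = c(3, 0, 0)),
                        c(5, 5, 5), c(1, 1, 1))
  expect_equal(max(abs(tr$vectors[, , , 1] - 3)), 0)
  expect_equal(max(abs(tr$vectors[, , , 2:3])), 0)

  # 90-degree in-plane rotation vs direct per-voxel matrix application
  p <- affine_params(rotation = c(0, 0, 90), center = c(2, 2, 2))
  f <- affine_to_field(p, c(5, 5, 5), c(1, 1, 1))
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  for (v in list(c(0, 0, 0), c(4, 2, 1), c(3, 1, 4))) {
    u_expect <- c(2, 2, 2) + R %*% (v - c(2, 2, 2)) - v
    expect_lt(max(abs(f$vectors[v[1] + 1, v[2] + 1, v[3] + 1, ] -
                        as.numeric(u_expect))), 1e-9)
  }
})

test_that("elastic fields honor the magnitude cap and are smooth", {
  shape <- c(16, 16, 8); sp <- c(1, 1, 2)
  zero <- sample_elastic(elastic_spec(max_displacement = 0), shape, sp,
                         hr_rng(1))
  expect_true(all(zero$vectors == 0))

  rng <- hr_rng(2)
  for (i in 1:5) {
    f <- sample_elastic(elastic_spec(control_spacings = c(4, 8),
                                     max_displacement = 7), shape, sp, rng)
    mm <- field_voxels_to_mm(f)
    expect_lte(sqrt(max(apply(mm^2, 1:3, sum))), 7 + 1e-6)
  }

  # smoothness: per-draw max finite-difference gradient stays within 50%
  # of a reference draw's value on average
  es <- elastic_spec(control_spacings = 4, max_displacement = 5,
                     smoothness_sigma = 2)
  max_grad <- function(f) {
    mx <- 0
    for (cmp in 1:3) {
      a <- f$vectors[, , , cmp]
      mx <- max(mx, abs(apply(a, c(2, 3), diff)),
                abs(apply(a, c(1, 3), diff)))
    }
    mx
  }
  rng <- hr_rng(3)
  ref <- max_grad(sample_elastic(es, shape, sp, rng))
  grads <- replicate(30, max_grad(sample_elastic(es, shape, sp, rng)))
  expect_lt(abs(mean(grads) - ref) / ref, 0.5)

  expect_error(elastic_spec(max_displacement = -1), ">= 0")
  expect_error(elastic_spec(control_spacings = numeric(0)), "non-empty")
})

test_that("field composition is consistent with sequential warping", {
  shape <- c(8, 8, 8)
  rng <- hr_rng(7)
  F1 <- sample_elastic(elastic_spec(control_spacings = 4,
                                    max_displacement = 2), shape,
                       c(1, 1, 1), rng)
  z <- zero_field(shape)
  expect_identical(compose_fields(z, F1)$vectors, F1$vectors)
  expect_equal(compose_fields(F1, z)$vectors, F1$vectors)

  t1 <- constant_field(shape, c(1, 0.5, 0)); t2 <- constant_field(shape, c(0.25, -1, 0.5))
  comp <- compose_fields(t1, t2)
  expect_equal(max(abs(sweep(hybridreg:::field_mat(comp), 2,
                             c(1.25, -0.5, 0.5), "-"))), 0)

  # warp(warp(I, outer), inner) == warp(I, compose(outer, inner)) on a
  # smooth (near-multilinear) volume; compared away from the border, where
  # the clamping of intermediate coordinates necessarily differs
  idx <- hybridreg:::vox_index_mat(shape)
  I <- volume(array(0.1 * idx[, 1] + 0.07 * idx[, 2] + 0.05 * idx[, 3] +
                      0.004 * idx[, 1] * idx[, 2] +
                      0.0008 * (idx[, 1]^2 + idx[, 2]^2), shape))
  F1s <- sample_elastic(elastic_spec(control_spacings = 4,
                                     max_displacement = 1,
                                     smoothness_sigma = 3), shape,
                        c(1, 1, 1), rng)
  F2s <- sample_elastic(elastic_spec(control_spacings = 4,
                                     max_displacement = 1,
                                     smoothness_sigma = 3), shape,
                        c(1, 1, 1), rng)
  seq_warp <- warp_volume(warp_volume(I, F1s), F2s)
  one_warp <- warp_volume(I, compose_fields(F1s, F2s))
  core <- 3:6
  expect_lt(max(abs(seq_warp$values[core, core, core] -
                      one_warp$values[core, core, core])), 1e-3)

  expect_error(compose_fields(F1, zero_field(c(4, 4, 4))), "mismatch")
})

test_that("deformation draws select regimes and stay reproducible", {
  shape <- c(16, 16, 1); sp <- c(1, 1, 2)
  cfg0 <- simulator_config(large_fraction = 0)
  rng <- hr_rng(1)
  for (i in 1:5)
    expect_identical(sample_deformation(cfg0, shape, sp, rng)$regime, "small")

  cfg1 <- simulator_config(large_fraction = 1)
  expect_identical(sample_deformation(cfg1, shape, sp, hr_rng(2))$regime,
                   "large")

  # elastic-only large regime respects the mm cap through composition
  reg <- list(affine = affine_ranges(rotation = c(0, 0), scale = c(1, 1),
                                     shear = c(0, 0), translation = c(0, 0)),
              elastic = elastic_spec(max_displacement = 15))
  cfg <- simulator_config(small = reg, large = reg, large_fraction = 1)
  rng <- hr_rng(4)
  for (i in 1:5) {
    f <- sample_deformation(cfg, shape, sp, rng)$field
    mm <- field_voxels_to_mm(f)
    expect_lte(sqrt(max(apply(mm^2, 1:3, sum))), 15 + 1e-6)
  }

  d1 <- sample_deformation(simulator_config(), shape, sp, hr_rng(9))
  d2 <- sample_deformation(simulator_config(), shape, sp, hr_rng(9))
  expect_identical(d1$field$vectors, d2$field$vectors)

  expect_error(simulator_config(large_fraction = 1.2), "large_fraction")
})
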