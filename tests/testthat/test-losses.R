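test_that("field loss matches closed forms and the loop oracle", {
  z <- zero_field(c(4, 4, 4))
  expect_identical(field_loss(z, z), 0)

  f345 <- constant_field(c(4, 4, 4), c(3, 4, 0))
  expect_equal(field_loss(f345, z), 5)
  expect_equal(field_loss(z, f345), 5)   # symmetry

  rng <- hr_rng(1)
  mk <- function() displacement_field(
    array(with_rng(rng, rnorm(6^3 * 3)), c(6, 6, 6, 3)), c(0.36, 0.36, 2))
  a <- mk(); b <- mk()
  expect_lt(abs(field_loss(a, b) - field_loss_loop_oracle(a, b)) /
              field_loss_loop_oracle(a, b), 1e-10)

  # metric properties on random triples
  for (i in 1:5) {
    x <- mk(); y <- mk(); w <- mk()
    expect_gte(field_loss(x, y), 0)
    expect_equal(field_loss(x, y), field_loss(y, x))
    expect_lte(field_loss(x, w), field_loss(x, y) + field_loss(y, w) + 1e-12)
  }
  expect_error(field_loss(a, zero_field(c(5, 6, 6))), "mismatch")
})

test_that("squared-NCC loss matches the per-window loop oracle", {
  w <- similarity_window(radius = 2, epsilon = 1e-5)
  rng <- hr_rng(2)
  for (i in 1:3) {
    a <- array(with_rng(rng, rnorm(12^3)), c(12, 12, 12))
    b <- a + 0.4 * array(with_rng(rng, rnorm(12^3)), c(12, 12, 12))
    got <- local_sq_ncc_loss(volume(a), volume(b), w)
    want <- ncc_loop_oracle(a, b, c(2, 2, 2), 1e-5)
    expect_lt(abs(got - want) / abs(want), 1e-6)
  }
})

test_that("squared-NCC loss has the defining similarity properties", {
  w <- similarity_window(radius = 2, epsilon = 1e-5)
  rng <- hr_rng(3)
  a <- volume(array(with_rng(rng, rnorm(10^3)), c(10, 10, 10)))

  self <- local_sq_ncc_loss(a, a, w)
  expect_gte(self, -1)
  expect_lt(abs(self - (-1)), 1e-3)

  flip <- volume(-a$values)
  expect_equal(local_sq_ncc_loss(a, flip, w), self, tolerance = 1e-12)

  # invariance to affine intensity maps
  b <- volume(array(with_rng(rng, rnorm(10^3)), c(10, 10, 10)))
  base <- local_sq_ncc_loss(a, b, w)
  resc <- local_sq_ncc_loss(volume(3.1 * a$values - 2), volume(0.5 * b$values + 7), w)
  expect_lt(abs(base - resc), 1e-4)

  # constant windows contribute about zero rather than blowing up
  const <- volume(array(0, c(10, 10, 10)))
  expect_lt(abs(local_sq_ncc_loss(a, const, w)), 1e-6)

  expect_error(local_sq_ncc_loss(a, volume(array(0, c(9, 10, 10))), w),
               "mismatch")
})

test_that("loss gradients agree with finite differences", {
  shape <- c(6, 6, 6)
  rng <- hr_rng(4)
  r0 <- with_rng(rng, rnorm(prod(shape)))
  p0 <- with_rng(rng, rnorm(prod(shape)))
  w <- similarity_window(radius = 2, epsilon = 1e-5)
  g <- hybridreg:::ncc_loss_with_grad(r0, p0, shape, w)
  h <- 1e-6
  for (ii in with_rng(rng, sample.int(prod(shape), 10))) {
    pp <- p0; pp[ii] <- pp[ii] + h
    fd <- (hybridreg:::ncc_loss_with_grad(r0, pp, shape, w)$loss - g$loss) / h
    expect_lt(abs(g$grad[ii] - fd), 1e-3 * max(1, abs(fd)))
  }

  # field-loss gradient
  a <- displacement_field(array(with_rng(rng, rnorm(prod(shape) * 3)),
                                c(shape, 3)), c(1, 1, 2))
  b <- displacement_field(array(with_rng(rng, rnorm(prod(shape) * 3)),
                                c(shape, 3)), c(1, 1, 2))
  gf <- hybridreg:::field_loss_grad(a, b)
  l0 <- field_loss(a, b)
  for (k in 1:5) {
    i <- with_rng(rng, sample.int(prod(shape), 1))
    cmp <- with_rng(rng, sample.int(3, 1))
    a2 <- a; a2$vectors[, , , cmp][i] <- a2$vectors[, , , cmp][i] + h
    fd <- (field_loss(a2, b) - l0) / h
    expect_lt(abs(gf[i, cmp] - fd), 1e-3 * max(1, abs(fd)))
  }

  # warp gradient wrt the field
  vol <- hybridreg:::cpp_gauss_smooth(with_rng(rng, rnorm(prod(shape))),
                                      shape, c(1.5, 1.5, 1.5))
  fm <- matrix(with_rng(rng, runif(prod(shape) * 3, -1, 1)), ncol = 3)
  gup <- with_rng(rng, rnorm(prod(shape)))
  dF <- hybridreg:::cpp_warp_bwd_field(vol, shape, fm, gup)
  w0 <- sum(gup * hybridreg:::cpp_warp(vol, shape, fm, FALSE))
  for (k in 1:5) {
    i <- with_rng(rng, sample.int(prod(shape), 1))
    cmp <- with_rng(rng, sample.int(3, 1))
    fm2 <- fm; fm2[i, cmp] <- fm2[i, cmp] + h
    fd <- (sum(gup * hybridreg:::cpp_warp(vol, shape, fm2, FALSE)) - w0) / h
    expect_lt(abs(dF[i, cmp] - fd), 1e-3 * max(1, abs(fd)))
  }
})

test_that("hybrid loss combines its parts with the default weights", {
  # exact stub arithmetic: 1/13 * 13 + 0.4 * (-0.5) + 0.4 * (-0.25) = 0.7
  expect_identical(hybrid_total(13, -0.5, -0.25), 1 - 0.2 - 0.1)
  expect_identical(hybrid_total(2, -0.3, -0.9, loss_weights(0, 1, 0)), -0.3)

  rng <- hr_rng(5)
  shape <- c(10, 10, 10)
  I <- volume(array(with_rng(rng, rnorm(prod(shape))), shape))
  f <- zero_field(shape)
  w <- similarity_window(radius = 2)
  hl <- hybrid_loss(f, f, I, I, I, I, loss_weights(), w)
  # perfect prediction: field term 0, both similarity terms about -1
  expect_lt(abs(hl$total - (-0.8)), 1e-3)
  expect_identical(hl$parts[["l_field"]], 0)

  # total always reconstructs from the logged parts
  J <- volume(array(with_rng(rng, rnorm(prod(shape))), shape))
  g <- displacement_field(array(with_rng(rng, rnorm(prod(shape) * 3)),
                                c(shape, 3)))
  h2 <- hybrid_loss(g, f, I, J, J, I, loss_weights(), w)
  expect_equal(h2$total, hybrid_total(h2$parts[["l_field"]],
                                      h2$parts[["l_sim0"]],
                                      h2$parts[["l_sim1"]]))

  expect_error(loss_weights(-0.1), "finite and >= 0")
})
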