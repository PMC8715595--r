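test_that("warping identities and shift oracles hold", {
  v <- volume(array(seq_len(4 * 4 * 4), c(4, 4, 4)))
  z <- zero_field(c(4, 4, 4))
  expect_identical(warp_volume(v, z, "nearest")$values, v$values)
  expect_lt(max(abs(warp_volume(v, z, "linear")$values - v$values)), 1e-7)

  # constant integer fields read ahead, matching the clamped-shift oracle
  for (u in list(c(2, 0, 0), c(0, -1, 0), c(1, 2, -1))) {
    f <- constant_field(c(4, 4, 4), u)
    expect_identical(warp_volume(v, f, "nearest")$values,
                     shift_clamp_oracle(v$values, u))
  }

  # nearest interpolation cannot invent values
  rngf <- sample_elastic(elastic_spec(max_displacement = 3), c(8, 8, 4),
                         c(1, 1, 1), hr_rng(1))
  vv <- volume(array(sample(1:5, 8 * 8 * 4, TRUE), c(8, 8, 4)))
  expect_true(all(warp_volume(vv, rngf, "nearest")$values %in% vv$values))

  expect_error(warp_volume(v, zero_field(c(5, 4, 4))), "mismatch")
})

test_that("linear warping matches the analytic ramp", {
  ramp <- volume(array(rep(0:7, 16), c(8, 4, 4)))   # value = x index
  f <- constant_field(c(8, 4, 4), c(0.5, 0, 0))
  w <- warp_volume(ramp, f, "linear")
  interior <- w$values[1:7, , ]                      # clamp affects last row
  expected <- array(rep(0:6 + 0.5, 16), c(7, 4, 4))
  expect_lt(max(abs(interior - expected)), 1e-6)
})

test_that("mask warping shifts content and stays binary", {
  m <- label_mask(array(as.integer(runif(8 * 8 * 2) > 0.6), c(8, 8, 2)))
  z <- zero_field(c(8, 8, 2))
  expect_identical(warp_mask(m, z)$values, m$values)

  u <- c(2, -1, 0)
  wm <- warp_mask(m, constant_field(c(8, 8, 2), u))
  expect_identical(wm$values,
                   array(as.integer(shift_clamp_oracle(m$values, u)),
                         c(8, 8, 2)))
  f <- sample_elastic(elastic_spec(max_displacement = 3), c(8, 8, 2),
                      c(1, 1, 1), hr_rng(3))
  expect_true(all(warp_mask(m, f)$values %in% c(0L, 1L)))
})

test_that("point transport converts units and matches dense sampling", {
  l <- landmark_set(c("a", "b"), rbind(c(1, 1, 2), c(2, 0.72, 4)))
  z <- zero_field(c(8, 8, 4), c(0.36, 0.36, 2))
  tz <- transform_points(l, z)
  expect_equal(tz$points_mm, l$points_mm)
  expect_true(all(tz$gold_vectors_mm == 0))

  f <- constant_field(c(8, 8, 4), c(1, 0, 1), c(0.36, 0.36, 2))
  tf <- transform_points(l, f)
  expect_equal(tf$gold_vectors_mm[1, ], c(0.36, 0, 2))
  expect_equal(tf$points_mm[2, ], c(2 + 0.36, 0.72, 6))

  # smooth field: vectors equal direct trilinear sampling of the dense grid
  shape <- c(10, 10, 6)
  sm <- sample_elastic(elastic_spec(control_spacings = 4,
                                    max_displacement = 2), shape,
                       c(1, 1, 1), hr_rng(5))
  rng <- hr_rng(6)
  pts <- cbind(with_rng(rng, runif(10, 1, 8)), with_rng(rng, runif(10, 1, 8)),
               with_rng(rng, runif(10, 1, 4)))
  tp <- transform_points(landmark_set(sprintf("p%d", 1:10), pts), sm)
  fm <- hybridreg:::field_mat(sm)
  manual <- function(i) {
    p <- pts[i, ]
    p0 <- floor(p); t <- p - p0
    acc <- c(0, 0, 0)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, t, 1 - t))
      idx <- (p0[1] + dx) + shape[1] * ((p0[2] + dy) + shape[2] * (p0[3] + dz))
      acc <- acc + w * fm[idx + 1, ]
    }
    acc
  }
  for (i in 1:10)
    expect_lt(max(abs(tp$gold_vectors_mm[i, ] - manual(i))), 1e-9)

  # out-of-extent points are flagged, not clamped
  lo <- landmark_set("out", rbind(c(-1, 2, 2)))
  to <- transform_points(lo, z)
  expect_false(attr(to, "in_bounds")[1])
  expect_true(all(is.na(to$gold_vectors_mm[1, ])))
})

test_that("voxel-to-mm conversion is a per-axis scaling", {
  f <- constant_field(c(4, 4, 2), c(1, 0, 1), c(0.36, 0.36, 2))
  mm <- field_voxels_to_mm(f)
  expect_equal(mm[2, 3, 1, ], c(0.36, 0, 2))
  expect_equal(sqrt(sum(mm[1, 1, 1, ]^2)), sqrt(0.36^2 + 2^2))
  id <- constant_field(c(4, 4, 2), c(1, 2, 3), c(1, 1, 1))
  expect_identical(field_voxels_to_mm(id), id$vectors)
  expect_true(all(field_voxels_to_mm(zero_field(c(4, 4, 2))) == 0))
})
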