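test_that("landmark endpoint error matches its oracles", {
  # self-consistency: the generating field scores zero against itself
  sub <- subject2d(1)
  rng <- hr_rng(1)
  pair <- make_eval_pair(sub, simulator_config(), rng)
  self <- landmark_epe(pair$gold_field, pair$landmarks)
  expect_lte(self$mean_mm, 1e-6)

  # hand-computed single-vector case at anisotropic spacing
  lm <- landmark_set("p", rbind(c(1, 1, 2)), rbind(c(0.36, 0, 2)))
  z <- zero_field(c(8, 8, 4), c(0.36, 0.36, 2))
  expect_equal(landmark_epe(z, lm)$mean_mm, sqrt(0.36^2 + 2^2))

  # random sparse sets vs a per-point loop oracle
  shape <- c(10, 10, 6)
  f <- sample_elastic(elastic_spec(control_spacings = 4,
                                   max_displacement = 3), shape,
                      c(1, 1, 2), hr_rng(2))
  rng <- hr_rng(3)
  pts <- cbind(with_rng(rng, runif(8, 1, 8)), with_rng(rng, runif(8, 1, 8)),
               with_rng(rng, runif(8, 2, 8)))
  gold <- matrix(with_rng(rng, rnorm(24)), ncol = 3)
  lm2 <- landmark_set(sprintf("p%d", 1:8), pts, gold)
  got <- landmark_epe(f, lm2)
  tp <- transform_points(landmark_set(lm2$names, pts), f)
  for (i in 1:8)
    expect_lt(abs(got$per_point_mm[i] -
                    sqrt(sum((tp$gold_vectors_mm[i, ] - gold[i, ])^2))), 1e-10)
  expect_equal(got$mean_mm, mean(got$per_point_mm))

  expect_error(landmark_epe(z, landmark_set("q", rbind(c(1, 1, 1)))),
               "no gold")

  # out-of-extent points are excluded and reported
  lm3 <- landmark_set(c("in", "out"), rbind(c(1, 1, 2), c(50, 1, 2)),
                      rbind(c(0, 0, 0), c(0, 0, 0)))
  r3 <- landmark_epe(z, lm3)
  expect_identical(r3$excluded, "out")
  expect_true(is.na(r3$per_point_mm[["out"]]))
})

test_that("normalized mutual information behaves as an information measure", {
  rng <- hr_rng(4)
  a <- volume(array(with_rng(rng, rnorm(64^3)), c(64, 64, 64)))
  expect_lt(abs(nmi(a, a) - 1), 1e-9)

  b <- volume(array(with_rng(rng, runif(64^3)), c(64, 64, 64)))
  c2 <- volume(array(with_rng(rng, runif(64^3)), c(64, 64, 64)))
  expect_lt(nmi(b, c2), 0.05)                  # independent noise

  expect_lt(abs(nmi(a, b) - nmi(b, a)), 1e-12) # symmetry

  expect_error(nmi(volume(array(1, c(4, 4, 1))), volume(array(1, c(4, 4, 1)))),
               "constant image")
  expect_error(nmi(a, volume(array(0, c(4, 4, 4)))), "mismatch")
})

test_that("Dice matches the closed forms", {
  m1 <- label_mask(array(c(rep(1, 8), rep(0, 8)), c(4, 4, 1)))
  expect_identical(dice(m1, m1), 1)
  m2 <- label_mask(array(c(rep(0, 8), rep(1, 8)), c(4, 4, 1)))
  expect_identical(dice(m1, m2), 0)
  half <- label_mask(array(c(rep(0, 4), rep(1, 8), rep(0, 4)), c(4, 4, 1)))
  expect_identical(dice(m1, half), 0.5)        # |a|=8, |b|=8, overlap 4
  empty <- label_mask(array(0, c(4, 4, 1)))
  expect_error(dice(empty, empty), "empty")
})

test_that("the paired t-test reports the closed-form statistic", {
  r <- paired_ttest(c(2, 4, 6), c(1, 2, 3))    # d = (1, 2, 3)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_identical(r$df, 2)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  swapped <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)

  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("cohort evaluation brackets any model between oracle and identity", {
  subs <- list(subject2d(1), subject2d(2))
  rep_or <- evaluate_cohort("oracle", subs, pairing_seed = 1, n_pairs = 4)
  expect_lte(rep_or$aggregates["epe_mm", "mean"], 1e-6)
  expect_gte(rep_or$aggregates["dice", "mean"], 0.99)

  rep_id <- evaluate_cohort("identity", subs, pairing_seed = 1, n_pairs = 4)
  # identity baseline equals the mean gold-vector norm, recomputed directly
  rngc <- hr_rng(hybridreg:::derive_seed(1, 29L))
  manual <- vapply(1:4, function(i) {
    p <- make_eval_pair(subs[[1L + (i - 1L) %% 2L]], simulator_config(), rngc)
    mean(sqrt(rowSums(p$landmarks$gold_vectors_mm^2)))
  }, 0)
  expect_equal(rep_id$aggregates["epe_mm", "mean"], mean(manual),
               tolerance = 1e-10)

  # untrained model sits between oracle and identity
  m <- build_network(network_spec(base_channels = 8), 1)
  rep_m <- evaluate_cohort(m, subs, pairing_seed = 1, n_pairs = 4)
  expect_gte(rep_m$aggregates["epe_mm", "mean"], 0)
  expect_lte(rep_m$aggregates["epe_mm", "mean"],
             rep_id$aggregates["epe_mm", "mean"] + 0.5)

  # determinism: identical reports apart from runtimes
  rep2 <- evaluate_cohort("identity", subs, pairing_seed = 1, n_pairs = 4)
  drop_rt <- function(r) r$per_case[, setdiff(names(r$per_case), "runtime_s")]
  expect_identical(drop_rt(rep_id), drop_rt(rep2))

  # aggregates recompute from per-case rows
  expect_identical(rep_id$aggregates["epe_mm", "mean"],
                   mean(rep_id$per_case$epe_mm))
  expect_identical(rep_id$aggregates["dice", "sd"], sd(rep_id$per_case$dice))
})

test_that("intersubject pairing scores landmark correspondence", {
  subs <- list(subject2d(1), subject2d(2), subject2d(3))
  rep_i <- evaluate_cohort("identity", subs, pairing_seed = 2, n_pairs = 3,
                           pairing = "intersubject")
  expect_true(all(is.finite(rep_i$per_case$epe_mm)))
  expect_gt(rep_i$aggregates["epe_mm", "mean"], 0)
})
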