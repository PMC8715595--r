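test_that("supervised pairs carry exact gold supervision", {
  sub <- subject2d(1)
  rng <- hr_rng(1)
  idp <- make_supervised_pair(sub$volume, identity_simulator(), rng)
  expect_true(all(idp$Fg0$vectors == 0))
  expect_lt(max(abs(idp$I0$values - sub$volume$values)), 1e-7)

  # the gold field maps each landmark onto its counterpart feature: mark
  # the moving image at a landmark, warp it, and check the mark appears at
  # the reference-space location solving q + u(q) = p (fixed-point solve)
  rng <- hr_rng(2)
  sup <- make_supervised_pair(sub$volume, simulator_config(large_fraction = 0),
                              rng)
  marked <- sub$volume
  shape <- hybridreg:::dims3(marked)
  pv <- round(sweep(sub$landmarks$points_mm, 2, marked$spacing, "/"))
  for (i in seq_len(nrow(pv)))
    marked$values[pv[i, 1] + 1, pv[i, 2] + 1, max(pv[i, 3] + 1, 1)] <- 50
  wm <- warp_volume(marked, sup$Fg0, "nearest")
  fm <- hybridreg:::field_mat(sup$Fg0)
  ok <- 0
  for (i in seq_len(nrow(pv))) {
    q <- pv[i, ]                      # iterate q <- p - u(q)
    for (it in 1:30) {
      u <- vapply(1:3, function(cmp)
        hybridreg:::cpp_sample_linear(fm[, cmp], shape, rbind(q)), 0)
      q <- pv[i, ] - u
    }
    qi <- pmin(pmax(round(q) + 1, 1), shape)
    nb <- wm$values[max(qi[1] - 1, 1):min(qi[1] + 1, shape[1]),
                    max(qi[2] - 1, 1):min(qi[2] + 1, shape[2]), qi[3]]
    if (any(nb == 50)) ok <- ok + 1
  }
  expect_gte(ok, nrow(pv) - 1)        # within 1 voxel for nearly all points

  rngA <- hr_rng(9); rngB <- hr_rng(9)
  a <- make_supervised_pair(sub$volume, simulator_config(), rngA)
  b <- make_supervised_pair(sub$volume, simulator_config(), rngB)
  expect_identical(a$Fg0$vectors, b$Fg0$vectors)
})

test_that("self-supervised pairs are uniform over ordered distinct pairs", {
  cohort <- lapply(1:2, function(i) list(volume = subject2d(i)$volume))
  rng <- hr_rng(1)
  p <- sample_selfsup_pair(cohort, rng)
  expect_false(identical(p$M$values, p$I1$values))

  cohort4 <- lapply(1:4, function(i) list(volume = subject2d(1)$volume))
  rng <- hr_rng(2)
  counts <- table(replicate(1000, paste(sample_selfsup_pair(cohort4, rng)$idx,
                                        collapse = "-")))
  expect_identical(length(counts), 12L)
  # binomial 99% band around n/12
  expect_true(all(counts > 1000 / 12 - 2.58 * sqrt(1000 * (1 / 12) * (11 / 12))))
  expect_true(all(counts < 1000 / 12 + 2.58 * sqrt(1000 * (1 / 12) * (11 / 12))))

  expect_error(sample_selfsup_pair(cohort[1], rng), "at least 2")
})

test_that("noise augmentation has the configured scale", {
  v <- volume(array(0, c(64, 64, 1)))
  expect_identical(augment_noise(v, 0, hr_rng(1))$values, v$values)
  n <- augment_noise(v, 0.05, hr_rng(1))
  expect_gt(sd(n$values), 0.045)      # chi-square band for 4096 draws
  expect_lt(sd(n$values), 0.055)
  expect_identical(augment_noise(v, 0.05, hr_rng(3))$values,
                   augment_noise(v, 0.05, hr_rng(3))$values)
  expect_error(augment_noise(v, -1, hr_rng(1)), ">= 0")
})

test_that("training bookkeeping reconstructs totals and stays bounded", {
  cohort <- lapply(1:3, function(i) subject2d(i))
  cfg <- train_config(steps = 2, seed = 4, val_every = 1000)
  m <- build_network(network_spec(base_channels = 8), 1)
  tr <- train_network(m, cohort, cfg)
  w <- cfg$weights
  expect_lt(max(abs(tr$history$total -
                      (w$alpha * tr$history$l_field +
                         w$beta * tr$history$l_sim0 +
                         w$gamma * tr$history$l_sim1))), 1e-6)

  # degenerate run: zero-magnitude simulator, field loss only
  cfg0 <- train_config(weights = loss_weights(1, 0, 0),
                       simulator = identity_simulator(), steps = 5, seed = 1)
  tr0 <- train_network(build_network(network_spec(base_channels = 8), 1),
                       cohort, cfg0)
  expect_lt(tr0$history$l_field[1], 0.1)   # near-identity initialization
  expect_true(all(tr0$history$l_field < 0.5))
})

test_that("pure field supervision strictly improves on a fixed pair", {
  sub <- subject2d(1)
  rng <- hr_rng(2)
  sup <- make_supervised_pair(sub$volume, simulator_config(), rng)
  m <- build_network(network_spec(base_channels = 8), 1)
  st <- hybridreg:::adam_init(m$params)
  lf <- numeric(60)
  for (i in seq_len(60)) {
    g <- hybridreg:::pair_grads(m, sub$volume, sup$I0,
                                as.numeric(sub$volume$values),
                                as.numeric(sup$I0$values), sup$Fg0,
                                1, 0, similarity_window(), rng)
    lf[i] <- g$l_field
    u <- hybridreg:::adam_step(m$params, g$grads, st, i, 1e-3)
    m$params <- u$params; st <- u$state
  }
  expect_lt(lf[60], 0.7 * lf[1])
})

test_that("training runs are seed-deterministic", {
  cohort <- lapply(1:3, function(i) subject2d(i))
  cfg <- train_config(steps = 5, seed = 11, val_every = 1000)
  t1 <- train_network(build_network(network_spec(base_channels = 8), 2),
                      cohort, cfg)
  t2 <- train_network(build_network(network_spec(base_channels = 8), 2),
                      cohort, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
})

test_that("validation scores oracle and identity stubs correctly", {
  subs <- list(subject2d(1), subject2d(2))
  rng <- hr_rng(5)
  pairs <- lapply(subs, make_eval_pair, sim = simulator_config(), rng = rng)
  vo <- validate("oracle", pairs)
  expect_lte(vo$epe_mm, 1e-6)
  expect_gte(vo$dice, 0.99)

  vi <- validate("identity", pairs)
  manual <- mean(vapply(pairs, function(p)
    mean(sqrt(rowSums(p$landmarks$gold_vectors_mm^2))), 0))
  expect_equal(vi$epe_mm, manual, tolerance = 1e-10)

  m <- build_network(network_spec(base_channels = 8), 1)
  expect_identical(validate(m, pairs)$epe_mm, validate(m, pairs)$epe_mm)
  expect_error(validate(m, list()), "empty")
})
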