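# Hybrid-supervised training loop.
#
# Each optimization step draws one moving image M and one distinct
# reference I1 from the cohort (self-supervised pair), manufactures one
# supervised pair by sampling a gold-standard field Fg0 from the simulator
# and warping M into I0 = M o (id + Fg0), forwards both pairs through the
# same weights, and takes a single Adam update on the hybrid loss
# alpha*L_field + beta*L_sim0 + gamma*L_sim1. Gradients from both pairs
# accumulate before the update. Gaussian noise augments all network inputs
# (after z-scoring); the losses always use the clean targets.

#' Training configuration
#'
#' @param weights a [loss_weights()].
#' @param window a [similarity_window()].
#' @param simulator a [simulator_config()].
#' @param steps number of optimization steps (>= 1).
#' @param learning_rate peak Adam learning rate.
#' @param lr_schedule `"cosine"` (linear warmup over the first 5% of steps,
#'   then cosine decay to 5% of the peak) or `"constant"`.
#' @param noise_sd sd of the Gaussian input-augmentation noise, on z-scored
#'   intensities.
#' @param clip_norm global gradient-norm clipping threshold (0 disables);
#'   caps occasional gradient spikes from the similarity terms so single
#'   steps cannot derail the optimization trajectory.
#' @param ema_decay exponential-moving-average decay for the evaluation
#'   weights (Polyak averaging); 0 disables. Validation and the returned
#'   model use the averaged weights, which damps the step-to-step noise of
#'   batch-size-1 optimization.
#' @param batch_size fixed at 1 (one supervised + one self-supervised pair
#'   per step).
#' @param seed integer seed governing every random draw of the run.
#' @param val_every validate (and checkpoint) every this many steps.
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @export
train_config <- function(weights = loss_weights(),
                         window = similarity_window(),
                         simulator = simulator_config(),
                         steps = 2000L, learning_rate = 1e-3,
                         lr_schedule = c("cosine", "constant"),
                         noise_sd = 0.05, clip_norm = 0.3,
                         ema_decay = 0.99,
                         batch_size = 1L, seed = 0L,
                         val_every = 100L, checkpoint_dir = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  if (ema_decay < 0 || ema_decay >= 1) stop("ema_decay must lie in [0, 1)")
  if (clip_norm < 0) stop("clip_norm must be >= 0")
  if (steps < 1) stop("steps must be >= 1")
  if (batch_size != 1L) stop("batch_size is fixed at 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(weights, "hr_loss_weights"),
            inherits(window, "hr_window"),
            inherits(simulator, "hr_sim_config"))
  structure(list(weights = weights, window = window, simulator = simulator,
                 steps = as.integer(steps), learning_rate = learning_rate,
                 lr_schedule = lr_schedule, noise_sd = noise_sd,
                 clip_norm = clip_norm, ema_decay = ema_decay,
                 batch_size = 1L, seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 checkpoint_dir = checkpoint_dir), class = "hr_train_config")
}

#' Manufacture one supervised training pair
#'
#' Draws a gold-standard field from the simulator and warps the moving
#' image with it (linear interpolation), so the drawn field is by
#' construction the exact gold standard for registering `M` to the
#' generated reference.
#'
#' @param M preprocessed moving `hr_volume`.
#' @param sim a [simulator_config()].
#' @param rng an [hr_rng()] stream.
#' @return list `(I0, Fg0, regime)`.
#' @export
make_supervised_pair <- function(M, sim, rng) {
  d <- sample_deformation(sim, dims3(M), M$spacing, rng)
  list(I0 = warp_volume(M, d$field, "linear"), Fg0 = d$field,
       regime = d$regime)
}

#' Draw a self-supervised pair from a cohort
#'
#' Uniform over ordered pairs of distinct subjects.
#'
#' @param cohort list of subjects (each with a `volume` element) or of
#'   `hr_volume`s.
#' @param rng an [hr_rng()] stream.
#' @return list `(M, I1, idx)` with `idx` the (moving, reference) indices.
#' @export
sample_selfsup_pair <- function(cohort, rng) {
  n <- length(cohort)
  if (n < 2) stop("cohort must contain at least 2 subjects")
  i <- with_rng(rng, sample.int(n, 1L))
  j <- with_rng(rng, sample.int(n - 1L, 1L))
  if (j >= i) j <- j + 1L
  vol <- function(s) if (inherits(s, "hr_volume")) s else s$volume
  list(M = vol(cohort[[i]]), I1 = vol(cohort[[j]]), idx = c(i, j))
}

#' Additive Gaussian noise augmentation
#'
#' @param v an `hr_volume`.
#' @param sd noise standard deviation (0 = identity).
#' @param rng an [hr_rng()] stream.
#' @export
augment_noise <- function(v, sd, rng) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(v)
  noise <- with_rng(rng, rnorm(length(v$values), 0, sd))
  volume(v$values + array(noise, dims3(v)), v$spacing, v$origin, v$domain)
}

# gradients for one (moving, reference) pair; `gold` is NULL for the
# self-supervised pair. Returns loss parts, network grads, prediction.
pair_grads <- function(model, Mvol, Rvol, Min, Rin, gold, w_field, w_sim,
                       window, rng) {
  shape <- dims3(Mvol)
  dims <- model$spec$dims
  fwd <- network_forward(model, cbind(Min, Rin), shape, training = TRUE,
                         rng = rng, keep_cache = TRUE)
  f <- out_to_field(fwd$out, shape, Mvol$spacing, dims)
  fm <- field_mat(f)

  l_field <- NA_real_
  dF <- matrix(0, nrow(fm), 3L)
  if (!is.null(gold) && w_field > 0) {
    l_field <- field_loss(f, gold)
    dF <- dF + w_field * field_loss_grad(f, gold)
  } else if (!is.null(gold)) {
    l_field <- field_loss(f, gold)
  }

  Mvec <- as.numeric(Mvol$values)
  warped <- cpp_warp(Mvec, shape, fm, FALSE)
  nc <- ncc_loss_with_grad(as.numeric(Rvol$values), warped, shape, window)
  if (w_sim > 0)
    dF <- dF + w_sim * cpp_warp_bwd_field(Mvec, shape, fm, nc$grad)

  grads <- network_backward(model, fwd, dF[, seq_len(dims), drop = FALSE])
  list(l_field = l_field, l_sim = nc$loss, grads = grads,
       warped = warped, field = f)
}

# per-step learning rate: linear warmup then cosine decay to 5% of peak
step_lr <- function(cfg, step) {
  if (cfg$lr_schedule == "constant") return(cfg$learning_rate)
  warm <- max(1L, round(0.05 * cfg$steps))
  if (step <= warm) return(cfg$learning_rate * step / warm)
  frac <- (step - warm) / max(1L, cfg$steps - warm)
  floor_lr <- 0.05 * cfg$learning_rate
  floor_lr + (cfg$learning_rate - floor_lr) * 0.5 * (1 + cos(pi * frac))
}

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = matrix(0, nrow(p$W), ncol(p$W)), vW = matrix(0, nrow(p$W), ncol(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_step <- function(params, grads, state, t, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a registration network on a cohort
#'
#' The core optimization loop; see the package vignette for the procedure.
#' Fully reproducible under `cfg$seed`. When validation pairs are supplied
#' the returned model is the checkpoint with the best validation landmark
#' endpoint error; otherwise it is the final-step model.
#'
#' @param model an `hr_network` from [build_network()].
#' @param cohort list of preprocessed (z-scored) training subjects.
#' @param cfg a [train_config()].
#' @param val_pairs optional list of evaluation pairs from
#'   [make_eval_pair()] used for periodic validation.
#' @return list `(model, history, val_history, best_step)`; `history` has
#'   one row per step with the loss parts and their weighted total.
#' @export
train_network <- function(model, cohort, cfg, val_pairs = NULL) {
  stopifnot(inherits(model, "hr_network"), inherits(cfg, "hr_train_config"))
  if (!length(cohort)) stop("empty training cohort")
  rng <- hr_rng(cfg$seed)
  wts <- cfg$weights
  state <- adam_init(model$params)
  hist <- matrix(NA_real_, cfg$steps, 5L,
                 dimnames = list(NULL, c("step", "l_field", "l_sim0",
                                         "l_sim1", "total")))
  regimes <- character(cfg$steps)
  val_rows <- list()
  best <- list(epe = Inf, params = model$params, step = 0L)
  ema <- if (cfg$ema_decay > 0) model$params else NULL

  for (step in seq_len(cfg$steps)) {
    pair <- sample_selfsup_pair(cohort, rng)
    sup <- make_supervised_pair(pair$M, cfg$simulator, rng)
    Mn <- as.numeric(augment_noise(pair$M, cfg$noise_sd, rng)$values)
    I0n <- as.numeric(augment_noise(sup$I0, cfg$noise_sd, rng)$values)
    I1n <- as.numeric(augment_noise(pair$I1, cfg$noise_sd, rng)$values)

    g0 <- pair_grads(model, pair$M, sup$I0, Mn, I0n, sup$Fg0,
                     wts$alpha, wts$beta, cfg$window, rng)
    g1 <- pair_grads(model, pair$M, pair$I1, Mn, I1n, NULL,
                     0, wts$gamma, cfg$window, rng)

    parts <- c(l_field = g0$l_field, l_sim0 = g0$l_sim, l_sim1 = g1$l_sim)
    bad <- names(parts)[!is.finite(parts)]
    if (length(bad))
      stop(sprintf("non-finite loss part `%s` at step %d", bad[1], step))
    total <- hybrid_total(parts[["l_field"]], parts[["l_sim0"]],
                          parts[["l_sim1"]], wts)
    hist[step, ] <- c(step, parts, total)
    regimes[step] <- sup$regime

    grads <- g0$grads
    for (nm in names(grads)) {
      grads[[nm]]$W <- grads[[nm]]$W + g1$grads[[nm]]$W
      grads[[nm]]$b <- grads[[nm]]$b + g1$grads[[nm]]$b
    }
    if (cfg$clip_norm > 0) {
      gn <- sqrt(sum(vapply(grads, function(g)
        sum(g$W^2) + sum(g$b^2), 0)))
      if (gn > cfg$clip_norm) {
        sc <- cfg$clip_norm / gn
        for (nm in names(grads)) {
          grads[[nm]]$W <- grads[[nm]]$W * sc
          grads[[nm]]$b <- grads[[nm]]$b * sc
        }
      }
    }
    upd <- adam_step(model$params, grads, state, step, step_lr(cfg, step))
    model$params <- upd$params
    state <- upd$state
    if (!is.null(ema)) {
      d <- cfg$ema_decay
      for (nm in names(ema)) {
        ema[[nm]]$W <- d * ema[[nm]]$W + (1 - d) * model$params[[nm]]$W
        ema[[nm]]$b <- d * ema[[nm]]$b + (1 - d) * model$params[[nm]]$b
      }
    }

    if (!is.null(val_pairs) && (step %% cfg$val_every == 0L ||
                                step == cfg$steps)) {
      eval_model <- model
      if (!is.null(ema)) eval_model$params <- ema
      vm <- validate(eval_model, val_pairs)
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(step = step, epe_mm = vm$epe_mm, epe_sd = vm$epe_sd,
                   nmi = vm$nmi, dice = vm$dice)
      if (vm$epe_mm < best$epe)
        best <- list(epe = vm$epe_mm, params = eval_model$params,
                     step = step)
      if (!is.null(cfg$checkpoint_dir)) {
        dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(model, file.path(cfg$checkpoint_dir,
                                 sprintf("step_%06d.rds", step)))
      }
    }
  }

  history <- data.frame(hist)
  history$regime <- regimes
  val_history <- if (length(val_rows)) do.call(rbind, val_rows) else NULL
  if (!is.null(val_pairs) && is.finite(best$epe)) {
    model$params <- best$params
    best_step <- best$step
  } else {
    if (!is.null(ema)) model$params <- ema
    best_step <- cfg$steps
  }
  list(model = model, history = history, val_history = val_history,
       best_step = best_step)
}

#' Build a simulated evaluation pair from one subject
#'
#' Draws a gold-standard deformation, warps the subject's volume into a
#' reference, transports the territory mask, and samples the generating
#' field at the subject's landmarks to obtain exact gold sparse deformation
#' vectors (the synthetic stand-in for manually annotated point
#' correspondences).
#'
#' @param subject preprocessed subject (volume, masks, landmarks).
#' @param sim a [simulator_config()].
#' @param rng an [hr_rng()] stream.
#' @return list with `moving`, `reference` (`hr_volume`s), `landmarks`
#'   (reference-space points with gold vectors), `territory_moving`,
#'   `territory_reference`, `gold_field`, `regime`.
#' @export
make_eval_pair <- function(subject, sim, rng) {
  d <- sample_deformation(sim, dims3(subject$volume),
                          subject$volume$spacing, rng)
  reference <- warp_volume(subject$volume, d$field, "linear")
  terr_ref <- warp_mask(subject$territory_mask, d$field)
  tp <- transform_points(subject$landmarks, d$field)
  lm <- landmark_set(subject$landmarks$names, subject$landmarks$points_mm,
                     tp$gold_vectors_mm)
  list(moving = subject$volume, reference = reference, landmarks = lm,
       territory_moving = subject$territory_mask,
       territory_reference = terr_ref, gold_field = d$field,
       regime = d$regime)
}

#' Validate a model on gold-annotated pairs
#'
#' Computes mean and sd of the landmark endpoint error (mm) plus mean
#' normalized mutual information and territory Dice over the supplied
#' pairs, in evaluation mode (deterministic).
#'
#' @param model an `hr_network`, or the string `"identity"` for the
#'   unregistered baseline, or `"oracle"` for the generating field itself.
#' @param val_pairs non-empty list of pairs from [make_eval_pair()].
#' @return list `(epe_mm, epe_sd, nmi, dice)`.
#' @export
validate <- function(model, val_pairs) {
  if (!length(val_pairs)) stop("empty validation set")
  rows <- lapply(val_pairs, function(p) {
    f <- eval_field_for(model, p)
    epe <- landmark_epe(f, p$landmarks)
    w <- warp_volume(p$moving, f, "linear")
    list(epe = epe$mean_mm,
         nmi = nmi(w, p$reference),
         dice = dice(warp_mask(p$territory_moving, f),
                     p$territory_reference))
  })
  epes <- vapply(rows, `[[`, 0, "epe")
  list(epe_mm = mean(epes), epe_sd = if (length(epes) > 1) sd(epes) else 0,
       nmi = mean(vapply(rows, `[[`, 0, "nmi")),
       dice = mean(vapply(rows, `[[`, 0, "dice")))
}

eval_field_for <- function(model, pair) {
  if (is.character(model)) {
    switch(model,
           identity = zero_field(dims3(pair$moving), pair$moving$spacing),
           oracle = pair$gold_field,
           stop("unknown field source: ", model))
  } else if (inherits(model, "hr_network")) {
    predict_field(model, pair$moving, pair$reference)
  } else if (inherits(model, "hybridreg_fit")) {
    predict_field(model$model, pair$moving, pair$reference)
  } else if (is.function(model)) {
    model(pair$moving, pair$reference)
  } else stop("cannot derive a field from this object")
}

#' Fit a hybrid-supervised registration network
#'
#' The top-level fitting function: builds the displacement-prediction
#' network, constructs simulated validation pairs, and runs the
#' hybrid-supervised training loop. Subjects must be preprocessed
#' (skull-stripped and z-scored; see [preprocess_subject()]).
#'
#' @param cohort list of preprocessed training subjects.
#' @param val_subjects optional list of preprocessed validation subjects;
#'   each contributes one simulated validation pair with exact gold
#'   landmark vectors.
#' @param config a [train_config()].
#' @param network a [network_spec()].
#' @return an object of class `hybridreg_fit`.
#' @seealso [predict.hybridreg_fit()], [evaluate_cohort()]
#' @export
hybridreg <- function(cohort, val_subjects = NULL, config = train_config(),
                      network = network_spec()) {
  model <- build_network(network, seed = derive_seed(config$seed, 11L))
  val_pairs <- NULL
  if (length(val_subjects)) {
    vr <- hr_rng(derive_seed(config$seed, 13L))
    val_pairs <- lapply(val_subjects, make_eval_pair,
                        sim = config$simulator, rng = vr)
  }
  tr <- train_network(model, cohort, config, val_pairs)
  structure(list(model = tr$model, history = tr$history,
                 val_history = tr$val_history, best_step = tr$best_step,
                 config = config, network_spec = network,
                 n_subjects = length(cohort)),
            class = "hybridreg_fit")
}
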