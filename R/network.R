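# Displacement-prediction network: a U-Net-style encoder-decoder with
# dilated convolutions, mapping a channel-concatenated (moving, reference)
# pair to a dense displacement field.
#
# The forward and backward passes are implemented directly on (nvox x
# channels) feature matrices with im2col/GEMM convolution kernels; no
# external deep-learning framework is involved. A 2D network operates on
# single-slice grids via 3x3x1 kernels and (2, 2, 1) pooling, so the same
# code path serves both dimensionalities.

#' Network architecture specification
#'
#' Defaults give the desk-scale 2D network: 4 resolution levels, 16 base
#' channels (doubling per level), one 3x3 convolution per dilation rate in
#' every block, ReLU activations, dropout p = 0.05 in the bottleneck and
#' decoder blocks (light regularization; heavier dropout visibly slows
#' convergence within short step budgets). The final 1x1 projection is
#' initialized near zero so an untrained network predicts a near-identity
#' transform.
#'
#' @param dims 2 or 3.
#' @param levels number of resolution levels (>= 2).
#' @param base_channels channels at the finest level (>= 4).
#' @param dilation_rates dilation factors of the convolutions inside each
#'   encoder/decoder block.
#' @param dropout_p dropout probability in \[0, 1), active in training mode
#'   only.
#' @export
network_spec <- function(dims = 2, levels = 4, base_channels = 16,
                         dilation_rates = c(1, 2), dropout_p = 0.05) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  if (levels < 2) stop("levels must be >= 2")
  if (base_channels < 4) stop("base_channels must be >= 4")
  if (!length(dilation_rates)) stop("dilation_rates must be non-empty")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  structure(list(dims = as.integer(dims), levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 dilation_rates = as.integer(dilation_rates),
                 dropout_p = dropout_p), class = "hr_network_spec")
}

level_channels <- function(spec, l) spec$base_channels * 2L^(l - 1L)
pool_factors <- function(spec) c(2L, 2L, if (spec$dims == 3L) 2L else 1L)
kernel_size <- function(spec) c(3L, 3L, if (spec$dims == 3L) 3L else 1L)
dil_vec <- function(spec, r) c(r, r, if (spec$dims == 3L) r else 1L)

# conv parameter layout: W is a (prod(kernel) * cin) x cout matrix whose
# rows run kernel-offset fastest, then input channel.
conv_plan <- function(spec) {
  plan <- list()
  nr <- length(spec$dilation_rates)
  for (l in seq_len(spec$levels)) {
    cl <- level_channels(spec, l)
    for (j in seq_len(nr)) {
      cin <- if (j == 1L) {
        if (l == 1L) 2L else level_channels(spec, l - 1L)
      } else cl
      plan[[sprintf("enc%d_conv%d", l, j)]] <-
        list(cin = cin, cout = cl, kernel = kernel_size(spec),
             dil = dil_vec(spec, spec$dilation_rates[j]))
    }
  }
  for (l in rev(seq_len(spec$levels - 1L))) {
    cl <- level_channels(spec, l)
    for (j in seq_len(nr)) {
      cin <- if (j == 1L) level_channels(spec, l + 1L) + cl else cl
      plan[[sprintf("dec%d_conv%d", l, j)]] <-
        list(cin = cin, cout = cl, kernel = kernel_size(spec),
             dil = dil_vec(spec, spec$dilation_rates[j]))
    }
  }
  plan[["final"]] <- list(cin = spec$base_channels, cout = spec$dims,
                          kernel = c(1L, 1L, 1L), dil = c(1L, 1L, 1L))
  plan
}

#' Build a displacement-prediction network
#'
#' Parameters use He-normal initialization from a seeded stream, except the
#' final projection layer which starts with sd 1e-5 and zero bias so the
#' untrained network predicts a near-zero (identity) displacement field.
#' Construction is fully determined by `(spec, seed)`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for parameter initialization.
#' @return an object of class `hr_network`.
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "hr_network_spec"))
  rng <- hr_rng(derive_seed(seed, 7L))
  plan <- conv_plan(spec)
  params <- lapply(names(plan), function(nm) {
    p <- plan[[nm]]
    fan_in <- prod(p$kernel) * p$cin
    sdv <- if (nm == "final") 1e-5 else sqrt(2 / fan_in)
    W <- matrix(with_rng(rng, rnorm(fan_in * p$cout, 0, sdv)), fan_in, p$cout)
    list(W = W, b = numeric(p$cout))
  })
  names(params) <- names(plan)
  structure(list(spec = spec, plan = plan, params = params),
            class = "hr_network")
}

#' Number of trainable parameters
#' @param model an `hr_network`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), 0))
}

#' @export
print.hr_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<hr_network %dD: %d levels, %d base channels, dilations %s, %s params>\n",
    s$dims, s$levels, s$base_channels,
    paste(s$dilation_rates, collapse = ","), format(n_params(x), big.mark = ",")))
  invisible(x)
}

check_divisible <- function(spec, shape) {
  need <- 2L^(spec$levels - 1L)
  axes <- c("x", "y", "z")
  check <- c(TRUE, TRUE, spec$dims == 3L)
  for (a in 1:3)
    if (check[a] && shape[a] %% need != 0L)
      stop(sprintf(
        "axis %s (length %d) is not divisible by 2^(levels-1) = %d",
        axes[a], shape[a], need))
  invisible(TRUE)
}

# Forward pass. X is an (nvox x 2) input matrix. Returns the output
# (nvox x dims) matrix plus, when `keep_cache`, everything the backward
# pass needs.
network_forward <- function(model, X, shape, training = FALSE, rng = NULL,
                            keep_cache = FALSE) {
  spec <- model$spec
  check_divisible(spec, shape)
  pf <- pool_factors(spec)
  nr <- length(spec$dilation_rates)
  ops <- vector("list", 0L)
  push <- function(op) if (keep_cache) ops[[length(ops) + 1L]] <<- op

  do_conv <- function(cur, sh, nm) {
    p <- model$params[[nm]]
    pl <- model$plan[[nm]]
    res <- cpp_conv_fwd(cur, sh, p$W, p$b, pl$kernel, pl$dil, keep_cache)
    push(list(type = "conv", name = nm, col = res$col, cin = ncol(cur),
              sh = sh))
    res$Y
  }
  do_relu <- function(Y) {
    A <- Y * (Y > 0)
    push(list(type = "relu", pre = Y))
    A
  }
  do_dropout <- function(cur) {
    if (!training || spec$dropout_p == 0) return(cur)
    keep <- with_rng(rng, runif(length(cur))) >= spec$dropout_p
    mask <- matrix(keep / (1 - spec$dropout_p), nrow(cur))
    push(list(type = "dropout", mask = mask))
    cur * mask
  }

  cur <- X
  sh <- as.integer(shape)
  skips <- vector("list", spec$levels - 1L)
  for (l in seq_len(spec$levels)) {
    for (j in seq_len(nr))
      cur <- do_relu(do_conv(cur, sh, sprintf("enc%d_conv%d", l, j)))
    if (l < spec$levels) {
      skips[[l]] <- cur
      pr <- cpp_maxpool_fwd(cur, sh, pf)
      push(list(type = "pool", idx = pr$idx, nvox_in = nrow(cur), level = l))
      cur <- pr$Y
      sh <- sh %/% pf
    } else {
      cur <- do_dropout(cur)
    }
  }
  for (l in rev(seq_len(spec$levels - 1L))) {
    up <- cpp_upsample_fwd(cur, sh, pf)
    push(list(type = "up", sh_in = sh))
    sh <- sh * pf
    cur <- cbind(up, skips[[l]])
    push(list(type = "concat", n_up = ncol(up), level = l))
    for (j in seq_len(nr))
      cur <- do_relu(do_conv(cur, sh, sprintf("dec%d_conv%d", l, j)))
    cur <- do_dropout(cur)
  }
  out <- do_conv(cur, sh, "final")
  list(out = out, ops = if (keep_cache) ops else NULL)
}

# Backward pass: walks the cached op list in reverse, returning per-
# parameter gradients (same structure as model$params).
network_backward <- function(model, fwd, dOut) {
  grads <- lapply(model$params, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  dskip <- list()
  dcur <- dOut
  pf <- pool_factors(model$spec)
  for (i in rev(seq_along(fwd$ops))) {
    op <- fwd$ops[[i]]
    switch(op$type,
      conv = {
        pl <- model$plan[[op$name]]
        bk <- cpp_conv_bwd(op$col, op$sh, op$cin, model$params[[op$name]]$W,
                           dcur, pl$kernel, pl$dil)
        grads[[op$name]]$W <- grads[[op$name]]$W + bk$dW
        grads[[op$name]]$b <- grads[[op$name]]$b + bk$db
        dcur <- bk$dX
      },
      relu = {
        dcur <- dcur * (op$pre > 0)
      },
      dropout = {
        dcur <- dcur * op$mask
      },
      pool = {
        dcur <- cpp_maxpool_bwd(op$idx, op$nvox_in, dcur)
        key <- as.character(op$level)
        if (!is.null(dskip[[key]])) dcur <- dcur + dskip[[key]]
      },
      concat = {
        n1 <- op$n_up
        dskip[[as.character(op$level)]] <- dcur[, -seq_len(n1), drop = FALSE]
        dcur <- dcur[, seq_len(n1), drop = FALSE]
      },
      up = {
        dcur <- cpp_upsample_bwd(dcur, op$sh_in, pf)
      })
  }
  grads
}

net_input <- function(moving, reference) {
  cbind(as.numeric(moving$values), as.numeric(reference$values))
}

# (nvox x dims) network output -> hr_field with 3 components
out_to_field <- function(out, shape, spacing, dims) {
  m <- matrix(0, nrow(out), 3L)
  m[, seq_len(dims)] <- out
  mat_to_field(m, shape, spacing)
}

#' Predict a displacement field for an image pair
#'
#' Runs the network in evaluation mode (dropout off); the output is
#' deterministic for fixed inputs and weights. For a 2D network the
#' out-of-plane component of the returned field is zero.
#'
#' @param model an `hr_network`.
#' @param moving,reference z-scored `hr_volume`s on the same
#'   network-compatible grid.
#' @return an `hr_field` with the inputs' spacing.
#' @export
predict_field <- function(model, moving, reference) {
  stopifnot(inherits(model, "hr_network"))
  check_same_grid(moving, reference, "moving and reference")
  shape <- dims3(moving)
  fwd <- network_forward(model, net_input(moving, reference), shape)
  out_to_field(fwd$out, shape, moving$spacing, model$spec$dims)
}
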