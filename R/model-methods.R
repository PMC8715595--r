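# S3 methods for the fitted registration model.

#' @export
print.hybridreg_fit <- function(x, ...) {
  cat("Hybrid-supervised deformable registration fit\n")
  s <- x$network_spec
  cat(sprintf("  network: %dD, %d levels, %d base channels, %s parameters\n",
              s$dims, s$levels, s$base_channels,
              format(n_params(x$model), big.mark = ",")))
  cat(sprintf("  trained: %d steps on %d subjects (batch size 1)\n",
              nrow(x$history), x$n_subjects))
  w <- x$config$weights
  cat(sprintf("  loss weights: alpha = %.4g, beta = %.4g, gamma = %.4g\n",
              w$alpha, w$beta, w$gamma))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: field %.4g mm, sim0 %.4g, sim1 %.4g (total %.4g)\n",
              last$l_field, last$l_sim0, last$l_sim1, last$total))
  if (!is.null(x$val_history)) {
    b <- x$val_history[which.min(x$val_history$epe_mm), ]
    cat(sprintf("  best validation EPE: %.3f mm at step %d\n",
                b$epe_mm, x$best_step))
  }
  invisible(x)
}

#' @export
summary.hybridreg_fit <- function(object, ...) {
  out <- list(network = object$network_spec, config = object$config,
              n_steps = nrow(object$history),
              n_params = n_params(object$model),
              loss_head = head(object$history, 3),
              loss_tail = tail(object$history, 3),
              val_history = object$val_history,
              best_step = object$best_step)
  class(out) <- "summary.hybridreg_fit"
  out
}

#' @export
print.summary.hybridreg_fit <- function(x, ...) {
  cat(sprintf("hybridreg fit: %d steps, %s parameters, best step %d\n",
              x$n_steps, format(x$n_params, big.mark = ","), x$best_step))
  cat("first steps:\n"); print(x$loss_head, digits = 4)
  cat("last steps:\n"); print(x$loss_tail, digits = 4)
  if (!is.null(x$val_history)) {
    cat("validation:\n"); print(x$val_history, digits = 4)
  }
  invisible(x)
}

#' Network parameters of a fit
#'
#' @param object a `hybridreg_fit`.
#' @param ... unused.
#' @return named list of weight matrices and bias vectors.
#' @export
coef.hybridreg_fit <- function(object, ...) object$model$params

#' Register an image pair with a fitted model
#'
#' @param object a `hybridreg_fit`.
#' @param moving,reference z-scored `hr_volume`s on a network-compatible
#'   grid.
#' @param what `"field"` for the displacement field only, `"both"` to also
#'   return the warped moving image.
#' @param ... unused.
#' @return an `hr_field`, or list `(field, warped)`.
#' @export
predict.hybridreg_fit <- function(object, moving, reference,
                                  what = c("field", "both"), ...) {
  what <- match.arg(what)
  f <- predict_field(object$model, moving, reference)
  if (what == "field") return(f)
  list(field = f, warped = warp_volume(moving, f, "linear"))
}

#' Plot training loss history
#'
#' Draws the three weighted sub-losses and the total against the training
#' step, plus validation endpoint error when available.
#'
#' @param x a `hybridreg_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hybridreg_fit <- function(x, ...) {
  h <- x$history
  w <- x$config$weights
  y <- cbind(total = h$total, field = w$alpha * h$l_field,
             sim0 = w$beta * h$l_sim0, sim1 = w$gamma * h$l_sim1)
  op <- graphics::par(mfrow = if (is.null(x$val_history)) c(1, 1) else c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$step, y, type = "l", lty = 1,
                    col = c("black", "red3", "steelblue", "seagreen"),
                    xlab = "step", ylab = "weighted loss", ...)
  graphics::legend("topright", colnames(y), lty = 1, bty = "n",
                   col = c("black", "red3", "steelblue", "seagreen"))
  if (!is.null(x$val_history))
    graphics::plot(x$val_history$step, x$val_history$epe_mm, type = "b",
                   xlab = "step", ylab = "validation EPE (mm)")
  invisible(x)
}

#' Draw deformation fields from a fit's simulator
#'
#' Samples gold-standard deformation fields from the simulator
#' configuration the model was trained with, on a given grid.
#'
#' @param object a `hybridreg_fit`.
#' @param nsim number of fields.
#' @param seed integer seed.
#' @param shape,spacing target grid (defaults to a desk-scale 2D grid).
#' @param ... unused.
#' @return list of `hr_field`s with a `regime` attribute each.
#' @export
simulate.hybridreg_fit <- function(object, nsim = 1, seed = 0L,
                                   shape = c(64, 64, 1),
                                   spacing = c(1, 1, 2), ...) {
  rng <- hr_rng(seed)
  lapply(seq_len(nsim), function(i) {
    d <- sample_deformation(object$config$simulator, shape, spacing, rng)
    attr(d$field, "regime") <- d$regime
    d$field
  })
}
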