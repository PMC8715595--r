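# The hybrid training loss and its components.
#
# Three sub-losses: a supervised field-deviation term (mean L2 distance, in
# mm, between predicted and gold displacement vectors) and two local
# squared normalized cross-correlation image-similarity terms, one per
# image pair. The field term is computed in mm rather than voxels so that
# anisotropic spacings (e.g. 0.36 x 0.36 x 2 mm) weight the axes
# physically, consistent with endpoint errors being reported in mm.

#' Weights of the hybrid loss
#'
#' Defaults `alpha = 1/13`, `beta = gamma = 0.4` balance the contributions
#' of the field-deviation and the two image-similarity terms.
#'
#' @param alpha weight of the supervised field-deviation loss.
#' @param beta weight of the supervised-pair image similarity.
#' @param gamma weight of the self-supervised-pair image similarity.
#' @export
loss_weights <- function(alpha = 1 / 13, beta = 0.4, gamma = 0.4) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and >= 0")
  structure(as.list(w), class = "hr_loss_weights")
}

#' Local-similarity window settings
#'
#' Windows have half-width `radius` voxels per axis (so 2r+1 wide) and are
#' border-clamped; along a singleton axis the window does not extend.
#' `epsilon` stabilizes the denominator on constant windows (e.g. stripped
#' background), which then contribute approximately zero.
#'
#' @param radius half-width in voxels (scalar or length 3), >= 1.
#' @param epsilon small positive stabilizer.
#' @export
similarity_window <- function(radius = 4, epsilon = 1e-5) {
  if (any(radius < 1)) stop("window radius must be >= 1")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  structure(list(radius = as.integer(radius), epsilon = epsilon),
            class = "hr_window")
}

window_radii <- function(w, shape) pmin(w$radius, shape - 1L)

#' Field-deviation loss
#'
#' Mean over voxels of the Euclidean norm of `pred - gold`, on mm-converted
#' vectors. Nonnegative and symmetric in its arguments; zero iff the fields
#' are identical.
#'
#' @param pred,gold `hr_field`s on the same grid.
#' @return scalar mm deviation.
#' @export
field_loss <- function(pred, gold) {
  check_same_grid(pred, gold, "fields")
  d <- sweep(field_mat(pred) - field_mat(gold), 2L, pred$spacing, `*`)
  mean(sqrt(rowSums(d^2)))
}

# gradient of field_loss wrt pred, as an (nvox x 3) voxel-unit matrix
field_loss_grad <- function(pred, gold) {
  d <- sweep(field_mat(pred) - field_mat(gold), 2L, pred$spacing, `*`)
  nrm <- sqrt(rowSums(d^2))
  nz <- nrm > 0
  g <- matrix(0, nrow(d), 3L)
  g[nz, ] <- d[nz, , drop = FALSE] / nrm[nz]
  sweep(g, 2L, pred$spacing, `*`) / nrow(d)
}

#' Local squared-NCC image-similarity loss
#'
#' Negative mean, over all voxels, of the squared windowed normalized
#' cross-correlation between `ref` and `pred` (windows centered at every
#' voxel, border-clamped). Ranges in (-1, 0]; equals about -1 for perfectly
#' (anti-)correlated images and approximately 0 where either window is
#' constant.
#'
#' @param ref,pred `hr_volume`s on the same grid, in the same intensity
#'   domain.
#' @param w a [similarity_window()].
#' @return scalar loss.
#' @export
local_sq_ncc_loss <- function(ref, pred, w = similarity_window()) {
  check_same_grid(ref, pred, "images")
  shape <- dims3(ref)
  res <- cpp_ncc_loss(as.numeric(ref$values), as.numeric(pred$values),
                      shape, window_radii(w, shape), w$epsilon, FALSE)
  res$loss
}

ncc_loss_with_grad <- function(ref_vec, pred_vec, shape, w) {
  cpp_ncc_loss(ref_vec, pred_vec, shape, window_radii(w, shape),
               w$epsilon, TRUE)
}

#' Combine sub-losses into the hybrid total
#'
#' `total = alpha * l_field + beta * l_sim0 + gamma * l_sim1`.
#'
#' @param l_field,l_sim0,l_sim1 scalar sub-loss values.
#' @param wts a [loss_weights()].
#' @export
hybrid_total <- function(l_field, l_sim0, l_sim1, wts = loss_weights()) {
  stopifnot(inherits(wts, "hr_loss_weights"))
  wts$alpha * l_field + wts$beta * l_sim0 + wts$gamma * l_sim1
}

#' Hybrid supervised loss
#'
#' Weighted sum of the field-deviation loss between the predicted and
#' gold-standard fields of the supervised pair and the two local squared-NCC
#' image similarities (supervised pair and self-supervised pair).
#'
#' @param Fp0 predicted field for the supervised pair.
#' @param Fg0 gold-standard (simulated) field.
#' @param I0 supervised-pair reference image.
#' @param Ip0 supervised-pair predicted (warped) image.
#' @param I1 self-supervised reference image.
#' @param Ip1 self-supervised predicted (warped) image.
#' @param wts a [loss_weights()].
#' @param w a [similarity_window()].
#' @return list `(total, parts)` with `parts` the named vector
#'   `(l_field, l_sim0, l_sim1)`.
#' @export
hybrid_loss <- function(Fp0, Fg0, I0, Ip0, I1, Ip1, wts = loss_weights(),
                        w = similarity_window()) {
  parts <- c(l_field = field_loss(Fp0, Fg0),
             l_sim0 = local_sq_ncc_loss(I0, Ip0, w),
             l_sim1 = local_sq_ncc_loss(I1, Ip1, w))
  list(total = hybrid_total(parts[["l_field"]], parts[["l_sim0"]],
                            parts[["l_sim1"]], wts),
       parts = parts)
}
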