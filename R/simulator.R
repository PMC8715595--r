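# Gold-standard deformation-field simulator: random multiscale affine +
# elastic displacement fields, with a configurable fraction of large
# deformations. Fields are stored in voxel units (backward-warping
# convention); all mm statements convert per axis through the spacing.

#' Affine transform parameters
#'
#' The affine map acts about `center` (mm):
#' `A(x) = center + translation + R S_h S (x - center)` with rotation `R`
#' (degrees, applied as Rz Ry Rx), shear `S_h` (upper-triangular unit
#' matrix) and diagonal scaling `S`.
#'
#' @param rotation degrees, length 3.
#' @param scale unitless, length 3, positive.
#' @param shear unitless, length 3 (xy, xz, yz entries).
#' @param translation mm, length 3.
#' @param center rotation/scaling center in mm.
#' @export
affine_params <- function(rotation = c(0, 0, 0), scale = c(1, 1, 1),
                          shear = c(0, 0, 0), translation = c(0, 0, 0),
                          center = c(0, 0, 0)) {
  if (any(scale <= 0)) stop("scale components must be > 0")
  structure(list(rotation = as.numeric(rotation), scale = as.numeric(scale),
                 shear = as.numeric(shear),
                 translation = as.numeric(translation),
                 center = as.numeric(center)), class = "hr_affine")
}

#' Uniform sampling ranges for affine parameters
#'
#' Each entry is an interval `(lo, hi)` applied independently to each of the
#' three components of the corresponding parameter.
#'
#' @param rotation degrees interval.
#' @param scale unitless interval.
#' @param shear unitless interval.
#' @param translation mm interval.
#' @export
affine_ranges <- function(rotation = c(-10, 10), scale = c(0.9, 1.1),
                          shear = c(-0.05, 0.05), translation = c(-10, 10)) {
  r <- list(rotation = rotation, scale = scale, shear = shear,
            translation = translation)
  for (nm in names(r)) {
    iv <- r[[nm]]
    if (length(iv) != 2L || any(!is.finite(iv)))
      stop(sprintf("`%s` must be a finite interval", nm))
    if (iv[1] > iv[2])
      stop(sprintf("inverted interval for `%s`", nm))
  }
  structure(r, class = "hr_affine_ranges")
}

#' Draw affine parameters uniformly from ranges
#'
#' @param ranges an [affine_ranges()].
#' @param rng an [hr_rng()] stream.
#' @param center rotation/scaling center in mm.
#' @export
sample_affine <- function(ranges, rng, center = c(0, 0, 0)) {
  stopifnot(inherits(ranges, "hr_affine_ranges"))
  draw <- function(iv) with_rng(rng, runif(3, iv[1], iv[2]))
  affine_params(rotation = draw(ranges$rotation), scale = draw(ranges$scale),
                shear = draw(ranges$shear),
                translation = draw(ranges$translation), center = center)
}

affine_matrix <- function(p) {
  th <- p$rotation * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, p$shear[1], p$shear[2]),
              c(0, 1, p$shear[3]),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx %*% Sh %*% diag(p$scale)
}

#' Rasterize affine parameters into a displacement field
#'
#' The field is `u(x) = (A(x_mm) - x_mm) / spacing` (voxel units); identity
#' parameters give the exactly-zero field.
#'
#' @param p an [affine_params()].
#' @param shape grid shape.
#' @param spacing voxel spacing in mm.
#' @return an `hr_field`.
#' @export
affine_to_field <- function(p, shape, spacing) {
  stopifnot(inherits(p, "hr_affine"))
  xyz <- vox_mm_mat(shape, spacing)
  M <- affine_matrix(p)
  rel <- sweep(xyz, 2L, p$center, `-`)
  mapped <- rel %*% t(M)
  u_mm <- sweep(mapped, 2L, p$center + p$translation, `+`) - xyz
  mat_to_field(sweep(u_mm, 2L, spacing, `/`), shape, spacing)
}

#' Multiscale elastic deformation specification
#'
#' @param control_spacings coarse control-grid spacings in voxels (each
#'   >= 2); one random field is drawn per scale and the scales are summed.
#' @param max_displacement maximum vector magnitude in mm; the summed field
#'   is rescaled so its maximum mm magnitude equals this value exactly
#'   (`rescale = "exact"`) or only capped when exceeded (`"cap"`).
#' @param smoothness_sigma Gaussian smoothing sigma in voxels.
#' @param rescale `"exact"` or `"cap"`.
#' @export
elastic_spec <- function(control_spacings = c(8, 16, 32),
                         max_displacement = 5, smoothness_sigma = 2,
                         rescale = c("exact", "cap")) {
  rescale <- match.arg(rescale)
  if (!length(control_spacings) || any(control_spacings < 2))
    stop("control_spacings must be non-empty, each >= 2")
  if (max_displacement < 0) stop("max_displacement must be >= 0")
  structure(list(control_spacings = as.numeric(control_spacings),
                 max_displacement = max_displacement,
                 smoothness_sigma = smoothness_sigma, rescale = rescale),
            class = "hr_elastic_spec")
}

#' Draw a random multiscale elastic displacement field
#'
#' Per control spacing, i.i.d. standard-normal per-axis displacements are
#' drawn on the coarse grid, interpolated to full resolution, Gaussian
#' smoothed, and summed across scales; the summed field is then rescaled to
#' the configured maximum mm magnitude. On a single-slice grid the
#' out-of-plane component is zero.
#'
#' @param spec an [elastic_spec()].
#' @param shape grid shape.
#' @param spacing voxel spacing in mm.
#' @param rng an [hr_rng()] stream.
#' @return an `hr_field`.
#' @export
sample_elastic <- function(spec, shape, spacing, rng) {
  stopifnot(inherits(spec, "hr_elastic_spec"))
  if (spec$max_displacement < 0) stop("max_displacement must be >= 0")
  nvox <- prod(shape)
  two_d <- shape[3] == 1L
  u <- matrix(0, nvox, 3)
  idx <- vox_index_mat(shape)
  for (s in spec$control_spacings) {
    nc <- pmax(2L, as.integer(ceiling((shape - 1) / s)) + 1L)
    if (two_d) nc[3] <- 1L
    draws <- with_rng(rng, rnorm(prod(nc) * 3))
    coarse <- matrix(draws, prod(nc), 3)
    if (two_d) coarse[, 3] <- 0
    pts <- sweep(idx, 2L, s, `/`)
    pts[, 3] <- if (two_d) 0 else pts[, 3]
    for (cmp in 1:3) {
      if (two_d && cmp == 3L) next
      comp <- cpp_sample_linear(coarse[, cmp], nc, pts)
      comp <- cpp_gauss_smooth(comp, shape,
                               rep(spec$smoothness_sigma, 3))
      u[, cmp] <- u[, cmp] + comp
    }
  }
  mm2 <- rowSums(sweep(u, 2L, spacing, `*`)^2)
  mx <- sqrt(max(mm2))
  if (spec$max_displacement == 0 || mx == 0) {
    u[] <- 0
  } else if (spec$rescale == "exact" || mx > spec$max_displacement) {
    u <- u * (spec$max_displacement / mx)
  }
  mat_to_field(u, shape, spacing)
}

#' Compose two displacement fields
#'
#' Backward-map composition `u(x) = inner(x) + outer(x + inner(x))` with the
#' outer field sampled by linear interpolation (border-clamped), so that
#' warping by the composite equals warping by `outer` then by `inner`.
#' Composing with a zero field returns the other field exactly.
#'
#' @param outer,inner `hr_field`s on the same grid.
#' @return an `hr_field`.
#' @export
compose_fields <- function(outer, inner) {
  check_same_grid(outer, inner, "fields")
  shape <- dims3(inner)
  im <- field_mat(inner)
  om <- field_mat(outer)
  pts <- vox_index_mat(shape) + im
  samp <- vapply(1:3, function(cmp) cpp_sample_linear(om[, cmp], shape, pts),
                 numeric(nrow(im)))
  mat_to_field(im + samp, shape, inner$spacing)
}

#' Simulator configuration: small and large deformation regimes
#'
#' With probability `large_fraction` a draw uses the large regime, else the
#' small one. Defaults: small regime rotation +/-10 deg, scale 0.9-1.1,
#' shear +/-0.05, translation +/-10 mm, elastic max 5 mm; large regime
#' rotation +/-20 deg, scale 0.8-1.25, translation +/-20 mm, elastic max
#' 15 mm; `large_fraction` 0.2.
#'
#' @param small,large lists with elements `affine` ([affine_ranges()]) and
#'   `elastic` ([elastic_spec()]).
#' @param large_fraction probability in \[0, 1\] of drawing the large regime.
#' @export
simulator_config <- function(
    small = list(affine = affine_ranges(),
                 elastic = elastic_spec(max_displacement = 5)),
    large = list(affine = affine_ranges(rotation = c(-20, 20),
                                        scale = c(0.8, 1.25),
                                        translation = c(-20, 20)),
                 elastic = elastic_spec(max_displacement = 15)),
    large_fraction = 0.2) {
  if (large_fraction < 0 || large_fraction > 1)
    stop("large_fraction must lie in [0, 1]")
  stopifnot(inherits(small$affine, "hr_affine_ranges"),
            inherits(large$affine, "hr_affine_ranges"),
            inherits(small$elastic, "hr_elastic_spec"),
            inherits(large$elastic, "hr_elastic_spec"))
  if (large$elastic$max_displacement < small$elastic$max_displacement)
    stop("large-regime max_displacement must be >= small-regime")
  structure(list(small = small, large = large,
                 large_fraction = large_fraction), class = "hr_sim_config")
}

# On a single-slice grid, suppress out-of-plane affine motion: only the
# in-plane rotation (about z), in-plane shear and in-plane translation act.
project_affine_2d <- function(p) {
  p$rotation[1:2] <- 0
  p$shear[2:3] <- 0
  p$translation[3] <- 0
  p$scale[3] <- 1
  p
}

#' Draw one gold-standard deformation field
#'
#' Samples a regime (small/large), draws affine parameters about the grid
#' center and a multiscale elastic field, and composes them with the
#' elastic field outermost: `u(x) = affine(x) + elastic(x + affine(x))`.
#'
#' @param cfg a [simulator_config()].
#' @param shape grid shape.
#' @param spacing voxel spacing in mm.
#' @param rng an [hr_rng()] stream.
#' @return list `(field, regime)` with `regime` `"small"` or `"large"`.
#' @export
sample_deformation <- function(cfg, shape, spacing, rng) {
  stopifnot(inherits(cfg, "hr_sim_config"))
  big <- with_rng(rng, runif(1)) < cfg$large_fraction
  reg <- if (big) cfg$large else cfg$small
  center <- (shape - 1) * spacing / 2
  ap <- sample_affine(reg$affine, rng, center = center)
  if (shape[3] == 1L) ap <- project_affine_2d(ap)
  af <- affine_to_field(ap, shape, spacing)
  el <- sample_elastic(reg$elastic, shape, spacing, rng)
  list(field = compose_fields(el, af),
       regime = if (big) "large" else "small")
}
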