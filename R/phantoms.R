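# Synthetic skull-bearing brain-CT phantoms.
#
# The phantom is an ellipsoidal head: a bone shell (skull) around a brain
# compartment, paired ellipsoidal CSF-filled ventricles, and a vascular-
# territory label shaped as a radial-shell sector of the brain (emulating a
# middle-cerebral-artery supply territory). Landmarks are deterministic
# feature points computed from the rasterized geometry (ventricular horn
# tips and inner-skull midpoints), so ground-truth correspondence under any
# known deformation is exact. A single-slice grid (nz = 1) gives the 2D
# phantom used for desk-scale experiments; out-of-plane geometry is then
# treated as cylindrical (the z terms of the ellipsoids are dropped).

#' Phantom geometry and intensity specification
#'
#' Defaults give a desk-scale head at 64x64x16 voxels, (1, 1, 2) mm spacing.
#' The `"paper"` preset mirrors a clinical nonenhanced head CT raster
#' (512x512x64 at 0.36 x 0.36 x 2 mm); it is configurable but far heavier.
#' Hounsfield defaults are plausible nonenhanced-CT values: bone 1000,
#' brain 35, CSF 8, air -1000, noise sd 4.
#'
#' @param grid_shape integer voxel counts per axis; `nz = 1` gives a 2D
#'   phantom.
#' @param spacing voxel spacing in mm.
#' @param head_radii outer skull ellipsoid radii in mm.
#' @param skull_thickness bone shell thickness in mm.
#' @param skull_hu,brain_hu,csf_hu,background_hu Hounsfield intensities
#'   (must satisfy `skull_hu > brain_hu > csf_hu`).
#' @param ventricle_offset mm offset of each ventricle center from the head
#'   center (mirrored in x for the left/right pair).
#' @param ventricle_radii ventricle ellipsoid radii in mm.
#' @param territory_radial inner/outer normalized radius of the territory
#'   shell (fractions of the brain radius, in (0, 1]).
#' @param territory_angle azimuth window in degrees (measured in the xy
#'   plane from the +x axis) delimiting the territory sector.
#' @param noise_sd additive Gaussian noise, HU.
#' @param n_landmarks number of landmarks (>= 4).
#' @param variation_scale unitless in \[0, 1\]; scales intersubject geometry
#'   jitter in [generate_subject()].
#' @param preset `"desk"` (default) or `"paper"` grid scale.
#' @return object of class `hr_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 16), spacing = c(1, 1, 2),
                         head_radii = c(26, 29, 12), skull_thickness = 3,
                         skull_hu = 1000, brain_hu = 35, csf_hu = 8,
                         background_hu = -1000,
                         ventricle_offset = c(7, 3, 0),
                         ventricle_radii = c(4.5, 10, 5),
                         territory_radial = c(0.35, 0.97),
                         territory_angle = c(-70, 70),
                         noise_sd = 4, n_landmarks = 8,
                         variation_scale = 0.3,
                         preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper" && missing(grid_shape)) {
    grid_shape <- c(512, 512, 64)
    spacing <- c(0.36, 0.36, 2)
    head_radii <- c(80, 90, 55)
    skull_thickness <- 6
    ventricle_offset <- c(18, 8, 0)
    ventricle_radii <- c(12, 30, 22)
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    head_radii = as.numeric(head_radii),
    skull_thickness = as.numeric(skull_thickness),
    skull_hu = skull_hu, brain_hu = brain_hu, csf_hu = csf_hu,
    background_hu = background_hu,
    ventricle_offset = as.numeric(ventricle_offset),
    ventricle_radii = as.numeric(ventricle_radii),
    territory_radial = as.numeric(territory_radial),
    territory_angle = as.numeric(territory_angle),
    noise_sd = noise_sd, n_landmarks = as.integer(n_landmarks),
    variation_scale = variation_scale), class = "hr_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 1L) ||
      any(s$grid_shape[1:2] < 8L))
    stop("invalid phantom spec: grid_shape must be at least 8x8(x1)")
  if (any(s$spacing <= 0)) stop("invalid phantom spec: spacing must be > 0")
  if (any(s$head_radii <= 0) || any(s$ventricle_radii <= 0) ||
      s$skull_thickness <= 0)
    stop("invalid phantom spec: all radii/thickness must be > 0")
  if (!(s$skull_hu > s$brain_hu && s$brain_hu > s$csf_hu))
    stop("invalid phantom spec: need skull_hu > brain_hu > csf_hu")
  if (s$n_landmarks < 4L)
    stop("invalid phantom spec: n_landmarks must be >= 4")
  if (s$variation_scale < 0 || s$variation_scale > 1)
    stop("invalid phantom spec: variation_scale must lie in [0, 1]")
  if (s$territory_radial[1] <= 0 || s$territory_radial[2] > 1 ||
      diff(s$territory_radial) <= 0)
    stop("invalid phantom spec: territory_radial must be increasing in (0, 1]")
  # geometry must fit inside the grid's physical extent
  extent <- (s$grid_shape - 1) * s$spacing
  center <- extent / 2
  ax <- if (s$grid_shape[3] == 1L) 1:2 else 1:3
  if (any(center[ax] - s$head_radii[ax] < 0) ||
      any(center[ax] + s$head_radii[ax] > extent[ax]))
    stop("invalid phantom spec: head_radii do not fit inside the grid")
  if (any(s$head_radii[ax] - s$skull_thickness <= 0))
    stop("invalid phantom spec: skull_thickness exceeds head_radii")
  invisible(TRUE)
}

#' @export
print.hr_phantom_spec <- function(x, ...) {
  cat(sprintf("<hr_phantom_spec %s @ %s mm, variation %.2f>\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), x$variation_scale))
  invisible(x)
}

# normalized ellipsoidal radius of mm coordinates `xyz` (nvox x 3) about
# `center` with radii `r`; a single-slice grid drops the z term.
norm_radius <- function(xyz, center, r, two_d) {
  q <- (xyz[, 1] - center[1])^2 / r[1]^2 + (xyz[, 2] - center[2])^2 / r[2]^2
  if (!two_d) q <- q + (xyz[, 3] - center[3])^2 / r[3]^2
  sqrt(q)
}

#' Generate one phantom
#'
#' Rasterizes the spec geometry onto the grid, adds Gaussian HU noise, and
#' derives deterministic feature landmarks. Landmarks are the anterior and
#' posterior horn tips of each ventricle plus inner-skull midpoints (pulled
#' two voxels inward so that every landmark lies strictly inside the brain);
#' extra landmarks beyond these eight are placed on an interior brain
#' ellipse at evenly spaced azimuths.
#'
#' @param spec an [phantom_spec()].
#' @param seed integer seed; output is bit-reproducible for a fixed
#'   (spec, seed).
#' @return list with elements `volume` (`hr_volume`, HU),
#'   `territory_mask`, `brain_mask` (`hr_mask`) and `landmarks`
#'   (`hr_landmarks`).
#' @export
generate_phantom <- function(spec, seed) {
  validate_phantom_spec(spec)
  rng <- hr_rng(seed)
  shape <- spec$grid_shape
  two_d <- shape[3] == 1L
  xyz <- vox_mm_mat(shape, spec$spacing)
  extent <- (shape - 1) * spec$spacing
  center <- extent / 2

  rho_head <- norm_radius(xyz, center, spec$head_radii, two_d)
  inner_r <- spec$head_radii - spec$skull_thickness
  rho_in <- norm_radius(xyz, center, inner_r, two_d)

  head <- rho_head <= 1
  brain <- rho_in < 1
  skull <- head & !brain

  cR <- center + c(spec$ventricle_offset[1], spec$ventricle_offset[2],
                   spec$ventricle_offset[3])
  cL <- center + c(-spec$ventricle_offset[1], spec$ventricle_offset[2],
                   spec$ventricle_offset[3])
  ventR <- norm_radius(xyz, cR, spec$ventricle_radii, two_d) <= 1 & brain
  ventL <- norm_radius(xyz, cL, spec$ventricle_radii, two_d) <= 1 & brain

  theta <- atan2(xyz[, 2] - center[2], xyz[, 1] - center[1]) * 180 / pi
  territory <- brain & rho_in >= spec$territory_radial[1] &
    rho_in <= spec$territory_radial[2] &
    theta >= spec$territory_angle[1] & theta <= spec$territory_angle[2]

  hu <- rep(spec$background_hu, nrow(xyz))
  hu[brain] <- spec$brain_hu
  hu[ventR | ventL] <- spec$csf_hu
  hu[skull] <- spec$skull_hu
  if (spec$noise_sd > 0)
    hu <- hu + with_rng(rng, rnorm(length(hu), 0, spec$noise_sd))

  lm <- phantom_landmarks(spec, xyz, center, brain, ventR, ventL, rho_in)

  list(volume = volume(array(hu, shape), spec$spacing, domain = "HU"),
       territory_mask = label_mask(array(territory, shape), spec$spacing),
       brain_mask = label_mask(array(brain, shape), spec$spacing),
       landmarks = lm)
}

# deterministic feature landmarks from rasterized geometry
phantom_landmarks <- function(spec, xyz, center, brain, ventR, ventL, rho_in) {
  horn <- function(mask, anterior) {
    w <- which(mask)
    if (!length(w)) return(NULL)
    yv <- xyz[w, 2]
    ext <- if (anterior) max(yv) else min(yv)
    cand <- w[yv == ext]
    xyz[cand[which.min(cand)], , drop = TRUE]
  }
  inward <- function(p) {
    # pull a boundary point toward the head center until strictly interior
    dir <- center - p
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) return(p)
    step <- dir / nd * 2 * max(spec$spacing)
    for (i in 1:10) {
      p <- p + step
      if (norm_radius(rbind(p), center, spec$head_radii - spec$skull_thickness,
                      spec$grid_shape[3] == 1L) < 0.96) break
    }
    p
  }
  extreme <- function(axis, positive) {
    w <- which(brain)
    v <- xyz[w, axis]
    ext <- if (positive) max(v) else min(v)
    cand <- w[v == ext]
    inward(xyz[cand[which.min(cand)], , drop = TRUE])
  }
  pts <- rbind(horn(ventR, TRUE), horn(ventR, FALSE),
               horn(ventL, TRUE), horn(ventL, FALSE),
               extreme(1, TRUE), extreme(1, FALSE),
               extreme(2, TRUE), extreme(2, FALSE))
  nms <- c("vent_r_ant", "vent_r_post", "vent_l_ant", "vent_l_post",
           "skull_right", "skull_left", "skull_ant", "skull_post")[
             seq_len(nrow(pts))]
  n <- spec$n_landmarks
  if (n > nrow(pts)) {
    extra <- n - nrow(pts)
    ang <- 2 * pi * (seq_len(extra) - 0.5) / extra
    r <- (spec$head_radii - spec$skull_thickness) * 0.55
    zpt <- if (spec$grid_shape[3] == 1L) center[3] else center[3]
    add <- cbind(center[1] + r[1] * cos(ang), center[2] + r[2] * sin(ang), zpt)
    pts <- rbind(pts, add)
    nms <- c(nms, sprintf("interior_%02d", seq_len(extra)))
  } else if (n < nrow(pts)) {
    pts <- pts[seq_len(n), , drop = FALSE]
    nms <- nms[seq_len(n)]
  }
  landmark_set(nms, pts)
}

#' Generate a phantom subject with intersubject geometry jitter
#'
#' Geometry parameters (head radii, skull thickness, ventricle placement and
#' size, territory sector, in-plane head position) are jittered by random
#' offsets proportional to `spec$variation_scale` before rasterization,
#' emulating anatomical variation across individuals. `variation_scale = 0`
#' reduces exactly to [generate_phantom()].
#'
#' @inheritParams generate_phantom
#' @return same structure as [generate_phantom()].
#' @export
generate_subject <- function(spec, seed) {
  validate_phantom_spec(spec)
  vs <- spec$variation_scale
  if (vs == 0) return(generate_phantom(spec, seed))
  jrng <- hr_rng(derive_seed(seed, 104729L))
  u <- function(n) with_rng(jrng, runif(n, -1, 1))
  s <- spec
  s$head_radii <- spec$head_radii * (1 + 0.10 * vs * u(3))
  s$skull_thickness <- spec$skull_thickness * (1 + 0.10 * vs * u(1))
  s$ventricle_radii <- spec$ventricle_radii * (1 + 0.25 * vs * u(3))
  s$ventricle_offset <- spec$ventricle_offset + vs * u(3) * c(2, 2, 1)
  s$territory_angle <- spec$territory_angle + vs * u(2) * 15
  if (diff(s$territory_angle) <= 5)
    s$territory_angle <- spec$territory_angle
  rad <- spec$territory_radial + vs * u(2) * c(0.05, 0.02)
  if (rad[1] > 0 && rad[2] <= 1 && diff(rad) > 0) s$territory_radial <- rad
  validate_phantom_spec(s)
  generate_phantom(s, seed)
}

#' Generate a cohort of phantom subjects
#'
#' Per-subject seeds are derived deterministically from `(seed, index)`, so
#' a cohort is reproducible and its subjects mutually distinct whenever
#' `variation_scale > 0`.
#'
#' @inheritParams generate_phantom
#' @param n number of subjects (>= 1).
#' @return list of `n` subjects as returned by [generate_subject()].
#' @export
generate_cohort <- function(spec, n, seed) {
  if (n < 1) stop("`n` must be >= 1")
  lapply(seq_len(n), function(i) generate_subject(spec, derive_seed(seed, i)))
}
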