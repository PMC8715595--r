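# Preprocessing: skull stripping, Z-score normalization, shape padding.

#' Strip the skull from a head CT volume
#'
#' Bone is thresholded (default 300 HU), closed morphologically (radius 1
#' voxel), and the brain is taken as the largest connected component of
#' sub-bone tissue fully enclosed by the bone shell (i.e. not reachable from
#' the grid border without crossing bone). Voxels outside the brain mask are
#' set to `fill` HU. A volume that contains no bone but does contain tissue
#' is treated as already stripped (its largest tissue component becomes the
#' mask), which makes the operation idempotent on its own output.
#'
#' @param v an `hr_volume` in the HU domain.
#' @param bone_hu bone threshold in HU.
#' @param tissue_hu lower HU bound for "tissue" when no bone is present.
#' @param fill HU value written outside the brain mask.
#' @return list `(volume, brain_mask)`.
#' @export
strip_skull <- function(v, bone_hu = 300, tissue_hu = -500, fill = -1000) {
  stopifnot(inherits(v, "hr_volume"))
  if (v$domain != "HU") stop("strip_skull expects an HU-domain volume")
  shape <- dims3(v)
  vals <- as.numeric(v$values)
  bone <- as.integer(vals >= bone_hu)

  if (!any(bone == 1L)) {
    tissue <- as.integer(vals > tissue_hu)
    if (!any(tissue == 1L))
      stop("no skull found: no voxels above the bone threshold")
    lab <- cpp_label_cc6(tissue, shape)
    keep <- which.max(tabulate(lab[lab > 0]))
    mask <- as.integer(lab == keep)
  } else {
    closed <- close6(bone, shape)
    nonbone <- as.integer(closed == 0L)
    lab <- cpp_label_cc6(nonbone, shape)
    border <- border_labels(lab, shape)
    counts <- tabulate(lab[lab > 0])
    enclosed <- setdiff(which(counts > 0), border)
    if (!length(enclosed))
      stop("no skull found: bone shell does not enclose any tissue")
    keep <- enclosed[which.max(counts[enclosed])]
    mask <- as.integer(lab == keep)
  }
  out <- vals
  out[mask == 0L] <- fill
  list(volume = volume(array(out, shape), v$spacing, v$origin, "HU"),
       brain_mask = label_mask(array(mask, shape), v$spacing, v$origin))
}

# morphological closing, 6-connectivity, radius 1
close6 <- function(mask, shape) {
  d <- cpp_dilate6(mask, shape, 1L)
  inv <- as.integer(d == 0L)
  as.integer(cpp_dilate6(inv, shape, 1L) == 0L)
}

# labels of components touching the grid border (singleton axes excluded,
# so a single-slice grid is treated as 2D)
border_labels <- function(lab, shape) {
  a <- array(lab, shape)
  out <- integer(0)
  if (shape[1] > 1L) out <- c(out, a[1, , ], a[shape[1], , ])
  if (shape[2] > 1L) out <- c(out, a[, 1, ], a[, shape[2], ])
  if (shape[3] > 1L) out <- c(out, a[, , 1], a[, , shape[3]])
  unique(out[out > 0])
}

#' Z-score normalize a volume within a mask
#'
#' Statistics (mean and population standard deviation, i.e. divisor `n`)
#' are computed over mask voxels only; within the mask the result has mean 0
#' and sd 1, outside the mask values are set to 0. Restricting the
#' statistics to the brain keeps the background from dominating them.
#'
#' @param v an `hr_volume`.
#' @param mask an `hr_mask` with at least 2 voxels set.
#' @return a z-scored `hr_volume`.
#' @export
zscore <- function(v, mask) {
  stopifnot(inherits(v, "hr_volume"), inherits(mask, "hr_mask"))
  check_same_grid(v, mask, "volume and mask")
  idx <- mask$values != 0L
  n <- sum(idx)
  if (n < 2) stop("mask must contain at least 2 voxels")
  x <- v$values[idx]
  mu <- mean(x)
  sdev <- sqrt(sum((x - mu)^2) / n)
  if (sdev <= 0) stop("zero within-mask variance: degenerate input")
  out <- array(0, dims3(v))
  out[idx] <- (x - mu) / sdev
  volume(out, v$spacing, v$origin, "zscored")
}

#' Pad a volume to axis multiples
#'
#' Pads each axis at its far end with `fill` so every axis length becomes
#' the next multiple of `k` (needed by the pooling encoder). The returned
#' crop record inverts the padding exactly via [unpad()].
#'
#' @param v an `hr_volume` (or `hr_mask`, or `hr_field`).
#' @param k positive integer multiple.
#' @param fill pad value.
#' @return list `(volume, crop_record)`.
#' @export
pad_to_multiple <- function(v, k, fill = 0) {
  if (k < 1) stop("`k` must be >= 1")
  shape <- dims3(v)
  target <- as.integer(ceiling(shape / k) * k)
  rec <- structure(list(original = shape, padded = target), class = "hr_crop")
  if (all(target == shape)) return(list(volume = v, crop_record = rec))
  pad_arr <- function(a, extra_dim = NULL) {
    d <- c(target, extra_dim)
    out <- array(fill, d)
    out[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), ] <- a
    out
  }
  out <- if (inherits(v, "hr_field")) {
    displacement_field(pad_arr(array(v$vectors, c(shape, 3L)), 3L), v$spacing)
  } else {
    a <- array(fill, target)
    a[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <- v$values
    if (inherits(v, "hr_mask")) label_mask(a, v$spacing, v$origin)
    else volume(a, v$spacing, v$origin, v$domain)
  }
  list(volume = out, crop_record = rec)
}

#' Undo padding applied by [pad_to_multiple()]
#'
#' @param x padded `hr_volume`, `hr_mask` or `hr_field`.
#' @param record the crop record returned by [pad_to_multiple()].
#' @return `x` cropped back to the original shape, bit-exactly.
#' @export
unpad <- function(x, record) {
  stopifnot(inherits(record, "hr_crop"))
  s <- record$original
  if (!identical(dims3(x), record$padded))
    stop("crop record does not match this grid")
  if (inherits(x, "hr_field")) {
    displacement_field(
      x$vectors[seq_len(s[1]), seq_len(s[2]), seq_len(s[3]), , drop = FALSE],
      x$spacing)
  } else {
    a <- x$values[seq_len(s[1]), seq_len(s[2]), seq_len(s[3]), drop = FALSE]
    a <- array(a, s)
    if (inherits(x, "hr_mask")) label_mask(a, x$spacing, x$origin)
    else volume(a, x$spacing, x$origin, x$domain)
  }
}

#' Preprocess a phantom subject for training
#'
#' Applies [strip_skull()] then [zscore()] to the subject's volume; the
#' subject's masks and landmarks are carried through unchanged.
#'
#' @param subject a subject list from [generate_subject()].
#' @return the subject with `volume` replaced by its z-scored, stripped
#'   version and `brain_mask` by the mask found by skull stripping.
#' @export
preprocess_subject <- function(subject) {
  st <- strip_skull(subject$volume)
  subject$volume <- zscore(st$volume, st$brain_mask)
  subject$brain_mask <- st$brain_mask
  subject
}
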