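# Core containers: volumes, binary masks, displacement fields, landmarks.
# Volumes are 3D arrays in (x, y, z) order with per-axis voxel spacing in mm;
# a 2D image is represented as a single-slice grid (nz = 1). The physical mm
# coordinate of voxel (i, j, k) (0-based) is index * spacing + origin.

#' CT-like scalar volume
#'
#' @param values 3D numeric array (a 2D matrix is promoted to a single-slice
#'   volume).
#' @param spacing per-axis voxel spacing in mm (length 3, positive).
#' @param origin physical mm coordinate of voxel (0, 0, 0).
#' @param domain intensity domain, `"HU"` (Hounsfield units) or `"zscored"`.
#' @return object of class `hr_volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   domain = c("HU", "zscored")) {
  domain <- match.arg(domain)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite mm values")
  if (any(dim(values)[1:2] < 2L))
    stop("grid must have at least 2 voxels along x and y")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), domain = domain),
            class = "hr_volume")
}

#' Binary label mask
#'
#' @param values 3D array with values in {0, 1} (logical accepted).
#' @inheritParams volume
#' @return object of class `hr_mask`.
#' @export
label_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- as.integer(values != 0)
  if (!all(values %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be binary")
  structure(list(values = array(v, dim(values)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "hr_mask")
}

#' Dense displacement field
#'
#' Per-voxel displacement vectors in *voxel units* under the backward-warping
#' convention: the warped image reads the source at `x + u(x)`. Physical-unit
#' statements convert per axis through `spacing`.
#'
#' @param vectors 4D array `(nx, ny, nz, 3)` of voxel-unit displacements.
#' @param spacing per-axis voxel spacing in mm.
#' @return object of class `hr_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with last dimension 3")
  if (any(!is.finite(vectors))) stop("field contains non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  structure(list(vectors = vectors, spacing = as.numeric(spacing)),
            class = "hr_field")
}

#' Zero displacement field
#'
#' @param shape grid shape (length 3).
#' @param spacing per-axis voxel spacing in mm.
#' @export
zero_field <- function(shape, spacing = c(1, 1, 1)) {
  displacement_field(array(0, c(shape, 3L)), spacing)
}

#' Named landmark points
#'
#' Points live in physical mm coordinates. Gold displacement vectors (sparse
#' deformation vectors in mm), when present, give the known displacement of
#' each point under a reference deformation.
#'
#' @param names unique point names.
#' @param points_mm n x 3 matrix of mm coordinates.
#' @param gold_vectors_mm optional n x 3 matrix of mm displacement vectors.
#' @return object of class `hr_landmarks`.
#' @export
landmark_set <- function(names, points_mm, gold_vectors_mm = NULL) {
  points_mm <- rbind(points_mm)
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (length(names) != nrow(points_mm))
    stop("`names` and `points_mm` lengths differ")
  if (ncol(points_mm) != 3L) stop("`points_mm` must have 3 columns")
  if (!is.null(gold_vectors_mm)) {
    gold_vectors_mm <- rbind(gold_vectors_mm)
    if (nrow(gold_vectors_mm) != nrow(points_mm) || ncol(gold_vectors_mm) != 3L)
      stop("`gold_vectors_mm` must match `points_mm` in shape")
  }
  structure(list(names = as.character(names),
                 points_mm = unname(points_mm),
                 gold_vectors_mm = if (is.null(gold_vectors_mm)) NULL
                                   else unname(gold_vectors_mm)),
            class = "hr_landmarks")
}

# ---- internal helpers -------------------------------------------------------

dims3 <- function(x) dim(if (inherits(x, "hr_field")) x$vectors else x$values)[1:3]

# field as an (nvox x 3) matrix, voxel linear order
field_mat <- function(f) {
  d <- dim(f$vectors)
  matrix(f$vectors, prod(d[1:3]), 3L)
}

mat_to_field <- function(m, shape, spacing) {
  displacement_field(array(m, c(shape, 3L)), spacing)
}

same_grid <- function(a, b) {
  identical(dims3(a), dims3(b)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dims3(a), dims3(b)))
    stop(sprintf("%s have mismatched grid shapes (%s vs %s)", what,
                 paste(dims3(a), collapse = "x"),
                 paste(dims3(b), collapse = "x")))
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)))
    stop(sprintf("%s have mismatched voxel spacings", what))
  invisible(TRUE)
}

# 0-based voxel index grid as an (nvox x 3) matrix
vox_index_mat <- function(shape) {
  cbind(rep.int(seq_len(shape[1]) - 1L, shape[2] * shape[3]),
        rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3]),
        rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2]))
}

# physical mm coordinates of all voxel centers
vox_mm_mat <- function(shape, spacing, origin = c(0, 0, 0)) {
  idx <- vox_index_mat(shape)
  sweep(sweep(idx, 2L, spacing, `*`), 2L, origin, `+`)
}

#' @export
print.hr_volume <- function(x, ...) {
  d <- dims3(x)
  cat(sprintf("<hr_volume %dx%dx%d, spacing %s mm, %s, range [%.3g, %.3g]>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              x$domain, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.hr_mask <- function(x, ...) {
  d <- dims3(x)
  cat(sprintf("<hr_mask %dx%dx%d, %d foreground voxels>\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' @export
print.hr_field <- function(x, ...) {
  d <- dims3(x)
  m <- field_mat(x)
  mm <- sweep(m, 2L, x$spacing, `*`)
  cat(sprintf("<hr_field %dx%dx%d, max |u| %.3g mm>\n",
              d[1], d[2], d[3], sqrt(max(rowSums(mm^2)))))
  invisible(x)
}

#' @export
print.hr_landmarks <- function(x, ...) {
  cat(sprintf("<hr_landmarks: %d points%s>\n", length(x$names),
              if (is.null(x$gold_vectors_mm)) "" else " with gold vectors"))
  invisible(x)
}
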