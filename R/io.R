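# File formats: NIfTI-1 volumes, masks and 4D displacement fields (via
# RNifti), CSV landmark files.

vol_xform <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read a 3D NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param domain intensity domain to tag the volume with.
#' @return an `hr_volume` with spacing and origin from the header.
#' @export
read_volume <- function(path, domain = "HU") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read NIfTI file `%s`: %s", path,
                    conditionMessage(e))))
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)        # single-slice volumes
  if (length(d) != 3L)
    stop(sprintf("`%s`: expected a 3D volume, found %dD data", path,
                 length(d)))
  xf <- RNifti::xform(img)
  sp <- if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0) {
    sqrt(colSums(xf[1:3, 1:3]^2))     # axis scales survive 2D storage
  } else {
    c(abs(RNifti::pixdim(img)), 1, 1)[1:3]
  }
  volume(array(as.numeric(img), d), sp, as.numeric(xf[1:3, 4]),
         domain = domain)
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing and origin are recorded in the header and survive a
#' write/read round trip.
#'
#' @param v an `hr_volume` or `hr_mask`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(vol_xform(v$spacing, v$origin),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @inheritParams read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  label_mask(array(as.integer(v$values != 0), dims3(v)), v$spacing, v$origin)
}

#' Read a displacement field from 4D NIfTI
#'
#' The file must be 4D with last-axis length 3 (vector components, voxel
#' units).
#'
#' @param path NIfTI file.
#' @return an `hr_field`.
#' @export
read_field <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read NIfTI file `%s`: %s", path,
                    conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf("`%s`: displacement fields are 4D with last axis 3", path))
  sp <- abs(RNifti::pixdim(img))[1:3]
  displacement_field(array(as.numeric(img), d), sp)
}

#' Write a displacement field as 4D NIfTI
#' @param f an `hr_field`.
#' @param path output path.
#' @export
write_field <- function(f, path) {
  img <- RNifti::asNifti(f$vectors)
  RNifti::pixdim(img) <- c(f$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Expected header `name,x_mm,y_mm,z_mm` with optional gold-vector columns
#' `gx_mm,gy_mm,gz_mm`. Order-preserving; duplicate names and non-numeric
#' coordinates raise errors citing the offending line.
#'
#' @param path CSV file.
#' @return an `hr_landmarks`.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("`%s`: landmark CSV needs columns %s", path,
                 paste(need, collapse = ",")))
  dup <- which(duplicated(df$name))
  if (length(dup))
    stop(sprintf("`%s`: duplicate landmark name `%s` at line %d", path,
                 df$name[dup[1]], dup[1] + 1L))
  pts <- sapply(df[, c("x_mm", "y_mm", "z_mm")], function(col)
    suppressWarnings(as.numeric(col)))
  pts <- rbind(pts)
  bad <- which(rowSums(!is.finite(pts)) > 0)
  if (length(bad))
    stop(sprintf("`%s`: non-numeric coordinates at line %d", path,
                 bad[1] + 1L))
  gold <- NULL
  gcols <- c("gx_mm", "gy_mm", "gz_mm")
  if (all(gcols %in% names(df))) gold <- as.matrix(df[, gcols])
  landmark_set(df$name, pts, gold)
}

#' Write landmarks to CSV
#' @param l an `hr_landmarks`.
#' @param path output CSV path.
#' @export
write_landmarks <- function(l, path) {
  df <- data.frame(name = l$names, x_mm = l$points_mm[, 1],
                   y_mm = l$points_mm[, 2], z_mm = l$points_mm[, 3])
  if (!is.null(l$gold_vectors_mm)) {
    df$gx_mm <- l$gold_vectors_mm[, 1]
    df$gy_mm <- l$gold_vectors_mm[, 2]
    df$gz_mm <- l$gold_vectors_mm[, 3]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
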