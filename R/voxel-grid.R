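#' Labelled voxel grid
#'
#' The simulation domain: a 3D integer label array (tissue codes, see
#' [tissue_labels]) plus the voxel size and a voxel-to-world affine. World
#' coordinates are stereotactic millimetres; the affine maps 0-based voxel
#' indices (voxel-centre convention) to world mm, matching the usual
#' neuroimaging convention.
#'
#' @param labels 3D integer array of tissue labels.
#' @param voxel_size Voxel edge length(s) in mm; length 1 or 3.
#' @param affine Optional 4x4 voxel-index-to-world matrix. Defaults to a
#'   scaled identity (world = index * voxel_size). The upper 3x3 block must
#'   have orthogonal columns with norms equal to the voxel size, so that
#'   distances in world and grid frames agree.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(labels, voxel_size, affine = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  dims <- dim(labels)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  M <- affine[1:3, 1:3]
  if (max(abs(crossprod(M) - diag(voxel_size^2))) > 1e-6)
    stop("affine columns must be orthogonal with norms equal to voxel_size")
  storage.mode(labels) <- "integer"
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine,
                 labels = labels),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  tab <- table(x$labels)
  cat("labels:", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                       collapse = " "), "\n")
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param grid A `voxel_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

#' Convert world coordinates to voxel indices
#'
#' @param points World point(s), mm: length-3 vector or n x 3 matrix.
#' @param grid A `voxel_grid`.
#' @param continuous If `TRUE`, return fractional 0-based indices instead of
#'   rounding to the nearest voxel centre.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(points, grid, continuous = FALSE) {
  p <- rbind(t(as_point_matrix(points)), 1)
  v <- t(solve(grid$affine, p)[1:3, , drop = FALSE])
  idx <- if (continuous) v else round(v)
  bad <- idx[, 1] < -0.5 | idx[, 1] > grid$dims[1] - 0.5 |
         idx[, 2] < -0.5 | idx[, 2] > grid$dims[2] - 0.5 |
         idx[, 3] < -0.5 | idx[, 3] > grid$dims[3] - 0.5
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g, %g) mm lies outside the grid",
                 as_point_matrix(points)[i, 1], as_point_matrix(points)[i, 2],
                 as_point_matrix(points)[i, 3]))
  }
  unname(idx)
}

#' Convert voxel indices to world coordinates
#'
#' @param index 0-based voxel indices: length-3 vector or n x 3 matrix.
#' @inheritParams world_to_voxel
#' @return n x 3 matrix of world mm coordinates (voxel centres).
#' @export
voxel_to_world <- function(index, grid) {
  v <- rbind(t(as_point_matrix(index)), 1)
  t((grid$affine %*% v)[1:3, , drop = FALSE])
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3, byrow = TRUE)
  if (ncol(p) != 3) stop("points must have 3 columns")
  p
}

# Grid-local frame used by the transport engine: continuous position in mm
# with voxel (i,j,k) occupying [i*h, (i+1)*h). Voxel centre i maps to
# (i + 0.5) * h.
world_to_local <- function(points, grid) {
  v <- world_to_voxel(points, grid, continuous = TRUE)
  sweep(v + 0.5, 2, grid$voxel_size, `*`)
}

# Directions transform through the affine's linear part; for the
# orthogonal-scaled affines voxel_grid() admits this preserves lengths.
world_dir_to_local <- function(dirs, grid) {
  d <- as_point_matrix(dirs)
  v <- t(solve(grid$affine[1:3, 1:3], t(d)))
  loc <- sweep(v, 2, grid$voxel_size, `*`)
  loc / sqrt(rowSums(loc^2))
}

#' Read a label volume from a NIfTI file
#'
#' @param path NIfTI file with one integer tissue label per voxel.
#' @return A `voxel_grid`.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = "matrix")
  voxel_size <- sqrt(colSums(aff[1:3, 1:3]^2))
  voxel_grid(array(as.integer(round(img)), dim = dim(img)),
             voxel_size = voxel_size, affine = unclass(aff)[1:4, 1:4])
}

#' Write a volume on a grid's geometry to NIfTI
#'
#' @param data 3D array on the grid (labels, mask, or fluence map).
#' @param grid The `voxel_grid` supplying geometry.
#' @param path Output NIfTI path (`.nii` for an uncompressed file).
#' @export
write_volume <- function(data, grid, path) {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
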