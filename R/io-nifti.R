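## NIfTI-1 readers/writers. Volumes use 0-based voxel indices and RAS world
## axes via the stored sform, consistent with the NIfTI standard.

#' @importFrom RNifti readNifti writeNifti asNifti xform pixdim niftiHeader
NULL

niftiWithAffine <- function(arr, affine, voxelSize) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSize
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

#' Read a labeled tissue volume from NIfTI
#'
#' The file must contain a 3D integer-valued volume; the affine and voxel
#' size come from the header.
#'
#' @param path NIfTI file path
#' @return a \linkS4class{TissueGrid}
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("labels must be a 3D volume, got ", length(d), "D")
  vals <- as.vector(img)
  if (any(vals != round(vals)))
    stop("labels must be integer-valued")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  newTissueGrid(d, RNifti::pixdim(img)[1:3],
                labels = array(as.integer(vals), d), affine = aff)
}

#' Write a labeled tissue volume to NIfTI
#'
#' @param grid a \linkS4class{TissueGrid}
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeLabels <- function(grid, path) {
  stopifnot(is(grid, "TissueGrid"))
  img <- niftiWithAffine(grid@labels, grid@affine, grid@voxelSize)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read/write scalar or 4D volumes
#'
#' Plain NIfTI I/O for scalar maps and 4D (space x time) volumes, keeping
#' the affine of a reference grid.
#'
#' @param vol numeric 3D or 4D array
#' @param path file path
#' @param grid optional \linkS4class{TissueGrid} supplying affine/voxel size
#' @return \code{writeVolume}: the path, invisibly; \code{readVolume}: the
#'   array with attributes \code{affine} and \code{voxelSize}
#' @export
writeVolume <- function(vol, path, grid = NULL) {
  if (is.null(grid)) {
    img <- RNifti::asNifti(vol)
  } else {
    img <- niftiWithAffine(vol, grid@affine, grid@voxelSize)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim(img))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  attr(out, "affine") <- aff
  attr(out, "voxelSize") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write/read a tensor field as NIfTI volumes
#'
#' The scaled conductivity tensor is stored as a 4D volume with the 6
#' unique components in the order xx, yy, zz, xy, xz, yz; the permittivity
#' as a separate scalar volume.
#'
#' @param field a \linkS4class{TensorField}
#' @param sigmaPath path for the 6-component tensor volume
#' @param epsPath path for the permittivity volume
#' @param voxelSize voxel size used when reading back
#' @return paths invisibly / a \linkS4class{TensorField}
#' @export
writeTensorField <- function(field, sigmaPath, epsPath) {
  stopifnot(is(field, "TensorField"))
  aff <- centeredAffine(field@dims, field@voxelSize)
  RNifti::writeNifti(niftiWithAffine(field@sigma, aff, field@voxelSize),
                     sigmaPath, datatype = "double")
  RNifti::writeNifti(niftiWithAffine(field@eps, aff, field@voxelSize),
                     epsPath, datatype = "double")
  invisible(c(sigmaPath, epsPath))
}

#' @rdname writeTensorField
#' @export
readTensorField <- function(sigmaPath, epsPath) {
  sig <- readVolume(sigmaPath)
  eps <- readVolume(epsPath)
  d <- dim(sig)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensor volume must be 4D with 6 components (xx,yy,zz,xy,xz,yz)")
  vs <- attr(sig, "voxelSize")
  attributes(sig) <- list(dim = d)
  attributes(eps) <- list(dim = dim(eps))
  new("TensorField", dims = as.integer(d[1:3]), voxelSize = as.numeric(vs),
      sigma = sig, eps = eps)
}

#' Read a tissue property table from CSV or YAML
#'
#' CSV columns (or YAML list fields): \code{label}, \code{name},
#' \code{sigma_S_per_m}, \code{eps_rel}.
#'
#' @param path file path (.csv or .yml/.yaml)
#' @return a \linkS4class{TissueTable}
#' @export
readTissueTable <- function(path) {
  if (!file.exists(path)) stop("tissue table not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(y, as.data.frame))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "name", "sigma_S_per_m", "eps_rel")
  if (!all(need %in% names(df)))
    stop("tissue table needs columns ", paste(need, collapse = ", "))
  TissueTable(df$label, df$name, df$sigma_S_per_m, df$eps_rel)
}

#' @rdname readTissueTable
#' @param table a \linkS4class{TissueTable} to write
#' @export
writeTissueTable <- function(table, path) {
  stopifnot(is(table, "TissueTable"))
  tb <- table@table
  utils::write.csv(data.frame(label = tb$label, name = tb$name,
                              sigma_S_per_m = tb$sigma, eps_rel = tb$epsRel),
                   path, row.names = FALSE)
  invisible(path)
}
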