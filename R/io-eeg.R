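## EEG recordings (CSV or EDF) and electrode tables (TSV).

#' Read a multichannel EEG recording
#'
#' CSV: one column per channel with a header row of channel names; an
#' optional leading time column (named "time", "t" or "seconds") sets the
#' sampling rate, otherwise \code{fs} must be given. EDF: the 16-bit
#' European Data Format, dispatched on the ".edf" extension.
#'
#' @param path file path (.csv or .edf)
#' @param fs sampling rate in Hz (required for CSV without a time column)
#' @return an \linkS4class{EEGRecording}
#' @export
readEEG <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("EEG file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(readEDF(path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed EEG CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty EEG file")
  if (anyNA(df)) stop("malformed EEG CSV: ragged or non-numeric rows")
  t0 <- 0
  if (tolower(names(df)[1]) %in% c("time", "t", "seconds")) {
    tv <- df[[1]]
    if (length(tv) < 2L) stop("time column too short to infer fs")
    fs <- 1 / stats::median(diff(tv))
    t0 <- tv[1]
    df <- df[, -1, drop = FALSE]
  }
  if (is.null(fs)) stop("sampling rate fs required (no time column found)")
  data <- t(as.matrix(df))
  if (!is.numeric(data)) stop("malformed EEG CSV: non-numeric values")
  rownames(data) <- names(df)
  new("EEGRecording", data = data, fs = fs, t0 = t0)
}

#' Write a recording to CSV (with a time column) or EDF
#'
#' @param rec an \linkS4class{EEGRecording}
#' @param path output path; ".edf" selects the EDF writer
#' @return the path, invisibly
#' @export
writeEEG <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  if (tolower(tools::file_ext(path)) == "edf") return(writeEDF(rec, path))
  tv <- rec@t0 + (seq_len(ncol(rec@data)) - 1) / rec@fs
  df <- data.frame(time = tv, t(rec@data), check.names = FALSE)
  names(df) <- c("time", rownames(rec@data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an electrode table and map it onto a grid
#'
#' Tab-separated table with a \code{name} column plus either world
#' coordinates \code{x, y, z} (mm; mapped through the inverse affine) or
#' 0-based voxel coordinates \code{i, j, k}.
#'
#' @param path TSV file path
#' @param grid the \linkS4class{TissueGrid} the electrodes are mapped to
#' @return a \linkS4class{SensorArray}
#' @export
readElectrodes <- function(path, grid) {
  if (!file.exists(path)) stop("electrode table not found: ", path)
  stopifnot(is(grid, "TissueGrid"))
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"name" %in% names(df)) stop("electrode table needs a 'name' column")
  if (all(c("x", "y", "z") %in% names(df))) {
    world <- as.matrix(df[, c("x", "y", "z")])
    hom <- solve(grid@affine) %*% rbind(t(world), 1)
    vox <- t(hom[1:3, , drop = FALSE])
  } else if (all(c("i", "j", "k") %in% names(df))) {
    vox <- as.matrix(df[, c("i", "j", "k")])
    world <- t((grid@affine %*% rbind(t(vox), 1))[1:3, , drop = FALSE])
  } else {
    stop("electrode table needs columns x,y,z (world mm) or i,j,k (voxel)")
  }
  new("SensorArray", names = as.character(df$name), voxels = vox,
      world = world, dims = grid@dims)
}

#' Construct a sensor array from voxel positions
#'
#' @param names channel names
#' @param voxels n x 3 matrix of 0-based (possibly fractional) voxel
#'   coordinates
#' @param grid the target \linkS4class{TissueGrid} (or integer(3) dims)
#' @return a \linkS4class{SensorArray}
#' @export
makeSensorArray <- function(names, voxels, grid) {
  dims <- if (is(grid, "TissueGrid")) gridDims(grid) else as.integer(grid)
  new("SensorArray", names = as.character(names), voxels = as.matrix(voxels),
      world = matrix(numeric(0), 0, 3), dims = as.integer(dims))
}
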