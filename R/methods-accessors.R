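#' @describeIn gridDims dimensions of a labeled grid
#' @export
setMethod("gridDims", "TissueGrid", function(x) x@dims)

#' @describeIn gridDims dimensions of a tensor field
#' @export
setMethod("gridDims", "TensorField", function(x) x@dims)

#' @describeIn voxelSize voxel size of a labeled grid
#' @export
setMethod("voxelSize", "TissueGrid", function(x) x@voxelSize)

#' @describeIn voxelSize voxel size of a tensor field
#' @export
setMethod("voxelSize", "TensorField", function(x) x@voxelSize)

#' @describeIn affineMatrix affine of a labeled grid
#' @export
setMethod("affineMatrix", "TissueGrid", function(x) x@affine)

#' @describeIn labelVolume label array of a grid
#' @export
setMethod("labelVolume", "TissueGrid", function(x) x@labels)

#' @describeIn sigmaTensor tensor components of a field
#' @export
setMethod("sigmaTensor", "TensorField", function(x) x@sigma)

#' @describeIn epsVolume permittivity of a field
#' @export
setMethod("epsVolume", "TensorField", function(x) x@eps)

#' @describeIn nChannels channels of a recording
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @describeIn nChannels channels of a sensor array
#' @export
setMethod("nChannels", "SensorArray", function(x) length(x@names))

#' @describeIn samplingRate sampling rate of a recording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn samplingRate sampling rate of a reconstructed potential
#' @export
setMethod("samplingRate", "SpectralPotential", function(x) x@fs)

#' @describeIn channelNames names of recording channels
#' @export
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))

#' @describeIn channelNames names of sensor channels
#' @export
setMethod("channelNames", "SensorArray", function(x) x@names)

#' @describeIn modeAmplitudes amplitudes of a mode set
#' @export
setMethod("modeAmplitudes", "ModeSet", function(x) x@amplitudes)

#' @describeIn equilibriumDistribution equilibrium distribution of a mode set
#' @export
setMethod("equilibriumDistribution", "ModeSet", function(x) x@muStar)

#' @describeIn modeMap spatial map of mode m embedded in the full volume
#' @export
setMethod("modeMap", "ModeSet", function(x, m) {
  stopifnot(m >= 1L, m <= length(x@amplitudes))
  vol <- array(0, x@dims)
  vol[x@voxelIndex] <- x@maps[, m]
  vol
})

#' @describeIn modeTimecourses time courses of a mode set
#' @export
setMethod("modeTimecourses", "ModeSet", function(x) x@timecourses)

setMethod("show", "TissueGrid", function(object) {
  cat(sprintf("TissueGrid: %s voxels, %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(signif(object@voxelSize, 4), collapse = " x ")))
  tab <- table(object@labels)
  cat("  labels:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  if (!is.null(object@meta$resolution))
    cat("  resolution tag:", object@meta$resolution, "\n")
})

setMethod("show", "TissueTable", function(object) {
  cat("TissueTable:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "TensorField", function(object) {
  s <- isotropicPart(object)
  cat(sprintf("TensorField: %s voxels; isotropic Sigma in [%.4g, %.4g] 1/s\n",
              paste(object@dims, collapse = " x "), min(s), max(s)))
})

setMethod("show", "DispersionResult", function(object) {
  cat(sprintf("DispersionResult: omega = %.6g 1/s, gamma = %.6g 1/s (k in %s)\n",
              object@omega, object@gamma, object@kUnits))
})

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d channels on a %s grid\n",
              length(object@names), paste(object@dims, collapse = " x ")))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              nrow(object@data), ncol(object@data), object@fs, object@t0))
})

setMethod("show", "SpectralPotential", function(object) {
  cat(sprintf("SpectralPotential: %d bins (%s Hz)%s\n",
              length(object@freqs),
              paste(signif(range(object@freqs), 4), collapse = "-"),
              if (length(object@phiT)) sprintf(", time domain %d samples @ %g Hz",
                                               dim(object@phiT)[4], object@fs)
              else ""))
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet: %d modes over %d voxels; amplitudes %s\n",
              length(object@amplitudes), nrow(object@maps),
              paste(signif(object@amplitudes, 3), collapse = ", ")))
})
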