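#' Grid dimensions in voxels
#' @param x a TissueGrid, TensorField or related object
#' @return integer(3)
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Voxel size in mm
#' @param x a TissueGrid or TensorField
#' @return numeric(3)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel-to-world affine (4x4, 0-based voxel indices, RAS world axes)
#' @param x a TissueGrid
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' Integer label volume
#' @param x a TissueGrid
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))

#' Scaled conductivity tensor components (dims x 6, order xx,yy,zz,xy,xz,yz)
#' @param x a TensorField
#' @export
setGeneric("sigmaTensor", function(x) standardGeneric("sigmaTensor"))

#' Permittivity volume (F/m)
#' @param x a TensorField
#' @export
setGeneric("epsVolume", function(x) standardGeneric("epsVolume"))

#' Number of channels of a recording or sensor array
#' @param x an EEGRecording or SensorArray
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Sampling rate in Hz
#' @param x an EEGRecording or SpectralPotential
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel names
#' @param x an EEGRecording or SensorArray
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Mode amplitudes, non-increasing with rank
#' @param x a ModeSet
#' @export
setGeneric("modeAmplitudes", function(x) standardGeneric("modeAmplitudes"))

#' Equilibrium voxel distribution of a mode decomposition
#' @param x a ModeSet
#' @export
setGeneric("equilibriumDistribution",
           function(x) standardGeneric("equilibriumDistribution"))

#' Spatial map of one mode as a 3D volume
#' @param x a ModeSet
#' @param m mode rank (1 = largest amplitude)
#' @export
setGeneric("modeMap", function(x, m) standardGeneric("modeMap"))

#' Mode time courses (time x mode matrix)
#' @param x a ModeSet
#' @export
setGeneric("modeTimecourses", function(x) standardGeneric("modeTimecourses"))
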