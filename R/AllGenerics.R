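#' @rdname ColonySim-accessors
#' @export
setGeneric("occupiedSites", function(x) standardGeneric("occupiedSites"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("finalTime", function(x) standardGeneric("finalTime"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("simStatus", function(x) standardGeneric("simStatus"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname ColonySim-accessors
#' @export
setGeneric("trajectory", function(x, ...) standardGeneric("trajectory"))

#' @rdname VoxelStack-accessors
#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))

#' @rdname VoxelStack-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("nSatellites", function(x) standardGeneric("nSatellites"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("mainColonyId", function(x) standardGeneric("mainColonyId"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("satelliteVolumes", function(x) standardGeneric("satelliteVolumes"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("comDistances", function(x) standardGeneric("comDistances"))

#' @rdname MorphologyReport-accessors
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' Analyze a colony or voxel stack with the 3D morphology pipeline
#'
#' Runs the full image-analysis chain: optional half-colony crop, Otsu
#' thresholding (grayscale input only; binary inputs, including simulated
#' lattices, skip it), minimum-volume filtering of small clusters,
#' connected-component labeling and per-object metrics, summarized as a
#' [MorphologyReport].
#'
#' @param x a [VoxelStack], [ColonySim], or 3D array.
#' @param ... passed to methods; see [analyzeColony,VoxelStack-method].
#' @return a [MorphologyReport].
#' @export
setGeneric("analyzeColony", function(x, ...) standardGeneric("analyzeColony"))
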