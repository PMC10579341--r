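#' Construct simulation parameters
#'
#' @param k division rate (1/time). The study's convention is k = 1, so
#'   simulated time is measured in cell doubling times.
#' @param ks jump rate (1/time) of exposed (N2) cells.
#' @param sigma standard deviation of the isotropic Gaussian jump
#'   displacement, in lattice units (1 site corresponds to ~1 um).
#' @param L linear lattice size, sites. 301 comfortably holds a 1e6-event
#'   compact colony (equivalent-sphere radius ~62 sites).
#' @param maxEvents total division + jump event budget.
#' @param seed integer RNG seed (NA: use the current RNG state).
#' @param boundaryMargin early-stop distance from the lattice edge; default
#'   max(3 * sigma, 5), so that results are never edge-contaminated.
#' @param n2MinEmpty empty-face-neighbour threshold for jump capability.
#' @param boundaryVariant growth-site weighting, "dedup" or "multiplicity".
#' @param redrawCap maximum jump-displacement redraws before the jump is
#'   abandoned.
#' @return a validated [SimParams] object.
#' @examples
#' SimParams(ks = 0.05, sigma = 7, maxEvents = 1e4, seed = 1)
#' @export
SimParams <- function(k = 1, ks = 0, sigma = 0, L = 301L, maxEvents = 1e6,
                      seed = NA_integer_,
                      boundaryMargin = max(ceiling(3 * sigma), 5),
                      n2MinEmpty = 4L,
                      boundaryVariant = c("dedup", "multiplicity"),
                      redrawCap = 10000L) {
    boundaryVariant <- match.arg(boundaryVariant)
    new("SimParams", k = as.numeric(k), ks = as.numeric(ks),
        sigma = as.numeric(sigma), L = as.integer(L),
        maxEvents = as.numeric(maxEvents), seed = as.integer(seed),
        boundaryMargin = as.integer(boundaryMargin),
        n2MinEmpty = as.integer(n2MinEmpty),
        boundaryVariant = boundaryVariant, redrawCap = as.integer(redrawCap))
}

#' Construct a voxel stack
#'
#' @param values 3D array (or matrix, promoted to one z-slice).
#' @param voxelSize um per voxel along x, y, z (scalar recycled).
#' @param origin physical position of the corner of voxel (0,0,0), um.
#' @return a [VoxelStack].
#' @export
VoxelStack <- function(values, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    new("VoxelStack", values = values, voxelSize = as.numeric(voxelSize),
        origin = as.numeric(origin))
}

#' Accessors for ColonySim results
#'
#' @param x a [ColonySim].
#' @param ... unused.
#' @return \code{occupiedSites}: integer matrix of 0-based site coordinates;
#'   \code{nCells}: final cell count; \code{finalTime}: simulated time;
#'   \code{simStatus}: termination status; \code{eventLog}: per-event
#'   data.frame; \code{trajectory}: data.frame with t, n_cells, event_type.
#' @name ColonySim-accessors
NULL

#' @rdname ColonySim-accessors
#' @export
setMethod("occupiedSites", "ColonySim", function(x) x@sites)

#' @rdname ColonySim-accessors
#' @export
setMethod("nCells", "ColonySim", function(x) nrow(x@sites))

#' @rdname ColonySim-accessors
#' @export
setMethod("nCells", "LatticeState", function(x) x@nCells)

#' @rdname ColonySim-accessors
#' @export
setMethod("finalTime", "ColonySim", function(x) x@time)

#' @rdname ColonySim-accessors
#' @export
setMethod("simStatus", "ColonySim", function(x) x@status)

#' @rdname ColonySim-accessors
#' @export
setMethod("simParams", "ColonySim", function(x) x@params)

#' @rdname ColonySim-accessors
#' @export
setMethod("eventLog", "ColonySim", function(x) x@eventLog)

#' @rdname ColonySim-accessors
#' @export
setMethod("trajectory", "ColonySim", function(x, ...) {
    log <- x@eventLog
    data.frame(t = log$t, n_cells = log$n_cells, event_type = log$event_type)
})

#' Accessors for VoxelStack geometry
#'
#' @param x a [VoxelStack] or [LabeledObjects].
#' @name VoxelStack-accessors
NULL

#' @rdname VoxelStack-accessors
#' @export
setMethod("stackValues", "VoxelStack", function(x) x@values)

#' @rdname VoxelStack-accessors
#' @export
setMethod("voxelSize", "VoxelStack", function(x) x@voxelSize)

#' @rdname VoxelStack-accessors
#' @export
setMethod("voxelSize", "LabeledObjects", function(x) x@voxelSize)

#' Accessors for MorphologyReport
#'
#' @param x a [MorphologyReport].
#' @name MorphologyReport-accessors
NULL

#' @rdname MorphologyReport-accessors
#' @export
setMethod("objectTable", "MorphologyReport", function(x) x@objectTable)

#' @rdname MorphologyReport-accessors
#' @export
setMethod("nSatellites", "MorphologyReport", function(x) x@nSatellites)

#' @rdname MorphologyReport-accessors
#' @export
setMethod("mainColonyId", "MorphologyReport", function(x) x@mainId)

#' @rdname MorphologyReport-accessors
#' @export
setMethod("satelliteVolumes", "MorphologyReport", function(x) {
    tab <- x@objectTable
    tab$volume_um3[!tab$is_main]
})

#' @rdname MorphologyReport-accessors
#' @export
setMethod("comDistances", "MorphologyReport", function(x) {
    tab <- x@objectTable
    tab$dist_to_main_um[!tab$is_main]
})

#' @rdname MorphologyReport-accessors
#' @export
setMethod("totalVolume", "MorphologyReport", function(x) x@totalVolume)

setMethod("show", "SimParams", function(object) {
    cat("SimParams: k =", object@k, " ks =", object@ks,
        " sigma =", object@sigma, "\n")
    cat("  L =", object@L, " maxEvents =", format(object@maxEvents),
        " seed =", object@seed, "\n")
    cat("  boundaryMargin =", object@boundaryMargin,
        " n2MinEmpty =", object@n2MinEmpty,
        " boundaryVariant =", object@boundaryVariant, "\n")
})

setMethod("show", "ColonySim", function(object) {
    cat("ColonySim:", nrow(object@sites), "cells at t =",
        format(object@time, digits = 5), sprintf("(%s)\n", object@status))
    cat("  params: sigma =", object@params@sigma, " ks =", object@params@ks,
        " L =", object@params@L, " seed =", object@params@seed, "\n")
    tp <- table(object@eventLog$event_type)
    cat("  events:", paste(names(tp), as.integer(tp), collapse = ", "), "\n")
})

setMethod("show", "VoxelStack", function(object) {
    d <- dim(object@values)
    cat(sprintf("VoxelStack: %d x %d x %d voxels, voxel size (%g, %g, %g) um\n",
        d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
        object@voxelSize[3]))
    cat("  intensity range:", paste(format(range(object@values)), collapse = " .. "), "\n")
})

setMethod("show", "MorphologyReport", function(object) {
    cat("MorphologyReport:", nrow(object@objectTable), "object(s),",
        object@nSatellites, "satellite(s)\n")
    cat(sprintf("  total volume %.1f um^3; filter >= %g um^3, connectivity %d\n",
        object@totalVolume, object@minVolume, object@connectivity))
})

setMethod("show", "SweepSummary", function(object) {
    cat("SweepSummary:", nrow(object@summaryTable), "grid cell(s),",
        nrow(object@records), "run(s)\n")
    print(object@summaryTable, digits = 3)
})
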