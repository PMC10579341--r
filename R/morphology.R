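# 3D colony morphology: thresholding, small-cluster removal, component
# labeling and per-object metrics, applied identically to confocal-style
# voxel stacks and simulated lattices (which skip thresholding, being binary).

#' Otsu threshold of a grayscale stack
#'
#' Classic Otsu binarization: the intensity histogram (256 equal-width bins
#' over the observed range) is split at the boundary that maximizes the
#' between-class variance; ties are broken toward the lower threshold.
#' Voxels strictly above the threshold become foreground.
#'
#' @param stack a grayscale [VoxelStack] with at least 2 distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return a binary [VoxelStack] (logical values); the numeric threshold is
#'   attached as attribute \code{"threshold"} of the values array.
#' @seealso [otsuLevel()] for the threshold alone.
#' @export
otsuThreshold <- function(stack, nbins = 256L) {
    thr <- otsuLevel(stack, nbins)
    mask <- stack@values > thr
    attr(mask, "threshold") <- thr
    new("VoxelStack", values = mask, voxelSize = stack@voxelSize,
        origin = stack@origin)
}

#' @rdname otsuThreshold
#' @export
otsuLevel <- function(stack, nbins = 256L) {
    v <- as.numeric(stack@values)
    rng <- range(v)
    if (rng[1] == rng[2])
        stop("constant-intensity stack: Otsu threshold is undefined")
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
    h <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), nbins),
                  nbins)
    p <- h / sum(h)
    centers <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
    w0 <- cumsum(p)                       # class 0: bins 1..t
    mu <- cumsum(p * centers)
    muT <- mu[nbins]
    # between-class variance for split after bin t = 1..nbins-1
    t <- seq_len(nbins - 1L)
    valid <- w0[t] > 0 & w0[t] < 1
    bcv <- rep(-Inf, nbins - 1L)
    bcv[valid] <- (muT * w0[t][valid] - mu[t][valid])^2 /
        (w0[t][valid] * (1 - w0[t][valid]))
    best <- which.max(bcv)                # ties: which.max takes the first
    breaks[best + 1L]                     # upper edge of the last class-0 bin
}

#' Remove connected components below a minimum volume
#'
#' Background-noise removal: every connected cluster of foreground voxels
#' with physical volume strictly smaller than \code{minVolume} is deleted.
#' The default of 11 um^3 removes clusters "smaller than 11 um^3": a cluster
#' of exactly 11 um^3 is retained.
#'
#' @param binary a binary [VoxelStack].
#' @param minVolume minimum retained component volume, um^3.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return the filtered binary [VoxelStack]; an empty result is allowed.
#' @export
removeSmallComponents <- function(binary, minVolume = 11, connectivity = 26L) {
    mask <- binary@values != 0
    lab <- .label3dCpp(as.logical(mask), dim(mask), as.integer(connectivity))
    nObj <- attr(lab, "n_objects")
    if (nObj > 0L) {
        voxVol <- prod(binary@voxelSize)
        sizes <- tabulate(lab, nObj)
        drop <- which(sizes * voxVol < minVolume)
        if (length(drop)) mask[lab %in% drop] <- FALSE
    }
    new("VoxelStack", values = array(mask, dim(mask)),
        voxelSize = binary@voxelSize, origin = binary@origin)
}

#' Label connected components in 3D
#'
#' Deterministic flood-fill labeling: objects are numbered in order of their
#' smallest linear voxel index, so the labeling is reproducible and
#' independent of input history.
#'
#' @inheritParams removeSmallComponents
#' @return a [LabeledObjects].
#' @export
labelComponents <- function(binary, connectivity = 26L) {
    mask <- binary@values != 0
    lab <- .label3dCpp(as.logical(mask), dim(mask), as.integer(connectivity))
    nObj <- attr(lab, "n_objects")
    new("LabeledObjects",
        labels = array(as.integer(lab), dim(mask)),
        objectIds = seq_len(nObj),
        connectivity = as.integer(connectivity),
        voxelSize = binary@voxelSize, origin = binary@origin)
}

#' Volume of the 3D convex hull of a point set
#'
#' Quickhull on arbitrary 3D points; degenerate inputs (fewer than 4
#' points, collinear or coplanar sets) have zero hull volume.
#'
#' @param points numeric matrix (n x 3).
#' @return hull volume (same cubed units as the coordinates).
#' @examples
#' pts <- as.matrix(expand.grid(0:1, 0:1, 0:1)) # unit cube corners
#' convexHullVolume(pts)
#' @export
convexHullVolume <- function(points) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    .hullVolumeCpp(points)
}

#' Per-object morphology metrics
#'
#' For every labeled object: voxel count, physical volume (voxels x voxel
#' volume), centre of mass (unweighted mean of voxel centres, physical um),
#' and convexity (solidity): the object's voxel count divided by the voxel
#' count of its convex image -- the voxels whose centres fall inside the
#' convex hull of the object's voxel centres. This is the standard solidity
#' of 3D region analysis: it lies in (0, 1], equals 1 for filled convex
#' digitized solids, and is robust to the staircase discretization of small
#' round objects. Objects whose centre set has a degenerate (zero-volume)
#' hull -- single voxels, lines, planes -- are flagged and reported with
#' convexity 1.
#'
#' @param objects a [LabeledObjects].
#' @return data.frame: id, n_voxels, volume_um3, com_x/com_y/com_z,
#'   convexity, degenerate_hull. Zero objects give an empty data.frame.
#' @export
componentMetrics <- function(objects) {
    lab <- objects@labels
    ids <- objects@objectIds
    vs <- objects@voxelSize
    org <- objects@origin
    voxVol <- prod(vs)
    out <- data.frame(id = integer(), n_voxels = integer(),
                      volume_um3 = numeric(), com_x = numeric(),
                      com_y = numeric(), com_z = numeric(),
                      convexity = numeric(), degenerate_hull = logical())
    if (length(ids) == 0L) return(out)
    idx <- which(lab > 0L)
    labv <- lab[idx]
    co <- arrayInd(idx, dim(lab)) - 1L     # 0-based voxel coordinates
    for (id in ids) {
        sel <- labv == id
        vox <- co[sel, , drop = FALSE]
        nv <- nrow(vox)
        com <- org + (colMeans(vox) + 0.5) * vs
        ci <- .convexImageCountCpp(vox)
        conv <- if (ci$degenerate) 1 else nv / ci$n_hull
        out <- rbind(out, data.frame(
            id = id, n_voxels = nv, volume_um3 = nv * voxVol,
            com_x = com[1], com_y = com[2], com_z = com[3],
            convexity = conv, degenerate_hull = ci$degenerate))
    }
    out
}

#' Satellite summary of a set of objects
#'
#' The largest-volume object (ties: smallest label) is the main colony;
#' every other connected component is a satellite -- a cluster completely
#' detached from the main colony. Appends per-object distance to the main
#' colony's centre of mass and the nearest-neighbour object (COM-to-COM).
#'
#' @param metrics data.frame from [componentMetrics()] (at least 1 row), or
#'   a [LabeledObjects].
#' @param connectivity,minVolume bookkeeping recorded in the report.
#' @return a [MorphologyReport].
#' @export
satelliteStatistics <- function(metrics, connectivity = 26L, minVolume = 11) {
    if (is(metrics, "LabeledObjects")) {
        connectivity <- metrics@connectivity
        metrics <- componentMetrics(metrics)
    }
    stopifnot(nrow(metrics) >= 1L)
    mainId <- metrics$id[order(-metrics$volume_um3, metrics$id)][1]
    com <- as.matrix(metrics[, c("com_x", "com_y", "com_z")])
    mainCom <- com[metrics$id == mainId, ]
    d2main <- sqrt(colSums((t(com) - mainCom)^2))
    metrics$is_main <- metrics$id == mainId
    metrics$dist_to_main_um <- ifelse(metrics$is_main, NA_real_, d2main)
    n <- nrow(metrics)
    if (n > 1L) {
        dm <- as.matrix(stats::dist(com))
        diag(dm) <- Inf
        nnIdx <- apply(dm, 1, which.min)
        metrics$nn_id <- metrics$id[nnIdx]
        metrics$nn_dist_um <- dm[cbind(seq_len(n), nnIdx)]
    } else {
        metrics$nn_id <- NA_integer_
        metrics$nn_dist_um <- NA_real_
    }
    new("MorphologyReport", objectTable = metrics,
        mainId = as.integer(mainId), nSatellites = n - 1L,
        totalVolume = sum(metrics$volume_um3),
        connectivity = as.integer(connectivity),
        minVolume = as.numeric(minVolume))
}

#' Keep one half of a stack, cut at the main object's centre of mass
#'
#' Emulates restricting analysis to the half-colony closest to the
#' objective in confocal imaging: voxels on the discarded side of a plane
#' through the main object's centre of mass, perpendicular to \code{axis},
#' are zeroed. \code{keep = "lower"} keeps voxel indices up to and including
#' the COM voxel; "upper" keeps the rest, so the two halves partition the
#' foreground exactly.
#'
#' @param stack a [VoxelStack] (grayscale or binary).
#' @param axis "x", "y" or "z" (default "z", the optical axis).
#' @param keep "lower" or "upper".
#' @param at optional 0-based cut index overriding the COM computation.
#' @return the cropped [VoxelStack].
#' @export
cropHalf <- function(stack, axis = c("z", "x", "y"),
                     keep = c("lower", "upper"), at = NULL) {
    axis <- match.arg(axis)
    keep <- match.arg(keep)
    ax <- match(axis, c("x", "y", "z"))
    d <- dim(stack@values)
    if (d[ax] < 2L) stop("cannot crop a 1-voxel-thick axis")
    if (is.null(at)) {
        mask <- if (is.logical(stack@values)) stack@values else {
            if (length(unique(as.vector(stack@values))) > 2L)
                stackValues(otsuThreshold(stack))
            else stack@values != min(stack@values)
        }
        lab <- .label3dCpp(as.logical(mask), d, 26L)
        nObj <- attr(lab, "n_objects")
        if (nObj == 0L) stop("no foreground: cut plane undefined")
        mainLab <- which.max(tabulate(lab, nObj))
        idx <- arrayInd(which(array(lab, d) == mainLab), d) - 1L
        at <- floor(mean(idx[, ax]))
    }
    v <- stack@values
    sel <- slice.index(v, ax) - 1L
    if (keep == "lower") v[sel > at] <- if (is.logical(v)) FALSE else 0
    else v[sel <= at] <- if (is.logical(v)) FALSE else 0
    new("VoxelStack", values = v, voxelSize = stack@voxelSize,
        origin = stack@origin)
}

#' @describeIn analyzeColony full pipeline on a voxel stack. Grayscale
#'   input is Otsu-thresholded first; binary input (logical values, or
#'   \code{binary = TRUE}) skips thresholding.
#' @param minVolume minimum object volume retained, um^3 (default 11).
#' @param connectivity labeling connectivity (default 26).
#' @param crop optional half-colony crop before thresholding, e.g.
#'   \code{"z:lower"} (axis:keep).
#' @param binary force treating the input as binary.
#' @export
setMethod("analyzeColony", "VoxelStack",
    function(x, minVolume = 11, connectivity = 26L, crop = NULL,
             binary = is.logical(x@values)) {
        if (!is.null(crop)) {
            parts <- strsplit(crop, ":", fixed = TRUE)[[1]]
            x <- cropHalf(x, axis = parts[1],
                          keep = if (length(parts) > 1L) parts[2] else "lower")
        }
        bin <- if (binary) {
            new("VoxelStack", values = x@values != 0,
                voxelSize = x@voxelSize, origin = x@origin)
        } else otsuThreshold(x)
        bin <- removeSmallComponents(bin, minVolume, connectivity)
        lab <- labelComponents(bin, connectivity)
        if (length(lab@objectIds) == 0L) {
            return(new("MorphologyReport",
                objectTable = componentMetrics(lab),
                mainId = NA_integer_, nSatellites = 0L, totalVolume = 0,
                connectivity = as.integer(connectivity),
                minVolume = as.numeric(minVolume)))
        }
        satelliteStatistics(componentMetrics(lab),
                            connectivity = connectivity,
                            minVolume = minVolume)
    })

#' @describeIn analyzeColony converts the simulated lattice to a binary
#'   stack (1 um isotropic voxels) and analyzes it without thresholding,
#'   mirroring how in-silico colonies are fed through the imaging pipeline.
#' @export
setMethod("analyzeColony", "ColonySim",
    function(x, minVolume = 11, connectivity = 26L, crop = NULL) {
        analyzeColony(latticeToStack(occupiedSites(x)),
                      minVolume = minVolume, connectivity = connectivity,
                      crop = crop, binary = TRUE)
    })

#' @describeIn analyzeColony arrays are wrapped as an isotropic 1-um stack.
#' @export
setMethod("analyzeColony", "array", function(x, ...) {
    analyzeColony(VoxelStack(x), ...)
})
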