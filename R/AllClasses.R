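#' @import methods
NULL

#' Simulation parameters for the modified Eden growth model
#'
#' Container for one simulation's contract: division rate \code{k}
#' (set to 1 in the original study, so time is measured in doubling times),
#' jump rate \code{ks}, jump-displacement standard deviation \code{sigma}
#' (lattice units; one lattice site corresponds to one cell volume of about
#' 1 um^3, so lattice units read as micrometres), linear lattice size
#' \code{L}, total division+jump event budget \code{maxEvents} and RNG seed.
#'
#' @slot k division rate (1/time); must be > 0.
#' @slot ks jump rate (1/time); must be >= 0.
#' @slot sigma standard deviation of the Gaussian jump displacement, in
#'   lattice units; must be >= 0.
#' @slot L linear lattice size in sites; must be >= 3.
#' @slot maxEvents event budget (divisions + jumps); must be >= 1.
#' @slot seed integer RNG seed, or NA to leave the RNG state untouched.
#' @slot boundaryMargin early-stop distance from the lattice edge (sites).
#' @slot n2MinEmpty minimum number of empty face-neighbours for a cell to be
#'   jump-capable (population N2). The default 4 follows the model's
#'   pseudo-code ("less than four ... N1, otherwise N2"); set 3 for the
#'   alternative "three or more" reading.
#' @slot boundaryVariant "dedup" (growth uniform over distinct empty surface
#'   sites) or "multiplicity" (surface sites weighted by the number of
#'   adjacent cells).
#' @slot redrawCap maximum number of displacement redraws per jump before the
#'   jump is abandoned.
#'
#' @seealso [SimParams()] for the user constructor, [runColony()].
#' @export
setClass("SimParams",
    representation(
        k = "numeric", ks = "numeric", sigma = "numeric",
        L = "integer", maxEvents = "numeric", seed = "integer",
        boundaryMargin = "integer", n2MinEmpty = "integer",
        boundaryVariant = "character", redrawCap = "integer"),
    validity = function(object) {
        msg <- character()
        chk1 <- function(x, nm) if (length(x) != 1L || is.na(x))
            sprintf("'%s' must be a single non-NA value", nm) else NULL
        for (nm in c("k", "ks", "sigma", "L", "maxEvents", "boundaryMargin",
                     "n2MinEmpty", "boundaryVariant", "redrawCap"))
            msg <- c(msg, chk1(slot(object, nm), nm))
        if (length(msg)) return(msg)
        if (object@k <= 0) msg <- c(msg, "k must be > 0")
        if (object@ks < 0) msg <- c(msg, "ks must be >= 0")
        if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
        if (object@L < 3L) msg <- c(msg, "L must be >= 3")
        if (object@maxEvents < 1) msg <- c(msg, "maxEvents must be >= 1")
        if (object@boundaryMargin < 1L) msg <- c(msg, "boundaryMargin must be >= 1")
        if (object@n2MinEmpty < 1L || object@n2MinEmpty > 6L)
            msg <- c(msg, "n2MinEmpty must be in 1..6")
        if (!object@boundaryVariant %in% c("dedup", "multiplicity"))
            msg <- c(msg, "boundaryVariant must be 'dedup' or 'multiplicity'")
        if (object@redrawCap < 1L) msg <- c(msg, "redrawCap must be >= 1")
        if (length(msg)) msg else TRUE
    })

#' Sparse lattice state for the reference engine
#'
#' World state of the lattice model: a dense logical occupancy array (one
#' cell per site at most), the simulated clock and the cell count. Used by
#' the plain-R reference engine and the low-level lattice operations; the
#' fast incremental engine keeps its own internal state.
#'
#' @slot occ 3D logical array of occupancy, dim c(L, L, L).
#' @slot t simulated time, in units of 1/k.
#' @slot nCells number of occupied sites.
#'
#' @seealso [latticeState()], [classifyPopulations()].
#' @export
setClass("LatticeState",
    representation(occ = "array", t = "numeric", nCells = "integer"),
    validity = function(object) {
        d <- dim(object@occ)
        if (length(d) != 3L || length(unique(d)) != 1L)
            return("occ must be a cubic 3D array")
        if (!is.logical(object@occ)) return("occ must be logical")
        if (object@nCells != sum(object@occ))
            return("nCells must equal the number of occupied sites")
        if (object@t < 0) return("t must be >= 0")
        TRUE
    })

#' Result of one colony simulation
#'
#' Final lattice occupancy, trajectory and per-event log of a modified Eden
#' growth run.
#'
#' @slot params the [SimParams] the run was executed with.
#' @slot sites integer matrix (n x 3) of occupied sites, 0-based x/y/z,
#'   in ascending encoded-site order.
#' @slot time final simulated time (units of 1/k).
#' @slot status "completed" (event budget exhausted), "truncated" (colony
#'   approached the lattice edge) or "jammed" (no cell can act).
#' @slot eventLog data.frame with one row per executed event: event_index,
#'   t, tau, total_rate, event_type (growth/jump/jump_aborted), from_x..to_z
#'   (0-based; from_* NA for growth, to_* NA for aborted jumps) and n_cells
#'   after the event.
#' @slot nAborted number of jumps abandoned after the redraw cap.
#'
#' @seealso [runColony()], [trajectory()], [analyzeColony()].
#' @export
setClass("ColonySim",
    representation(
        params = "SimParams", sites = "matrix", time = "numeric",
        status = "character", eventLog = "data.frame", nAborted = "integer"),
    validity = function(object) {
        if (!object@status %in% c("completed", "truncated", "jammed"))
            return("unknown status")
        if (ncol(object@sites) != 3L) return("sites must have 3 columns")
        TRUE
    })

#' A 3D voxel stack with physical geometry
#'
#' A grayscale or binary image volume plus its voxel size, the unit in which
#' all morphology metrics (volumes, center-of-mass distances, hull volumes)
#' are reported. Voxel indices are 0-based in all user-facing coordinates;
#' the centre of voxel (i,j,k) sits at physical position
#' origin + (i + 0.5, j + 0.5, k + 0.5) * voxelSize.
#'
#' @slot values 3D numeric/integer/logical array of intensities (grayscale)
#'   or 0/1 (binary).
#' @slot voxelSize numeric length-3, micrometres per voxel along x, y, z.
#' @slot origin numeric length-3 physical offset of voxel (0,0,0), um.
#'
#' @seealso [VoxelStack()], [otsuThreshold()], [analyzeColony()].
#' @export
setClass("VoxelStack",
    representation(values = "array", voxelSize = "numeric", origin = "numeric"),
    validity = function(object) {
        if (length(dim(object@values)) != 3L) return("values must be a 3D array")
        if (any(dim(object@values) < 1L)) return("all dimensions must be >= 1")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            return("voxelSize must be 3 positive numbers")
        if (length(object@origin) != 3L) return("origin must have length 3")
        TRUE
    })

#' Labeled connected components of a binary stack
#'
#' @slot labels 3D integer array; 0 is background, objects are 1..n.
#' @slot objectIds sorted positive labels present.
#' @slot connectivity 6, 18 or 26.
#' @slot voxelSize,origin geometry inherited from the source stack.
#'
#' @seealso [labelComponents()], [componentMetrics()].
#' @export
setClass("LabeledObjects",
    representation(labels = "array", objectIds = "integer",
                   connectivity = "integer", voxelSize = "numeric",
                   origin = "numeric"),
    validity = function(object) {
        if (!object@connectivity %in% c(6L, 18L, 26L))
            return("connectivity must be 6, 18 or 26")
        TRUE
    })

#' Morphology report for a segmented colony
#'
#' Per-object metrics plus the satellite summary: the largest object is the
#' main colony, every other connected component is a satellite (a cluster
#' completely detached from the main colony).
#'
#' @slot objectTable data.frame, one row per object: id, n_voxels,
#'   volume_um3, com_x/com_y/com_z (um), convexity, degenerate_hull,
#'   is_main, dist_to_main_um, nn_id, nn_dist_um.
#' @slot mainId label of the largest-volume object (ties: smallest label).
#' @slot nSatellites number of non-main objects.
#' @slot totalVolume summed object volume, um^3.
#' @slot connectivity labeling connectivity used.
#' @slot minVolume small-object filter threshold used, um^3.
#'
#' @seealso [satelliteStatistics()], [analyzeColony()].
#' @export
setClass("MorphologyReport",
    representation(objectTable = "data.frame", mainId = "integer",
                   nSatellites = "integer", totalVolume = "numeric",
                   connectivity = "integer", minVolume = "numeric"),
    validity = function(object) {
        n <- nrow(object@objectTable)
        if (n > 0L && object@nSatellites != n - 1L)
            return("nSatellites must be number of objects minus 1")
        TRUE
    })

#' Specification of a synthetic ground-truth voxel stack
#'
#' Describes a quasi-spherical main colony (an ellipsoid), a set of small
#' spherical satellites, additive Gaussian noise and salt speckle (isolated
#' bright voxels below the small-object filter), from which [makeStack()]
#' rasterizes a grayscale stack with exactly known ground truth.
#'
#' @slot shape integer length-3 stack dimensions (voxels).
#' @slot voxelSize numeric length-3, um/voxel.
#' @slot mainCenter,mainSemiAxes main-colony ellipsoid centre and semi-axes, um.
#' @slot satellites data.frame with columns cx, cy, cz, r (um).
#' @slot background,objectIntensity,noiseSd intensity model (arbitrary units).
#' @slot speckleRate expected fraction of background voxels turned into
#'   isolated bright speckle voxels.
#' @slot seed integer RNG seed.
#' @export
setClass("FixtureSpec",
    representation(shape = "integer", voxelSize = "numeric",
                   mainCenter = "numeric", mainSemiAxes = "numeric",
                   satellites = "data.frame", background = "numeric",
                   objectIntensity = "numeric", noiseSd = "numeric",
                   speckleRate = "numeric", seed = "integer"),
    validity = function(object) {
        if (length(object@shape) != 3L || any(object@shape < 1L))
            return("shape must be 3 positive integers")
        if (any(object@voxelSize <= 0)) return("voxelSize must be positive")
        if (any(object@mainSemiAxes <= 0)) return("mainSemiAxes must be positive")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (object@speckleRate < 0 || object@speckleRate > 0.01)
            return("speckleRate must be in [0, 0.01]")
        TRUE
    })

#' Ground truth accompanying a synthetic stack
#'
#' @slot mask 3D logical array: the noise-free foreground.
#' @slot objects data.frame per planted object: id, type (main/satellite),
#'   n_voxels, volume_um3, com_x/com_y/com_z (um).
#' @slot expectedCount number of objects expected after the minimum-volume
#'   filter (speckle excluded).
#' @export
setClass("FixtureTruth",
    representation(mask = "array", objects = "data.frame",
                   expectedCount = "integer"))

#' Specification of a (sigma x ks) parameter sweep
#'
#' @slot sigmaValues jump-distance grid (default c(2, 5, 7, 10)).
#' @slot ksValues jump-rate grid (default c(0.001, 0.05, 0.1, 0.2)).
#' @slot replicates replicate simulations per grid cell (default 30).
#' @slot baseParams [SimParams] template; sigma/ks/seed are overwritten
#'   per cell and replicate.
#' @slot baseSeed base RNG seed; replicate j of cell i runs with seed
#'   baseSeed + (i-1)*replicates + (j-1).
#' @export
setClass("SweepSpec",
    representation(sigmaValues = "numeric", ksValues = "numeric",
                   replicates = "integer", baseParams = "SimParams",
                   baseSeed = "integer"),
    validity = function(object) {
        if (length(object@sigmaValues) < 1L || length(object@ksValues) < 1L)
            return("parameter grids must be nonempty")
        if (object@replicates < 1L) return("replicates must be >= 1")
        TRUE
    })

#' Results of a parameter sweep
#'
#' @slot spec the [SweepSpec] executed.
#' @slot records data.frame with one row per run: sigma, ks, replicate,
#'   seed, status, n_cells, final_time, n_satellites, main_volume_fraction,
#'   total_volume_um3, satellite_volumes and com distances are stored in the
#'   list-columns satellite_volumes / com_distances.
#' @slot trajectories list of per-run resampled population curves
#'   (data.frame t, n_cells), same order as records rows.
#' @slot summaryTable per-cell aggregates: sigma, ks, n_runs, mean/sd
#'   satellites, mean final population, cv of total volume, mean main-colony
#'   volume fraction, regime label.
#' @seealso [runSweep()], [compareRegimes()].
#' @export
setClass("SweepSummary",
    representation(spec = "SweepSpec", records = "data.frame",
                   trajectories = "list", summaryTable = "data.frame"))
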