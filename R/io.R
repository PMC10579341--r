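# Readers, writers and configuration shared by all modules. Stacks travel
# as multi-page TIFF (one page per z-slice) with a JSON sidecar carrying the
# voxel size, or as a raw float32/uint8 array with the same sidecar. Site
# lists, event logs and sweep summaries are plain CSV; reports and run
# manifests are JSON; configs are YAML or JSON.

.sidecarPath <- function(path) paste0(path, ".json")

#' Read a voxel stack
#'
#' Supports multi-page grayscale/binary TIFF (8/16-bit values are returned
#' unscaled) and the raw-array dialect (\code{.bin} + JSON sidecar with
#' dim, dtype and voxel size). The voxel size is taken from the JSON
#' sidecar \code{<path>.json} when present; an explicit \code{voxelSize}
#' argument wins over the sidecar (with a notice), and the absence of both
#' is an error.
#'
#' @param path file path (.tif/.tiff or .bin).
#' @param voxelSize optional um/voxel override, length 1 or 3.
#' @return a [VoxelStack].
#' @export
readStack <- function(path, voxelSize = NULL) {
    if (!file.exists(path)) stop("cannot read stack: ", path)
    side <- NULL
    if (file.exists(.sidecarPath(path)))
        side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    if (grepl("\\.bin$", path)) {
        if (is.null(side)) stop("raw stack requires a JSON sidecar: ",
                                .sidecarPath(path))
        d <- as.integer(side$dim)
        n <- prod(d)
        con <- file(path, "rb")
        on.exit(close(con))
        vals <- switch(side$dtype,
            float64 = readBin(con, "double", n, size = 8),
            float32 = readBin(con, "double", n, size = 4),
            uint8 = as.numeric(readBin(con, "integer", n, size = 1,
                                       signed = FALSE)),
            stop("unsupported raw dtype: ", side$dtype))
        values <- array(vals, dim = d)
    } else {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (!is.list(pages)) pages <- list(pages)
        shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
        if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
            stop("inconsistent page shapes in ", path)
        # readTIFF pages are row x col matrices; store as x (rows) by y (cols)
        values <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2],
                                               length(pages)))
    }
    vsz <- voxelSize
    if (!is.null(vsz) && !is.null(side$voxel_size_um))
        message("voxelSize argument overrides the sidecar voxel size")
    if (is.null(vsz)) vsz <- side$voxel_size_um
    if (is.null(vsz))
        stop("no voxel size: provide 'voxelSize' or a sidecar with voxel_size_um")
    if (length(vsz) == 1L) vsz <- rep(vsz, 3L)
    VoxelStack(values, as.numeric(vsz))
}

#' Write a voxel stack
#'
#' Binary stacks are written as 8-bit 0/255 TIFF pages, grayscale as 8- or
#' 16-bit depending on range. A JSON sidecar \code{<path>.json} always
#' carries dim and voxel size so [readStack()] round-trips losslessly.
#' Paths ending in \code{.bin} use the raw float64 dialect instead.
#'
#' @param stack a [VoxelStack].
#' @param path output path (.tif or .bin).
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path) {
    v <- stack@values
    if (grepl("\\.bin$", path)) {
        con <- file(path, "wb")
        writeBin(as.numeric(v), con, size = 8)
        close(con)
        dtype <- "float64"
    } else {
        if (is.logical(v)) {
            pages <- lapply(seq_len(dim(v)[3]),
                            function(z) (v[, , z] * 1) )
            bits <- 8L
        } else {
            mx <- max(v)
            bits <- if (mx <= 255 && min(v) >= 0 &&
                        all(v == round(v))) 8L else 16L
            scaleTo <- if (bits == 8L) 255 else 65535
            pages <- lapply(seq_len(dim(v)[3]), function(z)
                pmax(pmin(round(v[, , z]), scaleTo), 0) / scaleTo)
        }
        tiff::writeTIFF(pages, path, bits.per.sample = bits)
        dtype <- paste0("uint", bits)
    }
    jsonlite::write_json(
        list(dim = dim(v), dtype = dtype,
             voxel_size_um = stack@voxelSize, origin_um = stack@origin),
        .sidecarPath(path), auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' Read or write a sparse site list
#'
#' CSV with 0-based integer columns x, y, z; the export format of the
#' simulated lattice.
#'
#' @param x a [ColonySim] or an integer site matrix.
#' @param path CSV path.
#' @return \code{writeSiteList}: the path, invisibly; \code{readSiteList}:
#'   an integer matrix.
#' @export
writeSiteList <- function(x, path) {
    sites <- if (is(x, "ColonySim")) occupiedSites(x) else x
    utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSiteList
#' @export
readSiteList <- function(path) {
    d <- utils::read.csv(path)
    m <- as.matrix(d[, c("x", "y", "z")])
    storage.mode(m) <- "integer"
    m
}

#' Write the per-event log of a run
#'
#' CSV columns: event_index, t, tau, total_rate, event_type,
#' from_x..from_z, to_x..to_z (empty for inapplicable fields), n_cells.
#'
#' @param sim a [ColonySim].
#' @param path CSV path.
#' @export
writeEventLog <- function(sim, path) {
    utils::write.csv(eventLog(sim), path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to re-execute the run: package version, resolved
#' parameters, seed, termination status, final cell count and time, and
#' md5 checksums of any associated files.
#'
#' @param sim a [ColonySim].
#' @param path JSON path.
#' @param files optional character vector of file paths to checksum.
#' @param elapsed optional wall-clock seconds.
#' @export
writeManifest <- function(sim, path, files = character(), elapsed = NA) {
    p <- simParams(sim)
    man <- list(
        tool = "edenSat",
        version = as.character(utils::packageVersion("edenSat")),
        params = list(k = p@k, k_s = p@ks, sigma = p@sigma, L = p@L,
                      max_events = p@maxEvents, seed = p@seed,
                      boundary_margin = p@boundaryMargin,
                      n2_min_empty = p@n2MinEmpty,
                      boundary_variant = p@boundaryVariant,
                      redraw_cap = p@redrawCap),
        status = simStatus(sim),
        n_cells = nCells(sim),
        final_time = finalTime(sim),
        n_aborted_jumps = sim@nAborted,
        elapsed_sec = elapsed,
        files = if (length(files))
            as.list(tools::md5sum(files)) else NULL)
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Write a morphology report
#'
#' The summary goes to JSON; [writeObjectTable()] writes the per-object
#' table as CSV.
#'
#' @param report a [MorphologyReport].
#' @param path output path.
#' @export
writeReport <- function(report, path) {
    tab <- objectTable(report)
    out <- list(main_id = mainColonyId(report),
                n_satellites = nSatellites(report),
                total_volume_um3 = totalVolume(report),
                satellite_volumes_um3 = satelliteVolumes(report),
                com_distances_um = comDistances(report),
                connectivity = report@connectivity,
                min_volume_um3 = report@minVolume,
                objects = tab)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    invisible(path)
}

#' @rdname writeReport
#' @export
writeObjectTable <- function(report, path) {
    utils::write.csv(objectTable(report), path, row.names = FALSE, na = "")
    invisible(path)
}

.simKeys <- c("k", "k_s", "sigma", "L", "max_events", "seed",
              "boundary_margin", "n2_min_empty", "boundary_variant",
              "redraw_cap")
.sweepKeys <- c("sigma_values", "ks_values", "replicates", "base_seed",
                "base")

#' Load and validate a configuration file
#'
#' YAML or JSON (by extension). Missing keys take the documented defaults;
#' unknown keys and invariant violations are reported together, listing
#' every offending key. Simulation configs accept the keys
#' k, k_s, sigma, L, max_events, seed, boundary_margin, n2_min_empty,
#' boundary_variant, redraw_cap; sweep configs accept sigma_values,
#' ks_values, replicates, base_seed and a nested \code{base} simulation
#' config.
#'
#' @param path config file.
#' @param type "simulate" or "sweep".
#' @return a [SimParams] or [SweepSpec].
#' @export
loadConfig <- function(path, type = c("simulate", "sweep")) {
    type <- match.arg(type)
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(cfg)) cfg <- list()
    if (type == "simulate") .simParamsFromConfig(cfg) else {
        unknown <- setdiff(names(cfg), .sweepKeys)
        if (length(unknown))
            stop("unknown config key(s): ", paste(unknown, collapse = ", "))
        base <- if (!is.null(cfg$base)) .simParamsFromConfig(cfg$base)
                else SimParams(maxEvents = 1e6)
        args <- list(baseParams = base)
        if (!is.null(cfg$sigma_values)) args$sigmaValues <- unlist(cfg$sigma_values)
        if (!is.null(cfg$ks_values)) args$ksValues <- unlist(cfg$ks_values)
        if (!is.null(cfg$replicates)) args$replicates <- cfg$replicates
        if (!is.null(cfg$base_seed)) args$baseSeed <- cfg$base_seed
        do.call(sweepSpec, args)
    }
}

.simParamsFromConfig <- function(cfg) {
    unknown <- setdiff(names(cfg), .simKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    args <- list()
    map <- c(k = "k", k_s = "ks", sigma = "sigma", L = "L",
             max_events = "maxEvents", seed = "seed",
             boundary_margin = "boundaryMargin", n2_min_empty = "n2MinEmpty",
             boundary_variant = "boundaryVariant", redraw_cap = "redrawCap")
    for (key in names(cfg)) args[[map[[key]]]] <- cfg[[key]]
    tryCatch(do.call(SimParams, args), error = function(e)
        stop("invalid configuration: ", conditionMessage(e), call. = FALSE))
}
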