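# Synthetic ground-truth voxel stacks: a quasi-spherical main colony plus
# small detached satellites, additive Gaussian noise and sub-filter speckle.
# These emulate confocal z-stacks of embedded colonies well enough to
# exercise the full morphology pipeline against an exactly known answer.

#' Construct a fixture specification
#'
#' Defaults emulate the scales of confocal colony snapshots: a main colony
#' of ~1.1e5 um^3 in a ~243 x 243 x 213 um field of view with anisotropic
#' confocal voxels (1.52, 1.52, 1.33 um), three detached ~113 um^3
#' satellites placed 80-105 um from the main centre in random directions,
#' an object/background intensity gap of about 13 noise standard
#' deviations, and isolated speckle voxels below the 11 um^3 filter.
#'
#' @param shape stack dimensions, voxels.
#' @param voxelSize um per voxel (x, y, z).
#' @param mainCenter,mainSemiAxes main-colony ellipsoid, um; default centre
#'   of the volume, semi-axes 30 um.
#' @param satellites data.frame(cx, cy, cz, r) in um, or an integer count n
#'   to place n satellites of radius \code{satelliteRadius} at random
#'   non-overlapping positions 80-105 um from the main centre (drawn from
#'   the seeded RNG).
#' @param satelliteRadius radius used when \code{satellites} is a count, um.
#' @param background,objectIntensity,noiseSd intensity model.
#' @param speckleRate expected fraction of voxels turned into isolated
#'   bright speckles.
#' @param seed RNG seed; the stack is a deterministic function of the spec.
#' @return a validated [FixtureSpec]; overlapping objects are an error
#'   naming the offending pair.
#' @export
fixtureSpec <- function(shape = c(160L, 160L, 160L),
                        voxelSize = c(1.52, 1.52, 1.33),
                        mainCenter = NULL, mainSemiAxes = c(30, 30, 30),
                        satellites = 3L, satelliteRadius = 3,
                        background = 10, objectIntensity = 200,
                        noiseSd = 15, speckleRate = 2e-5, seed = 1L) {
    shape <- as.integer(shape)
    phys <- shape * voxelSize
    if (is.null(mainCenter)) mainCenter <- phys / 2
    if (is.numeric(satellites) && length(satellites) == 1L &&
        !is.data.frame(satellites)) {
        n <- as.integer(satellites)
        satellites <- data.frame(cx = numeric(), cy = numeric(),
                                 cz = numeric(), r = numeric())
        if (n > 0L) {
            set.seed(as.integer(seed) + 1000000L)
            placed <- 0L
            tries <- 0L
            while (placed < n && tries < 1000L) {
                tries <- tries + 1L
                u <- stats::rnorm(3)
                u <- u / sqrt(sum(u^2))
                dist <- stats::runif(1, 80, 105)
                cand <- mainCenter + u * dist
                if (any(cand < satelliteRadius + 2) ||
                    any(cand > phys - satelliteRadius - 2)) next
                ok <- .satelliteClear(cand, satelliteRadius, mainCenter,
                                      mainSemiAxes, satellites)
                if (!ok) next
                satellites <- rbind(satellites,
                    data.frame(cx = cand[1], cy = cand[2], cz = cand[3],
                               r = satelliteRadius))
                placed <- placed + 1L
            }
            if (placed < n) stop("could not place all satellites without overlap")
        }
    }
    .checkOverlaps(mainCenter, mainSemiAxes, satellites)
    new("FixtureSpec", shape = shape, voxelSize = as.numeric(voxelSize),
        mainCenter = as.numeric(mainCenter),
        mainSemiAxes = as.numeric(mainSemiAxes),
        satellites = satellites, background = as.numeric(background),
        objectIntensity = as.numeric(objectIntensity),
        noiseSd = as.numeric(noiseSd), speckleRate = as.numeric(speckleRate),
        seed = as.integer(seed))
}

.satelliteClear <- function(center, r, mainCenter, mainSemiAxes, satellites) {
    # clearance from the main ellipsoid: conservative bounding-sphere test
    gap <- 3
    if (sqrt(sum((center - mainCenter)^2)) < max(mainSemiAxes) + r + gap)
        return(FALSE)
    if (nrow(satellites) > 0L) {
        d <- sqrt((satellites$cx - center[1])^2 +
                  (satellites$cy - center[2])^2 +
                  (satellites$cz - center[3])^2)
        if (any(d < satellites$r + r + gap)) return(FALSE)
    }
    TRUE
}

.checkOverlaps <- function(mainCenter, mainSemiAxes, satellites) {
    n <- nrow(satellites)
    if (n == 0L) return(invisible(TRUE))
    d <- sqrt((satellites$cx - mainCenter[1])^2 +
              (satellites$cy - mainCenter[2])^2 +
              (satellites$cz - mainCenter[3])^2)
    bad <- which(d <= max(mainSemiAxes) + satellites$r)
    if (length(bad))
        stop(sprintf("satellite %d overlaps the main colony", bad[1]))
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            dij <- sqrt((satellites$cx[i] - satellites$cx[j])^2 +
                        (satellites$cy[i] - satellites$cy[j])^2 +
                        (satellites$cz[i] - satellites$cz[j])^2)
            if (dij <= satellites$r[i] + satellites$r[j])
                stop(sprintf("satellites %d and %d overlap", i, j))
        }
    }
    invisible(TRUE)
}

#' Rasterize a fixture specification into a grayscale stack
#'
#' A voxel is foreground when its centre lies inside one of the analytic
#' solids. Foreground voxels get the object intensity and background voxels
#' the background intensity; independent Gaussian noise is added everywhere
#' and a sparse set of isolated background voxels (at least 2 voxels clear
#' of any foreground or other speckle, so speckle can never join into a
#' filter-surviving cluster) is set to the object intensity.
#'
#' @param spec a [FixtureSpec].
#' @return list(stack = [VoxelStack], truth = [FixtureTruth]); identical
#'   spec (including seed) gives identical stacks.
#' @export
makeStack <- function(spec) {
    stopifnot(is(spec, "FixtureSpec"))
    .checkOverlaps(spec@mainCenter, spec@mainSemiAxes, spec@satellites)
    set.seed(spec@seed)
    d <- spec@shape
    vs <- spec@voxelSize
    # physical voxel-centre coordinate vectors
    cx <- (seq_len(d[1]) - 0.5) * vs[1]
    cy <- (seq_len(d[2]) - 0.5) * vs[2]
    cz <- (seq_len(d[3]) - 0.5) * vs[3]

    insideEllipsoid <- function(center, semi) {
        ex <- ((cx - center[1]) / semi[1])^2
        ey <- ((cy - center[2]) / semi[2])^2
        ez <- ((cz - center[3]) / semi[3])^2
        outer(outer(ex, ey, "+"), ez, "+") <= 1
    }

    objMask <- vector("list", 1L + nrow(spec@satellites))
    objMask[[1]] <- insideEllipsoid(spec@mainCenter, spec@mainSemiAxes)
    for (i in seq_len(nrow(spec@satellites))) {
        s <- spec@satellites[i, ]
        objMask[[i + 1L]] <- insideEllipsoid(c(s$cx, s$cy, s$cz), rep(s$r, 3))
    }
    mask <- Reduce(`|`, objMask)

    values <- array(spec@background, dim = d)
    values[mask] <- spec@objectIntensity

    # speckle: isolated bright voxels, rejected near foreground or each other
    nSpeckle <- stats::rbinom(1, prod(d), spec@speckleRate)
    speckle <- matrix(integer(), 0, 3)
    if (nSpeckle > 0L) {
        cand <- cbind(sample.int(d[1], nSpeckle * 3, replace = TRUE),
                      sample.int(d[2], nSpeckle * 3, replace = TRUE),
                      sample.int(d[3], nSpeckle * 3, replace = TRUE))
        for (r in seq_len(nrow(cand))) {
            if (nrow(speckle) >= nSpeckle) break
            p <- cand[r, ]
            lo <- pmax(p - 2L, 1L)
            hi <- pmin(p + 2L, d)
            if (any(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])) next
            if (nrow(speckle) > 0L &&
                any(colSums(abs(t(speckle) - p) <= 2L) == 3L)) next
            speckle <- rbind(speckle, p)
        }
        if (nrow(speckle)) values[speckle] <- spec@objectIntensity
    }

    if (spec@noiseSd > 0)
        values <- values + array(stats::rnorm(prod(d), 0, spec@noiseSd), d)

    voxVol <- prod(vs)
    objs <- lapply(seq_along(objMask), function(i) {
        m <- objMask[[i]]
        idx <- which(m)
        co <- arrayInd(idx, d) - 1L
        com <- (colMeans(co) + 0.5) * vs
        data.frame(id = i, type = if (i == 1L) "main" else "satellite",
                   n_voxels = length(idx), volume_um3 = length(idx) * voxVol,
                   com_x = com[1], com_y = com[2], com_z = com[3])
    })
    objs <- do.call(rbind, objs)
    expected <- sum(objs$volume_um3 >= 11)

    list(stack = VoxelStack(values, vs),
         truth = new("FixtureTruth", mask = mask, objects = objs,
                     expectedCount = as.integer(expected)))
}

#' Convert a lattice site list to a padded binary stack
#'
#' Bridges the simulator to the imaging pipeline: occupied sites become
#' foreground voxels (1 um isotropic by default) inside an empty margin of
#' \code{pad} voxels. [stackToSites()] inverts the mapping; the round trip
#' site list -> stack -> site list is the identity (up to row order).
#'
#' @param sites integer matrix (n x 3) of 0-based sites, or a [ColonySim].
#' @param pad empty margin, voxels.
#' @param voxelSize um per voxel.
#' @return a binary [VoxelStack]; the offset subtracted from the site
#'   coordinates is stored in its origin (um).
#' @export
latticeToStack <- function(sites, pad = 2L, voxelSize = c(1, 1, 1)) {
    if (is(sites, "ColonySim")) sites <- occupiedSites(sites)
    stopifnot(nrow(sites) > 0L)
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    lo <- apply(sites, 2, min)
    hi <- apply(sites, 2, max)
    d <- hi - lo + 1L + 2L * pad
    v <- array(FALSE, dim = d)
    shifted <- sweep(sites, 2, lo - pad) + 1L
    v[shifted] <- TRUE
    VoxelStack(v, voxelSize, origin = (lo - pad) * voxelSize)
}

#' @rdname latticeToStack
#' @param stack a binary [VoxelStack] produced by [latticeToStack()].
#' @export
stackToSites <- function(stack) {
    idx <- which(stack@values != 0)
    co <- arrayInd(idx, dim(stack@values)) - 1L
    off <- round(stack@origin / stack@voxelSize)
    out <- sweep(co, 2, -off)
    storage.mode(out) <- "integer"
    colnames(out) <- c("x", "y", "z")
    out
}
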