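# Shared helpers: independent brute-force oracles and small builders.

# Build a LatticeState from a matrix of 0-based sites.
makeState <- function(L, sites) {
    latticeState(L, sites = sites)
}

# All 0-based sites of an axis-aligned block [lo, hi] (inclusive).
blockSites <- function(lo, hi) {
    as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
}

# Brute-force population partition: per-site loops, no shared code with
# classifyPopulations. Returns sorted encoded-site vectors.
bruteForcePartition <- function(state, n2MinEmpty = 4L) {
    occ <- state@occ
    L <- dim(occ)[1]
    n1 <- n2 <- integer()
    boundary <- integer()
    bmult <- integer()
    cells <- which(occ, arr.ind = TRUE) - 1L
    lo <- pmax(apply(cells, 2, min) - 1L, 0L)
    hi <- pmin(apply(cells, 2, max) + 1L, L - 1L)
    for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3]) {
        code <- x + L * (y + L * z)
        nbs <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                     c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
        inside <- nbs[, 1] >= 0 & nbs[, 1] < L & nbs[, 2] >= 0 &
                  nbs[, 2] < L & nbs[, 3] >= 0 & nbs[, 3] < L
        occNb <- sum(apply(nbs[inside, , drop = FALSE] + 1, 1,
                           function(s) occ[s[1], s[2], s[3]]))
        if (occ[x + 1, y + 1, z + 1]) {
            emptyNb <- sum(inside) - occNb
            if (emptyNb >= 1 && emptyNb < n2MinEmpty) n1 <- c(n1, code)
            if (emptyNb >= n2MinEmpty) n2 <- c(n2, code)
        } else if (occNb >= 1) {
            boundary <- c(boundary, code)
            bmult <- c(bmult, occNb)
        }
    }
    list(n1 = sort(n1), n2 = sort(n2), boundary = sort(boundary),
         multiplicity = bmult[order(boundary)])
}

# Small, fast fixture spec used where the full default field of view is not
# needed: isotropic 1-um voxels, 64^3 stack, 12-um main colony, satellites
# of radius 2 um at ~22 um from the centre.
smallFixtureSpec <- function(seed = 1L, nSatellites = 3L, noiseSd = 8,
                             speckleRate = 0) {
    sats <- data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                       r = numeric())
    if (nSatellites > 0L) {
        ang <- seq(0, 2 * pi, length.out = nSatellites + 1L)[-1]
        sats <- data.frame(cx = 32 + 22 * cos(ang), cy = 32 + 22 * sin(ang),
                           cz = rep(32, nSatellites), r = 2)
    }
    fixtureSpec(shape = c(64L, 64L, 64L), voxelSize = c(1, 1, 1),
                mainCenter = c(32, 32, 32), mainSemiAxes = c(12, 12, 12),
                satellites = sats, background = 10, objectIntensity = 200,
                noiseSd = noiseSd, speckleRate = speckleRate, seed = seed)
}

# Binary stack from explicit 1-based foreground voxel indices.
stackFromVoxels <- function(dim, voxels, voxelSize = c(1, 1, 1)) {
    v <- array(FALSE, dim = dim)
    v[voxels] <- TRUE
    VoxelStack(v, voxelSize)
}
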