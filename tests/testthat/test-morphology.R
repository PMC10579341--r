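# Thresholding, filtering, labeling and object metrics.

test_that("Otsu separates a two-valued stack exactly, both polarities", {
    set.seed(1)
    v <- array(10, c(8, 8, 8))
    obj <- cbind(sample(3:6, 40, TRUE), sample(3:6, 40, TRUE),
                 sample(3:6, 40, TRUE))
    v[obj] <- 200
    stk <- VoxelStack(v)
    mask <- stackValues(otsuThreshold(stk))
    expect_identical(unname(which(mask)), unname(which(v == 200)))

    flipped <- VoxelStack(210 - v)      # intensity flip: complement mask
    maskF <- stackValues(otsuThreshold(flipped))
    expect_identical(which(maskF), which(v == 10))

    expect_error(otsuThreshold(VoxelStack(array(5, c(4, 4, 4)))), "constant")
})

test_that("Otsu agrees with an independent implementation on noisy data", {
    fx <- makeStack(smallFixtureSpec(seed = 3))
    v <- stackValues(fx$stack)
    rng <- range(v)
    lvl <- otsuLevel(fx$stack)
    # EBImage's Otsu (framewise) on the volume flattened to one frame:
    # Otsu depends only on the histogram, so the reshape is immaterial.
    # Thresholds may sit anywhere in the empty between-class gap, so the
    # comparison is on the resulting masks.
    norm <- matrix((v - rng[1]) / diff(rng), nrow = 64 * 64)
    ref <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    expect_lt(mean(xor(as.vector(v > lvl), as.vector(norm > ref))), 1e-3)
})

test_that("the minimum-volume filter applies 'smaller than' exactly", {
    mk <- function(n) {
        # a straight line of n voxels: one connected component
        stackFromVoxels(c(20, 5, 5), cbind(seq_len(n) + 1L, 3L, 3L))
    }
    expect_equal(sum(stackValues(removeSmallComponents(mk(10)))), 0)
    expect_equal(sum(stackValues(removeSmallComponents(mk(11)))), 11)
    # empty in, empty out
    empty <- stackFromVoxels(c(5, 5, 5), cbind(integer(), integer(), integer()))
    expect_equal(sum(stackValues(removeSmallComponents(empty))), 0)
})

test_that("no sub-threshold component survives the filter", {
    set.seed(4)
    v <- array(runif(30^3) < 0.08, c(30, 30, 30))
    filt <- removeSmallComponents(VoxelStack(v), minVolume = 11)
    lab <- labelComponents(filt)
    if (length(lab@objectIds) > 0) {
        sizes <- tabulate(lab@labels[lab@labels > 0])
        expect_true(all(sizes >= 11))
    }
    # nothing is ever added
    expect_true(all(which(stackValues(filt)) %in% which(v)))
})

test_that("labeling respects connectivity and is deterministic", {
    twoCubes <- stackFromVoxels(c(12, 12, 12),
        rbind(blockSites(c(1, 1, 1), c(3, 3, 3)) + 1L,
              blockSites(c(7, 7, 7), c(9, 9, 9)) + 1L))
    expect_length(labelComponents(twoCubes)@objectIds, 2)

    # corner contact: one object under 26-connectivity, two under 6
    corner <- stackFromVoxels(c(10, 10, 10),
        rbind(blockSites(c(1, 1, 1), c(3, 3, 3)) + 1L,
              blockSites(c(4, 4, 4), c(6, 6, 6)) + 1L))
    expect_length(labelComponents(corner, 26L)@objectIds, 1)
    expect_length(labelComponents(corner, 6L)@objectIds, 2)

    # idempotent and order-independent: same voxel partition regardless of
    # the order the voxels were painted in
    set.seed(5)
    vox <- unique(matrix(sample.int(15, 300, TRUE), ncol = 3))
    a <- labelComponents(stackFromVoxels(c(15, 15, 15), vox))
    b <- labelComponents(stackFromVoxels(c(15, 15, 15),
                                         vox[sample(nrow(vox)), ]))
    expect_identical(a@labels, b@labels)
})

test_that("object metrics: volume, COM and convexity on known solids", {
    cube <- stackFromVoxels(c(10, 10, 10), blockSites(c(2, 2, 2), c(3, 3, 3)) + 1L)
    m <- componentMetrics(labelComponents(cube))
    expect_equal(m$volume_um3, 8)
    expect_equal(c(m$com_x, m$com_y, m$com_z), c(3, 3, 3))
    expect_equal(m$convexity, 1)        # boxes are exactly convex

    # anisotropic voxels: physical units everywhere
    one <- stackFromVoxels(c(4, 4, 4), cbind(2L, 2L, 2L),
                           voxelSize = c(1.52, 1.52, 1.33))
    m1 <- componentMetrics(labelComponents(one))
    expect_equal(m1$volume_um3, 1.52 * 1.52 * 1.33)
    expect_equal(c(m1$com_x, m1$com_y, m1$com_z),
                 c(1.5 * 1.52, 1.5 * 1.52, 1.5 * 1.33))

    # a 3D plus is not convex
    plus <- stackFromVoxels(c(15, 15, 15), rbind(
        cbind(3:11, 7L, 7L), cbind(7L, 3:11, 7L), cbind(7L, 7L, 3:11)))
    mp <- componentMetrics(labelComponents(plus))
    expect_lt(mp$convexity, 1)

    # volume conservation across objects
    set.seed(6)
    v <- array(runif(20^3) < 0.1, c(20, 20, 20))
    lab <- labelComponents(VoxelStack(v))
    mm <- componentMetrics(lab)
    expect_equal(sum(mm$volume_um3), sum(v))
    expect_equal(sum(mm$n_voxels), sum(v))
})

test_that("convex hull volumes match closed forms", {
    cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    expect_equal(convexHullVolume(cube), 1)
    expect_equal(convexHullVolume(cube * 3), 27)
    tetra <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
    expect_equal(convexHullVolume(tetra), 8 / 6)
    octa <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                  c(0, 0, 2), c(0, 0, -2))
    expect_equal(convexHullVolume(octa), 4 / 3 * 8)
    # interior points never change the hull
    set.seed(7)
    inner <- matrix(runif(300, 0.1, 0.9), ncol = 3)
    expect_equal(convexHullVolume(rbind(cube, inner)), 1)
    # degenerate inputs have zero hull volume
    expect_equal(convexHullVolume(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))), 0)
    expect_equal(convexHullVolume(cbind(runif(20), runif(20), 0.5)), 0)
})

test_that("digitized balls of >= 100 voxels have convexity >= 0.9", {
    for (r in c(3.2, 5.1, 8.4)) {
        n <- ceiling(2 * r) + 3
        g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
        c0 <- (n + 1) / 2
        inside <- (g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2
        ball <- stackFromVoxels(c(n, n, n), as.matrix(g[inside, ]))
        m <- componentMetrics(labelComponents(ball))
        expect_gte(m$n_voxels, 100)
        expect_gte(m$convexity, 0.9)
        expect_lte(m$convexity, 1)
    }
})

test_that("satellite bookkeeping: main selection, counts, distances", {
    one <- stackFromVoxels(c(8, 8, 8), blockSites(c(2, 2, 2), c(4, 4, 4)) + 1L)
    r1 <- satelliteStatistics(componentMetrics(labelComponents(one)))
    expect_equal(nSatellites(r1), 0L)
    expect_length(comDistances(r1), 0)

    # volumes {1000, 8, 8}: the large object is main, ties elsewhere fine
    big <- stackFromVoxels(c(40, 14, 14),
        rbind(blockSites(c(1, 1, 1), c(10, 10, 10)) + 1L,
              blockSites(c(20, 2, 2), c(21, 3, 3)) + 1L,
              blockSites(c(30, 2, 2), c(31, 3, 3)) + 1L))
    r2 <- satelliteStatistics(componentMetrics(labelComponents(big)))
    expect_equal(nSatellites(r2), 2L)
    tab <- objectTable(r2)
    expect_equal(tab$volume_um3[tab$is_main], 1000)
    expect_true(all(comDistances(r2) > 0))
    expect_equal(satelliteVolumes(r2), c(8, 8))

    # two single-voxel objects 10 voxels apart: COM distance 10 um
    pair <- stackFromVoxels(c(15, 5, 5), rbind(c(2L, 2L, 2L), c(12L, 2L, 2L)))
    r3 <- satelliteStatistics(componentMetrics(labelComponents(pair)))
    expect_equal(comDistances(r3), 10)
    expect_equal(objectTable(r3)$nn_dist_um, c(10, 10))

    # equal volumes: main is the smallest label
    r4 <- satelliteStatistics(componentMetrics(labelComponents(
        stackFromVoxels(c(12, 5, 5), rbind(c(2L, 2L, 2L), c(9L, 2L, 2L))))))
    expect_equal(mainColonyId(r4), 1L)
})

test_that("half-colony cropping partitions the foreground at the COM", {
    n <- 25
    g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
    c0 <- (n + 1) / 2
    inside <- (g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= 9^2
    ball <- stackFromVoxels(c(n, n, n), as.matrix(g[inside, ]))

    lowerH <- cropHalf(ball, axis = "z", keep = "lower")
    upperH <- cropHalf(ball, axis = "z", keep = "upper")
    vl <- sum(stackValues(lowerH)); vu <- sum(stackValues(upperH))
    # halves differ by at most one voxel layer and partition exactly
    layer <- max(tabulate(as.matrix(g[inside, ])[, 3]))
    expect_lte(abs(vl - vu), layer)
    expect_equal(vl + vu, sum(inside))
    expect_equal(which(stackValues(lowerH)) , setdiff(which(stackValues(ball)),
                                                      which(stackValues(upperH))))

    thin <- stackFromVoxels(c(5, 5, 1), cbind(2L, 2L, 1L))
    expect_error(cropHalf(thin, axis = "z"), "thick")
})

test_that("the full pipeline skips thresholding on binary input and is deterministic", {
    sim <- runColony(SimParams(ks = 0, sigma = 0, L = 41, maxEvents = 3000,
                               seed = 9))
    r1 <- analyzeColony(sim)
    r2 <- analyzeColony(sim)
    expect_identical(objectTable(r1), objectTable(r2))
    expect_equal(nSatellites(r1), 0L)          # Eden limit: one component
    expect_equal(totalVolume(r1), 3001)
})

test_that("the pipeline recovers planted fixture objects", {
    fx <- makeStack(smallFixtureSpec(seed = 11))
    rep <- analyzeColony(fx$stack)
    truth <- fx$truth@objects
    expect_equal(nrow(objectTable(rep)), nrow(truth))
    expect_equal(nSatellites(rep), sum(truth$type == "satellite"))
    # volumes within 5 percent, matched by decreasing size
    got <- sort(objectTable(rep)$volume_um3, decreasing = TRUE)
    want <- sort(truth$volume_um3, decreasing = TRUE)
    expect_true(all(abs(got - want) / want < 0.05))
})
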