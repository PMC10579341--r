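# Sweep bookkeeping, population curves, growth exponents, regime labels.

test_that("sweeps run every replicate of every cell, reproducibly", {
    spec <- sweepSpec(sigmaValues = c(2, 5), ksValues = c(0.001, 0.1),
                      replicates = 3L,
                      baseParams = SimParams(L = 61L, maxEvents = 2000),
                      baseSeed = 100L)
    sw <- runSweep(spec)
    expect_equal(nrow(sw@records), 12L)
    expect_equal(nrow(sw@summaryTable), 4L)
    counts <- table(sw@records$sigma, sw@records$ks)
    expect_true(all(counts == 3L))
    # bit-identical re-execution
    sw2 <- runSweep(spec)
    expect_identical(sw@records, sw2@records)
})

test_that("population curves are the step functions of the event log", {
    sim <- runColony(SimParams(ks = 0, sigma = 0, L = 41, maxEvents = 2000,
                               seed = 3))
    tr <- trajectory(sim)
    pc <- populationCurve(tr, nPoints = 60)
    # with ks = 0, N(t) = 1 + number of events at or before t
    want <- 1 + vapply(pc$t, function(tt) sum(tr$t <= tt), 0)
    expect_equal(pc$n_mean, want)
    expect_true(all(diff(pc$n_mean) >= 0))

    # band over replicates equals the per-time SD
    sims <- lapply(4:6, function(s) trajectory(
        runColony(SimParams(ks = 0, sigma = 0, L = 41, maxEvents = 1500,
                            seed = s))))
    pc3 <- populationCurve(sims, nPoints = 40)
    mat <- as.matrix(pc3[, paste0("N_", 1:3)])
    expect_equal(pc3$n_sd, apply(mat, 1, sd))
    expect_equal(pc3$n_mean, rowMeans(mat))
    expect_lte(max(pc3$t), min(vapply(sims, function(d) max(d$t), 0)))

    expect_error(populationCurve(list()), "empty")
})

test_that("growth exponents recover exact power laws and flag exponentials", {
    t <- seq(1, 50, length.out = 400)
    cubic <- data.frame(t = t, n_cells = 2.5 * t^3)
    g <- growthExponent(cubic)
    expect_lt(abs(g$exponent - 3), 0.01)
    expect_gt(g$r2, 0.999)
    expect_false(g$nonPowerLaw)

    expo <- data.frame(t = t, n_cells = exp(0.4 * t))
    ge <- growthExponent(expo)
    expect_true(ge$nonPowerLaw)       # log N linear in t beats log-log

    expect_error(growthExponent(data.frame(t = 1:5, n_cells = (1:5)^3)),
                 "10 points")

    # the fitted window honours the requested final fraction
    g2 <- growthExponent(cubic, window = 0.25)
    expect_lt(abs(g2$exponent - 3), 0.01)
})

test_that("regime labels follow the documented thresholds", {
    expect_equal(classifyRegime(0.2, 0.95), "compact")
    expect_equal(classifyRegime(3.0, 0.80), "satellite")
    expect_equal(classifyRegime(5.0, 0.40), "dispersed")
    # dispersed takes precedence over the satellite-count rule
    expect_equal(classifyRegime(0.1, 0.30), "dispersed")
})

test_that("regime labels never move backwards along the parameter grid", {
    spec <- sweepSpec(sigmaValues = c(2, 7), ksValues = c(0.001, 0.1),
                      replicates = 3L,
                      baseParams = SimParams(L = 101L, maxEvents = 2e4),
                      baseSeed = 40L)
    sw <- runSweep(spec)
    lvl <- c(compact = 1L, satellite = 2L, dispersed = 3L)
    tab <- sw@summaryTable
    for (sg in unique(tab$sigma)) {
        r <- tab[tab$sigma == sg, ]
        r <- r[order(r$ks), ]
        expect_true(all(diff(lvl[r$regime]) >= 0))
    }
    for (ks in unique(tab$ks)) {
        r <- tab[tab$ks == ks, ]
        r <- r[order(r$sigma), ]
        expect_true(all(diff(lvl[r$regime]) >= 0))
    }
    # the corner cells behave as expected at this scale
    expect_equal(tab$regime[tab$sigma == 2 & tab$ks == 0.001], "compact")
    expect_gt(tab$mean_satellites[tab$sigma == 7 & tab$ks == 0.1],
              tab$mean_satellites[tab$sigma == 2 & tab$ks == 0.001])
})

test_that("comparing a cell against a near-identical cell is a null result", {
    # two ks values so close the dynamics are indistinguishable; different
    # seeds per cell make this an exchangeability check
    spec <- sweepSpec(sigmaValues = 5, ksValues = c(0.1, 0.1 + 1e-9),
                      replicates = 6L,
                      baseParams = SimParams(L = 61L, maxEvents = 4000),
                      baseSeed = 70L)
    sw <- runSweep(spec)
    cmp <- compareRegimes(sw, c(5, 0.1), c(5, 0.1 + 1e-9))
    expect_gt(cmp$cvRatio, 0.2)
    expect_lt(cmp$cvRatio, 5)
    expect_gt(cmp$satelliteTest$p.value, 0.01)

    tiny <- sweepSpec(sigmaValues = 5, ksValues = c(0.1, 0.2),
                      replicates = 2L,
                      baseParams = SimParams(L = 41L, maxEvents = 500),
                      baseSeed = 80L)
    expect_error(compareRegimes(runSweep(tiny), c(5, 0.1), c(5, 0.2)),
                 "5 replicates")
})
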