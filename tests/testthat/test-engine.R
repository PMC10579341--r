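# The Gillespie event loop: contracts, conservation, determinism,
# oracle equivalence, waiting-time law, truncation.

test_that("event budgets are honoured exactly in the Eden limit", {
    s1 <- runColony(SimParams(ks = 0, sigma = 0, L = 15, maxEvents = 1,
                              seed = 1))
    expect_equal(nCells(s1), 2L)
    expect_equal(simStatus(s1), "completed")

    s2 <- runColony(SimParams(ks = 0, sigma = 0, L = 61, maxEvents = 1e4,
                              seed = 1))
    expect_equal(nCells(s2), 10001L)       # every event is a growth
    expect_true(all(trajectory(s2)$event_type == "growth"))
})

test_that("identical parameters and seed reproduce runs bit-for-bit", {
    p <- SimParams(ks = 0.05, sigma = 3, L = 41, maxEvents = 1500, seed = 77)
    a <- runColony(p)
    b <- runColony(p)
    expect_identical(eventLog(a), eventLog(b))
    expect_identical(occupiedSites(a), occupiedSites(b))
    expect_identical(finalTime(a), finalTime(b))
})

test_that("incremental and naive reference engines agree event-for-event", {
    for (p in list(SimParams(ks = 0.05, sigma = 3, L = 41, maxEvents = 500,
                             seed = 42),
                   SimParams(ks = 0, sigma = 0, L = 41, maxEvents = 500,
                             seed = 9),
                   SimParams(ks = 0.3, sigma = 4, L = 41, maxEvents = 300,
                             seed = 3, n2MinEmpty = 3L,
                             boundaryVariant = "multiplicity"))) {
        a <- suppressWarnings(runColony(p))
        b <- suppressWarnings(runColony(p, engine = "reference"))
        expect_identical(eventLog(a), eventLog(b))
        expect_identical(occupiedSites(a), occupiedSites(b))
        expect_identical(simStatus(a), simStatus(b))
    }
})

test_that("growth adds one cell, jumps conserve, and the clock increases", {
    sim <- runColony(SimParams(ks = 0.2, sigma = 3, L = 61, maxEvents = 3000,
                               seed = 12))
    log <- eventLog(sim)
    dN <- diff(c(1L, log$n_cells))
    expect_true(all(dN[log$event_type == "growth"] == 1L))
    expect_true(all(dN[log$event_type != "growth"] == 0L))
    expect_true(all(diff(log$t) > 0))
    expect_true(all(log$tau > 0))
    # jumps vacate the origin at jump time: origin differs from target
    j <- log$event_type == "jump"
    expect_true(all((log$from_x[j] != log$to_x[j]) |
                    (log$from_y[j] != log$to_y[j]) |
                    (log$from_z[j] != log$to_z[j])))
})

test_that("the event log replays to the final occupied set", {
    sim <- runColony(SimParams(ks = 0.1, sigma = 4, L = 61, maxEvents = 2000,
                               seed = 21))
    log <- eventLog(sim)
    L <- simParams(sim)@L
    occ <- array(FALSE, c(L, L, L))
    occ[matrix(rep(L %/% 2 + 1L, 3), 1)] <- TRUE
    for (i in seq_len(nrow(log))) {
        if (log$event_type[i] == "growth") {
            to <- c(log$to_x[i], log$to_y[i], log$to_z[i]) + 1L
            expect_false(occ[matrix(to, 1)])
            occ[matrix(to, 1)] <- TRUE
        } else if (log$event_type[i] == "jump") {
            fr <- c(log$from_x[i], log$from_y[i], log$from_z[i]) + 1L
            to <- c(log$to_x[i], log$to_y[i], log$to_z[i]) + 1L
            expect_true(occ[matrix(fr, 1)])
            expect_false(occ[matrix(to, 1)])
            occ[matrix(fr, 1)] <- FALSE
            occ[matrix(to, 1)] <- TRUE
        }
    }
    replayed <- which(occ, arr.ind = TRUE) - 1L
    got <- occupiedSites(sim)
    expect_equal(replayed[order(replayed[, 3], replayed[, 2], replayed[, 1]), ],
                 got[order(got[, 3], got[, 2], got[, 1]), ],
                 ignore_attr = TRUE)
})

test_that("normalized waiting times are standard exponential", {
    sim <- runColony(SimParams(ks = 0.05, sigma = 5, L = 81,
                               maxEvents = 2e4, seed = 31))
    log <- eventLog(sim)
    u <- log$tau * log$total_rate
    ks <- suppressWarnings(stats::ks.test(u, "pexp", 1))
    expect_gt(ks$p.value, 0.01)
})

test_that("approaching the lattice edge stops the run with a flag", {
    p <- SimParams(ks = 0, sigma = 0, L = 15, maxEvents = 1e4, seed = 2,
                   boundaryMargin = 5L)
    sim <- runColony(p)
    expect_equal(simStatus(sim), "truncated")
    expect_lt(nrow(eventLog(sim)), 1e4)
    # the returned lattice is still a valid colony
    expect_equal(nCells(sim), nrow(eventLog(sim)) + 1L)
})

test_that("partitions recomputed from scratch match after arbitrary events", {
    sim <- suppressWarnings(runColony(SimParams(ks = 0.2, sigma = 4, L = 41,
                                                maxEvents = 800, seed = 14)))
    st <- makeState(41, occupiedSites(sim))
    got <- classifyPopulations(st)
    want <- bruteForcePartition(st)
    expect_equal(sort(got$n1), want$n1)
    expect_equal(sort(got$n2), want$n2)
    expect_equal(sort(got$boundary), want$boundary)
})
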