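# Low-level lattice operations: neighbour counting, population
# classification, rates and event-class selection.

test_that("empty neighbour counts match enclosure geometry", {
    st <- latticeState(9)                       # single cell at (4,4,4)
    expect_equal(emptyNeighborCount(st, c(4, 4, 4)), 6L)

    st3 <- makeState(9, blockSites(c(3, 3, 3), c(5, 5, 5)))
    expect_equal(emptyNeighborCount(st3, c(4, 4, 4)), 0L)  # enclosed centre
    expect_equal(emptyNeighborCount(st3, c(3, 4, 4)), 1L)  # face centre
    expect_equal(emptyNeighborCount(st3, c(3, 3, 3)), 3L)  # corner

    st2 <- makeState(9, blockSites(c(3, 3, 3), c(4, 4, 4)))
    expect_equal(emptyNeighborCount(st2, c(3, 3, 3)), 3L)  # 2x2x2 cube cell

    # lattice walls count as blocked
    stw <- makeState(9, matrix(c(0L, 4L, 4L), 1))
    expect_equal(emptyNeighborCount(stw, c(0, 4, 4)), 5L)

    expect_error(emptyNeighborCount(st, c(9, 0, 0)), "outside")
})

test_that("population classification matches a brute-force enumeration", {
    # forced-by-rule cases
    p1 <- classifyPopulations(latticeState(9))
    expect_length(p1$n1, 0)
    expect_length(p1$n2, 1)
    expect_length(p1$boundary, 6)

    p2 <- classifyPopulations(makeState(9, blockSites(c(3, 3, 3), c(4, 4, 4))))
    expect_length(p2$n1, 8)              # every 2x2x2 cell has 3 empty
    expect_length(p2$n2, 0)

    # 3x3x3 block and random colonies vs the independent per-site oracle
    shapes <- list(blockSites(c(3, 3, 3), c(5, 5, 5)))
    set.seed(11)
    for (i in 1:4) {
        n <- sample(5:25, 1)
        shapes[[i + 1]] <- unique(matrix(sample(2:7, 3 * n, replace = TRUE),
                                         ncol = 3))
    }
    for (s in shapes) {
        st <- makeState(10, s)
        for (thr in c(3L, 4L)) {
            got <- classifyPopulations(st, n2MinEmpty = thr)
            want <- bruteForcePartition(st, n2MinEmpty = thr)
            expect_equal(sort(got$n1), want$n1)
            expect_equal(sort(got$n2), want$n2)
            expect_equal(sort(got$boundary), want$boundary)
        }
        gotM <- classifyPopulations(st, boundaryVariant = "multiplicity")
        wantM <- bruteForcePartition(st)
        expect_equal(gotM$boundaryWeights[order(gotM$boundary)],
                     wantM$multiplicity[order(wantM$boundary)],
                     ignore_attr = TRUE)
    }

    # 3x3x3 expected composition: centre enclosed, 26 shell cells all N1
    p3 <- classifyPopulations(makeState(9, blockSites(c(3, 3, 3), c(5, 5, 5))))
    expect_length(p3$n1, 26)
    expect_length(p3$n2, 0)

    expect_error(classifyPopulations(
        new("LatticeState", occ = array(FALSE, c(3, 3, 3)), t = 0,
            nCells = 0L)), "empty")
})

test_that("total event rate follows the N1 k + N2 (k + ks) partition", {
    fakePart <- function(n1, n2) list(n1 = seq_len(n1), n2 = seq_len(n2))
    expect_equal(totalEventRate(fakePart(3, 2), SimParams(ks = 0.05)), 5.1)
    expect_equal(totalEventRate(fakePart(0, 1), SimParams(ks = 0.2)), 1.2)
    # Eden limit: ks = 0 collapses to (N1 + N2) k
    expect_equal(totalEventRate(fakePart(7, 4), SimParams(k = 2, ks = 0)), 22)
    # jammed colony signals 0, not an error
    expect_equal(totalEventRate(fakePart(0, 0), SimParams(ks = 0.1)), 0)
})

test_that("waiting times are -log(r)/T on the shared RNG stream", {
    set.seed(99); r <- runif(1)
    set.seed(99)
    expect_equal(drawWaitingTime(4), -log(r) / 4)
    expect_error(drawWaitingTime(0), "rate")

    # Monte-Carlo mean against the analytic 1/T
    set.seed(1)
    taus <- replicate(1e5, drawWaitingTime(2))
    se <- sd(taus) / sqrt(length(taus))
    expect_lt(abs(mean(taus) - 0.5), 3 * se)
})

test_that("event-class selection reproduces the rate shares", {
    fakePart <- function(n1, n2) list(n1 = seq_len(n1), n2 = seq_len(n2))
    # ks = 0: growth is certain
    set.seed(2)
    expect_true(all(replicate(200,
        selectEvent(fakePart(3, 2), SimParams(ks = 0))) == "growth"))

    # growth share (N1+N2) k / T = 5/5.1
    set.seed(3)
    draws <- replicate(1e5, selectEvent(fakePart(3, 2), SimParams(ks = 0.05)))
    pHat <- mean(draws == "growth")
    p <- 5 / 5.1
    expect_lt(abs(pHat - p), 3 * sqrt(p * (1 - p) / length(draws)))

    # 50/50 at N1 = 0, N2 = 1, k = ks = 1
    set.seed(4)
    draws <- replicate(2e4, selectEvent(fakePart(0, 1), SimParams(ks = 1)))
    expect_lt(abs(mean(draws == "growth") - 0.5),
              3 * sqrt(0.25 / length(draws)))
})
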