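# Low-level lattice operations of the modified Eden growth model, in plain R.
# These back the reference engine and are individually testable; the fast
# incremental engine (src/engine.cpp) implements the same contracts with
# incremental bookkeeping and must agree with these bit-for-bit.
#
# Site coordinates are 0-based integer (x, y, z). The encoded site order
# code = x + L*y + L^2*z equals (R linear array index - 1), so which() on the
# occupancy array enumerates sites in ascending code order -- the order over
# which uniform site choices are made in both engines.

#' Create a lattice state
#'
#' @param L linear lattice size (sites).
#' @param sites integer matrix (n x 3) of 0-based occupied sites; the default
#'   is the single-cell initial condition at the lattice centre.
#' @param t initial simulated time.
#' @return a [LatticeState].
#' @examples
#' st <- latticeState(21)
#' nCells(st)
#' @export
latticeState <- function(L, sites = matrix(rep(L %/% 2, 3), 1), t = 0) {
    L <- as.integer(L)
    occ <- array(FALSE, dim = c(L, L, L))
    sites <- matrix(as.integer(sites), ncol = 3)
    if (any(sites < 0L) || any(sites >= L)) stop("sites outside the lattice")
    occ[sites + 1L] <- TRUE
    new("LatticeState", occ = occ, t = as.numeric(t),
        nCells = as.integer(sum(occ)))
}

.siteCode <- function(sites, L) {
    sites[, 1] + L * (sites[, 2] + L * sites[, 3])
}

.codeToSite <- function(code, L) {
    cbind(x = code %% L, y = (code %/% L) %% L, z = code %/% (L * L))
}

#' Count the empty face-neighbours of a site
#'
#' Neighbours outside the lattice count as blocked (the lattice has closed
#' walls).
#'
#' @param state a [LatticeState].
#' @param site 0-based integer (x, y, z).
#' @return integer in 0..6.
#' @examples
#' st <- latticeState(9)
#' emptyNeighborCount(st, c(4, 4, 4)) # isolated cell: 6
#' @export
emptyNeighborCount <- function(state, site) {
    L <- dim(state@occ)[1]
    site <- as.integer(site)
    if (length(site) != 3L || any(site < 0L) || any(site >= L))
        stop("site outside the lattice")
    n <- 0L
    for (d in 1:3) {
        for (s in c(-1L, 1L)) {
            nb <- site
            nb[d] <- nb[d] + s
            if (nb[d] >= 0L && nb[d] < L && !state@occ[matrix(nb + 1L, 1)])
                n <- n + 1L
        }
    }
    n
}

# occupied-cell neighbour counts for every site, by array shifts
.neighborCellCounts <- function(occ) {
    d <- dim(occ)
    nbr <- array(0L, dim = d)
    o <- occ
    if (d[1] > 1L) {
        nbr[-d[1], , ] <- nbr[-d[1], , ] + o[-1, , ]
        nbr[-1, , ] <- nbr[-1, , ] + o[-d[1], , ]
    }
    if (d[2] > 1L) {
        nbr[, -d[2], ] <- nbr[, -d[2], ] + o[, -1, ]
        nbr[, -1, ] <- nbr[, -1, ] + o[, -d[2], ]
    }
    if (d[3] > 1L) {
        nbr[, , -d[3]] <- nbr[, , -d[3]] + o[, , -1]
        nbr[, , -1] <- nbr[, , -1] + o[, , -d[3]]
    }
    nbr
}

#' Partition the colony into growth-only and jump-capable populations
#'
#' Classifies every cell by its number of empty face-neighbours: cells with
#' none are enclosed (in neither population), cells with fewer than
#' \code{n2MinEmpty} empty neighbours can only divide (N1), the rest can both
#' divide and jump (N2). Also collects the colony surface: every empty site
#' face-adjacent to at least one cell.
#'
#' @param state a non-empty [LatticeState].
#' @param n2MinEmpty N2 eligibility threshold (default 4).
#' @param boundaryVariant "dedup": each surface site listed once;
#'   "multiplicity": weighted by the number of adjacent cells.
#' @return a list with encoded-site vectors \code{n1}, \code{n2},
#'   \code{boundary} (ascending), \code{boundaryWeights}, and \code{L}.
#' @examples
#' p <- classifyPopulations(latticeState(9))
#' length(p$n2) # a single cell has 6 empty neighbours: jump-capable
#' @export
classifyPopulations <- function(state, n2MinEmpty = 4L,
                                boundaryVariant = c("dedup", "multiplicity")) {
    boundaryVariant <- match.arg(boundaryVariant)
    occ <- state@occ
    if (!any(occ)) stop("empty lattice: nothing to classify")
    L <- dim(occ)[1]

    # recompute from scratch, restricted to the colony bounding box plus one
    # site of padding (everything outside is empty and not colony-adjacent)
    allIdx <- which(occ)
    allXyz <- .codeToSite(allIdx - 1, L)
    w0 <- pmax(apply(allXyz, 2, min) - 1L, 0L)         # window start, 0-based
    w1 <- pmin(apply(allXyz, 2, max) + 1L, L - 1L)
    win <- occ[(w0[1]:w1[1]) + 1L, (w0[2]:w1[2]) + 1L, (w0[3]:w1[3]) + 1L,
               drop = FALSE]
    win <- array(win, dim = w1 - w0 + 1L)
    nbr <- .neighborCellCounts(win)

    toGlobal <- function(idxWin) {
        xyz <- arrayInd(idxWin, dim(win)) - 1L
        g <- sweep(xyz, 2, w0, "+")
        list(code = g[, 1] + L * (g[, 2] + L * g[, 3]), xyz = g)
    }

    cells <- toGlobal(which(win))
    walls <- (cells$xyz[, 1] == 0L) + (cells$xyz[, 1] == L - 1L) +
             (cells$xyz[, 2] == 0L) + (cells$xyz[, 2] == L - 1L) +
             (cells$xyz[, 3] == 0L) + (cells$xyz[, 3] == L - 1L)
    emptyNb <- 6L - walls - nbr[which(win)]

    bWin <- which(!win & nbr > 0L)
    bCode <- toGlobal(bWin)$code
    ord <- order(bCode)
    w <- if (boundaryVariant == "dedup") rep(1L, length(bWin)) else nbr[bWin][ord]

    ordC <- order(cells$code)
    cellCode <- cells$code[ordC]
    emptyNb <- emptyNb[ordC]

    list(n1 = cellCode[emptyNb >= 1L & emptyNb < n2MinEmpty],
         n2 = cellCode[emptyNb >= n2MinEmpty],
         boundary = bCode[ord],
         boundaryWeights = w,
         L = L)
}

#' Total Gillespie event rate
#'
#' T = N1 * k + N2 * (k + ks): every non-enclosed cell divides at rate k and
#' jump-capable cells additionally jump at rate ks.
#'
#' @param partition result of [classifyPopulations()].
#' @param params a [SimParams].
#' @return the total rate; 0 signals a jammed colony (termination, not an
#'   error).
#' @export
totalEventRate <- function(partition, params) {
    length(partition$n1) * params@k +
        length(partition$n2) * (params@k + params@ks)
}

#' Draw an exponential waiting time
#'
#' tau = -log(r) / T with r uniform on (0, 1); the Gillespie inter-event
#' time at total rate T.
#'
#' @param T total event rate, > 0.
#' @return waiting time, > 0.
#' @export
drawWaitingTime <- function(T) {
    if (T <= 0) stop("total rate must be > 0")
    repeat {
        r <- stats::runif(1)
        if (r > 0) break
    }
    -log(r) / T
}

#' Select the next event class
#'
#' Growth is chosen with probability (N1 + N2) * k / T, its share of the
#' total rate, a jump otherwise.
#'
#' @inheritParams totalEventRate
#' @return "growth" or "jump".
#' @export
selectEvent <- function(partition, params) {
    T <- totalEventRate(partition, params)
    if (T <= 0) stop("total rate must be > 0")
    a <- stats::runif(1)
    n <- length(partition$n1) + length(partition$n2)
    if (a <= n * params@k / T) "growth" else "jump"
}

# weighted uniform pick over sites in ascending code order; consumes one
# uniform draw. Returns the 1-based position.
.pickWeighted <- function(weights) {
    W <- sum(weights)
    u <- stats::runif(1)
    kk <- min(floor(u * W), W - 1)
    cum <- cumsum(weights)
    findInterval(kk, cum) + 1L
}

#' Apply a growth event
#'
#' Adds one cell at a surface site chosen uniformly (dedup variant) or
#' proportionally to adjacency (multiplicity variant).
#'
#' @param state a [LatticeState].
#' @param partition result of [classifyPopulations()] on \code{state}.
#' @return list(state = updated [LatticeState], record = event record with
#'   \code{site_to} as a 0-based coordinate triple).
#' @export
growthEvent <- function(state, partition) {
    if (length(partition$boundary) == 0L) stop("empty boundary: cannot grow")
    j <- .pickWeighted(partition$boundaryWeights)
    code <- partition$boundary[j]
    state@occ[code + 1] <- TRUE
    state@nCells <- state@nCells + 1L
    list(state = state,
         record = list(event_type = "growth", site_from = NULL,
                       site_to = drop(.codeToSite(code, partition$L))))
}

#' Apply a jump event
#'
#' Moves a jump-capable cell by a rounded isotropic Gaussian displacement.
#' Occupied targets (including the origin itself and anything outside the
#' closed lattice walls) trigger a full redraw of the 3-component
#' displacement; after \code{redrawCap} failed draws the jump is abandoned
#' and the state is returned unchanged.
#'
#' @inheritParams growthEvent
#' @param params a [SimParams] (sigma and redrawCap are used).
#' @param cell 0-based coordinates of the jumping cell; the default draws it
#'   uniformly from N2.
#' @return list(state, record); \code{record$event_type} is "jump" or
#'   "jump_aborted".
#' @export
jumpEvent <- function(state, partition, params, cell = NULL) {
    L <- partition$L
    if (is.null(cell)) {
        n2 <- partition$n2
        if (length(n2) == 0L) stop("no jump-capable cells")
        idx <- .pickWeighted(rep(1L, length(n2)))
        code <- n2[idx]
    } else {
        cell <- as.integer(cell)
        code <- cell[1] + L * (cell[2] + L * cell[3])
        if (!code %in% partition$n2) stop("cell is not jump-capable")
    }
    origin <- drop(.codeToSite(code, L))
    target <- NULL
    for (it in seq_len(params@redrawCap)) {
        d <- round(stats::rnorm(3, 0, params@sigma))
        cand <- origin + d
        if (any(cand < 0) || any(cand >= L)) next
        if (state@occ[matrix(cand + 1, 1)]) next
        target <- cand
        break
    }
    if (is.null(target)) {
        return(list(state = state,
                    record = list(event_type = "jump_aborted",
                                  site_from = origin, site_to = NULL)))
    }
    state@occ[matrix(origin + 1, 1)] <- FALSE
    state@occ[matrix(target + 1, 1)] <- TRUE
    list(state = state,
         record = list(event_type = "jump", site_from = origin,
                       site_to = as.integer(target)))
}
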