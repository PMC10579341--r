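#' Run a modified Eden growth simulation
#'
#' Simulates colony growth on a 3D cubic lattice with an exact Gillespie
#' loop. Starting from a single cell at the lattice centre, each iteration
#' classifies cells into growth-only (N1) and jump-capable (N2) populations,
#' computes the total rate T = N1 k + N2 (k + ks), advances the clock by an
#' exponential waiting time, and executes either a division into a uniformly
#' chosen surface site or a Gaussian jump of a uniformly chosen N2 cell.
#'
#' Both engines draw from R's global RNG in the same fixed per-event order
#' (waiting time, event class, event-specific draws, with uniform site
#' choices over ascending encoded-site order), so \code{"incremental"} and
#' \code{"reference"} produce bit-identical event logs for the same
#' parameters and seed. The reference engine recomputes the full partition
#' and surface array from scratch at every iteration and is intended for
#' small event budgets; the incremental engine maintains them in O(log n)
#' per event.
#'
#' The run stops when the event budget is exhausted ("completed"), when no
#' cell can act ("jammed"), or when the colony's historical bounding box
#' comes within \code{boundaryMargin} sites of the lattice edge
#' ("truncated"; the result is still returned, flagged).
#'
#' @param params a [SimParams].
#' @param engine "incremental" (default, compiled) or "reference" (plain R,
#'   full recomputation per event; the correctness oracle).
#' @return a [ColonySim].
#' @examples
#' sim <- runColony(SimParams(ks = 0.05, sigma = 3, L = 41,
#'                            maxEvents = 500, seed = 1))
#' nCells(sim)
#' @export
runColony <- function(params, engine = c("incremental", "reference")) {
    engine <- match.arg(engine)
    stopifnot(is(params, "SimParams"))
    validObject(params)
    if (!is.na(params@seed)) set.seed(params@seed)
    if (engine == "incremental") .runIncremental(params) else .runReference(params)
}

.runIncremental <- function(params) {
    res <- .edenRunCpp(params@L, params@k, params@ks, params@sigma,
                       params@maxEvents, params@n2MinEmpty,
                       params@boundaryVariant == "multiplicity",
                       params@boundaryMargin, params@redrawCap)
    if (res$n_aborted > 0)
        warning(sprintf("%d jump(s) abandoned after %d redraws",
                        res$n_aborted, params@redrawCap))
    L <- params@L
    type <- c("growth", "jump", "jump_aborted")[res$ev_type + 1L]
    fromXyz <- .codeToSite(ifelse(is.na(res$ev_from), NA, res$ev_from), L)
    toXyz <- .codeToSite(ifelse(is.na(res$ev_to), NA, res$ev_to), L)
    log <- data.frame(
        event_index = seq_along(res$ev_t), t = res$ev_t, tau = res$ev_tau,
        total_rate = res$ev_T, event_type = type,
        from_x = fromXyz[, 1], from_y = fromXyz[, 2], from_z = fromXyz[, 3],
        to_x = toXyz[, 1], to_y = toXyz[, 2], to_z = toXyz[, 3],
        n_cells = res$ev_pop)
    new("ColonySim", params = params,
        sites = matrix(as.integer(res$sites), ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z"))),
        time = res$t, status = res$status, eventLog = log,
        nAborted = as.integer(res$n_aborted))
}

.runReference <- function(params) {
    L <- params@L
    state <- latticeState(L)
    margin <- params@boundaryMargin
    # historical bounding box over every site ever occupied (monotone),
    # matching the incremental engine's truncation guard
    ctr <- rep(L %/% 2, 3)
    lo <- ctr
    hi <- ctr

    n <- 0L
    cap <- as.integer(params@maxEvents)
    recT <- recTau <- recRate <- numeric(cap)
    recType <- character(cap)
    recFrom <- matrix(NA_integer_, cap, 3)
    recTo <- matrix(NA_integer_, cap, 3)
    recPop <- integer(cap)
    status <- "completed"
    nAborted <- 0L

    while (n < cap) {
        part <- classifyPopulations(state, params@n2MinEmpty,
                                    params@boundaryVariant)
        T <- totalEventRate(part, params)
        if (T <= 0) { status <- "jammed"; break }
        tau <- drawWaitingTime(T)
        state@t <- state@t + tau
        kind <- selectEvent(part, params)
        if (kind == "growth") {
            ev <- growthEvent(state, part)
        } else {
            ev <- jumpEvent(state, part, params)
        }
        state <- ev$state
        n <- n + 1L
        recT[n] <- state@t; recTau[n] <- tau; recRate[n] <- T
        recType[n] <- ev$record$event_type
        if (!is.null(ev$record$site_from))
            recFrom[n, ] <- as.integer(ev$record$site_from)
        if (!is.null(ev$record$site_to)) {
            recTo[n, ] <- as.integer(ev$record$site_to)
            lo <- pmin(lo, ev$record$site_to)
            hi <- pmax(hi, ev$record$site_to)
        }
        if (ev$record$event_type == "jump_aborted") nAborted <- nAborted + 1L
        recPop[n] <- state@nCells
        if (any(lo < margin) || any(hi > L - 1 - margin)) {
            status <- "truncated"
            break
        }
    }
    if (nAborted > 0)
        warning(sprintf("%d jump(s) abandoned after %d redraws",
                        nAborted, params@redrawCap))

    keep <- seq_len(n)
    log <- data.frame(
        event_index = keep, t = recT[keep], tau = recTau[keep],
        total_rate = recRate[keep], event_type = recType[keep],
        from_x = recFrom[keep, 1], from_y = recFrom[keep, 2],
        from_z = recFrom[keep, 3],
        to_x = recTo[keep, 1], to_y = recTo[keep, 2], to_z = recTo[keep, 3],
        n_cells = recPop[keep])
    sites <- .codeToSite(which(state@occ) - 1, L)
    storage.mode(sites) <- "integer"
    colnames(sites) <- c("x", "y", "z")
    new("ColonySim", params = params, sites = sites, time = state@t,
        status = status, eventLog = log, nAborted = nAborted)
}

#' Equivalent-sphere diameter of a colony
#'
#' With one occupied lattice site per ~1 um^3 cell volume, a compact colony
#' of V sites has linear width (6 V / pi)^(1/3) um: the diameter of the
#' sphere of equal volume.
#'
#' @param x a [ColonySim], or a site/cell count.
#' @return diameter in lattice units (um).
#' @examples
#' equivalentSphereDiameter(1e6) # ~124 um
#' @export
equivalentSphereDiameter <- function(x) {
    v <- if (is(x, "ColonySim")) nCells(x) else as.numeric(x)
    (6 * v / pi)^(1 / 3)
}
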