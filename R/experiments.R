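# Parameter-sweep study design: replicate simulations over a (sigma, ks)
# grid, morphology analysis of every run, population-vs-time curves,
# growth-exponent fits and regime classification.

#' Construct a sweep specification
#'
#' Defaults follow the in-silico study design: sigma in {2, 5, 7, 10},
#' ks in {0.001, 0.05, 0.1, 0.2}, 30 replicates per grid cell.
#'
#' @param sigmaValues,ksValues parameter grids.
#' @param replicates replicate runs per cell.
#' @param baseParams [SimParams] template (sigma, ks, seed overwritten).
#' @param baseSeed base seed; replicate j of cell i uses
#'   baseSeed + (i-1)*replicates + (j-1).
#' @return a [SweepSpec].
#' @export
sweepSpec <- function(sigmaValues = c(2, 5, 7, 10),
                      ksValues = c(0.001, 0.05, 0.1, 0.2),
                      replicates = 30L,
                      baseParams = SimParams(maxEvents = 1e6),
                      baseSeed = 1L) {
    new("SweepSpec", sigmaValues = as.numeric(sigmaValues),
        ksValues = as.numeric(ksValues), replicates = as.integer(replicates),
        baseParams = baseParams, baseSeed = as.integer(baseSeed))
}

#' Regime thresholds
#'
#' The regime of a grid cell is classified from replicate means:
#' "dispersed" when the main colony holds less than
#' \code{dispersedMainFraction} of the total volume, else "compact" when the
#' mean satellite count is below \code{compactMaxSatellites}, else
#' "satellite".
#'
#' @param meanSatellites mean post-analysis satellite count.
#' @param mainVolumeFraction mean main-colony share of total volume.
#' @param compactMaxSatellites,dispersedMainFraction thresholds (defaults
#'   0.5 and 0.5).
#' @return "compact", "satellite" or "dispersed".
#' @export
classifyRegime <- function(meanSatellites, mainVolumeFraction,
                           compactMaxSatellites = 0.5,
                           dispersedMainFraction = 0.5) {
    if (is.na(meanSatellites) || is.na(mainVolumeFraction))
        return(NA_character_)
    if (mainVolumeFraction < dispersedMainFraction) "dispersed"
    else if (meanSatellites < compactMaxSatellites) "compact"
    else "satellite"
}

#' Run a (sigma x ks) parameter sweep
#'
#' Executes \code{replicates} simulations per grid cell with the
#' deterministic seed policy, analyzes every run with the morphology
#' pipeline, and aggregates per-cell summary statistics and regime labels.
#' Truncated runs are recorded, never fatal.
#'
#' @param spec a [SweepSpec].
#' @param curvePoints number of points kept per resampled population curve.
#' @param verbose print progress.
#' @return a [SweepSummary].
#' @export
runSweep <- function(spec, curvePoints = 256L, verbose = FALSE) {
    stopifnot(is(spec, "SweepSpec"))
    grid <- expand.grid(sigma = spec@sigmaValues, ks = spec@ksValues,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- list()
    curves <- list()
    rec <- 0L
    for (i in seq_len(nrow(grid))) {
        for (j in seq_len(spec@replicates)) {
            seed <- spec@baseSeed + (i - 1L) * spec@replicates + (j - 1L)
            p <- spec@baseParams
            p@sigma <- grid$sigma[i]
            p@ks <- grid$ks[i]
            p@seed <- as.integer(seed)
            p@boundaryMargin <- as.integer(max(ceiling(3 * p@sigma), 5))
            validObject(p)
            sim <- suppressWarnings(runColony(p))
            rep_ <- analyzeColony(sim)
            tab <- objectTable(rep_)
            mainFrac <- if (nrow(tab) > 0L)
                max(tab$volume_um3) / sum(tab$volume_um3) else NA_real_
            rec <- rec + 1L
            rows[[rec]] <- data.frame(
                sigma = grid$sigma[i], ks = grid$ks[i], replicate = j,
                seed = seed, status = simStatus(sim), n_cells = nCells(sim),
                final_time = finalTime(sim),
                n_satellites = nSatellites(rep_),
                main_volume_fraction = mainFrac,
                total_volume_um3 = totalVolume(rep_))
            tr <- trajectory(sim)
            keep <- unique(round(seq(1L, nrow(tr), length.out = curvePoints)))
            curves[[rec]] <- data.frame(t = tr$t[keep],
                                        n_cells = tr$n_cells[keep])
            if (verbose)
                message(sprintf("sigma=%g ks=%g rep %d: %d cells, %d satellites",
                    grid$sigma[i], grid$ks[i], j, nCells(sim),
                    nSatellites(rep_)))
        }
    }
    records <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        sel <- records$sigma == grid$sigma[i] & records$ks == grid$ks[i]
        r <- records[sel, ]
        cv <- stats::sd(r$total_volume_um3) / mean(r$total_volume_um3)
        mf <- mean(r$main_volume_fraction, na.rm = TRUE)   # NA: empty report
        data.frame(sigma = grid$sigma[i], ks = grid$ks[i], n_runs = nrow(r),
                   mean_satellites = mean(r$n_satellites),
                   sd_satellites = stats::sd(r$n_satellites),
                   mean_n_cells = mean(r$n_cells),
                   cv_total_volume = cv,
                   mean_main_fraction = mf,
                   regime = classifyRegime(mean(r$n_satellites),
                                           if (is.nan(mf)) NA_real_ else mf))
    }))
    new("SweepSummary", spec = spec, records = records,
        trajectories = curves, summaryTable = summ)
}

#' Resample population trajectories onto a common time grid
#'
#' Evaluates the step-function population N(t) of each run on a uniform
#' grid from 0 to the minimum final time across runs, and returns the
#' per-time mean and SD band across replicates.
#'
#' @param trajectories a data.frame with columns t and n_cells, or a list
#'   of them (replicates).
#' @param nPoints grid resolution.
#' @param tMax optional upper end of the grid (default: minimum final time).
#' @return data.frame: t, n_mean, n_sd, plus one N_i column per replicate.
#' @export
populationCurve <- function(trajectories, nPoints = 200L, tMax = NULL) {
    if (is.data.frame(trajectories)) trajectories <- list(trajectories)
    if (length(trajectories) == 0L || any(!vapply(trajectories, nrow, 1L)))
        stop("empty trajectory")
    if (is.null(tMax))
        tMax <- min(vapply(trajectories, function(d) max(d$t), 1.0))
    tg <- seq(0, tMax, length.out = nPoints)
    mat <- vapply(trajectories, function(d) {
        # step function: population after the last event at or before t
        # (1 cell before the first event)
        stats::approx(x = c(0, d$t), y = c(1, d$n_cells), xout = tg,
                      method = "constant", rule = 2)$y
    }, numeric(nPoints))
    out <- data.frame(t = tg, n_mean = rowMeans(mat),
                      n_sd = apply(mat, 1, stats::sd))
    colnames(mat) <- paste0("N_", seq_along(trajectories))
    cbind(out, mat)
}

#' Late-time growth exponent of a population curve
#'
#' Least-squares slope of log N versus log t over the final
#' \code{window} fraction of the time range. A power law N ~ t^b gives
#' exponent b; exponential growth is flagged by comparing the power-law fit
#' R^2 against that of log N versus t (linear time): when the exponential
#' model fits better the curve is marked non-power-law.
#'
#' A finite colony carries a growth lag: the initial cell multiplies
#' near-exponentially until surface limitation sets in, so the population
#' follows N ~ (t - t0)^b rather than t^b and the plain log-log slope
#' overestimates b in any finite window. \code{timeOffset} subtracts a
#' known or estimated lag t0 before fitting, for lag-corrected estimates of
#' the asymptotic exponent.
#'
#' @param curve data.frame with columns t and either n_cells or n_mean, or
#'   a [ColonySim].
#' @param window final fraction of the time range fitted (default 0.5).
#' @param timeOffset growth lag t0 subtracted from the time axis before
#'   fitting (default 0: the plain log N vs log t slope).
#' @return list(exponent, r2, r2_exponential, nonPowerLaw, n).
#' @export
growthExponent <- function(curve, window = 0.5, timeOffset = 0) {
    if (is(curve, "ColonySim")) curve <- trajectory(curve)
    N <- if ("n_cells" %in% names(curve)) curve$n_cells else curve$n_mean
    t <- curve$t - timeOffset
    keep <- t > 0 & N > 0           # log scale: nonpositive times trimmed
    t <- t[keep]; N <- N[keep]
    t0 <- min(t); t1 <- max(t)
    sel <- t >= t1 - window * (t1 - t0)
    if (sum(sel) < 10L) stop("need >= 10 points in the fit window")
    fitP <- stats::lm(log(N[sel]) ~ log(t[sel]))
    fitE <- stats::lm(log(N[sel]) ~ t[sel])
    # exact synthetic curves trigger lm's perfect-fit warning; R^2 is still 1
    r2p <- suppressWarnings(summary(fitP)$r.squared)
    r2e <- suppressWarnings(summary(fitE)$r.squared)
    list(exponent = unname(stats::coef(fitP)[2]), r2 = r2p,
         r2_exponential = r2e, nonPowerLaw = r2e > r2p, n = sum(sel))
}

#' Compare two grid cells of a sweep
#'
#' Reports the difference of mean populations at equal simulated time (the
#' common minimum final time of the compared runs), the ratio of
#' coefficients of variation of total colony volume, and a one/two-sided
#' Wilcoxon rank-sum test on satellite counts. No biological claim is
#' attached; this is the quantitative comparison underlying regime
#' contrasts.
#'
#' @param summary a [SweepSummary].
#' @param cellA,cellB c(sigma, ks) of the two cells.
#' @param alternative passed to [stats::wilcox.test()] for satellites of A
#'   vs B (default "two.sided").
#' @return list with meanPopA/meanPopB at equal time, meanPopDiff, cvA,
#'   cvB, cvRatio, meanSatellitesA/B, and satelliteTest.
#' @export
compareRegimes <- function(summary, cellA, cellB,
                           alternative = "two.sided") {
    stopifnot(is(summary, "SweepSummary"))
    rows <- function(cell) which(summary@records$sigma == cell[1] &
                                 summary@records$ks == cell[2])
    ia <- rows(cellA); ib <- rows(cellB)
    if (length(ia) < 5L || length(ib) < 5L)
        stop("need >= 5 replicates in each compared cell")
    ra <- summary@records[ia, ]; rb <- summary@records[ib, ]

    tMax <- min(vapply(summary@trajectories[c(ia, ib)],
                       function(d) max(d$t), 1.0))
    popAt <- function(idx) vapply(summary@trajectories[idx], function(d)
        stats::approx(c(0, d$t), c(1, d$n_cells), xout = tMax,
                      method = "constant", rule = 2)$y, 1.0)
    pa <- popAt(ia); pb <- popAt(ib)

    cva <- stats::sd(ra$total_volume_um3) / mean(ra$total_volume_um3)
    cvb <- stats::sd(rb$total_volume_um3) / mean(rb$total_volume_um3)
    wt <- suppressWarnings(stats::wilcox.test(ra$n_satellites,
        rb$n_satellites, alternative = alternative))
    list(tCompared = tMax,
         meanPopA = mean(pa), meanPopB = mean(pb),
         meanPopDiff = mean(pa) - mean(pb),
         cvA = cva, cvB = cvb, cvRatio = cva / cvb,
         meanSatellitesA = mean(ra$n_satellites),
         meanSatellitesB = mean(rb$n_satellites),
         satelliteTest = wt)
}
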