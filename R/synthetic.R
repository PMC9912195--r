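# Seeded generators reproducing the standard experimental designs, so that
# every fitting and selection stage is testable without any external data.
# All generators are pure functions of (parameters, design, seed): the RNG
# state of the session is never touched (withr::with_seed) and the same seed
# reproduces the output exactly.

#' Default two-sided inhibition design
#'
#' The canonical product-inhibition experiment: the acceptor (nitrofurazone)
#' varied at 100 uM donor (NADPH), and the donor varied at 99 uM acceptor,
#' each with the inhibitor (NADP+) at 0, 250 and 500 uM.  Concentration
#' grids are 8-point two-fold serial dilutions from 10x the corresponding
#' Michaelis constant (so they span ~0.08-10x Km, the usual practice for a
#' titration intended to constrain both kcat and Km).
#'
#' @param KmA,KmB Michaelis constants used to centre the grids, uM (defaults
#'   72 and 12, the NADPH/nitrofurazone values)
#' @param inhibitorLevels inhibitor concentrations, uM
#' @param replicates replicate curves per condition
#' @param noiseSd Gaussian rate noise SD, 1/s (0 = noiseless; 5\% of kcat is
#'   a realistic bench value)
#' @param seed RNG seed (required when noiseSd > 0)
#' @return an [ExperimentDesign-class] of kind "two_sided_inhibition"
#' @export
defaultInhibitionDesign <- function(KmA = 72, KmB = 12,
                              inhibitorLevels = c(0, 250, 500),
                              replicates = 1L, noiseSd = 0,
                              seed = NA_integer_) {
    dil <- 2^-(7:0)  # 8-point two-fold series, top at 10x Km
    experimentDesign(
        kind = "two_sided_inhibition",
        grids = list(A = 10 * KmA * dil, B = 10 * KmB * dil),
        cosubstrate = c(A = 100, B = 99),
        inhibitorLevels = inhibitorLevels, replicates = replicates,
        noiseSd = noiseSd, seed = seed)
}

#' Single-substrate Michaelis design
#'
#' One titration of the donor at a fixed acceptor level (the coenzyme
#' comparison experiment).
#'
#' @param grid concentrations of the varied substrate, uM
#' @param cosubstrate fixed acceptor concentration, uM
#' @param replicates,noiseSd,seed as in [defaultInhibitionDesign()]
#' @export
michaelisDesign <- function(grid = 10 * 19 * 2^-(7:0), cosubstrate = 100,
                            replicates = 1L, noiseSd = 0,
                            seed = NA_integer_) {
    experimentDesign(kind = "michaelis", grids = list(A = grid),
                     cosubstrate = c(A = cosubstrate),
                     inhibitorLevels = 0, replicates = replicates,
                     noiseSd = noiseSd, seed = seed)
}

.applyNoise <- function(values, noiseSd) {
    if (noiseSd > 0) values + rnorm(length(values), sd = noiseSd) else values
}

#' Generate steady-state datasets from the rate law
#'
#' Evaluates the inhibited ping-pong rate law on the design's concentration
#' grids and adds i.i.d. Gaussian noise of the design's SD (homoscedastic,
#' consistent with the equal-weighting fitting convention).  With
#' \code{noiseSd = 0} the rates are the exact model values; identical seeds
#' give identical output.
#'
#' @param params a [KineticParameters-class]
#' @param design an [ExperimentDesign-class] of kind "michaelis" or
#'   "two_sided_inhibition"
#' @return list of [SteadyStateDataset-class]
#' @examples
#' kp <- kineticParameters(23.1, 72, 12, 249, 147)
#' ds <- generateSteadyState(kp, defaultInhibitionDesign())
#' length(ds)  # 2 substrate families x 3 inhibitor levels
#' @export
generateSteadyState <- function(params, design) {
    stopifnot(is(params, "KineticParameters"),
              is(design, "ExperimentDesign"),
              design@kind %in% c("michaelis", "two_sided_inhibition"))
    gen <- function() {
        out <- list()
        for (varied in names(design@grids)) {
            grid <- design@grids[[varied]]
            co <- design@cosubstrate[[varied]]
            for (I in design@inhibitorLevels) for (rep in
                                                   seq_len(design@replicates)) {
                v <- if (varied == "A")
                    pingpongInhibitedRate(grid, co, I, params)
                else
                    pingpongInhibitedRate(co, grid, I, params)
                d <- steadyStateDataset(
                    conc = grid, rates = .applyNoise(v, design@noiseSd),
                    variedSubstrate = varied, cosubstrate = co,
                    inhibitor = I,
                    id = sprintf("%svaried_I%g_rep%d", varied, I, rep))
                out[[d@id]] <- d
            }
        }
        out
    }
    if (is.na(design@seed)) gen() else withr::with_seed(design@seed, gen())
}

#' Generate a Michaelis-Menten titration directly
#'
#' Convenience generator for apparent single-substrate kinetics (the rows of
#' a kcat/Km comparison table): rates are \code{mmRate(S, kcat, Km)} plus
#' optional Gaussian noise.
#'
#' @param kcat,Km generating parameters
#' @param conc concentration grid, uM
#' @param noiseSd Gaussian noise SD, 1/s
#' @param seed RNG seed (required when noiseSd > 0)
#' @param ... passed to [steadyStateDataset()]
#' @return a [SteadyStateDataset-class]
#' @export
generateMichaelis <- function(kcat, Km, conc = 10 * Km * 2^-(7:0),
                              noiseSd = 0, seed = NA_integer_, ...) {
    if (noiseSd > 0 && is.na(seed))
        stop("a seed is mandatory for noisy generation", call. = FALSE)
    v <- mmRate(conc, kcat, Km)
    gen <- function() .applyNoise(v, noiseSd)
    rates <- if (is.na(seed)) gen() else withr::with_seed(seed, gen())
    steadyStateDataset(conc = conc, rates = rates, ...)
}

# shared assembly of a synthetic trace from a clean kobs decay
.assembleTrace <- function(kobs, decayCurve, samplingRate, duration,
                           noiseSd, seed, offset, amplitude, wavelength,
                           pathlength) {
    if (duration < 3 / kobs)
        stop("duration must span at least 3/kobs", call. = FALSE)
    if (samplingRate < 10 * kobs)
        stop("under-sampled trace: need >= 10 points per 1/kobs",
             call. = FALSE)
    tt <- seq(0, duration, by = 1 / samplingRate)
    y <- offset + amplitude * decayCurve(tt)
    if (noiseSd > 0) {
        if (is.na(seed))
            stop("a seed is mandatory for noisy generation", call. = FALSE)
        y <- withr::with_seed(seed, y + rnorm(length(y), sd = noiseSd))
    }
    absorbanceTrace(tt, y, wavelength = wavelength, pathlength = pathlength,
                    deadTime = 0)
}

#' Generate a synthetic stopped-flow trace
#'
#' Dispatches on the parameter object: from [HyperbolicParameters-class] the
#' trace is a clean exponential with \code{kobs = hyperbolicKobs(S, object)};
#' from a [MechanismScheme-class] the reductive half-reaction is simulated
#' with [simulateReductiveHalf()] and the oxidized-enzyme pool converted to
#' absorbance (in the rapid-equilibrium regime the two routes agree to
#' within a few percent).  The amplitude follows Beer-Lambert from the
#' enzyme concentration and extinction coefficient; optional homoscedastic
#' Gaussian absorbance noise is seeded.
#'
#' @rdname generateTransient-methods
#' @param object a [HyperbolicParameters-class] or [MechanismScheme-class]
#' @param S substrate concentration in the push, uM
#' @param samplingRate Hz (default 50x the expected kobs)
#' @param duration s (default 8 expected lifetimes)
#' @param noiseSd absorbance noise SD, AU
#' @param seed RNG seed (required when noiseSd > 0)
#' @param E0 enzyme concentration, uM
#' @param epsilon molar absorbance of the observable, M^-1 cm^-1 (default
#'   6220, NADPH at 340 nm)
#' @param offset end-point absorbance, AU
#' @param wavelength,pathlength trace metadata
#' @export
setMethod("generateTransient", "HyperbolicParameters",
    function(object, S, samplingRate = NULL, duration = NULL, noiseSd = 0,
             seed = NA_integer_, E0 = 5, epsilon = 6220, offset = 0.05,
             wavelength = 340, pathlength = 1) {
        .checkConc(S, "S")
        kobs <- hyperbolicKobs(S, object)
        if (kobs <= 0) stop("expected kobs is 0 at S = 0", call. = FALSE)
        if (is.null(duration)) duration <- 8 / kobs
        if (is.null(samplingRate)) samplingRate <- 50 * kobs
        amplitude <- E0 * epsilon * pathlength * 1e-6
        .assembleTrace(kobs, function(tt) exp(-kobs * tt), samplingRate,
                       duration, noiseSd, seed, offset, amplitude,
                       wavelength, pathlength)
    })

#' @rdname generateTransient-methods
#' @param rtol solver tolerance for the mechanism route
#' @export
setMethod("generateTransient", "MechanismScheme",
    function(object, S, samplingRate = NULL, duration = NULL, noiseSd = 0,
             seed = NA_integer_, E0 = 5, epsilon = 6220, offset = 0.05,
             wavelength = 340, pathlength = 1, rtol = 1e-8) {
        .checkConc(S, "S")
        r <- object@rates
        Kd <- r[["koffA"]] / max(r[["konA"]], 1e-12)
        kobs <- r[["kRed"]] * S / (Kd + S)
        if (kobs <= 0) stop("expected kobs is 0", call. = FALSE)
        if (is.null(duration)) duration <- 8 / kobs
        if (is.null(samplingRate)) samplingRate <- 50 * kobs
        tt <- seq(0, duration, by = 1 / samplingRate)
        pc <- simulateReductiveHalf(object, E0 = E0, S = S, tGrid = tt,
                                    rtol = rtol)
        oxFrac <- oxidizedEnzyme(pc) / E0
        .assembleTrace(kobs, function(ignored) oxFrac, samplingRate,
                       duration, noiseSd, seed, offset,
                       E0 * epsilon * pathlength * 1e-6, wavelength,
                       pathlength)
    })
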