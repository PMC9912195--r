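# S4 value classes for the kinetic objects handled by the package.
# Units are fixed package-wide: concentrations in uM, first-order rate
# constants in 1/s, second-order rate constants in 1/(uM s), absorbance in AU,
# time in s.  An infinite Ki encodes "no inhibition" in that half-reaction,
# so the reduced (competitive) models are exact sub-models of the mixed one.

.checkScalar <- function(x, name, positive = TRUE, allowInf = FALSE,
                         allowZero = FALSE) {
    if (length(x) != 1L || is.na(x))
        return(sprintf("'%s' must be a single non-missing number", name))
    if (!allowInf && !is.finite(x))
        return(sprintf("'%s' must be finite", name))
    if (positive && (if (allowZero) x < 0 else x <= 0))
        return(sprintf("'%s' must be %s", name,
                       if (allowZero) "non-negative" else "strictly positive"))
    NULL
}

#' Macroscopic steady-state constants of the ping-pong rate law
#'
#' Parameterizes the two-substrate substituted-enzyme (ping-pong bi-bi) rate
#' law with dead-end product inhibition in both half-reactions:
#' \deqn{v/E = \frac{k_{cat} A B}{K_{mA} B (1 + I/K_{iA}) +
#'   K_{mB} A (1 + I/K_{iB}) + A B}}
#' Substrate A is the electron donor (NAD(P)H), substrate B the electron
#' acceptor (e.g. nitrofurazone).  \code{KiA} scales the \eqn{K_{mA} B} term
#' and \code{KiB} the \eqn{K_{mB} A} term; either may be \code{Inf}, the
#' explicit "no inhibition in this half-reaction" sentinel that yields the
#' reduced competitive models exactly.
#'
#' @slot kcat turnover number, 1/s
#' @slot KmA Michaelis constant for the donor A, uM
#' @slot KmB Michaelis constant for the acceptor B, uM
#' @slot KiA inhibitor dissociation constant on the KmA*B term, uM (may be Inf)
#' @slot KiB inhibitor dissociation constant on the KmB*A term, uM (may be Inf)
#' @seealso [kineticParameters()], [pingpongInhibitedRate()]
#' @exportClass KineticParameters
setClass("KineticParameters",
    representation(kcat = "numeric", KmA = "numeric", KmB = "numeric",
                   KiA = "numeric", KiB = "numeric"),
    validity = function(object) {
        msgs <- c(.checkScalar(object@kcat, "kcat"),
                  .checkScalar(object@KmA, "KmA"),
                  .checkScalar(object@KmB, "KmB"),
                  .checkScalar(object@KiA, "KiA", allowInf = TRUE),
                  .checkScalar(object@KiB, "KiB", allowInf = TRUE))
        if (length(msgs)) msgs else TRUE
    })

#' @describeIn KineticParameters-class constructor
#' @param kcat,KmA,KmB,KiA,KiB see slots
#' @return a \code{KineticParameters} object
#' @examples
#' kineticParameters(kcat = 23.1, KmA = 72, KmB = 12, KiA = 249, KiB = 147)
#' @export
kineticParameters <- function(kcat, KmA, KmB, KiA = Inf, KiB = Inf) {
    new("KineticParameters", kcat = as.numeric(kcat), KmA = as.numeric(KmA),
        KmB = as.numeric(KmB), KiA = as.numeric(KiA), KiB = as.numeric(KiB))
}

#' Parameters of the hyperbolic kobs-vs-substrate relation
#'
#' The pseudo-first-order rate constant of an enzyme half-reaction observed by
#' stopped flow follows \eqn{k_{obs} = k S / (K_d + S)}: \code{k} is the
#' limiting first-order rate constant of the chemical step and \code{Kd} the
#' dissociation constant of the substrate-enzyme complex.
#'
#' @slot k limiting first-order rate constant, 1/s
#' @slot Kd dissociation constant, uM
#' @exportClass HyperbolicParameters
setClass("HyperbolicParameters",
    representation(k = "numeric", Kd = "numeric"),
    validity = function(object) {
        msgs <- c(.checkScalar(object@k, "k"), .checkScalar(object@Kd, "Kd"))
        if (length(msgs)) msgs else TRUE
    })

#' @describeIn HyperbolicParameters-class constructor
#' @param k,Kd see slots
#' @export
hyperbolicParameters <- function(k, Kd) {
    new("HyperbolicParameters", k = as.numeric(k), Kd = as.numeric(Kd))
}

#' Inhibition model tags
#'
#' The four nested variants of the ping-pong inhibition rate law:
#' \code{"mixed"} (both Ki finite), \code{"competitive_vs_A"} (only KiA
#' finite: the inhibitor competes with the donor), \code{"competitive_vs_B"}
#' (only KiB finite), and \code{"none"} (both infinite).
#'
#' @format character vector of the four valid tags
#' @export
inhibitionModels <- c("none", "competitive_vs_A", "competitive_vs_B", "mixed")

#' Infer the inhibition model tag from a parameter set
#'
#' @param params a [KineticParameters-class] object
#' @return one of [inhibitionModels]
#' @export
inhibitionModel <- function(params) {
    stopifnot(is(params, "KineticParameters"))
    a <- is.finite(params@KiA)
    b <- is.finite(params@KiB)
    if (a && b) "mixed" else if (a) "competitive_vs_A"
    else if (b) "competitive_vs_B" else "none"
}

# The 13 species of the monomeric substituted-enzyme mechanism.
.mechSpecies <- c("Eox", "EoxA", "EoxI", "Ered", "EredP1", "EredB", "EredI",
                  "EoxP2", "A", "P1", "B", "P2", "I")

.mechRateNames <- c("konA", "koffA", "kRed", "koffP1", "konP1",
                    "konB", "koffB", "kOx", "koffP2", "konP2",
                    "konIox", "koffIox", "konIred", "koffIred")

#' Microscopic rate constants of the substituted-enzyme mechanism
#'
#' Mass-action scheme of the bi-bi substituted (ping-pong) mechanism: the
#' oxidized enzyme binds the donor A (\code{konA}/\code{koffA}, uM^-1 s^-1 and
#' s^-1), hydride transfer reduces the flavin (\code{kRed}, irreversible), the
#' oxidized cofactor P1 is released (\code{koffP1}) and may rebind
#' (\code{konP1}), the reduced enzyme binds the acceptor B
#' (\code{konB}/\code{koffB}), the second chemical step reoxidizes the flavin
#' (\code{kOx}, irreversible) and the reduced product P2 is released
#' (\code{koffP2}/\code{konP2}).  A dead-end inhibitor I may bind the free
#' oxidized (\code{konIox}/\code{koffIox}) and free reduced
#' (\code{konIred}/\code{koffIred}) enzyme.  Both chemical steps are modelled
#' irreversible, as appropriate for nitro-group reduction.
#'
#' @slot rates named numeric vector of the 14 rate constants (see Details)
#' @seealso [mechanismScheme()], [simulateProgress()], [deriveMacroscopic()]
#' @exportClass MechanismScheme
setClass("MechanismScheme",
    representation(rates = "numeric"),
    validity = function(object) {
        r <- object@rates
        if (!identical(names(r), .mechRateNames))
            return(sprintf("rates must be named exactly: %s",
                           paste(.mechRateNames, collapse = ", ")))
        if (any(!is.finite(r)) || any(r < 0))
            return("all rate constants must be finite and >= 0")
        TRUE
    })

#' @describeIn MechanismScheme-class constructor; all rate constants default
#'   to 0 so that partial schemes (e.g. binding-only) are easy to state.
#' @param konA,koffA,kRed,koffP1,konP1,konB,koffB,kOx,koffP2,konP2 forward-cycle
#'   constants (uM^-1 s^-1 for kon*, s^-1 otherwise)
#' @param konIox,koffIox,konIred,koffIred dead-end inhibitor binding constants
#' @export
mechanismScheme <- function(konA = 0, koffA = 0, kRed = 0, koffP1 = 0,
                            konP1 = 0, konB = 0, koffB = 0, kOx = 0,
                            koffP2 = 0, konP2 = 0, konIox = 0, koffIox = 0,
                            konIred = 0, koffIred = 0) {
    r <- c(konA = konA, koffA = koffA, kRed = kRed, koffP1 = koffP1,
           konP1 = konP1, konB = konB, koffB = koffB, kOx = kOx,
           koffP2 = koffP2, konP2 = konP2, konIox = konIox,
           koffIox = koffIox, konIred = konIred, koffIred = koffIred)
    new("MechanismScheme", rates = setNames(as.numeric(r), names(r)))
}

#' Half-of-sites (negatively cooperative) dimer scheme
#'
#' Two copies of a monomer [MechanismScheme-class] coupled through cofactor
#' binding: the on-rate of the donor A at one site is multiplied by
#' \code{alpha} (0 < alpha <= 1) while the partner site is occupied by a
#' nicotinamide ligand.  \code{alpha = 1} recovers two independent sites;
#' \code{alpha -> 0} enforces strict half-of-sites behaviour (at most one
#' cofactor per dimer at saturation).  The penalty may alternatively be
#' applied to the off-rate (\code{couple = "off"}; same equilibrium, faster
#' release from the doubly occupied dimer).
#'
#' @slot base the per-site [MechanismScheme-class]
#' @slot alpha coupling factor in (0, 1]
#' @slot couple \code{"on"} (scale kon by alpha) or \code{"off"} (scale koff
#'   by 1/alpha)
#' @seealso [buildHalfOfSitesScheme()], [equilibriumSiteOccupancy()]
#' @exportClass HalfOfSitesScheme
setClass("HalfOfSitesScheme",
    representation(base = "MechanismScheme", alpha = "numeric",
                   couple = "character"),
    validity = function(object) {
        if (length(object@alpha) != 1L || is.na(object@alpha) ||
            object@alpha <= 0 || object@alpha > 1)
            return("alpha must be a single value in (0, 1]")
        if (!object@couple %in% c("on", "off"))
            return("couple must be \"on\" or \"off\"")
        TRUE
    })

#' One stopped-flow absorbance transient
#'
#' Time/absorbance series with its optical metadata.  Samples earlier than the
#' instrument dead time are discarded at construction (they are collected
#' before mixing is complete and carry no kinetic information); they are not
#' back-extrapolated.
#'
#' @slot time s, strictly increasing, all >= deadTime
#' @slot absorbance AU
#' @slot wavelength nm
#' @slot pathlength cm
#' @slot deadTime s
#' @exportClass AbsorbanceTrace
setClass("AbsorbanceTrace",
    representation(time = "numeric", absorbance = "numeric",
                   wavelength = "numeric", pathlength = "numeric",
                   deadTime = "numeric"),
    validity = function(object) {
        if (length(object@time) != length(object@absorbance))
            return("time and absorbance must have equal length")
        if (length(object@time) < 10L)
            return("a trace needs at least 10 samples")
        if (any(diff(object@time) <= 0))
            return("time must be strictly increasing")
        if (object@time[1] < object@deadTime)
            return("samples before the dead time must be truncated")
        if (object@pathlength <= 0) return("pathlength must be positive")
        TRUE
    })

#' @describeIn AbsorbanceTrace-class constructor; drops samples with
#'   \code{time < deadTime}.
#' @param time,absorbance,wavelength,pathlength,deadTime see slots
#' @export
absorbanceTrace <- function(time, absorbance, wavelength = 340,
                            pathlength = 1, deadTime = 0) {
    keep <- time >= deadTime
    new("AbsorbanceTrace", time = as.numeric(time[keep]),
        absorbance = as.numeric(absorbance[keep]),
        wavelength = as.numeric(wavelength),
        pathlength = as.numeric(pathlength), deadTime = as.numeric(deadTime))
}

#' One steady-state titration curve
#'
#' Initial rates per enzyme for a range of concentrations of one substrate at
#' a fixed concentration of the other, with an optional fixed dead-end
#' inhibitor level.  Rates are normalized by the enzyme concentration
#' (v/E, 1/s); the enzyme concentration itself (nM) is carried as metadata.
#'
#' @slot id dataset label
#' @slot variedSubstrate "A" (donor varied) or "B" (acceptor varied)
#' @slot conc concentrations of the varied substrate, uM
#' @slot cosubstrate fixed co-substrate concentration, uM
#' @slot inhibitor fixed inhibitor concentration, uM
#' @slot rates observed v/E, 1/s
#' @slot enzymeConc enzyme concentration, nM (NA if unknown)
#' @exportClass SteadyStateDataset
setClass("SteadyStateDataset",
    representation(id = "character", variedSubstrate = "character",
                   conc = "numeric", cosubstrate = "numeric",
                   inhibitor = "numeric", rates = "numeric",
                   enzymeConc = "numeric"),
    validity = function(object) {
        if (!object@variedSubstrate %in% c("A", "B"))
            return("variedSubstrate must be \"A\" or \"B\"")
        if (length(object@conc) != length(object@rates))
            return("conc and rates must have equal length")
        if (any(object@conc < 0)) return("concentrations must be >= 0")
        if (anyDuplicated(object@conc))
            return("concentrations must be distinct")
        if (object@cosubstrate < 0 || object@inhibitor < 0)
            return("cosubstrate and inhibitor must be >= 0")
        TRUE
    })

#' @describeIn SteadyStateDataset-class constructor
#' @param conc,rates,variedSubstrate,cosubstrate,inhibitor,enzymeConc,id see
#'   slots
#' @export
steadyStateDataset <- function(conc, rates, variedSubstrate = "A",
                               cosubstrate = 100, inhibitor = 0,
                               enzymeConc = NA_real_, id = "dataset") {
    new("SteadyStateDataset", id = id, variedSubstrate = variedSubstrate,
        conc = as.numeric(conc), cosubstrate = as.numeric(cosubstrate),
        inhibitor = as.numeric(inhibitor), rates = as.numeric(rates),
        enzymeConc = as.numeric(enzymeConc))
}

#' Simulated time course of a mechanism
#'
#' Time grid plus a species-by-time concentration matrix, with the linear
#' conservation pools of the generating scheme attached so that mass balance
#' can be audited after the fact.
#'
#' @slot time s, strictly increasing
#' @slot concentrations matrix (rows = time points, columns = species), uM
#' @slot pools named list of named coefficient vectors defining conserved
#'   linear combinations (total enzyme, nicotinamide pool, acceptor pool,
#'   inhibitor pool)
#' @exportClass ProgressCurve
setClass("ProgressCurve",
    representation(time = "numeric", concentrations = "matrix",
                   pools = "list"),
    validity = function(object) {
        if (nrow(object@concentrations) != length(object@time))
            return("concentrations must have one row per time point")
        if (any(diff(object@time) <= 0))
            return("time must be strictly increasing")
        TRUE
    })

#' A synthetic experimental design
#'
#' Describes one of the designs the generators emulate: a Michaelis-Menten
#' titration at fixed co-substrate (\code{"michaelis"}), the two-sided
#' inhibition design with both substrate families and several inhibitor
#' levels (\code{"two_sided_inhibition"}), or a set of stopped-flow pushes
#' (\code{"stopped_flow"}).
#'
#' @slot kind one of "michaelis", "two_sided_inhibition", "stopped_flow"
#' @slot grids named list of concentration grids, uM
#' @slot cosubstrate named numeric of fixed co-substrate levels, uM
#' @slot inhibitorLevels inhibitor concentrations, uM
#' @slot replicates number of replicate curves per condition
#' @slot noiseSd homoscedastic Gaussian noise SD (1/s for rates, AU for traces)
#' @slot seed RNG seed (NA allowed only for noiseless designs)
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
    representation(kind = "character", grids = "list",
                   cosubstrate = "numeric", inhibitorLevels = "numeric",
                   replicates = "integer", noiseSd = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (!object@kind %in% c("michaelis", "two_sided_inhibition",
                                "stopped_flow"))
            return("unknown design kind")
        if (!length(object@grids) ||
            any(!vapply(object@grids,
                        function(g) length(g) > 0 && all(g > 0), logical(1))))
            return("grids must be non-empty and positive")
        if (object@replicates < 1L) return("replicates must be >= 1")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (object@noiseSd > 0 && is.na(object@seed))
            return("a seed is mandatory for noisy designs")
        TRUE
    })

#' @describeIn ExperimentDesign-class constructor
#' @param kind,grids,cosubstrate,inhibitorLevels,replicates,noiseSd,seed see
#'   slots
#' @export
experimentDesign <- function(kind, grids, cosubstrate = numeric(0),
                             inhibitorLevels = 0, replicates = 1L,
                             noiseSd = 0, seed = NA_integer_) {
    new("ExperimentDesign", kind = kind, grids = grids,
        cosubstrate = cosubstrate, inhibitorLevels = inhibitorLevels,
        replicates = as.integer(replicates), noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Result of a nonlinear least-squares fit
#'
#' Parameter estimates with Wald inference (standard errors from
#' \eqn{s^2 (J^T J)^{-1}}, t statistics and two-sided P values on n - p
#' degrees of freedom for the null that the parameter is 0), the residual sum
#' of squares, AIC/AICc, the parameter covariance matrix, and quality flags
#' ("exact_fit", "degenerate", "extrapolated", "unidentifiable: ...",
#' "poor_fit", ...).
#'
#' @slot model model label ("michaelis", "hyperbolic", or an inhibition tag)
#' @slot coefficients data.frame: parameter, estimate, se, t, p
#' @slot rss residual sum of squares
#' @slot n number of data points
#' @slot p number of free parameters
#' @slot aic,aicc Akaike information criterion (Gaussian RSS form, K = p + 1)
#' @slot cov parameter covariance matrix (natural scale)
#' @slot flags character vector of quality flags (may be empty)
#' @slot details list of fit diagnostics (convergence, starts, derived
#'   quantities such as k/Kd)
#' @exportClass FitResult
setClass("FitResult",
    representation(model = "character", coefficients = "data.frame",
                   rss = "numeric", n = "numeric", p = "numeric",
                   aic = "numeric", aicc = "numeric", cov = "matrix",
                   flags = "character", details = "list"),
    validity = function(object) {
        if (object@n <= object@p)
            return("need more points than free parameters")
        pv <- object@coefficients$p
        if (length(pv) && any(!is.na(pv) & (pv <= 0 | pv > 1)))
            return("P values must lie in (0, 1]")
        TRUE
    })

#' Comparison of inhibition models fitted to the same data
#'
#' @slot fits named list of [FitResult-class] (or error condition) per model
#' @slot table data.frame: model, n, p, rss, aic, aicc, dAICc
#' @slot selected the selected model tag
#' @slot rule the selection rule that was applied
#' @exportClass ModelComparison
setClass("ModelComparison",
    representation(fits = "list", table = "data.frame",
                   selected = "character", rule = "character"))
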