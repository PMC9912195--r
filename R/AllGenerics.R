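#' @name NTRkinetics-generics
#' @title Generics defined by NTRkinetics
#' @description S4 generics whose methods dispatch on the scheme or parameter
#'   class: mechanism simulation works for both the monomer and the
#'   half-of-sites dimer, and synthetic transients can be drawn either from
#'   the closed-form hyperbola or from the full ODE mechanism.
#' @keywords internal
NULL

#' @rdname NTRkinetics-generics
#' @param scheme a [MechanismScheme-class] or [HalfOfSitesScheme-class]
#' @param ... passed to methods
#' @export
setGeneric("simulateProgress",
           function(scheme, ...) standardGeneric("simulateProgress"))

#' @rdname NTRkinetics-generics
#' @export
setGeneric("numericalInitialRate",
           function(scheme, ...) standardGeneric("numericalInitialRate"))

#' @rdname NTRkinetics-generics
#' @param object parameter object for transient generation
#' @export
setGeneric("generateTransient",
           function(object, ...) standardGeneric("generateTransient"))

# ---- show methods --------------------------------------------------------

.fmtKi <- function(x) if (is.finite(x)) sprintf("%.4g uM", x) else "Inf (none)"

setMethod("show", "KineticParameters", function(object) {
    cat("KineticParameters (ping-pong bi-bi, model:",
        inhibitionModel(object), ")\n",
        sprintf("  kcat = %.4g /s, KmA = %.4g uM, KmB = %.4g uM\n",
                object@kcat, object@KmA, object@KmB),
        "  KiA =", .fmtKi(object@KiA), ", KiB =", .fmtKi(object@KiB), "\n")
})

setMethod("show", "HyperbolicParameters", function(object) {
    cat(sprintf(
        "HyperbolicParameters: k = %.4g /s, Kd = %.4g uM, k/Kd = %.4g /(uM s)\n",
        object@k, object@Kd, object@k / object@Kd))
})

setMethod("show", "MechanismScheme", function(object) {
    cat("MechanismScheme (substituted-enzyme mass-action scheme)\n")
    r <- object@rates
    cat(sprintf("  donor:    konA = %.4g, koffA = %.4g, kRed = %.4g\n",
                r["konA"], r["koffA"], r["kRed"]))
    cat(sprintf("  P1:       koffP1 = %.4g, konP1 = %.4g\n",
                r["koffP1"], r["konP1"]))
    cat(sprintf("  acceptor: konB = %.4g, koffB = %.4g, kOx = %.4g\n",
                r["konB"], r["koffB"], r["kOx"]))
    cat(sprintf("  P2:       koffP2 = %.4g, konP2 = %.4g\n",
                r["koffP2"], r["konP2"]))
    cat(sprintf("  inhibitor: ox %.4g/%.4g, red %.4g/%.4g\n",
                r["konIox"], r["koffIox"], r["konIred"], r["koffIred"]))
})

setMethod("show", "HalfOfSitesScheme", function(object) {
    cat(sprintf(
        "HalfOfSitesScheme: alpha = %.4g (coupling on %s-rate)\n",
        object@alpha, object@couple))
    show(object@base)
})

setMethod("show", "AbsorbanceTrace", function(object) {
    cat(sprintf(
        "AbsorbanceTrace: %d samples over %.4g s at %g nm (path %g cm, dead time %g s)\n",
        length(object@time), diff(range(object@time)), object@wavelength,
        object@pathlength, object@deadTime))
})

setMethod("show", "SteadyStateDataset", function(object) {
    cat(sprintf(
        "SteadyStateDataset '%s': %s varied (%d conc, %.4g-%.4g uM), co-substrate %.4g uM, I = %.4g uM\n",
        object@id, object@variedSubstrate, length(object@conc),
        min(object@conc), max(object@conc), object@cosubstrate,
        object@inhibitor))
})

setMethod("show", "ProgressCurve", function(object) {
    cat(sprintf("ProgressCurve: %d time points over %.4g s, %d species\n",
                length(object@time), diff(range(object@time)),
                ncol(object@concentrations)))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: model '%s', n = %d, p = %d, RSS = %.6g\n",
                object@model, as.integer(object@n), as.integer(object@p),
                object@rss))
    cat(sprintf("  AIC = %.4g, AICc = %.4g\n", object@aic, object@aicc))
    print(object@coefficients, row.names = FALSE, digits = 4)
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "ModelComparison", function(object) {
    cat("ModelComparison (selected:", object@selected, ")\n")
    print(object@table, row.names = FALSE, digits = 4)
    cat("  rule:", object@rule, "\n")
})

# ---- accessors -----------------------------------------------------------

#' @describeIn FitResult-class estimates as a named vector
#' @param object a FitResult
#' @export
setMethod("coef", "FitResult", function(object) {
    setNames(object@coefficients$estimate, object@coefficients$parameter)
})

#' @describeIn FitResult-class parameter covariance matrix
#' @export
setMethod("vcov", "FitResult", function(object) object@cov)

#' Quality flags attached to a fit
#' @param fit a [FitResult-class]
#' @return character vector (empty when the fit is clean)
#' @export
fitFlags <- function(fit) fit@flags

#' Residual sum of squares of a fit
#' @param fit a [FitResult-class]
#' @export
fitRSS <- function(fit) fit@rss

#' Full inference table of a fit
#'
#' Estimates, standard errors from \eqn{s^2 (J^T J)^{-1}}, t statistics and
#' two-sided P values (t distribution on n - p degrees of freedom, null value
#' 0), as computed at fit time.
#'
#' @param fit a [FitResult-class]
#' @return data.frame with columns parameter, estimate, se, t, p
#' @export
parameterInference <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    fit@coefficients
}

#' Extract the fitted hyperbola as a parameter object
#' @param fit a [FitResult-class] from [fitKobsHyperbola()]
#' @return a [HyperbolicParameters-class]
#' @export
hyperbolicFromFit <- function(fit) {
    stopifnot(is(fit, "FitResult"), fit@model == "hyperbolic")
    cf <- coef(fit)
    hyperbolicParameters(cf[["k"]], cf[["Kd"]])
}

#' Extract fitted ping-pong constants as a parameter object
#'
#' Ki's absent from the fitted (reduced) model are returned as \code{Inf},
#' the package's explicit no-inhibition sentinel.
#'
#' @param fit a [FitResult-class] from [fitGlobalInhibition()]
#' @return a [KineticParameters-class]
#' @export
kineticParametersFromFit <- function(fit) {
    stopifnot(is(fit, "FitResult"),
              fit@model %in% inhibitionModels)
    cf <- coef(fit)
    kineticParameters(cf[["kcat"]], cf[["KmA"]], cf[["KmB"]],
                      if ("KiA" %in% names(cf)) cf[["KiA"]] else Inf,
                      if ("KiB" %in% names(cf)) cf[["KiB"]] else Inf)
}
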