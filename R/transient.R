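# Stopped-flow transient analysis: single-exponential kobs extraction,
# hyperbolic kobs(S) fits, and Beer-Lambert conversions.

#' Molar extinction coefficients used by the assays
#'
#' Reference molar absorbances (M^-1 cm^-1): the absorbance *change* at
#' 420 nm per mole of nitro substrate reduced (nitrofurazone, CB1954), and
#' the absolute coefficients used to quantify enzyme and excess flavin
#' (FMN at 454 and 280 nm, apoprotein at 280 nm).
#'
#' @param ... name = value overrides of individual entries
#' @return named positive numeric vector
#' @examples
#' extinctionCoefficients()[["FMN454"]]
#' @export
extinctionCoefficients <- function(...) {
    ec <- c(dNitrofurazone420 = 4300, dCB1954_420 = 1200,
            FMN454 = 12200, FMN280 = 20970, NfsA280 = 31190)
    over <- c(...)
    if (length(over)) {
        bad <- setdiff(names(over), names(ec))
        if (length(bad))
            stop("unknown coefficients: ", paste(bad, collapse = ", "),
                 call. = FALSE)
        ec[names(over)] <- over
    }
    if (any(ec <= 0)) stop("extinction coefficients must be > 0",
                           call. = FALSE)
    ec
}

#' Fit a single-exponential decay to an absorbance transient
#'
#' Model \eqn{A(t) = \mathrm{offset} + \mathrm{amplitude}\, e^{-k_{obs} t}}.
#' The offset is always fitted (the end-point absorbance of a real push is
#' never exactly zero); the amplitude may have either sign, so rises and
#' decays are handled identically.  Internally the conditionally linear
#' parameters (offset, amplitude) are profiled out and the optimization is
#' one-dimensional in \eqn{\log k_{obs}}, which makes the fit essentially
#' global; standard errors come from the full 3-parameter Jacobian.
#'
#' @param trace an [AbsorbanceTrace-class]
#' @param kobsCeiling instrument reliability ceiling, 1/s; a fitted kobs
#'   above it is flagged (not corrected).  The default \code{Inf} disables
#'   the flag; ~150/s is appropriate for a photodiode-array instrument with
#'   a long dead time.
#' @return a [FitResult-class] with parameters kobs, amplitude, offset;
#'   details carry the noise estimate and R-squared.  Errors if the
#'   amplitude is indistinguishable from zero (|amplitude| < 3 * noise SD,
#'   "no decay"); flags \code{"poor_fit"} when R-squared < 0.9 and
#'   \code{"short_trace"} when the trace spans < 3/kobs.
#' @export
fitExponential <- function(trace, kobsCeiling = Inf) {
    stopifnot(is(trace, "AbsorbanceTrace"))
    tt <- trace@time - trace@time[1]
    y <- trace@absorbance
    n <- length(y)
    noise <- sd(diff(y)) / sqrt(2)

    ntail <- max(3L, ceiling(n * 0.1))
    offset0 <- mean(tail(y, ntail))
    amp0 <- y[1] - offset0
    # the threshold floor catches exactly flat traces, where noise is 0 too
    if (abs(amp0) < max(3 * noise, 1e-9 * max(abs(y), 1)))
        stop("no decay: amplitude indistinguishable from noise",
             call. = FALSE)

    # profile out (offset, amplitude) for fixed k: linear least squares
    rssOfLogK <- function(lk) {
        e <- exp(-exp(lk) * tt)
        fit <- tryCatch(lm.fit(cbind(1, e), y), error = function(x) NULL)
        if (is.null(fit)) return(Inf)
        sum(fit$residuals^2)
    }
    span <- max(tt)
    # crude k scale from the 1/e crossing of the smoothed decay
    target <- offset0 + amp0 / exp(1)
    cross <- if (amp0 > 0) which(y <= target) else which(y >= target)
    k0 <- if (length(cross)) 1 / max(tt[cross[1]], span / n) else 3 / span
    opt <- optimize(rssOfLogK, interval = log(c(k0 / 300, k0 * 300)),
                    tol = 1e-9)
    kobs <- exp(opt$minimum)
    e <- exp(-kobs * tt)
    lin <- lm.fit(cbind(1, e), y)
    offset <- lin$coefficients[1]
    amplitude <- lin$coefficients[2]

    theta <- c(kobs = unname(kobs), amplitude = unname(amplitude),
               offset = unname(offset))
    predictNat <- function(th) th[["offset"]] +
        th[["amplitude"]] * exp(-th[["kobs"]] * tt)
    rss <- sum((y - predictNat(theta))^2)
    J <- .numJacobian(predictNat, theta)
    dof <- n - 3L
    s2 <- rss / dof
    covm <- tryCatch(s2 * solve(crossprod(J)), error = function(x) NULL)
    flags <- character(0)
    if (is.null(covm)) {
        covm <- matrix(NA_real_, 3, 3)
        se <- rep(NA_real_, 3)
        flags <- c(flags, "singular Jacobian: SEs unavailable")
    } else se <- sqrt(pmax(diag(covm), 0))
    dimnames(covm) <- list(names(theta), names(theta))

    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 < 0.9) flags <- c(flags, "poor_fit")
    if (max(tt) < 3 / kobs) flags <- c(flags, "short_trace")
    if (kobs > kobsCeiling)
        flags <- c(flags, sprintf("kobs above reliability ceiling (%g /s)",
                                  kobsCeiling))
    if (rss <= n * (1e-10 * max(abs(y)))^2) flags <- c(flags, "exact_fit")

    tval <- theta / se
    pval <- pmax(2 * pt(-abs(tval), dof), .Machine$double.xmin)
    coefs <- data.frame(parameter = names(theta), estimate = unname(theta),
                        se = unname(se), t = unname(tval), p = unname(pval))
    new("FitResult", model = "exponential", coefficients = coefs, rss = rss,
        n = as.numeric(n), p = 3, aic = .aicFromRSS(rss, n, 3),
        aicc = .aicFromRSS(rss, n, 3, correct = TRUE), cov = covm,
        flags = flags,
        details = list(noiseSd = noise, r2 = r2,
                       wavelength = trace@wavelength,
                       deadTime = trace@deadTime))
}

#' Observed kobs from a trace
#' @param trace an [AbsorbanceTrace-class]
#' @param ... passed to [fitExponential()]
#' @return kobs, 1/s
#' @export
observedRateConstant <- function(trace, ...) {
    coef(fitExponential(trace, ...))[["kobs"]]
}

#' Fit the hyperbolic concentration dependence of kobs
#'
#' Nonlinear least-squares fit of \eqn{k_{obs} = k S/(K_d + S)} to a set of
#' (S, kobs) pairs, with a fixed multistart grid
#' (\eqn{k_0 = \max(k_{obs}) \times \{1, 2, 5\}},
#' \eqn{K_{d,0} = \mathrm{median}(S) \times \{0.3, 1, 3\}}; best RSS wins,
#' ties broken by the smallest Kd).  The derived second-order constant
#' \eqn{k/K_d} is reported with its error propagated from the parameter
#' covariance.  The result is flagged \code{"extrapolated"} when
#' \eqn{\max(S) < K_d} (the fitted plateau lies beyond the sampled range, as
#' for menadione) and \code{"unidentifiable"}/"degenerate" in the flat or
#' linear-regime corner cases.
#'
#' @param S substrate concentrations, uM (>= 3 distinct values)
#' @param kobs observed rate constants, 1/s
#' @return a [FitResult-class] (model "hyperbolic"); \code{details$kOverKd}
#'   holds the estimate and SE of k/Kd
#' @export
fitKobsHyperbola <- function(S, kobs) {
    if (length(S) != length(kobs))
        stop("S and kobs must have equal length", call. = FALSE)
    if (length(unique(S)) < 3L)
        stop("need at least 3 distinct substrate concentrations",
             call. = FALSE)
    .checkConc(S, "S")
    starts <- list()
    for (Kf in c(0.3, 1, 3)) for (kf in c(1, 2, 5))
        starts[[length(starts) + 1L]] <-
            c(k = max(kobs) * kf, Kd = median(S) * Kf)
    # order so that equal-RSS ties resolve to the smallest Kd start
    starts <- starts[order(vapply(starts, `[[`, numeric(1), "Kd"))]
    predict <- function(th) th[["k"]] * S / (th[["Kd"]] + S)
    fit <- .lsqFit(predict, kobs, starts)

    flags <- character(0)
    if (max(S) < fit$theta[["Kd"]]) flags <- c(flags, "extrapolated")
    # delta method for k/Kd
    k <- fit$theta[["k"]]; Kd <- fit$theta[["Kd"]]
    g <- c(1 / Kd, -k / Kd^2)
    vr <- if (all(is.finite(fit$cov))) drop(t(g) %*% fit$cov %*% g)
          else NA_real_
    details <- list(kOverKd = c(estimate = k / Kd,
                                se = if (is.na(vr)) NA_real_
                                     else sqrt(max(vr, 0))))
    .makeFitResult(fit, "hyperbolic", flags, details)
}

#' Second-order rate constant from the linear (low-S) regime
#'
#' Zero-intercept linear regression of kobs on S, estimating the initial
#' slope \eqn{k/K_d} directly: the analysis of choice when \eqn{K_d} lies
#' beyond the measurable range (the NADH situation).
#'
#' @param S substrate concentrations, uM (>= 2 points)
#' @param kobs observed rate constants, 1/s
#' @return list with \code{slope} (k/Kd, 1/(uM s)), \code{se}, and the
#'   underlying \code{lm} fit
#' @export
secondOrderLimit <- function(S, kobs) {
    if (length(S) != length(kobs) || length(S) < 2L)
        stop("need at least 2 (S, kobs) points", call. = FALSE)
    .checkConc(S, "S")
    fit <- lm(kobs ~ 0 + S)
    # summary.lm warns on exact lines ("essentially perfect fit"); that case
    # is legitimate here (noiseless synthetic data)
    sm <- suppressWarnings(summary(fit))$coefficients
    list(slope = unname(sm[1, 1]), se = unname(sm[1, 2]), fit = fit)
}

#' Convert an absorbance slope to a concentration rate
#'
#' Beer-Lambert: \eqn{v = 10^6 \, (dA/dt) / (\epsilon \, l)} in uM/s for
#' \eqn{\epsilon} in M^-1 cm^-1 and path length in cm.
#'
#' @param dAdt absorbance slope, AU/s (vectorized)
#' @param epsilon molar absorbance (change), M^-1 cm^-1
#' @param pathlength cm
#' @return rate, uM/s
#' @export
rateFromSlope <- function(dAdt, epsilon, pathlength = 1) {
    if (any(epsilon <= 0) || any(pathlength <= 0))
        stop("epsilon and pathlength must be > 0", call. = FALSE)
    1e6 * dAdt / (epsilon * pathlength)
}

#' Protein concentration corrected for excess free flavin
#'
#' Both the apoprotein and FMN absorb at 280 nm while only FMN absorbs at
#' 454 nm, so the FMN contribution to A280 is estimated from A454 and
#' subtracted:
#' \deqn{[E] = 10^6 \, (A_{280} - A_{454}\,
#'   \epsilon^{FMN}_{280}/\epsilon^{FMN}_{454}) / \epsilon^{E}_{280}}
#'
#' @param A280,A454 absorbances, AU (1 cm path)
#' @param ec coefficients from [extinctionCoefficients()] (needs entries
#'   FMN454, FMN280, NfsA280)
#' @return protein concentration, uM
#' @export
proteinConcentration <- function(A280, A454, ec = extinctionCoefficients()) {
    if (any(A280 < 0) || any(A454 < 0))
        stop("absorbances must be >= 0", call. = FALSE)
    fmn280 <- A454 * ec[["FMN280"]] / ec[["FMN454"]]
    if (any(A280 - fmn280 < -1e-12))
        stop("over-corrected: FMN-attributable A280 exceeds measured A280",
             call. = FALSE)
    1e6 * pmax(A280 - fmn280, 0) / ec[["NfsA280"]]
}
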