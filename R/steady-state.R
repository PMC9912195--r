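# Steady-state fitting: Michaelis-Menten per curve, global ping-pong
# inhibition fits across datasets, AIC computation, and model selection
# among the nested inhibition variants.  All fits are unweighted
# (homoscedastic) least squares, matching the equal-weighting convention of
# the assays.

# Pool datasets into one prediction table with explicit A/B/I columns.
.poolDatasets <- function(datasets) {
    stopifnot(length(datasets) >= 1,
              all(vapply(datasets, is, logical(1), "SteadyStateDataset")))
    rows <- lapply(datasets, function(d) {
        if (d@variedSubstrate == "A")
            data.frame(A = d@conc, B = d@cosubstrate, I = d@inhibitor,
                       rate = d@rates, id = d@id)
        else
            data.frame(A = d@cosubstrate, B = d@conc, I = d@inhibitor,
                       rate = d@rates, id = d@id)
    })
    do.call(rbind, rows)
}

.modelParams <- function(model) {
    switch(model,
           none = c("kcat", "KmA", "KmB"),
           competitive_vs_A = c("kcat", "KmA", "KmB", "KiA"),
           competitive_vs_B = c("kcat", "KmA", "KmB", "KiB"),
           mixed = c("kcat", "KmA", "KmB", "KiA", "KiB"))
}

.pingpongPredictor <- function(tab, model) {
    hasKiA <- model %in% c("competitive_vs_A", "mixed")
    hasKiB <- model %in% c("competitive_vs_B", "mixed")
    function(th) {
        facA <- if (hasKiA) 1 + tab$I / th[["KiA"]] else 1
        facB <- if (hasKiB) 1 + tab$I / th[["KiB"]] else 1
        num <- th[["kcat"]] * tab$A * tab$B
        den <- th[["KmA"]] * tab$B * facA + th[["KmB"]] * tab$A * facB +
            tab$A * tab$B
        ifelse(den == 0, 0, num / den)
    }
}

# Data-scale start heuristics scaled by 5 log-spaced factors over [1e-2, 1e2].
.multistart <- function(base) {
    lapply(10^seq(-2, 2, length.out = 5), function(f) base * f)
}

#' Fit the Michaelis-Menten model to one titration curve
#'
#' Unweighted nonlinear least squares for apparent kcat and Km at the fixed
#' co-substrate level of the dataset, with Wald standard errors, t statistics
#' and P values (null: parameter = 0).
#'
#' @param dataset a [SteadyStateDataset-class] with >= 4 points over >= 3
#'   distinct concentrations
#' @return a [FitResult-class] (model "michaelis"); \code{details$kcatOverKm}
#'   carries the specificity constant with a delta-method SE.  Flagged
#'   \code{"extrapolated"} when the fitted Km exceeds 10x the largest assayed
#'   concentration and \code{"degenerate"} when Km collapses to the search
#'   boundary (flat data).
#' @examples
#' d <- steadyStateDataset(conc = 2^(0:7), rates = mmRate(2^(0:7), 24, 19))
#' fitMichaelis(d)
#' @export
fitMichaelis <- function(dataset) {
    stopifnot(is(dataset, "SteadyStateDataset"))
    S <- dataset@conc; v <- dataset@rates
    if (length(S) < 4L || length(unique(S)) < 3L)
        stop("need >= 4 points over >= 3 distinct concentrations",
             call. = FALSE)
    base <- c(kcat = max(v[v > 0], 1e-6), Km = median(S[S > 0]))
    predict <- function(th) th[["kcat"]] * S / (th[["Km"]] + S)
    fit <- .lsqFit(predict, v, .multistart(base))
    flags <- character(0)
    if (fit$theta[["Km"]] > 10 * max(S)) flags <- c(flags, "extrapolated")
    kc <- fit$theta[["kcat"]]; Km <- fit$theta[["Km"]]
    g <- c(1 / Km, -kc / Km^2)
    vr <- if (all(is.finite(fit$cov))) drop(t(g) %*% fit$cov %*% g)
          else NA_real_
    .makeFitResult(fit, "michaelis", flags,
                   list(kcatOverKm = c(estimate = kc / Km,
                                       se = if (is.na(vr)) NA_real_
                                            else sqrt(max(vr, 0)))))
}

#' Global fit of the inhibited ping-pong rate law across datasets
#'
#' Fits one shared parameter vector (kcat, KmA, KmB, plus the finite Ki's of
#' the requested inhibition variant) to all datasets simultaneously by
#' pooled unweighted least squares.  Parameters are optimized in log space
#' (positivity by construction) from a multistart grid; inference is
#' reported on the natural scale.
#'
#' @param datasets list of [SteadyStateDataset-class]; must contain at least
#'   one donor-varied and one acceptor-varied series, and at least one series
#'   with inhibitor present when an inhibition model is requested
#' @param model one of [inhibitionModels] (default "mixed")
#' @return a [FitResult-class]; Ki parameters that never see inhibitor are
#'   flagged unidentifiable, and a scaled-Jacobian condition number above
#'   1e8 flags the result as ill-conditioned
#' @export
fitGlobalInhibition <- function(datasets, model = "mixed") {
    model <- match.arg(model, inhibitionModels)
    tab <- .poolDatasets(datasets)
    varied <- vapply(datasets, function(d) d@variedSubstrate, character(1))
    if (!all(c("A", "B") %in% varied))
        stop("global fit needs at least one A-varied and one B-varied series",
             call. = FALSE)
    if (model != "none" && all(tab$I == 0))
        warning("inhibition model requested but no series has inhibitor; ",
                "Ki will be unidentifiable", call. = FALSE)
    pars <- .modelParams(model)
    Iscale <- if (any(tab$I > 0)) median(tab$I[tab$I > 0]) else
        median(c(tab$A, tab$B))
    base <- c(kcat = max(tab$rate[tab$rate > 0], 1e-6),
              KmA = median(tab$A), KmB = median(tab$B),
              KiA = Iscale, KiB = Iscale)[pars]
    fit <- .lsqFit(.pingpongPredictor(tab, model), tab$rate,
                   .multistart(base))
    .makeFitResult(fit, model, details = list(nDatasets = length(datasets)))
}

#' Akaike information criterion of a fit
#'
#' Gaussian RSS-based form with the residual variance counted as a free
#' parameter: \eqn{AIC = n \ln(RSS/n) + 2K}, \eqn{K = p + 1};
#' \eqn{AICc = AIC + 2K(K+1)/(n-K-1)}.  An exact fit (RSS = 0) returns
#' \code{-Inf}.
#'
#' @param fit a [FitResult-class]
#' @param variant "AIC" or "AICc"
#' @return the criterion value
#' @export
akaike <- function(fit, variant = c("AICc", "AIC")) {
    stopifnot(is(fit, "FitResult"))
    variant <- match.arg(variant)
    .aicFromRSS(fit@rss, fit@n, fit@p, correct = variant == "AICc")
}

#' Compare the inhibition variants on the same data
#'
#' Fits the mixed model and both single-half competitive reductions (and
#' optionally the uninhibited model) globally to the same datasets, ranks
#' them by AICc, and selects the minimum -- except that when a model with
#' fewer parameters lies within \code{deltaTie} (default 2) AICc units of
#' the best, the simpler model is selected (nested models that tie are not
#' evidence for the extra parameter).
#'
#' @param datasets as for [fitGlobalInhibition()]
#' @param models inhibition variants to compare
#' @param includeNone also fit the uninhibited model
#' @param deltaTie AICc margin within which the simpler model wins
#' @return a [ModelComparison-class]; constituent fit errors are retained in
#'   \code{fits} and excluded from selection
#' @export
compareModels <- function(datasets,
                          models = c("mixed", "competitive_vs_A",
                                     "competitive_vs_B"),
                          includeNone = FALSE, deltaTie = 2) {
    models <- match.arg(models, inhibitionModels, several.ok = TRUE)
    if (includeNone) models <- unique(c(models, "none"))
    fits <- lapply(models, function(m)
        tryCatch(fitGlobalInhibition(datasets, m), error = function(e) e))
    names(fits) <- models
    ok <- vapply(fits, is, logical(1), "FitResult")
    if (!any(ok)) stop("all model fits failed", call. = FALSE)
    tabRows <- lapply(models[ok], function(m) {
        f <- fits[[m]]
        data.frame(model = m, n = f@n, p = f@p, rss = f@rss, aic = f@aic,
                   aicc = f@aicc)
    })
    tab <- do.call(rbind, tabRows)
    best <- min(tab$aicc)
    tab$dAICc <- if (is.infinite(best)) ifelse(is.infinite(tab$aicc), 0, Inf)
                 else tab$aicc - best
    # selection: min AICc, but a simpler model within deltaTie wins
    cand <- tab[tab$dAICc < deltaTie, ]
    cand <- cand[order(cand$p, cand$aicc), ]
    selected <- cand$model[1]
    tab <- tab[order(tab$aicc), ]
    rule <- sprintf(
        "minimum AICc; a model with fewer parameters within %g AICc units of the best is preferred",
        deltaTie)
    new("ModelComparison", fits = fits, table = tab, selected = selected,
        rule = rule)
}

#' Selected model of a comparison
#' @param comparison a [ModelComparison-class]
#' @export
selectedModel <- function(comparison) {
    stopifnot(is(comparison, "ModelComparison"))
    comparison@selected
}

#' Comparison table of a model comparison
#' @param comparison a [ModelComparison-class]
#' @return data.frame with model, n, p, rss, aic, aicc, dAICc
#' @export
comparisonTable <- function(comparison) {
    stopifnot(is(comparison, "ModelComparison"))
    comparison@table
}
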