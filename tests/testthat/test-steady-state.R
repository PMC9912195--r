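# Steady-state fitting: Michaelis-Menten, global inhibition fits, AIC, and
# model selection among the nested inhibition variants.

test_that("Michaelis fits recover noiseless data exactly", {
    for (row in michaelisRows) {
        d <- generateMichaelis(row[["kcat"]], row[["Km"]])
        fit <- fitMichaelis(d)
        expect_equal(unname(coef(fit)), unname(row), tolerance = 1e-6)
        expect_true("exact_fit" %in% fitFlags(fit))
        expect_equal(fit@details$kcatOverKm[["estimate"]],
                     row[["kcat"]] / row[["Km"]], tolerance = 1e-6)
    }
    expect_error(fitMichaelis(steadyStateDataset(c(1, 2, 4), c(1, 2, 3))),
                 ">= 4 points")
})

test_that("flat titrations are flagged degenerate", {
    d <- steadyStateDataset(conc = c(1, 2, 4, 8, 16),
                            rates = rep(10, 5))
    fit <- fitMichaelis(d)
    expect_true("degenerate" %in% fitFlags(fit))
    expect_lt(coef(fit)[["Km"]], 1e-3)
})

test_that("noisy Michaelis estimates fall within 3 SE of truth", {
    kcat <- 24; Km <- 19
    conc <- 10 * Km * 2^-(7:0)
    good <- 0
    pLow <- 0
    for (r in 1:100) {
        d <- generateMichaelis(kcat, Km, conc, noiseSd = 0.05 * kcat,
                               seed = 5000 + r)
        fit <- fitMichaelis(d)
        cf <- parameterInference(fit)
        within3 <- abs(cf$estimate - c(kcat, Km)) <= 3 * cf$se
        if (all(within3)) good <- good + 1
        if (cf$p[cf$parameter == "kcat"] < 1e-4) pLow <- pLow + 1
    }
    expect_gte(good, 95)
    # kcat is always overwhelmingly significant at this noise level
    expect_gte(pLow, 99)
})

test_that("global mixed fit recovers the generating constants exactly", {
    kp <- mixedParams()
    ds <- generateSteadyState(kp, defaultInhibitionDesign())
    fit <- fitGlobalInhibition(ds, "mixed")
    expect_lt(relErr(coef(fit), c(23.1, 72, 12, 249, 147)), 1e-4)
    expect_identical(fit@model, "mixed")
    expect_identical(unname(fit@p), 5)
    # report path: the full mixed model lists exactly five parameters
    expect_identical(nrow(fitReport(fit)), 5L)
})

test_that("global fit validates its design and flags unidentifiable Ki", {
    kp <- mixedParams()
    ds <- generateSteadyState(kp, defaultInhibitionDesign())
    onlyA <- ds[grepl("^Avaried", names(ds))]
    expect_error(fitGlobalInhibition(onlyA, "mixed"), "A-varied and one B")
    noI <- generateSteadyState(kp, defaultInhibitionDesign(inhibitorLevels = 0))
    expect_warning(fit <- fitGlobalInhibition(noI, "mixed"),
                   "unidentifiable")
    expect_true(any(grepl("unidentifiable: KiA, KiB", fitFlags(fit))))
    # the identifiable core is still recovered
    expect_lt(relErr(coef(fit)[c("kcat", "KmA", "KmB")],
                     c(23.1, 72, 12)), 1e-4)
})

test_that("nested models cannot beat the truth on RSS", {
    kp <- mixedParams()
    des <- defaultInhibitionDesign(noiseSd = 23.1 * 0.05, seed = 99L)
    ds <- generateSteadyState(kp, des)
    rssOf <- function(m) fitRSS(fitGlobalInhibition(ds, m))
    expect_lte(rssOf("mixed"), rssOf("competitive_vs_A"))
    expect_lte(rssOf("competitive_vs_A"), rssOf("none"))
    # on noiseless mixed-generated data the reduced model is strictly worse
    dn <- generateSteadyState(kp, defaultInhibitionDesign())
    expect_gt(fitRSS(fitGlobalInhibition(dn, "competitive_vs_A")),
              fitRSS(fitGlobalInhibition(dn, "mixed")))
})

test_that("concentration rescaling moves Km and Ki but not kcat", {
    kp <- mixedParams()
    ds <- generateSteadyState(kp, defaultInhibitionDesign())
    c0 <- 3.7
    scaled <- lapply(ds, function(d) {
        steadyStateDataset(conc = c0 * d@conc, rates = d@rates,
                           variedSubstrate = d@variedSubstrate,
                           cosubstrate = c0 * d@cosubstrate,
                           inhibitor = c0 * d@inhibitor, id = d@id)
    })
    f0 <- coef(fitGlobalInhibition(ds, "mixed"))
    f1 <- coef(fitGlobalInhibition(scaled, "mixed"))
    expect_equal(f1[["kcat"]], f0[["kcat"]], tolerance = 1e-6)
    expect_equal(f1[c("KmA", "KmB", "KiA", "KiB")],
                 c0 * f0[c("KmA", "KmB", "KiA", "KiB")], tolerance = 1e-5)
})

test_that("AIC follows the Gaussian RSS formula", {
    fake <- function(rss, n, p) {
        cf <- data.frame(parameter = letters[seq_len(p)],
                         estimate = 1, se = 1, t = 1, p = 0.5)
        new("FitResult", model = "none", coefficients = cf, rss = rss,
            n = n, p = p, aic = 0, aicc = 0,
            cov = diag(p), flags = character(0), details = list())
    }
    expect_equal(akaike(fake(10, 40, 5), "AIC"), 40 * log(0.25) + 12)
    expect_equal(akaike(fake(10, 40, 5), "AIC"), -43.45, tolerance = 1e-3)
    # halving RSS lowers AIC by n ln 2; a useless extra parameter adds 2
    expect_equal(akaike(fake(5, 40, 5), "AIC"),
                 akaike(fake(10, 40, 5), "AIC") - 40 * log(2))
    expect_equal(akaike(fake(10, 40, 6), "AIC"),
                 akaike(fake(10, 40, 5), "AIC") + 2)
    expect_equal(akaike(fake(10, 40, 5), "AICc"),
                 40 * log(0.25) + 12 + 2 * 6 * 7 / (40 - 7))
    expect_identical(akaike(fake(0, 40, 5), "AIC"), -Inf)
})

test_that("model comparison selects the truth and applies the tie-break", {
    kp <- mixedParams()
    # noisy mixed-generated data: mixed should usually win
    des <- defaultInhibitionDesign(noiseSd = 0.05 * 23.1, seed = 10L)
    mc <- compareModels(generateSteadyState(kp, des))
    expect_identical(selectedModel(mc), "mixed")
    tab <- comparisonTable(mc)
    expect_identical(min(tab$dAICc), 0)
    # noiseless competitive-only data: both nested fits are exact, the
    # simpler model wins by the fewer-parameters tie-break
    kpc <- kineticParameters(23.1, 72, 12, KiA = 249, KiB = Inf)
    mc2 <- compareModels(generateSteadyState(kpc, defaultInhibitionDesign()))
    expect_identical(selectedModel(mc2), "competitive_vs_A")
})

test_that("inference table has the Wald structure", {
    kp <- mixedParams()
    des <- defaultInhibitionDesign(noiseSd = 0.05 * 23.1, seed = 3L)
    fit <- fitGlobalInhibition(generateSteadyState(kp, des), "mixed")
    cf <- parameterInference(fit)
    expect_identical(cf$parameter, c("kcat", "KmA", "KmB", "KiA", "KiB"))
    expect_true(all(cf$se > 0))
    expect_equal(cf$t, cf$estimate / cf$se)
    expect_true(all(cf$p > 0 & cf$p <= 1))
    expect_equal(cf$p, 2 * pt(-abs(cf$t), fit@n - fit@p),
                 tolerance = 1e-12)
    # noiseless limit: SEs collapse and the fit is flagged exact
    fit0 <- fitGlobalInhibition(generateSteadyState(kp, defaultInhibitionDesign()),
                                "mixed")
    expect_true("exact_fit" %in% fitFlags(fit0))
    expect_true(all(parameterInference(fit0)$se < 1e-6))
})
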