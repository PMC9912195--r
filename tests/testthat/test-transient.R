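# Transient analysis: exponential kobs extraction, hyperbolic kobs(S) fits,
# the linear-regime second-order constant, and Beer-Lambert conversions.

makeTrace <- function(kobs = 100, amplitude = -0.3, offset = 0.5,
                      n = 1000, duration = 0.05, noise = 0, seed = 1) {
    tt <- seq(0, duration, length.out = n)
    y <- offset + amplitude * exp(-kobs * tt)
    if (noise > 0) y <- y + withr::with_seed(seed, rnorm(n, sd = noise))
    absorbanceTrace(tt, y)
}

test_that("noiseless exponential traces are recovered exactly", {
    f <- fitExponential(makeTrace())
    expect_equal(coef(f)[["kobs"]], 100, tolerance = 1e-6)
    expect_equal(coef(f)[["amplitude"]], -0.3, tolerance = 1e-6)
    expect_equal(coef(f)[["offset"]], 0.5, tolerance = 1e-6)
    expect_true("exact_fit" %in% fitFlags(f))
    # rises are handled identically to decays, and the offset is immaterial
    fRise <- fitExponential(makeTrace(amplitude = +0.3, offset = 0.1))
    expect_equal(coef(fRise)[["kobs"]], 100, tolerance = 1e-6)
})

test_that("flat traces raise the no-decay error and noisy ones stay accurate", {
    flat <- absorbanceTrace(seq(0, 0.05, length.out = 100),
                            rep(0.4, 100))
    expect_error(fitExponential(flat), "no decay")
    # seeded noise at 0.002 AU over 1000 points: kobs within 2%
    f <- fitExponential(makeTrace(noise = 0.002, seed = 7))
    expect_equal(coef(f)[["kobs"]], 100, tolerance = 0.02)
    expect_true(all(is.finite(parameterInference(f)$se)))
    # a trace that ends long before the decay completes is flagged
    short <- makeTrace(kobs = 10, duration = 0.05)
    expect_true("short_trace" %in% fitFlags(fitExponential(short)))
    # reliability ceiling flags, never corrects
    fc <- fitExponential(makeTrace(), kobsCeiling = 50)
    expect_equal(coef(fc)[["kobs"]], 100, tolerance = 1e-6)
    expect_true(any(grepl("ceiling", fitFlags(fc))))
})

test_that("hyperbolic kobs fits recover the generating constants", {
    for (case in list(list(hp = nadphHyperbola(), S = nadphGrid,
                           extrapolated = FALSE),
                      list(hp = cb1954Hyperbola(), S = cb1954Grid,
                           extrapolated = TRUE),
                      list(hp = menadioneHyperbola(), S = menadioneGrid,
                           extrapolated = TRUE))) {
        kobs <- hyperbolicKobs(case$S, case$hp)
        fit <- fitKobsHyperbola(case$S, kobs)
        expect_equal(coef(fit)[["k"]], case$hp@k, tolerance = 1e-4)
        expect_equal(coef(fit)[["Kd"]], case$hp@Kd, tolerance = 1e-4)
        expect_identical("extrapolated" %in% fitFlags(fit),
                         case$extrapolated)
        # k/Kd is reported with the fit
        expect_equal(fit@details$kOverKd[["estimate"]],
                     case$hp@k / case$hp@Kd, tolerance = 1e-4)
    }
    expect_error(fitKobsHyperbola(c(10, 20), c(1, 2)), "3 distinct")
})

test_that("degenerate and unidentifiable kobs designs are flagged", {
    # saturated everywhere: Kd collapses to the search floor
    fitFlat <- fitKobsHyperbola(c(50, 100, 200, 400), rep(300, 4))
    expect_true("degenerate" %in% fitFlags(fitFlat))
    expect_lt(coef(fitFlat)[["Kd"]], 1e-3)
    # linear regime only: the slope is stable but k and Kd are not separable
    hp <- nadphHyperbola()
    S <- c(2, 4, 6, 8, 10)  # all <= Kd/10
    fitLin <- fitKobsHyperbola(S, hyperbolicKobs(S, hp))
    expect_true(any(grepl("unidentifiable|ill-conditioned|extrapolated",
                          fitFlags(fitLin))))
    expect_equal(fitLin@details$kOverKd[["estimate"]], 4.4,
                 tolerance = 0.05)
})

test_that("second-order limit regression matches the low-S slope", {
    expect_equal(secondOrderLimit(c(5, 10, 20), 0.2 * c(5, 10, 20))$slope,
                 0.200)
    hp <- nadphHyperbola()
    # within the linear regime (S <= Kd/10) the zero-intercept slope agrees
    # with k/Kd to 5%; note the S^2 weighting makes the top of the grid
    # dominate, so a grid pushed right to Kd/10 would sit at the bound
    S <- c(1, 2.5, 5)
    sl <- secondOrderLimit(S, hyperbolicKobs(S, hp))
    expect_equal(sl$slope, 4.4, tolerance = 0.05)
    expect_error(secondOrderLimit(5, 1), "at least 2")
    # coverage of the slope CI under 5% noise; the estimand is the
    # population value of the zero-intercept estimator on this design
    S5 <- c(1, 2, 3, 4, 5)
    mu <- hyperbolicKobs(S5, hp)
    truthSlope <- sum(S5 * mu) / sum(S5^2)
    hits <- 0
    for (r in 1:100) {
        kobs <- withr::with_seed(1000 + r,
                                 mu + rnorm(5, sd = 0.05 * max(mu)))
        est <- secondOrderLimit(S5, kobs)
        ci <- est$slope + c(-1, 1) * qt(0.975, 4) * est$se
        if (ci[1] <= truthSlope && truthSlope <= ci[2]) hits <- hits + 1
    }
    expect_gte(hits, 90)
})

test_that("Beer-Lambert conversions are exact arithmetic", {
    expect_equal(rateFromSlope(0.0043, 4300, 1), 1.0)
    expect_identical(rateFromSlope(0, 4300), 0)
    expect_equal(rateFromSlope(0.0043, 4300, 0.5),
                 2 * rateFromSlope(0.0043, 4300, 1))
    expect_error(rateFromSlope(1, -10), "> 0")

    ec <- extinctionCoefficients()
    expect_equal(proteinConcentration(0.3119, 0, ec), 10.0)
    # flavin-corrected: (0.5216 - 0.122 * 20970/12200) / 31190 * 1e6
    expect_equal(proteinConcentration(0.5216, 0.122, ec), 10.0,
                 tolerance = 1e-4)
    expect_identical(proteinConcentration(0, 0, ec), 0)
    expect_error(proteinConcentration(0.1, 1, ec), "over-corrected")
    expect_error(extinctionCoefficients(bogus = 1), "unknown")
})

test_that("trace construction truncates the dead time", {
    tt <- seq(0, 0.05, length.out = 200)
    tr <- absorbanceTrace(tt, exp(-100 * tt), deadTime = 0.0015)
    expect_gte(tr@time[1], 0.0015)
    expect_lt(length(tr@time), 200)
    expect_error(absorbanceTrace(tt[1:5], rep(1, 5)), "10 samples")
})
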