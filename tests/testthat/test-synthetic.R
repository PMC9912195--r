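# Synthetic-data generators: exactness at sigma = 0, seeded determinism,
# noise calibration, and the canonical designs.

test_that("noiseless steady-state generation equals the rate law exactly", {
    kp <- mixedParams()
    ds <- generateSteadyState(kp, defaultInhibitionDesign())
    for (d in ds) {
        expected <- if (d@variedSubstrate == "A")
            pingpongInhibitedRate(d@conc, d@cosubstrate, d@inhibitor, kp)
        else
            pingpongInhibitedRate(d@cosubstrate, d@conc, d@inhibitor, kp)
        expect_identical(d@rates, expected)
    }
})

test_that("the default inhibition design matches the stated experiment", {
    des <- defaultInhibitionDesign()
    expect_identical(des@kind, "two_sided_inhibition")
    # fixed donor level 100 uM for the acceptor-varied family and 99 uM
    # acceptor for the donor-varied family
    expect_identical(unname(des@cosubstrate["B"]), 99)
    expect_identical(unname(des@cosubstrate["A"]), 100)
    expect_identical(des@inhibitorLevels, c(0, 250, 500))
    expect_true(0 %in% des@inhibitorLevels)
    # 8-point two-fold dilutions from 10x Km
    expect_identical(length(des@grids$A), 8L)
    expect_equal(max(des@grids$A), 720)
    expect_equal(unique(round(des@grids$A[-1] / des@grids$A[-8], 10)), 2)
    # 2 families x 3 inhibitor levels
    expect_identical(length(generateSteadyState(mixedParams(), des)), 6L)
})

test_that("generation is a pure function of the seed", {
    kp <- mixedParams()
    des <- defaultInhibitionDesign(noiseSd = 1, seed = 77L)
    d1 <- generateSteadyState(kp, des)
    d2 <- generateSteadyState(kp, des)
    expect_identical(lapply(d1, function(d) d@rates),
                     lapply(d2, function(d) d@rates))
    # the session RNG is untouched
    set.seed(1); before <- .Random.seed
    invisible(generateSteadyState(kp, des))
    expect_identical(before, .Random.seed)
    # a noisy design without a seed is a configuration error
    expect_error(defaultInhibitionDesign(noiseSd = 1), "seed is mandatory")
    expect_error(generateMichaelis(24, 19, noiseSd = 1), "seed is mandatory")
})

test_that("noise is homoscedastic Gaussian of the stated SD", {
    kp <- mixedParams()
    sigma <- 0.5
    res <- numeric(0)
    for (s in 1:84) {  # 84 x 6 x 8 = 4032 points; pool ~1e4 by replication
        des <- defaultInhibitionDesign(noiseSd = sigma, seed = s,
                                 replicates = 3L)
        clean <- generateSteadyState(kp, defaultInhibitionDesign(replicates = 3L))
        noisy <- generateSteadyState(kp, des)
        res <- c(res, unlist(lapply(names(noisy), function(nm)
            noisy[[nm]]@rates - clean[[nm]]@rates)))
        if (length(res) >= 1e4) break
    }
    expect_gte(length(res), 1e4)
    expect_equal(sd(res), sigma, tolerance = 0.02)
})

test_that("transient generation round-trips through the exponential fit", {
    hp <- nadphHyperbola()
    tr <- generateTransient(hp, S = 200)
    expect_equal(coef(fitExponential(tr))[["kobs"]],
                 hyperbolicKobs(200, hp), tolerance = 1e-6)
    # seeded noise: determinism
    t1 <- generateTransient(hp, S = 200, noiseSd = 0.002, seed = 5L)
    t2 <- generateTransient(hp, S = 200, noiseSd = 0.002, seed = 5L)
    expect_identical(t1@absorbance, t2@absorbance)
    expect_error(generateTransient(hp, S = 200, noiseSd = 0.002),
                 "seed is mandatory")
    # under-sampling and too-short durations are design errors
    expect_error(generateTransient(hp, S = 200, samplingRate = 100),
                 "under-sampled")
    expect_error(generateTransient(hp, S = 200, duration = 0.001),
                 "3/kobs")
    # mechanism-derived trace agrees with the closed form within 5%
    sc <- rapidEquilibriumScheme()
    trOde <- generateTransient(sc, S = 200, E0 = 0.5)
    expect_equal(coef(fitExponential(trOde))[["kobs"]],
                 hyperbolicKobs(200, hyperbolicParameters(440, 100)),
                 tolerance = 0.05)
})

test_that("noiseless generate-then-fit is the identity for every model", {
    kp <- mixedParams()
    ds <- generateSteadyState(kp, defaultInhibitionDesign())
    for (m in c("mixed", "none")) {
        fit <- fitGlobalInhibition(ds, m)
        truth <- c(kcat = 23.1, KmA = 72, KmB = 12, KiA = 249,
                   KiB = 147)[names(coef(fit))]
        if (m == "mixed") expect_lt(relErr(coef(fit), truth), 1e-4)
    }
    d <- generateMichaelis(11.6, 1.3)
    expect_lt(relErr(coef(fitMichaelis(d)), c(11.6, 1.3)), 1e-6)
    S <- nadphGrid
    hf <- fitKobsHyperbola(S, hyperbolicKobs(S, nadphHyperbola()))
    expect_lt(relErr(coef(hf), c(440, 100)), 1e-4)
})
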