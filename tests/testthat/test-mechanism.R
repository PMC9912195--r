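# ODE mechanism simulator: conservation, oracle equivalence against the
# closed-form rate law, macroscopic closed forms, and stopped-flow
# consistency of the reductive half-reaction.

test_that("trajectories conserve every pool and zero enzyme means stasis", {
    sc <- rapidEquilibriumScheme()
    # no catalyst: everything constant
    pc0 <- simulateProgress(sc, speciesState(A = 100, B = 50, I = 25),
                            seq(0, 1, length.out = 11))
    expect_true(all(apply(pc0@concentrations, 2,
                          function(x) max(abs(x - x[1]))) == 0))
    # randomized initial states: enzyme, nicotinamide, acceptor and
    # inhibitor pools all conserved to solver accuracy
    set.seed(3)
    for (i in 1:5) {
        y0 <- speciesState(Eox = runif(1, 0.01, 0.5),
                           A = runif(1, 10, 500), B = runif(1, 10, 500),
                           I = runif(1, 0, 300))
        pc <- simulateProgress(sc, y0, seq(0, 0.02, length.out = 51),
                               rtol = 1e-8)
        drift <- conservationDrift(pc)
        scale <- c(sum(y0[c("Eox", "EoxA", "EoxI", "Ered", "EredP1",
                            "EredB", "EredI", "EoxP2")]),
                   sum(y0[c("A", "P1")]), sum(y0[c("B", "P2")]), y0[["I"]])
        expect_true(all(drift <= pmax(10 * 1e-8 * scale, 1e-10)))
    }
})

test_that("derive_macroscopic reproduces the lumped closed forms", {
    # symmetric chemistry: kcat is half of either step
    sym <- mechanismScheme(konA = 10, koffA = 1000, kRed = 800,
                           konB = 10, koffB = 1000, kOx = 800,
                           koffP1 = 8e5, koffP2 = 8e5)
    kp <- deriveMacroscopic(sym)
    expect_equal(kp@kcat, 400)
    expect_equal(kp@KmA, (800 / 1600) * (1800 / 10))  # 90
    expect_equal(kp@KmB, 90)
    expect_identical(kp@KiA, Inf)
    # Ki is the dissociation constant of the dead-end complex by definition
    withI <- mechanismScheme(konA = 10, koffA = 1000, kRed = 800,
                             konB = 10, koffB = 1000, kOx = 800,
                             koffP1 = 8e5, koffP2 = 8e5,
                             konIox = 10, koffIox = 2490,
                             konIred = 5, koffIred = 735)
    kpI <- deriveMacroscopic(withI)
    expect_equal(kpI@KiA, 249)
    expect_equal(kpI@KiB, 147)
    # slow product release voids the closed forms and is flagged
    slow <- mechanismScheme(konA = 10, koffA = 1000, kRed = 800,
                            konB = 10, koffB = 1000, kOx = 800,
                            koffP1 = 1000, koffP2 = 8e5)
    expect_identical(attr(deriveMacroscopic(slow), "flag"),
                     "outside_fast_release")
})

test_that("numerical initial rates agree with the rate law (oracle check)", {
    sc <- rapidEquilibriumScheme()
    kp <- deriveMacroscopic(sc)
    expect_null(attr(kp, "flag"))
    expect_identical(numericalInitialRate(sc, 0, 100), 0)
    # spot grid including inhibitor: 1% oracle equivalence
    for (A in c(10, 100)) for (B in c(40, 400)) for (I in c(0, 250)) {
        v <- numericalInitialRate(sc, A, B, I)
        expect_equal(v, pingpongInhibitedRate(A, B, I, kp),
                     tolerance = 0.01)
    }
    # first order in enzyme: doubling E0 leaves v/E unchanged within 0.5%
    v1 <- numericalInitialRate(sc, 100, 100, E0 = 0.002)
    v2 <- numericalInitialRate(sc, 100, 100, E0 = 0.004)
    expect_equal(v2, v1, tolerance = 0.005)
    expect_error(numericalInitialRate(sc, 100, 100, E0 = 50),
                 "catalytic conditions")
})

test_that("uninhibited ODE rates over a grid refit the ping-pong form", {
    sc <- rapidEquilibriumScheme()
    kp <- deriveMacroscopic(sc)
    grid <- expand.grid(A = kp@KmA * c(0.2, 1, 5),
                        B = kp@KmB * c(0.2, 1, 5))
    v <- mapply(function(a, b) numericalInitialRate(sc, a, b),
                grid$A, grid$B)
    ds <- list(
        steadyStateDataset(conc = kp@KmA * c(0.2, 1, 5),
                           rates = v[grid$B == kp@KmB],
                           variedSubstrate = "A", cosubstrate = kp@KmB),
        steadyStateDataset(conc = kp@KmB * c(0.2, 1, 5),
                           rates = v[grid$A == kp@KmA],
                           variedSubstrate = "B", cosubstrate = kp@KmA))
    fit <- fitGlobalInhibition(ds, "none")
    pred <- pingpongRate(grid$A, grid$B, kineticParametersFromFit(fit))
    r2 <- 1 - sum((v - pred)^2) / sum((v - mean(v))^2)
    expect_gt(r2, 0.999)
})

test_that("reductive half-reaction behaves as a pseudo-first-order decay", {
    sc <- rapidEquilibriumScheme()
    # E0 = 0: flat observable
    pc0 <- simulateReductiveHalf(sc, E0 = 0, S = 100,
                                 tGrid = seq(0, 0.02, length.out = 101))
    expect_true(all(oxidizedEnzyme(pc0) == 0))
    # at S = Kd the fitted kobs is kRed/2 within 5%
    tr <- generateTransient(sc, S = 100, E0 = 0.5)
    expect_equal(coef(fitExponential(tr))[["kobs"]], 440 / 2,
                 tolerance = 0.05)
    # kobs(S) across the titration refits the hyperbola: k and Kd within 5%
    S <- nadphGrid
    kobs <- vapply(S, function(s) {
        coef(fitExponential(generateTransient(sc, S = s, E0 = 0.5)))[["kobs"]]
    }, numeric(1))
    hf <- fitKobsHyperbola(S, kobs)
    expect_equal(coef(hf)[["k"]], 440, tolerance = 0.05)
    expect_equal(coef(hf)[["Kd"]], 100, tolerance = 0.05)
    expect_warning(simulateReductiveHalf(sc, E0 = 5, S = 20),
                   "pseudo-first-order")
})
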