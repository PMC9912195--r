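# Closed-form rate laws: exact values by direct substitution, limits, and
# algebraic properties under randomized inputs.

test_that("uninhibited ping-pong rate matches direct substitution and limits", {
    kp <- mixedParams()
    # 23.1 * 72 * 12 / (72*12 + 12*72 + 72*12) = 23.1 * 864 / 2592
    expect_equal(pingpongRate(72, 12, kp), 23.1 * 864 / 2592)
    expect_equal(pingpongRate(72, 12, kp), 7.70, tolerance = 1e-3)
    # saturation limit approaches kcat
    expect_equal(pingpongRate(1e9, 1e9, kp), 23.1, tolerance = 1e-4)
    # no donor (or acceptor) means no turnover, including the 0/0 corner
    expect_identical(pingpongRate(0, 50, kp), 0)
    expect_identical(pingpongRate(50, 0, kp), 0)
    expect_identical(pingpongRate(0, 0, kp), 0)
    expect_error(pingpongRate(-1, 5, kp), "must be finite and >= 0")
})

test_that("inhibited rate matches substitution and reduces exactly at I = 0", {
    kp <- mixedParams()
    # denominator: 72*12*(1+249/249) + 12*72*(1+249/147) + 72*12
    den <- 72 * 12 * (1 + 249 / 249) + 12 * 72 * (1 + 249 / 147) + 72 * 12
    expect_equal(pingpongInhibitedRate(72, 12, 249, kp), 23.1 * 864 / den)
    expect_equal(pingpongInhibitedRate(72, 12, 249, kp), 4.06,
                 tolerance = 1e-3)
    # reduction property over randomized parameter sets and concentrations
    set.seed(11)
    for (i in 1:25) {
        p <- kineticParameters(runif(1, 1, 100), runif(1, 1, 500),
                               runif(1, 1, 500), runif(1, 10, 1000),
                               runif(1, 10, 1000))
        A <- runif(1, 0, 1000); B <- runif(1, 0, 1000)
        expect_identical(pingpongInhibitedRate(A, B, 0, p),
                         pingpongRate(A, B, p))
    }
    # infinite inhibitor with a finite Ki abolishes turnover
    expect_equal(pingpongInhibitedRate(72, 12, 1e12, kp), 0,
                 tolerance = 1e-6)
})

test_that("rate law is monotone in substrates and inhibitor", {
    set.seed(7)
    for (i in 1:20) {
        p <- kineticParameters(runif(1, 1, 100), runif(1, 1, 500),
                               runif(1, 1, 500), runif(1, 10, 1000),
                               runif(1, 10, 1000))
        A <- sort(runif(5, 0, 2000)); B <- runif(1, 1, 2000)
        I <- sort(runif(5, 0, 2000))
        # non-decreasing in A (and by symmetry B), non-increasing in I
        expect_true(all(diff(pingpongInhibitedRate(A, B, I[1], p)) >= 0))
        expect_true(all(diff(pingpongInhibitedRate(B, A, I[1], p)) >= 0))
        expect_true(all(diff(pingpongInhibitedRate(A[3], B, I, p)) <= 0))
        # saturation limit is kcat regardless of inhibitor
        expect_equal(pingpongInhibitedRate(1e10, 1e10, I[5], p), p@kcat,
                     tolerance = 1e-5)
    }
})

test_that("model tag must match the finiteness pattern of the parameters", {
    kp <- mixedParams()
    expect_identical(inhibitionModel(kp), "mixed")
    expect_identical(inhibitionModel(kineticParameters(1, 1, 1)), "none")
    expect_identical(inhibitionModel(kineticParameters(1, 1, 1, KiA = 5)),
                     "competitive_vs_A")
    expect_silent(pingpongInhibitedRate(1, 1, 1, kp, model = "mixed"))
    expect_error(pingpongInhibitedRate(1, 1, 1, kp,
                                       model = "competitive_vs_A"),
                 "encode model")
})

test_that("hyperbolic kobs has the half-saturation point and upper bound", {
    hp <- nadphHyperbola()
    expect_equal(hyperbolicKobs(100, hp), 220)           # S = Kd -> k/2
    expect_equal(hyperbolicKobs(500, hp), 440 * 500 / 600)  # 366.67
    expect_identical(hyperbolicKobs(0, hp), 0)
    S <- 10^seq(-2, 5, length.out = 40)
    expect_true(all(hyperbolicKobs(S, hp) < hp@k))
    expect_error(hyperbolicKobs(-5, hp), ">= 0")
})

test_that("Michaelis-Menten rate and specificity constant", {
    expect_equal(mmRate(19, 24, 19), 12)
    expect_equal(mmRate(100, 24, 19), 24 * 100 / 119)
    expect_equal(mmRate(1e9, 24, 19), 24, tolerance = 1e-6)
    expect_error(mmRate(5, -1, 19), "> 0")
    expect_identical(specificityConstant(1, 1), 1)
    expect_equal(specificityConstant(24, 19), 24 / 19)     # ~1.263
    expect_equal(specificityConstant(20, 700), 20 / 700)   # ~0.0286
    expect_error(specificityConstant(0, 1), "> 0")
})
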