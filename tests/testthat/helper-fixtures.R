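# Shared fixtures: the canonical parameter sets of the nitroreductase
# system, constructed in code (no data files).

# global mixed-inhibition constants (donor = NADPH, acceptor = nitrofurazone,
# inhibitor = NADP+)
mixedParams <- function() kineticParameters(kcat = 23.1, KmA = 72, KmB = 12,
                                           KiA = 249, KiB = 147)

# stopped-flow half-reaction constants
nadphHyperbola <- function() hyperbolicParameters(k = 440, Kd = 100)
cb1954Hyperbola <- function() hyperbolicParameters(k = 330, Kd = 660)
menadioneHyperbola <- function() hyperbolicParameters(k = 480, Kd = 330)

# stopped-flow substrate grids (uM)
nadphGrid <- c(25, 50, 100, 200, 350, 500)
cb1954Grid <- c(50, 100, 200, 300, 400, 500)
menadioneGrid <- c(25, 50, 75, 100)

# Michaelis rows of the coenzyme-comparison table: kcat (1/s), Km (uM)
michaelisRows <- list(
    NADPH_NFZ = c(kcat = 24, Km = 19),
    NADH_NFZ = c(kcat = 20, Km = 700),
    NADPH_CB1954 = c(kcat = 11.6, Km = 1.3),
    NADH_CB1954 = c(kcat = 9.6, Km = 64))

relErr <- function(x, ref) max(abs(x / ref - 1))
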