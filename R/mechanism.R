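# Mass-action ODE simulation of the substituted-enzyme (ping-pong) mechanism:
# the engine behind the synthetic stopped-flow traces and the brute-force
# oracle for the closed-form rate laws.  Reaction networks are compiled to a
# sparse representation integrated in C++ (adaptive Cash-Karp 4(5)).

# reactions: list of list(from = character reactants (1 or 2),
#                         to = character products, k = rate constant)
.compileNetwork <- function(species, reactions) {
    idx <- function(nm) match(nm, species) - 1L
    nR <- length(reactions)
    react1 <- integer(nR); react2 <- integer(nR); k <- numeric(nR)
    ptr <- integer(nR + 1L); sidx <- integer(0); scoef <- numeric(0)
    for (j in seq_len(nR)) {
        rx <- reactions[[j]]
        from <- rx$from; to <- rx$to
        stopifnot(length(from) >= 1, length(from) <= 2,
                  all(c(from, to) %in% species))
        react1[j] <- idx(from[1])
        react2[j] <- if (length(from) == 2) idx(from[2]) else -1L
        k[j] <- rx$k
        net <- table(factor(to, levels = species)) -
            table(factor(from, levels = species))
        nz <- which(net != 0)
        ptr[j + 1L] <- ptr[j] + length(nz)
        sidx <- c(sidx, nz - 1L)
        scoef <- c(scoef, as.numeric(net[nz]))
    }
    list(species = species, react1 = react1, react2 = react2, k = k,
         ptr = ptr, idx = as.integer(sidx), coef = scoef)
}

.monomerReactions <- function(scheme) {
    r <- scheme@rates
    list(
        list(from = c("Eox", "A"),  to = "EoxA",          k = r[["konA"]]),
        list(from = "EoxA",         to = c("Eox", "A"),   k = r[["koffA"]]),
        list(from = "EoxA",         to = "EredP1",        k = r[["kRed"]]),
        list(from = "EredP1",       to = c("Ered", "P1"), k = r[["koffP1"]]),
        list(from = c("Ered", "P1"), to = "EredP1",       k = r[["konP1"]]),
        list(from = c("Ered", "B"), to = "EredB",         k = r[["konB"]]),
        list(from = "EredB",        to = c("Ered", "B"),  k = r[["koffB"]]),
        list(from = "EredB",        to = "EoxP2",         k = r[["kOx"]]),
        list(from = "EoxP2",        to = c("Eox", "P2"),  k = r[["koffP2"]]),
        list(from = c("Eox", "P2"), to = "EoxP2",         k = r[["konP2"]]),
        list(from = c("Eox", "I"),  to = "EoxI",          k = r[["konIox"]]),
        list(from = "EoxI",         to = c("Eox", "I"),   k = r[["koffIox"]]),
        list(from = c("Ered", "I"), to = "EredI",         k = r[["konIred"]]),
        list(from = "EredI",        to = c("Ered", "I"),  k = r[["koffIred"]]))
}

.enzymeForms <- c("Eox", "EoxA", "EoxI", "Ered", "EredP1", "EredB", "EredI",
                  "EoxP2")

.monomerPools <- function() {
    pool <- function(members) setNames(rep(1, length(members)), members)
    list(enzyme = pool(.enzymeForms),
         nicotinamide = pool(c("A", "P1", "EoxA", "EredP1")),
         acceptor = pool(c("B", "P2", "EredB", "EoxP2")),
         inhibitor = pool(c("I", "EoxI", "EredI")))
}

#' Initial species state for the monomer mechanism
#'
#' Named concentration vector over the 13 species of the mechanism, all
#' defaulting to 0.  \code{Eox} etc. are enzyme forms; \code{A}, \code{P1},
#' \code{B}, \code{P2}, \code{I} the free ligands.
#'
#' @param ... named concentrations in uM, e.g. \code{Eox = 0.1, A = 100}
#' @return named numeric over the mechanism species
#' @export
speciesState <- function(...) {
    y <- setNames(numeric(length(.mechSpecies)), .mechSpecies)
    args <- c(...)
    if (length(args)) {
        bad <- setdiff(names(args), .mechSpecies)
        if (length(bad))
            stop("unknown species: ", paste(bad, collapse = ", "),
                 call. = FALSE)
        if (any(args < 0)) stop("concentrations must be >= 0", call. = FALSE)
        y[names(args)] <- args
    }
    y
}

.runNetwork <- function(net, y0, tGrid, rtol, atol, pools,
                        maxSteps = 5e7) {
    m <- massActionIntegrate(unname(y0), tGrid, net$react1, net$react2,
                             net$k, net$ptr, net$idx, net$coef,
                             rtol, atol, maxSteps)
    colnames(m) <- net$species
    new("ProgressCurve", time = tGrid, concentrations = m, pools = pools)
}

#' Simulate a progress curve of the monomer mechanism
#'
#' Integrates the mass-action ODEs of the substituted-enzyme scheme on a
#' user-supplied time grid.  Linear conserved quantities (total enzyme,
#' nicotinamide, acceptor and inhibitor pools) are preserved to solver
#' accuracy because Runge-Kutta steps conserve them exactly and the solver
#' lands on every output time.
#'
#' @param scheme a [MechanismScheme-class]
#' @param initial named initial state from [speciesState()]
#' @param tGrid strictly increasing times, s (first element is the initial
#'   time)
#' @param rtol relative tolerance (default 1e-8)
#' @param atol absolute tolerance, uM; defaults to \code{rtol * 1e-3 *}
#'   largest initial concentration (floor 1e-12)
#' @return a [ProgressCurve-class]
#' @examples
#' sc <- rapidEquilibriumScheme()
#' pc <- simulateProgress(sc, speciesState(Eox = 0.1, A = 100, B = 100),
#'                        seq(0, 0.05, length.out = 101))
#' @export
setMethod("simulateProgress", "MechanismScheme",
    function(scheme, initial, tGrid, rtol = 1e-8, atol = NULL) {
        stopifnot(identical(names(initial), .mechSpecies),
                  all(initial >= 0), all(is.finite(initial)))
        if (is.null(atol)) atol <- max(rtol * 1e-3 * max(initial, 1e-6), 1e-12)
        net <- .compileNetwork(.mechSpecies, .monomerReactions(scheme))
        .runNetwork(net, initial, tGrid, rtol, atol, .monomerPools())
    })

#' Audit conservation of a progress curve
#'
#' Evaluates every conserved pool of the generating scheme along the
#' trajectory and reports its maximum absolute drift from the initial value.
#'
#' @param pc a [ProgressCurve-class]
#' @return named numeric of maximum absolute drifts (same units as
#'   concentrations)
#' @export
conservationDrift <- function(pc) {
    stopifnot(is(pc, "ProgressCurve"))
    vapply(pc@pools, function(w) {
        tot <- as.numeric(pc@concentrations[, names(w), drop = FALSE] %*% w)
        max(abs(tot - tot[1]))
    }, numeric(1))
}

#' Species trajectory accessor
#' @param pc a [ProgressCurve-class]
#' @param species species name(s); summed if several
#' @return numeric vector over the time grid
#' @export
speciesConc <- function(pc, species) {
    stopifnot(is(pc, "ProgressCurve"),
              all(species %in% colnames(pc@concentrations)))
    rowSums(pc@concentrations[, species, drop = FALSE])
}

# Effective chemistry timescale of a scheme (harmonic mean of the two
# chemical steps), used to size pre-steady-state windows.
.chemistryRate <- function(scheme) {
    r <- scheme@rates
    if (r[["kRed"]] <= 0 || r[["kOx"]] <= 0) return(NA_real_)
    1 / (1 / r[["kRed"]] + 1 / r[["kOx"]])
}

# Shared initial-rate extraction: simulate, discard the pre-steady-state
# burst, and take the slope of total P2 formation over the earliest window in
# which the instantaneous rate varies by < 2%, stopping before 5% depletion
# of the limiting substrate pool.
.initialRateCore <- function(simulate, productOf, remaining,
                             tPre, tDep, E0) {
    tEnd <- tPre + tDep
    tGrid <- c(seq(0, tPre, length.out = 41L),
               seq(tPre, tEnd, length.out = 241L)[-1])
    pc <- simulate(tGrid)
    p2 <- productOf(pc)
    tt <- pc@time
    post <- which(tt >= tPre)
    # stop at 5% depletion of the limiting substrate (free + enzyme-bound)
    dep <- rep(FALSE, length(tt))
    for (tot in remaining(pc))
        if (tot[1] > 0) dep <- dep | (tot < 0.95 * tot[1])
    lastOK <- if (any(dep)) which(dep)[1] - 1L else length(tt)
    win0 <- post[post <= lastOK]
    if (length(win0) < 8L)
        stop("no linear window: substrate depleted before steady state",
             call. = FALSE)
    # earliest (shortest) qualifying window first: depletion across the
    # window biases the average slope low, so shorter is more faithful
    for (frac in c(0.125, 0.25, 0.5, 1)) {
        win <- win0[seq_len(max(8L, ceiling(length(win0) * frac)))]
        if (length(win) > length(win0)) next
        half <- length(win) %/% 2
        s1 <- coef(lm(p2[win[1:half]] ~ tt[win[1:half]]))[2]
        s2 <- coef(lm(p2[win[(half + 1):length(win)]] ~
                          tt[win[(half + 1):length(win)]]))[2]
        if (!is.finite(s1) || !is.finite(s2)) next
        ref <- max(abs(s1), abs(s2))
        if (ref == 0) return(0)
        if (abs(s1 - s2) / ref < 0.02) {
            slope <- coef(lm(p2[win] ~ tt[win]))[2]
            return(unname(slope) / E0)
        }
    }
    stop("no linear window found: instantaneous rate varies by > 2%",
         call. = FALSE)
}

#' Numerical initial rate from the ODE mechanism
#'
#' Brute-force oracle for the steady-state rate law: simulates the mechanism
#' from free enzyme plus substrates (and optionally inhibitor), waits out the
#' pre-steady-state burst (10 effective chemical turnover times), and returns
#' the slope of product (P2) formation per enzyme over the first window where
#' the instantaneous rate is constant to within 2%, before 5% depletion of
#' the limiting substrate.
#'
#' @param scheme a [MechanismScheme-class]
#' @param A0,B0,I0 initial free donor / acceptor / inhibitor, uM
#' @param E0 total enzyme, uM; catalytic conditions are enforced
#'   (\code{E0 <= 0.01 * min(A0, B0)})
#' @param rtol relative solver tolerance
#' @param ... unused
#' @return rate per enzyme, 1/s
#' @export
setMethod("numericalInitialRate", "MechanismScheme",
    function(scheme, A0, B0, I0 = 0, E0 = NULL, rtol = 1e-8, ...) {
        .checkConc(A0, "A0"); .checkConc(B0, "B0"); .checkConc(I0, "I0")
        if (A0 == 0 || B0 == 0) return(0)
        # small enough that substrate consumed during the pre-steady-state
        # wait (~10 E0) biases the rate by < 0.2%
        if (is.null(E0)) E0 <- 1e-4 * min(A0, B0)
        if (E0 <= 0) stop("E0 must be > 0", call. = FALSE)
        if (E0 > 0.01 * min(A0, B0))
            stop("catalytic conditions require E0 <= 0.01 * min(A0, B0)",
                 call. = FALSE)
        kchem <- .chemistryRate(scheme)
        if (!is.finite(kchem))
            stop("scheme has no complete catalytic cycle (kRed or kOx is 0)",
                 call. = FALSE)
        # pre-steady-state relaxation slows down at subsaturating substrate
        r <- scheme@rates
        fA <- A0 / (A0 + r[["koffA"]] / max(r[["konA"]], 1e-12))
        fB <- B0 / (B0 + r[["koffB"]] / max(r[["konB"]], 1e-12))
        kEff <- 1 / (1 / (r[["kRed"]] * fA) + 1 / (r[["kOx"]] * fB))
        tPre <- 10 / kEff
        # measurement span: enough for a robust slope, capped well before 5%
        # depletion so the window average stays an *initial* rate
        tDep <- min(2 * tPre, 0.002 * min(A0, B0) / (kchem * E0))
        net <- .compileNetwork(.mechSpecies, .monomerReactions(scheme))
        y0 <- speciesState(Eox = E0, A = A0, B = B0, I = I0)
        atol <- max(rtol * 1e-3 * max(y0), 1e-12)
        .initialRateCore(
            simulate = function(tg) .runNetwork(net, y0, tg, rtol, atol,
                                                .monomerPools()),
            productOf = function(pc) speciesConc(pc, c("P2", "EoxP2")),
            remaining = function(pc)
                list(speciesConc(pc, c("A", "EoxA")),
                     speciesConc(pc, c("B", "EredB"))),
            tPre = tPre, tDep = tDep, E0 = E0)
    })

#' Macroscopic constants implied by a microscopic scheme
#'
#' Closed forms for the irreversible ping-pong cycle with fast product
#' release:
#' \deqn{k_{cat} = \frac{k_{red} k_{ox}}{k_{red} + k_{ox}}, \quad
#'  K_{mA} = \frac{k_{ox}}{k_{red}+k_{ox}} \frac{k_{off,A}+k_{red}}{k_{on,A}},
#'  \quad
#'  K_{mB} = \frac{k_{red}}{k_{red}+k_{ox}} \frac{k_{off,B}+k_{ox}}{k_{on,B}}}
#' and \eqn{K_{iA} = k_{off,I}^{ox}/k_{on,I}^{ox}} (dead-end binding to the
#' oxidized enzyme, which inflates the \eqn{K_{mA} B} term),
#' \eqn{K_{iB} = k_{off,I}^{red}/k_{on,I}^{red}}.  These hold when product
#' release is much faster than chemistry; if either \code{koffP} is below
#' 100x the chemical steps the result carries the flag attribute
#' \code{"outside_fast_release"} (the true kcat is then depressed by slow
#' release).
#'
#' @param scheme a [MechanismScheme-class]
#' @return a [KineticParameters-class]; attribute \code{"flag"} is set when
#'   the fast-release assumption is violated
#' @export
deriveMacroscopic <- function(scheme) {
    stopifnot(is(scheme, "MechanismScheme"))
    r <- scheme@rates
    if (r[["kRed"]] <= 0 || r[["kOx"]] <= 0 || r[["konA"]] <= 0 ||
        r[["konB"]] <= 0)
        stop("scheme must have a complete catalytic cycle", call. = FALSE)
    ksum <- r[["kRed"]] + r[["kOx"]]
    kp <- kineticParameters(
        kcat = r[["kRed"]] * r[["kOx"]] / ksum,
        KmA = (r[["kOx"]] / ksum) * (r[["koffA"]] + r[["kRed"]]) / r[["konA"]],
        KmB = (r[["kRed"]] / ksum) * (r[["koffB"]] + r[["kOx"]]) / r[["konB"]],
        KiA = if (r[["konIox"]] > 0) r[["koffIox"]] / r[["konIox"]] else Inf,
        KiB = if (r[["konIred"]] > 0) r[["koffIred"]] / r[["konIred"]] else Inf)
    fast <- 100 * max(r[["kRed"]], r[["kOx"]])
    if (r[["koffP1"]] < fast || r[["koffP2"]] < fast)
        attr(kp, "flag") <- "outside_fast_release"
    kp
}

#' Simulate the reductive half-reaction (stopped-flow push)
#'
#' Mixes oxidized enzyme with the donor only (no acceptor), emulating a
#' stopped-flow experiment monitoring disappearance of the oxidized flavin.
#' Under pseudo-first-order conditions (\code{S >= 10 * E0}) the oxidized
#' enzyme pool decays as a single exponential with
#' \eqn{k_{obs} = k_{red} S/(K_d + S)}.
#'
#' @param scheme a [MechanismScheme-class]
#' @param E0 enzyme concentration, uM
#' @param S donor concentration, uM
#' @param tGrid optional time grid, s; defaults to 8 expected lifetimes
#'   sampled at 1000 points
#' @param rtol relative solver tolerance
#' @return a [ProgressCurve-class]
#' @export
simulateReductiveHalf <- function(scheme, E0, S, tGrid = NULL, rtol = 1e-8) {
    stopifnot(is(scheme, "MechanismScheme"))
    .checkConc(E0, "E0"); .checkConc(S, "S")
    if (E0 > 0 && S < 10 * E0)
        warning("S < 10 * E0: pseudo-first-order approximation is unreliable",
                call. = FALSE)
    r <- scheme@rates
    if (is.null(tGrid)) {
        Kd <- r[["koffA"]] / max(r[["konA"]], 1e-12)
        kobs <- r[["kRed"]] * S / (Kd + S)
        if (!is.finite(kobs) || kobs <= 0)
            stop("cannot size a default time grid: expected kobs is 0",
                 call. = FALSE)
        tGrid <- seq(0, 8 / kobs, length.out = 1000L)
    }
    y0 <- speciesState(Eox = E0, A = S)
    net <- .compileNetwork(.mechSpecies, .monomerReactions(scheme))
    atol <- max(rtol * 1e-3 * max(y0, 1e-6), 1e-12)
    .runNetwork(net, y0, tGrid, rtol, atol, .monomerPools())
}

#' Total oxidized enzyme along a monomer progress curve
#'
#' The stopped-flow observable of the reductive half-reaction: the sum of all
#' oxidized enzyme forms.
#'
#' @param pc a [ProgressCurve-class] over the monomer species
#' @return numeric vector, uM
#' @export
oxidizedEnzyme <- function(pc) {
    speciesConc(pc, c("Eox", "EoxA", "EoxI", "EoxP2"))
}

#' Reference microscopic scheme in the rapid-equilibrium, fast-release regime
#'
#' A constructed parameterization (the underlying experiments constrain only
#' macroscopic constants): chemistry set to the stopped-flow limiting rates,
#' donor binding with the stopped-flow dissociation constant, binding steps
#' \code{bindingFactor}-fold and product release \code{releaseFactor}-fold
#' faster than chemistry so that [deriveMacroscopic()] closed forms apply,
#' and dead-end inhibitor binding with the steady-state inhibition constants.
#'
#' @param kRed hydride-transfer rate, 1/s (default 440, NADPH reduction)
#' @param KdA donor dissociation constant, uM (default 100)
#' @param kOx flavin reoxidation rate, 1/s (default 330, CB1954-like)
#' @param KdB acceptor dissociation constant, uM (default 660)
#' @param KiOx,KiRed dead-end inhibitor Kd at the oxidized / reduced enzyme,
#'   uM (defaults 249 / 147)
#' @param bindingFactor substrate off-rates as a multiple of the adjacent
#'   chemical step (default 100)
#' @param releaseFactor product release rates as a multiple of the fastest
#'   chemical step (default 1000; at 100x the lumped kcat would already be
#'   ~1\% off)
#' @return a [MechanismScheme-class]
#' @export
rapidEquilibriumScheme <- function(kRed = 440, KdA = 100, kOx = 330,
                                   KdB = 660, KiOx = 249, KiRed = 147,
                                   bindingFactor = 100,
                                   releaseFactor = 1000) {
    koffA <- bindingFactor * kRed
    koffB <- bindingFactor * kOx
    koffP <- releaseFactor * max(kRed, kOx)
    mechanismScheme(
        konA = koffA / KdA, koffA = koffA, kRed = kRed,
        koffP1 = koffP, konP1 = 0,
        konB = koffB / KdB, koffB = koffB, kOx = kOx,
        koffP2 = koffP, konP2 = 0,
        konIox = 10, koffIox = 10 * KiOx,
        konIred = 10, koffIred = 10 * KiRed)
}
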