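# Half-of-sites (alternating-sites) dimer variant: two copies of the monomer
# cycle coupled through cofactor binding.  The structural observation behind
# it is a homodimer in which only one site at a time holds a nicotinamide
# cofactor; kinetically this is encoded as a penalty factor alpha on the
# donor on-rate at a site whose partner site is already occupied.

# Forms whose site is considered occupied by a nicotinamide ligand (cofactor
# A, its oxidized product P1, or the dead-end inhibitor, itself NADP(H)-like).
.occupiedForms <- c("EoxA", "EredP1", "EoxI", "EredI")

.dimerSpecies <- function() {
    forms <- .enzymeForms
    c(as.vector(outer(forms, forms,
                      function(a, b) paste0("D.", a, ".", b))),
      c("A", "P1", "B", "P2", "I"))
}

# split a monomer reaction into its enzyme-form and free-ligand parts
.splitReaction <- function(rx) {
    list(eFrom = intersect(rx$from, .enzymeForms),
         lFrom = setdiff(rx$from, .enzymeForms),
         eTo = intersect(rx$to, .enzymeForms),
         lTo = setdiff(rx$to, .enzymeForms),
         k = rx$k)
}

.dimerReactions <- function(scheme, alpha, couple) {
    parts <- lapply(.monomerReactions(scheme), .splitReaction)
    forms <- .enzymeForms
    out <- vector("list", 0L)
    for (f1 in forms) for (f2 in forms) {
        state <- paste0("D.", f1, ".", f2)
        for (site in 1:2) {
            own <- if (site == 1) f1 else f2
            partner <- if (site == 1) f2 else f1
            for (pp in parts) {
                if (pp$k == 0 || pp$eFrom != own) next
                k <- pp$k
                isBindA <- identical(pp$lFrom, "A") &&
                    identical(pp$eTo, "EoxA")
                isUnbindA <- identical(pp$eFrom, "EoxA") &&
                    identical(pp$lTo, "A")
                if (partner %in% .occupiedForms) {
                    if (couple == "on" && isBindA) k <- k * alpha
                    if (couple == "off" && isUnbindA) k <- k / alpha
                }
                newState <- if (site == 1) paste0("D.", pp$eTo, ".", f2)
                            else paste0("D.", f1, ".", pp$eTo)
                out[[length(out) + 1L]] <-
                    list(from = c(state, pp$lFrom), to = c(newState, pp$lTo),
                         k = k)
            }
        }
    }
    out
}

.dimerPools <- function() {
    forms <- .enzymeForms
    states <- as.vector(outer(forms, forms,
                              function(a, b) paste0("D.", a, ".", b)))
    countSites <- function(members) {
        w <- vapply(states, function(s) {
            ff <- strsplit(s, ".", fixed = TRUE)[[1]][2:3]
            sum(ff %in% members)
        }, numeric(1))
        w[w > 0]
    }
    nico <- countSites(c("EoxA", "EredP1"))
    acc <- countSites(c("EredB", "EoxP2"))
    inh <- countSites(c("EoxI", "EredI"))
    list(enzyme = setNames(rep(1, length(states)), states),
         nicotinamide = c(setNames(c(1, 1), c("A", "P1")), nico),
         acceptor = c(setNames(c(1, 1), c("B", "P2")), acc),
         inhibitor = c(setNames(1, "I"), inh))
}

#' Build a half-of-sites dimer scheme
#'
#' @param base per-site [MechanismScheme-class]
#' @param alpha coupling factor in (0, 1]; the donor on-rate at a site is
#'   multiplied by \code{alpha} while the partner site holds a nicotinamide
#'   ligand.  \code{alpha = 1} gives two independent sites.
#' @param couple \code{"on"} (default; scale the on-rate) or \code{"off"}
#'   (scale the off-rate by \code{1/alpha}: same binding equilibrium,
#'   different kinetics)
#' @return a [HalfOfSitesScheme-class]
#' @export
buildHalfOfSitesScheme <- function(base, alpha, couple = c("on", "off")) {
    stopifnot(is(base, "MechanismScheme"))
    couple <- match.arg(couple)
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha <= 0 || alpha > 1)
        stop("alpha must be a single value in (0, 1]", call. = FALSE)
    new("HalfOfSitesScheme", base = base, alpha = alpha, couple = couple)
}

#' Initial species state for the dimer mechanism
#'
#' @param Edimer total dimer concentration (all enzyme starts as the doubly
#'   free oxidized dimer), uM
#' @param A,P1,B,P2,I free ligand concentrations, uM
#' @return named numeric over the dimer species
#' @export
dimerState <- function(Edimer = 0, A = 0, P1 = 0, B = 0, P2 = 0, I = 0) {
    sp <- .dimerSpecies()
    y <- setNames(numeric(length(sp)), sp)
    y["D.Eox.Eox"] <- Edimer
    y[c("A", "P1", "B", "P2", "I")] <- c(A, P1, B, P2, I)
    if (any(y < 0)) stop("concentrations must be >= 0", call. = FALSE)
    y
}

#' @describeIn buildHalfOfSitesScheme simulate a dimer progress curve on a
#'   time grid (same contract as the monomer method of
#'   [simulateProgress()]).
#' @param scheme a [HalfOfSitesScheme-class]
#' @param initial named state from [dimerState()]
#' @param tGrid strictly increasing times, s
#' @param rtol,atol solver tolerances
#' @export
setMethod("simulateProgress", "HalfOfSitesScheme",
    function(scheme, initial, tGrid, rtol = 1e-8, atol = NULL) {
        sp <- .dimerSpecies()
        stopifnot(identical(names(initial), sp), all(initial >= 0))
        if (is.null(atol)) atol <- max(rtol * 1e-3 * max(initial, 1e-6), 1e-12)
        net <- .compileNetwork(sp, .dimerReactions(scheme@base, scheme@alpha,
                                                   scheme@couple))
        .runNetwork(net, initial, tGrid, rtol, atol, .dimerPools())
    })

#' Sites per dimer currently in given forms
#'
#' @param pc a dimer [ProgressCurve-class]
#' @param forms monomer enzyme form names to count
#' @return numeric vector over the time grid: concentration-weighted site
#'   count, uM of sites
#' @export
dimerSiteConc <- function(pc, forms) {
    stopifnot(is(pc, "ProgressCurve"))
    states <- grep("^D\\.", colnames(pc@concentrations), value = TRUE)
    w <- vapply(states, function(s) {
        ff <- strsplit(s, ".", fixed = TRUE)[[1]][2:3]
        sum(ff %in% forms)
    }, numeric(1))
    as.numeric(pc@concentrations[, states, drop = FALSE] %*% w)
}

#' @describeIn buildHalfOfSitesScheme steady-state turnover per dimer from
#'   the ODE (product formation per dimer per second); same window logic as
#'   the monomer method of [numericalInitialRate()].
#' @param A0,B0,I0 initial ligand concentrations, uM
#' @param E0 dimer concentration, uM
#' @export
setMethod("numericalInitialRate", "HalfOfSitesScheme",
    function(scheme, A0, B0, I0 = 0, E0 = NULL, rtol = 1e-8, ...) {
        .checkConc(A0, "A0"); .checkConc(B0, "B0"); .checkConc(I0, "I0")
        if (A0 == 0 || B0 == 0) return(0)
        if (is.null(E0)) E0 <- 1e-4 * min(A0, B0)
        if (E0 <= 0 || 2 * E0 > 0.01 * min(A0, B0))
            stop("catalytic conditions require 2 * E0 <= 0.01 * min(A0, B0)",
                 call. = FALSE)
        base <- scheme@base
        kchem <- .chemistryRate(base)
        if (!is.finite(kchem))
            stop("scheme has no complete catalytic cycle", call. = FALSE)
        r <- base@rates
        fA <- A0 / (A0 + r[["koffA"]] / max(r[["konA"]], 1e-12))
        fB <- B0 / (B0 + r[["koffB"]] / max(r[["konB"]], 1e-12))
        kEff <- 1 / (1 / (r[["kRed"]] * fA * scheme@alpha) +
                     1 / (r[["kOx"]] * fB))
        tPre <- 10 / kEff
        tDep <- min(2 * tPre, 0.002 * min(A0, B0) / (2 * kchem * E0))
        net <- .compileNetwork(.dimerSpecies(),
                               .dimerReactions(base, scheme@alpha,
                                               scheme@couple))
        y0 <- dimerState(Edimer = E0, A = A0, B = B0, I = I0)
        atol <- max(rtol * 1e-3 * max(y0), 1e-12)
        pools <- .dimerPools()
        .initialRateCore(
            simulate = function(tg) .runNetwork(net, y0, tg, rtol, atol,
                                                pools),
            productOf = function(pc) speciesConc(pc, "P2") +
                dimerSiteConc(pc, "EoxP2"),
            remaining = function(pc)
                list(speciesConc(pc, "A") + dimerSiteConc(pc, "EoxA"),
                     speciesConc(pc, "B") + dimerSiteConc(pc, "EredB")),
            tPre = tPre, tDep = tDep, E0 = E0)
    })

#' Mean occupied sites per dimer at binding equilibrium
#'
#' For the binding-only dimer (no chemistry) the grand partition function per
#' dimer is \eqn{1 + 2x + \alpha x^2} with \eqn{x = L/K_d}
#' (\eqn{K_d = k_{off,A}/k_{on,A}}), so the mean number of ligand-occupied
#' sites is
#' \deqn{\bar n = \frac{2x + 2\alpha x^2}{1 + 2x + \alpha x^2}.}
#' Saturates at 2 for independent sites (\eqn{\alpha = 1}) and at 1 in the
#' strict half-of-sites limit (\eqn{\alpha \to 0}).
#'
#' @param scheme a [HalfOfSitesScheme-class]
#' @param L free ligand concentration, uM (vectorized)
#' @return mean occupied sites per dimer, in [0, 2)
#' @export
equilibriumSiteOccupancy <- function(scheme, L) {
    stopifnot(is(scheme, "HalfOfSitesScheme"))
    if (any(is.na(L)) || any(L < 0))
        stop("'L' must be >= 0", call. = FALSE)  # Inf = saturation is fine
    r <- scheme@base@rates
    if (r[["konA"]] <= 0)
        stop("base scheme has no donor binding step", call. = FALSE)
    Kd <- r[["koffA"]] / r[["konA"]]
    x <- L / Kd
    a <- scheme@alpha
    ifelse(is.infinite(x), 2, (2 * x + 2 * a * x^2) / (1 + 2 * x + a * x^2))
}
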