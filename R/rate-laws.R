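# Closed-form steady-state and pre-steady-state rate laws.  All functions are
# pure and vectorized over concentrations.

.checkConc <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0))
        stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
    invisible(x)
}

#' Uninhibited ping-pong bi-bi rate
#'
#' Steady-state rate per enzyme of the substituted-enzyme mechanism,
#' \deqn{v/E = k_{cat} A B / (K_{mA} B + K_{mB} A + A B).}
#' Returns 0 when either substrate is absent (no donor or no acceptor means
#' no turnover; the 0/0 at A = B = 0 is resolved to the physical value 0) and
#' approaches \code{kcat} as both substrates saturate.
#'
#' @param A donor concentration, uM (vectorized)
#' @param B acceptor concentration, uM (vectorized)
#' @param params a [KineticParameters-class]
#' @return rate per enzyme, 1/s
#' @examples
#' kp <- kineticParameters(23.1, 72, 12, 249, 147)
#' pingpongRate(72, 12, kp)
#' @export
pingpongRate <- function(A, B, params) {
    stopifnot(is(params, "KineticParameters"))
    .checkConc(A, "A"); .checkConc(B, "B")
    num <- params@kcat * A * B
    den <- params@KmA * B + params@KmB * A + A * B
    ifelse(den == 0, 0, num / den)
}

#' Ping-pong rate with dead-end inhibition of both half-reactions
#'
#' \deqn{v/E = \frac{k_{cat} A B}{K_{mA} B (1 + I/K_{iA}) +
#'   K_{mB} A (1 + I/K_{iB}) + A B}}
#' With \code{I = 0} this equals [pingpongRate()] exactly.  An infinite Ki
#' removes the corresponding inhibition term exactly, so the reduced
#' competitive models are evaluated without conditioning artifacts.
#'
#' @inheritParams pingpongRate
#' @param I inhibitor concentration, uM (vectorized)
#' @param model optional inhibition-model tag (one of [inhibitionModels]);
#'   when given, it is checked for consistency with the finiteness pattern of
#'   \code{params} and a mismatch is a configuration error.
#' @return rate per enzyme, 1/s
#' @examples
#' kp <- kineticParameters(23.1, 72, 12, 249, 147)
#' pingpongInhibitedRate(72, 12, 249, kp)
#' @export
pingpongInhibitedRate <- function(A, B, I, params, model = NULL) {
    stopifnot(is(params, "KineticParameters"))
    .checkConc(A, "A"); .checkConc(B, "B"); .checkConc(I, "I")
    if (!is.null(model)) {
        model <- match.arg(model, inhibitionModels)
        if (model != inhibitionModel(params))
            stop(sprintf(
                "parameters encode model '%s' but '%s' was requested",
                inhibitionModel(params), model), call. = FALSE)
    }
    facA <- if (is.finite(params@KiA)) 1 + I / params@KiA else 1
    facB <- if (is.finite(params@KiB)) 1 + I / params@KiB else 1
    num <- params@kcat * A * B
    den <- params@KmA * B * facA + params@KmB * A * facB + A * B
    ifelse(den == 0, 0, num / den)
}

#' Hyperbolic concentration dependence of the observed rate constant
#'
#' \deqn{k_{obs} = k S / (K_d + S)}: the pseudo-first-order rate constant of
#' an enzyme half-reaction under substrate excess, bounded above by \code{k}
#' and equal to \code{k/2} at \code{S = Kd}.
#'
#' @param S substrate concentration, uM (vectorized)
#' @param hp a [HyperbolicParameters-class]
#' @return kobs, 1/s
#' @export
hyperbolicKobs <- function(S, hp) {
    stopifnot(is(hp, "HyperbolicParameters"))
    .checkConc(S, "S")
    hp@k * S / (hp@Kd + S)
}

#' Michaelis-Menten rate
#'
#' @param S substrate concentration, uM (vectorized)
#' @param kcat turnover number, 1/s
#' @param Km Michaelis constant, uM
#' @return rate per enzyme, 1/s
#' @export
mmRate <- function(S, kcat, Km) {
    if (kcat <= 0 || Km <= 0 || !is.finite(kcat) || !is.finite(Km))
        stop("kcat and Km must be finite and > 0", call. = FALSE)
    .checkConc(S, "S")
    kcat * S / (Km + S)
}

#' Specificity constant kcat/Km
#'
#' The second-order rate constant governing turnover at low substrate.
#'
#' @param kcat turnover number, 1/s
#' @param Km Michaelis constant, uM
#' @return kcat/Km, 1/(uM s)
#' @export
specificityConstant <- function(kcat, Km) {
    if (any(kcat <= 0) || any(Km <= 0) || any(!is.finite(kcat)) ||
        any(!is.finite(Km)))
        stop("kcat and Km must be finite and > 0", call. = FALSE)
    kcat / Km
}
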