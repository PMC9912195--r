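# Shared nonlinear least-squares machinery.
#
# All models in the package have strictly positive parameters, so the
# optimizer works on log-transformed parameters (positivity by construction,
# no active bounds in well-posed problems) with multistart, and inference is
# done on the natural scale: SE from s^2 (J^T J)^-1 with a central-difference
# Jacobian of the model function, t statistics and two-sided P values on
# n - p degrees of freedom.

.numJacobian <- function(fn, theta) {
    f0 <- fn(theta)
    J <- matrix(NA_real_, length(f0), length(theta))
    for (i in seq_along(theta)) {
        h <- 1e-6 * max(abs(theta[i]), 1e-8)
        tp <- theta; tp[i] <- theta[i] + h
        tm <- theta; tm[i] <- theta[i] - h
        J[, i] <- (fn(tp) - fn(tm)) / (2 * h)
    }
    colnames(J) <- names(theta)
    J
}

# predict: function(theta) -> fitted values on the natural parameter scale.
# starts: list of named positive start vectors (all the same names/order).
# Returns the internal fit list; FitResult assembly happens in the callers.
.lsqFit <- function(predict, y, starts, boundFactor = 1e8) {
    n <- length(y)
    obj <- function(lp) {
        r <- y - predict(exp(lp))
        if (any(!is.finite(r))) return(1e300)
        sum(r * r)
    }
    best <- NULL
    for (s in seq_along(starts)) {
        start <- starts[[s]]
        lp0 <- log(start)
        lower <- lp0 - log(boundFactor)
        upper <- lp0 + log(boundFactor)
        opt <- tryCatch(
            nlminb(lp0, obj, lower = lower, upper = upper,
                   control = list(iter.max = 1000, eval.max = 5000,
                                  rel.tol = 1e-15, x.tol = 1e-14)),
            error = function(e) NULL)
        if (is.null(opt)) next
        # strictly-better rule: ties broken by the first start in the list
        if (is.null(best) || opt$objective < best$objective * (1 - 1e-12)) {
            best <- opt
            best$start <- s
        }
    }
    if (is.null(best))
        stop("nonlinear fit failed to converge from any start", call. = FALSE)

    theta <- setNames(exp(best$par), names(starts[[1]]))
    rss <- sum((y - predict(theta))^2)
    p <- length(theta)
    dof <- n - p
    J <- .numJacobian(predict, theta)

    flags <- character(0)
    colnorm <- sqrt(colSums(J^2))
    dead <- colnorm < 1e-10 * max(colnorm, .Machine$double.eps)
    if (any(dead))
        flags <- c(flags, paste0("unidentifiable: ",
                                 paste(names(theta)[dead], collapse = ", ")))
    Js <- J[, !dead, drop = FALSE]
    kappa <- if (ncol(Js)) kappa(sweep(Js, 2, sqrt(colSums(Js^2)), "/"),
                                 exact = TRUE) else Inf
    if (is.finite(kappa) && kappa > 1e8)
        flags <- c(flags, "ill-conditioned")

    s2 <- if (dof > 0) rss / dof else NA_real_
    covm <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
    se <- rep(NA_real_, p)
    ok <- !dead
    if (any(ok)) {
        JtJ <- crossprod(J[, ok, drop = FALSE])
        inv <- tryCatch(solve(JtJ), error = function(e) NULL)
        if (is.null(inv)) {
            flags <- c(flags, "singular Jacobian: SEs unavailable")
        } else {
            covm[ok, ok] <- s2 * inv
            se[ok] <- sqrt(pmax(diag(covm)[ok], 0))
        }
    }
    # below numerical resolution of the response scale the fit is exact:
    # RSS ratios down there are rounding noise, not evidence
    yscale <- max(abs(y), .Machine$double.eps)
    if (rss <= n * (1e-10 * yscale)^2) flags <- c(flags, "exact_fit")
    # estimates pinned to a multistart box edge indicate a boundary solution
    atBound <- abs(best$par - (log(starts[[best$start]]) - log(boundFactor))) <
        1e-6 | abs(best$par - (log(starts[[best$start]]) + log(boundFactor))) <
        1e-6
    if (any(atBound)) flags <- c(flags, "degenerate")

    tval <- theta / se
    pval <- 2 * pt(-abs(tval), df = dof)
    pval <- pmax(pval, .Machine$double.xmin)  # keep P in (0, 1]

    list(theta = theta, se = se, t = tval, p = pval, rss = rss, n = n,
         npar = p, cov = covm, flags = flags, J = J,
         convergence = best$convergence, message = best$message,
         start = best$start)
}

.makeFitResult <- function(fit, model, extraFlags = character(0),
                           details = list()) {
    coefs <- data.frame(parameter = names(fit$theta),
                        estimate = unname(fit$theta),
                        se = unname(fit$se), t = unname(fit$t),
                        p = unname(fit$p), stringsAsFactors = FALSE)
    exact <- "exact_fit" %in% fit$flags
    aic <- if (exact) -Inf else .aicFromRSS(fit$rss, fit$n, fit$npar)
    aicc <- if (exact) -Inf
            else if (fit$n > fit$npar + 2) .aicFromRSS(fit$rss, fit$n,
                                                       fit$npar,
                                                       correct = TRUE)
            else NA_real_  # AICc undefined this small; akaike() errors instead
    new("FitResult", model = model, coefficients = coefs, rss = fit$rss,
        n = as.numeric(fit$n), p = as.numeric(fit$npar), aic = aic,
        aicc = aicc, cov = fit$cov,
        flags = unique(c(fit$flags, extraFlags)),
        details = c(details,
                    list(convergence = fit$convergence,
                         message = fit$message, start = fit$start)))
}

# Gaussian RSS-based AIC with the residual variance counted as a parameter
# (K = p + 1); AICc adds the small-sample correction 2K(K+1)/(n-K-1).
.aicFromRSS <- function(rss, n, p, correct = FALSE) {
    if (rss == 0) return(-Inf)
    K <- p + 1
    aic <- n * log(rss / n) + 2 * K
    if (correct) {
        if (n - K - 1 <= 0)
            stop("AICc needs n > p + 2", call. = FALSE)
        aic <- aic + 2 * K * (K + 1) / (n - K - 1)
    }
    aic
}
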