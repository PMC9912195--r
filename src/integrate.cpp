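#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mass-action ODE right-hand side for a reaction network with at most two
// reactants per reaction.  Sparse net stoichiometry per reaction is given in
// CSR-like layout (ptr / idx / coef).
static inline void massActionRhs(const double* y, double* dy,
                                 int nSpecies, int nReactions,
                                 const int* r1, const int* r2,
                                 const double* k,
                                 const int* ptr, const int* idx,
                                 const double* coef) {
    for (int s = 0; s < nSpecies; ++s) dy[s] = 0.0;
    for (int j = 0; j < nReactions; ++j) {
        double v = k[j];
        if (v == 0.0) continue;
        if (r1[j] >= 0) v *= y[r1[j]];
        if (r2[j] >= 0) v *= y[r2[j]];
        if (v == 0.0) continue;
        for (int p = ptr[j]; p < ptr[j + 1]; ++p) dy[idx[p]] += coef[p] * v;
    }
}

// Adaptive embedded Runge-Kutta (Cash-Karp 4(5)) integrator for mass-action
// kinetics.  Explicit with PI-free step control; the schemes used in this
// package have rate-constant spreads of at most ~1e3 so an implicit method
// is not required.
//
// [[Rcpp::export]]
NumericMatrix massActionIntegrate(NumericVector y0, NumericVector tGrid,
                                  IntegerVector react1, IntegerVector react2,
                                  NumericVector rateConst,
                                  IntegerVector stoichPtr,
                                  IntegerVector stoichIdx,
                                  NumericVector stoichCoef,
                                  double rtol, double atol,
                                  double maxSteps) {
    const int nS = y0.size();
    const int nR = rateConst.size();
    const int nT = tGrid.size();
    if (nT < 1) stop("empty time grid");
    for (int i = 1; i < nT; ++i)
        if (tGrid[i] <= tGrid[i - 1]) stop("time grid must be strictly increasing");

    NumericMatrix out(nT, nS);
    std::vector<double> y(y0.begin(), y0.end());
    for (int s = 0; s < nS; ++s) out(0, s) = y[s];
    if (nT == 1) return out;

    // Cash-Karp tableau
    static const double b21 = 1.0 / 5.0;
    static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
    static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
    static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                        b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
    static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                        b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                        b65 = 253.0 / 4096.0;
    static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                        c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
    static const double d1 = c1 - 2825.0 / 27648.0;
    static const double d3 = c3 - 18575.0 / 48384.0;
    static const double d4 = c4 - 13525.0 / 55296.0;
    static const double d5 = -277.0 / 14336.0;
    static const double d6 = c6 - 1.0 / 4.0;

    const int* r1 = react1.begin();
    const int* r2 = react2.begin();
    const double* kk = rateConst.begin();
    const int* ptr = stoichPtr.begin();
    const int* idx = stoichIdx.begin();
    const double* cf = stoichCoef.begin();

    std::vector<double> k1(nS), k2(nS), k3(nS), k4(nS), k5(nS), k6(nS),
        ytmp(nS), yerr(nS), ynew(nS);

    double t = tGrid[0];
    const double tEnd = tGrid[nT - 1];
    double h = (tGrid[1] - tGrid[0]) / 16.0;
    const double hMin = (tEnd - t) * 1e-15;
    int iOut = 1;
    double steps = 0.0;

    massActionRhs(y.data(), k1.data(), nS, nR, r1, r2, kk, ptr, idx, cf);

    while (iOut < nT) {
        if (++steps > maxSteps)
            stop("mass-action integrator exceeded maximum step count "
                 "(t = %g of %g); system may be too stiff for the requested "
                 "tolerance", t, tEnd);
        // land on the next output point: avoids interpolation error and keeps
        // linear conserved quantities exact at reported times
        if (t + h > tGrid[iOut]) h = tGrid[iOut] - t;

        for (int s = 0; s < nS; ++s) ytmp[s] = y[s] + h * b21 * k1[s];
        massActionRhs(ytmp.data(), k2.data(), nS, nR, r1, r2, kk, ptr, idx, cf);
        for (int s = 0; s < nS; ++s)
            ytmp[s] = y[s] + h * (b31 * k1[s] + b32 * k2[s]);
        massActionRhs(ytmp.data(), k3.data(), nS, nR, r1, r2, kk, ptr, idx, cf);
        for (int s = 0; s < nS; ++s)
            ytmp[s] = y[s] + h * (b41 * k1[s] + b42 * k2[s] + b43 * k3[s]);
        massActionRhs(ytmp.data(), k4.data(), nS, nR, r1, r2, kk, ptr, idx, cf);
        for (int s = 0; s < nS; ++s)
            ytmp[s] = y[s] + h * (b51 * k1[s] + b52 * k2[s] + b53 * k3[s] +
                                  b54 * k4[s]);
        massActionRhs(ytmp.data(), k5.data(), nS, nR, r1, r2, kk, ptr, idx, cf);
        for (int s = 0; s < nS; ++s)
            ytmp[s] = y[s] + h * (b61 * k1[s] + b62 * k2[s] + b63 * k3[s] +
                                  b64 * k4[s] + b65 * k5[s]);
        massActionRhs(ytmp.data(), k6.data(), nS, nR, r1, r2, kk, ptr, idx, cf);

        double errMax = 0.0;
        for (int s = 0; s < nS; ++s) {
            ynew[s] = y[s] + h * (c1 * k1[s] + c3 * k3[s] + c4 * k4[s] +
                                  c6 * k6[s]);
            yerr[s] = h * (d1 * k1[s] + d3 * k3[s] + d4 * k4[s] + d5 * k5[s] +
                           d6 * k6[s]);
            double sc = atol + rtol * std::max(std::fabs(y[s]),
                                               std::fabs(ynew[s]));
            double e = std::fabs(yerr[s]) / sc;
            if (e > errMax) errMax = e;
            if (!std::isfinite(ynew[s]))
                stop("mass-action integrator produced a non-finite state at "
                     "t = %g; check the scheme's rate constants", t);
        }

        if (errMax <= 1.0) {
            double tNew = t + h;
            // emit dense output by linear interpolation within the step
            while (iOut < nT && tGrid[iOut] <= tNew + hMin) {
                double w = (tGrid[iOut] - t) / h;
                for (int s = 0; s < nS; ++s)
                    out(iOut, s) = y[s] + w * (ynew[s] - y[s]);
                ++iOut;
            }
            t = tNew;
            y.swap(ynew);
            massActionRhs(y.data(), k1.data(), nS, nR, r1, r2, kk, ptr, idx, cf);
            double fac = (errMax > 0.0)
                             ? 0.9 * std::pow(errMax, -0.2)
                             : 5.0;
            h *= std::min(5.0, std::max(0.2, fac));
        } else {
            h *= std::max(0.2, 0.9 * std::pow(errMax, -0.25));
            if (h < hMin)
                stop("mass-action integrator step size underflow at t = %g; "
                     "system too stiff for the requested tolerance", t);
        }
    }
    return out;
}
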