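#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand sides of the glutamine/ammonium exchange models.
//
// Monoculture state y = (A, W, R, X):
//   A Gln (mM), W NH4+ (mM), R alternative energy (mM), X live cells.
// Parameters p (length 12, fixed order):
//   k1 c1 k2 c2 h k3 r1 K1 r2 K2 d1 d2
//
// Coculture state y = (A, W, R, X, Y, L); parameters p (length 26):
//   CAF block p[0..11], CC block p[12..23] (same order), g = p[24], m = p[25].
// The merged model is the special case g = m = 0 (L stays 0); the
// "normalized fibroblast" counterfactual is the special case caf k2 = 0.

static inline double monod(double r, double K, double s) {
    if (r == 0.0) return 0.0;
    double den = K + s;
    if (den <= 0.0) return 0.0;
    return r * s / den;
}

static inline void rhs_mono(const double* p, const double* y, double* f) {
    const double A = y[0], W = y[1], R = y[2], X = y[3];
    const double glnloss = p[0] * A * X;      // k1*A*X
    const double recycle = p[2] * W * R * X;  // k2*W*R*X
    f[0] = -glnloss + p[3] * recycle;
    f[1] = p[1] * glnloss - recycle + p[4] * X;
    f[2] = -recycle - p[5] * R * X;
    f[3] = (monod(p[6], p[7], A) + monod(p[8], p[9], R) - p[10] * W - p[11]) * X;
}

static inline void rhs_co(const double* p, const double* y, double* f) {
    const double* pf = p;       // CAF
    const double* pc = p + 12;  // CC
    const double g = p[24], m = p[25];
    const double A = y[0], W = y[1], R = y[2], X = y[3], Y = y[4], L = y[5];
    const double glnloss_f = pf[0] * A * X;
    const double glnloss_c = pc[0] * A * Y;
    const double recycle_f = pf[2] * W * R * X;
    const double recycle_c = pc[2] * W * R * Y;
    const double stress = m * L * L;
    f[0] = -glnloss_f + pf[3] * recycle_f - glnloss_c + pc[3] * recycle_c;
    f[1] = pf[1] * glnloss_f - recycle_f + pc[1] * glnloss_c - recycle_c +
           pf[4] * X + pc[4] * Y;
    f[2] = -recycle_f - recycle_c - pf[5] * R * X - pc[5] * R * Y;
    f[3] = (monod(pf[6], pf[7], A) + monod(pf[8], pf[9], R) -
            pf[10] * W - pf[11] - stress) * X;
    f[4] = (monod(pc[6], pc[7], A) + monod(pc[8], pc[9], R) -
            pc[10] * W - pc[11] - stress) * Y;
    f[5] = g * X * Y;
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 35.0 / 384 - 5179.0 / 57600,
                    E3 = 500.0 / 1113 - 7571.0 / 16695,
                    E4 = 125.0 / 192 - 393.0 / 640,
                    E5 = -2187.0 / 6784 + 92097.0 / 339200,
                    E6 = 11.0 / 84 - 187.0 / 2100, E7 = -1.0 / 40;

#define MAXSTEPS 5000000

// Integrate y' = f(y) with the Dormand-Prince 5(4) pair, reporting the state
// at each entry of `times` (ascending, times[0] is the initial time).
// model: 1 = monoculture (4 states, 12 parameters),
//        2 = coculture   (6 states, 26 parameters).
// [[Rcpp::export(name = ".dp45_integrate")]]
NumericMatrix dp45_integrate(NumericVector y0, NumericVector times,
                             NumericVector pars, int model,
                             double rtol, double atol) {
    const int n = y0.size();
    const int nt = times.size();
    if (model == 1) {
        if (n != 4 || pars.size() != 12)
            stop("monoculture model needs 4 states and 12 parameters");
    } else if (model == 2) {
        if (n != 6 || pars.size() != 26)
            stop("coculture model needs 6 states and 26 parameters");
    } else {
        stop("unknown model code");
    }
    for (int i = 1; i < nt; ++i)
        if (!(times[i] > times[i - 1])) stop("times must be strictly increasing");

    void (*rhs)(const double*, const double*, double*) =
        (model == 1) ? rhs_mono : rhs_co;
    const double* p = REAL(pars);

    NumericMatrix out(nt, n);
    std::vector<double> y(y0.begin(), y0.end());
    std::vector<double> yn(n), ytmp(n);
    std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);

    for (int j = 0; j < n; ++j) out(0, j) = y[j];

    double t = times[0];
    const double tend = times[nt - 1];
    const double span = tend - t;
    double h = span * 1e-4;
    if (h <= 0.0) stop("empty integration span");
    long steps = 0;
    int iout = 1;
    bool have_k1 = false;

    while (iout < nt) {
        double tnext = times[iout];
        while (t < tnext) {
            if (++steps > MAXSTEPS)
                stop("integration failed: step limit exceeded (model too stiff "
                     "at these parameters; try solver = \"lsoda\")");
            if (t + h > tnext) h = tnext - t;
            if (h < span * 1e-14)
                stop("integration failed: step size collapsed");

            if (!have_k1) rhs(p, y.data(), k1.data());
            for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * A21 * k1[j];
            rhs(p, ytmp.data(), k2.data());
            for (int j = 0; j < n; ++j)
                ytmp[j] = y[j] + h * (A31 * k1[j] + A32 * k2[j]);
            rhs(p, ytmp.data(), k3.data());
            for (int j = 0; j < n; ++j)
                ytmp[j] = y[j] + h * (A41 * k1[j] + A42 * k2[j] + A43 * k3[j]);
            rhs(p, ytmp.data(), k4.data());
            for (int j = 0; j < n; ++j)
                ytmp[j] = y[j] + h * (A51 * k1[j] + A52 * k2[j] + A53 * k3[j] +
                                      A54 * k4[j]);
            rhs(p, ytmp.data(), k5.data());
            for (int j = 0; j < n; ++j)
                ytmp[j] = y[j] + h * (A61 * k1[j] + A62 * k2[j] + A63 * k3[j] +
                                      A64 * k4[j] + A65 * k5[j]);
            rhs(p, ytmp.data(), k6.data());
            for (int j = 0; j < n; ++j)
                yn[j] = y[j] + h * (B1 * k1[j] + B3 * k3[j] + B4 * k4[j] +
                                    B5 * k5[j] + B6 * k6[j]);
            rhs(p, yn.data(), k7.data());

            double err = 0.0;
            for (int j = 0; j < n; ++j) {
                double e = h * (E1 * k1[j] + E3 * k3[j] + E4 * k4[j] +
                                E5 * k5[j] + E6 * k6[j] + E7 * k7[j]);
                double sc = atol + rtol * std::max(std::fabs(y[j]),
                                                   std::fabs(yn[j]));
                double r = e / sc;
                err += r * r;
            }
            err = std::sqrt(err / n);
            if (!std::isfinite(err))
                stop("integration failed: non-finite state reached");

            if (err <= 1.0) {
                t += h;
                y.swap(yn);
                k1.swap(k7);  // FSAL
                have_k1 = true;
                double fac = (err == 0.0) ? 5.0
                             : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
                h *= fac;
            } else {
                h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
                // k1 still valid for the retried step
                have_k1 = true;
            }
        }
        for (int j = 0; j < n; ++j) out(iout, j) = y[j];
        ++iout;
    }
    return out;
}
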