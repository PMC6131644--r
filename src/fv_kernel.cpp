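#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit-Euler finite-volume integration of radial diffusion in a
// disc-shaped cleft (rotational symmetry, no z-resolution):
//   dc/dt = D (1/r) d/dr(r dc/dr) + f(r,t) - uptake(c)
// Conservative flux form on a uniform cell-centered grid with faces at 0 and
// S. Inner boundary reflecting (zero flux); outer boundary either Dirichlet
// (ghost value `baseline` at the face, half-cell spacing) or reflecting.
// Pulsed source: events at `freq` Hz, each releasing for `pulse_dur` seconds
// at instantaneous rate k_inst * fire[event] in cells with src_mask, while
// t < train_dur. freq <= 0 means constant release (amplitude fire[0]) for
// t < train_dur. Saturable Michaelis-Menten membrane uptake, clamped so a
// step never drives a cell negative.
//
// [[Rcpp::export]]
List fv_run_cpp(NumericVector c0,
                double D, double h, double baseline,
                double S, double dr,
                NumericVector face_r,        // length n+1, radii of faces
                NumericVector volumes,       // length n
                NumericVector areas,         // length n, membrane area
                LogicalVector src_mask,
                double k_inst,
                double freq, double pulse_dur, double train_dur,
                NumericVector fire,
                double Jmax, double Km, bool uptake_on,
                bool reflect_outer,
                double dt, int n_steps, int save_every)
{
    const int n = c0.size();
    std::vector<double> c(c0.begin(), c0.end());
    std::vector<double> cnew(n), flux(n + 1, 0.0);
    std::vector<double> vol(volumes.begin(), volumes.end());
    std::vector<double> av(n);          // membrane area / cell volume
    std::vector<char> src(n);
    for (int i = 0; i < n; ++i) {
        av[i] = areas[i] / vol[i];
        src[i] = src_mask[i] ? 1 : 0;
    }
    const int n_fire = fire.size();
    const double *pfire = REAL(fire);

    const int n_saves = n_steps / save_every + 1;
    NumericMatrix fields(n_saves, n);
    NumericVector save_times(n_saves);
    int isave = 0;
    for (int i = 0; i < n; ++i) fields(0, i) = c[i];
    save_times[0] = 0.0;
    ++isave;

    // per-face diffusion conductance: D * 2*pi*r_face*h / dr
    std::vector<double> cond(n + 1);
    for (int j = 0; j <= n; ++j) cond[j] = D * 2.0 * M_PI * face_r[j] * h / dr;
    const double cond_outer = D * 2.0 * M_PI * S * h / (dr / 2.0);

    double src_vol = 0.0;
    for (int i = 0; i < n; ++i) if (src[i]) src_vol += vol[i];

    double released = 0.0, uptaken = 0.0;
    int bad_step = -1;
    double bad_t = 0.0;

    for (int step = 0; step < n_steps; ++step) {
        const double t = step * dt;

        // source amplitude at time t
        double amp = 0.0;
        if (t < train_dur) {
            if (freq <= 0.0) {
                amp = pfire[0];
            } else {
                int ev = (int) std::floor(t * freq);
                if (ev >= 0 && ev < n_fire && (t - ev / freq) < pulse_dur)
                    amp = pfire[ev];
            }
        }
        const double src_rate = k_inst * amp;  // mol/(m^3 s) in source cells

        // diffusive fluxes through faces (outward positive)
        for (int j = 1; j < n; ++j)
            flux[j] = -cond[j] * (c[j] - c[j - 1]);
        flux[n] = reflect_outer ? 0.0 : -cond_outer * (baseline - c[n - 1]);

        bool bad = false;
        for (int i = 0; i < n; ++i) {
            double dc = dt / vol[i] * (flux[i] - flux[i + 1]);
            if (src[i]) dc += dt * src_rate;
            double ci = c[i] + dc;
            if (uptake_on && ci > 0.0) {
                double rem = av[i] * Jmax * ci / (Km + ci) * dt;
                if (rem > ci) rem = ci;      // never cross zero
                ci -= rem;
                uptaken += rem * vol[i];
            }
            if (!std::isfinite(ci) || ci < -1e-30) bad = true;
            cnew[i] = ci;
        }
        if (bad) { bad_step = step + 1; bad_t = t; break; }

        released += src_rate * src_vol * dt;
        c.swap(cnew);

        if ((step + 1) % save_every == 0 && isave < n_saves) {
            for (int i = 0; i < n; ++i) fields(isave, i) = c[i];
            save_times[isave] = (step + 1) * dt;
            ++isave;
        }
    }
    if (bad_step >= 0)
        stop("finite-volume step %d (t = %g s) produced a negative or "
             "non-finite concentration; reduce dt", bad_step, bad_t);

    return List::create(_["times"] = save_times,
                        _["fields"] = fields,
                        _["final"] = NumericVector(c.begin(), c.end()),
                        _["released_mol"] = released,
                        _["uptaken_mol"] = uptaken);
}
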