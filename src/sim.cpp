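#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear transfer function phi(U): 0 below rest, phi_max above
// threshold 1, linear in between.
static inline double phi_rate(double u, double phimax) {
    if (u <= 0.0) return 0.0;
    if (u >= 1.0) return phimax;
    return phimax * u;
}

// One contiguous simulation segment for a single two-compartment neuron.
//
// Per-synapse PSPs are carried by two exponential state variables Am, As
// (decay constants tau_m, tau_s), the exact discrete update of the
// double-exponential spike-response kernel: a spike binned at k increments
// both states at the end of bin k, so its first nonzero contribution is
// kappa(dt) at bin k+1 (causal, bin-left-aligned convolution).
//
// Pt carries the low-pass filtered PSP (time constant tau of the plasticity
// rule); tau <= 0 collapses Pt onto the raw PSP.
//
// The soma follows forward Euler:
//   C dU/dt = -gL U + gD (Vw - U) + gE (EE - U) + gI (EI - U)
// and weights follow, in rate mode,
//   dw_i/dt = eta (alpha phi(U) Pt_i - phi(Vstar) psp_i),
// with phi(U) replaced by a sampled spike indicator / dt in spike mode.
//
// State vectors are cloned; the updated state is returned so that callers
// can chain segments (training periods) with persistent synaptic traces.
// [[Rcpp::export]]
List cpp_sim_segment(IntegerVector ev_bin, IntegerVector ev_ch,
                     int n_bins, NumericVector gE, NumericVector gI,
                     NumericVector w_in, NumericVector Am_in,
                     NumericVector As_in, NumericVector Pt_in,
                     double U0, double dt,
                     double C, double gL, double gD, double EE, double EI,
                     double phimax, double taum, double taus,
                     double eta, double alpha, double tau,
                     bool learn, bool spike_mode, bool record) {
    const int n_syn = w_in.size();
    NumericVector w = clone(w_in), Am = clone(Am_in), As = clone(As_in),
                  Pt = clone(Pt_in);
    std::vector<double> psp(n_syn);
    const double dm = std::exp(-dt / taum), ds = std::exp(-dt / taus);
    const double kc = 1.0 / (taum - taus);
    const double aT = (tau > 0.0) ? std::exp(-dt / tau) : 0.0;
    const double bT = 1.0 - aT;
    const double vfac = gD / (gL + gD);
    const double Cms = C * 1000.0;  // nF -> nS * ms

    NumericVector phiU_tr(record ? n_bins : 0), phiV_tr(record ? n_bins : 0),
                  U_tr(record ? n_bins : 0), Vw_tr(record ? n_bins : 0);

    double U = U0;
    int ptr = 0;
    const int nev = ev_bin.size();
    const double *pgE = gE.begin(), *pgI = gI.begin();
    double *pw = w.begin(), *pAm = Am.begin(), *pAs = As.begin(),
           *pPt = Pt.begin();

    for (int k = 0; k < n_bins; ++k) {
        double vw = 0.0;
        for (int i = 0; i < n_syn; ++i) {
            pAm[i] *= dm;
            pAs[i] *= ds;
            const double p = kc * (pAm[i] - pAs[i]);
            psp[i] = p;
            vw += pw[i] * p;
        }
        const double ge = pgE[k], gi = pgI[k];
        const double gtot = gL + gD + ge + gi;
        if (dt * gtot / Cms >= 1.0)
            stop("forward Euler unstable: dt * g_tot / C >= 1");
        // Euler step first: all factors of the weight update are evaluated
        // at the same grid time (U has assimilated this bin's inputs).
        U += dt / Cms *
             (-gL * U + gD * (vw - U) + ge * (EE - U) + gi * (EI - U));
        const double vstar = vfac * vw;
        const double phiU = phi_rate(U, phimax);
        const double phiV = phi_rate(vstar, phimax);

        if (record) {
            phiU_tr[k] = phiU;
            phiV_tr[k] = phiV;
            U_tr[k] = U;
            Vw_tr[k] = vw;
        }

        double post = phiU;
        if (spike_mode) {
            const double pr = phiU * dt;
            if (pr > 1.0) stop("spike probability phi(U)*dt exceeds 1");
            post = (unif_rand() < pr) ? 1.0 / dt : 0.0;
        }

        if (learn) {
            const double cpot = dt * eta * alpha * post;
            const double cdep = dt * eta * phiV;
            for (int i = 0; i < n_syn; ++i) {
                pPt[i] = aT * pPt[i] + bT * psp[i];
                pw[i] += cpot * pPt[i] - cdep * psp[i];
            }
        } else {
            for (int i = 0; i < n_syn; ++i)
                pPt[i] = aT * pPt[i] + bT * psp[i];
        }

        while (ptr < nev && ev_bin[ptr] == k) {
            const int c = ev_ch[ptr];
            pAm[c] += 1.0;
            pAs[c] += 1.0;
            ++ptr;
        }
    }

    List out = List::create(_["w"] = w, _["Am"] = Am, _["As"] = As,
                            _["Pt"] = Pt, _["U"] = U);
    if (record) {
        out["phiU"] = phiU_tr;
        out["phiV"] = phiV_tr;
        out["U_trace"] = U_tr;
        out["Vw"] = Vw_tr;
    }
    return out;
}

// Recurrent all-to-all network segment. Every neuron is presynaptic to every
// other through plastic dendritic synapses W (W[i,j] = weight from neuron j
// onto neuron i, diagonal pinned at zero: no autapses). Somatic drive is
// shared within stimulation groups: gE_group is n_bins x n_groups and
// group[i] (0-based) selects the column for neuron i. Network spikes are
// sampled per bin from phi(U_i) dt and fed back as presynaptic events in the
// next bin; the plasticity rule stays in rate mode for the postsynaptic
// factor, as in the single-neuron simulations.
// [[Rcpp::export]]
List cpp_sim_recurrent(int n_bins, IntegerVector group, NumericMatrix gE_group,
                       NumericMatrix W_in, NumericVector Am_in,
                       NumericVector As_in, NumericVector Pt_in,
                       NumericVector U_in, double dt,
                       double C, double gL, double gD, double EE, double EI,
                       double phimax, double taum, double taus,
                       double eta, double alpha, double tau,
                       bool learn, bool record_rate) {
    const int n = U_in.size();
    NumericMatrix W = clone(W_in);
    NumericVector Am = clone(Am_in), As = clone(As_in), Pt = clone(Pt_in),
                  U = clone(U_in);
    std::vector<double> psp(n), vw(n), phiU(n), phiV(n);
    std::vector<int> spk(n);
    std::vector<int> spike_bin, spike_id;

    const double dm = std::exp(-dt / taum), ds = std::exp(-dt / taus);
    const double kc = 1.0 / (taum - taus);
    const double aT = (tau > 0.0) ? std::exp(-dt / tau) : 0.0;
    const double bT = 1.0 - aT;
    const double vfac = gD / (gL + gD);
    const double Cms = C * 1000.0;  // nF -> nS * ms

    NumericMatrix rate_tr(record_rate ? n_bins : 0, record_rate ? n : 0);

    for (int k = 0; k < n_bins; ++k) {
        for (int j = 0; j < n; ++j) {
            Am[j] *= dm;
            As[j] *= ds;
            psp[j] = kc * (Am[j] - As[j]);
            Pt[j] = aT * Pt[j] + bT * psp[j];
        }
        std::fill(vw.begin(), vw.end(), 0.0);
        for (int j = 0; j < n; ++j) {
            const double pj = psp[j];
            if (pj == 0.0) continue;
            const double *col = &W(0, j);
            for (int i = 0; i < n; ++i) vw[i] += col[i] * pj;
        }
        for (int i = 0; i < n; ++i) {
            const double ge = gE_group(k, group[i]);
            const double gtot = gL + gD + ge;
            if (dt * gtot / Cms >= 1.0)
                stop("forward Euler unstable: dt * g_tot / C >= 1");
            U[i] += dt / Cms *
                    (-gL * U[i] + gD * (vw[i] - U[i]) + ge * (EE - U[i]));
            const double vstar = vfac * vw[i];
            phiU[i] = phi_rate(U[i], phimax);
            phiV[i] = phi_rate(vstar, phimax);
            if (record_rate) rate_tr(k, i) = phiU[i];
            spk[i] = (unif_rand() < phiU[i] * dt) ? 1 : 0;
        }
        if (learn) {
            for (int j = 0; j < n; ++j) {
                const double potj = dt * eta * alpha * Pt[j];
                const double depj = dt * eta * psp[j];
                double *col = &W(0, j);
                for (int i = 0; i < n; ++i)
                    col[i] += potj * phiU[i] - depj * phiV[i];
                col[j] = 0.0;  // no autapses
            }
        }
        for (int i = 0; i < n; ++i) {
            if (spk[i]) {
                Am[i] += 1.0;
                As[i] += 1.0;
                spike_bin.push_back(k);
                spike_id.push_back(i + 1);
            }
        }
    }

    List out = List::create(_["W"] = W, _["Am"] = Am, _["As"] = As,
                            _["Pt"] = Pt, _["U"] = U,
                            _["spike_bin"] = wrap(spike_bin),
                            _["spike_neuron"] = wrap(spike_id));
    if (record_rate) out["rate"] = rate_tr;
    return out;
}
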