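// Fast integrator for the coupled dynamic-field architectures.
//
// All fields are updated synchronously: outputs g(u) are computed from the
// state at time t for every field, then every field takes one Euler step.
// Lateral kernels and inter-field projections arrive as precomputed tap
// vectors (per-degree weights already multiplied by the grid spacing and
// truncated to their support); scalar gains arrive as length-1 taps.
// Noise uses the R RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double u, double beta) {
  return 1.0 / (1.0 + std::exp(-beta * u));
}

// wrap into [0, 360)
static inline double wrap360(double x) {
  while (x >= 360.0) x -= 360.0;
  while (x < 0.0) x += 360.0;
  return x;
}

// circular convolution of x with centered taps (length 2w+1)
static std::vector<double> conv_circ(const std::vector<double>& x,
                                     const NumericVector& taps) {
  int n = x.size();
  int len = taps.size();
  int w = (len - 1) / 2;
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = -w; j <= w; ++j) {
      int k = i + j;
      if (k < 0) k += n; else if (k >= n) k -= n;
      acc += taps[j + w] * x[k];
    }
    y[i] = acc;
  }
  return y;
}

struct Field1D {
  std::vector<double> u, g, input, xi;
  double h, tau, q, beta, hboost;
  NumericVector lat_taps;   // local DoG part (may be length 0)
  NumericVector noise_taps; // spatial correlation of the noise (unit variance)
  double ginh;              // global inhibition coefficient (times sum g * dx)
  double dx;
  bool present;
  Field1D() : present(false) {}
  void init(List p, NumericVector u0, double dx_, double hboost_) {
    present = true;
    u = as<std::vector<double> >(u0);
    h = p["h"]; tau = p["tau"]; q = p["q"]; beta = p["beta"];
    lat_taps = p.containsElementNamed("lat_taps") ?
      as<NumericVector>(p["lat_taps"]) : NumericVector(0);
    noise_taps = p.containsElementNamed("noise_taps") ?
      as<NumericVector>(p["noise_taps"]) : NumericVector(0);
    ginh = p.containsElementNamed("ginh") ? as<double>(p["ginh"]) : 0.0;
    dx = dx_; hboost = hboost_;
    g.assign(u.size(), 0.0);
    input.assign(u.size(), 0.0);
  }
  void outputs() {
    for (size_t i = 0; i < u.size(); ++i) g[i] = sigm(u[i], beta);
  }
  void reset_input() { std::fill(input.begin(), input.end(), 0.0); }
  void add_lateral() {
    if (lat_taps.size() > 0) {
      std::vector<double> lv = conv_circ(g, lat_taps);
      for (size_t i = 0; i < u.size(); ++i) input[i] += lv[i];
    }
    if (ginh != 0.0) {
      double s = 0.0;
      for (size_t i = 0; i < g.size(); ++i) s += g[i];
      s *= ginh * dx;
      for (size_t i = 0; i < u.size(); ++i) input[i] -= s;
    }
  }
  void add_conv(const std::vector<double>& src, const NumericVector& taps,
                double scale = 1.0) {
    if (taps.size() == 0 || scale == 0.0) return;
    if (taps.size() == 1) {
      for (size_t i = 0; i < u.size(); ++i)
        input[i] += scale * taps[0] * src[i];
    } else {
      std::vector<double> v = conv_circ(src, taps);
      for (size_t i = 0; i < u.size(); ++i) input[i] += scale * v[i];
    }
  }
  void add_uniform(double val) {
    for (size_t i = 0; i < u.size(); ++i) input[i] += val;
  }
  void add_vector(const NumericVector& v) {
    if (v.size() == 0) return;
    for (size_t i = 0; i < u.size(); ++i) input[i] += v[i];
  }
  void step(double dt) {
    double sq = q * std::sqrt(dt);
    if (q > 0 && noise_taps.size() > 1) {
      xi.resize(u.size());
      for (size_t i = 0; i < u.size(); ++i) xi[i] = R::norm_rand();
      std::vector<double> sm = conv_circ(xi, noise_taps);
      for (size_t i = 0; i < u.size(); ++i) {
        double du = (-u[i] + h + hboost + input[i]) * (dt / tau);
        u[i] += du + sq * sm[i];
      }
    } else {
      for (size_t i = 0; i < u.size(); ++i) {
        double du = (-u[i] + h + hboost + input[i]) * (dt / tau);
        if (q > 0) du += sq * R::norm_rand();
        u[i] += du;
      }
    }
  }
  double integral() const {
    double s = 0.0;
    for (size_t i = 0; i < g.size(); ++i) s += g[i];
    return s * dx;
  }
};

struct Node {
  double u, h, tau, q, beta, self_exc, g;
  bool present;
  Node() : present(false) {}
  void init(List p, double u0) {
    present = true;
    u = u0;
    h = p["h"]; tau = p["tau"]; q = p["q"]; beta = p["beta"];
    self_exc = p["self_exc"];
    g = 0.0;
  }
  void output() { g = sigm(u, beta); }
  void step(double drive, double dt) {
    double du = (-u + h + drive + self_exc * g) * (dt / tau);
    if (q > 0) du += q * std::sqrt(dt) * R::norm_rand();
    u += du;
  }
};

static NumericVector getv(List cp, const char* name) {
  if (!cp.containsElementNamed(name)) return NumericVector(0);
  return as<NumericVector>(cp[name]);
}
static double gets(List cp, const char* name) {
  if (!cp.containsElementNamed(name)) return 0.0;
  return as<double>(cp[name]);
}

// [[Rcpp::export]]
List cpp_run_phase(List state, List par, List ext, int nsteps, double dt) {
  int variant = as<int>(par["variant"]);
  int nc = as<int>(par["nc"]);
  int ns = as<int>(par["ns"]);
  double dxc = 360.0 / nc, dxs = 360.0 / ns;

  // --- 2D color-space sensory field -------------------------------------
  List pcs = par["cs"];
  NumericMatrix ucs_in = as<NumericMatrix>(state["cs"]);
  std::vector<double> ucs(ucs_in.begin(), ucs_in.end());
  std::vector<double> gcs(nc * ns, 0.0);
  double cs_h = pcs["h"], cs_tau = pcs["tau"], cs_q = pcs["q"],
         cs_beta = pcs["beta"], cs_ginh = gets(pcs, "ginh");
  NumericVector exc_c = getv(pcs, "exc_c"), exc_s = getv(pcs, "exc_s");
  NumericVector inh_c = getv(pcs, "inh_c"), inh_s = getv(pcs, "inh_s");

  // --- 1D fields ---------------------------------------------------------
  Field1D fa, fc, inh, fwm, sa, ior, sla;
  fa.init(par["fa"], state["fa"], dxc, gets(ext, "fa_hboost"));
  fc.init(par["fc"], state["fc"], dxc, 0.0);
  inh.init(par["inh"], state["inh"], dxc, 0.0);
  fwm.init(par["fwm"], state["fwm"], dxc, 0.0);
  bool m2 = (variant == 2);
  if (m2) {
    sa.init(par["sa"], state["sa"], dxs, 0.0);
    ior.init(par["ior"], state["ior"], dxs, 0.0);
    sla.init(par["sla"], state["sla"], dxc, 0.0);
  }
  Node pd, cos_;
  if (m2) {
    pd.init(par["pd"], as<double>(state["pd"]));
    cos_.init(par["cos"], as<double>(state["cos"]));
  }

  // --- couplings ----------------------------------------------------------
  List cp = par["cp"];
  NumericVector cs_fa = getv(cp, "cs_fa"), cs_fc = getv(cp, "cs_fc"),
    cs_fwm = getv(cp, "cs_fwm"), fa_fc = getv(cp, "fa_fc"),
    fc_fwm = getv(cp, "fc_fwm"), fc_inh = getv(cp, "fc_inh"),
    fwm_inh = getv(cp, "fwm_inh"), inh_fc = getv(cp, "inh_fc"),
    inh_fwm = getv(cp, "inh_fwm"), fwm_fa = getv(cp, "fwm_fa"),
    fc_fa = getv(cp, "fc_fa"), cs_sa = getv(cp, "cs_sa"),
    ior_sa = getv(cp, "ior_sa"), sa_ior = getv(cp, "sa_ior"),
    fwm_sla = getv(cp, "fwm_sla"), fa_sla = getv(cp, "fa_sla"),
    sla_fwm = getv(cp, "sla_fwm"), inh_fa = getv(cp, "inh_fa");
  double fa_cs = gets(cp, "fa_cs"), sa_cs = gets(cp, "sa_cs"),
    sla_pd = gets(cp, "sla_pd"), pd_cos = gets(cp, "pd_cos"),
    cos_fa = gets(cp, "cos_fa"), cos_sa = gets(cp, "cos_sa"),
    cos_sla = gets(cp, "cos_sla"), cos_ior = gets(cp, "cos_ior");

  // --- external inputs ----------------------------------------------------
  NumericMatrix cs_input(nc, ns);
  if (ext.containsElementNamed("cs_input"))
    cs_input = as<NumericMatrix>(ext["cs_input"]);
  NumericVector fwm_input = getv(ext, "fwm_input");
  NumericVector sla_input = getv(ext, "sla_input");
  // readout considers only sites on the response wheel (mask = 1)
  NumericMatrix read_mask(0, 0);
  bool has_mask = ext.containsElementNamed("read_mask");
  if (has_mask) read_mask = as<NumericMatrix>(ext["read_mask"]);

  // --- readout / consolidation bookkeeping -------------------------------
  bool readout = gets(ext, "readout") > 0.5;
  double read_thr = gets(ext, "read_threshold");
  int hold_steps = (int) gets(ext, "hold_steps");
  int hold_count = 0, resp_step = -1;
  int prev_site = -1;
  double resp_space = NA_REAL, resp_color = NA_REAL;
  IntegerVector item_sites = state.containsElementNamed("item_sites") ?
    as<IntegerVector>(state["item_sites"]) : IntegerVector(0);
  double cons_thr = gets(par, "cons_threshold");
  int cons_halfw = (int) gets(par, "cons_halfwidth");
  NumericVector cons_step = state.containsElementNamed("cons_step") ?
    clone(as<NumericVector>(state["cons_step"])) : NumericVector(0);
  double step_offset = gets(ext, "step_offset");

  std::vector<double> pcol(nc), pspace(ns), conv_tmp(nc * ns), lat_cs(nc * ns);

  for (int t = 0; t < nsteps; ++t) {
    // outputs at time t
    for (int i = 0; i < nc * ns; ++i) gcs[i] = sigm(ucs[i], cs_beta);
    fa.outputs(); fc.outputs(); inh.outputs(); fwm.outputs();
    if (m2) { sa.outputs(); ior.outputs(); sla.outputs();
              pd.output(); cos_.output(); }

    // projections of the sensory field output
    std::fill(pcol.begin(), pcol.end(), 0.0);
    std::fill(pspace.begin(), pspace.end(), 0.0);
    double gsum = 0.0;
    for (int s = 0; s < ns; ++s) {
      const double* col = &gcs[(size_t) s * nc];
      double csum = 0.0;
      for (int i = 0; i < nc; ++i) {
        pcol[i] += col[i];
        csum += col[i];
      }
      pspace[s] = csum * dxc;
      gsum += csum;
    }
    for (int i = 0; i < nc; ++i) pcol[i] *= dxs;

    // CS lateral interactions: separable DoG terms + global offset
    std::fill(lat_cs.begin(), lat_cs.end(), 0.0);
    if (exc_c.size() > 0) {
      // convolve along color within each column, then along space
      int wc = (exc_c.size() - 1) / 2, wsp = (exc_s.size() - 1) / 2;
      for (int s = 0; s < ns; ++s) {
        const double* col = &gcs[(size_t) s * nc];
        double* out = &conv_tmp[(size_t) s * nc];
        for (int i = 0; i < nc; ++i) {
          double acc = 0.0;
          for (int j = -wc; j <= wc; ++j) {
            int k = i + j; if (k < 0) k += nc; else if (k >= nc) k -= nc;
            acc += exc_c[j + wc] * col[k];
          }
          out[i] = acc;
        }
      }
      for (int i = 0; i < nc; ++i) {
        for (int s = 0; s < ns; ++s) {
          double acc = 0.0;
          for (int j = -wsp; j <= wsp; ++j) {
            int k = s + j; if (k < 0) k += ns; else if (k >= ns) k -= ns;
            acc += exc_s[j + wsp] * conv_tmp[(size_t) k * nc + i];
          }
          lat_cs[(size_t) s * nc + i] += acc;
        }
      }
    }
    if (inh_c.size() > 0) {
      int wc = (inh_c.size() - 1) / 2, wsp = (inh_s.size() - 1) / 2;
      for (int s = 0; s < ns; ++s) {
        const double* col = &gcs[(size_t) s * nc];
        double* out = &conv_tmp[(size_t) s * nc];
        for (int i = 0; i < nc; ++i) {
          double acc = 0.0;
          for (int j = -wc; j <= wc; ++j) {
            int k = i + j; if (k < 0) k += nc; else if (k >= nc) k -= nc;
            acc += inh_c[j + wc] * col[k];
          }
          out[i] = acc;
        }
      }
      for (int i = 0; i < nc; ++i) {
        for (int s = 0; s < ns; ++s) {
          double acc = 0.0;
          for (int j = -wsp; j <= wsp; ++j) {
            int k = s + j; if (k < 0) k += ns; else if (k >= ns) k -= ns;
            acc += inh_s[j + wsp] * conv_tmp[(size_t) k * nc + i];
          }
          lat_cs[(size_t) s * nc + i] -= acc;
        }
      }
    }
    double cs_glob = cs_ginh * gsum * dxc * dxs;

    // 1D field inputs
    fa.reset_input(); fc.reset_input(); inh.reset_input(); fwm.reset_input();
    fa.add_lateral(); fc.add_lateral(); inh.add_lateral(); fwm.add_lateral();
    fa.add_conv(pcol, cs_fa);
    fa.add_conv(fwm.g, fwm_fa);
    fa.add_conv(inh.g, inh_fa);    // negative taps: stored colors lose attention
    fc.add_conv(pcol, cs_fc);
    fc.add_conv(fa.g, fa_fc);
    fc.add_conv(inh.g, inh_fc);     // taps are negative (inhibitory)
    inh.add_conv(fc.g, fc_inh);
    inh.add_conv(fwm.g, fwm_inh);
    fwm.add_conv(pcol, cs_fwm);
    fwm.add_conv(fc.g, fc_fwm);
    fwm.add_conv(inh.g, inh_fwm);   // negative taps
    fwm.add_vector(fwm_input);
    if (m2) {
      fa.add_conv(fc.g, fc_fa);
      fa.add_uniform(-cos_fa * cos_.g);
      sa.reset_input(); sa.add_lateral();
      sa.add_conv(pspace, cs_sa);
      sa.add_conv(ior.g, ior_sa);   // negative taps
      sa.add_uniform(-cos_sa * cos_.g);
      ior.reset_input(); ior.add_lateral();
      // sub-threshold trace of the attended location; the CoS release boost
      // lifts it over threshold so the visited location latches
      ior.add_conv(sa.g, sa_ior);
      ior.add_uniform(cos_ior * cos_.g);
      sla.reset_input(); sla.add_lateral();
      sla.add_conv(fwm.g, fwm_sla);
      sla.add_conv(fa.g, fa_sla);
      sla.add_uniform(-cos_sla * cos_.g);
      sla.add_vector(sla_input);
      fwm.add_conv(sla.g, sla_fwm);
    }

    // CS update
    double sq = cs_q * std::sqrt(dt);
    for (int s = 0; s < ns; ++s) {
      double sain = m2 ? sa_cs * sa.g[s] : 0.0;
      for (int i = 0; i < nc; ++i) {
        size_t idx = (size_t) s * nc + i;
        double in = cs_input(i, s) + lat_cs[idx] - cs_glob + sain
          + fa_cs * fa.g[i];
        double du = (-ucs[idx] + cs_h + in) * (dt / cs_tau);
        if (cs_q > 0) du += sq * R::norm_rand();
        ucs[idx] += du;
      }
    }

    // 1D and node updates
    fa.step(dt); fc.step(dt); inh.step(dt); fwm.step(dt);
    if (m2) {
      sa.step(dt); ior.step(dt); sla.step(dt);
      double pdg = pd.g, slaint = sla.integral();
      pd.step(sla_pd * slaint, dt);
      cos_.step(pd_cos * pdg, dt);
    }

    // consolidation bookkeeping: first above-threshold crossing near each item
    for (int j = 0; j < item_sites.size(); ++j) {
      if (cons_step[j] >= 0) continue;
      int c0 = item_sites[j];
      for (int o = -cons_halfw; o <= cons_halfw; ++o) {
        int k = c0 + o; if (k < 0) k += nc; else if (k >= nc) k -= nc;
        if (fwm.u[k] > cons_thr) { cons_step[j] = step_offset + t + 1; break; }
      }
    }

    // readout: stable above-threshold peak in the sensory field
    if (readout && resp_step < 0) {
      double best = -1e300; int bi = -1, bs = -1;
      for (int s = 0; s < ns; ++s) {
        const double* col = &ucs[(size_t) s * nc];
        for (int i = 0; i < nc; ++i) {
          if (has_mask && read_mask(i, s) == 0.0) continue;
          if (col[i] > best) { best = col[i]; bi = i; bs = s; }
        }
      }
      if (best > read_thr) {
        int dsite = std::abs(bs - prev_site);
        if (dsite > ns / 2) dsite = ns - dsite;
        if (prev_site >= 0 && dsite <= 2) hold_count++; else hold_count = 1;
        prev_site = bs;
        if (hold_count >= hold_steps) {
          resp_step = t + 1;
          // parabolic refinement along space on the max-over-color profile
          auto colmax = [&](int s) {
            int ss = s; if (ss < 0) ss += ns; else if (ss >= ns) ss -= ns;
            const double* col = &ucs[(size_t) ss * nc];
            double m = -1e300;
            for (int i = 0; i < nc; ++i) {
              if (has_mask && read_mask(i, ss) == 0.0) continue;
              if (col[i] > m) m = col[i];
            }
            return m;
          };
          double a = colmax(bs - 1), b = colmax(bs), c = colmax(bs + 1);
          double denom = a - 2 * b + c;
          double off = denom < 0 ? 0.5 * (a - c) / denom : 0.0;
          resp_space = wrap360((bs + off) * dxs);
          // color coordinate of the response peak (refined the same way)
          auto rowval = [&](int i) {
            int ii = i; if (ii < 0) ii += nc; else if (ii >= nc) ii -= nc;
            return ucs[(size_t) bs * nc + ii];
          };
          double ra = rowval(bi - 1), rb = rowval(bi), rc = rowval(bi + 1);
          double rden = ra - 2 * rb + rc;
          double roff = rden < 0 ? 0.5 * (ra - rc) / rden : 0.0;
          resp_color = wrap360((bi + roff) * dxc);
        }
      } else {
        hold_count = 0; prev_site = -1;
      }
    }
  }

  // write back
  NumericMatrix ucs_out(nc, ns);
  std::copy(ucs.begin(), ucs.end(), ucs_out.begin());
  List out = List::create(
    _["cs"] = ucs_out,
    _["fa"] = wrap(fa.u), _["fc"] = wrap(fc.u),
    _["inh"] = wrap(inh.u), _["fwm"] = wrap(fwm.u),
    _["resp_step"] = resp_step, _["resp_space"] = resp_space,
    _["resp_color"] = resp_color,
    _["cons_step"] = cons_step, _["item_sites"] = item_sites);
  if (m2) {
    out["sa"] = wrap(sa.u); out["ior"] = wrap(ior.u);
    out["sla"] = wrap(sla.u);
    out["pd"] = pd.u; out["cos"] = cos_.u;
  }
  return out;
}
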