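// Coarse-grained overdamped Langevin engine for cotranslational membrane
// integration. Units: nm, s, kcal/mol. One bead = three residues. The
// C-terminal (most recently synthesized) bead is tethered at the peptidyl-
// transferase-center anchor at the top of a truncated exit tunnel; the
// membrane is an implicit slab pierced by the translocon pore, whose
// lateral gate switches between open and closed by Metropolis moves.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// Small fast counter-free RNG (xoshiro256++ seeded via splitmix64) with a
// cached Box-Muller pair for normal draws; deterministic given the seed.
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

struct Geom {
  double z_mem_top, z_mem_bot; // slab faces (z_mem_top > z_mem_bot)
  double r_pore;               // aqueous translocon pore radius
  double r_tunnel;             // ribosome exit-tunnel radius
  double z_tun_bot, z_tun_top; // tunnel extent; anchor sits at z_tun_top
  double taper_w;              // z-width of the lipid interface taper
  double r_switch_w;           // radial width of the pore->lipid switch
  double r_free;               // beyond this radius the bilayer is open
  double sector_cos;           // cos(half-width) of the lateral-gate sector
  double r_gate_region;        // radial extent of the gate-occupancy region
  double z_gate_top;           // top of the gate-occupancy region
};

struct Par {
  double dt, D, kBT;
  double k_bond, r_bond, k_anchor, k_wall;
  double k_excl, d_excl; // single-file bead-bead repulsion in the channel
  double k_head;         // headgroup-crossing barrier height (kcal/mol)
  double volt;       // membrane potential, volts (cytoplasm minus periplasm)
  double gate_dG0;   // free energy open - closed, empty gate (kcal/mol)
  double gate_coupling;
  int gate_interval; // steps between gate flip attempts
};

const double KCAL_PER_EV = 23.0605; // 1 eV per elementary charge

// Smooth 0->1 switch on [0, w] (cosine ramp); derivative via *ds.
inline double smoothstep(double x, double w, double* ds) {
  if (x <= 0) { *ds = 0; return 0; }
  if (x >= w) { *ds = 0; return 1; }
  double u = x / w;
  *ds = 0.5 * M_PI * std::sin(M_PI * u) / w;
  return 0.5 * (1.0 - std::cos(M_PI * u));
}

// Depth inside the slab (0 outside, ramps to 1 across taper_w at each face).
inline double slab_depth(double z, const Geom& G, double* dsdz) {
  *dsdz = 0;
  if (z <= G.z_mem_bot || z >= G.z_mem_top) return 0;
  double d_top = G.z_mem_top - z;
  double d_bot = z - G.z_mem_bot;
  double ds;
  if (d_top < d_bot) {
    double s = smoothstep(d_top, G.taper_w, &ds);
    *dsdz = -ds;
    return s;
  }
  double s = smoothstep(d_bot, G.taper_w, &ds);
  *dsdz = ds;
  return s;
}

inline bool in_sector(double x, double y, const Geom& G) {
  double r = std::sqrt(x * x + y * y);
  if (r < 1e-9) return true;
  return (x / r) >= G.sector_cos; // sector centered on +x
}

// Confined channel region (tunnel exit gap + translocon) where nascent
// chain beads cannot pass one another: single-file ordering.
inline bool in_channel(double x, double y, double z, const Geom& G) {
  if (z >= G.z_tun_bot || z <= G.z_mem_bot - 0.5) return false;
  return x * x + y * y < G.r_free * G.r_free;
}

inline bool lipid_accessible(double x, double y, bool gate_open, const Geom& G) {
  double r2 = x * x + y * y;
  if (r2 >= G.r_free * G.r_free) return true;
  return gate_open && in_sector(x, y, G);
}

// Per-bead field energy (walls + transfer + electrostatics); adds -dU to f.
double bead_field_energy(double x, double y, double z, double h, double q,
                         bool gate_open, const Geom& G, const Par& P,
                         double* fx, double* fy, double* fz) {
  double U = 0;
  double r = std::sqrt(x * x + y * y);
  double thick = G.z_mem_top - G.z_mem_bot;

  // ceiling above the anchor plane
  if (z > G.z_tun_top) {
    double p = z - G.z_tun_top;
    U += 0.5 * P.k_wall * p * p;
    if (fz) *fz -= P.k_wall * p;
  }

  // ribosome body: tunnel z-range is solid outside the tunnel radius;
  // escape routes: radially back in, or down through the gap below
  if (z > G.z_tun_bot && z <= G.z_tun_top && r > G.r_tunnel) {
    double p_r = r - G.r_tunnel;
    double p_z = z - G.z_tun_bot;
    if (p_r <= p_z) {
      U += 0.5 * P.k_wall * p_r * p_r;
      if (fx && r > 1e-9) {
        *fx -= P.k_wall * p_r * x / r;
        *fy -= P.k_wall * p_r * y / r;
      }
    } else {
      U += 0.5 * P.k_wall * p_z * p_z;
      if (fz) *fz -= P.k_wall * p_z;
    }
  }

  // membrane slab: forbidden lipid unless accessible
  if (z > G.z_mem_bot && z < G.z_mem_top && r > G.r_pore &&
      !lipid_accessible(x, y, gate_open, G)) {
    double p_up = G.z_mem_top - z;
    double p_dn = z - G.z_mem_bot;
    double p_in = r - G.r_pore;
    if (p_in <= p_up && p_in <= p_dn) {
      U += 0.5 * P.k_wall * p_in * p_in;
      if (fx && r > 1e-9) {
        *fx -= P.k_wall * p_in * x / r;
        *fy -= P.k_wall * p_in * y / r;
      }
    } else if (p_up <= p_dn) {
      U += 0.5 * P.k_wall * p_up * p_up;
      if (fz) *fz += P.k_wall * p_up;
    } else {
      U += 0.5 * P.k_wall * p_dn * p_dn;
      if (fz) *fz -= P.k_wall * p_dn;
    }
  }

  // headgroup barrier: crossing either membrane face outside the pore
  // costs energy, so the lipid interior is reached through the lateral
  // gate (from inside the channel) rather than from the aqueous faces
  if (P.k_head > 0) {
    const double w = 0.15;
    double dz_t = z - G.z_mem_top;
    double dz_b = z - G.z_mem_bot;
    double bump = 0, dbump = 0;
    if (std::abs(dz_t) < 3 * w) {
      double e = std::exp(-dz_t * dz_t / (2 * w * w));
      bump += e;
      dbump += e * (-dz_t / (w * w));
    }
    if (std::abs(dz_b) < 3 * w) {
      double e = std::exp(-dz_b * dz_b / (2 * w * w));
      bump += e;
      dbump += e * (-dz_b / (w * w));
    }
    if (bump > 0) {
      double dsr;
      double sr = smoothstep(r - G.r_pore, G.r_switch_w, &dsr);
      U += P.k_head * sr * bump;
      if (fz) *fz -= P.k_head * sr * dbump;
      if (fx && r > 1e-9) {
        *fx -= P.k_head * bump * dsr * x / r;
        *fy -= P.k_head * bump * dsr * y / r;
      }
    }
  }

  // transfer free energy: h * depth(z) * radial_switch(r)
  if (h != 0 && z > G.z_mem_bot && z < G.z_mem_top) {
    double dsdz, dsr;
    double sz = slab_depth(z, G, &dsdz);
    double sr = smoothstep(r - G.r_pore, G.r_switch_w, &dsr);
    U += h * sz * sr;
    if (fz) *fz -= h * dsdz * sr;
    if (fx && r > 1e-9) {
      *fx -= h * sz * dsr * x / r;
      *fy -= h * sz * dsr * y / r;
    }
  }

  // electrostatics: potential 0 in cytoplasm (above slab), -volt in
  // periplasm (below); linear across the slab. With volt = -0.1 V the
  // periplasm is +100 mV relative to the cytoplasm and exporting +1
  // charge costs 0.1 eV = 2.31 kcal/mol.
  if (q != 0 && P.volt != 0) {
    double frac; // 0 cytoplasmic side -> 1 periplasmic side
    if (z >= G.z_mem_top) frac = 0;
    else if (z <= G.z_mem_bot) frac = 1;
    else frac = (G.z_mem_top - z) / thick;
    U += q * (-P.volt) * KCAL_PER_EV * frac;
    // dU/dz = -q(-volt)K/thick, so the force on a positive charge points
    // up (toward the cytoplasm) when the potential is negative inside
    if (fz && z > G.z_mem_bot && z < G.z_mem_top)
      *fz += q * (-P.volt) * KCAL_PER_EV / thick;
  }
  return U;
}

// Gate-occupancy coupling: sum of h over beads inside the gate region.
double gate_occupancy_h(const std::vector<double>& px,
                        const std::vector<double>& py,
                        const std::vector<double>& pz,
                        const std::vector<double>& h, int n, const Geom& G) {
  double s = 0;
  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(px[i] * px[i] + py[i] * py[i]);
    if (pz[i] > G.z_mem_bot && pz[i] < G.z_gate_top && r < G.r_gate_region)
      s += (h[i] < 0 ? h[i] : 0); // only hydrophobic beads bias the gate
  }
  return s;
}

// Gate-state-dependent part of the total energy (used for flip moves):
// wall energies of all beads under that state, plus the open-state bias.
double gate_state_energy(const std::vector<double>& px,
                         const std::vector<double>& py,
                         const std::vector<double>& pz,
                         const std::vector<double>& h, int n, bool open,
                         const Geom& G, const Par& P) {
  double U = 0;
  for (int i = 0; i < n; ++i)
    U += bead_field_energy(px[i], py[i], pz[i], 0.0, 0.0, open, G, P,
                           nullptr, nullptr, nullptr);
  if (open) U += P.gate_dG0 + P.gate_coupling *
                   gate_occupancy_h(px, py, pz, h, n, G);
  return U;
}

Geom geom_from_list(const List& g) {
  Geom G;
  G.z_mem_top = as<double>(g["z_mem_top"]);
  G.z_mem_bot = as<double>(g["z_mem_bot"]);
  G.r_pore = as<double>(g["r_pore"]);
  G.r_tunnel = as<double>(g["r_tunnel"]);
  G.z_tun_bot = as<double>(g["z_tun_bot"]);
  G.z_tun_top = as<double>(g["z_tun_top"]);
  G.taper_w = as<double>(g["taper_w"]);
  G.r_switch_w = as<double>(g["r_switch_w"]);
  G.r_free = as<double>(g["r_free"]);
  G.sector_cos = std::cos(as<double>(g["sector_halfwidth_rad"]));
  G.r_gate_region = as<double>(g["r_gate_region"]);
  G.z_gate_top = as<double>(g["z_gate_top"]);
  return G;
}

Par par_from_list(const List& p) {
  Par P;
  P.dt = as<double>(p["dt"]);
  P.D = as<double>(p["D"]);
  P.kBT = as<double>(p["kBT"]);
  P.k_bond = as<double>(p["k_bond"]);
  P.r_bond = as<double>(p["r_bond"]);
  P.k_anchor = as<double>(p["k_anchor"]);
  P.k_wall = as<double>(p["k_wall"]);
  P.k_excl = as<double>(p["k_excl"]);
  P.d_excl = as<double>(p["d_excl"]);
  P.k_head = as<double>(p["k_head"]);
  P.volt = as<double>(p["volt"]);
  P.gate_dG0 = as<double>(p["gate_dG0"]);
  P.gate_coupling = as<double>(p["gate_coupling"]);
  P.gate_interval = as<int>(p["gate_interval"]);
  return P;
}

} // namespace

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, NumericVector h,
                            NumericVector q, List geom, List par,
                            bool gate_open) {
  Geom G = geom_from_list(geom);
  Par P = par_from_list(par);
  int n = pos.nrow();
  double U = 0;
  for (int i = 0; i < n; ++i)
    U += bead_field_energy(pos(i, 0), pos(i, 1), pos(i, 2), h[i], q[i],
                           gate_open, G, P, nullptr, nullptr, nullptr);
  for (int i = 0; i + 1 < n; ++i) {
    double dx = pos(i + 1, 0) - pos(i, 0);
    double dy = pos(i + 1, 1) - pos(i, 1);
    double dz = pos(i + 1, 2) - pos(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double s = d - P.r_bond;
    U += 0.5 * P.k_bond * s * s;
  }
  if (P.k_excl > 0) {
    for (int i = 0; i < n; ++i) {
      if (!in_channel(pos(i, 0), pos(i, 1), pos(i, 2), G)) continue;
      for (int j = i + 2; j < n; ++j) {
        if (!in_channel(pos(j, 0), pos(j, 1), pos(j, 2), G)) continue;
        double dx = pos(j, 0) - pos(i, 0);
        double dy = pos(j, 1) - pos(i, 1);
        double dz = pos(j, 2) - pos(i, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < P.d_excl * P.d_excl) {
          double d = std::sqrt(d2);
          double pen = P.d_excl - d;
          U += 0.5 * P.k_excl * pen * pen;
        }
      }
    }
  }
  if (gate_open) {
    std::vector<double> px(n), py(n), pz(n), hh(h.begin(), h.end());
    for (int i = 0; i < n; ++i) {
      px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    }
    U += P.gate_dG0 +
         P.gate_coupling * gate_occupancy_h(px, py, pz, hh, n, G);
  }
  return U;
}

// Main engine: grow the chain bead by bead, then sample the anchor force.
// h, q: per-bead hydrophobicity (kcal/mol) and charge of the full arrested
// chain, N-terminal bead first; the last bead present is anchored.
// [[Rcpp::export]]
List cpp_run_arrested(NumericVector h, NumericVector q, List geom, List par,
                      int n_beads_init, int growth_interval_steps,
                      int equil_steps, int sample_interval_steps,
                      int n_samples, double seed) {
  Geom G = geom_from_list(geom);
  Par P = par_from_list(par);
  const int n_final = h.size();
  if (n_beads_init < 1 || n_beads_init > n_final)
    stop("invalid initial bead count");

  Rng rng(static_cast<uint64_t>(seed));

  std::vector<double> px(n_final), py(n_final), pz(n_final);
  int n = n_beads_init;
  for (int i = 0; i < n; ++i) {
    px[i] = 0; py[i] = 0;
    pz[i] = G.z_tun_top - P.r_bond * (n - 1 - i);
  }
  bool gate_open = false;

  const double mob = P.D / P.kBT * P.dt;
  const double noise = std::sqrt(2.0 * P.D * P.dt);
  const double anchor_z = G.z_tun_top;

  std::vector<double> fx(n_final), fy(n_final), fz(n_final);
  std::vector<double> hh(h.begin(), h.end());

  long gate_attempts = 0, gate_open_count = 0;
  NumericVector force_samples(n_samples);
  int sample_idx = 0;

  long growth_steps = static_cast<long>(n_final - n_beads_init) *
                      growth_interval_steps;
  long total_steps = growth_steps + equil_steps +
                     static_cast<long>(n_samples) * sample_interval_steps;

  for (long step = 1; step <= total_steps; ++step) {
    // translation: add the next bead at the anchor
    if (n < n_final && growth_interval_steps > 0 &&
        step <= growth_steps && step % growth_interval_steps == 0) {
      // nudge the released bead down-tunnel if it overlaps the anchor
      double d = std::abs(pz[n - 1] - anchor_z) +
                 std::sqrt(px[n - 1] * px[n - 1] + py[n - 1] * py[n - 1]);
      if (d < 0.05) pz[n - 1] = anchor_z - 0.4;
      px[n] = 0; py[n] = 0; pz[n] = anchor_z;
      ++n;
    }

    // forces
    for (int i = 0; i < n; ++i) { fx[i] = fy[i] = fz[i] = 0; }
    for (int i = 0; i < n; ++i)
      bead_field_energy(px[i], py[i], pz[i], h[i], q[i], gate_open, G, P,
                        &fx[i], &fy[i], &fz[i]);
    for (int i = 0; i + 1 < n; ++i) {
      double dx = px[i + 1] - px[i];
      double dy = py[i + 1] - py[i];
      double dz = pz[i + 1] - pz[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-9) continue;
      double fmag = P.k_bond * (d - P.r_bond) / d;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[i + 1] -= fmag * dx; fy[i + 1] -= fmag * dy; fz[i + 1] -= fmag * dz;
    }
    // single-file excluded volume inside the channel region
    if (P.k_excl > 0) {
      for (int i = 0; i < n; ++i) {
        if (!in_channel(px[i], py[i], pz[i], G)) continue;
        for (int j = i + 2; j < n; ++j) {
          if (!in_channel(px[j], py[j], pz[j], G)) continue;
          double dx = px[j] - px[i];
          double dy = py[j] - py[i];
          double dz = pz[j] - pz[i];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < P.d_excl * P.d_excl && d2 > 1e-12) {
            double d = std::sqrt(d2);
            double fmag = P.k_excl * (P.d_excl - d) / d;
            fx[j] += fmag * dx; fy[j] += fmag * dy; fz[j] += fmag * dz;
            fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
          }
        }
      }
    }

    // anchor restraint on the current C-terminal bead
    {
      int a = n - 1;
      fx[a] += -P.k_anchor * px[a];
      fy[a] += -P.k_anchor * py[a];
      fz[a] += -P.k_anchor * (pz[a] - anchor_z);
    }

    for (int i = 0; i < n; ++i) {
      px[i] += mob * fx[i] + noise * rng.gauss();
      py[i] += mob * fy[i] + noise * rng.gauss();
      pz[i] += mob * fz[i] + noise * rng.gauss();
    }

    // lateral-gate Metropolis flip
    if (P.gate_interval > 0 && step % P.gate_interval == 0) {
      double dU = gate_state_energy(px, py, pz, hh, n, !gate_open, G, P) -
                  gate_state_energy(px, py, pz, hh, n, gate_open, G, P);
      if (dU <= 0 || rng.unif() < std::exp(-dU / P.kBT)) gate_open = !gate_open;
      ++gate_attempts;
      if (gate_open) ++gate_open_count;
    }

    // force sampling after growth + equilibration
    long post = step - growth_steps - equil_steps;
    if (post > 0 && post % sample_interval_steps == 0 &&
        sample_idx < n_samples) {
      // tension on the anchored C-terminus, positive = pulled toward the
      // membrane (bead displaced below the anchor)
      force_samples[sample_idx++] = P.k_anchor * (anchor_z - pz[n - 1]);
    }
  }

  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = px[i]; final_pos(i, 1) = py[i]; final_pos(i, 2) = pz[i];
  }
  double mean_force = 0;
  for (int s = 0; s < n_samples; ++s) mean_force += force_samples[s];
  mean_force /= n_samples;
  double open_frac = gate_attempts > 0
                         ? static_cast<double>(gate_open_count) /
                               static_cast<double>(gate_attempts)
                         : NA_REAL;
  return List::create(
      _["force_samples"] = force_samples, _["mean_force"] = mean_force,
      _["gate_open_fraction"] = open_frac, _["final_pos"] = final_pos,
      _["n_beads"] = n);
}

// Free 3-D diffusion: displacement of n_walkers after n_steps.
// [[Rcpp::export]]
NumericMatrix cpp_free_diffusion(int n_walkers, int n_steps, double dt,
                                 double D, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double noise = std::sqrt(2.0 * D * dt);
  NumericMatrix out(n_walkers, 3);
  for (int w = 0; w < n_walkers; ++w) {
    double x = 0, y = 0, z = 0;
    for (int s = 0; s < n_steps; ++s) {
      x += noise * rng.gauss();
      y += noise * rng.gauss();
      z += noise * rng.gauss();
    }
    out(w, 0) = x; out(w, 1) = y; out(w, 2) = z;
  }
  return out;
}

// 1-D overdamped Langevin in U(x) = c1*x + c2*x^2 + c4*(x^2-1)^2;
// returns every `thin`-th position after `burn` steps.
// [[Rcpp::export]]
NumericVector cpp_sim_1d(long n_steps, double dt, double D, double kBT,
                         double c1, double c2, double c4, double x0,
                         long burn, int thin, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double mob = D / kBT * dt;
  double noise = std::sqrt(2.0 * D * dt);
  std::vector<double> keep;
  keep.reserve((n_steps - burn) / thin + 1);
  double x = x0;
  for (long s = 1; s <= n_steps; ++s) {
    double F = -(c1 + 2 * c2 * x + 4 * c4 * x * (x * x - 1));
    x += mob * F + noise * rng.gauss();
    if (s > burn && (s - burn) % thin == 0) keep.push_back(x);
  }
  return NumericVector(keep.begin(), keep.end());
}

// Gate-only Metropolis on a static chain; returns the open fraction.
// [[Rcpp::export]]
double cpp_gate_equilibrium(NumericMatrix pos, NumericVector h, List geom,
                            List par, long n_attempts, double seed) {
  Geom G = geom_from_list(geom);
  Par P = par_from_list(par);
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), hh(h.begin(), h.end());
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
  }
  Rng rng(static_cast<uint64_t>(seed));
  bool open = false;
  long open_count = 0;
  for (long a = 0; a < n_attempts; ++a) {
    double dU = gate_state_energy(px, py, pz, hh, n, !open, G, P) -
                gate_state_energy(px, py, pz, hh, n, open, G, P);
    if (dU <= 0 || rng.unif() < std::exp(-dU / P.kBT)) open = !open;
    if (open) ++open_count;
  }
  return (double)open_count / n_attempts;
}
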