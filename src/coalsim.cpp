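// Two-population isolation(-with-migration) coalescent with finite-sites HKY
// mutation, plus the fast paths used by the hierarchical-ABC reference table,
// the assemblage IM reference table, and the fixed-S neutrality nulls.
//
// Conventions (shared with the R side, see the methods vignette):
//  * time is measured in units of 4*N_ave generations, where N_ave is the
//    reference size defined by theta_ave = 4*N_ave*mu (per site);
//  * a deme with per-site theta_i has pairwise coalescence rate
//    2*theta_ave/theta_i, i.e. k lineages coalesce at rate k*(k-1)*theta_ave/theta_i;
//  * mutations accrue at rate theta_ave per site per unit time on every branch,
//    independent of the deme's theta (the msBayes clock: divergence depends on
//    tau, not on the pair's population size);
//  * all randomness comes from R's RNG, so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <map>
#include <string>
using namespace Rcpp;

// ---------------------------------------------------------------- numerics --

static double harmonic1(int m) {
  double s = 0.0;
  for (int i = 1; i <= m; ++i) s += 1.0 / i;
  return s;
}
static double harmonic2(int m) {
  double s = 0.0;
  for (int i = 1; i <= m; ++i) s += 1.0 / (double(i) * i);
  return s;
}

struct TajC { double a1, e1, e2; };

static TajC tajima_constants(int n) {
  TajC tc;
  double a1 = harmonic1(n - 1), a2 = harmonic2(n - 1);
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * ((double)n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  tc.a1 = a1;
  tc.e1 = c1 / a1;
  tc.e2 = c2 / (a1 * a1 + a2);
  return tc;
}

// [[Rcpp::export]]
NumericVector cpp_tajima_constants(int n) {
  TajC tc = tajima_constants(n);
  return NumericVector::create(_["a1"] = tc.a1, _["e1"] = tc.e1, _["e2"] = tc.e2);
}

static int sample_int(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// ------------------------------------------------------ genealogy + mutation --

struct PairSim {
  int ntips;
  int nsites;                      // mutated sites only
  std::vector<int> site_pos;       // sorted positions in [0, L)
  std::vector<unsigned char> tips; // ntips x nsites, base codes 0=A 1=C 2=G 3=T
};

struct Mut { int node; int site_idx; double time; };

// coalesce two uniformly chosen members of `act` at time t
static void do_coalesce(std::vector<int>& act, double t, int& nxt,
                        std::vector<double>& ntime, std::vector<int>& parent) {
  int k = (int)act.size();
  int i = sample_int(k);
  int j = sample_int(k - 1);
  if (j >= i) ++j;
  int a = act[i], b = act[j];
  ntime[nxt] = t;
  parent[a] = nxt;
  parent[b] = nxt;
  if (i > j) std::swap(i, j);
  act.erase(act.begin() + j);
  act[i] = nxt;
  ++nxt;
}

// next coalescence time for k lineages in a deme whose present-day size
// parameter is th (hazard base a = k(k-1)*th_ave/th), backward-exponential
// growth exponent g (size shrinks as exp(-g*t) back in time, i.e. hazard
// grows as exp(+g*t)), starting from absolute time t0; R_PosInf if no event
static double next_coal_time(double k, double a, double g, double t0) {
  if (k < 2 || a <= 0) return R_PosInf;
  if (!R_finite(a)) return t0; // zero-size deme: instant coalescence
  double E = exp_rand();
  double rate = k * (k - 1.0) * a;
  if (g <= 0) return t0 + E / rate;
  // integrated hazard (rate/g)*(exp(g t) - exp(g t0)) = E
  double x = std::exp(g * t0) + g * E / rate;
  return std::log(x) / g;
}

static void sim_pair(int n1, int n2, int L,
                     double th1, double th2, double thA,
                     double tau, double m1, double m2,
                     double th_ave, double kappa, const double* freqs,
                     PairSim& out,
                     double b1frac = 1.0, double b2frac = 1.0) {
  if (L <= 0) stop("sequence length must be positive");
  const int ntips = n1 + n2;
  const int nn = 2 * ntips - 1;
  std::vector<double> ntime(nn, 0.0);
  std::vector<int> parent(nn, -1);
  std::vector<int> act1, act2;
  act1.reserve(ntips); act2.reserve(ntips);
  for (int i = 0; i < n1; ++i) act1.push_back(i);
  for (int i = 0; i < n2; ++i) act2.push_back(n1 + i);
  int nxt = ntips;
  double t = 0.0;
  const double c1 = th1 > 0 ? th_ave / th1 : R_PosInf;
  const double c2 = th2 > 0 ? th_ave / th2 : R_PosInf;
  const double cA = thA > 0 ? th_ave / thA : R_PosInf;
  // founding bottleneck: descendant deme i is at fraction b_i of its present
  // size from tau back to g_end = 0.75*tau, and grows exponentially over the
  // most recent 0.75*tau. b = 1 disables the phase (constant size).
  const double g_end = 0.75 * tau;
  const double g1 = (b1frac < 1.0 && g_end > 0) ? -std::log(b1frac) / g_end : 0.0;
  const double g2 = (b2frac < 1.0 && g_end > 0) ? -std::log(b2frac) / g_end : 0.0;

  // phase 1: two demes, until tau
  while (t < tau) {
    int phase = (t < g_end) ? 0 : 1;
    double phase_end = (phase == 0) ? g_end : tau;
    double a1 = c1, a2 = c2, gg1 = 0.0, gg2 = 0.0;
    if (phase == 0) { gg1 = g1; gg2 = g2; }
    else { // bottleneck plateau at fraction b of present size
      if (R_finite(a1)) a1 = c1 / b1frac;
      if (R_finite(a2)) a2 = c2 / b2frac;
    }
    double k1 = (double)act1.size(), k2 = (double)act2.size();
    double tc1 = next_coal_time(k1, a1, gg1, t);
    double tc2 = next_coal_time(k2, a2, gg2, t);
    double tm1 = (k1 > 0 && m1 > 0) ? t + exp_rand() / (k1 * m1) : R_PosInf;
    double tm2 = (k2 > 0 && m2 > 0) ? t + exp_rand() / (k2 * m2) : R_PosInf;
    double tmin = std::min(std::min(tc1, tc2), std::min(tm1, tm2));
    if (tmin >= tau) { t = tau; break; }
    if (tmin >= phase_end) { t = phase_end; continue; }
    t = tmin;
    if (tmin == tc1) {
      do_coalesce(act1, t, nxt, ntime, parent);
    } else if (tmin == tc2) {
      do_coalesce(act2, t, nxt, ntime, parent);
    } else if (tmin == tm1) {
      int i = sample_int((int)act1.size());
      act2.push_back(act1[i]);
      act1.erase(act1.begin() + i);
    } else {
      int i = sample_int((int)act2.size());
      act1.push_back(act2[i]);
      act2.erase(act2.begin() + i);
    }
  }
  t = std::max(t, tau);

  // phase 2: merged ancestral deme
  for (size_t i = 0; i < act2.size(); ++i) act1.push_back(act2[i]);
  act2.clear();
  while (act1.size() > 1) {
    double k = (double)act1.size();
    if (R_finite(cA)) t += exp_rand() / (k * (k - 1.0) * cA);
    do_coalesce(act1, t, nxt, ntime, parent);
  }
  const int root = act1[0];

  // mutations: Poisson on total tree length
  std::vector<double> cumbl(nn, 0.0);
  double TL = 0.0;
  for (int i = 0; i < nn; ++i) {
    if (i != root) TL += ntime[parent[i]] - ntime[i];
    cumbl[i] = TL;
  }
  int nmut = (TL > 0 && th_ave > 0) ? (int)R::rpois(TL * th_ave * (double)L) : 0;

  std::vector<Mut> muts;
  muts.reserve(nmut);
  std::vector<int> pos_tmp;
  pos_tmp.reserve(nmut);
  for (int m = 0; m < nmut; ++m) {
    double u = unif_rand() * TL;
    int b = (int)(std::lower_bound(cumbl.begin(), cumbl.end(), u) - cumbl.begin());
    if (b >= nn) b = nn - 1;
    if (b == root) continue; // zero-length root "branch" (cannot happen, guard)
    Mut mm;
    mm.node = b;
    int pos = (int)(unif_rand() * L);
    if (pos >= L) pos = L - 1;
    mm.site_idx = pos; // holds position for now
    double lo = ntime[b], hi = ntime[parent[b]];
    mm.time = lo + unif_rand() * (hi - lo);
    muts.push_back(mm);
    pos_tmp.push_back(pos);
  }

  std::sort(pos_tmp.begin(), pos_tmp.end());
  pos_tmp.erase(std::unique(pos_tmp.begin(), pos_tmp.end()), pos_tmp.end());
  const int ns = (int)pos_tmp.size();
  out.ntips = ntips;
  out.nsites = ns;
  out.site_pos = pos_tmp;
  out.tips.assign((size_t)ntips * ns, 0);
  if (ns == 0) {
    // still need bases for full-sequence output; handled by caller via freqs
    return;
  }
  for (size_t m = 0; m < muts.size(); ++m) {
    muts[m].site_idx = (int)(std::lower_bound(pos_tmp.begin(), pos_tmp.end(),
                                              muts[m].site_idx) - pos_tmp.begin());
  }

  // group mutations by branch, oldest (largest time) first within a branch
  std::sort(muts.begin(), muts.end(), [](const Mut& a, const Mut& b) {
    if (a.node != b.node) return a.node < b.node;
    return a.time > b.time;
  });
  std::vector<int> moff(nn + 1, 0);
  for (size_t m = 0; m < muts.size(); ++m) moff[muts[m].node + 1]++;
  for (int i = 0; i < nn; ++i) moff[i + 1] += moff[i];

  // evolve states root -> tips in one flat buffer; a parent always has a
  // larger node index than its children, so a single descending pass works
  std::vector<unsigned char> state((size_t)nn * ns);
  double cf[4];
  cf[0] = freqs[0];
  for (int b = 1; b < 4; ++b) cf[b] = cf[b - 1] + freqs[b];
  unsigned char* rootst = &state[(size_t)root * ns];
  for (int s = 0; s < ns; ++s) {
    double u = unif_rand() * cf[3];
    int b = 0;
    while (b < 3 && u > cf[b]) ++b;
    rootst[s] = (unsigned char)b;
  }
  for (int node = nn - 2; node >= 0; --node) {
    unsigned char* st = &state[(size_t)node * ns];
    std::copy(&state[(size_t)parent[node] * ns],
              &state[(size_t)parent[node] * ns] + ns, st);
    // HKY jumps; transition iff (a ^ b) == 2 with A=0 C=1 G=2 T=3
    for (int m = moff[node]; m < moff[node + 1]; ++m) {
      int s = muts[m].site_idx;
      int a = st[s];
      double w[4], tot = 0.0;
      for (int b = 0; b < 4; ++b) {
        w[b] = (b == a) ? 0.0 : freqs[b] * (((a ^ b) == 2) ? kappa : 1.0);
        tot += w[b];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int nb = 0;
      for (int b = 0; b < 4; ++b) { acc += w[b]; if (u <= acc) { nb = b; break; } }
      st[s] = (unsigned char)nb;
    }
  }
  std::copy(state.begin(), state.begin() + (size_t)ntips * ns,
            out.tips.begin());
}

// --------------------------------------------------------------- statistics --

// out[0..10]: pi, netpi_raw, theta_w, tajd_denom, inv_tajd, S, pi1, pi2, dxy,
//             tajima_d (NA if S==0), d_defined (0/1)
static void pair_stats_from(const PairSim& ps, int n1, int n2, int L,
                            double inv_guard, double* out) {
  const int n = ps.ntips;
  const int ns = ps.nsites;
  double pd_tot = 0.0, pd_1 = 0.0, pd_2 = 0.0, betw = 0.0;
  int S = 0;
  for (int s = 0; s < ns; ++s) {
    int c1[4] = {0, 0, 0, 0}, c2[4] = {0, 0, 0, 0};
    for (int i = 0; i < n1; ++i) c1[ps.tips[(size_t)i * ns + s]]++;
    for (int i = n1; i < n; ++i) c2[ps.tips[(size_t)i * ns + s]]++;
    int nb = 0;
    double same_t = 0.0, same_1 = 0.0, same_2 = 0.0, same_b = 0.0;
    for (int b = 0; b < 4; ++b) {
      int ct = c1[b] + c2[b];
      if (ct > 0) ++nb;
      same_t += 0.5 * ct * (ct - 1.0);
      same_1 += 0.5 * c1[b] * (c1[b] - 1.0);
      same_2 += 0.5 * c2[b] * (c2[b] - 1.0);
      same_b += (double)c1[b] * c2[b];
    }
    if (nb >= 2) ++S;
    pd_tot += 0.5 * n * (n - 1.0) - same_t;
    if (n1 > 1) pd_1 += 0.5 * n1 * (n1 - 1.0) - same_1;
    if (n2 > 1) pd_2 += 0.5 * n2 * (n2 - 1.0) - same_2;
    betw += (double)n1 * n2 - same_b;
  }
  const double prs = 0.5 * n * (n - 1.0);
  double khat = pd_tot / prs;
  double pi = khat / L;
  double pi1 = n1 > 1 ? pd_1 / (0.5 * n1 * (n1 - 1.0)) / L : 0.0;
  double pi2 = n2 > 1 ? pd_2 / (0.5 * n2 * (n2 - 1.0)) / L : 0.0;
  double dxy = betw / ((double)n1 * n2) / L;
  double netpi = dxy - 0.5 * (pi1 + pi2);
  TajC tc = tajima_constants(n);
  double theta_w = S / (tc.a1 * L);
  double s_ps = (double)S / L;
  double denom_ps = S > 0 ? std::sqrt(tc.e1 * s_ps + tc.e2 * s_ps * (s_ps - 1.0)) : 0.0;
  double D = NA_REAL, inv = 0.0;
  int defined = 0;
  if (S > 0) {
    double den = std::sqrt(tc.e1 * S + tc.e2 * S * (S - 1.0));
    if (den > 0 && R_finite(den)) { // n = 3 has e1 = e2 = 0: D undefined
      D = (khat - S / tc.a1) / den;
      defined = 1;
      if (std::fabs(D) < 1e-3) inv = (D >= 0 ? 1.0 : -1.0) * inv_guard;
      else inv = 1.0 / D;
    }
  }
  out[0] = pi; out[1] = netpi; out[2] = theta_w; out[3] = denom_ps;
  out[4] = inv; out[5] = (double)S; out[6] = pi1; out[7] = pi2;
  out[8] = dxy; out[9] = D; out[10] = (double)defined;
}

static void check_freqs(const NumericVector& freqs) {
  if (freqs.size() != 4) stop("freqs must have length 4");
  double s = 0.0;
  for (int i = 0; i < 4; ++i) {
    if (freqs[i] < 0) stop("freqs must be non-negative");
    s += freqs[i];
  }
  if (std::fabs(s - 1.0) > 1e-6) stop("freqs must sum to 1");
}

// [[Rcpp::export]]
NumericVector cpp_sim_pair_stats(int n1, int n2, int L,
                                 double theta1, double theta2, double thetaA,
                                 double tau, double m1, double m2,
                                 double theta_ave, double kappa,
                                 NumericVector freqs, double inv_guard = 1000.0,
                                 double b1frac = 1.0, double b2frac = 1.0) {
  check_freqs(freqs);
  PairSim ps;
  sim_pair(n1, n2, L, theta1, theta2, thetaA, tau, m1, m2,
           theta_ave, kappa, freqs.begin(), ps, b1frac, b2frac);
  NumericVector out(11);
  pair_stats_from(ps, n1, n2, L, inv_guard, out.begin());
  out.attr("names") = CharacterVector::create(
    "pi", "net_pi", "theta_w", "tajd_denom", "inv_tajima_d", "s",
    "pi_1", "pi_2", "dxy", "tajima_d", "d_defined");
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_sim_pair_seqs(int n1, int n2, int L,
                                  double theta1, double theta2, double thetaA,
                                  double tau, double m1, double m2,
                                  double theta_ave, double kappa,
                                  NumericVector freqs,
                                  double b1frac = 1.0, double b2frac = 1.0) {
  check_freqs(freqs);
  PairSim ps;
  sim_pair(n1, n2, L, theta1, theta2, thetaA, tau, m1, m2,
           theta_ave, kappa, freqs.begin(), ps, b1frac, b2frac);
  const char* bases = "ACGT";
  // background (non-mutated) sites shared by all tips
  double cf[4];
  cf[0] = freqs[0];
  for (int b = 1; b < 4; ++b) cf[b] = cf[b - 1] + freqs[b];
  std::string templ(L, 'A');
  for (int s = 0; s < L; ++s) {
    double u = unif_rand() * cf[3];
    int b = 0;
    while (b < 3 && u > cf[b]) ++b;
    templ[s] = bases[b];
  }
  int ntips = n1 + n2;
  CharacterVector out(ntips);
  for (int i = 0; i < ntips; ++i) {
    std::string seq = templ;
    for (int s = 0; s < ps.nsites; ++s)
      seq[ps.site_pos[s]] = bases[ps.tips[(size_t)i * ps.nsites + s]];
    out[i] = seq;
  }
  return out;
}

// -------------------------------------------------- surjective assignments --

// number of ways to assign r items to psi labeled events such that d given
// currently-empty events all end up non-empty (inclusion-exclusion)
static double surj_ways(int r, int d, int psi) {
  double tot = 0.0, C = 1.0;
  for (int j = 0; j <= d; ++j) {
    double term = C * std::pow((double)(psi - j), (double)r);
    tot += (j % 2 == 0) ? term : -term;
    C = C * (d - j) / (j + 1.0);
  }
  return tot;
}

// uniform surjection from K items onto psi events (exact sequential sampler)
static void sample_surjection(int K, int psi, int* ev) {
  std::vector<int> empty_ev, used_ev;
  for (int j = 0; j < psi; ++j) empty_ev.push_back(j);
  for (int p = 0; p < K; ++p) {
    int r = K - p;
    int d = (int)empty_ev.size();
    double W = surj_ways(r, d, psi);
    double wnew = d > 0 ? surj_ways(r - 1, d - 1, psi) : 0.0;
    double u = unif_rand() * W;
    if (d > 0 && u < d * wnew) {
      int i = sample_int(d);
      int e = empty_ev[i];
      ev[p] = e;
      empty_ev.erase(empty_ev.begin() + i);
      used_ev.push_back(e);
    } else {
      ev[p] = used_ev[sample_int((int)used_ev.size())];
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_sample_surjection(int k, int psi) {
  if (psi < 1 || psi > k) stop("psi must be in 1..k");
  IntegerVector ev(k);
  sample_surjection(k, psi, ev.begin());
  for (int i = 0; i < k; ++i) ev[i] += 1;
  return ev;
}

// ------------------------------------------------------- reference tables --

// Row layout (K pairs, pairs sorted ascending by clamped net pi, ties by pi):
//   psi, e_tau, omega, tau[1..K], event_rank[1..K], then per pair the 4-stat
//   block (pi, net_pi_clamped, theta_w, stat4).
// stat4_mode: 0 = per-site Tajima's D denominator, 1 = guarded 1/D.
// [[Rcpp::export]]
NumericMatrix cpp_reference_table(int n_draws, int psi_min, int psi_max,
                                  double tau_upper, double theta_upper,
                                  double anc_upper, double mig_upper,
                                  IntegerVector n1, IntegerVector n2,
                                  IntegerVector L, double theta_ave,
                                  double kappa, NumericVector freqs,
                                  int stat4_mode = 0, double inv_guard = 1000.0,
                                  double bot_lower = 0.01) {
  check_freqs(freqs);
  const int K = n1.size();
  if (n2.size() != K || L.size() != K) stop("n1, n2, L must have equal length");
  if (psi_min < 1 || psi_max > K || psi_min > psi_max) stop("invalid psi range");
  const int ncol = 3 + 2 * K + 4 * K;
  NumericMatrix out(n_draws, ncol);
  std::vector<int> ev(K);
  std::vector<double> taus(K), tau_pair(K), st(11);
  std::vector<int> erank(K), ord(K);
  NumericMatrix pair_stats(K, 4);

  for (int d = 0; d < n_draws; ++d) {
    int psi = psi_min + sample_int(psi_max - psi_min + 1);
    for (int j = 0; j < psi; ++j) taus[j] = unif_rand() * tau_upper;
    sample_surjection(K, psi, &ev[0]);
    // event rank by ascending event time
    std::vector<int> eord(psi);
    for (int j = 0; j < psi; ++j) eord[j] = j;
    std::sort(eord.begin(), eord.end(),
              [&](int a, int b) { return taus[a] < taus[b]; });
    std::vector<int> rank_of(psi);
    for (int j = 0; j < psi; ++j) rank_of[eord[j]] = j + 1;

    double pis[64], netc[64];
    for (int p = 0; p < K; ++p) {
      tau_pair[p] = taus[ev[p]];
      erank[p] = rank_of[ev[p]];
      double th_p = unif_rand() * theta_upper;
      double b = unif_rand();
      double th1 = 2.0 * b * th_p;
      double th2 = 2.0 * (1.0 - b) * th_p;
      double thA = unif_rand() * anc_upper * th_p;
      double mig = mig_upper > 0 ? unif_rand() * mig_upper : 0.0;
      double b1f = bot_lower < 1.0 ? bot_lower + unif_rand() * (1.0 - bot_lower) : 1.0;
      double b2f = bot_lower < 1.0 ? bot_lower + unif_rand() * (1.0 - bot_lower) : 1.0;
      PairSim ps;
      sim_pair(n1[p], n2[p], L[p], th1, th2, thA, tau_pair[p], mig, mig,
               theta_ave, kappa, freqs.begin(), ps, b1f, b2f);
      pair_stats_from(ps, n1[p], n2[p], L[p], inv_guard, &st[0]);
      double netpi = st[1] < 0 ? 0.0 : st[1];
      pair_stats(p, 0) = st[0];
      pair_stats(p, 1) = netpi;
      pair_stats(p, 2) = st[2];
      pair_stats(p, 3) = stat4_mode == 0 ? st[3] : st[4];
      pis[p] = st[0];
      netc[p] = netpi;
    }
    // sort pairs ascending by net pi, ties by pi
    for (int p = 0; p < K; ++p) ord[p] = p;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (netc[a] != netc[b]) return netc[a] < netc[b];
      return pis[a] < pis[b];
    });
    double mtau = 0.0;
    for (int p = 0; p < K; ++p) mtau += tau_pair[p];
    mtau /= K;
    double vtau = 0.0;
    for (int p = 0; p < K; ++p) {
      double dd = tau_pair[p] - mtau;
      vtau += dd * dd;
    }
    vtau /= K; // population variance, pairs as units
    out(d, 0) = (double)psi;
    out(d, 1) = mtau;
    out(d, 2) = mtau > 0 ? vtau / mtau : 0.0;
    for (int p = 0; p < K; ++p) {
      int q = ord[p];
      out(d, 3 + p) = tau_pair[q];
      out(d, 3 + K + p) = (double)erank[q];
      for (int s = 0; s < 4; ++s) out(d, 3 + 2 * K + 4 * p + s) = pair_stats(q, s);
    }
  }
  return out;
}

// Assemblage IM reference table.
// Parameters per draw: theta1, theta2, thetaA (per-site, reference species),
// t_site (per-site mutation-scaled divergence time), m1, m2, h_2..h_K.
// Per-species summaries: pi1, pi2, dxy, net_pi, s_per_site, tajima_d (0 if undef).
// [[Rcpp::export]]
NumericMatrix cpp_assemblage_table(int n_draws,
                                   IntegerVector n1, IntegerVector n2,
                                   IntegerVector L,
                                   double theta_upper, double thetaA_upper,
                                   double t_upper, double mig_upper,
                                   double h_min, double theta_ave,
                                   double kappa, NumericVector freqs) {
  check_freqs(freqs);
  const int K = n1.size();
  if (n2.size() != K || L.size() != K) stop("n1, n2, L must have equal length");
  const int npar = 6 + (K - 1);
  const int ncol = npar + 6 * K;
  NumericMatrix out(n_draws, ncol);
  std::vector<double> st(11), h(K);
  for (int d = 0; d < n_draws; ++d) {
    double th1 = unif_rand() * theta_upper;
    double th2 = unif_rand() * theta_upper;
    double thA = unif_rand() * thetaA_upper;
    double ts = unif_rand() * t_upper;
    double mm1 = mig_upper > 0 ? unif_rand() * mig_upper : 0.0;
    double mm2 = mig_upper > 0 ? unif_rand() * mig_upper : 0.0;
    h[0] = 1.0;
    for (int s = 1; s < K; ++s) h[s] = h_min + unif_rand() * (1.0 - h_min);
    double tau = theta_ave > 0 ? ts / theta_ave : 0.0;
    out(d, 0) = th1; out(d, 1) = th2; out(d, 2) = thA;
    out(d, 3) = ts; out(d, 4) = mm1; out(d, 5) = mm2;
    for (int s = 1; s < K; ++s) out(d, 5 + s) = h[s];
    for (int s = 0; s < K; ++s) {
      PairSim ps;
      sim_pair(n1[s], n2[s], L[s], th1 * h[s], th2 * h[s], thA * h[s],
               tau, mm1, mm2, theta_ave, kappa, freqs.begin(), ps);
      pair_stats_from(ps, n1[s], n2[s], L[s], 1000.0, &st[0]);
      int base = npar + 6 * s;
      out(d, base + 0) = st[6];                       // pi1
      out(d, base + 1) = st[7];                       // pi2
      out(d, base + 2) = st[8];                       // dxy
      out(d, base + 3) = st[1];                       // net pi (raw)
      out(d, base + 4) = st[5] / (double)L[s];        // S per site
      out(d, base + 5) = st[10] > 0 ? st[9] : 0.0;    // Tajima's D, 0 if undef
    }
  }
  return out;
}

// ----------------------------------------------- fixed-S neutrality nulls --

// Single-population Kingman coalescent conditioned on S segregating sites
// (infinite sites). Returns per replicate: khat (mean pairwise differences),
// number of distinct haplotypes, and Ramos-Onsins & Rozas's R2.
// [[Rcpp::export]]
NumericMatrix cpp_fixed_s_reps(int n, int S, int reps) {
  if (n < 2) stop("n must be >= 2");
  NumericMatrix out(reps, 3);
  const int nn = 2 * n - 1;
  std::vector<double> ntime(nn), blen(nn), cum(nn);
  std::vector<int> parent(nn);
  std::vector<int> ndesc(nn);
  std::vector<std::vector<int> > tipsets(nn);
  for (int r = 0; r < reps; ++r) {
    std::vector<int> act(n);
    for (int i = 0; i < n; ++i) { act[i] = i; ntime[i] = 0.0; }
    std::fill(parent.begin(), parent.end(), -1);
    int nxt = n;
    double t = 0.0;
    while ((int)act.size() > 1) {
      double k = (double)act.size();
      t += exp_rand() / (k * (k - 1.0) * 0.5);
      do_coalesce(act, t, nxt, ntime, parent);
    }
    int root = act[0];
    // descendant tip sets per node
    for (int i = 0; i < nn; ++i) { tipsets[i].clear(); }
    for (int i = 0; i < n; ++i) tipsets[i].push_back(i);
    for (int i = 0; i < nn; ++i) {
      if (i == root) continue;
      // process in index order: parents always have larger index than children
    }
    for (int i = 0; i < nn - 1; ++i) {
      int p = parent[i];
      for (size_t j = 0; j < tipsets[i].size(); ++j) tipsets[p].push_back(tipsets[i][j]);
    }
    double TL = 0.0;
    for (int i = 0; i < nn; ++i) {
      blen[i] = (i == root) ? 0.0 : ntime[parent[i]] - ntime[i];
      TL += blen[i];
      cum[i] = TL;
    }
    // place S mutations, record descendant counts and tip membership
    std::vector<double> U(n, 0.0);
    std::vector<std::vector<int> > tipmut(n);
    double khat = 0.0;
    for (int m = 0; m < S; ++m) {
      double u = unif_rand() * TL;
      int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (b >= nn) b = nn - 1;
      int dct = (int)tipsets[b].size();
      khat += (double)dct * (n - dct) / (0.5 * n * (n - 1.0));
      for (size_t j = 0; j < tipsets[b].size(); ++j) tipmut[tipsets[b][j]].push_back(m);
      if (dct == 1) {
        U[tipsets[b][0]] += 1.0;
      } else if (dct == n - 1) {
        // the single tip carrying the ancestral base has the minority nucleotide
        std::vector<char> in(n, 0);
        for (size_t j = 0; j < tipsets[b].size(); ++j) in[tipsets[b][j]] = 1;
        for (int i = 0; i < n; ++i) if (!in[i]) { U[i] += 1.0; break; }
      }
    }
    // distinct haplotypes
    std::vector<std::vector<int> > sorted_h(tipmut);
    std::sort(sorted_h.begin(), sorted_h.end());
    int nh = (int)(std::unique(sorted_h.begin(), sorted_h.end()) - sorted_h.begin());
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double dd = U[i] - khat / 2.0;
      ss += dd * dd;
    }
    double r2 = S > 0 ? std::sqrt(ss / n) / S : NA_REAL;
    out(r, 0) = khat;
    out(r, 1) = (double)nh;
    out(r, 2) = r2;
  }
  colnames(out) = CharacterVector::create("khat", "n_hap", "r2");
  return out;
}
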