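// Structured-coalescent ancestral recombination graph (ARG) simulator for a
// two-population split-with-bottleneck model with partial selfing and an
// optional star-approximation selective sweep in the cultivated population.
//
// Scaling conventions (all conversions from natural units happen in R):
//   * time is measured in units of 4*N0e generations, N0e the wild effective
//     size after selfing correction;
//   * theta = 4*N0e*mu*L is the full-locus mutation rate;
//   * rho_w / rho_c = 4*N0e*r*(1-F_pop)*L are full-locus effective
//     recombination rates for lineages currently in the wild / cultivated
//     population;
//   * x1 = N1e/N0e is the relative cultivated size; tau1 the split time;
//   * a completed sweep at scaled time stau (<= tau1) makes every cultivated
//     lineage keep, around the sweep site, an interval (pos-El, pos+Er) with
//     El, Er ~ Exp(mean lambda bp); that interval joins an instantaneous star
//     coalescence while the flanks escape as free lineages.  Marginally each
//     site at distance d escapes with probability 1-exp(-d/lambda).
//
// Mutations are laid down lazily: every ancestral segment keeps its birth
// time and descendant set; when the segment dies (coalescence, split, or
// local MRCA) mutations are drawn Poisson(theta * len/L * lifetime).  This is
// exact for the infinite-sites model because a segment's descendant set is
// constant over its lifetime.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

typedef std::array<uint64_t, 2> Mask;  // up to 128 samples

inline int popcnt_and(const Mask &a, const Mask &b) {
  return __builtin_popcountll(a[0] & b[0]) + __builtin_popcountll(a[1] & b[1]);
}
inline Mask mask_or(const Mask &a, const Mask &b) {
  Mask r;
  r[0] = a[0] | b[0];
  r[1] = a[1] | b[1];
  return r;
}
inline bool mask_eq(const Mask &a, const Mask &b) {
  return a[0] == b[0] && a[1] == b[1];
}

struct Seg {
  double l, r;   // [l, r) in bp (continuous)
  Mask d;        // descendant sample set
  double birth;  // scaled time of creation
};

struct Lin {
  std::vector<Seg> segs;  // sorted, non-overlapping
  int pop;                // 0 = wild, 1 = cultivated
  double extent() const { return segs.back().r - segs.front().l; }
};

struct Site {
  double pos;
  Mask d;
};

// Collects mutations either as full site records or as running summaries.
struct Recorder {
  bool full = false;
  double theta_per = 0.0;  // theta / L
  int nw = 0, nc = 0;
  Mask wmask{{0, 0}}, cmask{{0, 0}};
  double piw = 0, pic = 0, dxy = 0;
  int Sw = 0, Sc = 0, Stot = 0;
  std::vector<Site> sites;
  std::mt19937_64 *rng = nullptr;

  void reset() {
    piw = pic = dxy = 0;
    Sw = Sc = Stot = 0;
    sites.clear();
  }

  void hit(const Mask &d, double l, double r) {
    if (full) {
      std::uniform_real_distribution<double> U(l, r);
      sites.push_back(Site{U(*rng), d});
      return;
    }
    const int xw = popcnt_and(d, wmask);
    const int xc = popcnt_and(d, cmask);
    ++Stot;
    if (nw > 1) {
      if (xw > 0 && xw < nw) ++Sw;
      piw += 2.0 * xw * (nw - xw) / (static_cast<double>(nw) * (nw - 1));
    }
    if (nc > 1) {
      if (xc > 0 && xc < nc) ++Sc;
      pic += 2.0 * xc * (nc - xc) / (static_cast<double>(nc) * (nc - 1));
    }
    if (nw > 0 && nc > 0)
      dxy += (xw * static_cast<double>(nc - xc) + xc * static_cast<double>(nw - xw)) /
             (static_cast<double>(nw) * nc);
  }

  void death(const Seg &s, double t) {
    const double dt = t - s.birth;
    if (dt <= 0 || theta_per <= 0) return;
    const double lam = theta_per * (s.r - s.l) * dt;
    if (lam <= 0) return;
    std::poisson_distribution<int> P(lam);
    const int n = P(*rng);
    for (int i = 0; i < n; ++i) hit(s.d, s.l, s.r);
  }
};

struct SimParams {
  int nw, nc;
  double L, theta, rho_w, rho_c;
  double tau1;  // split time; ignored when nc == 0
  double x1;    // N1e / N0e
  bool sweep = false;
  double spos = 0, slam = 0, stau = 0;
};

// Append a merged piece, dropping intervals that reached their local MRCA.
inline void push_piece(Lin &out, double l, double r, const Mask &d, double t,
                       const Mask &fullmask) {
  if (r - l <= 0) return;
  if (mask_eq(d, fullmask)) return;  // local MRCA: interval leaves the ARG
  if (!out.segs.empty()) {
    Seg &b = out.segs.back();
    if (b.r == l && mask_eq(b.d, d) && b.birth == t) {
      b.r = r;
      return;
    }
  }
  out.segs.push_back(Seg{l, r, d, t});
}

// Coalesce two lineages at time t.  All parent segments die (drawing their
// mutations); overlapping intervals merge descendant sets.
void merge_two(Lin A, Lin B, Lin &out, double t, const Mask &fullmask,
               Recorder &rec) {
  for (const Seg &s : A.segs) rec.death(s, t);
  for (const Seg &s : B.segs) rec.death(s, t);
  out.segs.clear();
  size_t i = 0, j = 0;
  while (i < A.segs.size() || j < B.segs.size()) {
    if (j >= B.segs.size() ||
        (i < A.segs.size() && A.segs[i].r <= B.segs[j].l)) {
      push_piece(out, A.segs[i].l, A.segs[i].r, A.segs[i].d, t, fullmask);
      ++i;
      continue;
    }
    if (i >= A.segs.size() ||
        (j < B.segs.size() && B.segs[j].r <= A.segs[i].l)) {
      push_piece(out, B.segs[j].l, B.segs[j].r, B.segs[j].d, t, fullmask);
      ++j;
      continue;
    }
    Seg &a = A.segs[i];
    Seg &b = B.segs[j];
    if (a.l < b.l) {
      push_piece(out, a.l, b.l, a.d, t, fullmask);
      a.l = b.l;
    } else if (b.l < a.l) {
      push_piece(out, b.l, a.l, b.d, t, fullmask);
      b.l = a.l;
    } else {
      const double e = std::min(a.r, b.r);
      push_piece(out, a.l, e, mask_or(a.d, b.d), t, fullmask);
      a.l = e;
      b.l = e;
      if (a.l >= a.r) ++i;
      if (b.l >= b.r) ++j;
    }
  }
}

// Split a lineage at breakpoint bp into left (kept in 'lin') and right
// ('out').  A segment containing bp dies and two children are born at t.
void split_at(Lin &lin, double bp, double t, Lin &out, Recorder &rec) {
  out.segs.clear();
  out.pop = lin.pop;
  std::vector<Seg> left;
  left.reserve(lin.segs.size());
  for (const Seg &s : lin.segs) {
    if (s.r <= bp) {
      left.push_back(s);
    } else if (s.l >= bp) {
      out.segs.push_back(s);
    } else {
      rec.death(s, t);
      left.push_back(Seg{s.l, bp, s.d, t});
      out.segs.push_back(Seg{bp, s.r, s.d, t});
    }
  }
  lin.segs.swap(left);
}

class Simulator {
 public:
  Simulator(const SimParams &p, std::mt19937_64 &rng, Recorder &rec)
      : p_(p), rng_(rng), rec_(rec) {}

  void run() {
    init();
    const int n = p_.nw + p_.nc;
    double t = 0;
    bool sweep_pending = p_.sweep && p_.nc > 0;
    bool merge_pending = p_.nc > 0;
    long iter = 0;
    std::uniform_real_distribution<double> U01(0.0, 1.0);
    resync();

    while (!lin_.empty()) {
      if (++iter > 100000000L)
        stop("coalescent simulation exceeded the event budget");
      if ((iter & 2047L) == 0) resync();  // guard against float drift
      const int k0 = k_[0], k1 = k_[1];
      const double ext0 = std::max(ext_[0], 0.0);
      const double ext1 = std::max(ext_[1], 0.0);
      const double c0 = static_cast<double>(k0) * (k0 - 1);  // x0 = 1
      const double c1 = (k1 > 1) ? static_cast<double>(k1) * (k1 - 1) / p_.x1 : 0.0;
      const double r0 = (p_.rho_w > 0) ? p_.rho_w * ext0 / p_.L : 0.0;
      const double r1 = (p_.rho_c > 0) ? p_.rho_c * ext1 / p_.L : 0.0;
      const double tot = c0 + c1 + r0 + r1;

      double bound = R_PosInf;
      if (sweep_pending) bound = std::min(bound, p_.stau);
      if (merge_pending) bound = std::min(bound, p_.tau1);

      double dt;
      if (tot <= 0) {
        if (!R_FINITE(bound))
          stop("coalescent simulation stalled with zero total rate");
        dt = bound - t + 1.0;  // force the boundary
      } else {
        std::exponential_distribution<double> E(tot);
        dt = E(rng_);
      }

      if (t + dt >= bound) {
        t = bound;
        if (sweep_pending && bound == p_.stau) {
          apply_sweep(t);
          sweep_pending = false;
        } else {
          // population merge: cultivated lineages join the wild population
          for (Lin &l : lin_) l.pop = 0;
          merge_pending = false;
        }
        resync();
        continue;
      }
      t += dt;

      double u = U01(rng_) * tot;
      if (u < c0) {
        coalesce(0, t);
      } else if (u < c0 + c1) {
        coalesce(1, t);
      } else if (u < c0 + c1 + r0) {
        recombine(0, ext0, t);
      } else {
        recombine(1, ext1, t);
      }
      (void)n;
    }
  }

 private:
  void init() {
    lin_.clear();
    lin_.reserve(p_.nw + p_.nc);
    for (int i = 0; i < p_.nw + p_.nc; ++i) {
      Lin l;
      l.pop = (i < p_.nw) ? 0 : 1;
      Mask m{{0, 0}};
      m[i >> 6] = (1ULL << (i & 63));
      l.segs.push_back(Seg{0.0, p_.L, m, 0.0});
      lin_.push_back(std::move(l));
    }
    full_ = Mask{{0, 0}};
    for (int i = 0; i < p_.nw + p_.nc; ++i) full_[i >> 6] |= (1ULL << (i & 63));
  }

  // Recount lineage numbers and extent sums from scratch.
  void resync() {
    k_[0] = k_[1] = 0;
    ext_[0] = ext_[1] = 0;
    for (const Lin &l : lin_) {
      ++k_[l.pop];
      ext_[l.pop] += l.extent();
    }
  }

  void coalesce(int pop, double t) {
    if (k_[pop] < 2) return;
    std::uniform_int_distribution<int> Ui(0, k_[pop] - 1);
    int a = Ui(rng_), b;
    do {
      b = Ui(rng_);
    } while (b == a);
    int ia = -1, ib = -1, seen = 0;
    for (size_t i = 0; i < lin_.size() && (ia < 0 || ib < 0); ++i) {
      if (lin_[i].pop != pop) continue;
      if (seen == a) ia = static_cast<int>(i);
      if (seen == b) ib = static_cast<int>(i);
      ++seen;
    }
    ext_[pop] -= lin_[ia].extent() + lin_[ib].extent();
    Lin out;
    out.pop = pop;
    merge_two(std::move(lin_[ia]), std::move(lin_[ib]), out, t, full_, rec_);
    k_[pop] -= 1;
    if (out.segs.empty()) {
      lin_.erase(lin_.begin() + std::max(ia, ib));
      lin_.erase(lin_.begin() + std::min(ia, ib));
      k_[pop] -= 1;
    } else {
      ext_[pop] += out.extent();
      lin_[ia] = std::move(out);
      lin_.erase(lin_.begin() + ib);
    }
  }

  void recombine(int pop, double ext_tot, double t) {
    std::uniform_real_distribution<double> U(0.0, ext_tot);
    double u = U(rng_);
    int target = -1;
    for (size_t i = 0; i < lin_.size(); ++i) {
      if (lin_[i].pop != pop) continue;
      const double e = lin_[i].extent();
      if (u < e) {
        target = static_cast<int>(i);
        break;
      }
      u -= e;
    }
    if (target < 0) return;  // numerical slack
    Lin &l = lin_[target];
    const double lo = l.segs.front().l, hi = l.segs.back().r;
    std::uniform_real_distribution<double> Ub(lo, hi);
    const double bp = Ub(rng_);
    if (bp <= lo || bp >= hi) return;
    ext_[pop] -= l.extent();
    Lin right;
    split_at(l, bp, t, right, rec_);
    if (!right.segs.empty() && !l.segs.empty()) {
      ext_[pop] += l.extent() + right.extent();
      k_[pop] += 1;
      lin_.push_back(std::move(right));
    } else if (!right.segs.empty() && l.segs.empty()) {
      l = std::move(right);
      ext_[pop] += l.extent();
    } else if (!l.segs.empty()) {
      ext_[pop] += l.extent();
    }
  }

  void apply_sweep(double t) {
    std::exponential_distribution<double> E(1.0 / p_.slam);
    std::vector<Lin> swept;
    std::vector<Lin> keep;
    keep.reserve(lin_.size());
    for (Lin &l : lin_) {
      if (l.pop != 1) {
        keep.push_back(std::move(l));
        continue;
      }
      const double a = p_.spos - E(rng_);
      const double b = p_.spos + E(rng_);
      // partition segments into (<a) escape, [a,b] swept, (>b) escape
      Lin leftout, mid, rightout;
      leftout.pop = mid.pop = rightout.pop = 1;
      for (const Seg &s : l.segs) {
        const bool cut = (s.l < a && s.r > a) || (s.l < b && s.r > b);
        if (cut) rec_.death(s, t);  // pieces restart their mutation clocks
        const double birth = cut ? t : s.birth;
        double cl = s.l;
        if (cl < a) {
          const double e = std::min(s.r, a);
          leftout.segs.push_back(Seg{cl, e, s.d, birth});
          cl = e;
        }
        if (cl < s.r && cl < b) {
          const double e = std::min(s.r, b);
          mid.segs.push_back(Seg{cl, e, s.d, birth});
          cl = e;
        }
        if (cl < s.r) rightout.segs.push_back(Seg{cl, s.r, s.d, birth});
      }
      if (!leftout.segs.empty()) keep.push_back(std::move(leftout));
      if (!rightout.segs.empty()) keep.push_back(std::move(rightout));
      if (!mid.segs.empty()) swept.push_back(std::move(mid));
    }
    lin_.swap(keep);
    if (swept.empty()) return;
    Lin star = std::move(swept[0]);
    star.pop = 1;
    for (size_t i = 1; i < swept.size(); ++i) {
      Lin out;
      out.pop = 1;
      merge_two(std::move(star), std::move(swept[i]), out, t, full_, rec_);
      star = std::move(out);
    }
    if (!star.segs.empty()) lin_.push_back(std::move(star));
  }

  SimParams p_;
  int k_[2] = {0, 0};
  double ext_[2] = {0, 0};
  std::mt19937_64 &rng_;
  Recorder &rec_;
  std::vector<Lin> lin_;
  Mask full_;
};

void setup_recorder(Recorder &rec, const SimParams &p, std::mt19937_64 &rng,
                    bool full) {
  rec.full = full;
  rec.theta_per = (p.L > 0) ? p.theta / p.L : 0.0;
  rec.nw = p.nw;
  rec.nc = p.nc;
  rec.wmask = Mask{{0, 0}};
  rec.cmask = Mask{{0, 0}};
  for (int i = 0; i < p.nw; ++i) rec.wmask[i >> 6] |= (1ULL << (i & 63));
  for (int i = p.nw; i < p.nw + p.nc; ++i) rec.cmask[i >> 6] |= (1ULL << (i & 63));
  rec.rng = &rng;
}

SimParams make_params(int n_wild, int n_cult, double L, double theta,
                      double rho_w, double rho_c, double tau1, double x1,
                      bool sweep, double spos, double slam, double stau) {
  if (n_wild + n_cult < 2 || n_wild + n_cult > 128)
    stop("sample size must be between 2 and 128");
  if (L <= 0) stop("locus length must be positive");
  if (theta < 0 || rho_w < 0 || rho_c < 0) stop("rates must be non-negative");
  if (n_cult > 0 && !(tau1 > 0)) stop("split time must be positive");
  if (n_cult > 0 && !(x1 > 0)) stop("relative bottleneck size must be positive");
  if (sweep && !(slam > 0)) stop("sweep length lambda must be positive");
  if (sweep && (stau <= 0 || stau > tau1))
    stop("sweep fixation time must lie in (0, tau1]");
  SimParams p;
  p.nw = n_wild;
  p.nc = n_cult;
  p.L = L;
  p.theta = theta;
  p.rho_w = rho_w;
  p.rho_c = rho_c;
  p.tau1 = tau1;
  p.x1 = x1;
  p.sweep = sweep;
  p.spos = spos;
  p.slam = slam;
  p.stau = stau;
  return p;
}

}  // namespace

//' @useDynLib sweepqtl, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".cpp_sim_locus")]]
List cpp_sim_locus(int n_wild, int n_cult, double L, double theta,
                   double rho_w, double rho_c, double tau1, double x1,
                   bool sweep, double spos, double slam, double stau,
                   int seed) {
  SimParams p = make_params(n_wild, n_cult, L, theta, rho_w, rho_c, tau1, x1,
                            sweep, spos, slam, stau);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  Recorder rec;
  setup_recorder(rec, p, rng, true);
  rec.reset();
  Simulator sim(p, rng, rec);
  sim.run();

  const int n = p.nw + p.nc;
  const int S = static_cast<int>(rec.sites.size());
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return rec.sites[a].pos < rec.sites[b].pos;
  });
  NumericVector pos(S);
  IntegerMatrix G(n, S);
  for (int j = 0; j < S; ++j) {
    const Site &s = rec.sites[ord[j]];
    pos[j] = s.pos;
    for (int i = 0; i < n; ++i)
      G(i, j) = (s.d[i >> 6] >> (i & 63)) & 1ULL;
  }
  return List::create(_["pos"] = pos, _["geno"] = G);
}

// Per-replicate summaries: columns pi_wild, pi_cult, S_wild, S_cult, dxy,
// S_total (pi_* and dxy are per-locus sums of per-site quantities).
// [[Rcpp::export(name = ".cpp_sim_batch")]]
NumericMatrix cpp_sim_batch(int R, int n_wild, int n_cult, double L,
                            double theta, double rho_w, double rho_c,
                            double tau1, double x1, bool sweep, double spos,
                            double slam, double stau, int seed) {
  if (R < 1) stop("R must be >= 1");
  SimParams p = make_params(n_wild, n_cult, L, theta, rho_w, rho_c, tau1, x1,
                            sweep, spos, slam, stau);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  Recorder rec;
  setup_recorder(rec, p, rng, false);
  NumericMatrix out(R, 6);
  colnames(out) = CharacterVector::create("pi_wild", "pi_cult", "S_wild",
                                          "S_cult", "dxy", "S_total");
  for (int r = 0; r < R; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    rec.reset();
    Simulator sim(p, rng, rec);
    sim.run();
    out(r, 0) = rec.piw;
    out(r, 1) = rec.pic;
    out(r, 2) = rec.Sw;
    out(r, 3) = rec.Sc;
    out(r, 4) = rec.dxy;
    out(r, 5) = rec.Stot;
  }
  return out;
}
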