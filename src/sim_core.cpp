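// Continuous-time stochastic simulation core for the humoral immune model.
//
// All pending events form an exponential race: a group of k i.i.d. events
// with mean waiting time tau is a single channel of rate k/tau; the next
// event is drawn with probability proportional to channel rate and the
// clock advances by an exponential with mean 1/(sum of rates). Winner
// identity within a channel is uniform. This is the superposition property
// of exponential clocks, so the dynamics are identical to racing every
// scheduled event individually.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BC {                 // individually tracked B cell
  int x, y;                 // BCR on the antigen lattice
  int px, py;               // presented peptide (valid when pres >= 0)
  int pres;                 // -1 none, 0..nself-1 self pop, 1000+j foreign j
  int state;                // 0 naive, 1 activated, 2 strongly activated, 3 memory
  int strong;               // consecutive strong divisions (plasma countdown)
  double last;              // time of last regulatory contact / presentation start
};

struct TH {                 // individually tracked T helper cell
  int x, y;                 // TCR on the peptide lattice
  int state;                // 0 naive, 1 activated, 2 strongly activated
  int mask;                 // bit i: regulatory and within thrad of self mirror i
  bool reg;                 // positively selected regulatory cell
};

struct PC { int x, y; };    // plasma cell (keeps its mother BCR shape)

struct FP {                 // foreign antigen population (one per injection)
  int x, y;
  double t0, count0, tau;
  bool injected, elim_done, merged;
  double count, maxc, elim, births, kills;
};

inline int linfd(int x1, int y1, int x2, int y2) {
  int dx = std::abs(x2 - x1), dy = std::abs(y2 - y1);
  return dx > dy ? dx : dy;
}

inline double thr(double n, double K) {
  double f = 1.0 - n / K;
  return f > 0.0 ? f : 0.0;
}

// receptor mutation: with probability pmut, displace (x, y) by a uniform
// point on the l-infinity sphere of integer radius drawn uniformly from
// [lo, hi]; the result is clamped to the lattice
inline void mutate_point(int &x, int &y, int lo, int hi, double pmut,
                         int N, int N2) {
  if (unif_rand() >= pmut) return;
  int m = lo + (int)(unif_rand() * (hi - lo + 1));
  if (m > hi) m = hi;
  if (m < 1) return;
  int k = (int)(unif_rand() * (8 * m));
  if (k >= 8 * m) k = 8 * m - 1;
  int side = k / (2 * m), pos = k % (2 * m), dx = 0, dy = 0;
  switch (side) {
    case 0: dx = -m + pos; dy = -m;       break;
    case 1: dx = m;        dy = -m + pos; break;
    case 2: dx = m - pos;  dy = m;        break;
    default: dx = -m;      dy = m - pos;  break;
  }
  x += dx; y += dy;
  if (x < 0) x = 0; if (x > N) x = N;
  if (y < -N2) y = -N2; if (y > N2) y = N2;
}

} // namespace

// test hook: draw `n` mutated copies of a receptor (used by unit tests)
// [[Rcpp::export]]
IntegerMatrix mutate_shape_cpp(int x, int y, int n, int lo, int hi,
                               double pmut, int N) {
  IntegerMatrix out(n, 2);
  int N2 = N / 2;
  for (int i = 0; i < n; ++i) {
    int xx = x, yy = y;
    mutate_point(xx, yy, lo, hi, pmut, N, N2);
    out(i, 0) = xx; out(i, 1) = yy;
  }
  return out;
}

// [[Rcpp::export]]
List sim_run_cpp(List cfg) {
  // ---- parameters ----------------------------------------------------
  const int    N        = as<int>(cfg["N"]);
  const int    N2       = N / 2;
  const double t_max    = as<double>(cfg["t_max"]);
  const double stride   = as<double>(cfg["record_every"]);
  const int    comptype = as<int>(cfg["comptype"]);
  const bool   ers      = comptype == 0;
  const bool   medrepr  = as<int>(cfg["medrepr"]) == 1;
  const bool   weakrepr = as<int>(cfg["weakrepr"]) == 1;
  const double r0       = as<double>(cfg["r0"]);
  const double thrad    = as<double>(cfg["thrad"]);
  const double taub0    = as<double>(cfg["taub0"]);
  const double tauth0   = as<double>(cfg["tauth0"]);
  const double tauthm   = as<double>(cfg["tauthm"]);
  const double taubm    = as<double>(cfg["taubm"]);
  const double t_imm    = as<double>(cfg["t_immigration"]);
  const double pmut     = as<double>(cfg["pmut"]);
  const double pmem     = as<double>(cfg["pmem"]);
  const int    rminnew  = as<int>(cfg["rminnew"]);
  const double crnew    = as<double>(cfg["crnew"]);
  const int    rminsprd = as<int>(cfg["rminsprd"]);
  const double crspread = as<double>(cfg["crspread"]);
  const int    s_plasma = as<int>(cfg["s_plasma"]);
  const double plasma_life = as<double>(cfg["plasma_life"]);
  const double marrow_init = as<double>(cfg["marrow_init"]);
  const double tau_marrow  = as<double>(cfg["tau_marrow"]);
  const double k_marrow    = as<double>(cfg["k_marrow"]);
  const bool   b_negsel    = as<int>(cfg["b_negsel"]) == 1;
  const double b_negsel_radius = as<double>(cfg["b_negsel_radius"]);
  const double ring_inner = as<double>(cfg["ring_inner"]);
  const double ring_outer = as<double>(cfg["ring_outer"]);
  const double kb       = as<double>(cfg["kb"]);
  const double kth      = as<double>(cfg["kth"]);
  const double b_life   = as<double>(cfg["b_life"]);
  const double th_life  = as<double>(cfg["th_life"]);
  const double tau_control = as<double>(cfg["tau_control"]);
  const double tcrit    = as<double>(cfg["tcrit_stress"]);
  const double danger_burst = as<double>(cfg["danger_burst"]);
  const double il_burst = as<double>(cfg["il_burst"]);
  const double k_danger = as<double>(cfg["k_danger"]);
  const double k_il     = as<double>(cfg["k_il"]);
  const double tau_danger_act   = as<double>(cfg["tau_danger_act"]);
  const double tau_danger_decay = as<double>(cfg["tau_danger_decay"]);
  const double tau_il_act   = as<double>(cfg["tau_il_act"]);
  const double tau_il_decay = as<double>(cfg["tau_il_decay"]);
  const double k_treg   = as<double>(cfg["k_treg"]);
  const double p_weak_div   = as<double>(cfg["p_weak_div"]);
  const double p_th_weak_div = as<double>(cfg["p_th_weak_div"]);
  const double p_th_strong_div = as<double>(cfg["p_th_strong_div"]);
  const double p_contraction = as<double>(cfg["p_contraction"]);
  const double aff_exp  = as<double>(cfg["aff_exp"]);
  const double act_speedup = as<double>(cfg["act_speedup"]);
  const double ab_burst = as<double>(cfg["ab_burst"]);
  const double tau_abprod = as<double>(cfg["tau_abprod"]);
  const double tau_ab_act = as<double>(cfg["tau_ab_act"]);
  const double ab_kill  = as<double>(cfg["ab_kill"]);
  const double tau_ab_decay = as<double>(cfg["tau_ab_decay"]);
  const double ab_radius = as<double>(cfg["ab_radius"]);
  const double k_ab     = as<double>(cfg["k_ab"]);
  const double k_foreign = as<double>(cfg["k_foreign"]);
  const double elim_thr  = as<double>(cfg["elim_threshold"]);
  const double death_thr = as<double>(cfg["death_threshold"]);
  const bool   debug_log = as<int>(cfg["debug_log"]) == 1;
  static const char *chName[20] = {
    "self_division", "foreign_division", "marrow_birth", "b_birth",
    "th_birth", "b_action", "b_action_fast", "b_control", "b_death",
    "th_action", "th_action_fast", "th_death", "ab_production",
    "plasma_death", "ab_action", "ab_death", "danger_action",
    "danger_death", "il_action", "il_death"};

  NumericMatrix selfM = cfg["self"];        // x y count divwait capacity
  NumericMatrix infM  = cfg["infections"];  // time count divwait x y
  NumericVector snapAt = cfg["snapshot_at"];

  const int ns = selfM.nrow();
  std::vector<double> selfX(ns), selfY(ns), selfCnt(ns), selfTau(ns), selfK(ns);
  std::vector<double> selfBirths(ns, 0.0), selfDeaths(ns, 0.0);
  double sumSelf = 0.0;
  for (int i = 0; i < ns; ++i) {
    selfX[i] = selfM(i, 0); selfY[i] = selfM(i, 1);
    selfCnt[i] = selfM(i, 2); selfTau[i] = selfM(i, 3); selfK[i] = selfM(i, 4);
    sumSelf += selfCnt[i];
  }

  const int nf = infM.nrow();
  std::vector<FP> fps(nf);
  for (int j = 0; j < nf; ++j) {
    FP f; f.t0 = infM(j, 0); f.count0 = infM(j, 1); f.tau = infM(j, 2);
    f.x = (int)infM(j, 3); f.y = (int)infM(j, 4);
    f.injected = false; f.elim_done = false; f.merged = false;
    f.count = 0.0; f.maxc = 0.0; f.elim = NA_REAL; f.births = 0; f.kills = 0;
    fps[j] = f;
  }
  // injections ordered by time
  std::vector<int> injOrder(nf);
  for (int j = 0; j < nf; ++j) injOrder[j] = j;
  std::sort(injOrder.begin(), injOrder.end(),
            [&](int a, int b) { return fps[a].t0 < fps[b].t0; });
  int injIdx = 0;
  double sumFor = 0.0;

  std::vector<double> snaps(snapAt.begin(), snapAt.end());
  std::sort(snaps.begin(), snaps.end());
  int snapIdx = 0;
  List snapOut;

  // ---- state ---------------------------------------------------------
  std::vector<BC> slowB, fastB;   // slow: states 0/3; fast: 1/2
  std::vector<TH> slowT, fastT;   // slow: state 0;   fast: 1/2
  std::vector<PC> plasma;
  std::vector<int> abx, aby; std::vector<double> abn;
  double abTot = 0.0, danger = 0.0, il = 0.0, marrow = marrow_init;
  std::vector<long> ringCnt(ns, 0L);
  long nReg = 0;                  // live regulatory Th cells (niche census)
  double t = 0.0, deathTime = NA_REAL;
  bool dead = false;

  // division counters: weak_T weak_B intermediate_T intermediate_B strong_T strong_B
  double cnt[6] = {0, 0, 0, 0, 0, 0};
  // ledgers
  double bBirths = 0, bDeaths = 0, bToPlasma = 0, bNegDel = 0;
  double thBirths = 0, thDeaths = 0, thymDel = 0;
  double plasmaDeaths = 0, abProd = 0, abDec = 0, abUsedKills = 0;
  double dEmit = 0, dCons = 0, dDec = 0;
  double ilEmit = 0, ilCons = 0, ilDec = 0;
  double mBirths = 0;

  // mutation magnitude ranges
  const int loN = rminnew, hiN = std::max(rminnew, (int)std::lround(rminnew / crnew));
  const int loS = rminsprd, hiS = std::max(rminsprd, (int)std::lround(rminsprd / crspread));

  // timeseries buffer
  std::vector<double> tsbuf;
  const int NC = 14;
  double next_rec = 0.0;

  auto nB = [&]() { return (double)(slowB.size() + fastB.size()); };
  auto nBall = [&]() { return (double)(slowB.size() + fastB.size() + plasma.size()); };
  auto nTh = [&]() { return (double)(slowT.size() + fastT.size()); };

  auto record = [&]() {
    tsbuf.push_back(next_rec);
    tsbuf.push_back(sumSelf);
    tsbuf.push_back(sumFor);
    tsbuf.push_back(nBall());
    tsbuf.push_back(abTot);
    tsbuf.push_back(nTh());
    tsbuf.push_back(danger);
    tsbuf.push_back(marrow);
    for (int k = 0; k < 6; ++k) tsbuf.push_back(cnt[k]);
    next_rec += stride;
  };

  auto ui = [&](int n) {
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
  };

  auto aff = [&](int d, double r) {
    double a = 1.0 - (double)d / (r + 1.0);
    if (a <= 0.0) return 0.0;
    if (aff_exp == 2.0) return a * a;
    return std::pow(a, aff_exp);
  };

  auto mutate = [&](int &x, int &y, int lo, int hi) {
    mutate_point(x, y, lo, hi, pmut, N, N2);
  };

  // pick an antigen-bearing population with probability proportional to count
  // returns false when no antigen exists; (isSelf, idx) identify the winner
  auto pickAntigen = [&](bool &isSelf, int &idx) {
    double tot = sumSelf + sumFor;
    if (tot <= 0.0) return false;
    double u = unif_rand() * tot;
    for (int i = 0; i < ns; ++i) {
      if (u < selfCnt[i]) { isSelf = true; idx = i; return true; }
      u -= selfCnt[i];
    }
    for (int j = 0; j < nf; ++j) {
      if (!fps[j].injected || fps[j].count <= 0) continue;
      if (u < fps[j].count) { isSelf = false; idx = j; return true; }
      u -= fps[j].count;
    }
    // numerical tail: fall back to the last nonempty population
    for (int j = nf - 1; j >= 0; --j)
      if (fps[j].injected && fps[j].count > 0) { isSelf = false; idx = j; return true; }
    for (int i = ns - 1; i >= 0; --i)
      if (selfCnt[i] > 0) { isSelf = true; idx = i; return true; }
    return false;
  };

  auto fpKill = [&](int j, double k) {
    FP &f = fps[j];
    double kk = std::min(k, f.count);
    if (kk <= 0) return;
    f.count -= kk; f.kills += kk; sumFor -= kk;
    if (!f.elim_done && f.count < elim_thr) { f.elim = t - f.t0; f.elim_done = true; }
  };

  // thymic selection of a TCR candidate; returns survival, sets reg/mask
  auto thymicSelect = [&](int x, int y, bool &reg, int &mask) {
    int dstar = INT_MAX;
    for (int i = 0; i < ns; ++i)
      dstar = std::min(dstar, linfd(x, y, (int)selfX[i], -(int)selfY[i]));
    reg = false; mask = 0;
    if (ers) {
      if (dstar < ring_inner) return false;
      if (dstar <= ring_outer) {
        reg = true;
        for (int i = 0; i < ns; ++i)
          if (linfd(x, y, (int)selfX[i], -(int)selfY[i]) <= thrad) mask |= (1 << i);
      }
      return true;
    }
    return dstar > ring_outer;   // negative-only selection
  };

  // peripheral tolerance: offspring mutated into the self-exclusion ball
  // are deleted, like marrow candidates (same b_negsel switch)
  auto bTolerated = [&](int x, int y) {
    if (!b_negsel) return true;
    for (int i = 0; i < ns; ++i)
      if (linfd(x, y, (int)selfX[i], -(int)selfY[i]) < b_negsel_radius)
        return false;
    return true;
  };

  // B division. parent addressed by (group, index); kind 0 weak, 1 intermediate, 2 strong
  auto bDivide = [&](bool parFast, int i, int kind) {
    std::vector<BC> &vec = parFast ? fastB : slowB;
    BC off = vec[i];
    off.pres = -1; off.last = t; off.strong = 0;
    if (kind == 0) {
      cnt[1] += 1; off.state = 0;
      mutate(off.x, off.y, loS, hiS);
    } else if (kind == 1) {
      cnt[3] += 1; off.state = 1;
      mutate(off.x, off.y, loN, hiN);
    } else {
      cnt[5] += 1;
      vec[i].strong += 1;
      // memory parents seed memory offspring; blast tempo needs T help
      off.state = (vec[i].state == 3 || unif_rand() < pmem) ? 3 : 2;
      mutate(off.x, off.y, loN, hiN);
      if (vec[i].strong >= s_plasma) {     // terminal differentiation
        plasma.push_back({vec[i].x, vec[i].y});
        bToPlasma += 1;
        vec[i] = vec.back(); vec.pop_back();
      }
    }
    if (!bTolerated(off.x, off.y)) { bNegDel += 1; return; }
    bBirths += 1;
    if (off.state == 1 || off.state == 2) fastB.push_back(off);
    else slowB.push_back(off);
  };

  // Th division; kind 0 weak, 1 intermediate, 2 strong
  auto thDivide = [&](bool parFast, int i, int kind) {
    std::vector<TH> &vec = parFast ? fastT : slowT;
    TH off = vec[i];
    off.mask = 0;
    if (kind == 0) {
      cnt[0] += 1; off.state = 0;
      mutate(off.x, off.y, loS, hiS);
      bool wasReg = off.reg;
      off.reg = false;
      if (wasReg) {        // regulatory status is re-validated on the annuli
        int dstar = INT_MAX;
        for (int s = 0; s < ns; ++s)
          dstar = std::min(dstar, linfd(off.x, off.y, (int)selfX[s], -(int)selfY[s]));
        if (dstar >= ring_inner && dstar <= ring_outer) {
          off.reg = true;
          for (int s = 0; s < ns; ++s)
            if (linfd(off.x, off.y, (int)selfX[s], -(int)selfY[s]) <= thrad)
              off.mask |= (1 << s);
          for (int s = 0; s < ns; ++s)
            if (off.mask & (1 << s)) ringCnt[s] += 1;
          nReg += 1;
        }
      }
    } else {
      cnt[kind == 1 ? 2 : 4] += 1;
      off.state = kind == 1 ? 1 : 2;
      off.reg = false;
      mutate(off.x, off.y, loN, hiN);
    }
    thBirths += 1;
    if (off.state == 0) slowT.push_back(off);
    else fastT.push_back(off);
  };

  auto moveB = [&](bool fromFast, int i) {   // flip a B cell between groups
    std::vector<BC> &src = fromFast ? fastB : slowB;
    std::vector<BC> &dst = fromFast ? slowB : fastB;
    dst.push_back(src[i]);
    src[i] = src.back(); src.pop_back();
  };

  auto snapshotNow = [&](double at) {
    std::vector<int> kk, xx, yy; std::vector<double> cc;
    for (auto &h : slowT) { kk.push_back(0); xx.push_back(h.x); yy.push_back(h.y); cc.push_back(1); }
    for (auto &h : fastT) { kk.push_back(0); xx.push_back(h.x); yy.push_back(h.y); cc.push_back(1); }
    for (auto &b : slowB) { kk.push_back(1); xx.push_back(b.x); yy.push_back(b.y); cc.push_back(1); }
    for (auto &b : fastB) { kk.push_back(1); xx.push_back(b.x); yy.push_back(b.y); cc.push_back(1); }
    for (auto &p : plasma) { kk.push_back(1); xx.push_back(p.x); yy.push_back(p.y); cc.push_back(1); }
    for (int i = 0; i < ns; ++i) { kk.push_back(2); xx.push_back((int)selfX[i]); yy.push_back((int)selfY[i]); cc.push_back(selfCnt[i]); }
    for (int j = 0; j < nf; ++j) if (fps[j].injected) { kk.push_back(3); xx.push_back(fps[j].x); yy.push_back(fps[j].y); cc.push_back(fps[j].count); }
    snapOut.push_back(List::create(_["time"] = at,
                                   _["kind"] = IntegerVector(kk.begin(), kk.end()),
                                   _["x"] = IntegerVector(xx.begin(), xx.end()),
                                   _["y"] = IntegerVector(yy.begin(), yy.end()),
                                   _["count"] = NumericVector(cc.begin(), cc.end())));
  };

  // ---- event handlers ------------------------------------------------

  auto bAction = [&](bool fast) {
    std::vector<BC> &vec = fast ? fastB : slowB;
    if (vec.empty()) return;
    int i = ui((int)vec.size());
    bool isSelf; int idx;
    if (!pickAntigen(isSelf, idx)) return;
    int ax = isSelf ? (int)selfX[idx] : fps[idx].x;
    int ay = isSelf ? (int)selfY[idx] : fps[idx].y;
    int d = linfd(vec[i].x, vec[i].y, ax, -ay);
    if (d > r0) return;
    if (unif_rand() >= aff(d, r0)) return;      // affinity-weighted capture
    if (isSelf) { selfCnt[idx] -= 1; selfDeaths[idx] += 1; sumSelf -= 1; }
    else fpKill(idx, 1);
    BC &b = vec[i];
    int np = isSelf ? idx : 1000 + idx;
    if (b.pres != np) { b.pres = np; b.last = t; }
    b.px = ax; b.py = ay;
    double tb = thr(nBall(), kb);
    switch (b.state) {
      case 0:   // naive: weak homeostatic division on self presentation.
                // proliferation needs a stronger tonic signal than capture,
                // hence the extra affinity factor
        if (isSelf && weakrepr && ers &&
            unif_rand() < p_weak_div * aff(d, r0) * aff(d, r0) * tb)
          bDivide(fast, i, 0);
        break;
      case 1:   // activated: polyclonal intermediate division
        if (medrepr && unif_rand() < tb) bDivide(fast, i, 1);
        break;
      case 2:   // strongly activated: clonal expansion
        if (unif_rand() < tb) bDivide(fast, i, 2);
        break;
      case 3:   // memory: strong-type division on foreign contact without
                // the stress period; full blast tempo still requires the
                // two-signal Th contact (handled in th detection)
        if (!isSelf && unif_rand() < tb) bDivide(fast, i, 2);
        break;
    }
  };

  auto bControl = [&]() {
    int n1 = (int)slowB.size(), n2 = (int)fastB.size();
    if (n1 + n2 == 0) return;
    int k = ui(n1 + n2);
    bool fast = k >= n1; int i = fast ? k - n1 : k;
    std::vector<BC> &vec = fast ? fastB : slowB;
    BC &b = vec[i];
    // effectors with no antigen anywhere contract like presenting ones
    if ((b.state == 1 || b.state == 2) && sumFor <= 0 &&
        (b.pres < 0 || b.pres >= 1000)) {
      if (unif_rand() < p_contraction) {
        vec[i] = vec.back(); vec.pop_back();
        bDeaths += 1;
      } else {
        b.pres = -1;                 // survivors persist as memory
        b.state = 3; b.strong = 0;
        moveB(fast, i);
      }
      return;
    }
    if (b.pres < 0) return;
    if (b.pres < 1000) {               // self peptide: homeostatic check
      if (ringCnt[b.pres] > 0) {
        b.last = t;                    // regulatory contact maintained
        if (b.state == 1) { b.state = 0; moveB(fast, i); }
      }
      return;
    }
    int fj = b.pres - 1000;
    if (fps[fj].count <= 0) {          // pathogen cleared: clonal
      if (b.state == 1 || b.state == 2) {  // contraction of effectors
        if (unif_rand() < p_contraction) {
          vec[i] = vec.back(); vec.pop_back();
          bDeaths += 1;
          return;
        }
        b.pres = -1;                   // survivors persist as memory
        b.state = 3; b.strong = 0;
        moveB(fast, i);
        return;
      }
      b.pres = -1;
      return;
    }
    if (t - b.last > tcrit) {          // foreign peptide unattended too long
      if (b.state == 0) { b.state = 1; moveB(fast, i); fast = true; }
      if (unif_rand() < thr(danger, k_danger)) {
        danger += danger_burst; dEmit += danger_burst;
      }
    }
  };

  auto thAction = [&](bool fast) {
    std::vector<TH> &vec = fast ? fastT : slowT;
    if (vec.empty()) return;
    int i = ui((int)vec.size());
    bool moved = false;
    // detection: inspect one random B cell's MHCII
    int nb1 = (int)slowB.size(), nb2 = (int)fastB.size();
    if (nb1 + nb2 > 0) {
      int k = ui(nb1 + nb2);
      bool bfast = k >= nb1; int bi = bfast ? k - nb1 : k;
      std::vector<BC> &bv = bfast ? fastB : slowB;
      if (bv[bi].pres >= 0) {
        int d = linfd(vec[i].x, vec[i].y, bv[bi].px, -bv[bi].py);
        if (d <= thrad) {
          if (bv[bi].pres < 1000) {   // self peptide: homeostatic contact
            if (ers && vec[i].reg) {
              int sp = bv[bi].pres;   // ring niche of the presented peptide
              bv[bi].last = t;
              if (bv[bi].state == 1) { bv[bi].state = 0; moveB(bfast, bi); }
              if (weakrepr &&
                  unif_rand() < p_th_weak_div * thr((double)ringCnt[sp], k_treg))
                thDivide(fast, i, 0);
            }
          } else if (!vec[i].reg) {   // foreign peptide: two-signal activation
            if (bv[bi].state != 2) {
              int st = bv[bi].state;
              bv[bi].state = 2; bv[bi].strong = 0;
              if (st == 0 || st == 3) moveB(bfast, bi);
            }
            if (vec[i].state != 2) {
              vec[i].state = 2;
              if (!fast) {            // promote to fast group
                fastT.push_back(vec[i]);
                vec[i] = vec.back(); vec.pop_back();
                moved = true;
              }
            }
          }
        }
      }
    }
    if (moved) return;
    TH &h = vec[i];
    if (h.state == 2) {
      if (sumFor <= 0) {               // infection cleared: the expanded
        h.state = 0;                   // clone persists but goes quiescent
        if (fast) {
          slowT.push_back(h);
          vec[i] = vec.back(); vec.pop_back();
        }
        return;
      }
      if (unif_rand() < p_th_strong_div * thr(nTh(), kth)) thDivide(fast, i, 2);
    } else if (h.state == 1) {
      if (danger <= 0.5) {            // emergency over: stand down
        h.state = 0;
        slowT.push_back(h);
        vec[i] = vec.back(); vec.pop_back();
      } else {
        if (unif_rand() < thr(il, k_il)) { il += il_burst; ilEmit += il_burst; }
        if (medrepr && unif_rand() < thr(nTh(), kth)) thDivide(fast, i, 1);
      }
    }
  };

  auto bBirth = [&]() {
    int x = ui(N + 1), y = ui(N + 1) - N2;
    if (b_negsel) {
      for (int i = 0; i < ns; ++i)
        if (linfd(x, y, (int)selfX[i], -(int)selfY[i]) < b_negsel_radius) {
          bNegDel += 1; return;
        }
    }
    slowB.push_back({x, y, 0, 0, -1, 0, 0, t});
    bBirths += 1;
  };

  auto thBirth = [&]() {
    int x = ui(N + 1), y = ui(N + 1) - N2;
    bool reg; int mask;
    if (!thymicSelect(x, y, reg, mask)) { thymDel += 1; return; }
    slowT.push_back({x, y, 0, mask, reg});
    for (int i = 0; i < ns; ++i) if (mask & (1 << i)) ringCnt[i] += 1;
    if (reg) nReg += 1;
    thBirths += 1;
  };

  auto bDeath = [&]() {
    int n1 = (int)slowB.size(), n2 = (int)fastB.size();
    if (n1 + n2 == 0) return;
    int k = ui(n1 + n2);
    std::vector<BC> &vec = k >= n1 ? fastB : slowB;
    int i = k >= n1 ? k - n1 : k;
    vec[i] = vec.back(); vec.pop_back();
    bDeaths += 1;
  };

  auto thDeath = [&]() {
    int n1 = (int)slowT.size(), n2 = (int)fastT.size();
    if (n1 + n2 == 0) return;
    int k = ui(n1 + n2);
    std::vector<TH> &vec = k >= n1 ? fastT : slowT;
    int i = k >= n1 ? k - n1 : k;
    for (int s = 0; s < ns; ++s) if (vec[i].mask & (1 << s)) ringCnt[s] -= 1;
    if (vec[i].reg) nReg -= 1;
    vec[i] = vec.back(); vec.pop_back();
    thDeaths += 1;
  };

  auto abProduce = [&]() {
    if (plasma.empty()) return;
    int j = ui((int)plasma.size());
    if (unif_rand() >= thr(abTot, k_ab)) return;
    int i = -1;
    for (size_t q = 0; q < abx.size(); ++q)
      if (abx[q] == plasma[j].x && aby[q] == plasma[j].y) { i = (int)q; break; }
    if (i < 0) { abx.push_back(plasma[j].x); aby.push_back(plasma[j].y); abn.push_back(0.0); i = (int)abx.size() - 1; }
    abn[i] += ab_burst; abTot += ab_burst; abProd += ab_burst;
  };

  auto pickAbPool = [&]() {
    double u = unif_rand() * abTot;
    for (size_t q = 0; q < abn.size(); ++q) {
      if (u < abn[q]) return (int)q;
      u -= abn[q];
    }
    return (int)abn.size() - 1;
  };

  auto abAction = [&]() {
    if (abTot <= 0) return;
    int q = pickAbPool();
    bool isSelf; int idx;
    if (!pickAntigen(isSelf, idx)) return;
    int ax = isSelf ? (int)selfX[idx] : fps[idx].x;
    int ay = isSelf ? (int)selfY[idx] : fps[idx].y;
    if (linfd(abx[q], aby[q], ax, -ay) > ab_radius) return;
    if (isSelf) {
      double kk = std::min(ab_kill, selfCnt[idx]);
      selfCnt[idx] -= kk; selfDeaths[idx] += kk; sumSelf -= kk;
    } else {
      fpKill(idx, ab_kill);
    }
    abUsedKills += 1;
  };

  auto abDeath = [&]() {
    if (abTot <= 0) return;
    int q = pickAbPool();
    abn[q] -= 1; abTot -= 1; abDec += 1;
    if (abn[q] < 0) { abTot -= abn[q]; abDec += abn[q]; abn[q] = 0; }
  };

  auto dangerAction = [&]() {
    if (danger <= 0) return;
    danger -= 1; dCons += 1;
    int n1 = (int)slowT.size(), n2 = (int)fastT.size();
    if (n1 + n2 == 0) return;                 // signal dissipates
    int k = ui(n1 + n2);
    if (k < n1 && slowT[k].state == 0 && !slowT[k].reg) {
      slowT[k].state = 1;                     // recruited into the first line
      fastT.push_back(slowT[k]);
      slowT[k] = slowT.back(); slowT.pop_back();
    }
  };

  auto ilAction = [&]() {
    if (il <= 0) return;
    il -= 1; ilCons += 1;
    int n1 = (int)slowB.size(), n2 = (int)fastB.size();
    if (n1 + n2 == 0) return;
    int k = ui(n1 + n2);
    if (k >= n1) {      // only cells that lost regulatory control respond:
      int i = k - n1;   // presentation requires a fresh affinity-gated capture
      if (fastB[i].state == 1 && fastB[i].pres >= 1000 && medrepr &&
          unif_rand() < thr(nBall(), kb))
        bDivide(true, i, 1);
    } else if (slowB[k].state == 3 && slowB[k].pres >= 1000 &&
               unif_rand() < thr(nBall(), kb)) {
      bDivide(false, k, 2);   // memory recall: strong-kind expansion
    }
  };

  // ---- main loop -----------------------------------------------------
  std::vector<double> selfRate(ns), forRate(nf);
  const double EPSJ = 1e-9;

  for (;;) {
    // channel rates
    double rSelf = 0;
    for (int i = 0; i < ns; ++i) {
      selfRate[i] = selfCnt[i] / selfTau[i] * thr(selfCnt[i], selfK[i]);
      rSelf += selfRate[i];
    }
    double rFor = 0;
    for (int j = 0; j < nf; ++j) {
      forRate[j] = fps[j].injected ?
        fps[j].count / fps[j].tau * thr(fps[j].count, k_foreign) : 0.0;
      rFor += forRate[j];
    }
    double rMar = marrow / tau_marrow * thr(marrow, k_marrow);
    double rBb = t >= t_imm ? thr(nBall(), kb) / taubm : 0.0;
    double rTb = t >= t_imm ? thr(nTh(), kth) / tauthm : 0.0;
    double rBaS = slowB.size() / taub0;
    double rBaF = fastB.size() * act_speedup / taub0;
    double rBc = ers ? nB() / tau_control : 0.0;
    double rBd = nB() / b_life;
    double rTaS = slowT.size() / tauth0;
    double rTaF = fastT.size() * act_speedup / tauth0;
    double rTd = nTh() / th_life;
    double rPp = plasma.size() / tau_abprod;
    double rPd = plasma.size() / plasma_life;
    double rAa = abTot / tau_ab_act;
    double rAd = abTot / tau_ab_decay;
    double rDa = danger / tau_danger_act;
    double rDd = danger / tau_danger_decay;
    double rIa = il / tau_il_act;
    double rId = il / tau_il_decay;
    double rates[18] = {rSelf, rFor, rMar, rBb, rTb, rBaS, rBaF, rBc, rBd,
                        rTaS, rTaF, rTd, rPp, rPd, rAa, rAd, rDa, rDd};
    double rDanIl = rIa + rId;   // folded below as channels 18/19
    double total = rDanIl;
    for (int c = 0; c < 18; ++c) total += rates[c];

    // next hard boundary: injection or snapshot or horizon
    double bnd = t_max; int btype = 0;
    if (injIdx < nf && fps[injOrder[injIdx]].t0 < bnd) {
      bnd = fps[injOrder[injIdx]].t0; btype = 1;
    }
    if (snapIdx < (int)snaps.size() && snaps[snapIdx] < bnd) {
      bnd = snaps[snapIdx]; btype = 2;
    }

    double tn = total > 0 ? t + exp_rand() / total : bnd + EPSJ;

    if (tn >= bnd) {
      if (btype == 0) {
        while (next_rec <= t_max + 1e-12) record();
        t = t_max;
        break;
      }
      while (next_rec < bnd - 1e-12) record();
      t = bnd;
      if (btype == 1) {
        FP &f = fps[injOrder[injIdx]];
        // merge with an already-injected population of identical shape/time
        bool merged = false;
        for (int j = 0; j < nf; ++j) {
          FP &g = fps[j];
          if (&g != &f && g.injected && g.x == f.x && g.y == f.y && g.t0 == f.t0) {
            g.count += f.count0; g.births += f.count0; sumFor += f.count0;
            if (g.count > g.maxc) g.maxc = g.count;
            f.injected = true; f.count = 0; f.merged = true;
            merged = true; break;
          }
        }
        if (!merged) {
          f.injected = true; f.count = f.count0; f.births = f.count0;
          f.maxc = f.count0; sumFor += f.count0;
          if (f.count < elim_thr) { f.elim = 0.0; f.elim_done = true; }
        }
        injIdx += 1;
      } else {
        snapshotNow(snaps[snapIdx]);
        snapIdx += 1;
      }
      continue;
    }

    while (next_rec < tn - 1e-12) record();
    t = tn;

    // channel dispatch
    double u = unif_rand() * total;
    int ch = -1;
    for (int c = 0; c < 18; ++c) {
      if (u < rates[c]) { ch = c; break; }
      u -= rates[c];
    }
    if (ch < 0) ch = u < rIa ? 18 : 19;
    if (debug_log) REprintf("t=%.3f event=%s\n", t, chName[ch]);

    switch (ch) {
      case 0: {   // self division
        double v = unif_rand() * rSelf;
        int i = 0;
        for (; i < ns - 1; ++i) { if (v < selfRate[i]) break; v -= selfRate[i]; }
        selfCnt[i] += 1; selfBirths[i] += 1; sumSelf += 1;
        break;
      }
      case 1: {   // foreign division
        double v = unif_rand() * rFor;
        int j = 0;
        for (; j < nf - 1; ++j) { if (v < forRate[j]) break; v -= forRate[j]; }
        fps[j].count += 1; fps[j].births += 1; sumFor += 1;
        if (fps[j].count > fps[j].maxc) fps[j].maxc = fps[j].count;
        if (fps[j].count >= death_thr) { deathTime = t; dead = true; }
        break;
      }
      case 2: marrow += 1; mBirths += 1; break;
      case 3: bBirth(); break;
      case 4: thBirth(); break;
      case 5: bAction(false); break;
      case 6: bAction(true); break;
      case 7: bControl(); break;
      case 8: bDeath(); break;
      case 9: thAction(false); break;
      case 10: thAction(true); break;
      case 11: thDeath(); break;
      case 12: abProduce(); break;
      case 13: {  // plasma death
        if (!plasma.empty()) {
          int j = ui((int)plasma.size());
          plasma[j] = plasma.back(); plasma.pop_back();
          plasmaDeaths += 1;
        }
        break;
      }
      case 14: abAction(); break;
      case 15: abDeath(); break;
      case 16: dangerAction(); break;
      case 17: danger -= 1; dDec += 1; break;
      case 18: ilAction(); break;
      default: il -= 1; ilDec += 1; break;
    }
    if (dead) break;
  }

  // ---- outputs -------------------------------------------------------
  int nrow = (int)(tsbuf.size() / NC);
  NumericMatrix ts(nrow, NC);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < NC; ++c) ts(r, c) = tsbuf[r * NC + c];

  NumericMatrix fout(nf, 9);
  for (int j = 0; j < nf; ++j) {
    FP &f = fps[j];
    fout(j, 0) = f.t0; fout(j, 1) = f.count0; fout(j, 2) = f.tau;
    fout(j, 3) = f.x; fout(j, 4) = f.y;
    fout(j, 5) = f.merged ? 2 : (f.injected ? 1 : 0);
    fout(j, 6) = f.count; fout(j, 7) = f.maxc;
    fout(j, 8) = f.elim_done ? f.elim : NA_REAL;
  }

  int nbc = (int)(slowB.size() + fastB.size());
  IntegerMatrix bout(nbc, 3);
  {
    int r = 0;
    for (auto &b : slowB) { bout(r, 0) = b.x; bout(r, 1) = b.y; bout(r, 2) = b.state; ++r; }
    for (auto &b : fastB) { bout(r, 0) = b.x; bout(r, 1) = b.y; bout(r, 2) = b.state; ++r; }
  }
  int nth = (int)(slowT.size() + fastT.size());
  IntegerMatrix tout(nth, 4);
  {
    int r = 0;
    for (auto &h : slowT) { tout(r, 0) = h.x; tout(r, 1) = h.y; tout(r, 2) = h.state; tout(r, 3) = h.reg ? 1 : 0; ++r; }
    for (auto &h : fastT) { tout(r, 0) = h.x; tout(r, 1) = h.y; tout(r, 2) = h.state; tout(r, 3) = h.reg ? 1 : 0; ++r; }
  }
  IntegerMatrix pout((int)plasma.size(), 2);
  for (int r = 0; r < (int)plasma.size(); ++r) { pout(r, 0) = plasma[r].x; pout(r, 1) = plasma[r].y; }
  NumericMatrix about((int)abx.size(), 3);
  for (int r = 0; r < (int)abx.size(); ++r) { about(r, 0) = abx[r]; about(r, 1) = aby[r]; about(r, 2) = abn[r]; }

  return List::create(
    _["timeseries"] = ts,
    _["foreign"] = fout,
    _["self_counts"] = NumericVector(selfCnt.begin(), selfCnt.end()),
    _["self_births"] = NumericVector(selfBirths.begin(), selfBirths.end()),
    _["self_deaths"] = NumericVector(selfDeaths.begin(), selfDeaths.end()),
    _["bcells"] = bout,
    _["thcells"] = tout,
    _["plasma"] = pout,
    _["antibodies"] = about,
    _["pools"] = NumericVector::create(
      _["danger"] = danger, _["interleukin"] = il, _["marrow"] = marrow,
      _["antibody"] = abTot),
    _["counters"] = NumericVector::create(
      _["weak_T"] = cnt[0], _["weak_B"] = cnt[1],
      _["intermediate_T"] = cnt[2], _["intermediate_B"] = cnt[3],
      _["strong_T"] = cnt[4], _["strong_B"] = cnt[5]),
    _["ledger"] = NumericVector::create(
      _["b_births"] = bBirths, _["b_deaths"] = bDeaths,
      _["b_to_plasma"] = bToPlasma, _["b_negsel_deleted"] = bNegDel,
      _["th_births"] = thBirths, _["th_deaths"] = thDeaths,
      _["th_thymic_deleted"] = thymDel,
      _["plasma_deaths"] = plasmaDeaths,
      _["ab_produced"] = abProd, _["ab_decayed"] = abDec,
      _["danger_emitted"] = dEmit, _["danger_consumed"] = dCons,
      _["danger_decayed"] = dDec,
      _["il_emitted"] = ilEmit, _["il_consumed"] = ilCons,
      _["il_decayed"] = ilDec,
      _["marrow_births"] = mBirths),
    _["ring_counts"] = NumericVector(ringCnt.begin(), ringCnt.end()),
    _["snapshots"] = snapOut,
    _["death_time"] = deathTime,
    _["end_time"] = t);
}
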