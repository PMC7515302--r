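// Asynchronous Monte Carlo engine for the predator-prey lattice.
//
// Site codes: 0 = empty, 1 = prey, 2 = predator.
// One MCS = L*L trials. All randomness flows through R's RNG (unif_rand),
// so runs are bit-reproducible under set.seed(). Draw order per trial:
//   1. site index
//   2a. non-learning occupant: Moore neighbour index (1 draw)
//   2b. learning occupant: epsilon test (1 draw), then either uniform
//       action (1 draw) or, on a Q-value tie, uniform tie-break (1 draw)
//   3. reproduction Bernoulli where the rule calls for it (1 draw)
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int S_EMPTY = 0, S_PREY = 1, S_PRED = 2;

// Event kinds (EventLog encoding, shared with R)
static const int EV_MOVE = 1;        // predator -> empty
static const int EV_PRED_BIRTH = 2;  // predation + offspring
static const int EV_PRED_MOVE = 3;   // predation + move
static const int EV_PREY_BIRTH = 4;
static const int EV_PREY_MOVE = 5;
static const int EV_BLOCKED = 6;     // failed pairing (conspecifics etc.)
static const int EV_NOOP = 7;        // empty first site or stand-still

// Action index 0..8: up, down, left, right, up-left, up-right,
// down-left, down-right, stand-still. First 8 double as the Moore
// neighbour order for random partners.
static const int ADR[9] = {-1, 1, 0, 0, -1, -1, 1, 1, 0};
static const int ADC[9] = {0, 0, -1, 1, -1, 1, -1, 1, 0};

static const double FOOD_TOL = 1e-9;

struct Policy {
  bool active = false;
  bool collect = false;
  int vr = 0, half = 0, npix = 0, nh = 0, na = 0;
  double eps = 1.0;
  NumericVector base;  // nh
  NumericMatrix D1;    // npix x nh (prey-code delta vs empty)
  NumericMatrix D2;    // npix x nh (predator-code delta)
  NumericMatrix W4;    // nh x na
  NumericVector b4;    // na
};

static Policy parse_policy(Nullable<List> pl, bool collect) {
  Policy p;
  if (pl.isNull()) return p;
  List l(pl);
  p.active = true;
  p.collect = collect;
  p.vr = as<int>(l["vr"]);
  p.half = p.vr / 2;
  p.npix = p.vr * p.vr;
  p.eps = as<double>(l["eps"]);
  p.base = l["base"];
  p.D1 = as<NumericMatrix>(l["D1"]);
  p.D2 = as<NumericMatrix>(l["D2"]);
  p.W4 = as<NumericMatrix>(l["W4"]);
  p.b4 = l["b4"];
  p.nh = p.base.size();
  p.na = p.b4.size();
  return p;
}

struct TransStore {
  int npix = 0;
  std::vector<int> s, s2;  // npix codes per transition, concatenated
  std::vector<int> a;      // 1-based action
  std::vector<double> r;
  std::vector<int> term;
  int n() const { return (int)a.size(); }
};

struct Sim {
  int L, LL;
  IntegerMatrix grid;
  NumericMatrix food;
  IntegerMatrix age;
  double bX, bY, fX_init, decay;
  int prey_max_age;
  int npred = 0, nprey = 0;
  // per-MCS map from site to the index of the transition created there
  // this MCS (for terminal flagging); -1 = none
  std::vector<int> lt_pred, lt_prey;
  TransStore tp, ty;
  bool track_pred = false, track_prey = false;

  int wrap(int x) const { int m = x % L; return m < 0 ? m + L : m; }

  void lt_move(std::vector<int>& lt, int from, int to) {
    lt[to] = lt[from];
    lt[from] = -1;
  }
  void prey_dies(int idx) {
    if (track_prey && lt_prey[idx] >= 0) {
      ty.term[lt_prey[idx]] = 1;
      lt_prey[idx] = -1;
    }
  }
  void pred_dies(int idx) {
    if (track_pred && lt_pred[idx] >= 0) {
      tp.term[lt_pred[idx]] = 1;
      lt_pred[idx] = -1;
    }
  }

  // Apply one pairwise interaction (Moore-adjacent sites assumed).
  int interact(int r1, int c1, int r2, int c2) {
    int i1 = c1 * L + r1, i2 = c2 * L + r2;
    int occ1 = grid[i1], occ2 = grid[i2];
    if (occ1 == S_EMPTY) return EV_NOOP;
    if (occ1 == S_PRED) {
      if (occ2 == S_EMPTY) {
        grid[i2] = S_PRED; food[i2] = food[i1];
        grid[i1] = S_EMPTY;
        if (track_pred) lt_move(lt_pred, i1, i2);
        return EV_MOVE;
      }
      if (occ2 == S_PREY) {
        prey_dies(i2); nprey--;
        food[i1] = fX_init;  // parent's reserve restored by the meal
        if (unif_rand() < bX) {
          grid[i2] = S_PRED; food[i2] = fX_init; npred++;
          return EV_PRED_BIRTH;
        }
        grid[i2] = S_PRED; food[i2] = food[i1];
        grid[i1] = S_EMPTY;
        if (track_pred) lt_move(lt_pred, i1, i2);
        return EV_PRED_MOVE;
      }
      return EV_BLOCKED;  // predator + predator
    }
    // occ1 == S_PREY
    if (occ2 == S_EMPTY) {
      if (unif_rand() < bY) {
        grid[i2] = S_PREY; age[i2] = 0; nprey++;
        return EV_PREY_BIRTH;
      }
      grid[i2] = S_PREY; age[i2] = age[i1];
      grid[i1] = S_EMPTY;
      if (track_prey) lt_move(lt_prey, i1, i2);
      return EV_PREY_MOVE;
    }
    return EV_BLOCKED;  // prey + occupied
  }

  // End-of-MCS sweep: every predator pays the metabolic cost and starves
  // at (numerically) zero reserve; every prey ages by one MCS and dies
  // beyond the maximum age.
  void metabolism_and_age(bool flag_terminals) {
    for (int i = 0; i < LL; i++) {
      int occ = grid[i];
      if (occ == S_PRED) {
        food[i] -= decay;
        if (food[i] <= FOOD_TOL) {
          grid[i] = S_EMPTY; npred--;
          if (flag_terminals) pred_dies(i);
        }
      } else if (occ == S_PREY) {
        age[i] += 1;
        if (age[i] > prey_max_age) {
          grid[i] = S_EMPTY; nprey--;
          if (flag_terminals) prey_dies(i);
        }
      }
    }
  }

  void extract_obs(int r, int c, const Policy& P, int* out) const {
    int h = P.half, vr = P.vr;
    for (int i = 0; i < vr; i++) {
      int rr = wrap(r + i - h);
      for (int j = 0; j < vr; j++) {
        int cc = wrap(c + j - h);
        out[i * vr + j] = grid[cc * L + rr];
      }
    }
  }

  // Shell-shaped state reward evaluated on an observation window.
  double reward_from_obs(const int* obs, int species, const Policy& P) const {
    int h = P.half, vr = P.vr;
    double rew = 0.0;
    int total = 0;
    int want = (species == S_PRED) ? S_PREY : S_PRED;
    for (int i = 0; i < vr; i++) {
      for (int j = 0; j < vr; j++) {
        if (i == h && j == h) continue;
        if (obs[i * vr + j] != want) continue;
        int k = std::max(std::abs(i - h), std::abs(j - h));
        total++;
        if (species == S_PRED) {
          rew += (k == 1) ? 20.0 : (k == 2) ? 10.0 : 1.0;
        } else {
          if (k == 1) rew -= 10.0;
          else if (k == 2) rew -= 1.0;
        }
      }
    }
    if (species == S_PRED) return total == 0 ? -10.0 : rew;
    return total == 0 ? 10.0 : rew;
  }

  // Greedy Q evaluation via the folded per-pixel lookup (tanh omitted:
  // it is monotone, so the argmax is unchanged).
  int greedy_action(const Policy& P, const int* obs, double* zbuf, double* qbuf) const {
    int nh = P.nh, na = P.na;
    for (int j = 0; j < nh; j++) zbuf[j] = P.base[j];
    for (int p = 0; p < P.npix; p++) {
      int code = obs[p];
      if (code == S_PREY) {
        const double* d = &P.D1[0] + p;
        for (int j = 0; j < nh; j++) zbuf[j] += d[(size_t)j * P.npix];
      } else if (code == S_PRED) {
        const double* d = &P.D2[0] + p;
        for (int j = 0; j < nh; j++) zbuf[j] += d[(size_t)j * P.npix];
      }
    }
    for (int j = 0; j < nh; j++) if (zbuf[j] < 0) zbuf[j] = 0;
    for (int a = 0; a < na; a++) {
      double q = P.b4[a];
      const double* w = &P.W4[0] + (size_t)a * nh;
      for (int j = 0; j < nh; j++) q += w[j] * zbuf[j];
      qbuf[a] = q;
    }
    double qmax = qbuf[0];
    for (int a = 1; a < na; a++) if (qbuf[a] > qmax) qmax = qbuf[a];
    int nties = 0, pick = 0;
    int ties[16];
    for (int a = 0; a < na; a++) if (qbuf[a] == qmax) ties[nties++] = a;
    if (nties == 1) return ties[0];
    pick = (int)(unif_rand() * nties);
    if (pick >= nties) pick = nties - 1;
    return ties[pick];
  }
};

// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix grid, NumericMatrix food, IntegerMatrix age,
                 double bX, double bY, double fX_init, double decay,
                 int prey_max_age, int n_mcs,
                 Nullable<List> pred_policy, Nullable<List> prey_policy,
                 bool collect_pred, bool collect_prey, bool record_log) {
  Sim S;
  S.L = grid.nrow(); S.LL = S.L * S.L;
  S.grid = grid; S.food = food; S.age = age;
  S.bX = bX; S.bY = bY; S.fX_init = fX_init; S.decay = decay;
  S.prey_max_age = prey_max_age;
  for (int i = 0; i < S.LL; i++) {
    if (grid[i] == S_PRED) S.npred++;
    else if (grid[i] == S_PREY) S.nprey++;
  }
  Policy PX = parse_policy(pred_policy, collect_pred);
  Policy PY = parse_policy(prey_policy, collect_prey);
  S.track_pred = PX.active && PX.collect;
  S.track_prey = PY.active && PY.collect;
  if (S.track_pred) { S.tp.npix = PX.npix; S.lt_pred.assign(S.LL, -1); }
  if (S.track_prey) { S.ty.npix = PY.npix; S.lt_prey.assign(S.LL, -1); }

  IntegerMatrix series(n_mcs, 2);
  IntegerMatrix log;
  if (record_log) log = IntegerMatrix((R_xlen_t)S.LL * n_mcs, 5);
  R_xlen_t logrow = 0;

  std::vector<int> obuf(512), obuf2(512);
  std::vector<double> zbuf(256), qbuf(64);
  int mcs_done = 0;

  for (int m = 0; m < n_mcs; m++) {
    if (S.track_pred) std::fill(S.lt_pred.begin(), S.lt_pred.end(), -1);
    if (S.track_prey) std::fill(S.lt_prey.begin(), S.lt_prey.end(), -1);
    for (int t = 0; t < S.LL; t++) {
      int idx = (int)(unif_rand() * S.LL);
      if (idx >= S.LL) idx = S.LL - 1;
      int r = idx % S.L, c = idx / S.L;
      int occ = S.grid[idx];
      int kind, r2 = 0, c2 = 0;
      bool logged_pair = false;
      if (occ == S_EMPTY) {
        kind = EV_NOOP;
      } else {
        Policy* P = (occ == S_PRED) ? &PX : &PY;
        if (!P->active) {
          int k = (int)(unif_rand() * 8);
          if (k >= 8) k = 7;
          r2 = S.wrap(r + ADR[k]); c2 = S.wrap(c + ADC[k]);
          kind = S.interact(r, c, r2, c2);
          logged_pair = true;
        } else {
          S.extract_obs(r, c, *P, obuf.data());
          int a;
          double u = unif_rand();
          if (u < P->eps) {
            a = (int)(unif_rand() * 9);
            if (a >= 9) a = 8;
          } else {
            a = S.greedy_action(*P, obuf.data(), zbuf.data(), qbuf.data());
          }
          int fr = r, fc = c;
          if (a == 8) {
            kind = EV_NOOP;
          } else {
            r2 = S.wrap(r + ADR[a]); c2 = S.wrap(c + ADC[a]);
            kind = S.interact(r, c, r2, c2);
            logged_pair = true;
            if (kind == EV_MOVE || kind == EV_PRED_MOVE || kind == EV_PREY_MOVE) {
              fr = r2; fc = c2;
            }
          }
          if (P->collect) {
            TransStore& TS = (occ == S_PRED) ? S.tp : S.ty;
            S.extract_obs(fr, fc, *P, obuf2.data());
            double rew = S.reward_from_obs(obuf2.data(), occ, *P);
            TS.s.insert(TS.s.end(), obuf.begin(), obuf.begin() + P->npix);
            TS.s2.insert(TS.s2.end(), obuf2.begin(), obuf2.begin() + P->npix);
            TS.a.push_back(a + 1);
            TS.r.push_back(rew);
            TS.term.push_back(0);
            std::vector<int>& lt = (occ == S_PRED) ? S.lt_pred : S.lt_prey;
            lt[fc * S.L + fr] = TS.n() - 1;
          }
        }
      }
      if (record_log) {
        log(logrow, 0) = kind;
        log(logrow, 1) = r + 1; log(logrow, 2) = c + 1;
        if (logged_pair) { log(logrow, 3) = r2 + 1; log(logrow, 4) = c2 + 1; }
        else { log(logrow, 3) = NA_INTEGER; log(logrow, 4) = NA_INTEGER; }
        logrow++;
      }
    }
    S.metabolism_and_age(true);
    series(m, 0) = S.npred;
    series(m, 1) = S.nprey;
    mcs_done++;
    if (S.npred == 0 && S.nprey == 0) break;
  }

  List out = List::create(
      _["series"] = series, _["mcs_done"] = mcs_done,
      _["log"] = record_log ? (SEXP)log : R_NilValue,
      _["trans_pred"] = R_NilValue, _["trans_prey"] = R_NilValue);
  if (record_log) out["log_rows"] = (double)logrow;
  // observations are packed one column per transition (npix x n)
  auto pack = [](TransStore& TS) {
    int n = TS.n();
    IntegerMatrix s(TS.npix, n), s2(TS.npix, n);
    std::copy(TS.s.begin(), TS.s.end(), s.begin());
    std::copy(TS.s2.begin(), TS.s2.end(), s2.begin());
    return List::create(_["s"] = s, _["a"] = IntegerVector(TS.a.begin(), TS.a.end()),
                        _["r"] = NumericVector(TS.r.begin(), TS.r.end()),
                        _["s2"] = s2,
                        _["terminal"] = IntegerVector(TS.term.begin(), TS.term.end()));
  };
  if (S.track_pred) out["trans_pred"] = pack(S.tp);
  if (S.track_prey) out["trans_prey"] = pack(S.ty);
  return out;
}

// Single pairwise interaction on a world (testing / module surface).
// Coordinates are 1-based (row, col). Mutates the world in place.
// [[Rcpp::export]]
int cpp_interact(IntegerMatrix grid, NumericMatrix food, IntegerMatrix age,
                 double bX, double bY, double fX_init,
                 int r1, int c1, int r2, int c2) {
  Sim S;
  S.L = grid.nrow(); S.LL = S.L * S.L;
  S.grid = grid; S.food = food; S.age = age;
  S.bX = bX; S.bY = bY; S.fX_init = fX_init;
  return S.interact(r1 - 1, c1 - 1, r2 - 1, c2 - 1);
}

// In-place circular write of a transition batch into the replay storage
// (avoids R's copy-on-modify on the large buffer matrices). pos is 1-based.
// [[Rcpp::export]]
void cpp_buffer_write(IntegerMatrix bs, IntegerMatrix bs2, IntegerVector ba,
                      NumericVector br, IntegerVector bterm,
                      IntegerMatrix s, IntegerMatrix s2, IntegerVector a,
                      NumericVector r, IntegerVector term, IntegerVector pos) {
  int npix = bs.nrow(), n = a.size();
  for (int i = 0; i < n; i++) {
    int p = pos[i] - 1;
    std::copy(&s[0] + (size_t)i * npix, &s[0] + (size_t)(i + 1) * npix,
              &bs[0] + (size_t)p * npix);
    std::copy(&s2[0] + (size_t)i * npix, &s2[0] + (size_t)(i + 1) * npix,
              &bs2[0] + (size_t)p * npix);
    ba[p] = a[i]; br[p] = r[i]; bterm[p] = term[i];
  }
}

// Metabolism + ageing sweep as a standalone operation (mutates in place).
// [[Rcpp::export]]
void cpp_apply_metabolism(IntegerMatrix grid, NumericMatrix food,
                          IntegerMatrix age, double decay, int prey_max_age) {
  Sim S;
  S.L = grid.nrow(); S.LL = S.L * S.L;
  S.grid = grid; S.food = food; S.age = age;
  S.decay = decay; S.prey_max_age = prey_max_age;
  S.metabolism_and_age(false);
}

// Periodic-wrapped vr x vr window codes around a 1-based (r, c), row-major.
// [[Rcpp::export]]
IntegerVector cpp_observe(IntegerMatrix grid, int r, int c, int vr) {
  Sim S;
  S.L = grid.nrow(); S.LL = S.L * S.L;
  S.grid = grid;
  Policy P; P.vr = vr; P.half = vr / 2; P.npix = vr * vr;
  std::vector<int> buf(P.npix);
  S.extract_obs(r - 1, c - 1, P, buf.data());
  return IntegerVector(buf.begin(), buf.end());
}

// Shell reward from raw window codes (species: 1 prey, 2 predator).
// [[Rcpp::export]]
double cpp_reward_from_codes(IntegerVector codes, int species, int vr) {
  Sim S;
  Policy P; P.vr = vr; P.half = vr / 2; P.npix = vr * vr;
  std::vector<int> buf(codes.begin(), codes.end());
  return S.reward_from_obs(buf.data(), species, P);
}

// Q-values of a folded behaviour policy on one observation (tanh applied;
// used to test fold/inference equivalence).
// [[Rcpp::export]]
NumericVector cpp_policy_eval(List policy, IntegerVector codes) {
  Policy P = parse_policy(Nullable<List>(policy), false);
  std::vector<int> obs(codes.begin(), codes.end());
  std::vector<double> zbuf(P.nh), qbuf(P.na);
  Sim S;
  S.greedy_action(P, obs.data(), zbuf.data(), qbuf.data());
  NumericVector out(P.na);
  for (int a = 0; a < P.na; a++) out[a] = std::tanh(qbuf[a]);
  return out;
}
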