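// Lattice Monte-Carlo engine for chiral RNA-world dynamics.
//
// State lives in C++ for the duration of a run; the R interface exchanges a
// plain list-of-data-frames representation (see state_from_r / state_to_r).
// All randomness comes from R's RNG stream (unif_rand), so set.seed() on the
// R side fully determines a trajectory.  Random draws are made in an order
// that never depends on which chirality a molecule carries, so that a
// globally mirrored initial state yields the exactly mirrored trajectory.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline double ru() { return unif_rand(); }
// uniform integer in [0, n)
static inline int ri(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// ----------------------------------------------------------------- types ---

struct Chain {
  std::string seq;   // bases 'A','U','C','G'
  std::string chir;  // 'D' or 'L', one per residue
  int len() const { return (int)seq.size(); }
};

struct Att {
  Chain c;
  int start;  // 0-based template position of the chain's first residue
};

struct Cplx {
  Chain tmpl;
  std::vector<Att> atts;  // contiguous block, sorted by start
  int block_start() const { return atts.front().start; }
  int block_end() const { return atts.back().start + atts.back().c.len() - 1; }
  int paired() const {
    int r = 0;
    for (const Att& a : atts) r += a.c.len();
    return r;
  }
  int mass() const { return tmpl.len() + paired(); }
};

struct Room {
  std::string prec;  // chirality of each free precursor
  std::vector<Chain> chains;
  std::vector<Cplx> cplx;
};

struct Params {
  double P_AT, P_BB, P_CIC, P_FP, P_MN, P_MPN, P_ND, P_NDE, P_NF, P_NFR,
      P_RL, P_SP, P_TL, P_TLR;
  double F_CSS, F_CST;
  int N, C_T;
  std::string CS_REP, CS_NSR;
};

struct Ladder {
  double r1, r2, r3, rn;
  double mult(int len) const {
    if (len <= 1) return r1;
    if (len == 2) return r2;
    if (len == 3) return r3;
    return rn;
  }
};

struct Engine {
  Params P;
  Ladder ladS, ladT;  // surface / template primer-effect ladders
  bool no_term;
  int N;
  std::vector<Room> rooms;  // row-major N*N
  long step;
  long clamped;  // count of probabilities clamped into [0,1]
  std::vector<double> sep_cache;  // P_SP^((r+1)/2) for r = 1..cache size

  double sep_prob(int r) const {
    if (r >= 1 && r <= (int)sep_cache.size()) return sep_cache[r - 1];
    return std::pow(P.P_SP, (r + 1) / 2.0);
  }

  double clamp01(double p) {
    if (p > 1.0) { clamped++; return 1.0; }
    if (p < 0.0) { clamped++; return 0.0; }
    return p;
  }
  int idx(int r, int c) const { return r * N + c; }
  int neighbor(int room, int dir) const {
    int r = room / N, c = room % N;
    switch (dir) {
      case 0: r = (r + 1) % N; break;
      case 1: r = (r + N - 1) % N; break;
      case 2: c = (c + 1) % N; break;
      default: c = (c + N - 1) % N; break;
    }
    return idx(r, c);
  }
};

static inline char rand_base() {
  static const char B[4] = {'A', 'U', 'C', 'G'};
  return B[ri(4)];
}

static inline bool wc_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C');
}

static void reverse_chain(Chain& c) {
  std::reverse(c.seq.begin(), c.seq.end());
  std::reverse(c.chir.begin(), c.chir.end());
}

// Cross-inhibition is encoded structurally: a heterochiral junction at a
// chain end marks that end as terminated.  end: 0 = front, 1 = back.
static inline bool end_blocked(const Chain& c, int end, bool no_term) {
  if (no_term) return false;
  int n = c.len();
  if (n < 2) return false;
  if (end == 0) return c.chir[0] != c.chir[1];
  return c.chir[n - 1] != c.chir[n - 2];
}

// Ribozyme recognition: the chain must contain the catalytic domain as a
// contiguous base subsequence (chains are directionless, so both residue
// orders are checked), the matched residues must share one chirality, and
// the whole chain must not exceed twice the domain length.
static bool detect_ribozyme(const Chain& ch, const std::string& dom,
                            char* out_chir) {
  int L = ch.len(), D = (int)dom.size();
  if (D < 1 || L < D || L > 2 * D) return false;
  std::string rdom(dom.rbegin(), dom.rend());
  for (int pass = 0; pass < 2; ++pass) {
    const std::string& d = (pass == 0) ? dom : rdom;
    for (int s = 0; s + D <= L; ++s) {
      bool ok = true;
      for (int k = 0; k < D; ++k)
        if (ch.seq[s + k] != d[k]) { ok = false; break; }
      if (!ok) continue;
      char c0 = ch.chir[s];
      for (int k = 1; k < D; ++k)
        if (ch.chir[s + k] != c0) { ok = false; break; }
      if (ok) { if (out_chir) *out_chir = c0; return true; }
    }
    if (pass == 0 && rdom == dom) break;
  }
  return false;
}

// ------------------------------------------------------------ conversion ---

static Chain chain_from(const std::string& seq, const std::string& chir) {
  if (seq.size() != chir.size())
    stop("sequence and chirality strings differ in length");
  Chain c; c.seq = seq; c.chir = chir;
  return c;
}

static void state_from_r(Engine& E, List state) {
  E.N = as<int>(state["N"]);
  E.step = (long)as<double>(state["step"]);
  E.rooms.assign((size_t)E.N * E.N, Room());
  DataFrame prec = as<DataFrame>(state["precursors"]);
  IntegerVector pr = prec["row"], pc = prec["col"];
  CharacterVector pch = prec["chirality"];
  for (int i = 0; i < pr.size(); ++i) {
    std::string s = as<std::string>(pch[i]);
    E.rooms[E.idx(pr[i], pc[i])].prec.push_back(s[0]);
  }
  DataFrame chn = as<DataFrame>(state["chains"]);
  IntegerVector cr = chn["row"], cc = chn["col"];
  CharacterVector cs = chn["seq"], ck = chn["chir"];
  for (int i = 0; i < cr.size(); ++i)
    E.rooms[E.idx(cr[i], cc[i])].chains.push_back(
        chain_from(as<std::string>(cs[i]), as<std::string>(ck[i])));
  List cx = as<List>(state["complexes"]);
  for (int i = 0; i < cx.size(); ++i) {
    List one = cx[i];
    Cplx c;
    c.tmpl = chain_from(as<std::string>(one["template_seq"]),
                        as<std::string>(one["template_chir"]));
    IntegerVector st = one["att_start"];
    CharacterVector as_ = one["att_seq"], ac = one["att_chir"];
    for (int k = 0; k < st.size(); ++k) {
      Att a;
      a.c = chain_from(as<std::string>(as_[k]), as<std::string>(ac[k]));
      a.start = st[k];
      c.atts.push_back(a);
    }
    if (c.atts.empty()) stop("complex without attachments");
    for (size_t k = 0; k + 1 < c.atts.size(); ++k)
      if (c.atts[k + 1].start != c.atts[k].start + c.atts[k].c.len())
        stop("complex attachments must form one contiguous block");
    if (c.block_start() < 0 || c.block_end() >= c.tmpl.len())
      stop("attachments exceed template length");
    int room = E.idx(as<int>(one["row"]), as<int>(one["col"]));
    E.rooms[room].cplx.push_back(c);
  }
}

static List state_to_r(const Engine& E) {
  std::vector<int> pr, pc, cr, cc;
  std::vector<std::string> pch, cs, ck;
  List cxl;
  for (int room = 0; room < E.N * E.N; ++room) {
    int r = room / E.N, c = room % E.N;
    const Room& R = E.rooms[room];
    for (char ch : R.prec) {
      pr.push_back(r); pc.push_back(c); pch.push_back(std::string(1, ch));
    }
    for (const Chain& cn : R.chains) {
      cr.push_back(r); cc.push_back(c);
      cs.push_back(cn.seq); ck.push_back(cn.chir);
    }
    for (const Cplx& cx : R.cplx) {
      IntegerVector st((int)cx.atts.size());
      CharacterVector as_((int)cx.atts.size()), ac((int)cx.atts.size());
      for (size_t k = 0; k < cx.atts.size(); ++k) {
        st[k] = cx.atts[k].start;
        as_[k] = cx.atts[k].c.seq;
        ac[k] = cx.atts[k].c.chir;
      }
      cxl.push_back(List::create(
          _["row"] = r, _["col"] = c, _["template_seq"] = cx.tmpl.seq,
          _["template_chir"] = cx.tmpl.chir, _["att_start"] = st,
          _["att_seq"] = as_, _["att_chir"] = ac));
    }
  }
  return List::create(
      _["N"] = E.N, _["step"] = (double)E.step,
      _["precursors"] = DataFrame::create(
          _["row"] = wrap(pr), _["col"] = wrap(pc),
          _["chirality"] = wrap(pch), _["stringsAsFactors"] = false),
      _["chains"] = DataFrame::create(
          _["row"] = wrap(cr), _["col"] = wrap(cc), _["seq"] = wrap(cs),
          _["chir"] = wrap(ck), _["stringsAsFactors"] = false),
      _["complexes"] = cxl);
}

static Params params_from_r(List p) {
  Params P;
  P.P_AT = as<double>(p["P_AT"]);   P.P_BB = as<double>(p["P_BB"]);
  P.P_CIC = as<double>(p["P_CIC"]); P.P_FP = as<double>(p["P_FP"]);
  P.P_MN = as<double>(p["P_MN"]);   P.P_MPN = as<double>(p["P_MPN"]);
  P.P_ND = as<double>(p["P_ND"]);   P.P_NDE = as<double>(p["P_NDE"]);
  P.P_NF = as<double>(p["P_NF"]);   P.P_NFR = as<double>(p["P_NFR"]);
  P.P_RL = as<double>(p["P_RL"]);   P.P_SP = as<double>(p["P_SP"]);
  P.P_TL = as<double>(p["P_TL"]);   P.P_TLR = as<double>(p["P_TLR"]);
  P.F_CSS = as<double>(p["F_CSS"]); P.F_CST = as<double>(p["F_CST"]);
  P.N = as<int>(p["N"]);            P.C_T = as<int>(p["C_T"]);
  P.CS_REP = as<std::string>(p["CS_REP"]);
  P.CS_NSR = as<std::string>(p["CS_NSR"]);
  return P;
}

// ---------------------------------------------------------------- phases ---

struct Credits {
  std::vector<int> nsrD, nsrL, repD, repL;
};

static void phase_census(Engine& E, Credits& cr, bool need_nsr,
                         bool need_rep) {
  int n = E.N * E.N;
  cr.nsrD.assign(n, 0); cr.nsrL.assign(n, 0);
  cr.repD.assign(n, 0); cr.repL.assign(n, 0);
  if (!need_nsr && !need_rep) return;
  for (int room = 0; room < n; ++room) {
    for (const Chain& c : E.rooms[room].chains) {
      char ch;
      if (need_nsr && detect_ribozyme(c, E.P.CS_NSR, &ch))
        (ch == 'D' ? cr.nsrD : cr.nsrL)[room]++;
      if (need_rep && detect_ribozyme(c, E.P.CS_REP, &ch))
        (ch == 'D' ? cr.repD : cr.repL)[room]++;
    }
  }
}

// choose k distinct indices out of n by partial Fisher-Yates; result in sel
static void pick_indices(int n, int k, std::vector<int>& sel) {
  static std::vector<int> idx;
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  sel.resize(k);
  for (int j = 0; j < k; ++j) {
    int r = j + ri(n - j);
    std::swap(idx[j], idx[r]);
    sel[j] = idx[j];
  }
}

// racemization of precursors, then (possibly NSR-catalysed) nucleotide
// formation; a formed nucleotide is a 1-mer chain with a uniform random
// base.  Per-molecule Bernoulli events are sampled as a binomial count of
// occurrences plus a uniform choice of which molecules they hit, which is
// the identical distribution.
static void phase_precursors(Engine& E, Credits& cr) {
  std::vector<int> sel;
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    int n = (int)R.prec.size();
    if (n == 0) continue;
    // racemization
    if (E.P.P_CIC == 0.5) {
      // fair coin per precursor, 32 flips per RNG draw
      int i = 0;
      while (i < n) {
        unsigned int w = (unsigned int)(ru() * 4294967296.0);
        for (int b = 0; b < 32 && i < n; ++b, ++i) {
          if (w & 1u) R.prec[i] = (R.prec[i] == 'D') ? 'L' : 'D';
          w >>= 1;
        }
      }
    } else if (E.P.P_CIC > 0) {
      int k = (int)R::rbinom((double)n, E.P.P_CIC);
      pick_indices(n, k, sel);
      for (int i : sel) R.prec[i] = (R.prec[i] == 'D') ? 'L' : 'D';
    }
    // nucleotide formation
    bool credits = cr.nsrD[room] > 0 || cr.nsrL[room] > 0;
    if (!credits) {
      if (E.P.P_NF <= 0) continue;
      int k = (int)R::rbinom((double)n, E.P.P_NF);
      if (k == 0) continue;
      pick_indices(n, k, sel);
      std::sort(sel.begin(), sel.end(), std::greater<int>());
      for (int i : sel) {
        Chain nt;
        nt.seq = std::string(1, rand_base());
        nt.chir = std::string(1, R.prec[i]);
        R.chains.push_back(std::move(nt));
        R.prec.erase(R.prec.begin() + i);
      }
    } else {
      // NSR catalysis present: per-molecule loop with credit accounting
      std::string keep;
      keep.reserve(R.prec.size());
      for (char ch : R.prec) {
        int& credit = (ch == 'D') ? cr.nsrD[room] : cr.nsrL[room];
        double p = (credit > 0) ? E.P.P_NFR : E.P.P_NF;
        if (ru() < p) {
          if (credit > 0) credit--;
          Chain nt;
          nt.seq = std::string(1, rand_base());
          nt.chir = std::string(1, ch);
          R.chains.push_back(std::move(nt));
        } else {
          keep.push_back(ch);
        }
      }
      R.prec.swap(keep);
    }
  }
}

// free nucleotides (1-mer chains) decay back to precursors
static void phase_nt_decay(Engine& E) {
  if (E.P.P_ND <= 0) return;
  std::vector<int> ones, sel;
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    ones.clear();
    for (size_t i = 0; i < R.chains.size(); ++i)
      if (R.chains[i].len() == 1) ones.push_back((int)i);
    if (ones.empty()) continue;
    int k = (int)R::rbinom((double)ones.size(), E.P.P_ND);
    if (k == 0) continue;
    pick_indices((int)ones.size(), k, sel);
    std::vector<char> dead(R.chains.size(), 0);
    for (int j : sel) {
      R.prec.push_back(R.chains[ones[j]].chir[0]);
      dead[ones[j]] = 1;
    }
    std::vector<Chain> keep;
    keep.reserve(R.chains.size() - k);
    for (size_t i = 0; i < R.chains.size(); ++i)
      if (!dead[i]) keep.push_back(std::move(R.chains[i]));
    R.chains.swap(keep);
  }
}

// -- collisions -------------------------------------------------------------

// surface-mediated end-to-end ligation of two free chains
static void try_surface_ligation(Engine& E, std::vector<Chain>& ch,
                                 std::vector<char>& alive, int a, int b,
                                 double u) {
  if (E.P.P_RL <= 0) return;  // route disabled: no draws needed
  int la = ch[a].len(), lb = ch[b].len();
  // the acceptance uniform u arrives first: if it already exceeds an upper
  // bound on the rate the attempt is rejected without spending further
  // draws (the final test below uses the same uniform, so this is exact)
  double upper = E.P.P_RL * std::max(E.ladS.mult(la), E.ladS.mult(lb));
  if (u >= E.clamp01(upper)) return;
  int ext, inc;
  if (la != lb) { ext = (la > lb) ? a : b; }
  else          { ext = (ru() < 0.5) ? a : b; }
  inc = (ext == a) ? b : a;
  int ext_end = (ru() < 0.5) ? 0 : 1;
  int inc_end = (ru() < 0.5) ? 0 : 1;
  if (end_blocked(ch[ext], ext_end, E.no_term)) return;
  if (end_blocked(ch[inc], inc_end, E.no_term)) return;
  char ec = (ext_end == 0) ? ch[ext].chir.front() : ch[ext].chir.back();
  char ic = (inc_end == 0) ? ch[inc].chir.front() : ch[inc].chir.back();
  double factor = (ec == ic) ? 1.0 : E.P.F_CSS;
  double rate = E.clamp01(E.P.P_RL * E.ladS.mult(ch[ext].len()) * factor);
  if (u >= rate) return;
  Chain merged = ch[ext];
  if (ext_end == 0) reverse_chain(merged);   // joining end at the back
  Chain tail = ch[inc];
  if (inc_end == 1) reverse_chain(tail);     // joining end at the front
  merged.seq += tail.seq;
  merged.chir += tail.chir;
  ch[ext] = std::move(merged);
  alive[inc] = 0;
}

// base-pairing success probability for a substrate aligned on a template
static double pairing_prob(const Engine& E, const Chain& tmpl, int start,
                           const Chain& sub) {
  double p = E.P.P_AT;
  for (int k = 0; k < sub.len(); ++k)
    if (!wc_pair(tmpl.seq[start + k], sub.seq[k])) p *= E.P.P_FP;
  return p;
}

// substrate orientation on the template is chosen at random (chains are
// directionless); monomers need no draw
static Chain oriented_copy(const Chain& c) {
  Chain s = c;
  if (s.len() > 1 && ru() < 0.5) reverse_chain(s);
  return s;
}

// attraction of a free chain onto a bare template (another free chain)
static bool try_attract_new(Engine& E, std::vector<Chain>& ch,
                            std::vector<char>& alive, std::vector<Cplx>& cx,
                            std::vector<char>& calive, int a, int b,
                            double u) {
  if (E.P.P_AT <= 0) return false;  // route disabled: no draws needed
  if (u >= E.P.P_AT) return false;  // success prob never exceeds P_AT
  int la = ch[a].len(), lb = ch[b].len();
  int t;
  if (la != lb) { t = (la > lb) ? a : b; }
  else          { t = (ru() < 0.5) ? a : b; }
  int s = (t == a) ? b : a;
  int span = ch[t].len() - ch[s].len();
  int start = (span == 0) ? 0 : ri(span + 1);
  Chain sub = oriented_copy(ch[s]);
  double p = pairing_prob(E, ch[t], start, sub);
  if (u >= p) return false;
  Cplx c;
  c.tmpl = ch[t];
  Att at; at.c = std::move(sub); at.start = start;
  c.atts.push_back(std::move(at));
  cx.push_back(std::move(c));
  calive.push_back(1);
  alive[a] = 0; alive[b] = 0;
  return true;
}

// attraction of a free chain next to the growing block of an existing complex
static void try_attract_extend(Engine& E, std::vector<Chain>& ch,
                               std::vector<char>& alive, Cplx& c, int s) {
  if (E.P.P_AT <= 0) return;
  int ls = ch[s].len();
  bool left = c.block_start() - ls >= 0;
  bool right = c.block_end() + ls <= c.tmpl.len() - 1;
  if (!left && !right) return;
  double u = ru();
  if (u >= E.P.P_AT) return;
  bool use_left = left && (!right || ru() < 0.5);
  int start = use_left ? c.block_start() - ls : c.block_end() + 1;
  Chain sub = oriented_copy(ch[s]);
  double p = pairing_prob(E, c.tmpl, start, sub);
  if (u >= p) return;
  Att at; at.c = std::move(sub); at.start = start;
  if (use_left) c.atts.insert(c.atts.begin(), std::move(at));
  else          c.atts.push_back(std::move(at));
  alive[s] = 0;
}

// C_T rounds of random pairwise grouping; each pair attempts either
// end-to-end ligation or template attraction ("one of the two events")
static void phase_collisions(Engine& E) {
  struct H { int kind; int id; };  // kind 0 = chain, 1 = complex
  if (E.P.P_RL <= 0 && E.P.P_AT <= 0) return;  // both routes disabled
  static std::vector<char> alive, calive;
  static std::vector<H> pool;
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    std::vector<Chain>& ch = R.chains;
    std::vector<Cplx>& cx = R.cplx;
    alive.assign(ch.size(), 1);
    calive.assign(cx.size(), 1);
    for (int t = 0; t < E.P.C_T; ++t) {
      pool.clear();
      for (size_t i = 0; i < ch.size(); ++i)
        if (alive[i]) pool.push_back({0, (int)i});
      for (size_t i = 0; i < cx.size(); ++i)
        if (calive[i]) pool.push_back({1, (int)i});
      int m = (int)pool.size();
      if (m < 2) break;
      // uniform random perfect matching: choose the idle molecule first
      // when the count is odd, then repeatedly pair the last remaining
      // element with a uniformly chosen partner
      if (m % 2 == 1) {
        int j = ri(m);
        std::swap(pool[j], pool[m - 1]);
        m--;
      }
      while (m >= 2) {
        int j = (m == 2) ? 0 : ri(m - 1);
        H x = pool[m - 1], y = pool[j];
        pool[j] = pool[m - 2];
        m -= 2;
        if (x.kind == 0 && y.kind == 0) {
          // both branches are open between two free chains; one uniform
          // drives both the branch choice and, rescaled, the acceptance
          double v = ru();
          if (v < 0.5)
            try_surface_ligation(E, ch, alive, x.id, y.id, 2.0 * v);
          else
            try_attract_new(E, ch, alive, cx, calive, x.id, y.id,
                            2.0 * v - 1.0);
        } else if (x.kind != y.kind) {
          int s = (x.kind == 0) ? x.id : y.id;
          Cplx& c = cx[(x.kind == 1) ? x.id : y.id];
          try_attract_extend(E, ch, alive, c, s);
        }
        // complex-complex collisions are inert
      }
    }
    // compact dead entries in place
    size_t w = 0;
    for (size_t i = 0; i < ch.size(); ++i)
      if (alive[i]) { if (w != i) ch[w] = std::move(ch[i]); ++w; }
    ch.resize(w);
    w = 0;
    for (size_t i = 0; i < cx.size(); ++i)
      if (calive[i]) { if (w != i) cx[w] = std::move(cx[i]); ++w; }
    cx.resize(w);
  }
}

// -- template-directed ligation ---------------------------------------------

static bool uniform_chir(const std::string& s, char* out) {
  for (char c : s)
    if (c != s[0]) return false;
  *out = s[0];
  return true;
}

static void phase_template_ligation(Engine& E, Credits& cr) {
  for (int room = 0; room < E.N * E.N; ++room) {
    for (Cplx& c : E.rooms[room].cplx) {
      size_t i = 0;
      while (i + 1 < c.atts.size()) {
        Att& A = c.atts[i];
        Att& B = c.atts[i + 1];
        bool a_ext;
        if (A.c.len() != B.c.len()) a_ext = A.c.len() > B.c.len();
        else                        a_ext = ru() < 0.5;
        Chain& ext = a_ext ? A.c : B.c;
        Chain& inc = a_ext ? B.c : A.c;
        int ext_end = a_ext ? 1 : 0;  // junction side of the extender
        if (end_blocked(ext, ext_end, E.no_term) ||
            end_blocked(inc, 1 - ext_end, E.no_term)) { ++i; continue; }
        bool ligated = false;
        // enzymatic route: template, both substrates and an available REP
        // of one common chirality
        char ct, ca, cb;
        if (E.P.P_TLR > 0 && uniform_chir(c.tmpl.chir, &ct) &&
            uniform_chir(A.c.chir, &ca) && uniform_chir(B.c.chir, &cb) &&
            ct == ca && ca == cb &&
            ((ct == 'D' ? cr.repD : cr.repL)[room] > 0)) {
          if (ru() < E.P.P_TLR) {
            (ct == 'D' ? cr.repD : cr.repL)[room]--;
            ligated = true;
          }
        } else {
          // non-enzymatic route with chiral selection at the junction
          char ec = a_ext ? A.c.chir.back() : B.c.chir.front();
          char ic = a_ext ? B.c.chir.front() : A.c.chir.back();
          int ipos = a_ext ? B.start : A.start + A.c.len() - 1;
          char tc = c.tmpl.chir[ipos];
          double factor = (ic == ec && ic == tc) ? 1.0 : E.P.F_CST;
          double rate =
              E.clamp01(E.P.P_TL * E.ladT.mult(ext.len()) * factor);
          if (ru() < rate) ligated = true;
        }
        if (ligated) {
          A.c.seq += B.c.seq;
          A.c.chir += B.c.chir;
          c.atts.erase(c.atts.begin() + i + 1);
          // stay at i: the next junction is now between the merged
          // attachment and the former i+2
        } else {
          ++i;
        }
      }
    }
  }
}

// -- degradation ------------------------------------------------------------

// normalization after end decay: drop emptied outer attachments, dissolve
// complexes whose template or attachment block vanished
static void normalize_cplx(Room& R, std::vector<Cplx>& keep, Cplx& c) {
  while (!c.atts.empty() && c.atts.front().c.len() == 0)
    c.atts.erase(c.atts.begin());
  while (!c.atts.empty() && c.atts.back().c.len() == 0)
    c.atts.pop_back();
  if (c.tmpl.len() == 0) {
    for (Att& a : c.atts)
      if (a.c.len() > 0) R.chains.push_back(std::move(a.c));
    return;
  }
  if (c.atts.empty()) {
    R.chains.push_back(std::move(c.tmpl));
    return;
  }
  keep.push_back(std::move(c));
}

// End decay.  Free-chain ends decay at P_NDE.  In a complex the template's
// ends decay at P_NDE when unpaired; a duplex end (template end paired with
// the outer residue of the attachment block) loses both residues at
// P_NDE^(3/2).  Attachment-block ends paired to template-interior residues
// are treated as protected.
static void phase_end_decay(Engine& E) {
  if (E.P.P_NDE <= 0) return;
  double p1 = E.P.P_NDE, p2 = std::pow(E.P.P_NDE, 1.5);
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    size_t nch = R.chains.size();  // fixed: precursors appended, not chains
    for (size_t j = 0; j < nch; ++j) {
      Chain& c = R.chains[j];
      if (c.len() >= 2 && ru() < p1) {
        R.prec.push_back(c.chir.front());
        c.seq.erase(c.seq.begin());
        c.chir.erase(c.chir.begin());
      }
      if (c.len() >= 2 && ru() < p1) {
        R.prec.push_back(c.chir.back());
        c.seq.pop_back();
        c.chir.pop_back();
      }
    }
    std::vector<Cplx> keep;
    keep.reserve(R.cplx.size());
    for (Cplx& c : R.cplx) {
      int len0 = c.tmpl.len();  // a 1-mer template has only one end
      // front end of the template
      if (c.tmpl.len() >= 1) {
        bool paired = c.block_start() == 0;
        double p = paired ? p2 : p1;
        if (ru() < p) {
          R.prec.push_back(c.tmpl.chir.front());
          c.tmpl.seq.erase(c.tmpl.seq.begin());
          c.tmpl.chir.erase(c.tmpl.chir.begin());
          if (paired) {
            Att& a = c.atts.front();
            R.prec.push_back(a.c.chir.front());
            a.c.seq.erase(a.c.seq.begin());
            a.c.chir.erase(a.c.chir.begin());
            a.start = 1;  // rebased to 0 by the shift below
          }
          for (Att& a : c.atts) a.start -= 1;
        }
      }
      // back end of the template (may already have shrunk)
      if (len0 >= 2 && c.tmpl.len() >= 1 &&
          !(c.atts.size() == 1 && c.atts.front().c.len() == 0)) {
        bool paired = !c.atts.empty() && c.atts.back().c.len() > 0 &&
                      c.block_end() == c.tmpl.len() - 1;
        double p = paired ? p2 : p1;
        if (ru() < p) {
          R.prec.push_back(c.tmpl.chir.back());
          c.tmpl.seq.pop_back();
          c.tmpl.chir.pop_back();
          if (paired) {
            Att& a = c.atts.back();
            R.prec.push_back(a.c.chir.back());
            a.c.seq.pop_back();
            a.c.chir.pop_back();
          }
        }
      }
      normalize_cplx(R, keep, c);
    }
    R.cplx.swap(keep);
  }
}

// split a complex at the given sorted template-bond indices; attachments
// spanning a cut are cut at the parallel bond
static void split_cplx_at(Room& R, std::vector<Cplx>& out_cplx,
                          const Cplx& c, const std::vector<int>& cuts) {
  int Lt = c.tmpl.len();
  std::vector<std::pair<int, int>> segs;
  int s = 0;
  for (int cut : cuts) { segs.push_back({s, cut}); s = cut + 1; }
  segs.push_back({s, Lt - 1});
  for (auto& se : segs) {
    int s0 = se.first, e0 = se.second;
    Cplx part;
    part.tmpl.seq = c.tmpl.seq.substr(s0, e0 - s0 + 1);
    part.tmpl.chir = c.tmpl.chir.substr(s0, e0 - s0 + 1);
    for (const Att& a : c.atts) {
      int a0 = a.start, a1 = a.start + a.c.len() - 1;
      int lo = std::max(a0, s0), hi = std::min(a1, e0);
      if (lo > hi) continue;
      Att piece;
      piece.c.seq = a.c.seq.substr(lo - a0, hi - lo + 1);
      piece.c.chir = a.c.chir.substr(lo - a0, hi - lo + 1);
      piece.start = lo - s0;
      part.atts.push_back(std::move(piece));
    }
    if (part.atts.empty())
      R.chains.push_back(std::move(part.tmpl));
    else
      out_cplx.push_back(std::move(part));
  }
}

// Phosphodiester-bond breaking.  A bond in a single-stranded region breaks
// at P_BB; where two parallel bonds exist (template bond plus the bond of
// the attachment residues paired across it) both break together at
// P_BB^(3/2).
static void phase_bond_break(Engine& E) {
  if (E.P.P_BB <= 0) return;
  double p1 = E.P.P_BB, p2 = std::pow(E.P.P_BB, 1.5);
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    std::vector<Chain> out;
    out.reserve(R.chains.size());
    for (Chain& c : R.chains) {
      int nb = c.len() - 1;
      if (nb <= 0) { out.push_back(std::move(c)); continue; }
      std::vector<int> cuts;
      int k = (int)R::rbinom((double)nb, p1);
      if (k > 0) {
        pick_indices(nb, k, cuts);
        std::sort(cuts.begin(), cuts.end());
      }
      if (cuts.empty()) { out.push_back(std::move(c)); continue; }
      int s = 0;
      for (int cut : cuts) {
        Chain frag;
        frag.seq = c.seq.substr(s, cut - s + 1);
        frag.chir = c.chir.substr(s, cut - s + 1);
        out.push_back(std::move(frag));
        s = cut + 1;
      }
      Chain frag;
      frag.seq = c.seq.substr(s);
      frag.chir = c.chir.substr(s);
      out.push_back(std::move(frag));
    }
    R.chains.swap(out);
    std::vector<Cplx> keep;
    keep.reserve(R.cplx.size());
    static std::vector<int> par, sng, cuts, sel;
    for (Cplx& c : R.cplx) {
      // classify bonds: parallel iff one attachment covers both j and j+1
      par.clear(); sng.clear(); cuts.clear();
      size_t ai = 0;
      for (int j = 0; j + 1 < c.tmpl.len(); ++j) {
        while (ai < c.atts.size() &&
               c.atts[ai].start + c.atts[ai].c.len() - 1 < j + 1)
          ++ai;
        bool parallel =
            ai < c.atts.size() && c.atts[ai].start <= j &&
            j + 1 <= c.atts[ai].start + c.atts[ai].c.len() - 1;
        (parallel ? par : sng).push_back(j);
      }
      int k2 = par.empty() ? 0 : (int)R::rbinom((double)par.size(), p2);
      int k1 = sng.empty() ? 0 : (int)R::rbinom((double)sng.size(), p1);
      if (k2 > 0) {
        pick_indices((int)par.size(), k2, sel);
        for (int j : sel) cuts.push_back(par[j]);
      }
      if (k1 > 0) {
        pick_indices((int)sng.size(), k1, sel);
        for (int j : sel) cuts.push_back(sng[j]);
      }
      if (cuts.empty()) {
        keep.push_back(std::move(c));
      } else {
        std::sort(cuts.begin(), cuts.end());
        split_cplx_at(R, keep, c, cuts);
      }
    }
    R.cplx.swap(keep);
  }
}

// duplex strand separation at P_SP^((r+1)/2), r = paired residues
static void phase_separation(Engine& E) {
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    std::vector<Cplx> keep;
    keep.reserve(R.cplx.size());
    for (Cplx& c : R.cplx) {
      int r = c.paired();
      double p = E.sep_prob(r);
      if (ru() < p) {
        R.chains.push_back(std::move(c.tmpl));
        for (Att& a : c.atts) R.chains.push_back(std::move(a.c));
      } else {
        keep.push_back(std::move(c));
      }
    }
    R.cplx.swap(keep);
  }
}

// diffusion to a uniformly chosen 4-neighbor room; a complex moves as one
// unit with mass = all of its residues.  Movers are pulled out of their
// rooms into a transfer buffer first and delivered afterwards, so nothing
// moves twice within the phase.
static void phase_movement(Engine& E) {
  static std::vector<int> sel, ones, movers;
  static std::vector<std::pair<int, char>> prec_out;
  static std::vector<std::pair<int, Chain>> chain_out;
  static std::vector<std::pair<int, Cplx>> cplx_out;
  prec_out.clear(); chain_out.clear(); cplx_out.clear();
  for (int room = 0; room < E.N * E.N; ++room) {
    Room& R = E.rooms[room];
    int n = (int)R.prec.size();
    if (n > 0 && E.P.P_MPN > 0) {
      int k = (int)R::rbinom((double)n, E.P.P_MPN);
      if (k > 0) {
        pick_indices(n, k, sel);
        std::sort(sel.begin(), sel.end(), std::greater<int>());
        for (int i : sel) {
          prec_out.push_back({E.neighbor(room, ri(4)), R.prec[i]});
          R.prec[i] = R.prec.back();
          R.prec.pop_back();
        }
      }
    }
    // 1-mers all share probability P_MN: binomial count + uniform choice;
    // longer chains are few and get individual draws
    if (!R.chains.empty() && E.P.P_MN > 0) {
      int nc = (int)R.chains.size();
      movers.clear();
      ones.clear();
      for (int i = 0; i < nc; ++i)
        if (R.chains[i].len() == 1) ones.push_back(i);
      if (!ones.empty()) {
        int k = (int)R::rbinom((double)ones.size(), E.clamp01(E.P.P_MN));
        pick_indices((int)ones.size(), k, sel);
        for (int j : sel) movers.push_back(ones[j]);
      }
      for (int i = 0; i < nc; ++i) {
        if (R.chains[i].len() == 1) continue;
        double p = E.P.P_MN / std::sqrt((double)R.chains[i].len());
        if (ru() < p) movers.push_back(i);
      }
      std::sort(movers.begin(), movers.end(), std::greater<int>());
      for (int i : movers) {
        chain_out.push_back({E.neighbor(room, ri(4)),
                             std::move(R.chains[i])});
        R.chains[i] = std::move(R.chains.back());
        R.chains.pop_back();
      }
    }
    if (!R.cplx.empty() && E.P.P_MN > 0) {
      movers.clear();
      for (int i = 0; i < (int)R.cplx.size(); ++i) {
        double p = E.P.P_MN / std::sqrt((double)R.cplx[i].mass());
        if (ru() < p) movers.push_back(i);
      }
      std::sort(movers.begin(), movers.end(), std::greater<int>());
      for (int i : movers) {
        cplx_out.push_back({E.neighbor(room, ri(4)),
                            std::move(R.cplx[i])});
        R.cplx[i] = std::move(R.cplx.back());
        R.cplx.pop_back();
      }
    }
  }
  for (auto& pr : prec_out) E.rooms[pr.first].prec.push_back(pr.second);
  for (auto& pr : chain_out)
    E.rooms[pr.first].chains.push_back(std::move(pr.second));
  for (auto& pr : cplx_out)
    E.rooms[pr.first].cplx.push_back(std::move(pr.second));
}

static double prof_t[9];
static bool prof_on = false;

static void engine_step(Engine& E, bool need_nsr, bool need_rep) {
  Credits cr;
  if (!prof_on) {
    phase_census(E, cr, need_nsr, need_rep);
    phase_precursors(E, cr);
    phase_nt_decay(E);
    phase_collisions(E);
    phase_template_ligation(E, cr);
    phase_end_decay(E);
    phase_bond_break(E);
    phase_separation(E);
    phase_movement(E);
  } else {
    clock_t t0 = clock(), t1;
#define TICK(i) t1 = clock(); prof_t[i] += (double)(t1 - t0) / CLOCKS_PER_SEC; t0 = t1;
    phase_census(E, cr, need_nsr, need_rep); TICK(0)
    phase_precursors(E, cr); TICK(1)
    phase_nt_decay(E); TICK(2)
    phase_collisions(E); TICK(3)
    phase_template_ligation(E, cr); TICK(4)
    phase_end_decay(E); TICK(5)
    phase_bond_break(E); TICK(6)
    phase_separation(E); TICK(7)
    phase_movement(E); TICK(8)
#undef TICK
  }
  E.step++;
}

// [[Rcpp::export]]
NumericVector cpp_profile(bool enable) {
  prof_on = enable;
  NumericVector out(9);
  for (int i = 0; i < 9; ++i) { out[i] = prof_t[i]; prof_t[i] = 0; }
  out.attr("names") = CharacterVector::create(
      "census", "precursors", "nt_decay", "collisions", "template_ligation",
      "end_decay", "bond_break", "separation", "movement");
  return out;
}

// ------------------------------------------------------------- recording ---

struct Rec {
  double step, ee;
  long D, L, precD, precL, ntD, ntL;
  long nsrD, nsrL, repD, repL;
  std::vector<long> histD, histL;  // lengths 1..20 and 21 = overflow
};

static void count_chain_hist(const Chain& c, std::vector<long>& hD,
                             std::vector<long>& hL) {
  int nd = 0;
  for (char ch : c.chir) nd += (ch == 'D');
  int nl = c.len() - nd;
  // classify by majority residue chirality; ties follow residue 0 so the
  // record stays exactly mirror-antisymmetric
  char cls = (nd > nl) ? 'D' : (nl > nd) ? 'L' : c.chir[0];
  int bin = std::min(c.len(), 21) - 1;
  (cls == 'D' ? hD : hL)[bin]++;
}

static Rec record_state(const Engine& E) {
  Rec r;
  r.step = (double)E.step;
  r.D = r.L = r.precD = r.precL = r.ntD = r.ntL = 0;
  r.nsrD = r.nsrL = r.repD = r.repL = 0;
  r.histD.assign(21, 0);
  r.histL.assign(21, 0);
  for (int room = 0; room < E.N * E.N; ++room) {
    const Room& R = E.rooms[room];
    for (char ch : R.prec) (ch == 'D' ? r.precD : r.precL)++;
    for (const Chain& c : R.chains) {
      for (char ch : c.chir) (ch == 'D' ? r.D : r.L)++;
      if (c.len() == 1) (c.chir[0] == 'D' ? r.ntD : r.ntL)++;
      count_chain_hist(c, r.histD, r.histL);
      char rc;
      if (detect_ribozyme(c, E.P.CS_NSR, &rc)) (rc == 'D' ? r.nsrD : r.nsrL)++;
      if (detect_ribozyme(c, E.P.CS_REP, &rc)) (rc == 'D' ? r.repD : r.repL)++;
    }
    for (const Cplx& c : R.cplx) {
      for (char ch : c.tmpl.chir) (ch == 'D' ? r.D : r.L)++;
      count_chain_hist(c.tmpl, r.histD, r.histL);
      for (const Att& a : c.atts) {
        for (char ch : a.c.chir) (ch == 'D' ? r.D : r.L)++;
        count_chain_hist(a.c, r.histD, r.histL);
      }
    }
  }
  r.D += r.precD;
  r.L += r.precL;
  r.ee = (double)(r.D - r.L) / (double)(r.D + r.L);
  return r;
}

// ------------------------------------------------------------ run driver ---

static void apply_inoculation(Engine& E, int count, int length,
                              const std::string& chir,
                              const std::string& seq) {
  for (int i = 0; i < count; ++i) {
    Chain c;
    if (seq.empty()) {
      c.seq.reserve(length);
      for (int k = 0; k < length; ++k) c.seq.push_back(rand_base());
    } else {
      c.seq = seq;
    }
    c.chir = std::string(c.seq.size(), chir[0]);
    E.rooms[ri(E.N * E.N)].chains.push_back(std::move(c));
  }
}

// [[Rcpp::export]]
List cpp_run(List state, List params, List control) {
  Engine E;
  E.P = params_from_r(params);
  NumericVector ls = control["surface_ladder"], lt = control["template_ladder"];
  E.ladS = {ls[0], ls[1], ls[2], ls[3]};
  E.ladT = {lt[0], lt[1], lt[2], lt[3]};
  E.no_term = as<bool>(control["no_termination"]);
  E.clamped = 0;
  E.sep_cache.resize(64);
  for (int r = 1; r <= 64; ++r)
    E.sep_cache[r - 1] = std::pow(E.P.P_SP, (r + 1) / 2.0);
  state_from_r(E, state);
  double steps = as<double>(control["steps"]);
  double record_every = as<double>(control["record_every"]);
  bool record_initial = as<bool>(control["record_initial"]);
  DataFrame inoc = as<DataFrame>(control["inoculations"]);
  NumericVector in_step = inoc["step"];
  IntegerVector in_count = inoc["count"], in_len = inoc["length"];
  CharacterVector in_chir = inoc["chirality"], in_seq = inoc["sequence"];
  bool need_nsr = E.P.P_NFR > 0, need_rep = E.P.P_TLR > 0;
  bool verbose = control.containsElementNamed("verbose") &&
                 as<bool>(control["verbose"]);

  std::vector<Rec> recs;
  if (record_initial) recs.push_back(record_state(E));
  long s0 = E.step;
  for (long k = 1; k <= (long)steps; ++k) {
    long cur = s0 + k - 1;  // step about to execute
    for (int j = 0; j < in_step.size(); ++j)
      if ((long)in_step[j] == cur)
        apply_inoculation(E, in_count[j], in_len[j],
                          as<std::string>(in_chir[j]),
                          as<std::string>(in_seq[j]));
    engine_step(E, need_nsr, need_rep);
    if (record_every > 0 && (E.step % (long)record_every) == 0)
      recs.push_back(record_state(E));
    if (verbose && (E.step % 10000) == 0) {
      Rec r = record_state(E);
      Rprintf("step %ld: ee %+.4f, %ld precursors, %ld nt, D %ld / L %ld\n",
              E.step, r.ee, r.precD + r.precL, r.ntD + r.ntL, r.D, r.L);
    }
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int n = (int)recs.size();
  NumericVector r_step(n), r_ee(n);
  IntegerVector r_D(n), r_L(n), r_pD(n), r_pL(n), r_nD(n), r_nL(n);
  IntegerVector r_nsrD(n), r_nsrL(n), r_repD(n), r_repL(n);
  List hists(42);
  std::vector<IntegerVector> hv;
  for (int j = 0; j < 42; ++j) hv.push_back(IntegerVector(n));
  for (int i = 0; i < n; ++i) {
    const Rec& r = recs[i];
    r_step[i] = r.step; r_ee[i] = r.ee;
    r_D[i] = (int)r.D; r_L[i] = (int)r.L;
    r_pD[i] = (int)r.precD; r_pL[i] = (int)r.precL;
    r_nD[i] = (int)r.ntD; r_nL[i] = (int)r.ntL;
    r_nsrD[i] = (int)r.nsrD; r_nsrL[i] = (int)r.nsrL;
    r_repD[i] = (int)r.repD; r_repL[i] = (int)r.repL;
    for (int j = 0; j < 21; ++j) {
      hv[j][i] = (int)r.histD[j];
      hv[21 + j][i] = (int)r.histL[j];
    }
  }
  List out = List::create(
      _["step"] = r_step, _["ee"] = r_ee, _["D_total"] = r_D,
      _["L_total"] = r_L, _["prec_D"] = r_pD, _["prec_L"] = r_pL,
      _["nt_D"] = r_nD, _["nt_L"] = r_nL, _["nsr_D"] = r_nsrD,
      _["nsr_L"] = r_nsrL, _["rep_D"] = r_repD, _["rep_L"] = r_repL);
  CharacterVector nms = out.names();
  std::vector<std::string> names(nms.begin(), nms.end());
  for (int j = 0; j < 21; ++j) {
    std::string lab = (j < 20) ? std::to_string(j + 1) : "21plus";
    names.push_back("len" + lab + "_D");
    out.push_back(hv[j]);
  }
  for (int j = 0; j < 21; ++j) {
    std::string lab = (j < 20) ? std::to_string(j + 1) : "21plus";
    names.push_back("len" + lab + "_L");
    out.push_back(hv[21 + j]);
  }
  out.attr("names") = wrap(names);
  DataFrame records(out);
  return List::create(_["records"] = records, _["state"] = state_to_r(E),
                      _["clamped"] = (double)E.clamped);
}

// [[Rcpp::export]]
List cpp_detect_ribozyme(std::string seq, std::string chir,
                         std::string domain) {
  Chain c = chain_from(seq, chir);
  char ch = 0;
  bool ok = detect_ribozyme(c, domain, &ch);
  CharacterVector out(1);
  if (ok) out[0] = std::string(1, ch); else out[0] = NA_STRING;
  return List::create(_["active"] = ok, _["chirality"] = out);
}

// [[Rcpp::export]]
List cpp_initialize(List params, int T_NPB) {
  Engine E;
  E.P = params_from_r(params);
  E.N = E.P.N;
  E.step = 0;
  E.clamped = 0;
  E.rooms.assign((size_t)E.N * E.N, Room());
  int nD = T_NPB / 2, nL = T_NPB / 2;
  if (T_NPB % 2 == 1) {
    if (ru() < 0.5) nD++; else nL++;
  }
  for (int i = 0; i < nD + nL; ++i) {
    char ch = (i < nD) ? 'D' : 'L';
    E.rooms[ri(E.N * E.N)].prec.push_back(ch);
  }
  return state_to_r(E);
}
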