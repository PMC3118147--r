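// Partitioned GTR (4-state) + doublet (16-state) pruning likelihood and
// Metropolis-Hastings MCMC over topology, branch lengths and model
// parameters. Discrete-gamma rate heterogeneity with mean-of-bin rates.
//
// Tree representation: nodes 0..ntip-1 are tips; internal nodes follow;
// the (unrooted) tree is stored rooted at an internal trifurcation.
// Branch lengths are indexed by the child node of each edge.

#include <RcppArmadillo.h>
#include <sstream>
#include <iomanip>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SCALE_FLOOR = 1e-240;

struct Eig {
  arma::mat U, V;
  arma::vec lam;
};

static arma::mat exch_mat(const arma::vec &exch) {
  arma::mat R(4, 4, arma::fill::zeros);
  int ix[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  for (int k = 0; k < 6; ++k) {
    R(ix[k][0], ix[k][1]) = exch[k];
    R(ix[k][1], ix[k][0]) = exch[k];
  }
  return R;
}

static arma::mat build_q4(const arma::vec &exch, const arma::vec &pi) {
  arma::mat R = exch_mat(exch);
  arma::mat Q(4, 4, arma::fill::zeros);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      if (i != j) Q(i, j) = R(i, j) * pi[j];
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i));
  double mu = 0;
  for (int i = 0; i < 4; ++i) mu += pi[i] * -Q(i, i);
  return Q / mu;
}

static arma::mat build_q16(const arma::vec &exch, const arma::vec &pi16) {
  arma::mat R = exch_mat(exch);
  arma::mat Q(16, 16, arma::fill::zeros);
  for (int a = 0; a < 16; ++a) {
    int x = a / 4, y = a % 4;
    for (int b = 0; b < 16; ++b) {
      if (a == b) continue;
      int u = b / 4, v = b % 4;
      if (y == v && x != u) Q(a, b) = R(x, u) * pi16[b];
      else if (x == u && y != v) Q(a, b) = R(y, v) * pi16[b];
      // both positions changing: rate 0
    }
  }
  for (int a = 0; a < 16; ++a) Q(a, a) = -arma::accu(Q.row(a));
  double mu = 0;
  for (int a = 0; a < 16; ++a) mu += pi16[a] * -Q(a, a);
  return Q / mu;
}

static Eig decompose(const arma::mat &Q, const arma::vec &pi) {
  int S = Q.n_rows;
  arma::vec d = arma::sqrt(pi);
  arma::mat Sym(S, S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      Sym(i, j) = Q(i, j) * d[i] / d[j];
  Sym = (Sym + Sym.t()) / 2.0;
  arma::vec lam;
  arma::mat vec;
  arma::eig_sym(lam, vec, Sym);
  Eig e;
  e.lam = lam;
  e.U = vec;
  e.U.each_col() /= d;
  e.V = vec.t();
  e.V.each_row() %= d.t();
  return e;
}

static void pmat(const Eig &e, double t, double *out, int S) {
  arma::vec el = arma::exp(e.lam * t);
  arma::mat P = e.U * arma::diagmat(el) * e.V;
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) {
      double v = P(i, j);
      out[i * S + j] = v > 0 ? v : 0.0;
    }
}

static std::vector<double> gamma_rates(double alpha, int K) {
  std::vector<double> r(K);
  std::vector<double> b(K + 1);
  b[0] = 0;
  for (int k = 1; k < K; ++k)
    b[k] = R::qgamma((double)k / K, alpha, 1.0 / alpha, 1, 0);
  std::vector<double> mass(K + 1);
  mass[0] = 0;
  for (int k = 1; k < K; ++k)
    mass[k] = R::pgamma(b[k], alpha + 1.0, 1.0 / alpha, 1, 0);
  mass[K] = 1.0;
  for (int k = 0; k < K; ++k) r[k] = K * (mass[k + 1] - mass[k]);
  return r;
}

// one data partition (4- or 16-state) with its patterns, transition
// matrices and cached partial likelihoods
struct Partition {
  int S;                 // state count
  int ncode;             // tip-state codes (S + ambiguity codes)
  int npat;
  std::vector<int> tip;  // ntip x npat (tip-major): tip*npat + p
  std::vector<double> w; // pattern weights
  arma::vec pi;
  Eig eig;
  // P: node*ncat*S*S; L: (node-ntip)*ncat*npat*S; scal: (node-ntip)*ncat*npat
  // tipC: per tip node, cached contribution vectors per code:
  // node*ncat*ncode*S (filled with the node's P matrix)
  std::vector<double> P, L, scal, tipC;
};

struct State {
  int ntip, N, root, ncat;
  std::vector<int> parent;
  std::vector<std::vector<int> > kids;
  std::vector<double> bl;
  arma::vec exch, pi4, pi16;
  double alpha;
  std::vector<double> rates;
  Partition p4, p16;
  bool use_data;
  std::vector<int> postorder; // internal nodes in postorder
};

static void compute_postorder(State &st) {
  st.postorder.clear();
  std::vector<int> stack;
  std::vector<int> out;
  stack.push_back(st.root);
  while (!stack.empty()) {
    int n = stack.back();
    stack.pop_back();
    out.push_back(n);
    for (size_t i = 0; i < st.kids[n].size(); ++i)
      if (st.kids[n][i] >= st.ntip) stack.push_back(st.kids[n][i]);
  }
  for (int i = (int)out.size() - 1; i >= 0; --i) st.postorder.push_back(out[i]);
}

// expand a tip state code into the child's contribution to parent state x
static inline double tip_contrib(const double *P, int S, int code, int x) {
  if (code < S) return P[x * S + code];
  if (S == 4) return 1.0; // missing
  if (code == 24) return 1.0;
  double s = 0;
  if (code < 20) { // first base known = code - 16
    int xb = code - 16;
    for (int y = 0; y < 4; ++y) s += P[x * S + 4 * xb + y];
  } else {         // second base known = code - 20
    int yb = code - 20;
    for (int xp = 0; xp < 4; ++xp) s += P[x * S + 4 * xp + yb];
  }
  return s;
}

static void set_pmat_node(State &st, Partition &pp, int node) {
  int S = pp.S;
  for (int c = 0; c < st.ncat; ++c) {
    double *P = &pp.P[((size_t)node * st.ncat + c) * S * S];
    pmat(pp.eig, st.bl[node] * st.rates[c], P, S);
    if (node < st.ntip) {
      double *C = &pp.tipC[(((size_t)node * st.ncat + c) * pp.ncode) * S];
      for (int code = 0; code < pp.ncode; ++code)
        for (int x = 0; x < S; ++x)
          C[(size_t)code * S + x] = tip_contrib(P, S, code, x);
    }
  }
}

static void set_all_pmats(State &st, Partition &pp) {
  for (int n = 0; n < st.N; ++n)
    if (n != st.root) set_pmat_node(st, pp, n);
}

static void update_partial(State &st, Partition &pp, int node) {
  int S = pp.S, npat = pp.npat, ncat = st.ncat, ntip = st.ntip;
  if (npat == 0) return;
  int ni = node - ntip;
  const std::vector<int> &kd = st.kids[node];
  for (int c = 0; c < ncat; ++c) {
    double *Lout = pp.L.data() + (((size_t)ni * ncat + c) * npat) * S;
    double *sc = pp.scal.data() + ((size_t)ni * ncat + c) * npat;
    for (int p = 0; p < npat; ++p) sc[p] = 0.0;
    for (size_t k = 0; k < kd.size(); ++k) {
      int ch = kd[k];
      bool first = (k == 0);
      if (ch < ntip) {
        const int *code = &pp.tip[(size_t)ch * npat];
        const double *Ct = &pp.tipC[(((size_t)ch * ncat + c) * pp.ncode) * S];
        if (first) {
          for (int p = 0; p < npat; ++p) {
            const double *C = Ct + (size_t)code[p] * S;
            double *out = Lout + (size_t)p * S;
            for (int x = 0; x < S; ++x) out[x] = C[x];
          }
        } else {
          for (int p = 0; p < npat; ++p) {
            const double *C = Ct + (size_t)code[p] * S;
            double *out = Lout + (size_t)p * S;
            for (int x = 0; x < S; ++x) out[x] *= C[x];
          }
        }
      } else {
        const double *P = &pp.P[((size_t)ch * ncat + c) * S * S];
        const double *Lc = &pp.L[(((size_t)(ch - ntip) * ncat + c) * npat) * S];
        const double *scc = &pp.scal[((size_t)(ch - ntip) * ncat + c) * npat];
        for (int p = 0; p < npat; ++p) {
          const double *Li = Lc + (size_t)p * S;
          double *out = Lout + (size_t)p * S;
          if (first) {
            for (int x = 0; x < S; ++x) {
              double s = 0;
              const double *Pr = P + (size_t)x * S;
              for (int y = 0; y < S; ++y) s += Pr[y] * Li[y];
              out[x] = s;
            }
          } else {
            for (int x = 0; x < S; ++x) {
              double s = 0;
              const double *Pr = P + (size_t)x * S;
              for (int y = 0; y < S; ++y) s += Pr[y] * Li[y];
              out[x] *= s;
            }
          }
        }
        for (int p = 0; p < npat; ++p) sc[p] += scc[p];
      }
    }
    for (int p = 0; p < npat; ++p) {
      double *out = Lout + (size_t)p * S;
      double mx = 0;
      for (int x = 0; x < S; ++x) if (out[x] > mx) mx = out[x];
      if (mx < SCALE_FLOOR && mx > 0) {
        for (int x = 0; x < S; ++x) out[x] /= mx;
        sc[p] += std::log(mx);
      }
    }
  }
}

static double partition_loglik(State &st, Partition &pp) {
  int S = pp.S, npat = pp.npat, ncat = st.ncat;
  int ri = st.root - st.ntip;
  double ll = 0;
  double sc[32];
  double lik[32];
  for (int p = 0; p < npat; ++p) {
    bool same_scale = true;
    for (int c = 0; c < ncat; ++c) {
      const double *L =
          &pp.L[((((size_t)ri * ncat + c) * npat) + p) * S];
      double s = 0;
      for (int x = 0; x < S; ++x) s += pp.pi[x] * L[x];
      lik[c] = s;
      sc[c] = pp.scal[(((size_t)ri * ncat + c) * npat) + p];
      if (c > 0 && sc[c] != sc[0]) same_scale = false;
    }
    if (same_scale) {
      double s = 0;
      for (int c = 0; c < ncat; ++c) s += lik[c];
      ll += pp.w[p] * (sc[0] + std::log(s / ncat));
    } else {
      double best = -1e300;
      for (int c = 0; c < ncat; ++c) {
        double v = (lik[c] > 0 ? std::log(lik[c]) : -1e300) + sc[c];
        lik[c] = v;
        if (v > best) best = v;
      }
      double acc2 = 0;
      for (int c = 0; c < ncat; ++c) acc2 += std::exp(lik[c] - best);
      ll += pp.w[p] * (best + std::log(acc2 / ncat));
    }
  }
  return ll;
}

static void recompute_all(State &st) {
  st.rates = gamma_rates(st.alpha, st.ncat);
  st.p4.eig = decompose(build_q4(st.exch, st.pi4), st.pi4);
  st.p16.eig = decompose(build_q16(st.exch, st.pi16), st.pi16);
  set_all_pmats(st, st.p4);
  set_all_pmats(st, st.p16);
  compute_postorder(st);
  for (size_t i = 0; i < st.postorder.size(); ++i) {
    update_partial(st, st.p4, st.postorder[i]);
    update_partial(st, st.p16, st.postorder[i]);
  }
}

static double total_loglik(State &st) {
  if (!st.use_data) return 0.0;
  double ll = 0;
  if (st.p4.npat) ll += partition_loglik(st, st.p4);
  if (st.p16.npat) ll += partition_loglik(st, st.p16);
  return ll;
}

// recompute partials from `from` (internal) up to the root
static void update_path(State &st, int from) {
  int n = from;
  while (n != -1) {
    if (n >= st.ntip) {
      update_partial(st, st.p4, n);
      update_partial(st, st.p16, n);
    }
    n = st.parent[n];
  }
}

// internal nodes from `from` up to the root (inclusive)
static void collect_path(const State &st, int from, std::vector<int> &nodes) {
  nodes.clear();
  int n = from;
  while (n != -1) {
    if (n >= st.ntip) nodes.push_back(n);
    n = st.parent[n];
  }
}

struct SavedPartials {
  std::vector<int> nodes;
  std::vector<double> L4, s4, L16, s16;
};

static void save_partials(const State &st, const std::vector<int> &nodes,
                          SavedPartials &sv) {
  sv.nodes = nodes;
  sv.L4.clear(); sv.s4.clear(); sv.L16.clear(); sv.s16.clear();
  size_t b4 = (size_t)st.ncat * st.p4.npat * 4;
  size_t c4 = (size_t)st.ncat * st.p4.npat;
  size_t b16 = (size_t)st.ncat * st.p16.npat * 16;
  size_t c16 = (size_t)st.ncat * st.p16.npat;
  for (size_t i = 0; i < nodes.size(); ++i) {
    size_t ni = nodes[i] - st.ntip;
    sv.L4.insert(sv.L4.end(), st.p4.L.data() + ni * b4,
                 st.p4.L.data() + (ni + 1) * b4);
    sv.s4.insert(sv.s4.end(), st.p4.scal.data() + ni * c4,
                 st.p4.scal.data() + (ni + 1) * c4);
    sv.L16.insert(sv.L16.end(), st.p16.L.data() + ni * b16,
                  st.p16.L.data() + (ni + 1) * b16);
    sv.s16.insert(sv.s16.end(), st.p16.scal.data() + ni * c16,
                  st.p16.scal.data() + (ni + 1) * c16);
  }
}

static void restore_partials(State &st, const SavedPartials &sv) {
  size_t b4 = (size_t)st.ncat * st.p4.npat * 4;
  size_t c4 = (size_t)st.ncat * st.p4.npat;
  size_t b16 = (size_t)st.ncat * st.p16.npat * 16;
  size_t c16 = (size_t)st.ncat * st.p16.npat;
  for (size_t i = 0; i < sv.nodes.size(); ++i) {
    size_t ni = sv.nodes[i] - st.ntip;
    std::copy(sv.L4.data() + i * b4, sv.L4.data() + (i + 1) * b4,
              st.p4.L.data() + ni * b4);
    std::copy(sv.s4.data() + i * c4, sv.s4.data() + (i + 1) * c4,
              st.p4.scal.data() + ni * c4);
    std::copy(sv.L16.data() + i * b16, sv.L16.data() + (i + 1) * b16,
              st.p16.L.data() + ni * b16);
    std::copy(sv.s16.data() + i * c16, sv.s16.data() + (i + 1) * c16,
              st.p16.scal.data() + ni * c16);
  }
}

static State build_state(const IntegerVector &parent,
                         const NumericVector &bl, int ntip,
                         const IntegerMatrix &tip4, const NumericVector &w4,
                         const IntegerMatrix &tip16, const NumericVector &w16,
                         const NumericVector &exch, const NumericVector &pi4,
                         const NumericVector &pi16, double alpha, int ncat,
                         bool use_data) {
  State st;
  st.ntip = ntip;
  st.N = parent.size();
  st.ncat = ncat;
  st.use_data = use_data;
  st.parent = as<std::vector<int> >(parent);
  st.bl = as<std::vector<double> >(bl);
  st.kids.assign(st.N, std::vector<int>());
  st.root = -1;
  for (int i = 0; i < st.N; ++i) {
    if (st.parent[i] == -1) st.root = i;
    else st.kids[st.parent[i]].push_back(i);
  }
  st.exch = as<arma::vec>(exch);
  st.pi4 = as<arma::vec>(pi4);
  st.pi16 = as<arma::vec>(pi16);
  st.alpha = alpha;

  int nint = st.N - ntip;
  st.p4.S = 4;
  st.p4.ncode = 5;
  st.p16.ncode = 25;
  st.p4.npat = tip4.ncol();
  st.p4.w = as<std::vector<double> >(w4);
  st.p4.pi = st.pi4;
  st.p4.tip.resize((size_t)ntip * st.p4.npat);
  for (int t = 0; t < ntip; ++t)
    for (int p = 0; p < st.p4.npat; ++p)
      st.p4.tip[(size_t)t * st.p4.npat + p] = tip4(t, p);
  st.p4.P.assign((size_t)st.N * ncat * 16, 0.0);
  st.p4.tipC.assign((size_t)ntip * ncat * st.p4.ncode * 4, 0.0);
  st.p4.L.assign((size_t)nint * ncat * st.p4.npat * 4, 0.0);
  st.p4.scal.assign((size_t)nint * ncat * std::max(st.p4.npat, 1), 0.0);

  st.p16.S = 16;
  st.p16.npat = tip16.ncol();
  st.p16.w = as<std::vector<double> >(w16);
  st.p16.pi = st.pi16;
  st.p16.tip.resize((size_t)ntip * st.p16.npat);
  for (int t = 0; t < ntip; ++t)
    for (int p = 0; p < st.p16.npat; ++p)
      st.p16.tip[(size_t)t * st.p16.npat + p] = tip16(t, p);
  st.p16.P.assign((size_t)st.N * ncat * 256, 0.0);
  st.p16.tipC.assign((size_t)ntip * ncat * st.p16.ncode * 16, 0.0);
  st.p16.L.assign((size_t)nint * ncat * st.p16.npat * 16, 0.0);
  st.p16.scal.assign((size_t)nint * ncat * std::max(st.p16.npat, 1), 0.0);

  recompute_all(st);
  return st;
}

// [[Rcpp::export]]
double loglik_cpp(IntegerVector parent, NumericVector bl, int ntip,
                  IntegerMatrix tip4, NumericVector w4, IntegerMatrix tip16,
                  NumericVector w16, NumericVector exch, NumericVector pi4,
                  NumericVector pi16, double alpha, int ncat) {
  State st = build_state(parent, bl, ntip, tip4, w4, tip16, w16, exch, pi4,
                         pi16, alpha, ncat, true);
  return total_loglik(st);
}

static std::string newick_node(const State &st, int node,
                               const CharacterVector &labels) {
  std::ostringstream os;
  if (node < st.ntip) {
    os << as<std::string>(labels[node]);
  } else {
    os << "(";
    for (size_t k = 0; k < st.kids[node].size(); ++k) {
      if (k) os << ",";
      os << newick_node(st, st.kids[node][k], labels);
    }
    os << ")";
  }
  if (node != st.root) os << ":" << std::setprecision(6) << st.bl[node];
  return os.str();
}

static double ldirichlet(const arma::vec &x, const arma::vec &a) {
  double s = R::lgammafn(arma::accu(a));
  for (size_t i = 0; i < x.n_elem; ++i)
    s += (a[i] - 1.0) * std::log(x[i]) - R::lgammafn(a[i]);
  return s;
}

static arma::vec rdirichlet(const arma::vec &a) {
  arma::vec x(a.n_elem);
  for (size_t i = 0; i < a.n_elem; ++i) x[i] = R::rgamma(a[i], 1.0);
  return x / arma::accu(x);
}

// [[Rcpp::export]]
List mcmc_cpp(IntegerVector parent, NumericVector bl, int ntip,
              CharacterVector tip_labels, IntegerMatrix tip4,
              NumericVector w4, IntegerMatrix tip16, NumericVector w16,
              NumericVector exch, NumericVector pi4, NumericVector pi16,
              double alpha, int ncat, int n_generations, int sample_interval,
              bool use_data, LogicalVector estimate) {
  RNGScope scope;
  State st = build_state(parent, bl, ntip, tip4, w4, tip16, w16, exch, pi4,
                         pi16, alpha, ncat, use_data);
  bool est_alpha = estimate[0], est_pi4 = estimate[1],
       est_pi16 = estimate[2], est_exch = estimate[3];

  double brlen_rate = 10.0;  // exponential prior on branch lengths
  double alpha_rate = 1.0;   // exponential prior on the gamma shape
  // Dirichlet proposal concentrations (tuned for workable acceptance
  // on the 4- and 16-dimensional simplices)
  double c_pi4 = 500.0, c_pi16 = 2000.0, c_exch = 200.0;

  double ll = total_loglik(st);
  double lp = 0;
  for (int n = 0; n < st.N; ++n)
    if (n != st.root) lp += -brlen_rate * st.bl[n];
  lp += -alpha_rate * st.alpha;

  // move weights: branch length, NNI, alpha, pi4, pi16, exch
  std::vector<double> wmove;
  wmove.push_back(0.45);
  wmove.push_back(0.35);
  wmove.push_back(est_alpha ? 0.08 : 0.0);
  wmove.push_back(est_pi4 ? 0.04 : 0.0);
  wmove.push_back(est_pi16 ? 0.04 : 0.0);
  wmove.push_back(est_exch ? 0.04 : 0.0);
  double wsum = 0;
  for (size_t i = 0; i < wmove.size(); ++i) wsum += wmove[i];

  std::vector<int> nonroot;
  for (int n = 0; n < st.N; ++n)
    if (n != st.root) nonroot.push_back(n);

  std::vector<std::string> tree_samples;
  std::vector<double> ll_trace, alpha_trace;
  std::vector<int> acc(6, 0), tries(6, 0);

  // per-move scratch buffers, reused across generations
  SavedPartials sv;
  std::vector<double> savP4, savP16, savC4, savC16;
  std::vector<int> path;

  for (int gen = 1; gen <= n_generations; ++gen) {
    double u = unif_rand() * wsum, cum = 0;
    int mv = 0;
    for (size_t i = 0; i < wmove.size(); ++i) {
      cum += wmove[i];
      if (u <= cum) { mv = (int)i; break; }
    }
    tries[mv]++;

    if (mv == 0) {
      // branch-length multiplier
      int node = nonroot[(int)(unif_rand() * nonroot.size())];
      double old_bl = st.bl[node];
      double mult = std::exp(1.4 * (unif_rand() - 0.5));
      double new_bl = old_bl * mult;
      // save the edge's P matrices and the partials on the root path
      int S4 = 16, S16 = 256;
      int nC4 = ncat * st.p4.ncode * 4, nC16 = ncat * st.p16.ncode * 16;
      savP4.assign(st.p4.P.data() + (size_t)node * ncat * S4,
                   st.p4.P.data() + (size_t)(node + 1) * ncat * S4);
      savP16.assign(st.p16.P.data() + (size_t)node * ncat * S16,
                    st.p16.P.data() + (size_t)(node + 1) * ncat * S16);
      if (node < st.ntip) {
        savC4.assign(st.p4.tipC.data() + (size_t)node * nC4,
                     st.p4.tipC.data() + (size_t)(node + 1) * nC4);
        savC16.assign(st.p16.tipC.data() + (size_t)node * nC16,
                      st.p16.tipC.data() + (size_t)(node + 1) * nC16);
      }
      collect_path(st, st.parent[node], path);
      save_partials(st, path, sv);
      st.bl[node] = new_bl;
      set_pmat_node(st, st.p4, node);
      set_pmat_node(st, st.p16, node);
      update_path(st, st.parent[node]);
      double new_ll = total_loglik(st);
      double new_lp = lp - brlen_rate * (new_bl - old_bl);
      double lhast = std::log(mult);
      if (std::log(unif_rand()) < new_ll - ll + new_lp - lp + lhast) {
        ll = new_ll; lp = new_lp; acc[mv]++;
      } else {
        st.bl[node] = old_bl;
        std::copy(savP4.begin(), savP4.end(),
                  st.p4.P.data() + (size_t)node * ncat * S4);
        std::copy(savP16.begin(), savP16.end(),
                  st.p16.P.data() + (size_t)node * ncat * S16);
        if (node < st.ntip) {
          std::copy(savC4.begin(), savC4.end(),
                    st.p4.tipC.data() + (size_t)node * nC4);
          std::copy(savC16.begin(), savC16.end(),
                    st.p16.tipC.data() + (size_t)node * nC16);
        }
        restore_partials(st, sv);
      }
    } else if (mv == 1) {
      // NNI on a random internal edge
      std::vector<int> iedges;
      for (int n = st.ntip; n < st.N; ++n)
        if (n != st.root) iedges.push_back(n);
      if (!iedges.empty()) {
        int v = iedges[(int)(unif_rand() * iedges.size())];
        int uu = st.parent[v];
        std::vector<int> sibs;
        for (size_t k = 0; k < st.kids[uu].size(); ++k)
          if (st.kids[uu][k] != v) sibs.push_back(st.kids[uu][k]);
        int s = sibs[(int)(unif_rand() * sibs.size())];
        int c = st.kids[v][(int)(unif_rand() * st.kids[v].size())];
        std::vector<int> sav_parent = st.parent;
        std::vector<std::vector<int> > sav_kids = st.kids;
        collect_path(st, v, path);
        save_partials(st, path, sv);
        // swap subtrees c (child of v) and s (child of u)
        for (size_t k = 0; k < st.kids[v].size(); ++k)
          if (st.kids[v][k] == c) st.kids[v][k] = s;
        for (size_t k = 0; k < st.kids[uu].size(); ++k)
          if (st.kids[uu][k] == s) st.kids[uu][k] = c;
        st.parent[c] = uu;
        st.parent[s] = v;
        update_path(st, v);
        double new_ll = total_loglik(st);
        if (std::log(unif_rand()) < new_ll - ll) {
          ll = new_ll; acc[mv]++;
          compute_postorder(st);
        } else {
          st.parent.swap(sav_parent);
          st.kids.swap(sav_kids);
          restore_partials(st, sv);
        }
      }
    } else {
      // global parameter moves: snapshot everything cheap to restore
      State sav = st;
      double new_lp = lp, lhast = 0;
      bool degenerate = false;
      if (mv == 2) {
        double mult = std::exp(1.0 * (unif_rand() - 0.5));
        st.alpha *= mult;
        new_lp = lp - alpha_rate * (st.alpha - sav.alpha);
        lhast = std::log(mult);
      } else if (mv == 3) {
        arma::vec prop = rdirichlet(c_pi4 * st.pi4);
        degenerate = prop.min() < 1e-5;  // numerical guard for eig_sym
        if (!degenerate) {
          lhast = ldirichlet(sav.pi4, c_pi4 * prop) -
                  ldirichlet(prop, c_pi4 * sav.pi4);
          st.pi4 = prop;
          st.p4.pi = prop;
        }
      } else if (mv == 4) {
        arma::vec prop = rdirichlet(c_pi16 * st.pi16);
        degenerate = prop.min() < 1e-5;
        if (!degenerate) {
          lhast = ldirichlet(sav.pi16, c_pi16 * prop) -
                  ldirichlet(prop, c_pi16 * sav.pi16);
          st.pi16 = prop;
          st.p16.pi = prop;
        }
      } else {
        arma::vec prop = rdirichlet(c_exch * st.exch);
        degenerate = prop.min() < 1e-5;
        if (!degenerate) {
          lhast = ldirichlet(sav.exch, c_exch * prop) -
                  ldirichlet(prop, c_exch * sav.exch);
          st.exch = prop;
        }
      }
      if (!degenerate) {
        // an out-of-range proposal counts as an immediate rejection
        recompute_all(st);
        double new_ll = total_loglik(st);
        if (std::log(unif_rand()) < new_ll - ll + new_lp - lp + lhast) {
          ll = new_ll; lp = new_lp; acc[mv]++;
        } else {
          st = sav;
        }
      } else {
        st = sav;
      }
    }

    if (gen % sample_interval == 0) {
      tree_samples.push_back(newick_node(st, st.root, tip_labels) + ";");
      ll_trace.push_back(ll);
      alpha_trace.push_back(st.alpha);
    }
  }

  return List::create(
      _["trees"] = wrap(tree_samples), _["loglik"] = wrap(ll_trace),
      _["alpha"] = wrap(alpha_trace), _["accepted"] = wrap(acc),
      _["tried"] = wrap(tries),
      _["final_exch"] = wrap(st.exch), _["final_pi4"] = wrap(st.pi4),
      _["final_pi16"] = wrap(st.pi16));
}
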