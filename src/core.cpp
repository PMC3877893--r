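// Computational kernels: affine-gap profile alignment (Gotoh) and the
// Felsenstein pruning log-likelihood under K2P with discrete-gamma rate
// categories and invariant sites. Bases are ordered A, C, G, T; tip states
// arrive as 4-bit masks (A=1, C=2, G=4, T=8; gap/N = 15).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e300;

// Profile-profile global alignment with affine gaps. Profiles are 4 x L
// matrices of residue frequencies (columns may sum to < 1 when gapped).
// A gap of length L costs gap_open + (L-1) * gap_extend.
// Tie-break during traceback: prefer diagonal, then up (consume A), then
// left (consume B).
// [[Rcpp::export]]
List nw_affine_profile_cpp(NumericMatrix profA, NumericMatrix profB,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  const int la = profA.ncol(), lb = profB.ncol();
  // substitution score between profile columns: sum_xy fA[x] fB[y] s(x,y)
  std::vector<double> sub((size_t)la * lb);
  for (int i = 0; i < la; ++i) {
    double sa = profA(0, i) + profA(1, i) + profA(2, i) + profA(3, i);
    for (int j = 0; j < lb; ++j) {
      double diag = 0.0, sb = 0.0;
      for (int x = 0; x < 4; ++x) {
        diag += profA(x, i) * profB(x, j);
        sb += profB(x, j);
      }
      sub[(size_t)i * lb + j] = diag * match + (sa * sb - diag) * mismatch;
    }
  }
  const size_t w = (size_t)lb + 1;
  std::vector<double> M((la + 1) * w, NEG_INF), X((la + 1) * w, NEG_INF),
      Y((la + 1) * w, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i)
    X[i * w] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= lb; ++j)
    Y[j] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = sub[(size_t)(i - 1) * lb + (j - 1)];
      double dM = M[(i - 1) * w + j - 1], dX = X[(i - 1) * w + j - 1],
             dY = Y[(i - 1) * w + j - 1];
      double best = dM;
      if (dX > best) best = dX;
      if (dY > best) best = dY;
      M[i * w + j] = best + s;
      double upM = M[(i - 1) * w + j] + gap_open,
             upX = X[(i - 1) * w + j] + gap_extend,
             upY = Y[(i - 1) * w + j] + gap_open;
      X[i * w + j] = std::max(upM, std::max(upX, upY));
      double lfM = M[i * w + j - 1] + gap_open,
             lfX = X[i * w + j - 1] + gap_open,
             lfY = Y[i * w + j - 1] + gap_extend;
      Y[i * w + j] = std::max(lfM, std::max(lfX, lfY));
    }
  }
  // traceback; state 0 = M, 1 = X (up), 2 = Y (left)
  int i = la, j = lb;
  double endM = M[la * w + lb], endX = X[la * w + lb], endY = Y[la * w + lb];
  double score = std::max(endM, std::max(endX, endY));
  int state = (endM >= endX && endM >= endY) ? 0 : (endX >= endY ? 1 : 2);
  std::vector<int> ops;  // 0 diag, 1 up, 2 left (reversed order)
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i > 0) ? 1 : 2; continue; }
      ops.push_back(0);
      double s = sub[(size_t)(i - 1) * lb + (j - 1)];
      double target = M[i * w + j] - s;
      double dM = M[(i - 1) * w + j - 1], dX = X[(i - 1) * w + j - 1],
             dY = Y[(i - 1) * w + j - 1];
      if (dM >= target - eps) state = 0;
      else if (dX >= target - eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (i == 0) { state = 2; continue; }
      ops.push_back(1);
      double target = X[i * w + j];
      double fromM = M[(i - 1) * w + j] + gap_open,
             fromX = X[(i - 1) * w + j] + gap_extend,
             fromY = Y[(i - 1) * w + j] + gap_open;
      if (fromM >= target - eps) state = 0;
      else if (fromX >= target - eps) state = 1;
      else { (void)fromY; state = 2; }
      --i;
    } else {
      if (j == 0) { state = 1; continue; }
      ops.push_back(2);
      double target = Y[i * w + j];
      double fromM = M[i * w + j - 1] + gap_open,
             fromY = Y[i * w + j - 1] + gap_extend,
             fromX = X[i * w + j - 1] + gap_open;
      if (fromM >= target - eps) state = 0;
      else if (fromY >= target - eps) state = 2;
      else { (void)fromX; state = 1; }
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

static inline void k2p_pmat(double t, double kappa, double P[4][4]) {
  // K80 closed form; transitions A<->G and C<->T.
  double e1 = std::exp(-4.0 * t / (kappa + 2.0));
  double e2 = std::exp(-2.0 * t * (kappa + 1.0) / (kappa + 2.0));
  double ps = 0.25 + 0.25 * e1 + 0.5 * e2;   // same base
  double pt = 0.25 + 0.25 * e1 - 0.5 * e2;   // transition
  double pv = 0.25 - 0.25 * e1;              // each transversion
  static const int partner[4] = {2, 3, 0, 1};
  for (int x = 0; x < 4; ++x)
    for (int y = 0; y < 4; ++y)
      P[x][y] = (x == y) ? ps : (y == partner[x] ? pt : pv);
}

// Pruning log-likelihood over compressed site patterns.
// edge_parent/edge_child: 1-based node ids in postorder (children before
// parents); tips are 1..n_tip, root is n_tip + 1. tip_mask: n_pattern x
// n_tip 4-bit masks. rates: category rates (mean 1); p_inv: invariant
// proportion with stationary 1/4 base frequencies.
// [[Rcpp::export]]
double k2p_loglik_cpp(IntegerVector edge_parent, IntegerVector edge_child,
                      NumericVector edge_length, int n_tip, int n_node,
                      IntegerMatrix tip_mask, NumericVector weight,
                      double kappa, NumericVector rates, double p_inv) {
  const int n_edge = edge_parent.size();
  const int n_pat = tip_mask.nrow();
  const int K = rates.size();
  const int root = n_tip;  // 0-based id of root (ape node n_tip + 1)
  std::vector<double> sitelog(n_pat, 0.0);
  std::vector<double> partial((size_t)n_node * 4);
  std::vector<double> catlog((size_t)n_pat * K);

  // constant-site compatibility: popcount of AND over tip masks
  std::vector<int> nconst(n_pat);
  for (int p = 0; p < n_pat; ++p) {
    int acc = 15;
    for (int t = 0; t < n_tip; ++t) acc &= tip_mask(p, t);
    int c = 0;
    for (int b = 0; b < 4; ++b) if (acc & (1 << b)) ++c;
    nconst[p] = c;
  }

  std::vector<double> P(16 * n_edge);
  for (int k = 0; k < K; ++k) {
    for (int e = 0; e < n_edge; ++e) {
      double Pm[4][4];
      k2p_pmat(edge_length[e] * rates[k], kappa, Pm);
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y) P[e * 16 + x * 4 + y] = Pm[x][y];
    }
    for (int p = 0; p < n_pat; ++p) {
      double logscale = 0.0;
      // init partials: tips from masks, internals to 1
      for (int nd = 0; nd < n_node; ++nd) {
        if (nd < n_tip) {
          int m = tip_mask(p, nd);
          for (int b = 0; b < 4; ++b)
            partial[nd * 4 + b] = (m & (1 << b)) ? 1.0 : 0.0;
        } else {
          for (int b = 0; b < 4; ++b) partial[nd * 4 + b] = 1.0;
        }
      }
      for (int e = 0; e < n_edge; ++e) {
        int par = edge_parent[e] - 1, ch = edge_child[e] - 1;
        const double *Pe = &P[e * 16];
        double mx = 0.0;
        for (int x = 0; x < 4; ++x) {
          double s = 0.0;
          for (int y = 0; y < 4; ++y) s += Pe[x * 4 + y] * partial[ch * 4 + y];
          partial[par * 4 + x] *= s;
          if (partial[par * 4 + x] > mx) mx = partial[par * 4 + x];
        }
        if (mx < 1e-200 && mx > 0.0) {
          for (int x = 0; x < 4; ++x) partial[par * 4 + x] /= mx;
          logscale += std::log(mx);
        }
      }
      double lik = 0.25 * (partial[root * 4 + 0] + partial[root * 4 + 1] +
                           partial[root * 4 + 2] + partial[root * 4 + 3]);
      catlog[(size_t)p * K + k] =
          (lik > 0.0) ? std::log(lik) + logscale : -1e300;
    }
  }
  double total = 0.0;
  for (int p = 0; p < n_pat; ++p) {
    // log-sum-exp over categories
    double mx = -1e300;
    for (int k = 0; k < K; ++k)
      if (catlog[(size_t)p * K + k] > mx) mx = catlog[(size_t)p * K + k];
    double var_part = 0.0;
    if (mx > -1e299) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += std::exp(catlog[(size_t)p * K + k] - mx);
      var_part = std::exp(mx) * s / K;
    }
    double lik = p_inv * (nconst[p] / 4.0) + (1.0 - p_inv) * var_part;
    total += weight[p] * std::log(lik);
  }
  return total;
}

// Inside/outside ("lower"/"upper") likelihood vectors for one edge, used to
// optimize that edge's length cheaply: for target edge e = (v, c),
// G[p, k, x] is the likelihood of all data outside the subtree of c given
// state x at v (root prior 1/4 folded in), I[p, k, y] the inside likelihood
// of c's subtree given state y at c, and S[p, k] the summed log scaling.
// Site likelihood at rate k is sum_xy G * P_e(t r_k) * I * exp(S).
// [[Rcpp::export]]
List k2p_edge_vectors_cpp(IntegerVector edge_parent, IntegerVector edge_child,
                          NumericVector edge_length, int n_tip, int n_node,
                          IntegerMatrix tip_mask, double kappa,
                          NumericVector rates, int target_edge) {
  const int n_edge = edge_parent.size();
  const int n_pat = tip_mask.nrow();
  const int K = rates.size();
  NumericMatrix G(n_pat, 4 * K), I(n_pat, 4 * K);
  NumericMatrix S(n_pat, K);
  const int tc = edge_child[target_edge] - 1;

  std::vector<double> inpart((size_t)n_node * 4);
  std::vector<double> insc(n_node);
  std::vector<double> up((size_t)n_edge * 4);
  std::vector<double> upsc(n_edge);
  std::vector<double> M((size_t)n_edge * 4);  // P_e * inside(child)

  std::vector<double> P(16 * n_edge);
  for (int k = 0; k < K; ++k) {
    for (int e = 0; e < n_edge; ++e) {
      double Pm[4][4];
      k2p_pmat(edge_length[e] * rates[k], kappa, Pm);
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y) P[e * 16 + x * 4 + y] = Pm[x][y];
    }
    for (int p = 0; p < n_pat; ++p) {
      // inside pass (postorder; edge list is postorder)
      for (int nd = 0; nd < n_node; ++nd) {
        insc[nd] = 0.0;
        if (nd < n_tip) {
          int m = tip_mask(p, nd);
          for (int b = 0; b < 4; ++b)
            inpart[nd * 4 + b] = (m & (1 << b)) ? 1.0 : 0.0;
        } else {
          for (int b = 0; b < 4; ++b) inpart[nd * 4 + b] = 1.0;
        }
      }
      for (int e = 0; e < n_edge; ++e) {
        int par = edge_parent[e] - 1, ch = edge_child[e] - 1;
        const double *Pe = &P[e * 16];
        double mx = 0.0;
        for (int x = 0; x < 4; ++x) {
          double s = 0.0;
          for (int y = 0; y < 4; ++y) s += Pe[x * 4 + y] * inpart[ch * 4 + y];
          M[e * 4 + x] = s;
          inpart[par * 4 + x] *= s;
          if (inpart[par * 4 + x] > mx) mx = inpart[par * 4 + x];
        }
        insc[par] += insc[ch];
        if (mx < 1e-200 && mx > 0.0) {
          for (int x = 0; x < 4; ++x) inpart[par * 4 + x] /= mx;
          insc[par] += std::log(mx);
        }
      }
      // outside pass (preorder = reversed postorder). up[e] excludes edge
      // e's own transition matrix; root prior 1/4 folded in.
      for (int e = n_edge - 1; e >= 0; --e) {
        int par = edge_parent[e] - 1;
        double acc[4];
        double sc = 0.0;
        if (par == n_tip) {  // parent is root
          for (int x = 0; x < 4; ++x) acc[x] = 0.25;
        } else {
          // find parent's own edge (the edge whose child is par)
          int pe = -1;
          for (int e2 = 0; e2 < n_edge; ++e2)
            if (edge_child[e2] - 1 == par) { pe = e2; break; }
          const double *Pp = &P[pe * 16];
          for (int x = 0; x < 4; ++x) {
            double s = 0.0;
            for (int z = 0; z < 4; ++z) s += up[pe * 4 + z] * Pp[z * 4 + x];
            acc[x] = s;
          }
          sc = upsc[pe];
        }
        // multiply in the M vectors of the parent's other child edges,
        // tracking their inside scalings
        for (int e2 = 0; e2 < n_edge; ++e2) {
          if (e2 == e || edge_parent[e2] - 1 != par) continue;
          for (int x = 0; x < 4; ++x) acc[x] *= M[e2 * 4 + x];
          sc += insc[edge_child[e2] - 1];
        }
        double mx = 0.0;
        for (int x = 0; x < 4; ++x) if (acc[x] > mx) mx = acc[x];
        if (mx < 1e-200 && mx > 0.0) {
          for (int x = 0; x < 4; ++x) acc[x] /= mx;
          sc += std::log(mx);
        }
        for (int x = 0; x < 4; ++x) up[e * 4 + x] = acc[x];
        upsc[e] = sc;
      }
      for (int x = 0; x < 4; ++x) {
        G(p, k * 4 + x) = up[target_edge * 4 + x];
        I(p, k * 4 + x) = inpart[tc * 4 + x];
      }
      S(p, k) = upsc[target_edge] + insc[tc];
    }
  }
  return List::create(_["G"] = G, _["I"] = I, _["S"] = S);
}
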