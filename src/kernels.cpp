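// Hot loops of the graph-attention layer: per-edge gather/scatter with
// per-head attention weights. Matrices are column-major; edge indices are
// 1-based (as produced by the R featurizer).

#include <Rcpp.h>
using namespace Rcpp;

// S[m, h] = p_dst[dst[m], h] + p_src[src[m], h]  (edge term added in R)
// [[Rcpp::export(name = ".mg_edge_scores")]]
NumericMatrix mg_edge_scores(const NumericMatrix& p_dst,
                             const NumericMatrix& p_src,
                             const IntegerVector& src,
                             const IntegerVector& dst) {
  const int M = src.size(), H = p_dst.ncol();
  NumericMatrix S(M, H);
  for (int h = 0; h < H; ++h) {
    const double* pd = &p_dst(0, h);
    const double* ps = &p_src(0, h);
    double* s = &S(0, h);
    for (int m = 0; m < M; ++m) {
      s[m] = pd[dst[m] - 1] + ps[src[m] - 1];
    }
  }
  return S;
}

// Numerically stable softmax over the in-edges of each destination node,
// independently per head.
// [[Rcpp::export(name = ".mg_softmax_dst")]]
NumericMatrix mg_softmax_dst(const NumericMatrix& L,
                             const IntegerVector& dst, const int n) {
  const int M = L.nrow(), H = L.ncol();
  NumericMatrix A(M, H);
  std::vector<double> mx(n), sm(n);
  for (int h = 0; h < H; ++h) {
    const double* l = &L(0, h);
    double* a = &A(0, h);
    std::fill(mx.begin(), mx.end(), R_NegInf);
    std::fill(sm.begin(), sm.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const int d = dst[m] - 1;
      if (l[m] > mx[d]) mx[d] = l[m];
    }
    for (int m = 0; m < M; ++m) {
      a[m] = std::exp(l[m] - mx[dst[m] - 1]);
      sm[dst[m] - 1] += a[m];
    }
    for (int m = 0; m < M; ++m) a[m] /= sm[dst[m] - 1];
  }
  return A;
}

// dL[m, h] = A[m, h] * (dA[m, h] - sum_{m': dst[m']=dst[m]} A dA)
// [[Rcpp::export(name = ".mg_softmax_dst_bwd")]]
NumericMatrix mg_softmax_dst_bwd(const NumericMatrix& A,
                                 const NumericMatrix& dA,
                                 const IntegerVector& dst, const int n) {
  const int M = A.nrow(), H = A.ncol();
  NumericMatrix dL(M, H);
  std::vector<double> t(n);
  for (int h = 0; h < H; ++h) {
    const double* a = &A(0, h);
    const double* da = &dA(0, h);
    double* dl = &dL(0, h);
    std::fill(t.begin(), t.end(), 0.0);
    for (int m = 0; m < M; ++m) t[dst[m] - 1] += a[m] * da[m];
    for (int m = 0; m < M; ++m) dl[m] = a[m] * (da[m] - t[dst[m] - 1]);
  }
  return dL;
}

// agg[dst[m], d] += Ad[m, head(d)] * Wh[src[m], d]
// [[Rcpp::export(name = ".mg_aggregate")]]
NumericMatrix mg_aggregate(const NumericMatrix& Wh, const NumericMatrix& Ad,
                           const IntegerVector& src, const IntegerVector& dst,
                           const int per_head) {
  const int n = Wh.nrow(), D = Wh.ncol(), M = src.size();
  NumericMatrix agg(n, D);
  for (int d = 0; d < D; ++d) {
    const int h = d / per_head;
    const double* wh = &Wh(0, d);
    const double* a = &Ad(0, h);
    double* out = &agg(0, d);
    for (int m = 0; m < M; ++m) {
      out[dst[m] - 1] += a[m] * wh[src[m] - 1];
    }
  }
  return agg;
}

// Fused graph normalization + ELU forward. Per feature d and graph g:
//   mu = mean(agg); v = agg + b - alpha*mu; s2 = mean(v^2)
//   vhat = v/sqrt(s2+eps); out = elu(gamma*vhat + beta)
// The bias b is folded in so the caller passes the raw aggregation.
// [[Rcpp::export(name = ".mg_gn_elu")]]
List mg_gn_elu(const NumericMatrix& agg, const NumericVector& b,
               const IntegerVector& gid, const NumericVector& ng,
               const int G, const NumericVector& alpha,
               const NumericVector& gamma, const NumericVector& beta) {
  const int n = agg.nrow(), D = agg.ncol();
  const double eps = 1e-5;
  NumericMatrix out(n, D), vhat(n, D), mu(G, D), sdm(G, D);
  std::vector<double> acc(G);
  for (int d = 0; d < D; ++d) {
    const double* x = &agg(0, d);
    double* o = &out(0, d);
    double* vh = &vhat(0, d);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n; ++i) acc[gid[i] - 1] += x[i] + b[d];
    for (int g = 0; g < G; ++g) mu(g, d) = acc[g] / ng[g];
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double v = x[i] + b[d] - alpha[d] * mu(gid[i] - 1, d);
      vh[i] = v;  // temporarily stores v
      acc[gid[i] - 1] += v * v;
    }
    for (int g = 0; g < G; ++g) sdm(g, d) = std::sqrt(acc[g] / ng[g] + eps);
    for (int i = 0; i < n; ++i) {
      vh[i] /= sdm(gid[i] - 1, d);
      const double gn = gamma[d] * vh[i] + beta[d];
      o[i] = gn > 0 ? gn : std::exp(gn) - 1;
    }
  }
  return List::create(Named("out") = out, Named("vhat") = vhat,
                      Named("mu") = mu, Named("sd") = sdm);
}

// Reverse of mg_gn_elu: returns dAgg and the parameter gradients.
// [[Rcpp::export(name = ".mg_gn_elu_bwd")]]
List mg_gn_elu_bwd(const NumericMatrix& dOut, const NumericMatrix& out,
                   const NumericMatrix& vhat, const NumericMatrix& mu,
                   const NumericMatrix& sdm, const IntegerVector& gid,
                   const NumericVector& ng, const int G,
                   const NumericVector& alpha, const NumericVector& gamma) {
  const int n = dOut.nrow(), D = dOut.ncol();
  NumericMatrix dAgg(n, D);
  NumericVector d_gamma(D), d_beta(D), d_alpha(D), d_b(D);
  std::vector<double> s1(G), sdv(G), dvh(n);
  for (int d = 0; d < D; ++d) {
    const double* dout_col = &dOut(0, d);
    const double* o = &out(0, d);
    const double* vh = &vhat(0, d);
    double* da = &dAgg(0, d);
    std::fill(s1.begin(), s1.end(), 0.0);
    double dg = 0, db = 0;
    for (int i = 0; i < n; ++i) {
      const double dgn = o[i] > 0 ? dout_col[i] : dout_col[i] * (o[i] + 1);
      const double dvhat = dgn * gamma[d];
      dvh[i] = dvhat;
      dg += dgn * vh[i];
      db += dgn;
      s1[gid[i] - 1] += dvhat * vh[i];
    }
    d_gamma[d] = dg; d_beta[d] = db;
    std::fill(sdv.begin(), sdv.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int g = gid[i] - 1;
      dvh[i] = (dvh[i] - vh[i] * s1[g] / ng[g]) / sdm(g, d);  // now dV
      sdv[g] += dvh[i];
    }
    double dal = 0, dbb = 0;
    for (int g = 0; g < G; ++g) dal -= mu(g, d) * sdv[g];
    d_alpha[d] = dal;
    for (int i = 0; i < n; ++i) {
      const int g = gid[i] - 1;
      da[i] = dvh[i] - alpha[d] * sdv[g] / ng[g];
      dbb += da[i];
    }
    d_b[d] = dbb;
  }
  return List::create(Named("dAgg") = dAgg, Named("d_gamma") = d_gamma,
                      Named("d_beta") = d_beta, Named("d_alpha") = d_alpha,
                      Named("d_b") = d_b);
}

// Reverse of mg_aggregate:
//   dWh[src[m], d] += Ad[m, head(d)] * dAgg[dst[m], d]
//   dAd[m, h] = sum_{d in head h} dAgg[dst[m], d] * Wh[src[m], d]
// [[Rcpp::export(name = ".mg_aggregate_bwd")]]
List mg_aggregate_bwd(const NumericMatrix& dAgg, const NumericMatrix& Wh,
                      const NumericMatrix& Ad, const IntegerVector& src,
                      const IntegerVector& dst, const int per_head) {
  const int n = Wh.nrow(), D = Wh.ncol(), M = src.size();
  const int H = Ad.ncol();
  NumericMatrix dWh(n, D), dAd(M, H);
  for (int d = 0; d < D; ++d) {
    const int h = d / per_head;
    const double* dag = &dAgg(0, d);
    const double* wh = &Wh(0, d);
    const double* a = &Ad(0, h);
    double* dwh = &dWh(0, d);
    double* dad = &dAd(0, h);
    for (int m = 0; m < M; ++m) {
      const int s = src[m] - 1, t = dst[m] - 1;
      dwh[s] += a[m] * dag[t];
      dad[m] += dag[t] * wh[s];
    }
  }
  return List::create(Named("dWh") = dWh, Named("dAd") = dAd);
}
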