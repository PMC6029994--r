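#include <Rcpp.h>
using namespace Rcpp;

// Exact convolution of a piecewise-linear input cp, sampled on a uniform
// grid of step dt, with cc * exp(-alpha * t). One-pass first-order
// recursion; the small alpha*dt branch avoids catastrophic cancellation.
// [[Rcpp::export]]
NumericVector conv_exp_cpp(NumericVector cp, double dt, double cc,
                           double alpha) {
  int n = cp.size();
  NumericVector y(n);
  double ad = alpha * dt, E = std::exp(-ad), I0, I1;
  if (ad > 1e-8) {
    I0 = (1.0 - E) / alpha;
    I1 = (1.0 - (1.0 + ad) * E) / (alpha * alpha);
  } else {
    I0 = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
    I1 = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
  }
  double acc = 0.0;
  for (int i = 1; i < n; ++i) {
    double c0 = cp[i - 1], c1 = cp[i];
    acc = E * acc + c1 * I0 - (c1 - c0) / dt * I1;
    y[i] = cc * acc;
  }
  return y;
}

// Convolution with cc * t * exp(-alpha * t) (repeated-root kernel), via
// the coupled recursion v <- E * (v + dt * w) + local, where w is the
// unit-amplitude plain-exponential convolution.
// [[Rcpp::export]]
NumericVector conv_texp_cpp(NumericVector cp, double dt, double cc,
                            double alpha) {
  int n = cp.size();
  NumericVector y(n);
  double ad = alpha * dt, E = std::exp(-ad), I0, I1, I2;
  if (ad > 1e-8) {
    I0 = (1.0 - E) / alpha;
    I1 = (1.0 - (1.0 + ad) * E) / (alpha * alpha);
    I2 = (2.0 - (2.0 + 2.0 * ad + ad * ad) * E) / (alpha * alpha * alpha);
  } else {
    I0 = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
    I1 = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
    I2 = dt * dt * dt * (1.0 / 3.0 - ad / 4.0 + ad * ad / 10.0);
  }
  double w = 0.0, v = 0.0;
  for (int i = 1; i < n; ++i) {
    double c0 = cp[i - 1], c1 = cp[i];
    double q = c1 * I1 - (c1 - c0) / dt * I2;
    v = E * (v + dt * w) + q;
    w = E * w + c1 * I0 - (c1 - c0) / dt * I1;
    y[i] = cc * v;
  }
  return y;
}

// Accumulate all exponential (and t-exponential) terms of the impulse
// response in one fused pass over the grid (no temporaries: one scalar
// recursion state per term).
// [[Rcpp::export]]
NumericVector conv_terms_cpp(NumericVector cp, double dt, NumericVector cc,
                             NumericVector alpha, NumericVector tcc,
                             NumericVector talpha) {
  int n = cp.size(), ne = cc.size(), nt = tcc.size();
  NumericVector y(n);
  std::vector<double> E(ne), I0(ne), I1(ne), acc(ne, 0.0);
  std::vector<double> Et(nt), J0(nt), J1(nt), J2(nt), wv(nt, 0.0), vv(nt, 0.0);
  for (int j = 0; j < ne; ++j) {
    double ad = alpha[j] * dt;
    E[j] = std::exp(-ad);
    if (ad > 1e-8) {
      I0[j] = (1.0 - E[j]) / alpha[j];
      I1[j] = (1.0 - (1.0 + ad) * E[j]) / (alpha[j] * alpha[j]);
    } else {
      I0[j] = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
      I1[j] = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
    }
  }
  for (int j = 0; j < nt; ++j) {
    double ad = talpha[j] * dt;
    Et[j] = std::exp(-ad);
    if (ad > 1e-8) {
      J0[j] = (1.0 - Et[j]) / talpha[j];
      J1[j] = (1.0 - (1.0 + ad) * Et[j]) / (talpha[j] * talpha[j]);
      J2[j] = (2.0 - (2.0 + 2.0 * ad + ad * ad) * Et[j]) /
              (talpha[j] * talpha[j] * talpha[j]);
    } else {
      J0[j] = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
      J1[j] = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
      J2[j] = dt * dt * dt * (1.0 / 3.0 - ad / 4.0 + ad * ad / 10.0);
    }
  }
  for (int i = 1; i < n; ++i) {
    double c1 = cp[i], slope = (cp[i] - cp[i - 1]) / dt, out = 0.0;
    for (int j = 0; j < ne; ++j) {
      acc[j] = E[j] * acc[j] + c1 * I0[j] - slope * I1[j];
      out += cc[j] * acc[j];
    }
    for (int j = 0; j < nt; ++j) {
      double q = c1 * J1[j] - slope * J2[j];
      vv[j] = Et[j] * (vv[j] + dt * wv[j]) + q;
      wv[j] = Et[j] * wv[j] + c1 * J0[j] - slope * J1[j];
      out += tcc[j] * vv[j];
    }
    y[i] = out;
  }
  return y;
}

// Sparse frame-average applicator: out[f] = sum over nonzeros of w * E.
// [[Rcpp::export]]
NumericVector frame_avg_cpp(NumericVector E, NumericVector wv,
                            IntegerVector idx, IntegerVector fid, int nf) {
  NumericVector out(nf);
  int n = wv.size();
  for (int k = 0; k < n; ++k) out[fid[k] - 1] += wv[k] * E[idx[k] - 1];
  return out;
}

// Fused kernel: convolution recursion and frame averaging in one pass.
// Sparse frame weights (wv, idx, fid) must be sorted by grid-node index
// idx (1-based); the output is scale * (frame-averaged convolution).
// [[Rcpp::export]]
NumericVector conv_frames_cpp(NumericVector cp, double dt, NumericVector cc,
                              NumericVector alpha, NumericVector tcc,
                              NumericVector talpha, NumericVector wv,
                              IntegerVector idx, IntegerVector fid, int nf,
                              double scale) {
  int n = cp.size(), ne = cc.size(), nt = tcc.size(), nnz = wv.size();
  NumericVector out(nf);
  std::vector<double> E(ne), I0(ne), I1(ne), acc(ne, 0.0);
  std::vector<double> Et(nt), J0(nt), J1(nt), J2(nt), ww(nt, 0.0), vv(nt, 0.0);
  for (int j = 0; j < ne; ++j) {
    double ad = alpha[j] * dt;
    E[j] = std::exp(-ad);
    if (ad > 1e-8) {
      I0[j] = (1.0 - E[j]) / alpha[j];
      I1[j] = (1.0 - (1.0 + ad) * E[j]) / (alpha[j] * alpha[j]);
    } else {
      I0[j] = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
      I1[j] = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
    }
  }
  for (int j = 0; j < nt; ++j) {
    double ad = talpha[j] * dt;
    Et[j] = std::exp(-ad);
    if (ad > 1e-8) {
      J0[j] = (1.0 - Et[j]) / talpha[j];
      J1[j] = (1.0 - (1.0 + ad) * Et[j]) / (talpha[j] * talpha[j]);
      J2[j] = (2.0 - (2.0 + 2.0 * ad + ad * ad) * Et[j]) /
              (talpha[j] * talpha[j] * talpha[j]);
    } else {
      J0[j] = dt * (1.0 - ad / 2.0 + ad * ad / 6.0);
      J1[j] = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0);
      J2[j] = dt * dt * dt * (1.0 / 3.0 - ad / 4.0 + ad * ad / 10.0);
    }
  }
  int ptr = 0;
  while (ptr < nnz && idx[ptr] == 1) ++ptr;  // node 1 has y = 0
  for (int i = 1; i < n; ++i) {
    double c1 = cp[i], slope = (cp[i] - cp[i - 1]) / dt, y = 0.0;
    for (int j = 0; j < ne; ++j) {
      acc[j] = E[j] * acc[j] + c1 * I0[j] - slope * I1[j];
      y += cc[j] * acc[j];
    }
    for (int j = 0; j < nt; ++j) {
      double q = c1 * J1[j] - slope * J2[j];
      vv[j] = Et[j] * (vv[j] + dt * ww[j]) + q;
      ww[j] = Et[j] * ww[j] + c1 * J0[j] - slope * J1[j];
      y += tcc[j] * vv[j];
    }
    y *= scale;
    while (ptr < nnz && idx[ptr] == i + 1) {
      out[fid[ptr] - 1] += wv[ptr] * y;
      ++ptr;
    }
  }
  return out;
}
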