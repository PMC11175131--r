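#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-cost recurrence shared by the cost-only and path variants:
// g(i,j) = (c_i - t_j)^2 + min(g(i-1,j), g(i,j-1), g(i-1,j-1)),
// no warping window, no path-length normalisation.

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector c, NumericVector t) {
  const int I = c.size(), J = t.size();
  std::vector<double> prev(J), cur(J);
  for (int j = 0; j < J; ++j) {
    double d = c[0] - t[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < I; ++i) {
    double d0 = c[i] - t[0];
    cur[0] = d0 * d0 + prev[0];
    for (int j = 1; j < J; ++j) {
      double d = c[i] - t[j];
      double m = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = d * d + m;
    }
    std::swap(prev, cur);
  }
  return prev[J - 1];
}

// Full matrix + backtracking. Tie-break in backtracking: diagonal, then
// vertical (i-1,j), then horizontal (i,j-1), giving deterministic paths.
// [[Rcpp::export]]
List dtw_align_cpp(NumericVector c, NumericVector t) {
  const int I = c.size(), J = t.size();
  NumericMatrix g(I, J);
  for (int i = 0; i < I; ++i) {
    for (int j = 0; j < J; ++j) {
      double d = c[i] - t[j];
      d *= d;
      if (i == 0 && j == 0)      g(i, j) = d;
      else if (i == 0)           g(i, j) = d + g(i, j - 1);
      else if (j == 0)           g(i, j) = d + g(i - 1, j);
      else {
        double m = std::min(g(i - 1, j - 1), std::min(g(i - 1, j), g(i, j - 1)));
        g(i, j) = d + m;
      }
    }
  }
  std::vector<int> pi, pj;
  int i = I - 1, j = J - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0)      { --j; }
    else if (j == 0) { --i; }
    else {
      double dg = g(i - 1, j - 1), dv = g(i - 1, j), dh = g(i, j - 1);
      double m = std::min(dg, std::min(dv, dh));
      if (dg == m)      { --i; --j; }
      else if (dv == m) { --i; }
      else              { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int Q = pi.size();
  IntegerMatrix path(Q, 2);
  for (int q = 0; q < Q; ++q) {
    path(q, 0) = pi[Q - 1 - q];
    path(q, 1) = pj[Q - 1 - q];
  }
  return List::create(_["distance"] = g(I - 1, J - 1), _["path"] = path);
}

// All-pairs DTW cost among a list of numeric vectors (medoid selection).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series) {
  const int n = series.size();
  NumericMatrix out(n, n);
  std::vector<NumericVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_cost_cpp(v[i], v[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// Exact Hampel filter: truncated windows at the edges, median of the window,
// scaled MAD about that median; flagged points replaced by the median.
// [[Rcpp::export]]
NumericVector hampel_filter_cpp(NumericVector x, int window, double threshold) {
  const int n = x.size();
  const int half = (window - 1) / 2;
  NumericVector out = clone(x);
  std::vector<double> buf;
  buf.reserve(window);
  auto median_of = [](std::vector<double>& v) {
    const int m = v.size();
    std::nth_element(v.begin(), v.begin() + m / 2, v.end());
    double hi = v[m / 2];
    if (m % 2 == 1) return hi;
    std::nth_element(v.begin(), v.begin() + m / 2 - 1, v.end());
    return (hi + v[m / 2 - 1]) / 2.0;
  };
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double med = median_of(buf);
    for (double& b : buf) b = std::fabs(b - med);
    double sc = 1.4826 * median_of(buf);
    if (sc > 0 && std::fabs(x[i] - med) > threshold * sc) out[i] = med;
  }
  return out;
}
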