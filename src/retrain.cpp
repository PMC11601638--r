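#include <Rcpp.h>
using namespace Rcpp;

// Online retraining passes for the hyperdimensional classifier.
//
// E    : n x d matrix of sample encodings (integer-valued, stored as double)
// y    : 1-based class index per sample (classes in sorted-label order)
// cv0  : C x d initial class hypervectors (bundles of training encodings)
// maxIter : maximum number of retraining passes (R)
//
// Within a pass, samples are visited in dataset order and every
// misclassification immediately subtracts the sample's encoding from the
// wrongly-predicted class vector and adds it to the true class vector.
// After each pass the error count is re-evaluated on the full set; the loop
// stops when it equals the previous count or maxIter passes were run.
// Ties in cosine similarity go to the first (lexicographically smallest)
// class, matching the R-level predict method.

static int predict_one(const NumericMatrix &E, const NumericMatrix &cv,
                       const std::vector<double> &rowNorm, int i) {
  const int d = E.ncol(), C = cv.nrow();
  if (rowNorm[i] == 0.0)
    stop("cosine similarity is undefined: sample %d encodes to the zero vector",
         i + 1);
  double best = R_NegInf;
  int bi = -1;
  for (int c = 0; c < C; ++c) {
    double dot = 0.0, nc = 0.0;
    for (int j = 0; j < d; ++j) {
      dot += cv(c, j) * E(i, j);
      nc += cv(c, j) * cv(c, j);
    }
    if (nc == 0.0)
      stop("cosine similarity is undefined: class vector %d is all-zero", c + 1);
    double cs = dot / (std::sqrt(nc) * rowNorm[i]);
    if (cs > best) { best = cs; bi = c; }
  }
  return bi;
}

static int count_errors(const NumericMatrix &E, const IntegerVector &y,
                        const NumericMatrix &cv,
                        const std::vector<double> &rowNorm) {
  int err = 0;
  for (int i = 0; i < E.nrow(); ++i)
    if (predict_one(E, cv, rowNorm, i) != y[i] - 1) ++err;
  return err;
}

// [[Rcpp::export(name = ".hd_retrain_cpp")]]
List hd_retrain_cpp(NumericMatrix E, IntegerVector y, NumericMatrix cv0,
                    int maxIter) {
  const int n = E.nrow(), d = E.ncol();
  if (y.size() != n) stop("label/encoding size mismatch");
  NumericMatrix cv = clone(cv0);

  std::vector<double> rowNorm(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += E(i, j) * E(i, j);
    rowNorm[i] = std::sqrt(s);
  }

  std::vector<int> trace;
  std::vector<int> adjPass, adjSample, adjFrom, adjTo;

  int prev = 0;
  int curr = count_errors(E, y, cv, rowNorm);
  trace.push_back(curr);
  int pass = 0;
  while (curr != prev && pass < maxIter) {
    ++pass;
    for (int i = 0; i < n; ++i) {
      int p = predict_one(E, cv, rowNorm, i);
      int truth = y[i] - 1;
      if (p != truth) {
        for (int j = 0; j < d; ++j) {
          cv(p, j) -= E(i, j);
          cv(truth, j) += E(i, j);
        }
        adjPass.push_back(pass);
        adjSample.push_back(i + 1);
        adjFrom.push_back(p + 1);
        adjTo.push_back(truth + 1);
      }
    }
    prev = curr;
    curr = count_errors(E, y, cv, rowNorm);
    trace.push_back(curr);
  }

  return List::create(
    _["class_vectors"] = cv,
    _["passes"] = pass,
    _["error_trace"] = wrap(trace),
    _["adjustments"] = DataFrame::create(
      _["pass"] = wrap(adjPass), _["sample"] = wrap(adjSample),
      _["from"] = wrap(adjFrom), _["to"] = wrap(adjTo)));
}
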