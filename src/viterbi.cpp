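#include <Rcpp.h>
using namespace Rcpp;

// Log-space Viterbi decoding with tie-breaking that favours state
// persistence (the incoming state equal to the current one), then the lowest
// state index. logE: nStates x T log emission; logT: nStates x nStates log
// transition. Initial distribution uniform over states.
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericMatrix logE, NumericMatrix logT) {
  const int S = logE.nrow();
  const int T = logE.ncol();
  if (T < 1) stop("need at least one marker");

  NumericVector delta(S), deltaNew(S);
  IntegerMatrix psi(S, T);
  const double logInit = -std::log((double)S);
  for (int s = 0; s < S; ++s) delta[s] = logInit + logE(s, 0);

  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      // prefer staying in state s on ties
      int best = s;
      double bestv = delta[s] + logT(s, s);
      for (int p = 0; p < S; ++p) {
        if (p == s) continue;
        double v = delta[p] + logT(p, s);
        if (v > bestv + 1e-12 ||
            (v > bestv - 1e-12 && best != s && p < best)) {
          bestv = v;
          best = p;
        }
      }
      psi(s, t) = best;
      deltaNew[s] = bestv + logE(s, t);
    }
    delta = clone(deltaNew);
  }

  int last = 0;
  for (int s = 1; s < S; ++s)
    if (delta[s] > delta[last] + 1e-12) last = s;
  double logProb = delta[last];

  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states

  return List::create(_["path"] = path, _["logProb"] = logProb);
}
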