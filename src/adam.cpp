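#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam step with decoupled weight decay on the (transposed)
// embedding weight matrix.  W, M and V are owned by the training loop and
// updated in place to avoid allocating several copies of a ~1e6-entry
// matrix on every mini-batch.
// [[Rcpp::export(name = ".adamStep")]]
void adamStep(NumericMatrix W, NumericMatrix M, NumericMatrix V,
              const NumericMatrix G, double lr, double wd,
              double beta1, double beta2, double eps, int t) {
  const R_xlen_t n = W.size();
  if (M.size() != n || V.size() != n || G.size() != n)
    stop("adamStep: dimension mismatch");
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = G[i];
    M[i] = beta1 * M[i] + (1.0 - beta1) * g;
    V[i] = beta2 * V[i] + (1.0 - beta2) * g * g;
    const double mhat = M[i] / c1;
    const double vhat = V[i] / c2;
    W[i] -= lr * mhat / (std::sqrt(vhat) + eps) + lr * wd * W[i];
  }
}
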