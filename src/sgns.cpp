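// Skip-gram negative-sampling core shared by the disease-only and the joint
// disease+gene trainers.  All randomness comes from a self-contained 64-bit
// counter RNG so that a given seed reproduces training bit-for-bit,
// independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: tiny, well-mixed, deterministic across platforms.
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

double log_sigmoid(double x) {
  if (x >= 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

double dot(const double* a, const double* b, int D) {
  double s = 0.0;
  for (int j = 0; j < D; ++j) s += a[j] * b[j];
  return s;
}

// One gradient-ascent step on
//   log sigma(v'_ctx . v) + sum_k log sigma(-v'_neg_k . v)
// updating the context output vector, each negative output vector and the
// center input vector.  All gradients are evaluated at the pre-update point.
// Returns the pre-update objective value.
double pair_step(double* vc, double* vctx, double* const* vneg, int nneg,
                 int D, double lr, std::vector<double>& cgrad) {
  const double pos = dot(vc, vctx, D);
  double obj = log_sigmoid(pos);
  const double gpos = 1.0 - sigmoid(pos);  // d obj / d pos

  for (int j = 0; j < D; ++j) cgrad[j] = gpos * vctx[j];

  std::vector<double> gneg(nneg);
  for (int k = 0; k < nneg; ++k) {
    const double nk = dot(vc, vneg[k], D);
    obj += log_sigmoid(-nk);
    const double s = sigmoid(nk);
    gneg[k] = -s;
    for (int j = 0; j < D; ++j) cgrad[j] -= s * vneg[k][j];
  }
  if (!std::isfinite(obj))
    stop("numerical divergence in negative-sampling update");

  for (int j = 0; j < D; ++j) {
    const double c = vc[j];
    vctx[j] += lr * gpos * c;
    for (int k = 0; k < nneg; ++k) vneg[k][j] += lr * gneg[k] * c;
  }
  for (int j = 0; j < D; ++j) vc[j] += lr * cgrad[j];
  return obj;
}

// Inverse-CDF draw from the noise distribution (cdf over candidate slots).
int draw_noise(const double* cdf, int n, Rng& rng) {
  const double u = rng.unif();
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    const int mid = (lo + hi) / 2;
    if (cdf[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

}  // namespace

//' @useDynLib dgembed, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export]]
List sgns_pair_update_cpp(NumericVector center, NumericVector ctx_out,
                          NumericMatrix negs_out, double lr) {
  const int D = center.size();
  if (ctx_out.size() != D || negs_out.ncol() != D)
    stop("dimension mismatch between center, context and negative vectors");
  const int nneg = negs_out.nrow();

  std::vector<double> vc(center.begin(), center.end());
  std::vector<double> vctx(ctx_out.begin(), ctx_out.end());
  std::vector<std::vector<double>> vneg(nneg, std::vector<double>(D));
  std::vector<double*> pneg(nneg);
  for (int k = 0; k < nneg; ++k) {
    for (int j = 0; j < D; ++j) vneg[k][j] = negs_out(k, j);
    pneg[k] = vneg[k].data();
  }
  std::vector<double> cgrad(D);
  const double obj = pair_step(vc.data(), vctx.data(), pneg.data(), nneg, D,
                               lr, cgrad);

  NumericMatrix negs_new(nneg, D);
  for (int k = 0; k < nneg; ++k)
    for (int j = 0; j < D; ++j) negs_new(k, j) = vneg[k][j];
  return List::create(_["center"] = NumericVector(vc.begin(), vc.end()),
                      _["context"] = NumericVector(vctx.begin(), vctx.end()),
                      _["negatives"] = negs_new,
                      _["objective"] = obj);
}

// [[Rcpp::export]]
List sgns_pair_gradient_cpp(NumericVector center, NumericVector ctx_out,
                            NumericMatrix negs_out) {
  const int D = center.size();
  const int nneg = negs_out.nrow();
  const double pos = dot(&center[0], &ctx_out[0], D);
  double obj = log_sigmoid(pos);
  const double gpos = 1.0 - sigmoid(pos);

  NumericVector gcenter(D), gctx(D);
  NumericMatrix gneg(nneg, D);
  for (int j = 0; j < D; ++j) {
    gctx[j] = gpos * center[j];
    gcenter[j] = gpos * ctx_out[j];
  }
  for (int k = 0; k < nneg; ++k) {
    double nk = 0.0;
    for (int j = 0; j < D; ++j) nk += center[j] * negs_out(k, j);
    obj += log_sigmoid(-nk);
    const double s = sigmoid(nk);
    for (int j = 0; j < D; ++j) {
      gneg(k, j) = -s * center[j];
      gcenter[j] -= s * negs_out(k, j);
    }
  }
  return List::create(_["center"] = gcenter, _["context"] = gctx,
                      _["negatives"] = gneg, _["objective"] = obj);
}

// [[Rcpp::export]]
IntegerVector sample_noise_cpp(NumericVector cdf, IntegerVector ids, int n,
                               int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ids[draw_noise(&cdf[0], cdf.size(), rng)];
  return out;
}

// Full trainer.  `records` holds 1-based vocabulary row indices; `gene_lists`
// has one (possibly empty) integer vector of gene rows per vocabulary row;
// `keep_prob` is the per-row subsampling keep probability; `noise_cdf` /
// `noise_ids` define the unigram^power noise distribution over disease rows.
// [[Rcpp::export]]
List sgns_train_cpp(List records, List gene_lists, NumericVector keep_prob,
                    NumericVector noise_cdf, IntegerVector noise_ids,
                    int W, int D, int b, int negatives, int epochs,
                    double lr_initial, double lr_final, int seed) {
  if (W < 1 || D < 1 || b < 1 || negatives < 1 || epochs < 1)
    stop("invalid training configuration");

  Rng rng(static_cast<uint64_t>(seed));

  // init: input rows uniform in (-0.5/D, 0.5/D), output rows zero
  std::vector<double> Vin(static_cast<size_t>(W) * D);
  std::vector<double> Vout(static_cast<size_t>(W) * D, 0.0);
  for (size_t i = 0; i < Vin.size(); ++i) Vin[i] = (rng.unif() - 0.5) / D;

  const int nrec = records.size();
  std::vector<std::vector<int>> recs(nrec);
  long long total_pairs = 0;
  for (int r = 0; r < nrec; ++r) {
    IntegerVector rv = records[r];
    recs[r].assign(rv.begin(), rv.end());
    const int M = recs[r].size();
    for (int m = 0; m < M; ++m) {
      const int lo = std::max(0, m - b), hi = std::min(M - 1, m + b);
      total_pairs += (hi - lo);  // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) {
    // no context anywhere: return the initialized model untouched
    NumericMatrix in_m(W, D), out_m(W, D);
    for (int w = 0; w < W; ++w)
      for (int j = 0; j < D; ++j) in_m(w, j) = Vin[static_cast<size_t>(w) * D + j];
    return List::create(_["input"] = in_m, _["output"] = out_m,
                        _["pairs_trained"] = 0.0, _["pairs_scheduled"] = 0.0,
                        _["pairs_dropped"] = 0.0);
  }

  std::vector<std::vector<int>> glists(W);
  for (int w = 0; w < W; ++w) {
    IntegerVector gv = gene_lists[w];
    glists[w].assign(gv.begin(), gv.end());
  }

  const int ncand = noise_cdf.size();
  std::vector<double> cgrad(D);
  std::vector<int> negbuf(negatives);
  std::vector<double*> pneg(negatives);
  std::vector<int> genebuf;

  long long sched = 0, trained = 0, dropped = 0;
  const double lr_span = lr_final - lr_initial;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < nrec; ++r) {
      const std::vector<int>& rec = recs[r];
      const int M = rec.size();
      for (int m = 0; m < M; ++m) {
        const int lo = std::max(0, m - b), hi = std::min(M - 1, m + b);
        const int npairs = hi - lo;
        if (npairs == 0) continue;
        const double lr =
            lr_initial + lr_span * (static_cast<double>(sched) / total_pairs);
        sched += npairs;

        const int c = rec[m] - 1;
        if (keep_prob[c] < 1.0 && rng.unif() >= keep_prob[c]) continue;

        // per-occurrence gene bag: fresh shuffle, then per-gene subsampling
        genebuf.clear();
        const std::vector<int>& gl = glists[c];
        if (!gl.empty()) {
          genebuf.assign(gl.begin(), gl.end());
          for (int i = static_cast<int>(genebuf.size()) - 1; i > 0; --i) {
            const int j = rng.below(i + 1);
            std::swap(genebuf[i], genebuf[j]);
          }
          size_t keep = 0;
          for (size_t i = 0; i < genebuf.size(); ++i) {
            const int g = genebuf[i] - 1;
            if (keep_prob[g] < 1.0 && rng.unif() >= keep_prob[g]) continue;
            genebuf[keep++] = genebuf[i];
          }
          genebuf.resize(keep);
        }

        for (int pos = lo; pos <= hi; ++pos) {
          if (pos == m) continue;
          const int ctx = rec[pos] - 1;

          // disease-center update, then one update per attached gene;
          // each update draws its own negatives (resampling collisions
          // with the positive target)
          const int ncenters = 1 + static_cast<int>(genebuf.size());
          for (int s = 0; s < ncenters; ++s) {
            bool ok = true;
            for (int k = 0; k < negatives; ++k) {
              int cand = -1;
              for (int attempt = 0; attempt < 100; ++attempt) {
                cand = noise_ids[draw_noise(&noise_cdf[0], ncand, rng)] - 1;
                if (cand != ctx) break;
                cand = -1;
              }
              if (cand < 0) { ok = false; break; }
              negbuf[k] = cand;
            }
            if (!ok) { ++dropped; continue; }
            const int crow = (s == 0) ? c : (genebuf[s - 1] - 1);
            for (int k = 0; k < negatives; ++k)
              pneg[k] = &Vout[static_cast<size_t>(negbuf[k]) * D];
            pair_step(&Vin[static_cast<size_t>(crow) * D],
                      &Vout[static_cast<size_t>(ctx) * D], pneg.data(),
                      negatives, D, lr, cgrad);
            ++trained;
          }
        }
      }
      if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  if (dropped > 0)
    Rcpp::warning("%lld update(s) dropped: negative sampling failed to avoid "
                  "the positive target after 100 attempts",
                  dropped);

  NumericMatrix in_m(W, D), out_m(W, D);
  for (int w = 0; w < W; ++w)
    for (int j = 0; j < D; ++j) {
      in_m(w, j) = Vin[static_cast<size_t>(w) * D + j];
      out_m(w, j) = Vout[static_cast<size_t>(w) * D + j];
    }
  return List::create(_["input"] = in_m, _["output"] = out_m,
                      _["pairs_trained"] = static_cast<double>(trained),
                      _["pairs_scheduled"] = static_cast<double>(sched),
                      _["pairs_dropped"] = static_cast<double>(dropped));
}
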