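// Training inner loop for the bimodal autoencoders: dense sigmoid stacks,
// backpropagation and AdaDelta, for both the mixed-input and the two-stage
// framework. Semantics mirror the R-level forward/backward helpers; the
// epoch-wise sample permutations are generated in R so the shuffle stream
// is part of the package's seeded RNG protocol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Layer {
  mat W; rowvec b;
  mat EgW, EdW; rowvec Egb, Edb;
};

typedef std::vector<Layer> Stack;

Stack as_stack(Rcpp::List lst) {
  Stack s;
  for (R_xlen_t i = 0; i < lst.size(); ++i) {
    Rcpp::List lay = lst[i];
    Layer L;
    L.W = Rcpp::as<mat>(lay["W"]);
    L.b = Rcpp::as<rowvec>(lay["b"]);
    L.EgW.zeros(L.W.n_rows, L.W.n_cols);
    L.EdW.zeros(L.W.n_rows, L.W.n_cols);
    L.Egb.zeros(L.b.n_elem);
    L.Edb.zeros(L.b.n_elem);
    s.push_back(L);
  }
  return s;
}

Rcpp::List stack_to_list(const Stack& s) {
  Rcpp::List out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    out[i] = Rcpp::List::create(
      Rcpp::Named("W") = s[i].W,
      Rcpp::Named("b") = Rcpp::NumericVector(s[i].b.begin(), s[i].b.end()));
  }
  return out;
}

inline mat sigmoid(mat z) { return 1.0 / (1.0 + exp(-z)); }

// forward pass; acts[0] is the input, acts[i+1] the i-th layer output.
// When zLast is given it receives the top layer's pre-activation.
void forward(const Stack& s, const mat& x, std::vector<mat>& acts,
             mat* zLast = nullptr) {
  acts.clear();
  acts.push_back(x);
  for (size_t i = 0; i < s.size(); ++i) {
    mat z = acts[i] * s[i].W;
    z.each_row() += s[i].b;
    if (zLast && i == s.size() - 1) *zLast = z;
    acts.push_back(sigmoid(z));
  }
}

void adadelta(mat& p, const mat& g, mat& Eg, mat& Ed, double rho,
              double eps) {
  Eg = rho * Eg + (1 - rho) * square(g);
  mat dx = -sqrt((Ed + eps) / (Eg + eps)) % g;
  Ed = rho * Ed + (1 - rho) * square(dx);
  p += dx;
}

void adadelta(rowvec& p, const rowvec& g, rowvec& Eg, rowvec& Ed,
              double rho, double eps) {
  Eg = rho * Eg + (1 - rho) * square(g);
  rowvec dx = -sqrt((Ed + eps) / (Eg + eps)) % g;
  Ed = rho * Ed + (1 - rho) * square(dx);
  p += dx;
}

// backward through a sigmoid stack; dTop is dL/dZ at the top layer when
// top_is_dz, else dL/dA. Applies AdaDelta updates in place and returns
// dL/dA at the stack input.
mat backward(Stack& s, const std::vector<mat>& acts, const mat& dTop,
             bool top_is_dz, double rho, double eps) {
  mat dA;
  for (int i = (int)s.size() - 1; i >= 0; --i) {
    mat dZ;
    if (i == (int)s.size() - 1 && top_is_dz) {
      dZ = dTop;
    } else {
      const mat& a = acts[i + 1];
      const mat& up = (i == (int)s.size() - 1) ? dTop : dA;
      dZ = up % (a % (1.0 - a));
    }
    mat gW = acts[i].t() * dZ;
    rowvec gb = sum(dZ, 0);
    dA = dZ * s[i].W.t();
    adadelta(s[i].W, gW, s[i].EgW, s[i].EdW, rho, eps);
    adadelta(s[i].b, gb, s[i].Egb, s[i].Edb, rho, eps);
  }
  return dA;
}

// binary cross-entropy summed over output dimensions, averaged over rows.
// Uses t*log(y) + (1-t)*log(1-y) = t*z + log(1-y) with z the logit.
double bce(const mat& y, const mat& z, const mat& t) {
  return -accu(t % z + log(1.0 - y + 1e-12)) / (double)y.n_rows;
}

} // namespace

// [[Rcpp::export(name = ".cppTrainBimodal")]]
Rcpp::List cppTrainBimodal(Rcpp::List weights, std::string framework,
                           const arma::mat& xv, const arma::mat& xa,
                           const arma::mat& tv, const arma::mat& ta,
                           const arma::imat& perms, int batchSize,
                           int epochOffset, double rho, double eps) {
  const bool mixed = framework == "mixed";
  const int n = xv.n_rows;
  const int epochs = perms.n_cols;

  Stack enc, encV, encA, mrg;
  if (mixed) {
    enc = as_stack(weights["encoder"]);
  } else {
    encV = as_stack(weights["encoderVisual"]);
    encA = as_stack(weights["encoderAuditory"]);
    mrg = as_stack(weights["merge"]);
  }
  Stack decV = as_stack(weights["decoderVisual"]);
  Stack decA = as_stack(weights["decoderAuditory"]);

  mat xMix;
  if (mixed) xMix = join_rows(xv, xa);

  vec bceLog(epochs), mseLog(epochs);
  std::vector<mat> aEnc, aEncV, aEncA, aMrg, aDecV, aDecA;

  for (int ep = 0; ep < epochs; ++ep) {
    double bceSum = 0, mseSum = 0;
    for (int s0 = 0; s0 < n; s0 += batchSize) {
      const int s1 = std::min(s0 + batchSize, n) - 1;
      uvec idx(s1 - s0 + 1);
      for (int k = s0; k <= s1; ++k) idx[k - s0] = perms(k, ep) - 1;
      const int nb = idx.n_elem;

      mat code;
      if (mixed) {
        forward(enc, xMix.rows(idx), aEnc);
        code = aEnc.back();
      } else {
        forward(encV, xv.rows(idx), aEncV);
        forward(encA, xa.rows(idx), aEncA);
        forward(mrg, join_rows(aEncV.back(), aEncA.back()), aMrg);
        code = aMrg.back();
      }
      mat zv, za;
      forward(decV, code, aDecV, &zv);
      forward(decA, code, aDecA, &za);
      const mat& yv = aDecV.back();
      const mat& ya = aDecA.back();
      mat tvb = tv.rows(idx), tab = ta.rows(idx);

      double lb = bce(yv, zv, tvb) + bce(ya, za, tab);
      if (!std::isfinite(lb))
        Rcpp::stop("non-finite training loss at epoch %d",
                   epochOffset + ep + 1);
      bceSum += lb * nb;
      mseSum += accu(square(tvb - yv)) + accu(square(tab - ya));

      // sigmoid + BCE output layers: dL/dZ = (y - t) / nb
      mat dV = backward(decV, aDecV, (yv - tvb) / nb, true, rho, eps);
      mat dA_ = backward(decA, aDecA, (ya - tab) / nb, true, rho, eps);
      mat dCode = dV + dA_;
      if (mixed) {
        backward(enc, aEnc, dCode, false, rho, eps);
      } else {
        mat dMrg = backward(mrg, aMrg, dCode, false, rho, eps);
        const int w1 = aEncV.back().n_cols;
        backward(encV, aEncV, dMrg.cols(0, w1 - 1), false, rho, eps);
        backward(encA, aEncA, dMrg.cols(w1, dMrg.n_cols - 1), false, rho,
                 eps);
      }
    }
    bceLog[ep] = bceSum / n;
    mseLog[ep] = mseSum / n;
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List wOut;
  if (mixed) {
    wOut = Rcpp::List::create(
      Rcpp::Named("encoder") = stack_to_list(enc),
      Rcpp::Named("decoderVisual") = stack_to_list(decV),
      Rcpp::Named("decoderAuditory") = stack_to_list(decA));
  } else {
    wOut = Rcpp::List::create(
      Rcpp::Named("encoderVisual") = stack_to_list(encV),
      Rcpp::Named("encoderAuditory") = stack_to_list(encA),
      Rcpp::Named("merge") = stack_to_list(mrg),
      Rcpp::Named("decoderVisual") = stack_to_list(decV),
      Rcpp::Named("decoderAuditory") = stack_to_list(decA));
  }
  return Rcpp::List::create(Rcpp::Named("weights") = wOut,
                            Rcpp::Named("bce") = bceLog,
                            Rcpp::Named("mse") = mseLog);
}
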