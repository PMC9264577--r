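// Siamese 1D-CNN trunk for deep-hash protein encoding: embedding lookup,
// four conv->ReLU->batchnorm->pool blocks, frozen random projections and a
// sigmoid range-control stage, with a hand-written backward pass for the
// contrastive / quantization / bit-balance training losses.
//
// Layout: a batch of B sequences of length L with C channels is one
// (B*L) x C matrix, sample s occupying rows [s*L, (s+1)*L). Convolutions
// are im2col + one GEMM over the whole batch; batchnorm uses biased batch
// variance and running averages with momentum 0.9. Conv weights are
// (k * C_in) x C_out with column block j (size C_in) holding kernel tap j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

struct BlockCache {
  mat col;      // im2col of the conv input, (B*L_in) x (k*C_in)
  mat Y;        // conv output, pre-ReLU
  mat Xhat;     // normalized post-ReLU
  vec invstd;
  int L_in;
};

// 'same' zero-padded stride-1 im2col over the stacked batch; k odd.
static mat im2col_batch(const mat& X, int B, int L, int k) {
  const int C = X.n_cols, pad = (k - 1) / 2;
  mat col(B * L, k * C, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int r0 = s * L;
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 > t0) {
        col.submat(r0 + t0, j * C, r0 + t1 - 1, (j + 1) * C - 1) =
          X.rows(r0 + t0 + shift, r0 + t1 - 1 + shift);
      }
    }
  }
  return col;
}

static mat col2im_batch(const mat& dcol, int B, int L, int k, int C) {
  const int pad = (k - 1) / 2;
  mat dX(B * L, C, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int r0 = s * L;
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 > t0) {
        dX.rows(r0 + t0 + shift, r0 + t1 - 1 + shift) +=
          dcol.submat(r0 + t0, j * C, r0 + t1 - 1, (j + 1) * C - 1);
      }
    }
  }
  return dX;
}

// Trunk forward. Fills caches in training mode; training mode uses batch
// batchnorm statistics and reports refreshed running averages through
// new_running.
static mat trunk_forward(const imat& tokens, const List& params,
                         const List& cfg, bool training,
                         std::vector<BlockCache>* caches,
                         List* new_running) {
  const int B = tokens.n_rows, L0 = tokens.n_cols;
  const IntegerVector channels = cfg["channels"];
  const IntegerVector ksizes = cfg["ksizes"];
  const IntegerVector pools = cfg["pool"];   // window (>=2) or 0 = global
  const int nb = channels.size();
  const mat emb = as<mat>(params["emb"]);
  const bool mask_zero = as<bool>(cfg["mask_zero"]);

  int L = L0;
  mat X(B * L, emb.n_cols, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t) {
      const int tok = tokens(s, t);
      if (!(mask_zero && tok == 0)) X.row(s * L + t) = emb.row(tok);
    }

  for (int b = 0; b < nb; ++b) {
    const std::string sb = std::to_string(b + 1);
    const mat W = as<mat>(params["W" + sb]);
    const vec bias = as<vec>(params["b" + sb]);
    const vec gamma = as<vec>(params["gamma" + sb]);
    const vec beta = as<vec>(params["beta" + sb]);
    const int k = ksizes[b], C_out = channels[b];

    mat col = im2col_batch(X, B, L, k);
    mat Y = col * W;
    Y.each_row() += bias.t();
    mat A = Y;
    A.transform([](double v) { return v > 0 ? v : 0.0; });  // ReLU

    vec mu(C_out), var(C_out);
    if (training) {
      mu = mean(A, 0).t();
      var = mean(square(A), 0).t() - square(mu);
      var.transform([](double v) { return v > 0 ? v : 0.0; });
      if (new_running) {
        const vec rm = as<vec>(params["rm" + sb]);
        const vec rv = as<vec>(params["rv" + sb]);
        (*new_running)["rm" + sb] = BN_MOMENTUM * rm + (1 - BN_MOMENTUM) * mu;
        (*new_running)["rv" + sb] = BN_MOMENTUM * rv + (1 - BN_MOMENTUM) * var;
      }
    } else {
      mu = as<vec>(params["rm" + sb]);
      var = as<vec>(params["rv" + sb]);
    }
    const vec invstd = 1.0 / sqrt(var + BN_EPS);

    mat Xhat = A;
    Xhat.each_row() -= mu.t();
    Xhat.each_row() %= invstd.t();
    mat Z = Xhat;
    Z.each_row() %= gamma.t();
    Z.each_row() += beta.t();

    const int w = pools[b];
    int L_out;
    mat P;
    if (w == 0) {                     // global average pool -> length 1
      L_out = 1;
      P.set_size(B, C_out);
      for (int s = 0; s < B; ++s)
        P.row(s) = mean(Z.rows(s * L, (s + 1) * L - 1), 0);
    } else {
      L_out = L / w;
      P.set_size(B * L_out, C_out);
      for (int s = 0; s < B; ++s)
        for (int t = 0; t < L_out; ++t)
          P.row(s * L_out + t) =
            mean(Z.rows(s * L + t * w, s * L + t * w + w - 1), 0);
    }

    if (caches) {
      BlockCache bc;
      bc.col = std::move(col); bc.Y = std::move(Y);
      bc.Xhat = std::move(Xhat); bc.invstd = invstd; bc.L_in = L;
      caches->push_back(std::move(bc));
    }
    X = std::move(P);
    L = L_out;
  }
  return X;   // (B x C_last): length collapsed to 1 by the global pool
}

// Trunk backward; returns gradients for emb / W / b / gamma / beta.
static List trunk_backward(const imat& tokens, const mat& dH,
                           const List& params, const List& cfg,
                           const std::vector<BlockCache>& caches) {
  const int B = tokens.n_rows;
  const IntegerVector channels = cfg["channels"];
  const IntegerVector ksizes = cfg["ksizes"];
  const IntegerVector pools = cfg["pool"];
  const int nb = channels.size();
  const mat emb = as<mat>(params["emb"]);
  const bool mask_zero = as<bool>(cfg["mask_zero"]);
  List grads;

  mat dP = dH;   // gradient w.r.t. pooled output of the current block
  for (int b = nb - 1; b >= 0; --b) {
    const std::string sb = std::to_string(b + 1);
    const BlockCache& bc = caches[b];
    const mat W = as<mat>(params["W" + sb]);
    const vec gamma = as<vec>(params["gamma" + sb]);
    const int k = ksizes[b], C_out = channels[b];
    const int L_in = bc.L_in, w = pools[b];

    // pool backward -> dZ
    mat dZ(B * L_in, C_out);
    if (w == 0) {
      for (int s = 0; s < B; ++s)
        dZ.rows(s * L_in, (s + 1) * L_in - 1) =
          repmat(dP.row(s) / (double)L_in, L_in, 1);
    } else {
      const int L_out = L_in / w;
      dZ.zeros();
      for (int s = 0; s < B; ++s)
        for (int t = 0; t < L_out; ++t)
          dZ.rows(s * L_in + t * w, s * L_in + t * w + w - 1) =
            repmat(dP.row(s * L_out + t) / (double)w, w, 1);
    }

    // batchnorm backward (batch statistics, biased variance)
    const double n = (double)B * L_in;
    const vec dgamma = sum(dZ % bc.Xhat, 0).t();
    const vec dbeta = sum(dZ, 0).t();
    mat dxhat = dZ;
    dxhat.each_row() %= gamma.t();
    const rowvec m1 = sum(dxhat, 0) / n;
    const rowvec m2 = sum(dxhat % bc.Xhat, 0) / n;
    mat dA = dxhat;
    dA.each_row() -= m1;
    dA -= bc.Xhat.each_row() % m2;
    dA.each_row() %= bc.invstd.t();

    // ReLU backward
    dA %= conv_to<mat>::from(bc.Y > 0);

    // conv backward (one GEMM each for dW and dcol)
    grads["W" + sb] = bc.col.t() * dA;
    grads["b" + sb] = sum(dA, 0).t();
    grads["gamma" + sb] = dgamma;
    grads["beta" + sb] = dbeta;
    mat dcol = dA * W.t();
    dP = col2im_batch(dcol, B, L_in, k, W.n_rows / k);
  }

  // embedding backward
  mat demb(emb.n_rows, emb.n_cols, fill::zeros);
  const int L = tokens.n_cols;
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t) {
      const int tok = tokens(s, t);
      if (!(mask_zero && tok == 0)) demb.row(tok) += dP.row(s * L + t);
    }
  grads["emb"] = demb;
  return grads;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Inference-mode encoding: trunk with running batchnorm statistics, then
// the requested frozen projection and the sigmoid range control.
// [[Rcpp::export]]
arma::mat cpp_encode(const arma::imat& tokens, const List& params,
                     const List& cfg, const std::string& role) {
  mat H = trunk_forward(tokens, params, cfg, false, nullptr, nullptr);
  const mat P = as<mat>(params[role == "ontic" ? "P_ont" : "P_que"]);
  return sigmoid(H * P);
}

// One training batch: joint trunk forward over the ontic and query inputs
// (shared parameters, shared batch statistics), pair losses, full backward.
// Returns mean loss components, parameter gradients and refreshed running
// batchnorm statistics.
// [[Rcpp::export]]
List cpp_pair_batch(const arma::imat& tok_ont, const arma::imat& tok_que,
                    const arma::vec& labels, const List& params,
                    const List& cfg, const List& loss_cfg,
                    bool compute_grads = true) {
  const int B = tok_ont.n_rows;
  if ((int)tok_que.n_rows != B || (int)labels.n_elem != B)
    stop("ontic/query/label batch sizes disagree");

  imat tokens = join_cols(tok_ont, tok_que);
  std::vector<BlockCache> caches;
  List new_running;
  mat H = trunk_forward(tokens, params, cfg, true,
                        compute_grads ? &caches : nullptr, &new_running);

  const mat P_ont = as<mat>(params["P_ont"]);
  const mat P_que = as<mat>(params["P_que"]);
  const int N = P_ont.n_cols;
  const mat H_ont = H.rows(0, B - 1);
  const mat H_que = H.rows(B, 2 * B - 1);
  const mat o = sigmoid(H_ont * P_ont);
  const mat q = sigmoid(H_que * P_que);

  const double in_dist = as<double>(loss_cfg["in_dist"]);
  const double unin_dist = as<double>(loss_cfg["unin_dist"]);
  const double qt = as<double>(loss_cfg["quan_thresh"]);
  const double lam_d = as<double>(loss_cfg["lambda_d"]);
  const double lam_h = as<double>(loss_cfg["lambda_h"]);
  const double lam_b = as<double>(loss_cfg["lambda_b"]);

  const mat diff = o - q;
  const vec dist = sum(abs(diff), 1);
  vec ld(B), lh(B), lb(B);
  mat d_o(B, N, fill::zeros), d_q(B, N, fill::zeros);

  for (int p = 0; p < B; ++p) {
    const double lab = labels(p);
    const double hinge_in = std::max(dist(p) - in_dist, 0.0);
    const double hinge_out = std::max(unin_dist - dist(p), 0.0);
    ld(p) = lab * hinge_in + (1 - lab) * hinge_out;

    const double term_o = qt * qt * N - accu(square(o.row(p) - qt));
    const double term_q = qt * qt * N - accu(square(q.row(p) - qt));
    lh(p) = std::max(term_o, 0.0) + std::max(term_q, 0.0);

    const double mo = mean(o.row(p)), mq = mean(q.row(p));
    lb(p) = (mo - 0.5) * (mo - 0.5) + (mq - 0.5) * (mq - 0.5);

    if (compute_grads) {
      rowvec sgn = sign(diff.row(p));
      double dcoef = 0.0;
      if (lab > 0.5 && hinge_in > 0) dcoef = 1.0;
      if (lab < 0.5 && hinge_out > 0) dcoef = -1.0;
      d_o.row(p) += lam_d * dcoef * sgn;
      d_q.row(p) -= lam_d * dcoef * sgn;
      if (term_o > 0) d_o.row(p) += lam_h * (-2.0) * (o.row(p) - qt);
      if (term_q > 0) d_q.row(p) += lam_h * (-2.0) * (q.row(p) - qt);
      d_o.row(p) += lam_b * 2.0 * (mo - 0.5) / N;
      d_q.row(p) += lam_b * 2.0 * (mq - 0.5) / N;
    }
  }

  const double mld = mean(ld), mlh = mean(lh), mlb = mean(lb);
  const double mtotal = lam_d * mld + lam_h * mlh + lam_b * mlb;

  List out = List::create(
    _["ld"] = mld, _["lh"] = mlh, _["lb"] = mlb, _["total"] = mtotal,
    _["running"] = new_running);
  if (!compute_grads) return out;

  d_o /= B; d_q /= B;   // mean over pairs
  const mat dZo = d_o % o % (1.0 - o);
  const mat dZq = d_q % q % (1.0 - q);
  const mat dH = join_cols(dZo * P_ont.t(), dZq * P_que.t());
  out["grads"] = trunk_backward(tokens, dH, params, cfg, caches);
  return out;
}
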