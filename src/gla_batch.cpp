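// Batched G-L-A forward/backward pass.  Mirrors the reference R
// implementation in R/gla-batch.R one-to-one; the two are cross-checked in
// the test suite.  Subjects are stacked along the row (ROI) dimension.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat gate_act_cpp(const mat& z, int kind) {
  if (kind == 0) return clamp(z, 0.0, datum::inf); // relu
  return 1.0 / (1.0 + exp(-z));                    // sigmoid
}

static mat gate_act_deriv_cpp(const mat& z, const mat& a, int kind) {
  if (kind == 0) return conv_to<mat>::from(z > 0.0);
  return a % (1.0 - a);
}

// [[Rcpp::export(name = ".gla_batch_pass_cpp")]]
Rcpp::List gla_batch_pass_cpp(const Rcpp::List& stacks,
                              const arma::ivec& labels,
                              const arma::vec& weights,
                              const Rcpp::List& params,
                              int kind, int R, int T_n) {
  const int B = stacks.size();
  const mat W_R = Rcpp::as<mat>(params["W_R"]);
  const int d = W_R.n_cols;
  const int BR = B * R;

  const mat W_f = Rcpp::as<mat>(params["W_f"]), U_f = Rcpp::as<mat>(params["U_f"]);
  const mat W_u = Rcpp::as<mat>(params["W_u"]), U_u = Rcpp::as<mat>(params["U_u"]);
  const mat W_c = Rcpp::as<mat>(params["W_c"]), U_c = Rcpp::as<mat>(params["U_c"]);
  const mat W_o = Rcpp::as<mat>(params["W_o"]), U_o = Rcpp::as<mat>(params["U_o"]);
  const vec b_f = Rcpp::as<vec>(params["b_f"]), b_u = Rcpp::as<vec>(params["b_u"]);
  const vec b_c = Rcpp::as<vec>(params["b_c"]), b_o = Rcpp::as<vec>(params["b_o"]);
  const mat V = Rcpp::as<mat>(params["V"]);
  const vec w_att = Rcpp::as<vec>(params["w_att"]);
  const mat W_cls = Rcpp::as<mat>(params["W_cls"]);
  const vec b_cls = Rcpp::as<vec>(params["b_cls"]);
  const int a_dim = V.n_rows;

  mat W_all = join_rows(join_rows(W_f, W_u), join_rows(W_c, W_o));
  mat U_all = join_rows(join_rows(U_f, U_u), join_rows(U_c, U_o));
  rowvec b_all = join_rows(join_rows(b_f.t(), b_u.t()),
                           join_rows(b_c.t(), b_o.t()));

  // graph convolution, time-major layout with subject blocks of R rows
  cube Xtm(BR, d, T_n);
  for (int b = 0; b < B; ++b) {
    mat Xg = Rcpp::as<mat>(stacks[b]) * W_R;  // (T*R) x d
    for (int t = 0; t < T_n; ++t)
      Xtm.slice(t).rows(b * R, (b + 1) * R - 1) = Xg.rows(t * R, (t + 1) * R - 1);
  }
  cube relu_mask = conv_to<cube>::from(Xtm > 0.0);
  Xtm %= relu_mask;

  mat H(BR, d, fill::zeros), C(BR, d, fill::zeros);
  cube Zc(BR, 4 * d, T_n), Cc(BR, d, T_n), tCc(BR, d, T_n);
  cube Fc(BR, d, T_n), Uc(BR, d, T_n), Oc(BR, d, T_n), CCc(BR, d, T_n);
  cube Cprev(BR, d, T_n), Hprev(BR, d, T_n);
  cube Mts(B, d, T_n);
  for (int t = 0; t < T_n; ++t) {
    const mat X = Xtm.slice(t);
    mat Z = X * W_all + H * U_all;
    Z.each_row() += b_all;
    Zc.slice(t) = Z;
    mat f = gate_act_cpp(Z.cols(0, d - 1), kind);
    mat u = gate_act_cpp(Z.cols(d, 2 * d - 1), kind);
    mat cc = tanh(Z.cols(2 * d, 3 * d - 1));
    mat o = gate_act_cpp(Z.cols(3 * d, 4 * d - 1), kind);
    Cprev.slice(t) = C;
    Hprev.slice(t) = H;
    mat C_new = f % C + u % cc;
    mat tC = tanh(C_new);
    mat H_new = o % tC;
    Fc.slice(t) = f; Uc.slice(t) = u; Oc.slice(t) = o; CCc.slice(t) = cc;
    Cc.slice(t) = C_new; tCc.slice(t) = tC;
    for (int b = 0; b < B; ++b)
      Mts.slice(t).row(b) = mean(H_new.rows(b * R, (b + 1) * R - 1), 0);
    H = H_new; C = C_new;
  }
  if (!H.is_finite()) Rcpp::stop("non-finite LSTM state in batched pass");

  // attention
  cube Sc(B, a_dim, T_n);
  mat raw(B, T_n);
  for (int t = 0; t < T_n; ++t) {
    Sc.slice(t) = tanh(Mts.slice(t) * V.t());
    raw.col(t) = Sc.slice(t) * w_att;
  }
  vec rmax = max(raw, 1);
  mat ex = exp(raw.each_col() - rmax);
  mat alpha = ex.each_col() / sum(ex, 1);
  mat h_att(B, d, fill::zeros);
  for (int t = 0; t < T_n; ++t)
    h_att += Mts.slice(t).each_col() % alpha.col(t);
  mat logits = h_att * W_cls.t();
  logits.each_row() += b_cls.t();
  vec lmax = max(logits, 1);
  mat el = exp(logits.each_col() - lmax);
  mat P = el.each_col() / sum(el, 1);

  double w_sum = accu(weights);
  vec p_true(B);
  for (int b = 0; b < B; ++b)
    p_true(b) = std::max(P(b, labels(b)), 1e-12);
  double loss = accu(weights % (-log(p_true))) / w_sum;

  // backward
  mat onehot(B, 2, fill::zeros);
  for (int b = 0; b < B; ++b) onehot(b, labels(b)) = 1.0;
  mat dlogits = P - onehot;
  dlogits.each_col() %= (weights / w_sum);
  mat gW_cls = dlogits.t() * h_att;
  vec gb_cls = sum(dlogits, 0).t();
  mat dh_att = dlogits * W_cls;

  mat dalpha(B, T_n);
  for (int t = 0; t < T_n; ++t)
    dalpha.col(t) = sum(dh_att % Mts.slice(t), 1);
  mat draw = alpha % (dalpha.each_col() - sum(alpha % dalpha, 1));
  cube dMt(B, d, T_n);
  vec gw_att(a_dim, fill::zeros);
  mat gV(a_dim, d, fill::zeros);
  for (int t = 0; t < T_n; ++t) {
    dMt.slice(t) = dh_att.each_col() % alpha.col(t);
    gw_att += Sc.slice(t).t() * draw.col(t);
    mat dZs = (draw.col(t) * w_att.t()) % (1.0 - square(Sc.slice(t)));
    gV += dZs.t() * Mts.slice(t);
    dMt.slice(t) += dZs * V;
  }

  mat dH_next(BR, d, fill::zeros), dC_next(BR, d, fill::zeros);
  cube dXtm(BR, d, T_n);
  mat gW_all(d, 4 * d, fill::zeros), gU_all(d, 4 * d, fill::zeros);
  rowvec gb_all(4 * d, fill::zeros);
  for (int t = T_n - 1; t >= 0; --t) {
    mat dH(BR, d);
    for (int b = 0; b < B; ++b)
      dH.rows(b * R, (b + 1) * R - 1) = repmat(dMt.slice(t).row(b) / R, R, 1);
    dH += dH_next;
    const mat& tC = tCc.slice(t);
    mat do_ = dH % tC;
    mat dC = dC_next + dH % Oc.slice(t) % (1.0 - square(tC));
    mat df = dC % Cprev.slice(t);
    mat du = dC % CCc.slice(t);
    mat dcc = dC % Uc.slice(t);
    dC_next = dC % Fc.slice(t);
    const mat& Z = Zc.slice(t);
    mat dZ(BR, 4 * d);
    dZ.cols(0, d - 1) = df % gate_act_deriv_cpp(Z.cols(0, d - 1), Fc.slice(t), kind);
    dZ.cols(d, 2 * d - 1) = du % gate_act_deriv_cpp(Z.cols(d, 2 * d - 1), Uc.slice(t), kind);
    dZ.cols(2 * d, 3 * d - 1) = dcc % (1.0 - square(CCc.slice(t)));
    dZ.cols(3 * d, 4 * d - 1) = do_ % gate_act_deriv_cpp(Z.cols(3 * d, 4 * d - 1), Oc.slice(t), kind);
    const mat X = Xtm.slice(t);
    gW_all += X.t() * dZ;
    gU_all += Hprev.slice(t).t() * dZ;
    gb_all += sum(dZ, 0);
    dXtm.slice(t) = dZ * W_all.t();
    dH_next = dZ * U_all.t();
  }
  dXtm %= relu_mask;
  mat gW_R(R, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dXg(T_n * R, d);
    for (int t = 0; t < T_n; ++t)
      dXg.rows(t * R, (t + 1) * R - 1) = dXtm.slice(t).rows(b * R, (b + 1) * R - 1);
    gW_R += Rcpp::as<mat>(stacks[b]).t() * dXg;
  }

  using Rcpp::Named;
  Rcpp::List grads = Rcpp::List::create(
    Named("W_R") = gW_R,
    Named("W_f") = gW_all.cols(0, d - 1),
    Named("U_f") = gU_all.cols(0, d - 1),
    Named("b_f") = gb_all.cols(0, d - 1).t(),
    Named("W_u") = gW_all.cols(d, 2 * d - 1),
    Named("U_u") = gU_all.cols(d, 2 * d - 1),
    Named("b_u") = gb_all.cols(d, 2 * d - 1).t(),
    Named("W_c") = gW_all.cols(2 * d, 3 * d - 1),
    Named("U_c") = gU_all.cols(2 * d, 3 * d - 1),
    Named("b_c") = gb_all.cols(2 * d, 3 * d - 1).t(),
    Named("W_o") = gW_all.cols(3 * d, 4 * d - 1),
    Named("U_o") = gU_all.cols(3 * d, 4 * d - 1),
    Named("b_o") = gb_all.cols(3 * d, 4 * d - 1).t(),
    Named("V") = gV,
    Named("w_att") = gw_att,
    Named("W_cls") = gW_cls,
    Named("b_cls") = gb_cls);
  return Rcpp::List::create(Named("loss") = loss, Named("w_sum") = w_sum,
                            Named("grads") = grads, Named("prob") = P);
}
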