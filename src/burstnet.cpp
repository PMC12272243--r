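// Compiled inference cores: HMM message passing and the dynamic
// mixture-of-covariances (DyNeMo-style) variational trainer.
// All randomness is drawn from R's RNG so set.seed() controls everything.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

// ---------------------------------------------------------------------------
// HMM: scaled forward-backward and Viterbi on precomputed log-densities.
// logB: n x K log observation densities; Pi: initial; A: K x K transition.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List hmm_forward_backward(const arma::mat& logB, const arma::vec& Pi, const arma::mat& A) {
  const int n = logB.n_rows, K = logB.n_cols;
  mat alpha(n, K), beta(n, K), gamma(n, K);
  vec scale(n);
  mat B(n, K);
  // per-row max-shifted densities for numerical stability
  vec rowmax = arma::max(logB, 1);
  for (int t = 0; t < n; ++t) B.row(t) = arma::exp(logB.row(t) - rowmax(t));

  alpha.row(0) = Pi.t() % B.row(0);
  scale(0) = arma::accu(alpha.row(0));
  alpha.row(0) /= scale(0);
  for (int t = 1; t < n; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % B.row(t);
    scale(t) = arma::accu(alpha.row(t));
    alpha.row(t) /= scale(t);
  }
  beta.row(n - 1).ones();
  for (int t = n - 2; t >= 0; --t) {
    beta.row(t) = (beta.row(t + 1) % B.row(t + 1)) * A.t();
    beta.row(t) /= scale(t + 1);
  }
  gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);

  // expected transition counts, summed over time
  mat Xi(K, K, arma::fill::zeros);
  for (int t = 0; t < n - 1; ++t) {
    mat x = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % A;
    Xi += x / arma::accu(x);
  }
  double loglik = arma::accu(arma::log(scale)) + arma::accu(rowmax);
  return List::create(_["gamma"] = gamma, _["xi"] = Xi, _["loglik"] = loglik);
}

// [[Rcpp::export]]
arma::ivec hmm_viterbi(const arma::mat& logB, const arma::vec& Pi, const arma::mat& A) {
  const int n = logB.n_rows, K = logB.n_cols;
  mat logA = arma::log(A + 1e-300);
  mat delta(n, K);
  arma::imat psi(n, K);
  delta.row(0) = arma::log(Pi.t() + 1e-300) + logB.row(0);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      vec cand = delta.row(t - 1).t() + logA.col(k);
      arma::uword am = cand.index_max();
      psi(t, k) = am;
      delta(t, k) = cand(am) + logB(t, k);
    }
  }
  arma::ivec path(n);
  path(n - 1) = delta.row(n - 1).index_max();
  for (int t = n - 2; t >= 0; --t) path(t) = psi(t + 1, path(t + 1));
  return path + 1; // 1-based states
}

// ---------------------------------------------------------------------------
// DyNeMo-style model.
//
// Generative model (on blocks of `stride` consecutive samples sharing one
// mixing vector): x_t ~ N(0, Sigma_b), Sigma_b = sum_j alpha_bj D_j,
// alpha_b = softmax(theta_b), theta_b ~ N(mu_b, exp(2r)) with mu_b produced
// by a single-layer tanh RNN (the temporal prior) driven by the previous
// latent. Inference is amortised: a single-layer tanh RNN over per-block
// variance features outputs the posterior means m_b; q has global log-stds.
// Trained by one-sample reparameterised ELBO with Adam and KL annealing.
// ---------------------------------------------------------------------------

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const mat& p) { m.zeros(p.n_rows, p.n_cols); v.zeros(p.n_rows, p.n_cols); }
  void step(mat& p, const mat& g, double lr, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    mat mh = m / (1 - std::pow(b1, t));
    mat vh = v / (1 - std::pow(b2, t));
    p -= lr * mh / (arma::sqrt(vh) + eps);
  }
};

struct DynemoPars {
  int d, J, H;
  mat Wi, Ui, Wm, Wp, Up, Wq;     // RNN weights
  vec bi, bm, s, bp, bq, r;       // biases and global log-stds
  std::vector<mat> L;             // Cholesky-like factors of mode covariances
  // diag of L stored as log via lpar: L(i,i) = exp(Lraw(i,i))
  std::vector<mat> Lraw;
  void build_L() {
    for (int j = 0; j < J; ++j) {
      L[j] = arma::trimatl(Lraw[j]);
      for (int i = 0; i < d; ++i) L[j](i, i) = std::exp(Lraw[j](i, i));
    }
  }
  mat Dj(int j) const { return L[j] * L[j].t(); }
};

static double rnorm1() { return norm_rand(); }

static mat rnorm_mat(int r, int c, double sd) {
  mat x(r, c);
  for (arma::uword i = 0; i < x.n_elem; ++i) x(i) = rnorm1() * sd;
  return x;
}

static void init_pars(DynemoPars& P, const mat& Y, int J, int H, int d) {
  P.d = d; P.J = J; P.H = H;
  double si = 1.0 / std::sqrt((double)d), sh = 1.0 / std::sqrt((double)H),
         sj = 1.0 / std::sqrt((double)J);
  P.Wi = rnorm_mat(H, d, si); P.Ui = rnorm_mat(H, H, sh);
  P.Wm = rnorm_mat(J, H, sh);
  P.Wp = rnorm_mat(H, J, sj); P.Up = rnorm_mat(H, H, sh);
  P.Wq = rnorm_mat(J, H, sh);
  P.bi.zeros(H); P.bm.zeros(J); P.bp.zeros(H); P.bq.zeros(J);
  P.s = vec(J, arma::fill::value(std::log(0.1)));
  P.r = vec(J, arma::fill::value(std::log(0.2)));
  P.L.resize(J); P.Lraw.resize(J);
  // mode covariances initialised from random contiguous data segments:
  // different segments carry different burst content, breaking symmetry
  int n = Y.n_rows;
  int seg = std::min(n, 2000);
  for (int j = 0; j < J; ++j) {
    int start = (int)std::floor(unif_rand() * (n - seg));
    mat C = arma::cov(Y.rows(start, start + seg - 1));
    C.diag() += 1e-3 * arma::mean(C.diag());
    mat Lc = arma::chol(C, "lower");
    P.Lraw[j] = Lc;
    for (int i = 0; i < d; ++i) P.Lraw[j](i, i) = std::log(Lc(i, i));
  }
  P.build_L();
}

struct Grads {
  mat Wi, Ui, Wm, Wp, Up, Wq;
  vec bi, bm, s, bp, bq, r;
  std::vector<mat> Lraw;
  void zero(const DynemoPars& P) {
    Wi.zeros(arma::size(P.Wi)); Ui.zeros(arma::size(P.Ui));
    Wm.zeros(arma::size(P.Wm)); Wp.zeros(arma::size(P.Wp));
    Up.zeros(arma::size(P.Up)); Wq.zeros(arma::size(P.Wq));
    bi.zeros(P.H); bm.zeros(P.J); s.zeros(P.J);
    bp.zeros(P.H); bq.zeros(P.J); r.zeros(P.J);
    Lraw.resize(P.J);
    for (int j = 0; j < P.J; ++j) Lraw[j].zeros(P.d, P.d);
  }
};

// Forward + backward over one sequence of blocks; accumulates gradients.
// Returns (nll + beta*kl) summed over the sequence (unnormalised).
// If `sample` is false the posterior mean is used (deterministic eval) and
// G may be null.
static double seq_pass(const DynemoPars& P, const mat& Y, const mat& U,
                       int b0, int B, int stride, double beta,
                       Grads* G, bool sample,
                       std::vector<mat>* Dcache) {
  const int d = P.d, J = P.J, H = P.H;
  const int n = Y.n_rows;
  mat h(H, B), g(H, B), m(J, B), mu(J, B), th(J, B), eps(J, B), alpha(J, B);
  vec hprev(H, arma::fill::zeros), gprev(H, arma::fill::zeros),
      thprev(J, arma::fill::zeros);
  vec es = arma::exp(P.s), e2r = arma::exp(2.0 * P.r);

  // caches for gradient
  std::vector<mat> dSig(G ? B : 0);

  double nll = 0.0, kl = 0.0;
  for (int b = 0; b < B; ++b) {
    int t0 = (b0 + b) * stride;
    int c = std::min(stride, n - t0);
    // inference RNN
    vec a_i = P.Wi * U.col(b0 + b) + P.Ui * hprev + P.bi;
    h.col(b) = arma::tanh(a_i);
    m.col(b) = P.Wm * h.col(b) + P.bm;
    // prior RNN driven by previous latent sample
    vec a_p = P.Wp * thprev + P.Up * gprev + P.bp;
    g.col(b) = arma::tanh(a_p);
    mu.col(b) = P.Wq * g.col(b) + P.bq;
    // latent
    if (sample) for (int j = 0; j < J; ++j) eps(j, b) = rnorm1();
    else eps.col(b).zeros();
    th.col(b) = m.col(b) + es % eps.col(b);
    vec am = th.col(b) - th.col(b).max();
    vec ea = arma::exp(am);
    alpha.col(b) = ea / arma::accu(ea);
    // likelihood on the block
    mat Sig(d, d, arma::fill::zeros);
    for (int j = 0; j < J; ++j) Sig += alpha(j, b) * (*Dcache)[j];
    mat Lc;
    bool ok = arma::chol(Lc, Sig, "lower");
    if (!ok) { Sig.diag() += 1e-6 * arma::mean(Sig.diag()); ok = arma::chol(Lc, Sig, "lower"); }
    if (!ok) stop("covariance not positive definite during training");
    double logdet = 2.0 * arma::accu(arma::log(Lc.diag()));
    mat Xb = Y.rows(t0, t0 + c - 1);             // c x d
    mat Z1 = arma::solve(arma::trimatl(Lc), Xb.t()); // d x c
    double quad = arma::accu(Z1 % Z1);
    nll += 0.5 * (c * d * std::log(2.0 * M_PI) + c * logdet + quad);
    // KL(q||p) with diagonal Gaussians
    vec dm = m.col(b) - mu.col(b);
    kl += arma::accu(P.r - P.s + (arma::exp(2.0 * P.s) + dm % dm) / (2.0 * e2r) - 0.5);
    if (G) {
      // d(nll)/d(Sigma) = 0.5 * (c * Sigma^-1 - Sigma^-1 S Sigma^-1)
      mat Li = arma::inv(arma::trimatl(Lc));
      mat Sinv = Li.t() * Li;
      mat Z = Li.t() * Z1;                        // Sigma^-1 X^T, d x c
      dSig[b] = 0.5 * (c * Sinv - Z * Z.t());
    }
    hprev = h.col(b); gprev = g.col(b); thprev = th.col(b);
  }
  if (!G) return nll + beta * kl;

  // backward
  vec dh_carry(H, arma::fill::zeros), dg_carry(H, arma::fill::zeros);
  vec dth_next(J, arma::fill::zeros); // dL/dtheta_{b} contribution from prior at b+1
  for (int b = B - 1; b >= 0; --b) {
    vec dalpha(J);
    for (int j = 0; j < J; ++j) {
      dalpha(j) = arma::accu(dSig[b] % (*Dcache)[j]);
      G->Lraw[j] += alpha(j, b) * dSig[b]; // temporarily store dD in Lraw
    }
    // softmax backprop
    vec a = alpha.col(b);
    vec dth = a % (dalpha - arma::dot(a, dalpha));
    dth += dth_next; // prior-chain contribution from block b+1
    vec dmv = dth; // theta = m + e^s eps
    G->s += dth % eps.col(b) % es;
    // KL terms
    vec dm = m.col(b) - mu.col(b);
    dmv += beta * dm / e2r;
    vec dmu = -beta * dm / e2r;
    G->s += beta * (arma::exp(2.0 * P.s) / e2r - 1.0);
    G->r += beta * (1.0 - (arma::exp(2.0 * P.s) + dm % dm) / e2r);
    // prior RNN backward (mu_b = Wq g_b + bq)
    G->Wq += dmu * g.col(b).t();
    G->bq += dmu;
    vec dg = P.Wq.t() * dmu + dg_carry;
    vec da_p = dg % (1.0 - g.col(b) % g.col(b));
    vec thprev_b = (b > 0) ? vec(th.col(b - 1)) : vec(J, arma::fill::zeros);
    G->Wp += da_p * thprev_b.t();
    G->bp += da_p;
    vec gprev_b = (b > 0) ? vec(g.col(b - 1)) : vec(H, arma::fill::zeros);
    G->Up += da_p * gprev_b.t();
    dg_carry = P.Up.t() * da_p;
    dth_next = P.Wp.t() * da_p; // flows to theta_{b-1}
    // inference RNN backward (m_b = Wm h_b + bm)
    G->Wm += dmv * h.col(b).t();
    G->bm += dmv;
    vec dh = P.Wm.t() * dmv + dh_carry;
    vec da_i = dh % (1.0 - h.col(b) % h.col(b));
    G->Wi += da_i * U.col(b0 + b).t();
    G->bi += da_i;
    vec hprev_b = (b > 0) ? vec(h.col(b - 1)) : vec(H, arma::fill::zeros);
    G->Ui += da_i * hprev_b.t();
    dh_carry = P.Ui.t() * da_i;
  }
  return nll + beta * kl;
}

// convert accumulated dD (stored in G.Lraw) into gradients w.r.t. Lraw
static void chain_chol(const DynemoPars& P, Grads& G) {
  for (int j = 0; j < P.J; ++j) {
    mat dD = G.Lraw[j];
    mat dL = (dD + dD.t()) * P.L[j];
    dL = arma::trimatl(dL);
    for (int i = 0; i < P.d; ++i) dL(i, i) *= P.L[j](i, i); // log-diag param
    G.Lraw[j] = dL;
  }
}

static List pars_to_list(const DynemoPars& P) {
  List Lst(P.J);
  for (int j = 0; j < P.J; ++j) Lst[j] = P.Dj(j);
  return List::create(
    _["Wi"] = P.Wi, _["Ui"] = P.Ui, _["bi"] = P.bi, _["Wm"] = P.Wm,
    _["bm"] = P.bm, _["s"] = P.s, _["Wp"] = P.Wp, _["Up"] = P.Up,
    _["bp"] = P.bp, _["Wq"] = P.Wq, _["bq"] = P.bq, _["r"] = P.r,
    _["mode_covariances"] = Lst);
}

// deterministic full-data forward pass: returns list(alpha (n_blocks x J),
// logits m, free_energy at beta = 1)
static List infer_pass(const DynemoPars& P, const mat& Y, const mat& U,
                       int stride, std::vector<mat>& Dc) {
  int nb = U.n_cols;
  double fe = seq_pass(P, Y, U, 0, nb, stride, 1.0, nullptr, false, &Dc);
  // recompute alpha from a plain forward (seq_pass discards it)
  mat alpha(nb, P.J), mlog(nb, P.J);
  vec hprev(P.H, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    vec h = arma::tanh(P.Wi * U.col(b) + P.Ui * hprev + P.bi);
    vec m = P.Wm * h + P.bm;
    vec ea = arma::exp(m - m.max());
    alpha.row(b) = (ea / arma::accu(ea)).t();
    mlog.row(b) = m.t();
    hprev = h;
  }
  return List::create(_["alpha"] = alpha, _["logits"] = mlog,
                      _["free_energy"] = fe);
}

static void pars_from_list(DynemoPars& P, const List& lst, int J, int H, int d) {
  P.d = d; P.J = J; P.H = H;
  P.Wi = as<mat>(lst["Wi"]); P.Ui = as<mat>(lst["Ui"]);
  P.bi = as<vec>(lst["bi"]); P.Wm = as<mat>(lst["Wm"]);
  P.bm = as<vec>(lst["bm"]); P.s = as<vec>(lst["s"]);
  P.Wp = as<mat>(lst["Wp"]); P.Up = as<mat>(lst["Up"]);
  P.bp = as<vec>(lst["bp"]); P.Wq = as<mat>(lst["Wq"]);
  P.bq = as<vec>(lst["bq"]); P.r = as<vec>(lst["r"]);
  List Dl = lst["mode_covariances"];
  P.L.resize(J); P.Lraw.resize(J);
  for (int j = 0; j < J; ++j) {
    mat D = as<mat>(Dl[j]);
    D.diag() += 1e-8 * arma::mean(D.diag());
    mat Lc = arma::chol(D, "lower");
    P.Lraw[j] = Lc;
    for (int i = 0; i < d; ++i) P.Lraw[j](i, i) = std::log(Lc(i, i));
  }
  P.build_L();
}

// [[Rcpp::export]]
List dynemo_core(const arma::mat& Y, int J, int H, int stride, int seq_blocks,
                 int batch_size, int n_epochs, double lr,
                 double anneal_frac, double data_frac, bool track_history,
                 Nullable<List> init = R_NilValue) {
  RNGScope scope;
  const int n = Y.n_rows, d = Y.n_cols;
  const int nb = n / stride; // complete blocks only
  if (nb < 2 * seq_blocks) stop("too few blocks for the sequence length");

  // per-block log-variance features, standardised across blocks
  mat U(d, nb);
  for (int b = 0; b < nb; ++b) {
    mat Xb = Y.rows(b * stride, (b + 1) * stride - 1);
    U.col(b) = arma::log(arma::mean(Xb % Xb, 0).t() + 1e-8);
  }
  vec um = arma::mean(U, 1), us = arma::stddev(U, 0, 1);
  U.each_col() -= um;
  U.each_col() /= (us + 1e-12);

  DynemoPars P;
  if (init.isNotNull()) pars_from_list(P, List(init), J, H, d);
  else init_pars(P, Y, J, H, d);
  Grads G;
  Adam aWi, aUi, abi, aWm, abm, as, aWp, aUp, abp, aWq, abq, ar;
  std::vector<Adam> aL(J);
  aWi.init(P.Wi); aUi.init(P.Ui); abi.init(mat(P.bi)); aWm.init(P.Wm);
  abm.init(mat(P.bm)); as.init(mat(P.s)); aWp.init(P.Wp); aUp.init(P.Up);
  abp.init(mat(P.bp)); aWq.init(P.Wq); abq.init(mat(P.bq)); ar.init(mat(P.r));
  for (int j = 0; j < J; ++j) aL[j].init(P.Lraw[j]);

  int n_seq = nb / seq_blocks;
  int seq_per_epoch = std::max(batch_size, (int)std::round(data_frac * n_seq));
  int n_updates_per_epoch = std::max(1, seq_per_epoch / batch_size);
  int total_updates = n_epochs * n_updates_per_epoch;
  int anneal_updates = std::max(1, (int)std::round(anneal_frac * total_updates));

  std::vector<double> history;
  int t_adam = 0;
  for (int ep = 0; ep < n_epochs; ++ep) {
    // sample sequence order via R RNG
    uvec order(n_seq);
    for (int i = 0; i < n_seq; ++i) order(i) = i;
    for (int i = n_seq - 1; i > 0; --i) {
      int k = (int)std::floor(unif_rand() * (i + 1));
      std::swap(order(i), order(k));
    }
    double ep_loss = 0.0; long ep_samples = 0;
    for (int u = 0; u < n_updates_per_epoch; ++u) {
      double beta = std::min(1.0, (double)(t_adam + 1) / anneal_updates);
      G.zero(P);
      P.build_L();
      std::vector<mat> Dc(J);
      for (int j = 0; j < J; ++j) Dc[j] = P.Dj(j);
      double loss = 0.0; long nsamp = 0;
      for (int i = 0; i < batch_size; ++i) {
        int sidx = order((u * batch_size + i) % n_seq);
        loss += seq_pass(P, Y, U, sidx * seq_blocks, seq_blocks, stride,
                         beta, &G, true, &Dc);
        nsamp += seq_blocks * stride;
      }
      chain_chol(P, G);
      double inv = 1.0 / nsamp;
      ep_loss += loss; ep_samples += nsamp;
      ++t_adam;
      mat bi_m(G.bi), bm_m(G.bm), s_m(G.s), bp_m(G.bp), bq_m(G.bq), r_m(G.r);
      mat pbi(P.bi), pbm(P.bm), ps(P.s), pbp(P.bp), pbq(P.bq), pr(P.r);
      aWi.step(P.Wi, G.Wi * inv, lr, t_adam);
      aUi.step(P.Ui, G.Ui * inv, lr, t_adam);
      abi.step(pbi, bi_m * inv, lr, t_adam); P.bi = pbi.col(0);
      aWm.step(P.Wm, G.Wm * inv, lr, t_adam);
      abm.step(pbm, bm_m * inv, lr, t_adam); P.bm = pbm.col(0);
      as.step(ps, s_m * inv, lr, t_adam); P.s = ps.col(0);
      aWp.step(P.Wp, G.Wp * inv, lr, t_adam);
      aUp.step(P.Up, G.Up * inv, lr, t_adam);
      abp.step(pbp, bp_m * inv, lr, t_adam); P.bp = pbp.col(0);
      aWq.step(P.Wq, G.Wq * inv, lr, t_adam);
      abq.step(pbq, bq_m * inv, lr, t_adam); P.bq = pbq.col(0);
      ar.step(pr, r_m * inv, lr, t_adam); P.r = pr.col(0);
      for (int j = 0; j < J; ++j) aL[j].step(P.Lraw[j], G.Lraw[j] * inv, lr, t_adam);
      // keep q/prior log-stds in a sane range
      P.s = arma::clamp(P.s, std::log(1e-3), std::log(10.0));
      P.r = arma::clamp(P.r, std::log(1e-3), std::log(10.0));
    }
    if (!std::isfinite(ep_loss))
      stop("non-finite training objective at epoch %d", ep + 1);
    if (track_history) history.push_back(ep_loss / ep_samples);
    Rcpp::checkUserInterrupt();
  }
  P.build_L();
  std::vector<mat> Dc(J);
  for (int j = 0; j < J; ++j) Dc[j] = P.Dj(j);
  List inf = infer_pass(P, Y, U, stride, Dc);
  double fe = Rcpp::as<double>(inf["free_energy"]) / (double)(nb * stride);
  return List::create(
    _["params"] = pars_to_list(P),
    _["alpha_blocks"] = inf["alpha"],
    _["logits"] = inf["logits"],
    _["free_energy"] = fe,
    _["loss_history"] = history,
    _["stride"] = stride,
    _["n_blocks"] = nb);
}

// ---------------------------------------------------------------------------
// multivariate normal log-densities for the HMM E-step:
// Y (n x d), covariances as a list; returns n x K log densities (zero mean).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat mvn_logdens(const arma::mat& Y, const List& covs) {
  const int n = Y.n_rows, d = Y.n_cols, K = covs.size();
  mat out(n, K);
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    mat S = as<mat>(covs[k]);
    mat Lc = arma::chol(S, "lower");
    double logdet = 2.0 * arma::accu(arma::log(Lc.diag()));
    mat Z = arma::solve(arma::trimatl(Lc), Y.t()); // d x n
    out.col(k) = (c0 - 0.5 * logdet) - 0.5 * arma::sum(Z % Z, 0).t();
  }
  return out;
}
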