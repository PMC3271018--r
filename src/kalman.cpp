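// Kalman forward-backward smoothing for the bilinear latent state-space model
//
// State:       s(t) = sum_j v_j(t) C_j s(t-1) + D u(t) + w(t),  w ~ N(0, diag(q))
// Observation: y_m(t) = h_m' x_m(t) + e_m(t),                   e ~ N(0, diag(r))
// with x_m(t) = (s_m(t), s_m(t-1), ..., s_m(t-L+1)) the lag-embedded latent
// signal and h_m the region's HRF over L lags.
//
// The filter runs on the augmented state z(t) = (s(t), s(t-1), ..., s(t-L+1))
// of dimension p = M*L; the transition exploits the shift structure so the
// predict step is O(p^2 M) rather than O(p^3). Buffers are preallocated and
// reused across time steps (the routine is called thousands of times per
// model fit, so constant factors matter).
//
// Returns the exact marginal log-likelihood (prediction-error decomposition)
// and the expected sufficient statistics needed by the EM M-step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List kalman_smooth_stats(const arma::mat& y,   // T x M observed series
                               const arma::mat& u,   // T x M external inputs
                               const arma::mat& v,   // T x J modulatory inputs
                               const arma::cube& C,  // M x M x J couplings, C(m,n,j) = n -> m
                               const arma::vec& d,   // length M, diag of D
                               const arma::mat& h,   // M x L HRF kernels (row m)
                               const arma::vec& q,   // M state noise variances
                               const arma::vec& r,   // M observation noise variances
                               const double sigma0,  // prior variance of z(1)
                               const bool want_stats = true) {
  const uword T = y.n_rows;
  const uword M = y.n_cols;
  const uword L = h.n_cols;
  const uword J = v.n_cols;
  const uword p = M * L;
  const uword pm = p - M;

  // observation matrix: row m has h(m, l) at column m + M*l
  mat H(M, p, fill::zeros);
  for (uword m = 0; m < M; ++m)
    for (uword l = 0; l < L; ++l)
      H(m, m + M * l) = h(m, l);

  const double log2pi = std::log(2.0 * M_PI);

  mat mf(p, T), mp(p, T);
  cube Pf(p, p, T), Pp(p, p, T);
  cube At(M, M, T, fill::zeros);
  double loglik = 0.0;

  // preallocated work buffers
  mat P_pred(p, p), Pu(p, p), PHt(p, M), S(M, M), Sc(M, M), K(p, M);
  mat topM(M, p), KS(p, M);
  vec m_pred(p), innov(M), tmpM(M);

  for (uword t = 0; t < T; ++t) {
    if (t == 0) {
      m_pred.zeros();
      P_pred.zeros();
      P_pred.diag().fill(sigma0);
    } else {
      const double* mprev = mf.colptr(t - 1);
      mat A(M, M, fill::zeros);
      for (uword j = 0; j < J; ++j) {
        double vj = v(t, j);
        if (vj != 0.0) A += vj * C.slice(j);
      }
      At.slice(t) = A;
      m_pred.head(M) = A * mf.col(t - 1).head(M) + d % u.row(t).t();
      std::memcpy(m_pred.memptr() + M, mprev, pm * sizeof(double));

      // P_pred = F P F' + Q_aug with F = [[A, 0], [I, 0]]
      const mat& Pprev = Pf.slice(t - 1);
      topM = A * Pprev.rows(0, M - 1);  // M x p
      P_pred.submat(0, 0, M - 1, M - 1) = topM.cols(0, M - 1) * A.t();
      P_pred.submat(0, 0, M - 1, M - 1).diag() += q;
      P_pred.submat(0, M, M - 1, p - 1) = topM.cols(0, pm - 1);
      P_pred.submat(M, 0, p - 1, M - 1) = P_pred.submat(0, M, M - 1, p - 1).t();
      P_pred.submat(M, M, p - 1, p - 1) = Pprev.submat(0, 0, pm - 1, pm - 1);
    }

    // measurement update
    PHt = P_pred * H.t();
    S = H * PHt;
    S.diag() += r;
    S = 0.5 * (S + S.t());
    innov = y.row(t).t() - H * m_pred;
    if (!chol(Sc, S)) {
      S.diag() += 1e-8;
      Sc = chol(S);
    }
    // K = PHt * S^{-1} via two triangular solves
    K = solve(trimatu(Sc), solve(trimatl(Sc.t()), PHt.t())).t();
    mf.col(t) = m_pred + K * innov;
    KS = K * S;
    Pu = P_pred - KS * K.t();
    Pu = 0.5 * (Pu + Pu.t());

    tmpM = solve(trimatl(Sc.t()), innov);
    loglik += -0.5 * (M * log2pi) - accu(log(Sc.diag())) -
              0.5 * dot(tmpM, tmpM);

    mp.col(t) = m_pred;
    Pp.slice(t) = P_pred;
    Pf.slice(t) = Pu;
  }

  if (!want_stats) {
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik);
  }

  // RTS smoother with EM sufficient statistics
  const uword JJ = J * J;
  cube Gvv(M, M, JJ, fill::zeros);  // sum v_j v_k E[s(t-1) s(t-1)']
  cube Gvu(M, M, J, fill::zeros);   // sum v_j E[s(t-1)] u(t,)'
  cube Gvy(M, M, J, fill::zeros);   // sum v_j E[s(t) s(t-1)']
  vec Guu(M, fill::zeros);          // sum u(t,m)^2
  vec Guy(M, fill::zeros);          // sum u(t,m) E[s_m(t)]
  mat Scur(M, M, fill::zeros);      // sum_{t>=2} E[s(t) s(t)']
  cube Gx(L, L, M, fill::zeros);    // sum_t E[x_m x_m']
  mat Gxy(L, M, fill::zeros);       // sum_t y(t,m) E[x_m]
  mat Gex(L, M, fill::zeros);       // sum_t E[x_m]
  vec Syy(M, fill::zeros);
  mat Es(T, M);                     // smoothed latent means (current block)

  // embedding index set per region
  std::vector<uvec> xidx(M);
  for (uword m = 0; m < M; ++m) {
    uvec idx(L);
    for (uword l = 0; l < L; ++l) idx(l) = m + M * l;
    xidx[m] = idx;
  }

  vec ms = mf.col(T - 1);
  mat Ps = Pf.slice(T - 1);

  // work buffers for the backward pass
  mat PfF(p, p), Jt(p, p), Pc(p, p), Czz(p, p), dP(p, p);
  vec ms_next(p), xs(L);

  auto accum_obs = [&](const vec& msm, const mat& Psm, uword t) {
    for (uword m = 0; m < M; ++m) {
      xs = msm.elem(xidx[m]);
      Gx.slice(m) += Psm.submat(xidx[m], xidx[m]) + xs * xs.t();
      Gxy.col(m) += y(t, m) * xs;
      Gex.col(m) += xs;
      Syy(m) += y(t, m) * y(t, m);
    }
    Es.row(t) = msm.head(M).t();
  };

  accum_obs(ms, Ps, T - 1);
  Scur += Ps.submat(0, 0, M - 1, M - 1) + ms.head(M) * ms.head(M).t();

  for (uword t = T - 1; t-- > 0;) {
    const mat& A1 = At.slice(t + 1);
    const mat& Pft = Pf.slice(t);
    // PfF = Pf_t * F_{t+1}' with F = [[A1, 0], [I, 0]]
    PfF.cols(0, M - 1) = Pft.cols(0, M - 1) * A1.t();
    PfF.cols(M, p - 1) = Pft.cols(0, pm - 1);
    Pc = Pp.slice(t + 1);
    Pc.diag() += 1e-12;
    if (!chol(Pc, Pc)) {
      Pc = Pp.slice(t + 1);
      Pc.diag() += 1e-8;
      Pc = chol(Pc);
    }
    // Jt = PfF * Ppred^{-1} via triangular solves
    Jt = solve(trimatu(Pc), solve(trimatl(Pc.t()), PfF.t())).t();

    ms_next = ms;
    mat Ps_next = Ps;  // copy needed for the lag-one covariance
    ms = mf.col(t) + Jt * (ms_next - mp.col(t + 1));
    dP = Ps_next - Pp.slice(t + 1);
    Ps = Pft + Jt * dP * Jt.t();
    Ps = 0.5 * (Ps + Ps.t());

    // E[z(t+1) z(t)'] = Ps_next Jt' + ms_next ms'
    Czz = Ps_next * Jt.t() + ms_next * ms.t();

    accum_obs(ms, Ps, t);
    if (t >= 1) {
      Scur += Ps.submat(0, 0, M - 1, M - 1) + ms.head(M) * ms.head(M).t();
    }

    // transition stats for the pair (t, t+1); inputs indexed at t+1
    mat Vprev = Ps.submat(0, 0, M - 1, M - 1) + ms.head(M) * ms.head(M).t();
    mat Ccur = Czz.submat(0, 0, M - 1, M - 1);  // E[s(t+1) s(t)']
    vec Esprev = ms.head(M);
    vec Escur = ms_next.head(M);
    for (uword j = 0; j < J; ++j) {
      double vj = v(t + 1, j);
      if (vj != 0.0) {
        for (uword k = 0; k < J; ++k) {
          double vk = v(t + 1, k);
          if (vk != 0.0) Gvv.slice(j * J + k) += vj * vk * Vprev;
        }
        Gvu.slice(j) += vj * Esprev * u.row(t + 1);
        Gvy.slice(j) += vj * Ccur;
      }
    }
    Guu += square(u.row(t + 1)).t();
    Guy += u.row(t + 1).t() % Escur;
  }

  return Rcpp::List::create(
      Rcpp::Named("loglik") = loglik, Rcpp::Named("Gvv") = Gvv,
      Rcpp::Named("Gvu") = Gvu, Rcpp::Named("Gvy") = Gvy,
      Rcpp::Named("Guu") = Guu, Rcpp::Named("Guy") = Guy,
      Rcpp::Named("Scur") = Scur, Rcpp::Named("Gx") = Gx,
      Rcpp::Named("Gxy") = Gxy, Rcpp::Named("Gex") = Gex,
      Rcpp::Named("Syy") = Syy,
      Rcpp::Named("Es") = Es, Rcpp::Named("T") = (int)T);
}

// Multi-subject variant: all subjects share inputs and parameters (group
// mode), so the covariance recursions (filter, smoother gain, smoothed
// covariance) are data-independent and computed ONCE, while per-subject
// mean recursions and data statistics are O(p^2) per step. This makes a
// group fit cost little more than a single-subject fit.

// [[Rcpp::export]]
Rcpp::List kalman_smooth_stats_multi(const Rcpp::List& ylist,  // S matrices T x M
                                     const arma::mat& u, const arma::mat& v,
                                     const arma::cube& C, const arma::vec& d,
                                     const arma::mat& h, const arma::vec& q,
                                     const arma::vec& r, const double sigma0) {
  const uword S = ylist.size();
  std::vector<mat> Y(S);
  for (uword s = 0; s < S; ++s) Y[s] = Rcpp::as<mat>(ylist[s]);
  const uword T = Y[0].n_rows;
  const uword M = Y[0].n_cols;
  const uword L = h.n_cols;
  const uword J = v.n_cols;
  const uword p = M * L;
  const uword pm = p - M;

  mat H(M, p, fill::zeros);
  for (uword m = 0; m < M; ++m)
    for (uword l = 0; l < L; ++l)
      H(m, m + M * l) = h(m, l);

  const double log2pi = std::log(2.0 * M_PI);

  cube Pf(p, p, T), Pp(p, p, T);
  cube Kt(p, M, T);
  cube At(M, M, T, fill::zeros);
  mat Scl(M, M);
  std::vector<mat> Schol(T);
  cube mf(p, T, S), mp(p, T, S);
  double loglik = 0.0;

  mat P_pred(p, p), Pu(p, p), PHt(p, M), Sm(M, M), K(p, M), topM(M, p),
      KS(p, M);
  vec innov(M), tmpM(M);

  for (uword t = 0; t < T; ++t) {
    if (t == 0) {
      P_pred.zeros();
      P_pred.diag().fill(sigma0);
    } else {
      mat A(M, M, fill::zeros);
      for (uword j = 0; j < J; ++j) {
        double vj = v(t, j);
        if (vj != 0.0) A += vj * C.slice(j);
      }
      At.slice(t) = A;
      const mat& Pprev = Pf.slice(t - 1);
      topM = A * Pprev.rows(0, M - 1);
      P_pred.submat(0, 0, M - 1, M - 1) = topM.cols(0, M - 1) * A.t();
      P_pred.submat(0, 0, M - 1, M - 1).diag() += q;
      P_pred.submat(0, M, M - 1, p - 1) = topM.cols(0, pm - 1);
      P_pred.submat(M, 0, p - 1, M - 1) =
          P_pred.submat(0, M, M - 1, p - 1).t();
      P_pred.submat(M, M, p - 1, p - 1) = Pprev.submat(0, 0, pm - 1, pm - 1);
    }

    PHt = P_pred * H.t();
    Sm = H * PHt;
    Sm.diag() += r;
    Sm = 0.5 * (Sm + Sm.t());
    if (!chol(Scl, Sm)) {
      Sm.diag() += 1e-8;
      Scl = chol(Sm);
    }
    K = solve(trimatu(Scl), solve(trimatl(Scl.t()), PHt.t())).t();
    KS = K * Sm;
    Pu = P_pred - KS * K.t();
    Pu = 0.5 * (Pu + Pu.t());
    Pp.slice(t) = P_pred;
    Pf.slice(t) = Pu;
    Kt.slice(t) = K;
    Schol[t] = Scl;

    const double ldet_half = accu(log(Scl.diag()));
    for (uword s = 0; s < S; ++s) {
      vec m_pred(p);
      if (t == 0) {
        m_pred.zeros();
      } else {
        const mat& A = At.slice(t);
        m_pred.head(M) =
            A * mf.slice(s).col(t - 1).head(M) + d % u.row(t).t();
        std::memcpy(m_pred.memptr() + M, mf.slice(s).colptr(t - 1),
                    pm * sizeof(double));
      }
      innov = Y[s].row(t).t() - H * m_pred;
      mf.slice(s).col(t) = m_pred + K * innov;
      mp.slice(s).col(t) = m_pred;
      tmpM = solve(trimatl(Scl.t()), innov);
      loglik += -0.5 * (M * log2pi) - ldet_half - 0.5 * dot(tmpM, tmpM);
    }
  }

  // backward pass: shared covariances, per-subject means
  const uword JJ = J * J;
  cube Gvv(M, M, JJ, fill::zeros);
  cube Gvu(M, M, J, fill::zeros);
  cube Gvy(M, M, J, fill::zeros);
  vec Guu(M, fill::zeros);
  vec Guy(M, fill::zeros);
  mat Scur(M, M, fill::zeros);
  cube Gx(L, L, M, fill::zeros);
  mat Gxy(L, M, fill::zeros);
  mat Gex(L, M, fill::zeros);
  vec Syy(M, fill::zeros);
  cube Es(T, M, S);

  std::vector<uvec> xidx(M);
  for (uword m = 0; m < M; ++m) {
    uvec idx(L);
    for (uword l = 0; l < L; ++l) idx(l) = m + M * l;
    xidx[m] = idx;
  }

  mat Ps = Pf.slice(T - 1);
  mat ms(p, S);
  for (uword s = 0; s < S; ++s) ms.col(s) = mf.slice(s).col(T - 1);

  mat PfF(p, p), Jt(p, p), Pc(p, p), dP(p, p);
  vec xs(L);

  // accumulate observation stats at time t given shared cov and means
  auto accum_obs = [&](const mat& msm, const mat& Psm, uword t) {
    for (uword m = 0; m < M; ++m) {
      mat Pxx = Psm.submat(xidx[m], xidx[m]);
      Gx.slice(m) += (double)S * Pxx;
      for (uword s = 0; s < S; ++s) {
        xs = vec(msm.col(s)).elem(xidx[m]);
        Gx.slice(m) += xs * xs.t();
        Gxy.col(m) += Y[s](t, m) * xs;
        Gex.col(m) += xs;
        Syy(m) += Y[s](t, m) * Y[s](t, m);
      }
    }
    for (uword s = 0; s < S; ++s) Es.slice(s).row(t) = msm.col(s).head(M).t();
  };

  accum_obs(ms, Ps, T - 1);
  Scur += (double)S * Ps.submat(0, 0, M - 1, M - 1);
  for (uword s = 0; s < S; ++s)
    Scur += ms.col(s).head(M) * ms.col(s).head(M).t();

  for (uword t = T - 1; t-- > 0;) {
    const mat& A1 = At.slice(t + 1);
    const mat& Pft = Pf.slice(t);
    PfF.cols(0, M - 1) = Pft.cols(0, M - 1) * A1.t();
    PfF.cols(M, p - 1) = Pft.cols(0, pm - 1);
    Pc = Pp.slice(t + 1);
    Pc.diag() += 1e-12;
    if (!chol(Pc, Pc)) {
      Pc = Pp.slice(t + 1);
      Pc.diag() += 1e-8;
      Pc = chol(Pc);
    }
    Jt = solve(trimatu(Pc), solve(trimatl(Pc.t()), PfF.t())).t();

    mat ms_next = ms;
    mat Ps_next = Ps;
    for (uword s = 0; s < S; ++s) {
      ms.col(s) = mf.slice(s).col(t) +
                  Jt * (ms_next.col(s) - mp.slice(s).col(t + 1));
    }
    dP = Ps_next - Pp.slice(t + 1);
    Ps = Pft + Jt * dP * Jt.t();
    Ps = 0.5 * (Ps + Ps.t());

    // shared covariance part of E[z(t+1) z(t)']
    mat Czz_cov = Ps_next * Jt.t();

    accum_obs(ms, Ps, t);
    if (t >= 1) {
      Scur += (double)S * Ps.submat(0, 0, M - 1, M - 1);
      for (uword s = 0; s < S; ++s)
        Scur += ms.col(s).head(M) * ms.col(s).head(M).t();
    }

    mat Vprev = (double)S * Ps.submat(0, 0, M - 1, M - 1);
    mat Ccur = (double)S * Czz_cov.submat(0, 0, M - 1, M - 1);
    vec Esprev(M, fill::zeros), Escur(M, fill::zeros);
    for (uword s = 0; s < S; ++s) {
      Vprev += ms.col(s).head(M) * ms.col(s).head(M).t();
      Ccur += ms_next.col(s).head(M) * ms.col(s).head(M).t();
      Esprev += ms.col(s).head(M);
      Escur += ms_next.col(s).head(M);
    }
    for (uword j = 0; j < J; ++j) {
      double vj = v(t + 1, j);
      if (vj != 0.0) {
        for (uword k = 0; k < J; ++k) {
          double vk = v(t + 1, k);
          if (vk != 0.0) Gvv.slice(j * J + k) += vj * vk * Vprev;
        }
        Gvu.slice(j) += vj * Esprev * u.row(t + 1);
        Gvy.slice(j) += vj * Ccur;
      }
    }
    Guu += (double)S * square(u.row(t + 1)).t();
    Guy += u.row(t + 1).t() % Escur;
  }

  return Rcpp::List::create(
      Rcpp::Named("loglik") = loglik, Rcpp::Named("Gvv") = Gvv,
      Rcpp::Named("Gvu") = Gvu, Rcpp::Named("Gvy") = Gvy,
      Rcpp::Named("Guu") = Guu, Rcpp::Named("Guy") = Guy,
      Rcpp::Named("Scur") = Scur, Rcpp::Named("Gx") = Gx,
      Rcpp::Named("Gxy") = Gxy, Rcpp::Named("Gex") = Gex,
      Rcpp::Named("Syy") = Syy, Rcpp::Named("T") = (int)T,
      Rcpp::Named("S") = (int)S);
}
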