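#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian dynamics core in (quaternion, z) coordinates.
//
// The inner loop mirrors the R-level euler_step()/rk_step() reference
// implementations exactly and draws its Gaussian increments from R's RNG
// (norm_rand), so a trajectory produced here is bit-identical to one
// stepped in R under the same seed.  D is configuration-independent;
// Dsqrt is its (lower) Cholesky factor, computed once by the caller.

static inline void bmul(const double *Q, const double *w, double *out) {
  // out(4) = b(Q) * w(3), b(Q) = 1/2 [[-Q1,-Q2,-Q3],[Q0,-Q3,Q2],
  //                                   [Q3,Q0,-Q1],[-Q2,Q1,Q0]]
  out[0] = 0.5 * (-Q[1] * w[0] - Q[2] * w[1] - Q[3] * w[2]);
  out[1] = 0.5 * (Q[0] * w[0] - Q[3] * w[1] + Q[2] * w[2]);
  out[2] = 0.5 * (Q[3] * w[0] + Q[0] * w[1] - Q[1] * w[2]);
  out[3] = 0.5 * (-Q[2] * w[0] + Q[1] * w[1] + Q[0] * w[2]);
}

static inline double renorm(const double *Qp, double *Qt) {
  // solve lambda^2 + 2 lambda (Qp.Qt) + |Qt|^2 = 1, root nearest +1,
  // overwrite Qt with Qt + lambda * Qp; returns lambda
  double p = 0.0, s = 0.0;
  for (int i = 0; i < 4; ++i) { p += Qp[i] * Qt[i]; s += Qt[i] * Qt[i]; }
  double disc = p * p - s + 1.0;
  if (disc < 0.0)
    stop("step-size error: quaternion renormalization failed; reduce dt");
  double lambda = -p + std::sqrt(disc);
  for (int i = 0; i < 4; ++i) Qt[i] += lambda * Qp[i];
  return lambda;
}

// [[Rcpp::export]]
List bd_core(NumericMatrix D, NumericMatrix Dsqrt, NumericVector Q0,
             NumericVector z0, double dt, int n_steps, int stride,
             bool runge_kutta) {
  const int m = D.nrow();       // 3 + ns
  const int ns = m - 3;
  const int ndump = n_steps / stride + 1;

  std::vector<double> Q(Q0.begin(), Q0.end());
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> n(m), u(m), d1(m), d2(m), gz(m);
  std::vector<double> bq1(4), bq2(4), Qt(4), Qv(4);

  NumericVector times(ndump);
  NumericMatrix Qout(ndump, 4), zout(ndump, ns);
  int idump = 0;
  times[0] = 0.0;
  for (int i = 0; i < 4; ++i) Qout(0, i) = Q[i];
  for (int i = 0; i < ns; ++i) zout(0, i) = z[i];
  idump = 1;

  const double sq2dt = std::sqrt(2.0 * dt);

  for (int step = 1; step <= n_steps; ++step) {
    // noise and its coloured projection u = Dsqrt * n
    for (int i = 0; i < m; ++i) n[i] = norm_rand();
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j <= i; ++j) acc += Dsqrt(i, j) * n[j];  // lower tri
      u[i] = acc;
    }
    // drift vector D * (0,0,0,z)
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < ns; ++j) acc += D(i, 3 + j) * z[j];
      d1[i] = acc;
    }

    if (!runge_kutta) {
      // Euler: incr = -dt W(Q) d1 + sq2dt W(Q) u
      for (int i = 0; i < m; ++i) gz[i] = -dt * d1[i] + sq2dt * u[i];
      bmul(Q.data(), gz.data(), bq1.data());
      for (int i = 0; i < 4; ++i) Qt[i] = bq1[i];
      renorm(Q.data(), Qt.data());
      for (int i = 0; i < 4; ++i) Q[i] = Qt[i];
      for (int j = 0; j < ns; ++j) z[j] += gz[3 + j];
    } else {
      // virtual Euler point (same noise), renormalized
      for (int i = 0; i < m; ++i) gz[i] = -dt * d1[i] + sq2dt * u[i];
      bmul(Q.data(), gz.data(), bq1.data());
      for (int i = 0; i < 4; ++i) Qv[i] = bq1[i];
      renorm(Q.data(), Qv.data());
      std::vector<double> ze(ns);
      for (int j = 0; j < ns; ++j) ze[j] = z[j] + gz[3 + j];
      // drift at the virtual point
      for (int i = 0; i < m; ++i) {
        double acc = 0.0;
        for (int j = 0; j < ns; ++j) acc += D(i, 3 + j) * ze[j];
        d2[i] = acc;
      }
      // averaged increment
      // rotational rows: -dt/2 (b(Q) w1 + b(Qv) w2) + sq2dt/2 (b(Q)+b(Qv)) u
      double w1[3], w2[3], un[3];
      for (int i = 0; i < 3; ++i) { w1[i] = d1[i]; w2[i] = d2[i]; un[i] = u[i]; }
      double t1[4], t2[4], t3[4], t4[4];
      bmul(Q.data(), w1, t1);
      bmul(Qv.data(), w2, t2);
      bmul(Q.data(), un, t3);
      bmul(Qv.data(), un, t4);
      for (int i = 0; i < 4; ++i)
        Qt[i] = -0.5 * dt * (t1[i] + t2[i]) + 0.5 * sq2dt * (t3[i] + t4[i]);
      renorm(Q.data(), Qt.data());
      for (int i = 0; i < 4; ++i) Q[i] = Qt[i];
      for (int j = 0; j < ns; ++j)
        z[j] += -0.5 * dt * (d1[3 + j] + d2[3 + j]) + sq2dt * u[3 + j];
    }

    for (int j = 0; j < ns; ++j)
      if (std::abs(z[j]) > 10.0)
        stop("instability: |z| exceeded 10 standard deviations; reduce dt");

    if (step % stride == 0 && idump < ndump) {
      times[idump] = step * dt;
      for (int i = 0; i < 4; ++i) Qout(idump, i) = Q[i];
      for (int i = 0; i < ns; ++i) zout(idump, i) = z[i];
      ++idump;
    }
  }

  return List::create(_["times"] = times, _["Q"] = Qout, _["z"] = zout);
}
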