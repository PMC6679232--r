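#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Quaternion convention: q = (w, x, y, z), unit norm, rotating sensor-frame
// vectors into the NED frame: v_ned = R(q) v_sensor.  At rest the
// accelerometer measures the gravity reaction along NED Down projected into
// the sensor frame, i.e. a_hat = R(q)^T e_down.

static inline void quat_mult(const double* a, const double* b, double* out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void quat_normalize(double* q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  if (n > 0.0) { q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n; }
}

// Exact incremental rotation for a body rate held constant over dt:
// q <- q (x) exp([0, w dt / 2]).  Using the quaternion exponential keeps the
// beta = 0 path identical to closed-form axis-angle integration.
static inline void gyro_advance(const double* q, const double* w, double dt,
                                double* out) {
  double h[3] = { 0.5*w[0]*dt, 0.5*w[1]*dt, 0.5*w[2]*dt };
  double th = std::sqrt(h[0]*h[0] + h[1]*h[1] + h[2]*h[2]);
  double e[4];
  if (th < 1e-12) {
    e[0] = 1.0; e[1] = h[0]; e[2] = h[1]; e[3] = h[2];
  } else {
    double s = std::sin(th) / th;
    e[0] = std::cos(th); e[1] = h[0]*s; e[2] = h[1]*s; e[3] = h[2]*s;
  }
  quat_mult(q, e, out);
  quat_normalize(out);
}

// One gradient-descent fusion step.  Returns false when accel or mag had zero
// norm and the step fell back to gyroscope-only integration.
static bool fusion_step(const double* q_prev, const double* acc,
                        const double* gyr, const double* mag,
                        double dt, double beta, double* q_out) {
  double qg[4];
  gyro_advance(q_prev, gyr, dt, qg);

  double na = std::sqrt(acc[0]*acc[0] + acc[1]*acc[1] + acc[2]*acc[2]);
  double nm = std::sqrt(mag[0]*mag[0] + mag[1]*mag[1] + mag[2]*mag[2]);
  if (na < 1e-12 || nm < 1e-12 || beta == 0.0) {
    q_out[0] = qg[0]; q_out[1] = qg[1]; q_out[2] = qg[2]; q_out[3] = qg[3];
    return !(na < 1e-12 || nm < 1e-12);
  }

  double ax = acc[0]/na, ay = acc[1]/na, az = acc[2]/na;
  double mx = mag[0]/nm, my = mag[1]/nm, mz = mag[2]/nm;

  const double w = q_prev[0], x = q_prev[1], y = q_prev[2], z = q_prev[3];

  // Gravity objective: R(q)^T e_down - a_hat.
  double f1 = 2.0*(x*z - w*y)       - ax;
  double f2 = 2.0*(y*z + w*x)       - ay;
  double f3 = 1.0 - 2.0*(x*x + y*y) - az;

  double gw = -2.0*y*f1 + 2.0*x*f2;
  double gx =  2.0*z*f1 + 2.0*w*f2 - 4.0*x*f3;
  double gy = -2.0*w*f1 + 2.0*z*f2 - 4.0*y*f3;
  double gz =  2.0*x*f1 + 2.0*y*f2;

  // Magnetic objective with the reference field recomputed from the current
  // estimate: h = R(q) m_hat, b = (|h_xy|, 0, h_z) in NED.
  double mq[4] = {0.0, mx, my, mz};
  double tmp[4], hq[4];
  double qc[4] = { w, -x, -y, -z };
  quat_mult(q_prev, mq, tmp);
  quat_mult(tmp, qc, hq);
  double bx = std::sqrt(hq[1]*hq[1] + hq[2]*hq[2]);
  double bz = hq[3];

  double mp1 = bx*(1.0 - 2.0*(y*y + z*z)) + 2.0*bz*(x*z - w*y);
  double mp2 = 2.0*bx*(x*y - w*z)         + 2.0*bz*(y*z + w*x);
  double mp3 = 2.0*bx*(x*z + w*y)         + bz*(1.0 - 2.0*(x*x + y*y));
  double f4 = mp1 - mx, f5 = mp2 - my, f6 = mp3 - mz;

  gw += (-2.0*bz*y)*f4 + (-2.0*bx*z + 2.0*bz*x)*f5 + (2.0*bx*y)*f6;
  gx += ( 2.0*bz*z)*f4 + ( 2.0*bx*y + 2.0*bz*w)*f5 + (2.0*bx*z - 4.0*bz*x)*f6;
  gy += (-4.0*bx*y - 2.0*bz*w)*f4 + (2.0*bx*x + 2.0*bz*z)*f5 +
        ( 2.0*bx*w - 4.0*bz*y)*f6;
  gz += (-4.0*bx*z + 2.0*bz*x)*f4 + (-2.0*bx*w + 2.0*bz*y)*f5 +
        ( 2.0*bx*x)*f6;

  double gn = std::sqrt(gw*gw + gx*gx + gy*gy + gz*gz);
  if (gn > 1e-12) {
    double s = beta * dt / gn;
    qg[0] -= s*gw; qg[1] -= s*gx; qg[2] -= s*gy; qg[3] -= s*gz;
    quat_normalize(qg);
  }
  q_out[0] = qg[0]; q_out[1] = qg[1]; q_out[2] = qg[2]; q_out[3] = qg[3];
  return true;
}

// [[Rcpp::export]]
NumericVector madgwick_step_cpp(NumericVector q, NumericVector acc,
                                NumericVector gyr, NumericVector mag,
                                double dt, double beta) {
  double out[4];
  bool ok = fusion_step(REAL(q), REAL(acc), REAL(gyr), REAL(mag),
                        dt, beta, out);
  NumericVector res(4);
  for (int i = 0; i < 4; ++i) res[i] = out[i];
  res.attr("fallback") = !ok;
  return res;
}

// [[Rcpp::export]]
List madgwick_fuse_cpp(NumericVector t, NumericMatrix acc, NumericMatrix gyr,
                       NumericMatrix mag, NumericVector q0, double beta,
                       double beta_init, double warmup_s) {
  int n = t.size();
  NumericMatrix q(n, 4);
  LogicalVector fallback(n);
  if (n == 0) return List::create(_["q"] = q, _["fallback"] = fallback);

  double cur[4] = { q0[0], q0[1], q0[2], q0[3] };
  quat_normalize(cur);
  for (int j = 0; j < 4; ++j) q(0, j) = cur[j];
  fallback[0] = false;

  for (int i = 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    if (dt <= 0.0) stop("timestamps must be strictly increasing (row %d)", i + 1);
    double b = (t[i] - t[0] < warmup_s) ? beta_init : beta;
    double a[3] = { acc(i,0), acc(i,1), acc(i,2) };
    double g[3] = { gyr(i,0), gyr(i,1), gyr(i,2) };
    double m[3] = { mag(i,0), mag(i,1), mag(i,2) };
    double nxt[4];
    bool ok = fusion_step(cur, a, g, m, dt, b, nxt);
    fallback[i] = !ok;
    for (int j = 0; j < 4; ++j) { q(i, j) = nxt[j]; cur[j] = nxt[j]; }
  }
  return List::create(_["q"] = q, _["fallback"] = fallback);
}
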