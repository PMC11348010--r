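#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, ch. 5). Returns closest point; bary receives barycentrics.
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1; bary[1] = 0; bary[2] = 0; return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0; bary[1] = 1; bary[2] = 0; return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0; return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0; bary[1] = 0; bary[2] = 1; return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// For each row of P find the closest surface point on the triangle mesh
// (V, F).  F is 1-based.  Returns an n x 9 matrix:
// [x, y, z, face, dist, b1, b2, b3, vert_of_max_bary]
// [[Rcpp::export]]
NumericMatrix cpp_nearest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericMatrix out(np, 9);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int q = 0; q < np; ++q) {
    double p[3] = { P(q, 0), P(q, 1), P(q, 2) };
    double best = R_PosInf, bq[3] = {0, 0, 0}, bbary[3] = {1, 0, 0};
    int bface = -1;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = { V(ia,0), V(ia,1), V(ia,2) };
      double b[3] = { V(ib,0), V(ib,1), V(ib,2) };
      double c[3] = { V(ic,0), V(ic,1), V(ic,2) };
      double cp[3], bary[3];
      closest_on_tri(p, a, b, c, cp, bary);
      double dx = p[0]-cp[0], dy = p[1]-cp[1], dz = p[2]-cp[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) {
        best = d2; bface = f;
        for (int i = 0; i < 3; ++i) { bq[i] = cp[i]; bbary[i] = bary[i]; }
      }
    }
    int kmax = 0;
    if (bbary[1] > bbary[kmax]) kmax = 1;
    if (bbary[2] > bbary[kmax]) kmax = 2;
    out(q, 0) = bq[0]; out(q, 1) = bq[1]; out(q, 2) = bq[2];
    out(q, 3) = bface + 1; out(q, 4) = std::sqrt(best);
    out(q, 5) = bbary[0]; out(q, 6) = bbary[1]; out(q, 7) = bbary[2];
    out(q, 8) = F(bface, kmax);
  }
  return out;
}

// Iterative gravity + spring relaxation used to flatten a curved panel.
// One outer iteration = one normalized gravity step (largest vertex
// displacement capped at gravity_step, all others scaled proportionally),
// then `substeps` damped Hookean spring steps over the mesh edges, then
// re-imposition of each probe-node's three fixed distances to its 10-5
// partner vertices (Gauss-Newton trilateration).  Terminates when
// max |z| <= z_tol.  E is 1-based m x 2; couplings cp_* may have 0 rows.
// [[Rcpp::export]]
List cpp_flatten_relax(NumericMatrix V0, IntegerMatrix E, NumericVector rest,
                       NumericVector ew,
                       IntegerMatrix Fc, NumericVector face_rest_area,
                       IntegerVector cp_node, IntegerMatrix cp_partner,
                       NumericMatrix cp_dist,
                       double gravity_step, double spring_cap, double damping,
                       int substeps, double z_tol, int max_iters,
                       int spring_mode, int polish_iters, double polish_tol) {
  // spring_mode: 0 = full-3D spring forces, 1 = planar (X-Y only),
  // 2 = hybrid: 3D while gravity makes progress, then planar
  int n = V0.nrow(), m = E.nrow(), nc = cp_node.size(), nf = Fc.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = V0(i,0); Y[i] = V0(i,1); Z[i] = V0(i,2); }
  std::vector<int> ei(m), ej(m);
  for (int e = 0; e < m; ++e) { ei[e] = E(e,0) - 1; ej[e] = E(e,1) - 1; }
  std::vector<double> FX(n), FY(n), FZ(n);
  std::vector<int> fa_(nf), fb_(nf), fc_(nf);
  for (int f = 0; f < nf; ++f) {
    fa_[f] = Fc(f,0) - 1; fb_[f] = Fc(f,1) - 1; fc_[f] = Fc(f,2) - 1;
  }
  // anti-inversion pass: Newton step on the 2D signed area of any
  // triangle inverted w.r.t. the majority orientation, so in-plane
  // buckling is ironed out as it appears instead of folding over.
  // Vertices in `frozen` (coupling nodes in the final phase) absorb no
  // correction; their share goes to the other triangle vertices.
  std::vector<bool> frozen(n, false);
  auto unflip_pass = [&]() {
    if (nf == 0) return;
    double possum = 0;
    for (int f = 0; f < nf; ++f) {
      double ax = X[fa_[f]], ay = Y[fa_[f]];
      double A2 = (X[fb_[f]]-ax)*(Y[fc_[f]]-ay) - (X[fc_[f]]-ax)*(Y[fb_[f]]-ay);
      possum += (A2 > 0) ? 1 : -1;
    }
    double orient = (possum >= 0) ? 1.0 : -1.0;
    for (int f = 0; f < nf; ++f) {
      if (face_rest_area[f] <= 0) continue;  // slivers exempt
      int a = fa_[f], b = fb_[f], c = fc_[f];
      double A2 = (X[b]-X[a])*(Y[c]-Y[a]) - (X[c]-X[a])*(Y[b]-Y[a]);
      double As = orient * A2 / 2.0;
      double target = 0.05 * face_rest_area[f];
      if (As >= target) continue;
      // gradients of signed area (majority orientation) per vertex
      double gax = orient * (Y[b]-Y[c]) / 2.0, gay = orient * (X[c]-X[b]) / 2.0;
      double gbx = orient * (Y[c]-Y[a]) / 2.0, gby = orient * (X[a]-X[c]) / 2.0;
      double gcx = orient * (Y[a]-Y[b]) / 2.0, gcy = orient * (X[b]-X[a]) / 2.0;
      if (frozen[a]) { gax = 0; gay = 0; }
      if (frozen[b]) { gbx = 0; gby = 0; }
      if (frozen[c]) { gcx = 0; gcy = 0; }
      double g2 = gax*gax+gay*gay+gbx*gbx+gby*gby+gcx*gcx+gcy*gcy;
      if (g2 < 1e-18) continue;
      double step = (target - As) / g2;
      double cap = 0.2;  // mm, keep the correction local
      double mx = std::sqrt(std::max({gax*gax+gay*gay, gbx*gbx+gby*gby,
                                      gcx*gcx+gcy*gcy})) * std::fabs(step);
      if (mx > cap) step *= cap / mx;
      X[a] += step*gax; Y[a] += step*gay;
      X[b] += step*gbx; Y[b] += step*gby;
      X[c] += step*gcx; Y[c] += step*gcy;
    }
  };
  std::vector<double> hist_maxz; hist_maxz.reserve(1024);
  double max_gravity_disp = 0.0;
  bool converged = false;
  bool planar = (spring_mode == 1);
  double stall_ref = R_PosInf;
  int stall_check = 0;
  int it = 0;
  for (it = 0; it < max_iters; ++it) {
    // (1) normalized gravity toward the z = 0 plane
    double maxz = 0.0;
    for (int i = 0; i < n; ++i) { double a = std::fabs(Z[i]); if (a > maxz) maxz = a; }
    if (maxz > 0) {
      double s = gravity_step / maxz;
      if (s > 1.0) s = 1.0;
      for (int i = 0; i < n; ++i) Z[i] -= s * Z[i];
      double g = s * maxz;
      if (g > max_gravity_disp) max_gravity_disp = g;
    }
    // (2) damped spring steps toward per-edge 3D rest lengths
    for (int ss = 0; ss < substeps; ++ss) {
      std::fill(FX.begin(), FX.end(), 0.0);
      std::fill(FY.begin(), FY.end(), 0.0);
      std::fill(FZ.begin(), FZ.end(), 0.0);
      for (int e = 0; e < m; ++e) {
        int a = ei[e], b = ej[e];
        double dx = X[b]-X[a], dy = Y[b]-Y[a], dz = Z[b]-Z[a];
        double len = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (len < 1e-12) continue;
        double f = ew[e] * (len - rest[e]) / len;
        FX[a] += f*dx; FY[a] += f*dy; FZ[a] += f*dz;
        FX[b] -= f*dx; FY[b] -= f*dy; FZ[b] -= f*dz;
      }
      for (int i = 0; i < n; ++i) {
        double dx = damping*FX[i], dy = damping*FY[i];
        double dz = planar ? 0.0 : damping*FZ[i];
        double nrm = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (nrm > spring_cap) { double s = spring_cap/nrm; dx *= s; dy *= s; dz *= s; }
        X[i] += dx; Y[i] += dy; Z[i] += dz;
      }
    }
    unflip_pass();
    double mz = 0.0;
    for (int i = 0; i < n; ++i) { double a = std::fabs(Z[i]); if (a > mz) mz = a; }
    hist_maxz.push_back(mz);
    if (mz <= z_tol) { converged = true; ++it; break; }
    if (spring_mode == 2 && !planar && ++stall_check >= 100) {
      // switch to planar springs once 3D descent stops making progress
      if (stall_ref - mz < 1.0) planar = true;
      stall_ref = mz;
      stall_check = 0;
    }
  }
  // in-plane polish: continue spring relaxation with Z frozen until the
  // spring displacements die out (does not affect the Z criterion)
  int polish_done = 0;
  double obj_prev = -1.0;
  if (converged) {
    std::vector<double> deg(n, 0.0);
    for (int e = 0; e < m; ++e) { deg[ei[e]] += ew[e]; deg[ej[e]] += ew[e]; }
    for (int i = 0; i < n; ++i) if (deg[i] < 1) deg[i] = 1;
    // global anisotropic rescale: Gauss-Newton on (sx, sy) minimizing
    // sum_e (|s .* d_e| - rest_e)^2; removes the low-frequency
    // compression that pointwise relaxation removes only slowly
    auto rescale = [&]() {
      double sx = 1.0, sy = 1.0;
      double cx = 0.0, cy = 0.0;
      for (int i = 0; i < n; ++i) { cx += X[i]; cy += Y[i]; }
      cx /= n; cy /= n;
      for (int gn = 0; gn < 8; ++gn) {
        double h11 = 0, h12 = 0, h22 = 0, g1 = 0, g2 = 0;
        for (int e = 0; e < m; ++e) {
          double dx = X[ej[e]]-X[ei[e]], dy = Y[ej[e]]-Y[ei[e]];
          double dz = Z[ej[e]]-Z[ei[e]];
          double lx = sx*dx, ly = sy*dy;
          double len = std::sqrt(lx*lx + ly*ly + dz*dz);
          if (len < 1e-12) continue;
          double r = len - rest[e];
          double j1 = sx*dx*dx/len, j2 = sy*dy*dy/len;
          h11 += j1*j1; h12 += j1*j2; h22 += j2*j2;
          g1 += j1*r; g2 += j2*r;
        }
        h11 += 1e-12; h22 += 1e-12;
        double det = h11*h22 - h12*h12;
        if (std::fabs(det) < 1e-24) break;
        sx -= ( h22*g1 - h12*g2) / det;
        sy -= (-h12*g1 + h11*g2) / det;
      }
      if (sx > 0.5 && sx < 2.0 && sy > 0.5 && sy < 2.0) {
        for (int i = 0; i < n; ++i) {
          X[i] = cx + sx*(X[i]-cx);
          Y[i] = cy + sy*(Y[i]-cy);
        }
      }
    };
    for (int pp = 0; pp < polish_iters; ++pp) {
      if (pp % 500 == 0) rescale();
      std::fill(FX.begin(), FX.end(), 0.0);
      std::fill(FY.begin(), FY.end(), 0.0);
      for (int e = 0; e < m; ++e) {
        int a = ei[e], b = ej[e];
        double dx = X[b]-X[a], dy = Y[b]-Y[a], dz = Z[b]-Z[a];
        double len = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (len < 1e-12) continue;
        double f = ew[e] * (len - rest[e]) / len;
        FX[a] += f*dx; FY[a] += f*dy;
        FX[b] -= f*dx; FY[b] -= f*dy;
      }
      double maxdisp = 0.0;
      for (int i = 0; i < n; ++i) {
        // degree-normalized Jacobi step (stable without a hard cap)
        double dx = 0.8*FX[i]/deg[i], dy = 0.8*FY[i]/deg[i];
        double nrm = std::sqrt(dx*dx + dy*dy);
        if (nrm > 1.0) { double s = 1.0/nrm; dx *= s; dy *= s; }
        X[i] += dx; Y[i] += dy;
        if (nrm > maxdisp) maxdisp = nrm;
      }
      unflip_pass();
      ++polish_done;
      if (maxdisp < polish_tol) break;
      if (polish_done % 256 == 0) {
        // objective-based early exit: total squared strain no longer improving
        double obj = 0;
        for (int e = 0; e < m; ++e) {
          double dx = X[ej[e]]-X[ei[e]], dy = Y[ej[e]]-Y[ei[e]], dz = Z[ej[e]]-Z[ei[e]];
          double r = std::sqrt(dx*dx + dy*dy + dz*dz) - rest[e];
          obj += r*r;
        }
        if (obj_prev >= 0 && obj > obj_prev * (1.0 - 1e-5)) break;
        obj_prev = obj;
      }
    }
  }
  // final exact re-imposition of the couplings: 2D trust-region
  // Gauss-Newton trilateration from the three partner vertices, each
  // round followed by a short spring relaxation with the coupling
  // nodes pinned so the surrounding membrane accommodates without
  // folding
  if (converged && nc > 0) {
    std::vector<bool> pinned(n, false);
    for (int c = 0; c < nc; ++c) pinned[cp_node[c] - 1] = true;
    frozen = pinned;
    std::vector<double> deg2(n, 0.0);
    for (int e = 0; e < m; ++e) { deg2[ei[e]] += ew[e]; deg2[ej[e]] += ew[e]; }
    for (int i = 0; i < n; ++i) if (deg2[i] < 1) deg2[i] = 1;
    auto pinned_polish = [&](int iters) {
      for (int pp = 0; pp < iters; ++pp) {
        std::fill(FX.begin(), FX.end(), 0.0);
        std::fill(FY.begin(), FY.end(), 0.0);
        for (int e = 0; e < m; ++e) {
          int a = ei[e], b = ej[e];
          double dx = X[b]-X[a], dy = Y[b]-Y[a], dz = Z[b]-Z[a];
          double len = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (len < 1e-12) continue;
          double f = ew[e] * (len - rest[e]) / len;
          FX[a] += f*dx; FY[a] += f*dy;
          FX[b] -= f*dx; FY[b] -= f*dy;
        }
        double maxdisp = 0.0;
        for (int i = 0; i < n; ++i) {
          if (pinned[i]) continue;
          double dx = 0.8*FX[i]/deg2[i], dy = 0.8*FY[i]/deg2[i];
          double nrm = std::sqrt(dx*dx + dy*dy);
          if (nrm > 1.0) { double sc = 1.0/nrm; dx *= sc; dy *= sc; }
          X[i] += dx; Y[i] += dy;
          if (nrm > maxdisp) maxdisp = nrm;
        }
        unflip_pass();
        if (maxdisp < polish_tol) break;
      }
    };
    for (int rounds = 0; rounds < 40; ++rounds) {
      double worst = 0;
      for (int c = 0; c < nc; ++c) {
        int v = cp_node[c] - 1;
        double px = X[v], py = Y[v];
        auto ssr2 = [&](double qx, double qy) {
          double s_ = 0;
          for (int k = 0; k < 3; ++k) {
            int w = cp_partner(c, k) - 1;
            double dx = qx - X[w], dy = qy - Y[w], dz = Z[v] - Z[w];
            double r = std::sqrt(dx*dx + dy*dy + dz*dz) - cp_dist(c, k);
            s_ += r*r;
          }
          return s_;
        };
        for (int gn = 0; gn < 24; ++gn) {
          // least-squares first, then approximate-minimax (p = 8)
          double pw = (gn < 8) ? 2.0 : 8.0;
          double JtJ[4] = {0,0,0,0}, Jtr[2] = {0,0};
          for (int k = 0; k < 3; ++k) {
            int w = cp_partner(c, k) - 1;
            double dx = px - X[w], dy = py - Y[w], dz = Z[v] - Z[w];
            double len = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (len < 1e-9) continue;
            double r = len - cp_dist(c, k);
            double wk = (pw > 2.0) ? std::pow(std::fabs(r) + 1e-9, pw - 2.0) : 1.0;
            double jx = dx/len, jy = dy/len;
            JtJ[0] += wk*jx*jx; JtJ[1] += wk*jx*jy; JtJ[3] += wk*jy*jy;
            Jtr[0] += wk*jx*r; Jtr[1] += wk*jy*r;
          }
          JtJ[2] = JtJ[1];
          JtJ[0] += 1e-9; JtJ[3] += 1e-9;
          double det = JtJ[0]*JtJ[3] - JtJ[1]*JtJ[2];
          if (std::fabs(det) < 1e-18) break;
          double sx = ( JtJ[3]*Jtr[0] - JtJ[1]*Jtr[1]) / det;
          double sy = (-JtJ[2]*Jtr[0] + JtJ[0]*Jtr[1]) / det;
          auto obj = [&](double qx, double qy) {
            double s_ = 0;
            for (int k = 0; k < 3; ++k) {
              int w = cp_partner(c, k) - 1;
              double dx = qx - X[w], dy = qy - Y[w], dz = Z[v] - Z[w];
              double r = std::sqrt(dx*dx + dy*dy + dz*dz) - cp_dist(c, k);
              s_ += std::pow(std::fabs(r), pw);
            }
            return s_;
          };
          double cur = obj(px, py);
          double sc = 1.0;
          int tries = 0;
          while (tries < 6 && obj(px - sc*sx, py - sc*sy) > cur) { sc *= 0.5; ++tries; }
          if (tries >= 6) { if (gn < 8) gn = 7; continue; }
          px -= sc*sx; py -= sc*sy;
        }
        double mv = std::sqrt((px-X[v])*(px-X[v]) + (py-Y[v])*(py-Y[v]));
        if (mv > worst) worst = mv;
        X[v] = px; Y[v] = py;
      }
      pinned_polish(800);
      if (worst < 1e-6) break;
    }
  }
  NumericMatrix Vout(n, 3);
  for (int i = 0; i < n; ++i) { Vout(i,0) = X[i]; Vout(i,1) = Y[i]; Vout(i,2) = Z[i]; }
  return List::create(_["vertices"] = Vout,
                      _["iterations"] = it,
                      _["polish_iterations"] = polish_done,
                      _["converged"] = converged,
                      _["max_gravity_disp"] = max_gravity_disp,
                      _["maxz_history"] = NumericVector(hist_maxz.begin(), hist_maxz.end()));
}
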