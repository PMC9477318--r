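// Discrete quasistatic elastica for a tapered, intrinsically curved whisker.
//
// The whisker centreline is a chain of rigid links joined by elastic joints.
// Joint j at node j (j = 0 .. N-2) carries bending stiffness EI_j/ds_j about
// the two local normals and torsional stiffness GJ_j/ds_j about the local
// tangent; joint 0 connects the clamp frame to the first link with half-link
// weight (trapezoidal end correction).  A single frictionless point load
// applied at material coordinate s_c deflects the chain; the internal moment
// at joint j is (p_c - p_j) x f, which sets the elastic rotation there.  The
// deflected shape is the fixed point of this moment/shape relation, and the
// contact problem solves (f_n1, f_n2, s_c) - the force in the plane normal to
// the contact tangent plus the contact arc length - so the material point s_c
// lands on the target.  Failure to converge is reported as slip.
//
// Units: mm, uN, uN*mm, uN/mm^2 throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

arma::mat33 expmap(const arma::vec3& w) {
  double th = arma::norm(w);
  arma::mat33 I(arma::fill::eye);
  if (th < 1e-14) return I;
  arma::vec3 a = w / th;
  arma::mat33 K = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// minimal rotation taking unit vector u onto unit vector v
arma::mat33 rot_between(const arma::vec3& u, const arma::vec3& v) {
  arma::vec3 ax = arma::cross(u, v);
  double s = arma::norm(ax), c = arma::dot(u, v);
  arma::mat33 I(arma::fill::eye);
  if (s < 1e-14) {
    if (c > 0) return I;
    arma::vec3 p = std::fabs(u(0)) < 0.9 ? arma::vec3{1, 0, 0} : arma::vec3{0, 1, 0};
    arma::vec3 n = arma::normalise(arma::cross(u, p));
    return expmap(M_PI * n);
  }
  return expmap(std::atan2(s, c) * arma::normalise(ax));
}

struct Rod {
  int N;                 // nodes
  mat P0;                // N x 3 undeflected nodes
  vec llen;              // N-1 link lengths
  vec snode;             // N cumulative arc lengths (material coordinate)
  arma::cube A0;         // intrinsic joint rotations, (3,3,N-1); joint j at node j
  arma::mat33 F0;        // clamp frame at the base
  vec kb, kt;            // joint stiffnesses (N-1): EI/ds, GJ/ds
};

Rod build_rod(const mat& nodes, const vec& EI, const vec& GJ) {
  Rod r;
  r.N = nodes.n_rows;
  r.P0 = nodes;
  int N = r.N;
  r.llen.set_size(N - 1);
  r.snode.set_size(N);
  r.snode(0) = 0.0;
  mat T(N - 1, 3);
  for (int j = 0; j < N - 1; ++j) {
    arma::rowvec3 d = nodes.row(j + 1) - nodes.row(j);
    r.llen(j) = arma::norm(d);
    r.snode(j + 1) = r.snode(j) + r.llen(j);
    T.row(j) = d / r.llen(j);
  }
  arma::vec3 t0 = T.row(0).t();
  arma::vec3 ref = std::fabs(t0(2)) < 0.9 ? arma::vec3{0, 0, 1} : arma::vec3{0, 1, 0};
  arma::vec3 n1 = arma::normalise(arma::cross(ref, t0));
  arma::vec3 n2 = arma::cross(t0, n1);
  r.F0.col(0) = t0; r.F0.col(1) = n1; r.F0.col(2) = n2;
  r.A0.set_size(3, 3, N - 1);
  r.A0.slice(0) = arma::mat33(arma::fill::eye);  // clamp -> link 0
  arma::mat33 Fprev = r.F0;
  for (int j = 1; j <= N - 2; ++j) {
    arma::vec3 tp = T.row(j - 1).t(), tc = T.row(j).t();
    arma::mat33 Fj = rot_between(tp, tc) * Fprev;
    r.A0.slice(j) = Fprev.t() * Fj;
    Fprev = Fj;
  }
  r.kb.set_size(N - 1);
  r.kt.set_size(N - 1);
  for (int j = 0; j <= N - 2; ++j) {
    double ds = (j == 0) ? 0.5 * r.llen(0)
                         : 0.5 * (r.llen(j - 1) + r.llen(j));
    r.kb(j) = EI(j) / ds;
    r.kt(j) = GJ(j) / ds;
  }
  return r;
}

// material coordinate -> link index and fraction
inline void locate(const Rod& rod, double sc, int& k, double& a) {
  int N = rod.N;
  if (sc <= 0) { k = 0; a = 0; return; }
  if (sc >= rod.snode(N - 1)) { k = N - 2; a = 1.0; return; }
  k = std::upper_bound(rod.snode.begin(), rod.snode.end(), sc) -
      rod.snode.begin() - 1;
  if (k > N - 2) k = N - 2;
  a = (sc - rod.snode(k)) / rod.llen(k);
}

// Deflected shape under point load f at material coordinate sc.
//
// Within one forward pass the joint rotations are fully determined by the
// contact position pc (moments (pc - p_j) x f, positions built in-pass), so
// the equilibrium shape is the fixed point of a 3-variable map
// pc -> forward(pc).  That map is solved by a damped Newton iteration with a
// finite-difference Jacobian, which remains convergent at large deflections
// where plain successive substitution oscillates.
struct PassOut { mat P; mat tlink; arma::vec3 pc; };

PassOut forward_pass(const Rod& rod, int k, double a, const arma::vec3& pc_in,
                     const arma::vec3& f, bool loaded) {
  int N = rod.N;
  PassOut o;
  o.P.set_size(N, 3);
  o.tlink.set_size(N - 1, 3);
  o.P.row(0) = rod.P0.row(0);
  arma::mat33 G = rod.F0;
  for (int j = 0; j <= N - 2; ++j) {
    arma::vec3 th(arma::fill::zeros);
    if (loaded && j <= k) {
      arma::vec3 pj = o.P.row(j).t();
      arma::vec3 m = G.t() * arma::cross(pc_in - pj, f);
      th(0) = m(0) / rod.kt(j);
      th(1) = m(1) / rod.kb(j);
      th(2) = m(2) / rod.kb(j);
    }
    G = G * expmap(th) * rod.A0.slice(j);
    o.tlink.row(j) = G.col(0).t();
    o.P.row(j + 1) = o.P.row(j) + (rod.llen(j) * G.col(0)).t();
  }
  o.pc = (1 - a) * o.P.row(k).t() + a * o.P.row(k + 1).t();
  return o;
}

bool relax_shape(const Rod& rod, double sc, const arma::vec3& f,
                 arma::vec3& pc_state, mat& P, mat& tlink, arma::vec3& pc,
                 int max_iter, double tol) {
  int k; double a;
  locate(rod, sc, k, a);
  bool loaded = arma::norm(f) > 0;
  arma::vec3 p0c = (1 - a) * rod.P0.row(k).t() + a * rod.P0.row(k + 1).t();
  arma::vec3 x = pc_state.is_finite() && arma::norm(pc_state) > 0 ? pc_state : p0c;
  if (!loaded) {
    PassOut o = forward_pass(rod, k, a, x, f, false);
    P = o.P; tlink = o.tlink; pc = o.pc; pc_state = o.pc;
    return true;
  }
  PassOut o = forward_pass(rod, k, a, x, f, true);
  double gn = arma::norm(o.pc - x);
  for (int iter = 0; iter < max_iter; ++iter) {
    if (!o.pc.is_finite()) return false;
    if (gn < tol) {
      P = o.P; tlink = o.tlink; pc = o.pc; pc_state = o.pc;
      return true;
    }
    // finite-difference Jacobian of g(x) = forward(x) - x
    double h = 1e-6;
    arma::mat33 J;
    for (int d = 0; d < 3; ++d) {
      arma::vec3 xd = x;
      xd(d) += h;
      PassOut od = forward_pass(rod, k, a, xd, f, true);
      if (!od.pc.is_finite()) return false;
      J.col(d) = (od.pc - xd - (o.pc - x)) / h;
    }
    arma::vec3 dx;
    if (!arma::solve(dx, J, -(o.pc - x))) return false;
    double lam = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 10; ++ls) {
      arma::vec3 xn = x + lam * dx;
      PassOut on = forward_pass(rod, k, a, xn, f, true);
      double gnn = arma::norm(on.pc - xn);
      if (on.pc.is_finite() && gnn < gn * 0.9999) {
        x = xn; o = on; gn = gnn; ok = true;
        break;
      }
      lam *= 0.5;
    }
    if (!ok) return false;
  }
  return false;
}

struct ContactResult {
  bool converged = false;
  std::string reason = "no_convergence";
  arma::vec3 f{arma::fill::zeros};
  arma::vec3 pc{arma::fill::zeros};
  arma::vec3 tc{arma::fill::zeros};
  double sc = -1;
  mat P;
  int iterations = 0;
};

// Newton solve for (force in the contact normal plane, contact arc length)
// such that the material point s_c reaches the target.
ContactResult solve_contact(const Rod& rod, const arma::vec3& target,
                            arma::vec3 f, double sc, arma::vec3& pc_state,
                            double tol_pos, int max_outer, int max_inner,
                            double tol_inner, double s_min) {
  ContactResult res;
  int N = rod.N;
  double L = rod.snode(N - 1);
  if (sc < 0) {
    // seed from the nearest undeflected node
    double d0 = arma::datum::inf;
    for (int j = 0; j < N; ++j) {
      double d = arma::norm(rod.P0.row(j).t() - target);
      if (d < d0) { d0 = d; sc = rod.snode(j); }
    }
  }
  sc = std::min(std::max(sc, s_min), L);
  mat P, tlink;
  arma::vec3 pc;
  if (!relax_shape(rod, sc, f, pc_state, P, tlink, pc, max_inner, tol_inner)) {
    res.reason = "inner_divergence";
    return res;
  }
  auto link_tangent = [&](double s) {
    int k; double a;
    locate(rod, s, k, a);
    return arma::vec3(tlink.row(k).t());
  };
  for (int outer = 0; outer < max_outer; ++outer) {
    res.iterations = outer + 1;
    arma::vec3 R = pc - target;
    if (arma::norm(R) < tol_pos) {
      // polish the frictionless constraint against the final tangent
      for (int kk = 0; kk < 8; ++kk) {
        arma::vec3 tcn = link_tangent(sc);
        double ft = arma::dot(f, tcn);
        if (std::fabs(ft) <= 1e-10 * (1.0 + arma::norm(f))) break;
        f -= ft * tcn;
        relax_shape(rod, sc, f, pc_state, P, tlink, pc, max_inner, tol_inner);
      }
      res.converged = true;
      res.reason = "converged";
      res.f = f; res.pc = pc; res.tc = link_tangent(sc);
      res.sc = sc; res.P = P;
      return res;
    }
    arma::vec3 t = link_tangent(sc);
    arma::vec3 ref = std::fabs(t(2)) < 0.9 ? arma::vec3{0, 0, 1} : arma::vec3{0, 1, 0};
    arma::vec3 n1 = arma::normalise(arma::cross(ref, t));
    arma::vec3 n2 = arma::cross(t, n1);
    // finite-difference Jacobian of pc w.r.t. (f_n1, f_n2, sc)
    double hf = 1e-3 * (1.0 + arma::norm(f));
    double hs = 0.25 * rod.llen(0);
    arma::mat33 J;
    bool jac_ok = true;
    for (int d = 0; d < 3; ++d) {
      arma::vec3 fd = f;
      double sd = sc;
      double h;
      if (d < 2) { fd += hf * (d == 0 ? n1 : n2); h = hf; }
      else {
        h = (sc + hs <= L) ? hs : -hs;
        sd = sc + h;
      }
      mat Pd, td;
      arma::vec3 pcs = pc_state, pcd;
      if (!relax_shape(rod, sd, fd, pcs, Pd, td, pcd, max_inner, tol_inner)) {
        jac_ok = false;
        break;
      }
      J.col(d) = (pcd - pc) / h;
    }
    if (!jac_ok || std::fabs(arma::det(J)) < 1e-14) {
      res.reason = "singular_jacobian";
      return res;
    }
    arma::vec3 dlt;
    if (!arma::solve(dlt, J, -R)) { res.reason = "singular_jacobian"; return res; }
    // damped line search on |R|
    double rn0 = arma::norm(R), lam = 1.0;
    bool accepted = false;
    for (int ls = 0; ls < 8; ++ls) {
      arma::vec3 fn = f + lam * (dlt(0) * n1 + dlt(1) * n2);
      double sn = std::min(std::max(sc + lam * dlt(2), s_min), L);
      arma::vec3 tn = link_tangent(sn);
      fn -= arma::dot(fn, tn) * tn;  // frictionless w.r.t. current shape
      mat Pn2, tln;
      arma::vec3 pcs = pc_state, pcn;
      if (relax_shape(rod, sn, fn, pcs, Pn2, tln, pcn, max_inner, tol_inner)) {
        double rnn = arma::norm(pcn - target);
        if (rnn < rn0 * 0.999 || lam < 0.15) {
          f = fn; sc = sn; pc_state = pcs; P = Pn2; tlink = tln; pc = pcn;
          accepted = true;
          break;
        }
      }
      lam *= 0.5;
    }
    if (!accepted) { res.reason = "line_search_failure"; return res; }
  }
  res.reason = "no_convergence";
  return res;
}

List contact_to_list(const ContactResult& r, const Rod& rod) {
  int ci = NA_INTEGER;
  if (r.converged) {
    int k; double a;
    locate(rod, r.sc, k, a);
    ci = (a < 0.5 ? k : k + 1) + 1;  // nearest node, 1-based
  }
  return List::create(
    _["converged"] = r.converged,
    _["reason"] = r.reason,
    _["force"] = NumericVector::create(r.f(0), r.f(1), r.f(2)),
    _["contact"] = NumericVector::create(r.pc(0), r.pc(1), r.pc(2)),
    _["tangent"] = NumericVector::create(r.tc(0), r.tc(1), r.tc(2)),
    _["s_c"] = r.sc,
    _["nodes"] = r.converged ? wrap(r.P) : R_NilValue,
    _["contact_index"] = ci,
    _["iterations"] = r.iterations);
}

arma::vec3 sph_of(const arma::vec3& p) {
  double rr = arma::norm(p);
  return {rr, std::atan2(p(1), p(0)), std::asin(p(2) / rr)};
}
arma::vec3 cart_of(const arma::vec3& s) {
  return {s(0) * std::cos(s(2)) * std::cos(s(1)),
          s(0) * std::cos(s(2)) * std::sin(s(1)),
          s(0) * std::sin(s(2))};
}

}  // namespace

// [[Rcpp::export]]
List cpp_deflect_force(const arma::mat& nodes, const arma::vec& EI,
                       const arma::vec& GJ, int node_index, const arma::vec& f,
                       int max_inner = 800, double tol_inner = 1e-10) {
  Rod rod = build_rod(nodes, EI, GJ);
  mat P, tlink;
  arma::vec3 pc, pc_state(arma::fill::zeros);
  double sc = rod.snode(node_index - 1);
  bool ok = relax_shape(rod, sc, arma::vec3(f.head(3)), pc_state, P, tlink, pc,
                        max_inner, tol_inner);
  return List::create(_["converged"] = ok,
                      _["nodes"] = ok ? wrap(P) : R_NilValue,
                      _["link_tangents"] = ok ? wrap(tlink) : R_NilValue);
}

// [[Rcpp::export]]
List cpp_solve_contact(const arma::mat& nodes, const arma::vec& EI,
                       const arma::vec& GJ, const arma::vec& target,
                       const arma::vec& f_init, double s_init = -1,
                       double tol_pos = 0.01, int max_outer = 30,
                       int max_inner = 300, double tol_inner = 1e-10,
                       double s_min = 0.5) {
  Rod rod = build_rod(nodes, EI, GJ);
  arma::vec3 pc_state(arma::fill::zeros);
  arma::vec3 f = {f_init(0), f_init(1), f_init(2)};
  ContactResult r = solve_contact(rod, arma::vec3(target.head(3)), f, s_init,
                                  pc_state, tol_pos, max_outer, max_inner,
                                  tol_inner, s_min);
  return contact_to_list(r, rod);
}

// Continuation solve: walk the target from a point on the undeflected whisker
// out to the requested target along a path in spherical coordinates, warm
// starting force, contact coordinate, and joint state at each step.
// [[Rcpp::export]]
List cpp_deflect_to_point(const arma::mat& nodes, const arma::vec& EI,
                          const arma::vec& GJ, const arma::vec& target,
                          double tol_pos = 0.01, int max_outer = 30,
                          int max_inner = 300, double tol_inner = 1e-10,
                          double s_min = 0.5, int max_steps = 60) {
  Rod rod = build_rod(nodes, EI, GJ);
  arma::vec3 tgt = {target(0), target(1), target(2)};
  int i0 = 0;
  double dbest = arma::datum::inf;
  for (int j = 0; j < rod.N; ++j) {
    double d = arma::norm(rod.P0.row(j).t() - tgt);
    if (d < dbest) { dbest = d; i0 = j; }
  }
  arma::vec3 s_from = sph_of(rod.P0.row(std::max(i0, 2)).t()), s_to = sph_of(tgt);
  double dang = std::max(std::fabs(s_to(1) - s_from(1)),
                         std::fabs(s_to(2) - s_from(2)));
  double dr = std::fabs(s_to(0) - s_from(0));
  int nstep = std::max(1, (int)std::ceil(std::max(dang / (3.0 * M_PI / 180.0),
                                                  dr / 1.0)));
  for (int attempt = 0; attempt < 2; ++attempt) {
    int k = std::min(nstep * (attempt + 1) * (attempt + 1), max_steps);
    arma::vec3 pc_state(arma::fill::zeros);
    arma::vec3 f(arma::fill::zeros);
    double sc = -1;
    ContactResult r;
    int s_fail = -1;
    for (int s = 1; s <= k; ++s) {
      double a = (double)s / k;
      arma::vec3 ss = s_from + a * (s_to - s_from);
      arma::vec3 ts = cart_of(ss);
      r = solve_contact(rod, ts, f, sc, pc_state, tol_pos, max_outer,
                        max_inner, tol_inner, s_min);
      if (!r.converged) { s_fail = s; break; }
      f = r.f;
      sc = r.sc;
    }
    if (s_fail < 0) return contact_to_list(r, rod);
    // failure in the outer third of the path is the slip boundary; a finer
    // path will not help, so report slip without retrying
    if (s_fail > 0.67 * k) break;
  }
  ContactResult bad;
  return contact_to_list(bad, rod);
}

// brute-force k nearest neighbours (small tables; partial selection per query)
// [[Rcpp::export]]
List cpp_knn(const arma::mat& data, const arma::mat& query, int k) {
  int n = data.n_rows, m = query.n_rows, d = data.n_cols;
  k = std::min(k, n);
  arma::imat idx(m, k);
  arma::mat dist(m, k);
  std::vector<std::pair<double, int>> buf(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int j = 0; j < d; ++j) {
        double z = data(i, j) - query(q, j);
        s += z * z;
      }
      buf[i] = {s, i};
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int i = 0; i < k; ++i) {
      idx(q, i) = buf[i].second + 1;
      dist(q, i) = std::sqrt(buf[i].first);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
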