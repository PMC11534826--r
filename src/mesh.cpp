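// Triangulated-surface core: marching-tetrahedra isosurface extraction,
// quadric edge-collapse decimation, and point-to-surface distance.
#include <Rcpp.h>
#include <map>
#include <set>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------- isosurface

// Kuhn 6-tetrahedra decomposition of the unit cube around the body diagonal
// 0-7; face diagonals match between neighbouring cubes, so the global
// triangulation is conforming (crack-free). Cube corner c in 0..7 has offset
// (c&1, (c>>1)&1, (c>>2)&1).
static const int TETS[6][4] = {
  {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}
};

struct EdgeKey {
  long long a, b;
  bool operator<(const EdgeKey& o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// Isosurface of vol at level iso. Returns list(vertices = n x 3 doubles
// (0-based voxel coords), faces = m x 3 1-based vertex indices). Triangles
// are oriented so normals point from values above iso toward values below.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  std::map<EdgeKey, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;

  auto lidx = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
  };
  auto val = [&](long long s) { return v[s]; };
  auto coord = [&](long long s, double* c) {
    c[0] = (double)(s % nx);
    c[1] = (double)((s / nx) % ny);
    c[2] = (double)(s / ((long long)nx * ny));
  };
  auto edge_vert = [&](long long a, long long b) -> int {
    EdgeKey k = (a < b) ? EdgeKey{a, b} : EdgeKey{b, a};
    std::map<EdgeKey, int>::iterator it = edge_vertex.find(k);
    if (it != edge_vertex.end()) return it->second;
    double ca[3], cb[3];
    coord(k.a, ca); coord(k.b, cb);
    double va = val(k.a), vb = val(k.b);
    double t = (va == vb) ? 0.5 : (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    vx.push_back(ca[0] + t * (cb[0] - ca[0]));
    vy.push_back(ca[1] + t * (cb[1] - ca[1]));
    vz.push_back(ca[2] + t * (cb[2] - ca[2]));
    int id = (int)vx.size();  // 1-based
    edge_vertex[k] = id;
    return id;
  };
  auto add_tri = [&](int a, int b, int c, const double* inside_pt) {
    // orient so the normal points away from the inside (above-iso) corner
    double p1[3] = {vx[a-1], vy[a-1], vz[a-1]};
    double p2[3] = {vx[b-1], vy[b-1], vz[b-1]};
    double p3[3] = {vx[c-1], vy[c-1], vz[c-1]};
    double u[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
    double w[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
    double nrm[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
    double d[3] = {p1[0]-inside_pt[0], p1[1]-inside_pt[1], p1[2]-inside_pt[2]};
    if (nrm[0]*d[0] + nrm[1]*d[1] + nrm[2]*d[2] < 0) std::swap(b, c);
    f1.push_back(a); f2.push_back(b); f3.push_back(c);
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        long long corner[8];
        double cval[8];
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = lidx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cval[c] = val(corner[c]);
          if (cval[c] > iso) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (cval[T[c]] > iso) in[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          double ip[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c) {
            double cc[3]; coord(corner[T[in[c]]], cc);
            ip[0] += cc[0] / nin; ip[1] += cc[1] / nin; ip[2] += cc[2] / nin;
          }
          if (nin == 1 || nin == 3) {
            int apex = -1;
            if (nin == 1) apex = in[0];
            else { // single outside corner
              bool isin[4] = {false, false, false, false};
              for (int c = 0; c < nin; ++c) isin[in[c]] = true;
              for (int c = 0; c < 4; ++c) if (!isin[c]) apex = c;
            }
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex)
                e[m++] = edge_vert(corner[T[apex]], corner[T[c]]);
            add_tri(e[0], e[1], e[2], ip);
          } else { // nin == 2: quad across the tet
            int a = in[0], b = in[1];
            bool isin[4] = {false, false, false, false};
            isin[a] = isin[b] = true;
            int out[2], m = 0;
            for (int c = 0; c < 4; ++c) if (!isin[c]) out[m++] = c;
            int e_a0 = edge_vert(corner[T[a]], corner[T[out[0]]]);
            int e_a1 = edge_vert(corner[T[a]], corner[T[out[1]]]);
            int e_b0 = edge_vert(corner[T[b]], corner[T[out[0]]]);
            int e_b1 = edge_vert(corner[T[b]], corner[T[out[1]]]);
            add_tri(e_a0, e_a1, e_b1, ip);
            add_tri(e_a0, e_b1, e_b0, ip);
          }
        }
      }

  int n = (int)vx.size(), m = (int)f1.size();
  NumericMatrix verts(n, 3);
  for (int s = 0; s < n; ++s) {
    verts(s, 0) = vx[s]; verts(s, 1) = vy[s]; verts(s, 2) = vz[s];
  }
  IntegerMatrix faces(m, 3);
  for (int s = 0; s < m; ++s) {
    faces(s, 0) = f1[s]; faces(s, 1) = f2[s]; faces(s, 2) = f3[s];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------- decimation

struct Quadric {
  double q[10]; // symmetric 4x4: order a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0; }
  void add_plane(double a, double b, double c, double d) {
    q[0]+=a*a; q[1]+=a*b; q[2]+=a*c; q[3]+=a*d;
    q[4]+=b*b; q[5]+=b*c; q[6]+=b*d;
    q[7]+=c*c; q[8]+=c*d; q[9]+=d*d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(const double* p) const {
    double x=p[0], y=p[1], z=p[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimize; returns false if the 3x3 system is near-singular
  bool minimize(double* p) const {
    double A[3][3] = {{q[0],q[1],q[2]},{q[1],q[4],q[5]},{q[2],q[5],q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    // Cramer with determinant guard
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    if (std::fabs(det) < 1e-9) return false;
    double inv = 1.0 / det;
    p[0] = inv * (b[0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
                - A[0][1]*(b[1]*A[2][2]-A[1][2]*b[2])
                + A[0][2]*(b[1]*A[2][1]-A[1][1]*b[2]));
    p[1] = inv * (A[0][0]*(b[1]*A[2][2]-A[1][2]*b[2])
                - b[0]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
                + A[0][2]*(A[1][0]*b[2]-b[1]*A[2][0]));
    p[2] = inv * (A[0][0]*(A[1][1]*b[2]-b[1]*A[2][1])
                - A[0][1]*(A[1][0]*b[2]-b[1]*A[2][0])
                + b[0]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]));
    return true;
  }
};

struct Collapse {
  double cost;
  int u, v;        // collapse u into v' replacing both
  int ver_u, ver_v;
  double pos[3];
  bool operator<(const Collapse& o) const { return cost > o.cost; } // min-heap
};

// Quadric edge-collapse decimation to n_target vertices. Collapses are only
// allowed between vertices with identical labels and must satisfy the link
// condition (exactly two common neighbors) to keep the surface manifold.
// Returns list(vertices, faces, labels).
// [[Rcpp::export]]
List cpp_decimate(NumericMatrix verts, IntegerMatrix faces,
                  IntegerVector labels, int n_target) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<double> P(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) P[3 * i + c] = verts(i, c);
  std::vector<int> F(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int c = 0; c < 3; ++c) F[3 * i + c] = faces(i, c) - 1;
  std::vector<int> lab(labels.begin(), labels.end());
  std::vector<bool> vdead(nv, false), fdead(nf, false);
  std::vector<int> ver(nv, 0);
  std::vector<std::set<int> > vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) vfaces[F[3 * f + c]].insert(f);

  std::vector<Quadric> Q(nv);
  auto face_plane = [&](int f, double* pl) -> bool {
    int a = F[3*f], b = F[3*f+1], c = F[3*f+2];
    double u[3], w[3];
    for (int t = 0; t < 3; ++t) {
      u[t] = P[3*b+t] - P[3*a+t];
      w[t] = P[3*c+t] - P[3*a+t];
    }
    double n[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
    double len = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
    if (len < 1e-12) return false;
    for (int t = 0; t < 3; ++t) pl[t] = n[t] / len;
    pl[3] = -(pl[0]*P[3*a] + pl[1]*P[3*a+1] + pl[2]*P[3*a+2]);
    return true;
  };
  for (int f = 0; f < nf; ++f) {
    double pl[4];
    if (!face_plane(f, pl)) continue;
    for (int c = 0; c < 3; ++c)
      Q[F[3*f+c]].add_plane(pl[0], pl[1], pl[2], pl[3]);
  }
  // boundary preservation: edges with a single incident face (the open rims
  // of a cropped section) receive a strong constraint quadric in the plane
  // through the edge perpendicular to the face
  {
    std::map<std::pair<int,int>, std::pair<int,int> > ecount; // edge -> (count, face)
    for (int f = 0; f < nf; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = F[3*f+c], b = F[3*f+(c+1)%3];
        std::pair<int,int> k = a < b ? std::make_pair(a,b) : std::make_pair(b,a);
        std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = ecount.find(k);
        if (it == ecount.end()) ecount[k] = std::make_pair(1, f);
        else it->second.first++;
      }
    for (std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second.first != 1) continue;
      int a = it->first.first, b = it->first.second, f = it->second.second;
      double pl[4];
      if (!face_plane(f, pl)) continue;
      double e[3] = {P[3*b]-P[3*a], P[3*b+1]-P[3*a+1], P[3*b+2]-P[3*a+2]};
      double n[3] = {e[1]*pl[2]-e[2]*pl[1], e[2]*pl[0]-e[0]*pl[2], e[0]*pl[1]-e[1]*pl[0]};
      double len = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
      if (len < 1e-12) continue;
      for (int t = 0; t < 3; ++t) n[t] /= len;
      double dd = -(n[0]*P[3*a] + n[1]*P[3*a+1] + n[2]*P[3*a+2]);
      const double w = 100.0;
      Quadric bq;
      bq.add_plane(n[0]*w, n[1]*w, n[2]*w, dd*w);
      Q[a] = Q[a] + bq;
      Q[b] = Q[b] + bq;
    }
  }

  auto neighbors = [&](int v, std::set<int>& out) {
    out.clear();
    for (std::set<int>::iterator it = vfaces[v].begin(); it != vfaces[v].end(); ++it)
      for (int c = 0; c < 3; ++c) {
        int w = F[3 * (*it) + c];
        if (w != v) out.insert(w);
      }
  };

  std::priority_queue<Collapse> heap;
  auto push_edge = [&](int u, int v) {
    if (u == v || vdead[u] || vdead[v] || lab[u] != lab[v]) return;
    Quadric q = Q[u] + Q[v];
    double p[3];
    if (!q.minimize(p)) {
      for (int t = 0; t < 3; ++t) p[t] = 0.5 * (P[3*u+t] + P[3*v+t]);
    }
    // keep the optimum inside the edge's bounding box (ill-conditioned
    // quadrics can otherwise throw vertices far from the surface)
    for (int t = 0; t < 3; ++t) {
      double lo = std::min(P[3*u+t], P[3*v+t]), hi = std::max(P[3*u+t], P[3*v+t]);
      if (p[t] < lo || p[t] > hi) {
        p[0] = 0.5 * (P[3*u] + P[3*v]);
        p[1] = 0.5 * (P[3*u+1] + P[3*v+1]);
        p[2] = 0.5 * (P[3*u+2] + P[3*v+2]);
        break;
      }
    }
    Collapse c;
    c.cost = q.eval(p);
    c.u = u; c.v = v; c.ver_u = ver[u]; c.ver_v = ver[v];
    c.pos[0] = p[0]; c.pos[1] = p[1]; c.pos[2] = p[2];
    heap.push(c);
  };
  {
    std::set<std::pair<int,int> > seen;
    for (int f = 0; f < nf; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = F[3*f+c], b = F[3*f+(c+1)%3];
        std::pair<int,int> k = a < b ? std::make_pair(a,b) : std::make_pair(b,a);
        if (seen.insert(k).second) push_edge(k.first, k.second);
      }
  }

  int alive = nv;
  std::set<int> nu, nv2, common;
  while (alive > n_target && !heap.empty()) {
    Collapse c = heap.top(); heap.pop();
    if (vdead[c.u] || vdead[c.v]) continue;
    if (ver[c.u] != c.ver_u || ver[c.v] != c.ver_v) continue;
    // link condition
    neighbors(c.u, nu);
    neighbors(c.v, nv2);
    common.clear();
    for (std::set<int>::iterator it = nu.begin(); it != nu.end(); ++it)
      if (nv2.count(*it)) common.insert(*it);
    int shared_faces = 0;
    for (std::set<int>::iterator it = vfaces[c.u].begin(); it != vfaces[c.u].end(); ++it)
      if (vfaces[c.v].count(*it)) ++shared_faces;
    if ((int)common.size() != shared_faces) continue; // would pinch the surface
    if (shared_faces == 0) continue;

    // collapse u into v; v moves to pos
    for (int t = 0; t < 3; ++t) P[3*c.v+t] = c.pos[t];
    Q[c.v] = Q[c.u] + Q[c.v];
    // faces shared by u and v die; faces of u get relinked to v
    std::vector<int> ufaces(vfaces[c.u].begin(), vfaces[c.u].end());
    for (size_t s = 0; s < ufaces.size(); ++s) {
      int f = ufaces[s];
      if (vfaces[c.v].count(f)) {
        fdead[f] = true;
        for (int t = 0; t < 3; ++t) vfaces[F[3*f+t]].erase(f);
      } else {
        for (int t = 0; t < 3; ++t)
          if (F[3*f+t] == c.u) F[3*f+t] = c.v;
        vfaces[c.v].insert(f);
      }
    }
    vfaces[c.u].clear();
    vdead[c.u] = true;
    --alive;
    ++ver[c.v];
    neighbors(c.v, nv2);
    for (std::set<int>::iterator it = nv2.begin(); it != nv2.end(); ++it)
      push_edge(c.v, *it);
  }

  // compact (dropping vertices left without any incident face)
  for (int i = 0; i < nv; ++i)
    if (!vdead[i] && vfaces[i].empty()) vdead[i] = true;
  std::vector<int> remap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nv; ++i) if (!vdead[i]) remap[i] = nvo++;
  NumericMatrix vo(nvo, 3);
  IntegerVector lo(nvo);
  for (int i = 0; i < nv; ++i)
    if (!vdead[i]) {
      for (int c = 0; c < 3; ++c) vo(remap[i], c) = P[3*i+c];
      lo[remap[i]] = lab[i];
    }
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (!fdead[f]) ++nfo;
  IntegerMatrix fo(nfo, 3);
  int t = 0;
  for (int f = 0; f < nf; ++f)
    if (!fdead[f]) {
      for (int c = 0; c < 3; ++c) fo(t, c) = remap[F[3*f+c]] + 1;
      ++t;
    }
  return List::create(_["vertices"] = vo, _["faces"] = fo, _["labels"] = lo);
}

// ------------------------------------------------------- point-mesh distance

static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  // Ericson's closest-point-on-triangle
  double ab[3], ac[3], ap[3];
  for (int t = 0; t < 3; ++t) {
    ab[t] = b[t]-a[t]; ac[t] = c[t]-a[t]; ap[t] = p[t]-a[t];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double best[3];
  if (d1 <= 0 && d2 <= 0) { best[0]=a[0]; best[1]=a[1]; best[2]=a[2]; }
  else {
    double bp[3], cp[3];
    for (int t = 0; t < 3; ++t) { bp[t] = p[t]-b[t]; cp[t] = p[t]-c[t]; }
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d3 >= 0 && d4 <= d3) { best[0]=b[0]; best[1]=b[1]; best[2]=b[2]; }
    else if (d6 >= 0 && d5 <= d6) { best[0]=c[0]; best[1]=c[1]; best[2]=c[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t0 = d1 / (d1 - d3);
        for (int t = 0; t < 3; ++t) best[t] = a[t] + t0*ab[t];
      } else {
        double vb = d5*d2 - d1*d6;
        if (vb <= 0 && d2 >= 0 && d6 <= 0) {
          double t0 = d2 / (d2 - d6);
          for (int t = 0; t < 3; ++t) best[t] = a[t] + t0*ac[t];
        } else {
          double va = d3*d6 - d5*d4;
          if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
            double t0 = (d4-d3) / ((d4-d3) + (d5-d6));
            for (int t = 0; t < 3; ++t) best[t] = b[t] + t0*(c[t]-b[t]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb*denom, w = vc*denom;
            for (int t = 0; t < 3; ++t) best[t] = a[t] + ab[t]*v + ac[t]*w;
          }
        }
      }
    }
  }
  double dx = p[0]-best[0], dy = p[1]-best[1], dz = p[2]-best[2];
  return dx*dx + dy*dy + dz*dz;
}

// Unsigned distance from each point to the triangle mesh, using a uniform
// grid over triangle bounding boxes with ring-expansion search.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  if (nf == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = R_PosInf; hi[c] = R_NegInf; }
  for (int i = 0; i < verts.nrow(); ++i)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], verts(i, c));
      hi[c] = std::max(hi[c], verts(i, c));
    }
  double cell = 0;
  for (int c = 0; c < 3; ++c) cell = std::max(cell, (hi[c]-lo[c]));
  cell = std::max(cell / 48.0, 1e-6);
  int gd[3];
  for (int c = 0; c < 3; ++c)
    gd[c] = std::max(1, (int)std::floor((hi[c]-lo[c]) / cell) + 1);
  std::vector<std::vector<int> > bins((size_t)gd[0]*gd[1]*gd[2]);
  auto bin_of = [&](const double* p, int* g) {
    for (int c = 0; c < 3; ++c) {
      int t = (int)std::floor((p[c]-lo[c]) / cell);
      if (t < 0) t = 0; if (t >= gd[c]) t = gd[c]-1;
      g[c] = t;
    }
  };
  for (int f = 0; f < nf; ++f) {
    double bl[3] = {R_PosInf,R_PosInf,R_PosInf}, bh[3] = {R_NegInf,R_NegInf,R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int vi = faces(f, c) - 1;
      for (int t = 0; t < 3; ++t) {
        bl[t] = std::min(bl[t], verts(vi, t));
        bh[t] = std::max(bh[t], verts(vi, t));
      }
    }
    int g0[3], g1[3];
    bin_of(bl, g0); bin_of(bh, g1);
    for (int k = g0[2]; k <= g1[2]; ++k)
      for (int j = g0[1]; j <= g1[1]; ++j)
        for (int i = g0[0]; i <= g1[0]; ++i)
          bins[(size_t)i + (size_t)gd[0]*((size_t)j + (size_t)gd[1]*k)].push_back(f);
  }
  for (int p = 0; p < np; ++p) {
    double pt[3] = {pts(p,0), pts(p,1), pts(p,2)};
    int g[3];
    bin_of(pt, g);
    double best = R_PosInf;
    int maxr = std::max(gd[0], std::max(gd[1], gd[2]));
    for (int r = 0; r <= maxr; ++r) {
      // once a hit exists, search one extra ring then stop
      bool any = false;
      for (int k = std::max(0,g[2]-r); k <= std::min(gd[2]-1,g[2]+r); ++k)
        for (int j = std::max(0,g[1]-r); j <= std::min(gd[1]-1,g[1]+r); ++j)
          for (int i = std::max(0,g[0]-r); i <= std::min(gd[0]-1,g[0]+r); ++i) {
            if (std::max(std::abs(i-g[0]), std::max(std::abs(j-g[1]), std::abs(k-g[2]))) != r)
              continue;
            const std::vector<int>& bin = bins[(size_t)i + (size_t)gd[0]*((size_t)j + (size_t)gd[1]*k)];
            for (size_t s = 0; s < bin.size(); ++s) {
              int f = bin[s];
              double a[3], b[3], c[3];
              for (int t = 0; t < 3; ++t) {
                a[t] = verts(faces(f,0)-1, t);
                b[t] = verts(faces(f,1)-1, t);
                c[t] = verts(faces(f,2)-1, t);
              }
              double d2 = point_tri_dist2(pt, a, b, c);
              if (d2 < best) best = d2;
              any = true;
            }
          }
      if (best < R_PosInf && (double)(r) * cell > std::sqrt(best) + cell) break;
      (void)any;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
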