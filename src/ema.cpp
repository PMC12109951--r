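#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Elementwise/reduction kernels for the attention module. All arrays are
// [C, P, B] with P = H*W (h fastest). Gates gh [C, H, B] / gw [C, W, B]
// are expanded on the fly instead of materializing [C, P, B] copies.

// [[Rcpp::export]]
List cpp_dir_reduce(NumericVector A, int H, int W) {
  IntegerVector d = A.attr("dim");
  int C = d[0], B = d[2];
  NumericVector rh(Dimension(C, H, B)), rw(Dimension(C, W, B)),
      rs(Dimension(C, B));
  const double* a = REAL(A);
  double* ph = REAL(rh); double* pw = REAL(rw); double* ps = REAL(rs);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* col = a + (((size_t)b * W + w) * H + h) * C;
        double* oh = ph + ((size_t)b * H + h) * C;
        double* ow = pw + ((size_t)b * W + w) * C;
        double* os = ps + (size_t)b * C;
        for (int c = 0; c < C; ++c) {
          double v = col[c];
          oh[c] += v; ow[c] += v; os[c] += v;
        }
      }
  return List::create(_["h"] = rh, _["w"] = rw, _["s"] = rs);
}

// [[Rcpp::export]]
NumericVector cpp_gate_mul(NumericVector Z, NumericVector gh,
                           NumericVector gw, int H, int W) {
  IntegerVector d = Z.attr("dim");
  int C = d[0], B = d[2];
  NumericVector out(Dimension(C, H * W, B));
  const double* z = REAL(Z);
  const double* ph = REAL(gh); const double* pw = REAL(gw);
  double* o = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t off = (((size_t)b * W + w) * H + h) * C;
        const double* vh = ph + ((size_t)b * H + h) * C;
        const double* vw = pw + ((size_t)b * W + w) * C;
        for (int c = 0; c < C; ++c)
          o[off + c] = z[off + c] * vh[c] * vw[c];
      }
  return out;
}

// [[Rcpp::export]]
List cpp_gate_bwd(NumericVector dX1, NumericVector Z, NumericVector gh,
                  NumericVector gw, int H, int W) {
  IntegerVector d = Z.attr("dim");
  int C = d[0], B = d[2];
  NumericVector dZ(Dimension(C, H * W, B));
  NumericVector dgh(Dimension(C, H, B)), dgw(Dimension(C, W, B));
  const double* dx = REAL(dX1); const double* z = REAL(Z);
  const double* ph = REAL(gh); const double* pw = REAL(gw);
  double* pz = REAL(dZ); double* oh = REAL(dgh); double* ow = REAL(dgw);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t off = (((size_t)b * W + w) * H + h) * C;
        size_t ih = ((size_t)b * H + h) * C;
        size_t iw = ((size_t)b * W + w) * C;
        for (int c = 0; c < C; ++c) {
          double g = dx[off + c], zz = z[off + c];
          double vh = ph[ih + c], vw = pw[iw + c];
          pz[off + c] = g * vh * vw;
          oh[ih + c] += g * zz * vw;
          ow[iw + c] += g * zz * vh;
        }
      }
  return List::create(_["dZ"] = dZ, _["dgh"] = dgh, _["dgw"] = dgw);
}

// m[p,b] = sum_c a[c,b] * X[c,p,b]
// [[Rcpp::export]]
NumericMatrix cpp_chan_weight(NumericVector X, NumericMatrix a) {
  IntegerVector d = X.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  NumericMatrix out(P, B);
  const double* x = REAL(X); const double* ap = REAL(a);
  double* o = REAL(out);
  for (int b = 0; b < B; ++b) {
    const double* ab = ap + (size_t)b * C;
    for (int p = 0; p < P; ++p) {
      const double* col = x + ((size_t)b * P + p) * C;
      double acc = 0;
      for (int c = 0; c < C; ++c) acc += ab[c] * col[c];
      o[(size_t)b * P + p] = acc;
    }
  }
  return out;
}

// backward of cpp_chan_weight: dX[c,p,b] = a[c,b]*dm[p,b];
// da[c,b] = sum_p X[c,p,b]*dm[p,b]
// [[Rcpp::export]]
List cpp_chan_weight_bwd(NumericVector X, NumericMatrix a, NumericMatrix dm) {
  IntegerVector d = X.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  NumericVector dX(Dimension(C, P, B));
  NumericMatrix da(C, B);
  const double* x = REAL(X); const double* ap = REAL(a);
  const double* dmp = REAL(dm);
  double* pdx = REAL(dX); double* pda = REAL(da);
  for (int b = 0; b < B; ++b) {
    const double* ab = ap + (size_t)b * C;
    double* dab = pda + (size_t)b * C;
    for (int p = 0; p < P; ++p) {
      double g = dmp[(size_t)b * P + p];
      size_t off = ((size_t)b * P + p) * C;
      for (int c = 0; c < C; ++c) {
        pdx[off + c] = ab[c] * g;
        dab[c] += x[off + c] * g;
      }
    }
  }
  return List::create(_["dX"] = dX, _["da"] = da);
}

// out[c,p,b] = Z[c,p,b] * wv[p,b]
// [[Rcpp::export]]
NumericVector cpp_spatial_gate(NumericVector Z, NumericMatrix wv) {
  IntegerVector d = Z.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  NumericVector out(Dimension(C, P, B));
  const double* z = REAL(Z); const double* w = REAL(wv);
  double* o = REAL(out);
  for (size_t j = 0; j < (size_t)P * B; ++j) {
    double g = w[j];
    for (int c = 0; c < C; ++c) o[j * C + c] = z[j * C + c] * g;
  }
  return out;
}

// dZ[c,p,b] = dO[c,p,b]*wv[p,b]; dwv[p,b] = sum_c dO[c,p,b]*Z[c,p,b]
// [[Rcpp::export]]
List cpp_spatial_gate_bwd(NumericVector dO, NumericVector Z,
                          NumericMatrix wv) {
  IntegerVector d = Z.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  NumericVector dZ(Dimension(C, P, B));
  NumericMatrix dwv(P, B);
  const double* g = REAL(dO); const double* z = REAL(Z);
  const double* w = REAL(wv);
  double* pz = REAL(dZ); double* pw = REAL(dwv);
  for (size_t j = 0; j < (size_t)P * B; ++j) {
    double gv = w[j], acc = 0;
    for (int c = 0; c < C; ++c) {
      pz[j * C + c] = g[j * C + c] * gv;
      acc += g[j * C + c] * z[j * C + c];
    }
    pw[j] = acc;
  }
  return List::create(_["dZ"] = dZ, _["dwv"] = dwv);
}

// add a per-(p,b) rank-one term: dX1[c,p,b] += a[c,b] * s[p,b] (in place on
// a freshly allocated copy passed from R)
// [[Rcpp::export]]
NumericVector cpp_add_outer(NumericVector dX, NumericMatrix a,
                            NumericMatrix s) {
  IntegerVector d = dX.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  NumericVector out = clone(dX);
  double* o = REAL(out);
  const double* ap = REAL(a); const double* sp = REAL(s);
  for (int b = 0; b < B; ++b) {
    const double* ab = ap + (size_t)b * C;
    for (int p = 0; p < P; ++p) {
      double g = sp[(size_t)b * P + p];
      size_t off = ((size_t)b * P + p) * C;
      for (int c = 0; c < C; ++c) o[off + c] += ab[c] * g;
    }
  }
  return out;
}

// out = dZ + ah[c,h,b] + aw[c,w,b] (directional-descriptor gradients
// broadcast back over the map)
// [[Rcpp::export]]
NumericVector cpp_add_dir(NumericVector dZ, NumericVector ah,
                          NumericVector aw, int H, int W) {
  IntegerVector d = dZ.attr("dim");
  int C = d[0], B = d[2];
  NumericVector out = clone(dZ);
  double* o = REAL(out);
  const double* ph = REAL(ah); const double* pw = REAL(aw);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t off = (((size_t)b * W + w) * H + h) * C;
        const double* vh = ph + ((size_t)b * H + h) * C;
        const double* vw = pw + ((size_t)b * W + w) * C;
        for (int c = 0; c < C; ++c) o[off + c] += vh[c] + vw[c];
      }
  return out;
}

// group fold: [C, P, B] with C = Cg*g  ->  [Cg, P, g*B] (groups fastest in
// the folded batch)
// [[Rcpp::export]]
NumericVector cpp_group_fold(NumericVector X, int groups) {
  IntegerVector d = X.attr("dim");
  int C = d[0], P = d[1], B = d[2];
  int Cg = C / groups;
  NumericVector out(Dimension(Cg, P, groups * B));
  const double* x = REAL(X);
  double* o = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int g = 0; g < groups; ++g)
      for (int p = 0; p < P; ++p) {
        const double* src = x + ((size_t)b * P + p) * C + (size_t)g * Cg;
        double* dst = o + (((size_t)(b * groups + g)) * P + p) * Cg;
        for (int c = 0; c < Cg; ++c) dst[c] = src[c];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_group_unfold(NumericVector Z, int groups) {
  IntegerVector d = Z.attr("dim");
  int Cg = d[0], P = d[1], B2 = d[2];
  int B = B2 / groups;
  NumericVector out(Dimension(Cg * groups, P, B));
  const double* z = REAL(Z);
  double* o = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int g = 0; g < groups; ++g)
      for (int p = 0; p < P; ++p) {
        const double* src = z + (((size_t)(b * groups + g)) * P + p) * Cg;
        double* dst = o + ((size_t)b * P + p) * (Cg * groups) +
          (size_t)g * Cg;
        for (int c = 0; c < Cg; ++c) dst[c] = src[c];
      }
  return out;
}
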